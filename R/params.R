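#' Simulation parameters for a loop-extrusion run
#'
#' Bundles the four control parameters of the lattice model of loop-extruding
#' factors (LEFs) -- lattice length `L`, LEF number `N`, head stepping speed
#' `v` and mean residence time `tau` -- together with the model-variant flags.
#' The two derived length scales that govern the collective behaviour are
#' computed on construction: the processivity `lambda = 2 * v * tau` (the mean
#' loop size an isolated LEF extrudes during one residence time) and the mean
#' separation between LEFs `d = L / N`. Their ratio `lambda / d` is the single
#' dimensionless control parameter of the model: `lambda/d << 1` gives a
#' sparse array of isolated loops, `lambda/d >> 1` a dense, gapless array of
#' stacked loops.
#'
#' @param L Integer lattice length in sites. One site corresponds to roughly
#'   one nucleosome plus linker (`bp_per_site`, default 200 bp, about 10 nm of
#'   fiber).
#' @param N Integer number of LEFs. Must satisfy `2 * N <= L` so all heads fit.
#' @param v Head stepping rate, in sites per unit time per unblocked head.
#'   A free LEF therefore grows its loop at rate `2 * v`.
#' @param tau Mean residence time of a LEF on the lattice, in time units.
#'   `Inf` disables turnover.
#' @param mode `"constant_N"` (dissociation is immediately followed by
#'   rebinding elsewhere, so exactly `N` LEFs are bound at all times) or
#'   `"explicit_exchange"` (dissociated LEFs enter a free pool and rebind at
#'   rate `k_on` each, so the bound count fluctuates around
#'   `N * k_on * tau / (1 + k_on * tau)`).
#' @param coupled_heads If `TRUE`, both heads of a LEF halt whenever either
#'   head is blocked (the variant that cannot form a gapless loop array).
#'   Default `FALSE`: each head moves independently.
#' @param activation_rate Per-LEF activation rate for gradual loading. When
#'   positive, all LEFs start inactive and each activates (and binds) at this
#'   rate; `0` means all LEFs are bound at time zero.
#' @param k_on Association rate per free LEF (`explicit_exchange` mode only).
#' @param bp_per_site Genomic scale used when exporting to genomic
#'   coordinates, in base pairs per lattice site.
#' @param seed Integer RNG seed; every stochastic choice in a run derives
#'   from it, making runs exactly reproducible.
#'
#' @return An object of class `sim_params`: a named list with the fields
#'   above plus the derived `lambda`, `d` and `lambda_over_d`.
#' @examples
#' p <- sim_params(L = 2000, N = 200, v = 1, tau = 450, seed = 1)
#' p$lambda_over_d # 90: deep in the dense, gapless regime
#' @export
sim_params <- function(L, N, v = 1, tau, mode = c("constant_N", "explicit_exchange"),
                       coupled_heads = FALSE, activation_rate = 0,
                       k_on = NULL, bp_per_site = 200, seed = NULL) {
  mode <- match.arg(mode)
  L <- as.integer(L)
  N <- as.integer(N)
  stopifnot(
    "L must be an integer >= 2" = length(L) == 1 && !is.na(L) && L >= 2,
    "N must be an integer >= 1" = length(N) == 1 && !is.na(N) && N >= 1,
    "heads must fit on the lattice: 2N <= L" = 2 * N <= L,
    "v must be > 0" = is.numeric(v) && length(v) == 1 && v > 0,
    "tau must be > 0" = is.numeric(tau) && length(tau) == 1 && tau > 0,
    "activation_rate must be >= 0" =
      is.numeric(activation_rate) && activation_rate >= 0,
    "bp_per_site must be > 0" = bp_per_site > 0
  )
  if (mode == "explicit_exchange") {
    stopifnot("k_on must be > 0 in explicit_exchange mode" =
                is.numeric(k_on) && length(k_on) == 1 && k_on > 0)
  } else {
    k_on <- 0
  }
  structure(
    list(
      L = L, N = N, v = as.numeric(v), tau = as.numeric(tau), mode = mode,
      coupled_heads = isTRUE(coupled_heads),
      activation_rate = as.numeric(activation_rate),
      k_on = as.numeric(k_on), bp_per_site = as.numeric(bp_per_site),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      lambda = 2 * v * tau, d = L / N, lambda_over_d = 2 * v * tau / (L / N)
    ),
    class = "sim_params"
  )
}

#' Parameters for a target processivity-to-separation ratio
#'
#' Convenience constructor: picks `tau` so that `lambda / d` equals the
#' requested ratio at the given `L`, `N` and `v`.
#'
#' @param lambda_over_d Target dimensionless ratio `lambda / d`.
#' @param L,N,v,... Passed on to [sim_params()].
#' @return A `sim_params` object with `tau = lambda_over_d * (L / N) / (2 v)`.
#' @examples
#' sim_params_ratio(20, L = 4000, N = 200)$tau
#' @export
sim_params_ratio <- function(lambda_over_d, L, N, v = 1, ...) {
  d <- L / N
  sim_params(L = L, N = N, v = v, tau = lambda_over_d * d / (2 * v), ...)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  lattice L = %d sites, N = %d LEFs (%s%s)\n", x$L, x$N, x$mode,
              if (x$coupled_heads) ", coupled heads" else ""))
  cat(sprintf("  v = %g sites/time, tau = %g time units\n", x$v, x$tau))
  cat(sprintf("  processivity lambda = 2 v tau = %g sites\n", x$lambda))
  cat(sprintf("  separation  d = L / N = %g sites\n", x$d))
  cat(sprintf("  lambda / d = %g (%s regime)\n", x$lambda_over_d,
              regime_label(x$lambda_over_d)))
  if (x$activation_rate > 0)
    cat(sprintf("  gradual activation at rate %g per LEF\n", x$activation_rate))
  if (x$mode == "explicit_exchange")
    cat(sprintf("  k_on = %g per free LEF\n", x$k_on))
  invisible(x)
}

# shared regime thresholds (sparse < 0.5 < transition < 20 < dense)
regime_label <- function(lambda_over_d) {
  ifelse(lambda_over_d < 0.5, "sparse",
         ifelse(lambda_over_d > 20, "dense", "transition"))
}
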