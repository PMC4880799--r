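#' Lambert W function (principal branch)
#'
#' Solves `w * exp(w) = x` for `x >= 0` by Halley iteration to relative
#' tolerance 1e-12. The steady-state loop size of a dense loop array is
#' governed by this function.
#'
#' @param x Non-negative numeric vector.
#' @return `w` with `w * exp(w) == x` to within 1e-12 relative.
#' @examples
#' lambert_w0(exp(1)) # 1
#' @export
lambert_w0 <- function(x) {
  stopifnot("lambert_w0 is defined on x >= 0 (principal branch)" =
              all(x >= 0, na.rm = TRUE))
  w <- ifelse(x < exp(1), x / exp(1), log(x) - log(pmax(log(x), 1)))
  w <- pmax(w, 0)
  for (i in 1:50) {
    ew <- exp(w)
    f <- w * ew - x
    # Halley step: f' = e^w (1 + w), f'' = e^w (2 + w)
    delta <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    w_new <- w - delta
    if (all(abs(w_new - w) <= 1e-13 * pmax(abs(w_new), 1), na.rm = TRUE)) {
      return(w_new)
    }
    w <- w_new
  }
  w
}

#' Predicted mean number of LEFs per loop
#'
#' In the dense steady state each loop is supported by a stack of LEFs whose
#' size is set by the balance of loop death (a stack fluctuating to zero) and
#' loop division (two LEFs landing in one loop): `n = 2 W(3 lambda / (8 d))`,
#' with `W` the Lambert W function.
#'
#' @param lam Processivity `lambda = 2 v tau` (sites or kb).
#' @param d Mean separation between LEFs `d = L / N` (same units).
#' @return Mean stack size `n` (dimensionless).
#' @examples
#' mean_lefs_per_loop(600, 30) # about 3 at lambda/d = 20
#' @export
mean_lefs_per_loop <- function(lam, d) {
  stopifnot(all(lam >= 0), all(d > 0))
  2 * lambert_w0(3 * lam / (8 * d))
}

#' Predicted mean loop length in the dense steady state
#'
#' `mean loop length = 2 d W(3 lambda / (8 d))`; identically
#' `mean_lefs_per_loop(lam, d) * d`, i.e. a gapless array with `n` LEFs per
#' loop spaced `d` apart.
#'
#' @inheritParams mean_lefs_per_loop
#' @return Mean loop length in the units of `lam` and `d`.
#' @examples
#' mean_loop_length(600, 30) # about 90 kb
#' @export
mean_loop_length <- function(lam, d) {
  d * mean_lefs_per_loop(lam, d)
}

#' Predicted mean loop length in the sparse state
#'
#' With rare LEF encounters every loop is grown by a single LEF at rate `2 v`
#' over an exponential residence time `tau`, so the population-average loop
#' size is the processivity `lambda` itself.
#'
#' @param lam Processivity `lambda = 2 v tau`.
#' @return `lam`.
#' @export
sparse_mean_loop_length <- function(lam) {
  stopifnot(all(lam >= 0))
  lam
}

#' Loop death rate (scaling law)
#'
#' A loop dies when its supporting LEF stack fluctuates to zero. The stack is
#' an immigration-death process (arrivals at `(ell/d)/tau`, per-LEF
#' departures at `1/tau`), giving a death rate
#' `R_death = (1/tau) (ell/d) exp(-ell/d)` up to a constant factor. The
#' unit-prefactor form is returned.
#'
#' @param ell Loop size (sites or kb).
#' @param d LEF separation (same units).
#' @param tau LEF residence time.
#' @return Death rate per loop per unit time.
#' @examples
#' rate_loop_death(30, 30, 1) # exp(-1), the maximum over ell
#' @export
rate_loop_death <- function(ell, d, tau) {
  stopifnot(all(ell >= 0), all(d > 0), all(tau > 0))
  (1 / tau) * (ell / d) * exp(-ell / d)
}

#' Loop division rate (scaling law)
#'
#' A loop divides when two LEFs land inside it nearly simultaneously and
#' extrude two consecutive child loops: `R_division = (1/tau) (ell/d)^3
#' (d/lambda)` up to a constant factor. Division grows steeply with loop
#' size while death decays, and the opposing dependences pin the steady-state
#' loop size where the two rates balance.
#'
#' @inheritParams rate_loop_death
#' @param lam Processivity `lambda`.
#' @return Division rate per loop per unit time.
#' @export
rate_loop_division <- function(ell, d, tau, lam) {
  stopifnot(all(ell >= 0), all(d > 0), all(tau > 0), all(lam > 0))
  (1 / tau) * (ell / d)^3 * (d / lam)
}

#' Stationary extinction flux of an immigration-death process
#'
#' For a birth-death chain with constant immigration rate `arrival_rate`
#' (Lambda) and per-individual death rate `death_rate` (mu), the stationary
#' occupancy is Poisson with mean `Lambda/mu`, and the stationary
#' probability flux into the empty state is
#' `mu * (Lambda/mu) * exp(-Lambda/mu)` -- the rate at which the population
#' hits zero. With `Lambda = (ell/d)/tau` and `mu = 1/tau` this is exactly
#' [rate_loop_death()]: the LEF stack under a loop is such a process.
#'
#' @param arrival_rate Immigration rate `Lambda` (> 0).
#' @param death_rate Per-individual death rate `mu` (> 0).
#' @return The stationary flux into state 0.
#' @examples
#' extinction_flux(1, 1) # exp(-1)
#' @export
extinction_flux <- function(arrival_rate, death_rate) {
  stopifnot(all(arrival_rate >= 0), all(death_rate > 0))
  m <- arrival_rate / death_rate
  death_rate * m * exp(-m)
}

#' Infer lambda/d from an observed mean loop size
#'
#' Numerically inverts the dense-state prediction
#' `mean loop length = 2 d W(3 lambda / (8 d))` (monotone in `lambda`) to
#' recover the processivity-to-separation ratio that would produce the
#' observed mean loop size.
#'
#' @param mean_loop Observed mean loop length (> 0).
#' @param d LEF separation, same units.
#' @return The ratio `lambda / d`.
#' @examples
#' infer_lambda_over_d(90, 30) # about 18, i.e. ~20 to one significant figure
#' @export
infer_lambda_over_d <- function(mean_loop, d) {
  stopifnot(
    "mean_loop must be > 0" = is.numeric(mean_loop) && all(mean_loop > 0),
    "d must be > 0" = all(d > 0)
  )
  vapply(mean_loop / d, function(r) {
    # invert n = 2 W(3x/8) at n = r: W(3x/8) = r/2 => 3x/8 = (r/2) e^(r/2)
    8 / 3 * (r / 2) * exp(r / 2)
  }, numeric(1))
}

#' Closed-form steady-state prediction
#'
#' Evaluates the analytical steady state for given `lambda` and `d`: mean
#' loop length, mean LEFs per loop, the regime label (sparse below
#' `lambda/d = 0.5`, dense above 20, transition between -- the thresholds are
#' rough), and the compaction coefficient when a loop-base width is given.
#' In the sparse regime the mean loop length is `lambda`; otherwise the
#' dense-state Lambert-W expression is used.
#'
#' @param lam Processivity `lambda` (kb or sites).
#' @param d LEF separation (same units).
#' @param a_nm Optional loop-base width in nm.
#' @param unit_kb Are `lam` and `d` in kb? (controls the compaction units;
#'   default `TRUE`).
#' @return A one-row tibble: `lambda`, `d`, `lambda_over_d`, `regime`,
#'   `mean_loop_length`, `mean_lefs_per_loop`, and `compaction_kb_per_nm`
#'   when `a_nm` is supplied.
#' @examples
#' predict_steady_state(600, 30, a_nm = 10)
#' @export
predict_steady_state <- function(lam, d, a_nm = NULL, unit_kb = TRUE) {
  stopifnot(all(lam > 0), all(d > 0))
  ratio <- lam / d
  regime <- regime_label(ratio)
  ell <- ifelse(regime == "sparse", sparse_mean_loop_length(lam),
                mean_loop_length(lam, d))
  out <- tibble::tibble(
    lambda = lam, d = d, lambda_over_d = ratio, regime = regime,
    mean_loop_length = ell,
    mean_lefs_per_loop = mean_lefs_per_loop(lam, d)
  )
  if (!is.null(a_nm)) {
    stopifnot(all(a_nm > 0))
    out$compaction_kb_per_nm <- if (unit_kb) ell / a_nm else NA_real_
  }
  out
}

#' Estimate LEF parameters from observed loop sizes
#'
#' Translates measured loop-array properties into the microscopic LEF
#' parameters, the calculation that places human mitotic chromosomes at the
#' lower edge of the dense state: with a mean loop length of 80--120 kb and
#' one condensin per ~30 kb, `lambda/d ~ 20`, so each loop is supported by
#' about 3 LEFs, condensin processivity is about 600 kb, and the linear
#' compaction reached in a gapless array with a 10--20 nm loop base is
#' 4--12 kb/nm.
#'
#' @param mean_loop_kb Observed mean loop length(s) in kb; a range such as
#'   `c(80, 120)` is summarised by its midpoint for the point estimates.
#' @param d_kb Separation between bound LEFs in kb.
#' @param a_nm_range Loop-base width range in nm, e.g. `c(10, 20)`.
#' @return A one-row tibble: `mean_loop_kb` (midpoint), `ell_over_d`,
#'   `lambda_over_d` (raw) and `lambda_over_d_rounded` (one significant
#'   figure), `lambda_kb`, `n_lefs_per_loop` and `n_lefs_per_loop_rounded`,
#'   `regime`, and `compaction_min`/`compaction_max` in kb/nm (smallest loop
#'   over widest base to largest loop over narrowest base).
#' @examples
#' estimate_human_parameters(c(80, 120), d_kb = 30, a_nm_range = c(10, 20))
#' @export
estimate_human_parameters <- function(mean_loop_kb, d_kb = 30,
                                      a_nm_range = c(10, 20)) {
  stopifnot(all(mean_loop_kb > 0), d_kb > 0, all(a_nm_range > 0))
  ell <- mean(range(mean_loop_kb))
  ratio <- infer_lambda_over_d(ell, d_kb)
  ratio_rounded <- signif(ratio, 1)
  nbar <- mean_lefs_per_loop(ratio * d_kb, d_kb)
  c_min <- min(mean_loop_kb) / max(a_nm_range)
  c_max <- max(mean_loop_kb) / min(a_nm_range)
  tibble::tibble(
    mean_loop_kb = ell,
    d_kb = d_kb,
    ell_over_d = ell / d_kb,
    lambda_over_d = ratio,
    lambda_over_d_rounded = ratio_rounded,
    lambda_kb = ratio_rounded * d_kb,
    n_lefs_per_loop = nbar,
    n_lefs_per_loop_rounded = round(nbar),
    regime = regime_label(ratio_rounded),
    compaction_min = c_min,
    compaction_max = c_max
  )
}
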