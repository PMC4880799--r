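#' Place LEFs on an empty lattice
#'
#' Binds each of the `N` LEFs at a uniformly random free adjacent site pair
#' `(i, i + 1)`, left head at `i`, right head at `i + 1` -- the minimal
#' nascent loop. With `activation_rate > 0` (gradual loading) no LEF is
#' placed; they bind one by one as they activate during [simulate_extrusion()].
#'
#' @param params A [sim_params()] object.
#' @return A `lattice_state`: a tibble with one row per LEF and columns
#'   `lef_id`, `left`, `right`, `bound`, `active` (positions are `NA` while
#'   unbound), carrying the lattice length and the time (0) as attributes.
#' @examples
#' p <- sim_params(L = 100, N = 4, tau = 50, seed = 7)
#' lef_initialize(p)
#' @export
lef_initialize <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  st <- cpp_initialize(unclass(params))
  new_lattice_state(st$left, st$right, st$bound, st$active,
                    time = 0, L = params$L)
}

new_lattice_state <- function(left, right, bound, active, time, L) {
  out <- tibble::tibble(
    lef_id = seq_along(left),
    left = ifelse(bound == 1L, left, NA_integer_),
    right = ifelse(bound == 1L, right, NA_integer_),
    bound = bound == 1L,
    active = active == 1L
  )
  attr(out, "time") <- time
  attr(out, "L") <- L
  class(out) <- c("lattice_state", class(out))
  out
}

state_vectors <- function(state) {
  list(
    left = as.integer(ifelse(state$bound, state$left, 0L)),
    right = as.integer(ifelse(state$bound, state$right, 0L)),
    bound = as.integer(state$bound),
    active = as.integer(state$active)
  )
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> t = %g, L = %d sites, %d/%d LEFs bound\n",
              attr(x, "time"), attr(x, "L"), sum(x$bound), nrow(x)))
  NextMethod()
}

#' Event propensities of a lattice state
#'
#' The full Gillespie rate table: each head of a bound LEF steps outward at
#' rate `v` when its destination site is on the lattice and unoccupied
#' (blocked heads and heads at the lattice ends have rate 0; in the
#' coupled-heads variant both heads of a LEF halt when either is blocked);
#' each bound LEF dissociates at rate `1/tau` regardless of blocking; free
#' LEFs bind at rate `k_on` (explicit exchange) and inactive LEFs activate at
#' `activation_rate`.
#'
#' @param state A `lattice_state`.
#' @param params The matching [sim_params()].
#' @return A tibble with columns `lef_id`, `event` (one of `step_left`,
#'   `step_right`, `dissociate`, `rebind`, `activate`) and `rate`, zero-rate
#'   entries dropped; the total propensity is in attribute `"total"`.
#' @examples
#' st <- loop_fixture(list(c(10, 50)), L = 100)
#' p <- sim_params(L = 100, N = 1, v = 1, tau = 10)
#' lef_propensities(st, p) # two moving heads at rate v, dissociation at 1/tau
#' @export
lef_propensities <- function(state, params) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "sim_params"))
  sv <- state_vectors(state)
  m <- cpp_propensities(unclass(params), sv$left, sv$right, sv$bound, sv$active)
  out <- tibble::tibble(
    lef_id = rep(seq_len(nrow(m)), times = ncol(m)),
    event = rep(colnames(m), each = nrow(m)),
    rate = as.vector(m)
  )
  out <- dplyr::arrange(dplyr::filter(out, .data$rate > 0), .data$lef_id)
  attr(out, "total") <- sum(m)
  out
}

#' Advance a lattice state by one Gillespie event
#'
#' Draws an exponential waiting time from the total propensity, selects one
#' event proportionally to its rate, and applies it. Uses the current R RNG
#' stream (call `set.seed()` for reproducibility).
#'
#' @param state A `lattice_state`.
#' @param params The matching [sim_params()].
#' @return A list with the advanced `state` and a one-or-two-row `events`
#'   tibble (`time`, `kind`, `lef_id`, `old_left`, `old_right`, `new_left`,
#'   `new_right`); a constant-N dissociation logs the dissociate and rebind
#'   records at the same instant.
#' @examples
#' p <- sim_params(L = 50, N = 1, tau = 20, seed = 3)
#' st <- lef_initialize(p)
#' lef_step(st, p)$events
#' @export
lef_step <- function(state, params) {
  pr <- lef_propensities(state, params)
  if (attr(pr, "total") <= 0) {
    stop("total propensity is zero: the lattice is fully jammed and no ",
         "exchange or activation can occur")
  }
  sv <- state_vectors(state)
  res <- cpp_run(unclass(params), sv$left, sv$right, sv$bound, sv$active,
                 t0 = attr(state, "time"), t_max = Inf, sample_interval = 0,
                 max_events = 1L, record_events = TRUE)
  list(
    state = new_lattice_state(res$left, res$right, res$bound, res$active,
                              time = res$time, L = params$L),
    events = events_tibble(res$events)
  )
}

event_kinds <- c("step_left", "step_right", "dissociate", "rebind", "activate")

events_tibble <- function(m) {
  tibble::tibble(
    time = m[, "time"],
    kind = event_kinds[m[, "kind"]],
    lef_id = as.integer(m[, "lef_id"]),
    old_left = int_or_na(m[, "old_left"]),
    old_right = int_or_na(m[, "old_right"]),
    new_left = int_or_na(m[, "new_left"]),
    new_right = int_or_na(m[, "new_right"])
  )
}

int_or_na <- function(x) {
  x <- as.integer(x)
  x[x == 0L] <- NA_integer_
  x
}

#' Simulate loop extrusion
#'
#' Runs the continuous-time (Gillespie) dynamics of `N` two-headed LEFs on a
#' lattice of `L` sites: heads step outward at rate `v` unless blocked by a
#' neighbouring head or the lattice end, and each LEF turns over at rate
#' `1/tau`. In `constant_N` mode a dissociated LEF instantly rebinds at a
#' random free adjacent site pair; in `explicit_exchange` mode it joins a free
#' pool and rebinds at rate `k_on`. With `activation_rate > 0` LEFs start
#' inactive and load gradually. The state is recorded every
#' `sample_interval` time units.
#'
#' @param params A [sim_params()] object; `params$seed` (if set) seeds the run.
#' @param t_max Total simulated time, in the same units as `tau`.
#' @param sample_interval Spacing of recorded snapshots; defaults to
#'   `tau / 50`, fine enough that loop death and division events unfolding on
#'   the timescale `tau` are resolved.
#' @param init Optional `lattice_state` to start from (default: fresh random
#'   placement via [lef_initialize()]).
#' @param record_events If `TRUE`, also keep the full event log (one row per
#'   Gillespie event; can be large).
#' @return A `lef_trajectory`: list with `params`, `snapshots` (a tibble with
#'   columns `time`, `lef_id`, `left`, `right`, `bound`, `active`), `events`
#'   (tibble or `NULL`), and `final_state`.
#' @examples
#' p <- sim_params(L = 200, N = 10, v = 1, tau = 30, seed = 1)
#' traj <- simulate_extrusion(p, t_max = 60)
#' traj
#' @export
simulate_extrusion <- function(params, t_max,
                               sample_interval = params$tau / 50,
                               init = NULL, record_events = FALSE) {
  stopifnot(inherits(params, "sim_params"), t_max > 0, sample_interval > 0)
  if (is.null(init)) {
    init <- lef_initialize(params) # seeds the RNG from params$seed
  } else if (!is.null(params$seed)) {
    set.seed(params$seed)
  }
  sv <- state_vectors(init)
  res <- cpp_run(unclass(params), sv$left, sv$right, sv$bound, sv$active,
                 t0 = attr(init, "time"), t_max = attr(init, "time") + t_max,
                 sample_interval = sample_interval, max_events = 0L,
                 record_events = record_events)
  snaps <- res$snapshots
  snapshots <- tibble::tibble(
    time = snaps[, "time"],
    lef_id = as.integer(snaps[, "lef_id"]),
    left = int_or_na(snaps[, "left"]),
    right = int_or_na(snaps[, "right"]),
    bound = snaps[, "bound"] == 1,
    active = snaps[, "active"] == 1
  )
  structure(
    list(
      params = params,
      snapshots = snapshots,
      events = if (record_events) events_tibble(res$events) else NULL,
      final_state = new_lattice_state(res$left, res$right, res$bound,
                                      res$active, time = res$time,
                                      L = params$L)
    ),
    class = "lef_trajectory"
  )
}

#' @export
print.lef_trajectory <- function(x, ...) {
  ts <- unique(x$snapshots$time)
  cat(sprintf(
    "<lef_trajectory> %d snapshots over t = [%g, %g], L = %d, N = %d, lambda/d = %g\n",
    length(ts), min(ts), max(ts), x$params$L, x$params$N,
    x$params$lambda_over_d))
  invisible(x)
}

#' Extract one snapshot of a trajectory as a lattice state
#'
#' @param traj A `lef_trajectory`.
#' @param time Requested time; the nearest recorded snapshot is returned.
#' @return A `lattice_state`.
#' @export
get_snapshot <- function(traj, time) {
  stopifnot(inherits(traj, "lef_trajectory"))
  ts <- unique(traj$snapshots$time)
  t0 <- ts[which.min(abs(ts - time))]
  snap <- traj$snapshots[traj$snapshots$time == t0, ]
  out <- new_lattice_state(
    ifelse(snap$bound, snap$left, 0L), ifelse(snap$bound, snap$right, 0L),
    as.integer(snap$bound), as.integer(snap$active),
    time = t0, L = traj$params$L
  )
  out$lef_id <- snap$lef_id
  out
}
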