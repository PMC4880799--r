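#' Match loops between two consecutive snapshots
#'
#' Pairs top-level loops of two loop tables by the overlap of their extruded
#' interiors (Jaccard index at least 0.5, best partner on each side; spans
#' are compared instead for nascent loops whose interior is under 3 sites)
#' and classifies what happened to the unmatched loops: a loop whose span is
#' now jointly covered (at least 50%) by two or more new loops *divided*; a
#' loop with no such successor *died* (its fiber was absorbed by the
#' neighbours); new loops not accounted for as division children are
#' *births*. Comparing interiors rather than spans means a division fragment
#' holding exactly half the parent scores just below the match threshold, so
#' clean splits register as divisions, not continuations.
#'
#' @param table_t,table_t2 `loop_table`s of two snapshots, earlier first.
#' @param jaccard_min Minimum Jaccard index for a continuation match
#'   (default 0.5).
#' @param division_cover Minimum fraction of the parent span the children
#'   must jointly cover for a division call (default 0.5).
#' @return A list of tibbles: `matches` (`loop_id_t`, `loop_id_t2`,
#'   `jaccard`), `deaths` (`loop_id_t`, `size`), `divisions` (`loop_id_t`,
#'   `size`, `n_children`), `births` (`loop_id_t2`, `size`).
#' @examples
#' a <- extract_loops(loop_fixture(list(c(10, 100)), L = 120))
#' b <- extract_loops(loop_fixture(list(c(10, 55), c(56, 100)), L = 120))
#' match_loops(a, b)$divisions
#' @export
match_loops <- function(table_t, table_t2, jaccard_min = 0.5,
                        division_cover = 0.5) {
  stopifnot(inherits(table_t, "loop_table"), inherits(table_t2, "loop_table"))
  t1 <- attr(table_t, "time")
  t2 <- attr(table_t2, "time")
  if (!is.null(t1) && !is.null(t2) && t2 < t1) {
    stop("snapshots out of order: second table is earlier than the first")
  }
  a <- table_t[table_t$top_level, ]
  b <- table_t2[table_t2$top_level, ]
  ov <- overlap_pairs(a$start, a$end, b$start, b$end)

  # Jaccard on extruded interiors, the same footprint loop sizes use: a
  # division fragment holding half the parent interior then scores just
  # under 1/2 and is not mistaken for the continuing parent. For nascent
  # loops (interior < 3 sites) the interior carries no overlap signal and
  # the full span is compared instead.
  ov$inter_int <- pmax(0L, pmin(a$end[ov$i], b$end[ov$j]) -
                         pmax(a$start[ov$i], b$start[ov$j]) - 1L)
  ov$union_int <- a$size[ov$i] + b$size[ov$j] - ov$inter_int
  nascent <- a$size[ov$i] < 3L | b$size[ov$j] < 3L
  union_span <- (a$end - a$start + 1L)[ov$i] + (b$end - b$start + 1L)[ov$j] -
    ov$inter
  ov$jaccard <- ifelse(nascent, ov$inter / union_span,
                       ifelse(ov$union_int > 0, ov$inter_int / ov$union_int, 0))

  hit <- ov[ov$jaccard >= jaccard_min, , drop = FALSE]
  if (nrow(hit)) {
    # keep each side's best partner so matching stays one-to-one
    hit <- hit[order(-hit$jaccard), , drop = FALSE]
    hit <- hit[!duplicated(hit$i) & !duplicated(hit$j), , drop = FALSE]
  }
  matches <- tibble::tibble(
    loop_id_t = a$loop_id[hit$i], loop_id_t2 = b$loop_id[hit$j],
    jaccard = hit$jaccard
  )

  # loops with no continuation either divided (their old span is now held
  # jointly by two or more fragments carved out of the interior) or died
  # (their fiber was released and is being absorbed by the neighbours)
  un_a <- setdiff(seq_len(nrow(a)), hit$i)
  un_b <- setdiff(seq_len(nrow(b)), hit$j)
  blen <- b$end - b$start + 1
  deaths <- integer(0)
  div_parent <- integer(0)
  div_nchild <- integer(0)
  child_used <- integer(0)
  for (i in un_a) {
    cand <- ov[ov$i == i & ov$j %in% setdiff(un_b, child_used), , drop = FALSE]
    # children must lie mostly (>= 50% of their own span) inside the parent
    if (nrow(cand)) {
      cand <- cand[cand$inter / blen[cand$j] >= 0.5, , drop = FALSE]
    }
    span_a <- a$end[i] - a$start[i] + 1
    if (nrow(cand) >= 2 && sum(cand$inter) >= division_cover * span_a) {
      div_parent <- c(div_parent, i)
      div_nchild <- c(div_nchild, nrow(cand))
      child_used <- c(child_used, cand$j)
    } else {
      deaths <- c(deaths, i)
    }
  }
  births <- setdiff(un_b, child_used)

  list(
    matches = matches,
    deaths = tibble::tibble(loop_id_t = a$loop_id[deaths],
                            size = a$size[deaths]),
    divisions = tibble::tibble(loop_id_t = a$loop_id[div_parent],
                               size = a$size[div_parent],
                               n_children = div_nchild),
    births = tibble::tibble(loop_id_t2 = b$loop_id[births],
                            size = b$size[births])
  )
}

# overlapping pairs of two sorted disjoint interval sets, by linear sweep
overlap_pairs <- function(s1, e1, s2, e2) {
  i <- 1L
  j <- 1L
  n1 <- length(s1)
  n2 <- length(s2)
  ii <- integer(0)
  jj <- integer(0)
  inter <- integer(0)
  while (i <= n1 && j <= n2) {
    ov <- min(e1[i], e2[j]) - max(s1[i], s2[j]) + 1L
    if (ov > 0L) {
      ii <- c(ii, i)
      jj <- c(jj, j)
      inter <- c(inter, ov)
    }
    if (e1[i] < e2[j]) i <- i + 1L else j <- j + 1L
  }
  data.frame(i = ii, j = jj, inter = inter)
}

#' Loop birth, death and division events along a trajectory
#'
#' Tracks top-level loops across consecutive snapshots with [match_loops()]
#' and returns every detected event, stamped with the transition time and
#' the size of the loop involved (the parent for divisions, the vanished
#' loop for deaths, the new loop for births).
#'
#' @param traj A `lef_trajectory` (sampling interval should be well below
#'   `tau` so events are not missed; the default `tau / 50` is).
#' @param t_min Discard transitions before this time (e.g. the steady-state
#'   onset from [detect_steady_state()]). Default 0.
#' @param stack_tolerance Passed to [extract_loops()].
#' @param tables Optional precomputed [trajectory_loops()] list.
#' @return A list: `events` tibble (`time`, `kind` in death / division /
#'   birth, `size`, `n_children`) and `exposure` tibble (`time`, `dt`,
#'   `size` of every top-level loop observed, for rate normalisation).
#' @export
loop_events <- function(traj, t_min = 0, stack_tolerance = 1, tables = NULL) {
  if (is.null(tables)) tables <- trajectory_loops(traj, stack_tolerance)
  times <- vapply(tables, attr, numeric(1), "time")
  keep <- times >= t_min
  tables <- tables[keep]
  times <- times[keep]
  if (length(tables) < 2) {
    stop("need at least two snapshots after t_min to detect events")
  }
  ev <- vector("list", length(tables) - 1)
  ex <- vector("list", length(tables) - 1)
  for (k in seq_len(length(tables) - 1)) {
    m <- match_loops(tables[[k]], tables[[k + 1]])
    dt <- times[k + 1] - times[k]
    ev[[k]] <- dplyr::bind_rows(
      tibble::tibble(time = times[k + 1], kind = "death",
                     size = m$deaths$size, n_children = NA_integer_),
      tibble::tibble(time = times[k + 1], kind = "division",
                     size = m$divisions$size,
                     n_children = m$divisions$n_children),
      tibble::tibble(time = times[k + 1], kind = "birth",
                     size = m$births$size, n_children = NA_integer_)
    )
    top <- tables[[k]][tables[[k]]$top_level, ]
    ex[[k]] <- tibble::tibble(time = times[k], dt = dt, size = top$size)
  }
  list(events = dplyr::bind_rows(ev), exposure = dplyr::bind_rows(ex))
}

#' Estimate loop death and division rates versus loop size
#'
#' Bins the steady-state loops by size in units of the LEF separation `d`
#' and estimates, per bin, the per-loop rates of death and division as
#' event counts divided by the total loop-time observed in the bin, with
#' Poisson counting errors. These are the empirical counterparts of the
#' scaling laws [rate_loop_death()] and [rate_loop_division()].
#'
#' @param traj A `lef_trajectory`.
#' @param t_min Start of the steady-state portion (see
#'   [detect_steady_state()]).
#' @param bin_width Bin width in units of `ell / d` (default 1).
#' @param stack_tolerance,tables Passed to [loop_events()].
#' @return A tibble with one row per (bin, kind): `x` (bin midpoint in
#'   `ell/d`), `kind`, `events`, `exposure` (loop-time), `rate`
#'   (= events/exposure; `NA` where there is no exposure) and `se`
#'   (`sqrt(events)/exposure`).
#' @export
estimate_event_rates <- function(traj, t_min = 0, bin_width = 1,
                                 stack_tolerance = 1, tables = NULL) {
  d <- traj$params$d
  le <- loop_events(traj, t_min = t_min, stack_tolerance = stack_tolerance,
                    tables = tables)
  bin_of <- function(size) floor(size / d / bin_width)
  expo <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(le$exposure, bin = bin_of(.data$size)), .data$bin),
    exposure = sum(.data$dt), .groups = "drop"
  )
  ev <- dplyr::filter(le$events, .data$kind %in% c("death", "division"))
  counts <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(ev, bin = bin_of(.data$size)),
                    .data$bin, .data$kind),
    events = dplyr::n(), .groups = "drop"
  )
  grid <- tidyr::expand_grid(bin = expo$bin, kind = c("death", "division"))
  out <- dplyr::left_join(grid, counts, by = c("bin", "kind"))
  out <- dplyr::left_join(out, expo, by = "bin")
  out$events[is.na(out$events)] <- 0L
  out$x <- (out$bin + 0.5) * bin_width
  out$rate <- ifelse(out$exposure > 0, out$events / out$exposure, NA_real_)
  out$se <- ifelse(out$exposure > 0, sqrt(out$events) / out$exposure,
                   NA_real_)
  res <- dplyr::arrange(
    dplyr::select(out, "x", "kind", "events", "exposure", "rate", "se"),
    .data$kind, .data$x
  )
  attr(res, "d") <- d
  attr(res, "params") <- traj$params
  class(res) <- c("loop_rates", class(res))
  res
}

#' Detect the steady state of a trajectory
#'
#' The compacted state is a true steady state: after a transient, loop-array
#' observables fluctuate around a level independent of the initial
#' condition. This detector computes a sliding-window mean of an observable
#' (default: mean top-level loop size, window `tau`) and reports the first
#' window end after which every later window mean stays within `rel_tol`
#' (relative) of the final-quarter mean.
#'
#' @param traj A `lef_trajectory`.
#' @param observable Column of [trajectory_loop_stats()] to monitor
#'   (default `"mean_loop_size"`), or a precomputed two-column tibble
#'   (`time`, value).
#' @param window Averaging window in time units (default `tau`).
#' @param rel_tol Relative tolerance (default 0.1).
#' @param hold How long (in units of `window`) the windowed mean must remain
#'   continuously inside the tolerance band, counted from the candidate
#'   settling time, for the steady state to be declared (default 3). `Inf`
#'   demands the band hold to the end of the trajectory; for small systems
#'   whose stationary fluctuations sporadically exceed the band that reading
#'   measures the last excursion in the observation horizon -- a quantity
#'   that grows with `t_max` -- rather than the physical transient, so a
#'   finite hold is the default.
#' @param stats Optional precomputed [trajectory_loop_stats()] tibble.
#' @return A one-row tibble: `t_ss` (`NA` when the trajectory never
#'   converges), `converged`, `steady_mean` and `steady_se` (batch-means
#'   standard error over non-overlapping windows after `t_ss`), `window`,
#'   `rel_tol`.
#' @examples
#' p <- sim_params(L = 400, N = 40, tau = 20, seed = 5)
#' traj <- simulate_extrusion(p, t_max = 200)
#' detect_steady_state(traj)
#' @export
detect_steady_state <- function(traj, observable = "mean_loop_size",
                                window = NULL, rel_tol = 0.1, hold = 3,
                                stats = NULL) {
  if (is.null(window)) window <- traj$params$tau
  if (is.data.frame(observable)) {
    ser <- tibble::tibble(time = observable[[1]], y = observable[[2]])
  } else {
    if (is.null(stats)) stats <- trajectory_loop_stats(traj)
    ser <- tibble::tibble(time = stats$time, y = stats[[observable]])
  }
  ser <- ser[order(ser$time), ]
  n <- nrow(ser)
  t0 <- ser$time[1]
  t_end <- ser$time[n]
  if (t_end - t0 < window) {
    stop("trajectory shorter than one averaging window")
  }
  # long-run reference level: the mean over the final half of the run.
  # The reference must be estimated more tightly than the tolerance band it
  # anchors; loop observables decorrelate on the residence time, so a
  # shorter tail (e.g. a final quarter spanning only ~5 tau) leaves several
  # percent of noise in the reference itself.
  target <- mean(ser$y[ser$time >= t0 + 0.5 * (t_end - t0)], na.rm = TRUE)

  # sliding-window means over [t - window, t] at every snapshot with full
  # window coverage (snapshots are equally spaced)
  ends <- which(ser$time >= t0 + window)
  wmean <- vapply(ends, function(k) {
    mean(ser$y[ser$time > ser$time[k] - window - 1e-9 &
                 ser$time <= ser$time[k] + 1e-9])
  }, numeric(1))
  ok <- !is.na(wmean) & abs(wmean - target) <= rel_tol * abs(target)
  t_end_w <- ser$time[ends]
  settled <- vapply(seq_along(ends), function(k) {
    horizon <- t_end_w[k] + hold * window
    all(ok[k:length(ends)][t_end_w[k:length(ends)] <= horizon + 1e-9])
  }, logical(1))
  t_ss <- if (any(settled)) t_end_w[which(settled)[1]] else NA_real_

  if (!is.na(t_ss)) {
    post <- ser[ser$time >= t_ss, ]
    batch <- floor((post$time - t_ss) / window)
    bm <- tapply(post$y, batch, mean, na.rm = TRUE)
    steady_mean <- mean(post$y, na.rm = TRUE)
    steady_se <- if (length(bm) > 1) sd(bm) / sqrt(length(bm)) else NA_real_
  } else {
    steady_mean <- NA_real_
    steady_se <- NA_real_
  }
  tibble::tibble(
    t_ss = t_ss, converged = !is.na(t_ss), steady_mean = steady_mean,
    steady_se = steady_se, window = window, rel_tol = rel_tol
  )
}

#' Steady-state convergence time versus LEF activation rate
#'
#' Instantaneous loading of all LEFs reaches the compacted steady state only
#' after up to ~10 residence times; loading them gradually (each LEF
#' activating at a fixed rate) can reach it much faster, with an optimal
#' activation rate achieving convergence in a fraction of `tau`. This sweep
#' measures the convergence time at each activation rate, plus the
#' instantaneous-loading reference (`activation_rate = Inf`).
#'
#' @param params A [sim_params()] (its `activation_rate` is overridden).
#' @param activation_rates Positive rates to scan; `Inf` means instantaneous
#'   loading.
#' @param t_max Simulated time per run (default `20 * tau`).
#' @param observable,rel_tol,window Passed to [detect_steady_state()];
#'   `"n_loops"` tracks the assembly of the loop array itself and is the
#'   natural observable for loading-schedule comparisons.
#' @param sample_interval Snapshot spacing (default `tau / 50`).
#' @return A tibble with one row per rate: `activation_rate`, `t_ss`,
#'   `t_ss_over_tau`, `converged`, `steady_mean`; the row index of the
#'   fastest converging rate is in attribute `"argmin"`.
#' @export
convergence_time_vs_activation <- function(params, activation_rates,
                                           t_max = 20 * params$tau,
                                           observable = "mean_loop_size",
                                           rel_tol = 0.1, window = NULL,
                                           sample_interval = params$tau / 50) {
  stopifnot(all(activation_rates > 0))
  rows <- purrr::map_dfr(activation_rates, function(r) {
    p <- params
    p$activation_rate <- if (is.finite(r)) r else 0
    ss <- detect_steady_state(
      simulate_extrusion(p, t_max = t_max, sample_interval = sample_interval),
      observable = observable, window = window, rel_tol = rel_tol
    )
    tibble::tibble(activation_rate = r, t_ss = ss$t_ss,
                   t_ss_over_tau = ss$t_ss / params$tau,
                   converged = ss$converged, steady_mean = ss$steady_mean)
  })
  conv <- which(rows$converged)
  attr(rows, "argmin") <- if (length(conv)) {
    conv[which.min(rows$t_ss[conv])]
  } else {
    NA_integer_
  }
  rows
}
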