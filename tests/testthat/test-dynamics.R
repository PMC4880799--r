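fix_tab <- function(spans, L, time = 0) {
  extract_loops(loop_fixture(spans, L = L, time = time))
}

test_that("loop matching classifies continuation, division and death", {
  a <- fix_tab(list(c(10, 100), c(150, 200)), L = 250)
  # identical tables: identity matching, no events
  m <- match_loops(a, fix_tab(list(c(10, 100), c(150, 200)), L = 250, 1))
  expect_equal(nrow(m$matches), 2)
  expect_equal(nrow(m$deaths) + nrow(m$divisions) + nrow(m$births), 0)

  # a span taken over by two interior loops is a division
  b <- fix_tab(list(c(10, 55), c(56, 100), c(150, 200)), L = 250, 1)
  m <- match_loops(a, b)
  expect_equal(nrow(m$divisions), 1)
  expect_equal(m$divisions$n_children, 2)
  expect_equal(nrow(m$births), 0)

  # a vanished span with only neighbour encroachment is a death; the
  # neighbours that absorbed its fiber still match their own past
  a2 <- fix_tab(list(c(1, 15), c(16, 30), c(31, 45)), L = 50)
  b2 <- fix_tab(list(c(1, 22), c(23, 45)), L = 50, 1)
  m <- match_loops(a2, b2)
  expect_equal(m$deaths$size, 13)
  expect_equal(nrow(m$matches), 2)
  expect_equal(nrow(m$births), 0)

  # new unmatched loops are births
  m <- match_loops(fix_tab(list(c(10, 30)), L = 100),
                   fix_tab(list(c(10, 30), c(60, 90)), L = 100, 1))
  expect_equal(m$births$size, 29)

  expect_error(
    match_loops(fix_tab(list(c(1, 5)), L = 10, time = 2),
                fix_tab(list(c(1, 5)), L = 10, time = 1)),
    "out of order"
  )
})

test_that("event counts balance the loop ledger between snapshots", {
  p <- sim_params_ratio(10, L = 2000, N = 100, seed = 41)
  traj <- simulate_extrusion(p, t_max = 20 * p$tau,
                             sample_interval = p$tau / 50)
  tabs <- trajectory_loops(traj)
  for (k in seq(100, length(tabs) - 1, by = 7)) {
    m <- match_loops(tabs[[k]], tabs[[k + 1]])
    n_t <- sum(tabs[[k]]$top_level)
    n_t2 <- sum(tabs[[k + 1]]$top_level)
    extra_children <- sum(m$divisions$n_children - 1)
    expect_equal(
      n_t - nrow(m$deaths) - nrow(m$divisions) + nrow(m$births) +
        nrow(m$divisions) + extra_children,
      n_t2
    )
  }
})

test_that("a frozen trajectory yields zero event rates", {
  p <- sim_params(L = 200, N = 4, v = 1, tau = 1e12, seed = 2)
  st <- loop_fixture(list(c(10, 60), c(80, 130), c(140, 170), c(171, 190)),
                     L = 200)
  # tau astronomically large and all heads blocked or slow: sample a short
  # window so no event falls between snapshots
  traj <- simulate_extrusion(p, t_max = 0.5, sample_interval = 0.05,
                             init = st)
  r <- estimate_event_rates(traj)
  expect_true(all(r$events == 0))
  expect_true(all(r$rate[!is.na(r$rate)] == 0))
})

test_that("death decays and division grows with loop size around a stable point", {
  p <- sim_params_ratio(15, L = 3000, N = 150, seed = 43)
  traj <- simulate_extrusion(p, t_max = 30 * p$tau,
                             sample_interval = p$tau / 50)
  r <- estimate_event_rates(traj, t_min = 10 * p$tau)
  death <- r[r$kind == "death" & r$events > 0, ]
  div <- r[r$kind == "division" & r$events > 0, ]
  expect_gt(nrow(death), 2)
  expect_gt(nrow(div), 1)
  # negative feedback: small loops die more than they divide, large loops
  # divide more than they die
  lo <- r[r$x == 0.5 | r$x == 1.5, ]
  expect_gt(sum(lo$rate[lo$kind == "death"], na.rm = TRUE),
            sum(lo$rate[lo$kind == "division"], na.rm = TRUE))
  hi_x <- max(div$x)
  hi <- r[r$x == hi_x, ]
  expect_gt(hi$rate[hi$kind == "division"],
            ifelse(is.na(hi$rate[hi$kind == "death"]), 0,
                   hi$rate[hi$kind == "death"]))
  # death rate decreases overall with loop size
  expect_gt(death$rate[1], death$rate[nrow(death)])
})

test_that("steady-state detection finds the settling time", {
  # constant observable: converged at the first full window
  obs <- tibble::tibble(time = seq(0, 100, by = 5), y = 7)
  p <- sim_params(L = 100, N = 2, tau = 10, seed = 1)
  traj <- structure(list(params = p, snapshots = NULL), class = "lef_trajectory")
  ss <- detect_steady_state(traj, observable = obs, window = 20)
  expect_true(ss$converged)
  expect_equal(ss$t_ss, 20)
  expect_equal(ss$steady_mean, 7)

  # an observable still accelerating at the end never converges
  obs$y <- 2^(obs$time / 5)
  ss <- detect_steady_state(traj, observable = obs, window = 20)
  expect_false(ss$converged)
  expect_true(is.na(ss$t_ss))
})

test_that("steady state is independent of the initial condition", {
  p <- sim_params_ratio(30, L = 4000, N = 200, seed = 31)
  a <- simulate_extrusion(p, t_max = 25 * p$tau, sample_interval = p$tau / 10)
  pg <- p
  pg$activation_rate <- 2 / p$tau
  pg$seed <- 32
  b <- simulate_extrusion(pg, t_max = 25 * p$tau, sample_interval = p$tau / 10)
  sa <- detect_steady_state(a)
  sb <- detect_steady_state(b)
  expect_true(sa$converged && sb$converged)
  expect_lt(abs(sa$steady_mean - sb$steady_mean),
            2 * sqrt(sa$steady_se^2 + sb$steady_se^2))
})

test_that("rate estimates are stable under halving the sampling interval", {
  p <- sim_params_ratio(10, L = 2000, N = 100, seed = 47)
  traj <- simulate_extrusion(p, t_max = 25 * p$tau,
                             sample_interval = p$tau / 100)
  r_fine <- estimate_event_rates(traj, t_min = 10 * p$tau)
  coarse <- traj
  keep <- unique(coarse$snapshots$time)[c(TRUE, FALSE)]
  coarse$snapshots <- coarse$snapshots[coarse$snapshots$time %in% keep, ]
  r_coarse <- estimate_event_rates(coarse, t_min = 10 * p$tau)
  # total death rate agrees within combined Poisson error
  tot <- function(r, kind) {
    rr <- r[r$kind == kind & !is.na(r$rate), ]
    c(sum(rr$events) / sum(rr$exposure),
      sqrt(sum(rr$events)) / sum(rr$exposure))
  }
  for (kind in c("death", "division")) {
    a <- tot(r_fine, kind)
    b <- tot(r_coarse, kind)
    expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2) + 1e-9)
  }
})

test_that("gradual activation can reach the steady loop array faster", {
  p <- sim_params_ratio(90, L = 2000, N = 200, seed = 7) # tau = 450
  rates <- c(0.5, 1, 2, 4, 8) / p$tau
  res <- convergence_time_vs_activation(
    p, c(rates, Inf), t_max = 15 * p$tau, observable = "n_loops",
    window = p$tau / 4
  )
  inst <- res$t_ss[is.infinite(res$activation_rate)]
  best <- min(res$t_ss[is.finite(res$activation_rate)], na.rm = TRUE)
  expect_true(res$converged[is.infinite(res$activation_rate)])
  expect_lt(best, inst)
  expect_false(is.na(attr(res, "argmin")))
})
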