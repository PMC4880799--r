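test_that("initialization binds each LEF at an adjacent free site pair", {
  p <- sim_params(L = 100, N = 1, tau = 10, seed = 5)
  st <- lef_initialize(p)
  expect_equal(st$right, st$left + 1L)
  expect_true(st$left >= 1 && st$right <= 100)

  # full occupancy: two LEFs on four sites
  p <- sim_params(L = 4, N = 2, tau = 10, seed = 1)
  st <- lef_initialize(p)
  expect_setequal(c(st$left, st$right), 1:4)
})

test_that("initialization and runs are reproducible from the seed", {
  p <- sim_params(L = 2000, N = 200, tau = 50, seed = 123)
  expect_identical(lef_initialize(p), lef_initialize(p))

  a <- simulate_extrusion(p, t_max = 100, sample_interval = 10,
                          record_events = TRUE)
  b <- simulate_extrusion(p, t_max = 100, sample_interval = 10,
                          record_events = TRUE)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$events, b$events)
})

test_that("placement failure on a near-full lattice names the density", {
  # at full occupancy a mid-lattice first placement strands the end sites
  p <- sim_params(L = 4, N = 2, tau = 10, seed = 4)
  expect_error(lef_initialize(p), "no free adjacent pair.*density")
})

test_that("propensities implement blocking, turnover and the coupled variant", {
  p <- sim_params(L = 100, N = 1, v = 2, tau = 10)
  st <- loop_fixture(list(c(40, 60)), L = 100)
  pr <- lef_propensities(st, p)
  expect_equal(attr(pr, "total"), 2 * 2 + 1 / 10)
  expect_setequal(pr$event, c("step_left", "step_right", "dissociate"))

  # facing heads block each other; outer heads keep moving
  p2 <- sim_params(L = 100, N = 2, v = 1, tau = 10)
  st2 <- loop_fixture(list(c(10, 50), c(51, 80)), L = 100)
  pr2 <- lef_propensities(st2, p2)
  moves <- pr2[grepl("step", pr2$event), ]
  expect_equal(nrow(moves), 2) # only the two outer heads
  expect_equal(attr(pr2, "total"), 2 * 1 + 2 / 10)

  # lattice ends block like occupied sites
  st3 <- loop_fixture(list(c(1, 5)), L = 100)
  pr3 <- lef_propensities(st3, p)
  expect_false("step_left" %in% pr3$event)

  # coupled heads: one blocked head halts both
  p4 <- sim_params(L = 100, N = 1, v = 1, tau = 10, coupled_heads = TRUE)
  pr4 <- lef_propensities(st3, p4)
  expect_false(any(grepl("step", pr4$event)))
  expect_equal(attr(pr4, "total"), 1 / 10)
})

test_that("a fully jammed lattice with no exchange signals instead of hanging", {
  p <- sim_params(L = 2, N = 1, tau = Inf)
  st <- loop_fixture(list(c(1, 2)), L = 2)
  expect_error(lef_step(st, p), "jammed")
})

test_that("single events preserve invariants and constant-N rebinding is immediate", {
  p <- sim_params(L = 30, N = 3, v = 1, tau = 0.5, seed = 77)
  st <- lef_initialize(p)
  set.seed(99)
  for (i in 1:60) {
    out <- lef_step(st, p)
    st <- out$state
    expect_valid_state(st, p)
  }
  # at tau = 0.5 most events are turnover: dissociation is always paired
  # with a same-instant rebind
  set.seed(42)
  ev <- list()
  for (i in 1:80) {
    out <- lef_step(st, p)
    st <- out$state
    ev[[i]] <- out$events
  }
  ev <- do.call(rbind, ev)
  diss <- ev[ev$kind == "dissociate", ]
  reb <- ev[ev$kind == "rebind", ]
  expect_gt(nrow(diss), 0)
  expect_equal(nrow(diss), nrow(reb))
  expect_equal(diss$time, reb$time)
  expect_equal(reb$new_right, reb$new_left + 1L)
})

test_that("an isolated LEF extrudes at rate 2v", {
  # no turnover: E[loop size at t] = 2 v t well before boundary contact
  t_end <- 40
  sizes <- vapply(1:150, function(s) {
    p <- sim_params(L = 5000, N = 1, v = 1, tau = Inf, seed = 3000 + s)
    tr <- simulate_extrusion(p, t_max = t_end, sample_interval = t_end)
    fs <- tr$final_state
    as.numeric(fs$right - fs$left - 1L)
  }, numeric(1))
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 2 * t_end), 3 * se)
})

test_that("every snapshot of a run satisfies the occupancy invariants", {
  p <- sim_params(L = 500, N = 50, v = 1, tau = 20, seed = 11)
  traj <- simulate_extrusion(p, t_max = 100, sample_interval = 5)
  for (s in snapshot_states(traj)) {
    b <- s[s$bound, ]
    expect_equal(nrow(b), 50) # constant-N conservation
    expect_true(all(b$left < b$right))
    expect_equal(anyDuplicated(c(b$left, b$right)), 0L)
  }
})

test_that("explicit exchange balances binding and unbinding", {
  # k_on = 1/tau: two-state occupancy gives half the LEFs bound on average
  p <- sim_params(L = 4000, N = 200, tau = 50, mode = "explicit_exchange",
                  k_on = 1 / 50, seed = 21)
  traj <- simulate_extrusion(p, t_max = 1000, sample_interval = 5)
  nb <- tapply(traj$snapshots$bound, traj$snapshots$time, sum)
  nb <- nb[-(1:50)] # discard loading transient
  se <- sd(nb) / sqrt(length(nb) / 10) # ~tau-correlated batches
  expect_lt(abs(mean(nb) - 100), 4 * max(se, 1))
})

test_that("fast exchange approaches the constant-N loop coverage", {
  covs <- vapply(c(1e3, NA), function(k_on) {
    p <- if (is.na(k_on)) {
      sim_params(L = 1000, N = 100, tau = 50, seed = 5)
    } else {
      sim_params(L = 1000, N = 100, tau = 50, mode = "explicit_exchange",
                 k_on = k_on / 50, seed = 5)
    }
    traj <- simulate_extrusion(p, t_max = 16 * 50, sample_interval = 25)
    st <- trajectory_loop_stats(traj)
    mean(st$coverage[st$time >= 12 * 50])
  }, numeric(1))
  expect_lt(abs(covs[1] - covs[2]), 0.05)
})
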