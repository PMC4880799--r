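# shared checks on engine states

expect_valid_state <- function(state, params) {
  b <- state[state$bound, ]
  expect_true(all(b$left >= 1 & b$right <= params$L))
  expect_true(all(b$left < b$right))
  expect_equal(anyDuplicated(c(b$left, b$right)), 0L)
  if (params$mode == "constant_N" && params$activation_rate == 0) {
    expect_equal(nrow(b), params$N)
  }
}

# per-snapshot state list of a trajectory
snapshot_states <- function(traj) {
  snaps <- traj$snapshots
  lapply(split(snaps, factor(snaps$time, levels = unique(snaps$time))),
         function(s) s)
}
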