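test_that("fixtures accept nested and disjoint spans, reject crossings", {
  st <- loop_fixture(list(c(10, 50), c(11, 49)), L = 100)
  expect_equal(sum(st$bound), 2)
  expect_error(loop_fixture(list(c(10, 50), c(40, 60)), L = 100), "crossing")
  expect_error(loop_fixture(list(c(10, 50), c(50, 60)), L = 100), "distinct")
  empty <- loop_fixture(list(), L = 10)
  expect_equal(nrow(empty), 0)
})

test_that("nesting forest assigns the smallest strictly containing parent", {
  st <- loop_fixture(list(c(10, 50), c(11, 49)), L = 100)
  f <- build_nesting_forest(st)
  expect_equal(f$parent_lef_id, c(NA, f$lef_id[1]))

  st <- loop_fixture(list(c(10, 50), c(60, 80)), L = 100)
  f <- build_nesting_forest(st)
  expect_true(all(is.na(f$parent_lef_id))) # two roots

  st <- loop_fixture(list(c(10, 100), c(11, 40), c(45, 99)), L = 120)
  f <- build_nesting_forest(st)
  expect_equal(f$parent_lef_id[-1], rep(f$lef_id[1], 2))
  expect_equal(f$depth, c(0L, 1L, 1L))
})

test_that("stack chains, branching and nested loops are classified", {
  # a reinforcing LEF one site inside each head is stacked
  tab <- extract_loops(loop_fixture(list(c(10, 50), c(11, 49)), L = 100))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_lefs, 2)
  expect_false(tab$branched)
  expect_equal(tab$size, 39)

  # two disjoint non-stacked children: the transient division state
  tab <- extract_loops(loop_fixture(list(c(10, 100), c(11, 40), c(45, 99)),
                                    L = 120))
  top <- tab[tab$top_level, ]
  expect_equal(nrow(top), 1)
  expect_equal(top$n_lefs, 1)
  expect_equal(top$n_lefs_total, 3)
  expect_true(top$branched)
  expect_equal(sum(!tab$top_level), 2) # children are nested loops
  expect_equal(tab$parent_loop_id[!tab$top_level], rep(top$loop_id, 2))

  # a single LEF is an unbranched loop of its own
  tab <- extract_loops(loop_fixture(list(c(5, 9)), L = 20))
  expect_equal(tab$n_lefs, 1)
  expect_false(tab$branched)
  expect_equal(tab$size, 3)

  # one nested re-extruding LEF does not make the loop branched
  tab <- extract_loops(loop_fixture(list(c(10, 50), c(20, 30)), L = 100))
  expect_false(tab$branched[tab$top_level])
})

test_that("stack tolerance widens the stacking window", {
  spans <- list(c(10, 50), c(12, 48))
  expect_equal(extract_loops(loop_fixture(spans, L = 100))$n_lefs[1], 1)
  expect_equal(
    extract_loops(loop_fixture(spans, L = 100), stack_tolerance = 2)$n_lefs[1],
    2
  )
})

test_that("loop statistics and the compaction coefficient", {
  # 80 of 100 interior sites inside two loops
  st <- loop_fixture(list(c(1, 42), c(43, 84)), L = 100)
  ls <- loop_stats(extract_loops(st))
  expect_equal(ls$coverage, 0.8)
  expect_equal(ls$mean_loop_size, 40)
  expect_equal(ls$gap_fraction, 0.16)

  # 600 sites at 200 bp/site = 120 kb; base a = 10 nm -> 12 kb/nm
  st <- loop_fixture(list(c(1, 602)), L = 700)
  ls <- loop_stats(extract_loops(st), a_nm = 10, bp_per_site = 200)
  expect_equal(ls$compaction_kb_per_nm, 12)
  # 400 sites = 80 kb over a 20 nm base -> 4 kb/nm
  st <- loop_fixture(list(c(1, 402)), L = 500)
  ls <- loop_stats(extract_loops(st), a_nm = 20, bp_per_site = 200)
  expect_equal(ls$compaction_kb_per_nm, 4)

  # empty state: coverage zero, means absent rather than zero
  ls <- loop_stats(extract_loops(loop_fixture(list(), L = 50)))
  expect_equal(ls$coverage, 0)
  expect_true(is.na(ls$mean_loop_size))
  expect_equal(ls$gap_fraction, 1)
})

test_that("accounting identity and loop ordering hold on simulated states", {
  p <- sim_params(L = 1000, N = 80, v = 1, tau = 40, seed = 17)
  traj <- simulate_extrusion(p, t_max = 300, sample_interval = 20)
  for (tab in trajectory_loops(traj)) {
    top <- tab[tab$top_level, ]
    gaps <- attr(tab, "gaps")
    # extruded interior + gaps + 2 head sites per top-level loop = L
    expect_equal(sum(top$size) + sum(gaps) + 2 * nrow(top), p$L)
    # top-level loops are disjoint and genomically ordered
    expect_true(all(diff(top$start) > 0))
    expect_true(all(top$start[-1] > top$end[-nrow(top)]))
  }
})

test_that("dense arrays are gapless and satisfy the loop-spacing identity", {
  p <- sim_params_ratio(30, L = 3000, N = 150, seed = 23)
  traj <- simulate_extrusion(p, t_max = 16 * p$tau, sample_interval = p$tau / 2)
  st <- trajectory_loop_stats(traj)
  st <- st[st$time >= 12 * p$tau, ]
  expect_gt(mean(st$coverage), 0.95)
  expect_lt(mean(st$gap_fraction), 0.05)
  # with no gaps, mean loop length ~ (LEFs per loop) x (LEF separation)
  expect_lt(
    abs(mean(st$mean_loop_size) - mean(st$mean_lefs_per_loop) * p$d) /
      (mean(st$mean_lefs_per_loop) * p$d),
    0.15
  )
})

test_that("sparse-state loops are single-LEF and unbranched", {
  p <- sim_params_ratio(0.1, L = 8000, N = 40, seed = 29)
  traj <- simulate_extrusion(p, t_max = 20 * p$tau, sample_interval = p$tau)
  st <- trajectory_loop_stats(traj)
  st <- st[st$time >= 5 * p$tau, ]
  expect_lt(mean(st$branched_fraction), 0.1)
  expect_lt(mean(st$mean_stack_size), 1.1)
})
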