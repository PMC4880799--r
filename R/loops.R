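#' Build a lattice state from explicit loop spans
#'
#' Constructs a `lattice_state` with bound LEFs at exactly the given head
#' positions -- the standard way to build small deterministic configurations
#' for testing the loop-array analysis.
#'
#' @param spans A list of `c(left, right)` pairs, or a two-column matrix /
#'   data frame of head positions (1-based inclusive sites).
#' @param L Lattice length; defaults to `max(right) + 1`.
#' @param time Time stamp for the state (default 0).
#' @return A `lattice_state`.
#' @examples
#' loop_fixture(list(c(10, 50), c(11, 49)), L = 100)
#' @export
loop_fixture <- function(spans, L = NULL, time = 0) {
  if (is.data.frame(spans)) spans <- as.matrix(spans[, 1:2])
  if (is.list(spans)) {
    spans <- if (length(spans) == 0) {
      matrix(integer(), ncol = 2)
    } else {
      do.call(rbind, spans)
    }
  }
  stopifnot(is.matrix(spans), ncol(spans) == 2)
  left <- as.integer(spans[, 1])
  right <- as.integer(spans[, 2])
  if (is.null(L)) L <- if (length(right)) max(right) + 1L else 2L
  stopifnot(
    "left head must be left of right head" = all(left < right),
    "sites must be within [1, L]" = all(left >= 1) && all(right <= L),
    "all head sites must be distinct" =
      anyDuplicated(c(left, right)) == 0
  )
  if (length(left)) {
    ord <- order(left)
    cpp_nesting_parents(left[ord], right[ord]) # errors on crossing spans
  }
  n <- length(left)
  new_lattice_state(left, right, rep(1L, n), rep(1L, n), time = time, L = L)
}

#' Nesting forest of the bound LEFs
#'
#' Because heads only move apart and block on contact, the intervals spanned
#' by LEFs are always properly nested or disjoint. Each LEF is assigned a
#' parent: the smallest-span LEF strictly containing it, or none for
#' top-level LEFs. Crossing (partially overlapping) intervals raise an error
#' -- they cannot arise from the dynamics and indicate a corrupt state.
#'
#' @param state A `lattice_state`.
#' @return A tibble ordered by `left` with columns `lef_id`, `left`, `right`,
#'   `parent_lef_id` (`NA` for roots) and `depth` (roots have depth 0).
#' @examples
#' st <- loop_fixture(list(c(10, 100), c(11, 40), c(45, 99)))
#' build_nesting_forest(st)
#' @export
build_nesting_forest <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  b <- state[state$bound, ]
  if (nrow(b) == 0) {
    return(tibble::tibble(lef_id = integer(), left = integer(),
                          right = integer(), parent_lef_id = integer(),
                          depth = integer()))
  }
  ord <- order(b$left)
  b <- b[ord, ]
  parent <- cpp_nesting_parents(b$left, b$right)
  depth <- integer(nrow(b))
  for (i in seq_len(nrow(b))) {
    depth[i] <- if (parent[i] == 0L) 0L else depth[parent[i]] + 1L
  }
  parent_lef_id <- rep(NA_integer_, nrow(b))
  parent_lef_id[parent > 0L] <- b$lef_id[parent[parent > 0L]]
  tibble::tibble(
    lef_id = b$lef_id, left = b$left, right = b$right,
    parent_lef_id = parent_lef_id,
    depth = depth
  )
}

#' Reconstruct the loop array of a lattice state
#'
#' Groups the bound LEFs into loops. A LEF is *stacked* on its parent when
#' both of its heads sit within `stack_tolerance` sites of the corresponding
#' parent heads -- the configuration produced by loop reinforcement, where a
#' newly bound LEF re-extrudes an existing loop until it is blocked at the
#' loop base. A loop is a maximal stack chain; its span is the outermost
#' member's head positions and `n_lefs` is the chain length. A LEF that is
#' *not* stacked on its parent starts a nested child loop (reinforcement in
#' progress, or the transient state just after a loop divides). A loop is
#' *branched* when the innermost member of its stack carries two or more
#' such child loops.
#'
#' @param state A `lattice_state` (or a forest from
#'   [build_nesting_forest()]).
#' @param stack_tolerance Maximum head-to-head distance (sites) for a LEF to
#'   count as stacked on its parent. The default 1 is the distance at which
#'   blocking halts a re-extruding head.
#' @return A `loop_table`: tibble with one row per loop -- `loop_id`,
#'   `start`, `end` (head sites of the outermost LEF), `size` (extruded
#'   interior sites, `end - start - 1`), `n_lefs` (stack-chain length),
#'   `n_lefs_total` (every LEF within the loop, including nested ones),
#'   `branched`, `n_children`,
#'   `parent_loop_id` (`NA` for top-level loops) and `top_level`. Attributes:
#'   `gaps` (lengths of the uncovered intervals between top-level loops and
#'   at the lattice ends), `L`, `time`.
#' @examples
#' st <- loop_fixture(list(c(10, 50), c(11, 49), c(60, 80)), L = 100)
#' extract_loops(st)
#' @export
extract_loops <- function(state, stack_tolerance = 1) {
  stopifnot(stack_tolerance >= 1)
  forest <- build_nesting_forest(state)
  L <- attr(state, "L")
  time <- attr(state, "time")
  n <- nrow(forest)
  if (n == 0) {
    out <- tibble::tibble(
      loop_id = integer(), start = integer(), end = integer(),
      size = integer(), n_lefs = integer(), n_lefs_total = integer(),
      branched = logical(), n_children = integer(),
      parent_loop_id = integer(), top_level = logical()
    )
    return(new_loop_table(out, gaps = L, L = L, time = time))
  }

  # parent index in row order of the (left-sorted) forest
  pidx <- match(forest$parent_lef_id, forest$lef_id)
  stacked <- !is.na(pidx) &
    (forest$left - forest$left[pidx]) <= stack_tolerance &
    (forest$right[pidx] - forest$right) <= stack_tolerance

  # chain id: each non-stacked LEF roots a loop; stacked LEFs inherit the
  # chain of their parent (parents precede children in left order)
  chain <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (stacked[i]) {
      chain[i] <- chain[pidx[i]]
    } else {
      next_id <- next_id + 1L
      chain[i] <- next_id
    }
  }

  root <- which(!stacked)                      # row index of each chain root
  innermost <- vapply(seq_len(next_id), function(k) max(which(chain == k)),
                      integer(1))
  n_lefs <- tabulate(chain, nbins = next_id)

  # child loops: chains whose root LEF has a parent; attribute each to the
  # parent's chain, flagging whether it hangs off the innermost stack member
  root_parent <- pidx[root]                    # NA for top-level chains
  parent_chain <- ifelse(is.na(root_parent), NA_integer_, chain[root_parent])
  on_innermost <- !is.na(root_parent) & root_parent == innermost[pmax(parent_chain, 1L)]
  n_children <- tabulate(parent_chain[!is.na(parent_chain)], nbins = next_id)
  n_inner_children <- tabulate(parent_chain[which(on_innermost)],
                               nbins = next_id)

  # total LEFs supporting each loop: the root's whole nesting subtree
  # (descendants of a row form a contiguous block in left-sorted order)
  subtree <- findInterval(forest$right, forest$left) - seq_len(n) + 1L

  out <- tibble::tibble(
    loop_id = seq_len(next_id),
    start = forest$left[root],
    end = forest$right[root],
    size = forest$right[root] - forest$left[root] - 1L,
    n_lefs = n_lefs,
    n_lefs_total = subtree[root],
    branched = n_inner_children >= 2L,
    n_children = n_children,
    parent_loop_id = parent_chain,
    top_level = is.na(parent_chain)
  )
  out <- out[order(out$start), ]
  # renumber loop and parent ids to match the sorted order
  new_of_old <- integer(next_id)
  new_of_old[out$loop_id] <- seq_len(nrow(out))
  out$parent_loop_id <- ifelse(is.na(out$parent_loop_id), NA_integer_,
                               new_of_old[out$parent_loop_id])
  out$loop_id <- seq_len(nrow(out))

  top <- out[out$top_level, ]
  starts <- c(1L, top$end + 1L)
  ends <- c(top$start - 1L, L)
  gaps <- (ends - starts + 1L)
  gaps <- gaps[gaps > 0]

  new_loop_table(out, gaps = as.integer(gaps), L = L, time = time)
}

new_loop_table <- function(df, gaps, L, time) {
  attr(df, "gaps") <- gaps
  attr(df, "L") <- L
  attr(df, "time") <- time
  class(df) <- c("loop_table", class(df))
  df
}

#' @export
print.loop_table <- function(x, ...) {
  cat(sprintf(
    "<loop_table> t = %g: %d loops (%d top-level) on L = %d sites, %d gaps\n",
    attr(x, "time"), nrow(x), sum(x$top_level), attr(x, "L"),
    length(attr(x, "gaps"))))
  NextMethod()
}

#' Compaction statistics of a loop array
#'
#' Summarises a [extract_loops()] table. Statistics describe the *top-level*
#' loops: `coverage` is the fraction of lattice sites extruded into loop
#' interiors, `mean_loop_size` the mean interior size in sites,
#' `mean_lefs_per_loop` the mean supporting-stack size, and
#' `branched_fraction` the fraction of loops whose stack carries two or more
#' child loops. When a loop-base width `a_nm` is given, the linear compaction
#' coefficient `c = mean loop length / a` is reported in kb per nm using
#' `bp_per_site` (a chromosome folded into a gapless loop array has axis
#' length equal to the summed widths of its loop bases).
#'
#' Two LEF-per-loop summaries are reported. `mean_lefs_per_loop` counts every
#' LEF supporting a top-level loop -- the full stack plus any nested LEFs
#' still re-extruding or holding a transient division state. In a gapless
#' array this equals `N` over the loop count, so the identity
#' `mean loop length ~ mean_lefs_per_loop * d` holds by construction and the
#' quantity is directly comparable to the steady-state prediction
#' [mean_lefs_per_loop()]. `mean_stack_size` counts only the strict stack
#' chain (heads within the stack tolerance of the loop base) and is the more
#' conservative reinforcement measure.
#'
#' @param table A `loop_table`.
#' @param a_nm Loop-base width in nm (optional; 10--20 nm is the chromatin
#'   fiber diameter scale).
#' @param bp_per_site Base pairs per lattice site (default 200).
#' @return A one-row tibble: `n_loops`, `coverage`, `mean_loop_size`,
#'   `mean_lefs_per_loop`, `mean_stack_size`, `branched_fraction`,
#'   `gap_fraction`, `mean_gap`, and (given `a_nm`) `compaction_kb_per_nm`.
#'   Means are `NA` when there are no loops.
#' @examples
#' st <- loop_fixture(list(c(10, 50), c(11, 49), c(60, 80)), L = 100)
#' loop_stats(extract_loops(st))
#' @export
loop_stats <- function(table, a_nm = NULL, bp_per_site = 200) {
  stopifnot(inherits(table, "loop_table"))
  L <- attr(table, "L")
  gaps <- attr(table, "gaps")
  top <- table[table$top_level, ]
  n <- nrow(top)
  out <- tibble::tibble(
    n_loops = n,
    coverage = if (n) sum(top$size) / L else 0,
    mean_loop_size = if (n) mean(top$size) else NA_real_,
    mean_lefs_per_loop = if (n) mean(top$n_lefs_total) else NA_real_,
    mean_stack_size = if (n) mean(top$n_lefs) else NA_real_,
    branched_fraction = if (n) mean(top$branched) else NA_real_,
    gap_fraction = sum(gaps) / L,
    mean_gap = if (length(gaps)) mean(gaps) else NA_real_
  )
  if (!is.null(a_nm)) {
    stopifnot(a_nm > 0)
    out$compaction_kb_per_nm <-
      out$mean_loop_size * bp_per_site / 1000 / a_nm
  }
  out
}

#' Per-snapshot loop statistics of a trajectory
#'
#' Applies [extract_loops()] + [loop_stats()] to every recorded snapshot.
#'
#' @param traj A `lef_trajectory`.
#' @param stack_tolerance Passed to [extract_loops()].
#' @param a_nm,bp_per_site Passed to [loop_stats()]; `bp_per_site` defaults
#'   to the run's parameter.
#' @return A tibble with one row per snapshot: `time` plus the [loop_stats()]
#'   columns.
#' @examples
#' p <- sim_params(L = 400, N = 20, tau = 25, seed = 2)
#' traj <- simulate_extrusion(p, t_max = 50)
#' trajectory_loop_stats(traj)
#' @export
trajectory_loop_stats <- function(traj, stack_tolerance = 1, a_nm = NULL,
                                  bp_per_site = NULL) {
  stopifnot(inherits(traj, "lef_trajectory"))
  if (is.null(bp_per_site)) bp_per_site <- traj$params$bp_per_site
  chunks <- split_snapshots(traj)
  purrr::map_dfr(chunks, function(snap) {
    t0 <- snap$time[1]
    st <- snapshot_to_state(snap, traj$params$L, t0)
    dplyr::bind_cols(
      tibble::tibble(time = t0),
      loop_stats(extract_loops(st, stack_tolerance), a_nm = a_nm,
                 bp_per_site = bp_per_site)
    )
  })
}

# one pass over the snapshot table, in time order
split_snapshots <- function(traj) {
  snaps <- traj$snapshots
  split(snaps, factor(snaps$time, levels = unique(snaps$time)))
}

snapshot_to_state <- function(snap, L, t0) {
  st <- new_lattice_state(
    ifelse(snap$bound, snap$left, 0L), ifelse(snap$bound, snap$right, 0L),
    as.integer(snap$bound), as.integer(snap$active), time = t0, L = L
  )
  st$lef_id <- snap$lef_id
  st
}

#' Loop tables for every snapshot of a trajectory
#'
#' @param traj A `lef_trajectory`.
#' @param stack_tolerance Passed to [extract_loops()].
#' @return A list of `loop_table` objects, one per snapshot, in time order.
#' @export
trajectory_loops <- function(traj, stack_tolerance = 1) {
  stopifnot(inherits(traj, "lef_trajectory"))
  lapply(split_snapshots(traj), function(snap) {
    extract_loops(snapshot_to_state(snap, traj$params$L, snap$time[1]),
                  stack_tolerance)
  })
}

#' @export
glance.loop_table <- function(x, ...) loop_stats(x, ...)

#' @export
tidy.loop_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "loop_table")
  attr(out, "gaps") <- NULL
  out
}
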