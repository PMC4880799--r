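#' Write / read a trajectory as tab-delimited text
#'
#' The format is plain text: `# key: value` header lines recording the
#' simulation parameters, then a tab-separated table with columns `time`,
#' `lef_id`, `left`, `right`, `bound`, `active` (one row per LEF per
#' snapshot; positions are `NA` while unbound). `read_trajectory()`
#' reconstructs the `lef_trajectory` exactly
#' (`read_trajectory(write_trajectory(x, f))` equals `x` up to the event
#' log, which is not serialised).
#'
#' @param traj A `lef_trajectory`.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `lef_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "lef_trajectory"))
  p <- traj$params
  hdr <- c(
    sprintf("# L: %d", p$L), sprintf("# N: %d", p$N),
    sprintf("# v: %.17g", p$v), sprintf("# tau: %.17g", p$tau),
    sprintf("# mode: %s", p$mode),
    sprintf("# coupled_heads: %s", p$coupled_heads),
    sprintf("# activation_rate: %.17g", p$activation_rate),
    sprintf("# k_on: %.17g", p$k_on),
    sprintf("# bp_per_site: %.17g", p$bp_per_site),
    sprintf("# seed: %s", if (is.null(p$seed)) "NA" else p$seed)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("time", "lef_id", "left", "right", "bound", "active"),
                   collapse = "\t"), con)
  s <- traj$snapshots
  writeLines(sprintf("%.17g\t%d\t%s\t%s\t%d\t%d", s$time, s$lef_id,
                     ifelse(is.na(s$left), "NA", s$left),
                     ifelse(is.na(s$right), "NA", s$right),
                     as.integer(s$bound), as.integer(s$active)), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  kv <- sub("^# ([^:]+): (.*)$", "\\1\t\\2", lines[hdr])
  keys <- vapply(strsplit(kv, "\t"), `[`, character(1), 1)
  vals <- vapply(strsplit(kv, "\t"), `[`, character(1), 2)
  names(vals) <- keys
  required <- c("L", "N", "v", "tau", "mode", "coupled_heads",
                "activation_rate", "k_on", "bp_per_site")
  missing_keys <- setdiff(required, keys)
  if (length(missing_keys)) {
    stop("trajectory header is missing keys: ",
         paste(missing_keys, collapse = ", "))
  }
  seed <- if (!"seed" %in% keys || vals[["seed"]] == "NA") NULL else
    as.integer(vals[["seed"]])
  params <- sim_params(
    L = as.integer(vals[["L"]]), N = as.integer(vals[["N"]]),
    v = as.numeric(vals[["v"]]), tau = as.numeric(vals[["tau"]]),
    mode = vals[["mode"]],
    coupled_heads = as.logical(vals[["coupled_heads"]]),
    activation_rate = as.numeric(vals[["activation_rate"]]),
    k_on = if (vals[["mode"]] == "explicit_exchange")
      as.numeric(vals[["k_on"]]) else NULL,
    bp_per_site = as.numeric(vals[["bp_per_site"]]), seed = seed
  )
  body <- setdiff(seq_along(lines), hdr)
  df <- utils::read.table(text = lines[body], header = TRUE, sep = "\t",
                          na.strings = "NA")
  bad <- which(!is.na(df$left) & !is.na(df$right) & df$left >= df$right)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: left head (%d) not left of right head (%d)",
                 body[1] + bad[1], df$left[bad[1]], df$right[bad[1]]))
  }
  snapshots <- tibble::tibble(
    time = df$time, lef_id = as.integer(df$lef_id),
    left = as.integer(df$left), right = as.integer(df$right),
    bound = df$bound == 1, active = df$active == 1
  )
  last <- snapshots[snapshots$time == max(snapshots$time), ]
  structure(
    list(params = params, snapshots = snapshots, events = NULL,
         final_state = snapshot_to_state(last, params$L, max(snapshots$time))),
    class = "lef_trajectory"
  )
}

#' Export a loop table as BEDPE
#'
#' Writes one BEDPE record per top-level loop. The two anchors are the head
#' sites converted from 1-based inclusive lattice coordinates to 0-based
#' half-open genomic intervals of width `bp_per_site` (site `i` maps to
#' `[(i-1)*bp_per_site, i*bp_per_site)`). The name column is the loop id and
#' the score column the supporting-stack size `n_lefs`. BEDPE has no header;
#' records are ordered by start.
#'
#' @param table A `loop_table`.
#' @param path Output file.
#' @param bp_per_site Base pairs per lattice site (default 200).
#' @param chrom_name Chromosome name for both anchors (default `"sim"`).
#' @return `path`, invisibly.
#' @examples
#' tab <- extract_loops(loop_fixture(list(c(10, 50)), L = 100))
#' f <- tempfile(fileext = ".bedpe")
#' export_bedpe(tab, f)
#' readLines(f)
#' @export
export_bedpe <- function(table, path, bp_per_site = 200, chrom_name = "sim") {
  stopifnot(inherits(table, "loop_table"), bp_per_site > 0)
  top <- table[table$top_level, ]
  top <- top[order(top$start), ]
  lines <- sprintf(
    "%s\t%.0f\t%.0f\t%s\t%.0f\t%.0f\tloop_%d\t%d",
    chrom_name, (top$start - 1) * bp_per_site, top$start * bp_per_site,
    chrom_name, (top$end - 1) * bp_per_site, top$end * bp_per_site,
    top$loop_id, top$n_lefs
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a flat run-configuration file
#'
#' A run configuration is a flat text file of `key = value` lines (`#`
#' comments allowed) covering the [sim_params()] fields plus run controls
#' (`t_max`, `sample_interval`, ...). Values are coerced: integers, numbers
#' and logicals are recognised, everything else stays character.
#'
#' @param path File path.
#' @return `read_run_config()`: a named list. `write_run_config()`: `path`,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- grep("=", lines, invert = TRUE)
  if (length(bad)) {
    stop("config line without 'key = value': ", lines[bad[1]])
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  parse1 <- function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  setNames(lapply(vals, parse1), keys)
}

#' @rdname read_run_config
#' @param config Named list of scalar values.
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}

#' Phase-diagram sweep over lambda/d
#'
#' Runs the simulator over a grid of conditions and summarises the
#' steady-state loop array of each run: loop coverage, mean loop size, mean
#' LEFs per loop, branched fraction and gap fraction. Conditions can be
#' given either as a vector of target `lambda_over_d` ratios (with `tau`
#' adjusted at fixed `L`, `N`, `v`) or as an explicit `grid` data frame with
#' columns `L`, `N`, `v`, `tau` -- the latter is how one checks that curves
#' measured while varying different microscopic parameters collapse onto a
#' single function of `lambda/d`.
#'
#' @param lambda_over_d Numeric vector of target ratios (ignored when `grid`
#'   is supplied).
#' @param L,N,v Lattice size, LEF count and speed used with
#'   `lambda_over_d`.
#' @param grid Optional data frame with columns `L`, `N`, `v`, `tau`.
#' @param replicates Independent replicates per condition; replicate `r` of
#'   condition `i` uses seed `base_seed + 1000 * i + r`.
#' @param base_seed Base RNG seed.
#' @param coupled_heads Run the coupled-heads variant.
#' @param t_max_tau Total simulated time in units of `tau` (default 16).
#' @param measure_from_tau Discard snapshots before this many `tau`
#'   (default 12, past the up-to-10-tau convergence transient).
#' @param sample_interval_tau Snapshot spacing in units of `tau`
#'   (default 0.5; fine sampling is unnecessary for time-averaged
#'   statistics).
#' @param stack_tolerance Passed to [extract_loops()].
#' @return A tibble with one row per condition x replicate: the condition
#'   columns, `lambda_over_d`, `replicate`, `seed`, and the time-averaged
#'   `coverage`, `mean_loop_size`, `mean_lefs_per_loop`, `branched_fraction`,
#'   `gap_fraction`.
#' @examples
#' \donttest{
#' sweep_phase_diagram(c(0.1, 1, 10), L = 1000, N = 50, replicates = 2)
#' }
#' @export
sweep_phase_diagram <- function(lambda_over_d = NULL, L = NULL, N = NULL,
                                v = 1, grid = NULL, replicates = 1,
                                base_seed = 1, coupled_heads = FALSE,
                                t_max_tau = 16, measure_from_tau = 12,
                                sample_interval_tau = 0.5,
                                stack_tolerance = 1) {
  if (is.null(grid)) {
    stopifnot(!is.null(lambda_over_d), !is.null(L), !is.null(N))
    grid <- tibble::tibble(L = L, N = N, v = v,
                           tau = lambda_over_d * (L / N) / (2 * v))
  }
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("L", "N", "v", "tau") %in% names(grid)))
  cases <- tidyr::expand_grid(i = seq_len(nrow(grid)),
                              replicate = seq_len(replicates))
  purrr::pmap_dfr(cases, function(i, replicate) {
    g <- grid[i, ]
    seed <- as.integer(base_seed + 1000 * i + replicate)
    p <- sim_params(L = g$L, N = g$N, v = g$v, tau = g$tau,
                    coupled_heads = coupled_heads, seed = seed)
    traj <- simulate_extrusion(
      p, t_max = t_max_tau * g$tau,
      sample_interval = sample_interval_tau * g$tau
    )
    st <- trajectory_loop_stats(traj, stack_tolerance = stack_tolerance)
    st <- st[st$time >= measure_from_tau * g$tau, ]
    tibble::tibble(
      L = g$L, N = g$N, v = g$v, tau = g$tau,
      lambda_over_d = p$lambda_over_d, replicate = replicate, seed = seed,
      coverage = mean(st$coverage),
      mean_loop_size = mean(st$mean_loop_size, na.rm = TRUE),
      mean_lefs_per_loop = mean(st$mean_lefs_per_loop, na.rm = TRUE),
      branched_fraction = mean(st$branched_fraction, na.rm = TRUE),
      gap_fraction = mean(st$gap_fraction)
    )
  })
}
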