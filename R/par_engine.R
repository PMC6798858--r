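# Phase-ordered parallel engine over the seam partition.
#
# The concurrency model is a contract: t workers process all subregions
# of one type concurrently (bottom seams, then centers, then top seams)
# with a barrier between phases, then a coordinator records metrics,
# starts/advances seam moves, and swaps the lists. This package realizes
# the contract with a serialized phase schedule — one legal interleaving
# of the concurrent execution — which makes runs reproducible for a
# fixed master seed and worker count. Each worker draws from its own
# splitmix64 stream keyed on (master seed, region index, step).

#' Initialize a parallel simulation state
#'
#' Builds lattice, initial partition (seams centered on the seed mass),
#' and the per-subregion cell lists.
#'
#' @inheritParams init_state
#' @param n_workers Number of regions/workers.
#' @param rho Imbalance threshold (percent) for starting seam moves.
#' @param master_seed Integer seed for the per-worker RNG streams.
#' @return An object of class `tumor_pstate`.
#' @export
init_parallel_state <- function(n_rows, n_cols, seeds = "center",
                                params = model_params(), n_workers = 2L,
                                rho = 10, master_seed = 1L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  params <- validate_params(params)
  seeds <- resolve_seeds(seeds, n_rows, n_cols)
  lattice <- matrix(0L, n_rows, n_cols)
  lattice[seeds] <- 1L
  cells <- cells_matrix(seeds[, 1L], seeds[, 2L], rep(params$ph_init, nrow(seeds)))
  tumor_rows <- if (nrow(seeds)) range(seeds[, 1L]) else
    rep(ceiling(n_rows / 2), 2L)
  partition <- initial_partition(tumor_rows[1L], tumor_rows[2L], n_workers,
                                 params$delta, n_rows, rho)
  partition <- assign_cells(partition, cells)
  structure(list(lattice = lattice, partition = partition, params = params,
                 step = 0L, master_seed = as.integer(master_seed)),
            class = "tumor_pstate")
}

#' @export
print.tumor_pstate <- function(x, ...) {
  cat(sprintf("Parallel tumor CA state: %d x %d lattice, %d live cells, step %d, %d region(s)\n",
              nrow(x$lattice), ncol(x$lattice), sum(x$lattice), x$step,
              length(x$partition$regions)))
  invisible(x)
}

# Bin a flat cell matrix into per-subregion lists under current geometry.
assign_cells <- function(partition, cells) {
  map <- subregion_of_rows(partition)
  for (i in seq_along(partition$regions))
    for (nm in c("top", "center", "bottom")) {
      sel <- map$region[cells[, "row"]] == i & map$part[cells[, "row"]] == nm
      partition$lists[[i]][[nm]] <- cells[sel, , drop = FALSE]
    }
  partition
}

# row -> (region index, part name) lookup vectors, length n_rows
subregion_of_rows <- function(partition) {
  region <- integer(partition$n_rows)
  part <- character(partition$n_rows)
  for (i in seq_along(partition$regions))
    for (nm in c("top", "center", "bottom")) {
      b <- partition$regions[[i]][[nm]]
      if (b[2L] > b[1L]) {
        rows <- seq.int(b[1L], b[2L] - 1L)
        region[rows] <- i
        part[rows] <- nm
      }
    }
  list(region = region, part = part)
}

geometry_matrix <- function(partition) {
  t(vapply(partition$regions,
           function(r) c(r$top, r$center, r$bottom), integer(6L)))
}

#' All cells currently on the partition's lists
#'
#' @param pstate A `tumor_pstate`.
#' @return An n x 3 `row`/`col`/`ph` matrix.
#' @export
partition_cells <- function(pstate) {
  do.call(rbind, unlist(lapply(pstate$partition$lists, function(l)
    l[c("top", "center", "bottom")]), recursive = FALSE))
}

#' Advance one parallel step
#'
#' Executes the three barrier-separated phases (bottom seams, centers,
#' top seams); each processed cell's surviving record and any daughter
#' are appended to the next list of the subregion that holds its
#' possibly-new position under the current geometry. After the third
#' barrier the coordinator takes the lattice census per region, starts
#' seam moves where the imbalance exceeds `rho`, advances all active
#' moves one phase, and swaps the lists. Ownership tags count any
#' next-list written by two workers within one phase; the seam layout
#' guarantees the count stays zero.
#'
#' @param pstate A `tumor_pstate`.
#' @return A list with `state` (advanced `tumor_pstate`) and `stats`:
#'   `processed`, `live`, per-region `counts`, `seam_rows`,
#'   `moves_started`, `moves_active`, `moves_completed`,
#'   `ownership_violations`.
#' @export
parallel_step <- function(pstate) {
  stopifnot(inherits(pstate, "tumor_pstate"))
  part <- pstate$partition
  res <- cpp_parallel_step(pstate$lattice, geometry_matrix(part), part$lists,
                           as_params_list(pstate$params),
                           pstate$master_seed, pstate$step)
  pstate$lattice <- res$lattice
  part$lists <- res$region_lists
  counts <- region_counts(part, pstate$lattice)
  started <- needs_adjustment(part, counts)
  part <- start_seam_moves(part, started)
  adv <- advance_seam_moves(part)
  part <- adv$partition
  pstate$partition <- part
  pstate$step <- pstate$step + 1L
  list(state = pstate,
       stats = list(processed = sum(res$processed), live = sum(counts),
                    counts = counts, seam_rows = seam_rows(part),
                    moves_started = length(started),
                    moves_active = length(part$moves),
                    moves_completed = adv$completed,
                    ownership_violations = res$ownership_violations))
}

#' Run the parallel engine
#'
#' @inheritParams init_parallel_state
#' @param n_steps Number of steps.
#' @param validate If `TRUE`, check all partition invariants after every
#'   step (used by the test suite; costs a little time).
#' @return A list with `state` (final `tumor_pstate`), `metrics` (per-
#'   step data.frame: `step`, `processed`, `live`, `cum_processed`,
#'   `moves_started`, `moves_active`, `moves_completed`,
#'   `ownership_violations`), `region_counts` (steps x t matrix) and
#'   `seam_rows` (steps x (t-1) matrix).
#' @examples
#' out <- run_parallel(60, 60, n_steps = 30, n_workers = 2, master_seed = 7)
#' tail(out$metrics, 2)
#' @export
run_parallel <- function(n_rows, n_cols, seeds = "center",
                         params = model_params(), n_steps = 100L,
                         n_workers = 2L, rho = 10, master_seed = 1L,
                         validate = FALSE) {
  pstate <- init_parallel_state(n_rows, n_cols, seeds, params, n_workers,
                                rho, master_seed)
  n_steps <- as.integer(n_steps)
  t <- length(pstate$partition$regions)
  metrics <- data.frame(step = seq_len(n_steps), processed = NA_integer_,
                        live = NA_integer_, moves_started = NA_integer_,
                        moves_active = NA_integer_, moves_completed = NA_integer_,
                        ownership_violations = NA_integer_)
  rc <- matrix(NA_integer_, n_steps, t)
  sr <- matrix(NA_integer_, n_steps, max(t - 1L, 0L))
  for (s in seq_len(n_steps)) {
    out <- parallel_step(pstate)
    pstate <- out$state
    st <- out$stats
    metrics[s, -1L] <- c(st$processed, st$live, st$moves_started,
                         st$moves_active, st$moves_completed,
                         st$ownership_violations)
    rc[s, ] <- st$counts
    if (t > 1L) sr[s, ] <- st$seam_rows
    if (validate) validate_partition(pstate$partition)
  }
  metrics$cum_processed <- cumsum(as.numeric(metrics$processed))
  list(state = pstate, metrics = metrics, region_counts = rc, seam_rows = sr)
}

#' Distributional equivalence of two engine configurations
#'
#' Bitwise identity between sequential and parallel runs is impossible —
#' the evaluation order differs — so equivalence is tested on the
#' distribution of final tumor sizes: `n_runs` independently seeded runs
#' per arm, compared with a two-sample Kolmogorov-Smirnov test.
#'
#' @param params A [model_params()] object.
#' @param n_rows,n_cols Lattice dimensions.
#' @param n_steps Steps per run.
#' @param n_runs Runs per arm (>= 30 recommended).
#' @param engine_a,engine_b `"sequential"` or `"parallel"`.
#' @param workers_a,workers_b Worker counts for parallel arms.
#' @param rho Imbalance threshold for parallel arms.
#' @param seed Base seed; run k of arm A uses `seed + k`, of arm B
#'   `seed + 100000 + k`.
#' @return A list of class `tumor_equiv`: `statistic`, `p.value`,
#'   `sizes_a`, `sizes_b`.
#' @export
equivalence_check <- function(params = model_params(), n_rows = 200L,
                              n_cols = 200L, n_steps = 300L, n_runs = 30L,
                              engine_a = "sequential", engine_b = "parallel",
                              workers_a = 2L, workers_b = 4L, rho = 10,
                              seed = 1L) {
  final_size <- function(engine, workers, run_seed) {
    if (engine == "sequential") {
      st <- init_state(n_rows, n_cols, "center", params, seed = run_seed)
      nrow(run_simulation(st, n_steps)$state$cells)
    } else {
      out <- run_parallel(n_rows, n_cols, "center", params, n_steps,
                          workers, rho, master_seed = run_seed)
      sum(out$state$lattice)
    }
  }
  sizes_a <- vapply(seq_len(n_runs), function(k)
    final_size(engine_a, workers_a, seed + k), numeric(1L))
  sizes_b <- vapply(seq_len(n_runs), function(k)
    final_size(engine_b, workers_b, seed + 100000L + k), numeric(1L))
  ks <- suppressWarnings(stats::ks.test(sizes_a, sizes_b, exact = FALSE))
  structure(list(statistic = unname(ks$statistic), p.value = ks$p.value,
                 sizes_a = sizes_a, sizes_b = sizes_b,
                 engine_a = engine_a, engine_b = engine_b),
            class = "tumor_equiv")
}

#' @export
print.tumor_equiv <- function(x, ...) {
  cat(sprintf("Final-size distributional equivalence (%s vs %s)\n",
              x$engine_a, x$engine_b))
  cat(sprintf("  KS statistic %.4f, p = %.4g, n = %d per arm\n",
              x$statistic, x$p.value, length(x$sizes_a)))
  cat(sprintf("  mean sizes: %.1f vs %.1f\n", mean(x$sizes_a), mean(x$sizes_b)))
  invisible(x)
}
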