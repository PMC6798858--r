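# Configuration, file formats, and sweep drivers.
#
# Config files are JSON; missing fields fall back to the reference
# parameter set and a sequential engine. Metrics go to CSV with the
# fixed header step, processed, live, cum_processed (plus the parallel
# columns when present). Snapshots are plain-text 0/1 grids: CSV, or
# P2 (ASCII) PGM with maxval 1 for visual inspection.

config_defaults <- function() {
  list(n_rows = 200L, n_cols = 200L, seeds = "center",
       engine = "sequential", n_steps = 200L, n_workers = 2L, rho = 10,
       p_survive = 0.8, p_signal = 0.2, p_migrate = 0.25,
       np_threshold = 1L, ph_init = 1L, delta = 1L,
       neighborhood = "von_neumann",
       seed = 1L, snapshot_interval = 0L, out_dir = ".")
}

#' Build a simulation configuration
#'
#' @param ... Named fields overriding the defaults; see
#'   [config_defaults] in the source for the full set. `engine` is one
#'   of `"sequential"`, `"parallel"`, `"oracle"`; `seeds` is `"center"`
#'   or a 2-column (row, col) matrix/list.
#' @return A validated list of class `tumor_config`.
#' @export
sim_config <- function(...) {
  over <- list(...)
  cfg <- config_defaults()
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "tumor_config"))
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  for (f in c("n_rows", "n_cols", "n_steps", "n_workers", "np_threshold",
              "ph_init", "delta", "seed", "snapshot_interval"))
    cfg[[f]] <- as.integer(cfg[[f]])
  chk(cfg$n_rows >= 1L && cfg$n_cols >= 1L, "lattice dimensions must be positive")
  chk(cfg$n_steps >= 0L, "`n_steps` must be non-negative")
  chk(cfg$engine %in% c("sequential", "parallel", "oracle"),
      "`engine` must be one of sequential, parallel, oracle")
  chk(cfg$n_workers >= 1L, "`n_workers` must be at least 1")
  chk(is.numeric(cfg$rho) && cfg$rho >= 0, "`rho` must be a non-negative percentage")
  chk(cfg$snapshot_interval >= 0L, "`snapshot_interval` must be non-negative")
  # delegate model-parameter checks
  config_params(cfg)
  if (cfg$engine == "parallel")
    chk(cfg$n_rows >= 3L * cfg$delta * cfg$n_workers,
        "lattice height below 3 * delta * n_workers; too many regions")
  cfg
}

config_params <- function(cfg) {
  model_params(cfg$p_survive, cfg$p_signal, cfg$p_migrate, cfg$np_threshold,
               cfg$ph_init, cfg$delta, cfg$neighborhood)
}

#' Load a simulation configuration from JSON
#'
#' Missing fields take the defaults (reference parameter set, sequential
#' engine); an empty file yields the all-defaults configuration. Invalid
#' values are rejected with a message naming the violated constraint.
#'
#' @param path Path to a JSON file.
#' @return A `tumor_config`.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  if (!is.null(raw$seeds) && !is.character(raw$seeds))
    raw$seeds <- matrix(as.integer(as.matrix(raw$seeds)), ncol = 2L)
  do.call(sim_config, raw)
}

#' Save a configuration to JSON
#'
#' Written so that [load_config()] round-trips to an identical
#' configuration.
#'
#' @param config A `tumor_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(validate_config(config))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a configured simulation
#'
#' Dispatches to the engine named in the configuration and optionally
#' writes periodic snapshots.
#'
#' @param config A `tumor_config`.
#' @param write_outputs If `TRUE`, write `metrics.csv`, periodic
#'   snapshots (when `snapshot_interval > 0`) and a final snapshot into
#'   `config$out_dir`.
#' @return As [run_simulation()] / [run_parallel()].
#' @export
run_config <- function(config, write_outputs = FALSE) {
  cfg <- validate_config(config)
  params <- config_params(cfg)
  seeds <- cfg$seeds
  snap_dir <- cfg$out_dir
  if (write_outputs && !dir.exists(snap_dir))
    dir.create(snap_dir, recursive = TRUE)
  snap_hook <- function(state, step) {
    if (write_outputs && cfg$snapshot_interval > 0L &&
        step %% cfg$snapshot_interval == 0L)
      write_snapshot(state$lattice,
                     file.path(snap_dir, sprintf("snapshot_%06d.csv", step)))
  }
  if (cfg$engine %in% c("sequential", "oracle")) {
    state <- init_state(cfg$n_rows, cfg$n_cols, seeds, params, seed = cfg$seed)
    if (cfg$engine == "oracle" || (write_outputs && cfg$snapshot_interval > 0L)) {
      metrics <- empty_metrics()
      processed <- live <- integer(cfg$n_steps)
      for (s in seq_len(cfg$n_steps)) {
        processed[s] <- nrow(state$cells)
        state <- if (cfg$engine == "oracle") step_oracle(state) else
          step_sequential(state)
        live[s] <- nrow(state$cells)
        snap_hook(state, s)
      }
      metrics <- data.frame(step = seq_len(cfg$n_steps), processed = processed,
                            live = live,
                            cum_processed = cumsum(as.numeric(processed)))
      out <- list(state = state, metrics = metrics)
    } else {
      out <- run_simulation(state, cfg$n_steps)
    }
  } else {
    out <- run_parallel(cfg$n_rows, cfg$n_cols, seeds, params, cfg$n_steps,
                        cfg$n_workers, cfg$rho, master_seed = cfg$seed)
    if (write_outputs && cfg$snapshot_interval > 0L)
      warning("periodic snapshots are only written by the sequential engines",
              call. = FALSE)
  }
  if (write_outputs) {
    write_metrics(out$metrics, file.path(cfg$out_dir, "metrics.csv"))
    lat <- if (inherits(out$state, "tumor_pstate")) out$state$lattice else
      out$state$lattice
    write_snapshot(lat, file.path(cfg$out_dir, "final_snapshot.csv"))
  }
  out
}

#' Write per-step metrics to CSV
#'
#' Fixed column order as in the metrics data.frame (`step`, `processed`,
#' `live`, `cum_processed`, plus the seam-move columns for parallel
#' runs); one row per step, header always present.
#'
#' @param metrics Metrics data.frame.
#' @param path Output path.
#' @export
write_metrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write a lattice snapshot
#'
#' `"csv"` writes a plain-text 0/1 grid (one lattice row per line,
#' comma-separated, no header). `"pgm"` writes an ASCII P2 PGM with
#' maxval 1 (0 = empty, 1 = tumor cell) for direct visual inspection.
#'
#' @param lattice Integer 0/1 matrix.
#' @param path Output path.
#' @param format `"csv"` or `"pgm"`; default guessed from the extension.
#' @export
write_snapshot <- function(lattice, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.pgm$", path, ignore.case = TRUE)) "pgm" else "csv"
  if (format == "csv") {
    utils::write.table(lattice, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (format == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(lattice), nrow(lattice)), "1"), con)
    writeLines(apply(lattice, 1L, paste, collapse = " "), con)
  } else stop("unknown snapshot format: ", format, call. = FALSE)
  invisible(path)
}

#' Read a lattice snapshot written by [write_snapshot()]
#'
#' @param path Snapshot path.
#' @param format `"csv"` or `"pgm"`; default guessed from the extension.
#' @return Integer 0/1 matrix.
#' @export
read_snapshot <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.pgm$", path, ignore.case = TRUE)) "pgm" else "csv"
  if (format == "csv") {
    m <- as.matrix(read.csv(path, header = FALSE))
  } else {
    lines <- readLines(path)
    stopifnot(lines[1L] == "P2")
    dims <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
    vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
    m <- matrix(vals, nrow = dims[2L], ncol = dims[1L], byrow = TRUE)
  }
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

sweep_run <- function(cfg, run_seed) {
  cfg$seed <- run_seed
  elapsed <- system.time(out <- run_config(cfg))[["elapsed"]]
  counts <- if (!is.null(out$region_counts))
    out$region_counts[nrow(out$region_counts), ] else NULL
  list(final_size = if (inherits(out$state, "tumor_pstate"))
         sum(out$state$lattice) else nrow(out$state$cells),
       total_processed = if (nrow(out$metrics))
         out$metrics$cum_processed[nrow(out$metrics)] else 0,
       elapsed = elapsed,
       balance_ratio = if (!is.null(counts) && min(counts) > 0)
         max(counts) / min(counts) else NA_real_)
}

sweep_table <- function(cfg_base, field, values, repeats) {
  rows <- lapply(seq_along(values), function(i) {
    cfg <- cfg_base
    cfg[[field]] <- values[i]
    cfg <- validate_config(cfg)
    runs <- lapply(seq_len(repeats), function(k)
      sweep_run(cfg, cfg_base$seed + 1000L * i + k))
    fs <- vapply(runs, `[[`, numeric(1L), "final_size")
    tp <- vapply(runs, `[[`, numeric(1L), "total_processed")
    el <- vapply(runs, `[[`, numeric(1L), "elapsed")
    br <- vapply(runs, `[[`, numeric(1L), "balance_ratio")
    data.frame(value = values[i],
               mean_final_size = mean(fs), sd_final_size = stats::sd(fs),
               mean_processed = mean(tp), sd_processed = stats::sd(tp),
               mean_cells_per_sec = mean(ifelse(el > 0, tp / el, NA_real_)),
               mean_balance_ratio = mean(br))
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- field
  out
}

#' Sweep the load-balancing threshold rho
#'
#' Runs `repeats` independently seeded parallel simulations per `rho`
#' value and summarizes final size, total cells processed, throughput
#' (informational; wall-clock-dependent) and the final max/min
#' per-region balance ratio.
#'
#' @param base_config A `tumor_config` (its `engine` is forced to
#'   `"parallel"`).
#' @param rho_values Numeric vector of thresholds (percent).
#' @param repeats Runs per grid point.
#' @return A data.frame with one row per `rho` value.
#' @export
sweep_rho <- function(base_config, rho_values, repeats = 5L) {
  cfg <- validate_config(base_config)
  cfg$engine <- "parallel"
  sweep_table(cfg, "rho", rho_values, repeats)
}

#' Sweep the worker count
#'
#' @param base_config A `tumor_config` (its `engine` is forced to
#'   `"parallel"`).
#' @param t_values Integer vector of worker counts.
#' @param repeats Runs per grid point.
#' @return A data.frame with one row per worker count.
#' @export
sweep_threads <- function(base_config, t_values, repeats = 5L) {
  cfg <- validate_config(base_config)
  cfg$engine <- "parallel"
  sweep_table(cfg, "n_workers", as.integer(t_values), repeats)
}
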