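# Shared fixtures: parameter presets and randomized state / partition
# generators used across test files.

table1_params <- function(...) model_params(...)

# immortal cells: deterministic, monotone growth — used where a test needs
# a tumor that reliably survives and loads the partition
immortal_params <- function(p_signal = 0.2, p_migrate = 0.25, ...) {
  model_params(p_survive = 1, p_signal = p_signal, p_migrate = p_migrate, ...)
}

# supercritical variant with real extinction/size spread, for KS calibration
spread_params <- function() model_params(p_survive = 0.95)

# random occupancy state with random PH counters, current list sorted row-major
random_state <- function(seed, n_rows = 20, n_cols = 20, fill = 0.3,
                         params = table1_params()) {
  set.seed(seed)
  lat <- matrix(rbinom(n_rows * n_cols, 1, fill), n_rows, n_cols)
  idx <- which(lat == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) idx <- cbind(1L, 1L)
  st <- init_state(n_rows, n_cols, idx, params)
  st$cells[, "ph"] <- sample(0:3, nrow(st$cells), replace = TRUE)
  sort_cells_rowmajor(st)
}

sorted_cells <- function(state) {
  cells <- if (inherits(state, "tumor_state")) state$cells else state
  cells[order(cells[, "row"], cells[, "col"]), , drop = FALSE]
}

expect_same_next_state <- function(state, rng_seed) {
  set.seed(rng_seed)
  a <- step_sequential(state)
  set.seed(rng_seed)
  b <- step_oracle(state)
  identical(a$lattice, b$lattice) && identical(a$cells, b$cells)
}

# Randomized partition construction + seam-move walk. For each case a
# partition with random (t, delta, height, tumor band) is built and then
# driven for `n_steps` coordinator rounds with random per-region counts;
# every round all invariants are re-checked. Returns the number of
# completed moves (so callers can assert the walk actually exercised the
# machinery).
partition_walk <- function(seed, n_steps = 15) {
  set.seed(seed)
  t <- sample(1:6, 1)
  delta <- sample(1:3, 1)
  n_rows <- 3 * delta * t + sample(0:40, 1)
  lo <- sample(seq_len(n_rows), 1)
  hi <- min(n_rows, lo + sample(0:20, 1))
  part <- initial_partition(lo, hi, t, delta, n_rows, rho = 10)
  validate_partition(part)
  completed <- 0L
  for (s in seq_len(n_steps)) {
    counts <- sample(0:1000, t, replace = TRUE)
    spans_before <- region_spans(part)
    moves <- needs_adjustment(part, counts)
    part <- start_seam_moves(part, moves)
    adv <- advance_seam_moves(part)
    part <- adv$partition
    completed <- completed + adv$completed
    validate_partition(part)
    # geometry may only ever shift boundaries by delta per round
    spans_after <- region_spans(part)
    stopifnot(all(abs(spans_after - spans_before) <= delta))
    stopifnot(spans_after[1, 1] == 1L,
              spans_after[nrow(spans_after), 2] == n_rows + 1L)
  }
  completed
}
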