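#' Initialize a simulation state
#'
#' Builds the lattice and the active-cell list for a fresh simulation.
#' The state follows the two-list scheme: at every step boundary the
#' current list enumerates exactly the occupied lattice sites.
#'
#' @param n_rows,n_cols Lattice dimensions (positive integers).
#' @param seeds Either the string `"center"` (one cell at the lattice
#'   center) or a 2-column matrix / data.frame of `(row, col)` seed
#'   positions, 1-based, distinct, in bounds. An empty matrix gives an
#'   empty (absorbing) tumor.
#' @param params A [model_params()] object; seed cells start with
#'   `PH = ph_init`.
#' @param seed Optional integer; if given, `set.seed(seed)` is called so
#'   the subsequent sequential run is reproducible.
#' @return An object of class `tumor_state`: a list with `lattice`
#'   (integer 0/1 matrix), `cells` (n x 3 matrix `row`/`col`/`ph`),
#'   `step` (0), and `params`.
#' @examples
#' st <- init_state(32, 32, "center", model_params(), seed = 1)
#' sum(st$lattice)
#' @export
init_state <- function(n_rows, n_cols, seeds = "center",
                       params = model_params(), seed = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  params <- validate_params(params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  seeds <- resolve_seeds(seeds, n_rows, n_cols)
  lattice <- matrix(0L, n_rows, n_cols)
  lattice[seeds] <- 1L
  cells <- cells_matrix(seeds[, 1L], seeds[, 2L],
                        rep(params$ph_init, nrow(seeds)))
  structure(list(lattice = lattice, cells = cells, step = 0L, params = params),
            class = "tumor_state")
}

resolve_seeds <- function(seeds, n_rows, n_cols) {
  if (is.character(seeds) && length(seeds) == 1L && seeds == "center") {
    seeds <- cbind(ceiling(n_rows / 2), ceiling(n_cols / 2))
  }
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) return(matrix(integer(), 0L, 2L))
  if (ncol(seeds) != 2L) stop("`seeds` must have two columns (row, col)", call. = FALSE)
  storage.mode(seeds) <- "integer"
  if (anyNA(seeds) ||
      any(seeds[, 1L] < 1L | seeds[, 1L] > n_rows |
          seeds[, 2L] < 1L | seeds[, 2L] > n_cols))
    stop("seed positions must lie inside the lattice", call. = FALSE)
  if (anyDuplicated(paste(seeds[, 1L], seeds[, 2L])))
    stop("seed positions must be distinct", call. = FALSE)
  dimnames(seeds) <- NULL
  seeds
}

#' @export
print.tumor_state <- function(x, ...) {
  cat(sprintf("Tumor CA state: %d x %d lattice, %d live cells, step %d\n",
              nrow(x$lattice), ncol(x$lattice), nrow(x$cells), x$step))
  invisible(x)
}

#' @export
plot.tumor_state <- function(x, ...) {
  # row 1 on top, matching the lattice orientation
  image(t(x$lattice[nrow(x$lattice):1, , drop = FALSE]),
        col = c("white", "firebrick"), axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Advance one step with the sequential list engine
#'
#' Processes the current active-cell list in list order: each cell is
#' evaluated with [evaluate_cell()] semantics and its fate applied in
#' place; survivors and daughters form the next list. Consumes R's
#' global RNG.
#'
#' @param state A `tumor_state` from [init_state()].
#' @return The advanced `tumor_state`.
#' @export
step_sequential <- function(state) {
  advance_state(state, oracle = FALSE)
}

#' Advance one step with the naive full-grid-scan oracle engine
#'
#' Scans every lattice site in row-major order and evaluates the cells
#' that were live at the start of the step, consuming RNG draws only for
#' live cells. When the current list is sorted row-major, this engine
#' and [step_sequential()] produce identical next states from identical
#' RNG states; the oracle exists as the independent reference for that
#' equivalence.
#'
#' @inheritParams step_sequential
#' @return The advanced `tumor_state`.
#' @export
step_oracle <- function(state) {
  advance_state(state, oracle = TRUE)
}

advance_state <- function(state, oracle) {
  stopifnot(inherits(state, "tumor_state"))
  res <- cpp_step(state$lattice, state$cells, as_params_list(state$params), oracle)
  state$lattice <- res$lattice
  state$cells <- res$cells
  state$step <- state$step + 1L
  state
}

#' Sort the active-cell list row-major
#'
#' Processing order within a step is list order; sorting row-major (rows,
#' then columns) puts the list engine on the exact path of the oracle
#' engine.
#'
#' @inheritParams step_sequential
#' @return The state with its current list sorted.
#' @export
sort_cells_rowmajor <- function(state) {
  state$cells <- state$cells[order(state$cells[, "row"], state$cells[, "col"]),
                             , drop = FALSE]
  state
}

#' Run the sequential engine for many steps
#'
#' Applies [step_sequential()] `n_steps` times, recording per-step
#' metrics. Without hooks the whole loop runs in compiled code.
#'
#' @inheritParams step_sequential
#' @param n_steps Number of steps (non-negative integer).
#' @param hooks Optional function `f(state)` called after every step
#'   (forces the slower step-at-a-time path).
#' @return A list with `state` (final `tumor_state`) and `metrics`, a
#'   data.frame with one row per step: `step`, `processed` (length of
#'   the list consumed), `live` (cells after the step), and
#'   `cum_processed`.
#' @examples
#' out <- run_simulation(init_state(32, 32, seed = 1), 50)
#' tail(out$metrics, 3)
#' @export
run_simulation <- function(state, n_steps, hooks = NULL) {
  stopifnot(inherits(state, "tumor_state"), n_steps >= 0L)
  n_steps <- as.integer(n_steps)
  if (n_steps == 0L)
    return(list(state = state, metrics = empty_metrics()))
  if (is.null(hooks)) {
    res <- cpp_run(state$lattice, state$cells, as_params_list(state$params), n_steps)
    state$lattice <- res$lattice
    state$cells <- res$cells
    first <- state$step + 1L
    state$step <- state$step + n_steps
    metrics <- data.frame(step = seq(first, length.out = n_steps),
                          processed = res$metrics[, "processed"],
                          live = res$metrics[, "live"])
  } else {
    processed <- live <- integer(n_steps)
    first <- state$step + 1L
    for (i in seq_len(n_steps)) {
      processed[i] <- nrow(state$cells)
      state <- step_sequential(state)
      live[i] <- nrow(state$cells)
      hooks(state)
    }
    metrics <- data.frame(step = seq(first, length.out = n_steps),
                          processed = processed, live = live)
  }
  metrics$cum_processed <- cumsum(as.numeric(metrics$processed))
  list(state = state, metrics = metrics)
}

empty_metrics <- function() {
  data.frame(step = integer(), processed = integer(), live = integer(),
             cum_processed = numeric())
}
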