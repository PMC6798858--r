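#' Construct a cell record
#'
#' A tumor cell is its lattice position plus its accumulated
#' proliferation-signal counter `PH`. Coordinates are 1-based; row 1 is
#' the topmost lattice row.
#'
#' @param row,col Lattice position (1-based integers).
#' @param ph Accumulated proliferation signals (non-negative integer).
#' @return A named integer vector `c(row, col, ph)`.
#' @export
cell_record <- function(row, col, ph = 0L) {
  stopifnot(length(row) == 1L, length(col) == 1L, length(ph) == 1L, ph >= 0L)
  c(row = as.integer(row), col = as.integer(col), ph = as.integer(ph))
}

cells_matrix <- function(row = integer(), col = integer(), ph = integer()) {
  m <- cbind(row = as.integer(row), col = as.integer(col), ph = as.integer(ph))
  storage.mode(m) <- "integer"
  m
}

#' Evaluate the stochastic fate of one cell
#'
#' Applies the per-cell transition rule once, against the current lattice,
#' without mutating it. One uniform draw `rr` partitions the outcome:
#' `rr >= p_survive` is death; `rr < p_signal` delivers a proliferation
#' signal (`PH` is incremented, and if `PH >= NP` the 4 axial — or 8
#' Moore — neighbor sites are scanned in RNG-shuffled order for an empty
#' division target); otherwise a second draw against `p_migrate` decides
#' a migration attempt with the same scan rule. A cell whose attempt
#' finds no empty site stays quiescent. `PH` is reset to 0 when a
#' `"proliferate"` fate is returned. Out-of-bounds sites count as
#' occupied. Draws come from R's global RNG (`set.seed()` reproducible).
#'
#' @param cell A cell record, see [cell_record()]. Its site must be
#'   occupied in `lattice`.
#' @param lattice Integer 0/1 occupancy matrix.
#' @param params A [model_params()] object.
#' @return A list with elements `kind` (one of `"die"`, `"quiescent"`,
#'   `"proliferate"`, `"migrate"`), `target` (`c(row, col)` for
#'   proliferate/migrate, otherwise `NULL`), and `cell` (the record with
#'   its updated `PH`).
#' @examples
#' set.seed(1)
#' lat <- matrix(0L, 9, 9); lat[5, 5] <- 1L
#' evaluate_cell(cell_record(5, 5, 1), lat, model_params())
#' @export
evaluate_cell <- function(cell, lattice, params) {
  params <- validate_params(params)
  res <- cpp_evaluate_cell(cell[["row"]], cell[["col"]], cell[["ph"]],
                           lattice, as_params_list(params))
  kind <- FATE_LEVELS[res$kind + 1L]
  target <- if (length(res$target_row))
    c(row = res$target_row[1L], col = res$target_col[1L]) else NULL
  list(kind = kind, target = target,
       cell = cell_record(cell[["row"]], cell[["col"]], res$ph))
}

#' Apply a fate to the lattice
#'
#' Writes one evaluated fate into a copy of the lattice. Because updates
#' within a step are in place, a division or migration target chosen as
#' empty at evaluation time may meanwhile be occupied; the cell then
#' stays quiescent for this step. A successful division places a
#' daughter with `PH = ph_init` at the target and returns parent and
#' daughter; death clears the site and returns no record.
#'
#' @param cell The evaluated cell record (with `PH` as returned by
#'   [evaluate_cell()]).
#' @param fate The fate list returned by [evaluate_cell()].
#' @param lattice Integer 0/1 occupancy matrix the fate was evaluated
#'   against (possibly updated in the meantime by earlier cells).
#' @param params A [model_params()] object (supplies `ph_init` for
#'   daughters).
#' @return A list with `cells` (matrix of 0, 1 or 2 surviving records)
#'   and `lattice` (the updated copy).
#' @export
apply_fate <- function(cell, fate, lattice, params) {
  params <- validate_params(params)
  kind <- match(fate$kind, FATE_LEVELS) - 1L
  if (is.na(kind)) stop("unknown fate kind: ", fate$kind, call. = FALSE)
  tr <- if (is.null(fate$target)) integer() else as.integer(fate$target[["row"]])
  tc <- if (is.null(fate$target)) integer() else as.integer(fate$target[["col"]])
  cpp_apply_fate(cell[["row"]], cell[["col"]], cell[["ph"]], kind, tr, tc,
                 lattice, as_params_list(params))
}

#' Empirical fate frequencies for an isolated cell
#'
#' Evaluates a lone cell with an entirely empty neighborhood `n` times
#' (fresh `PH = ph_init` each time) and tallies the four fates. Used to
#' check the rule's fate distribution against its analytic values.
#'
#' @param params A [model_params()] object.
#' @param n Number of independent evaluations.
#' @return Named integer vector of counts over
#'   `DIE`/`QUIESCENT`/`PROLIFERATE`/`MIGRATE`.
#' @export
tally_fates <- function(params, n) {
  cpp_tally_fates(as_params_list(validate_params(params)), as.integer(n))
}
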