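#' Model parameters for the tumor-growth automaton
#'
#' Bundles the transition probabilities and counters of the stochastic
#' per-cell rule. A single uniform draw `rr` per cell partitions fate:
#' `rr >= p_survive` kills the cell; `rr < p_signal` delivers a
#' proliferation signal (the cell divides once it has accumulated
#' `np_threshold` signals and a neighboring site is free); otherwise a
#' second draw against `p_migrate` decides whether the cell attempts to
#' migrate. Defaults are the reference parameter set of the model
#' (fast, compact growth).
#'
#' @param p_survive Probability a cell survives the step, in `[0, 1]`.
#'   Death probability is `1 - p_survive`.
#' @param p_signal Probability the cell receives a proliferation signal,
#'   in `[0, 1]`. Must not exceed `p_survive` for the three branches of
#'   the single-draw rule to be disjoint.
#' @param p_migrate Probability a surviving, non-signaled cell attempts
#'   migration, in `[0, 1]`.
#' @param np_threshold `NP`, number of accumulated signals required
#'   before a proliferation attempt; positive integer.
#' @param ph_init Initial `PH` signal counter of seed cells and
#'   newborn daughters; non-negative integer.
#' @param delta Maximum per-step displacement of any cell, in rows or
#'   columns (Chebyshev distance); positive integer. With the default
#'   nearest-neighbor rule every move has length 1, but `delta` also
#'   sets the minimum subregion height of the parallel decomposition.
#' @param neighborhood Candidate target sites for division/migration:
#'   `"von_neumann"` (4 axial neighbors, default) or `"moore"`
#'   (8 neighbors).
#'
#' @return An object of class `tumor_params` (a validated list).
#' @examples
#' p <- model_params()
#' p$p_survive
#' @export
model_params <- function(p_survive = 0.8, p_signal = 0.2, p_migrate = 0.25,
                         np_threshold = 1L, ph_init = 1L, delta = 1L,
                         neighborhood = c("von_neumann", "moore")) {
  neighborhood <- match.arg(neighborhood)
  p <- structure(
    list(p_survive = as.numeric(p_survive),
         p_signal = as.numeric(p_signal),
         p_migrate = as.numeric(p_migrate),
         np_threshold = as.integer(np_threshold),
         ph_init = as.integer(ph_init),
         delta = as.integer(delta),
         neighborhood = neighborhood),
    class = "tumor_params")
  validate_params(p)
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("Tumor CA parameters\n")
  cat(sprintf("  survive %.3g | signal %.3g | migrate %.3g\n",
              x$p_survive, x$p_signal, x$p_migrate))
  cat(sprintf("  NP = %d, initial PH = %d, delta = %d, %s neighborhood\n",
              x$np_threshold, x$ph_init, x$delta, x$neighborhood))
  invisible(x)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "tumor_params"))
  for (f in c("p_survive", "p_signal", "p_migrate")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a single probability in [0, 1]", f), call. = FALSE)
  }
  if (is.na(p$np_threshold) || p$np_threshold < 1L)
    stop("`np_threshold` must be a positive integer", call. = FALSE)
  if (is.na(p$ph_init) || p$ph_init < 0L)
    stop("`ph_init` must be a non-negative integer", call. = FALSE)
  if (is.na(p$delta) || p$delta < 1L)
    stop("`delta` must be a positive integer", call. = FALSE)
  p
}

as_params_list <- function(p) {
  p <- validate_params(p)
  unclass(p)
}
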