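# Region/seam geometry for the parallel engine.
#
# The lattice is cut into t horizontal regions, one per worker. Each
# region splits into a top seam part, a center, and a bottom seam part
# (the first region has no top part, the last no bottom part). Row bands
# are half-open [start, end) on 1-based rows; an empty part has
# start == end. Seam s (s = 1..t-1) is region s's bottom part plus
# region s+1's top part. Every existing part is at least `delta` rows
# high — delta being the longest per-step displacement of a cell — which
# puts >= 2*delta rows of other-type parts between any two same-type
# parts and makes the phase-ordered update write-disjoint.

#' Build the initial partition
#'
#' Places the `t - 1` internal region boundaries evenly inside a band of
#' height `H0 = max(tumor_row_max - tumor_row_min, 3 * delta * t)`
#' centered on the initial tumor mass, so that equal numbers of regions
#' lie above and below it; the first region is then extended up to row 1
#' and the last down to the last lattice row. Each seam part starts
#' `delta` rows thick.
#'
#' @param tumor_row_min,tumor_row_max Topmost / bottommost occupied rows
#'   of the initial tumor (1-based).
#' @param n_workers Number of regions / workers `t` (>= 1).
#' @param delta Maximum per-step displacement; minimum part height.
#' @param n_rows Lattice height; must be at least `3 * delta * n_workers`.
#' @param rho Imbalance threshold, percent: a seam move starts when the
#'   relative difference between adjacent regions' cell counts exceeds
#'   `rho`.
#' @return An object of class `tumor_partition`: regions with their part
#'   bands and per-subregion cell lists, plus the active seam moves.
#' @examples
#' p <- initial_partition(50, 50, n_workers = 2, delta = 1, n_rows = 100)
#' region_spans(p)
#' @export
initial_partition <- function(tumor_row_min, tumor_row_max, n_workers,
                              delta, n_rows, rho = 10) {
  t <- as.integer(n_workers)
  delta <- as.integer(delta)
  n_rows <- as.integer(n_rows)
  stopifnot(t >= 1L, delta >= 1L, rho >= 0)
  if (n_rows < 3L * delta * t)
    stop(sprintf("lattice height %d cannot hold %d regions of minimum height %d (3*delta)",
                 n_rows, t, 3L * delta), call. = FALSE)
  tumor_row_min <- as.integer(tumor_row_min)
  tumor_row_max <- as.integer(tumor_row_max)
  stopifnot(tumor_row_min >= 1L, tumor_row_max <= n_rows,
            tumor_row_min <= tumor_row_max)

  if (t == 1L) {
    boundaries <- c(1L, n_rows + 1L)
  } else {
    h0 <- max(tumor_row_max - tumor_row_min, 3L * delta * t)
    center <- (tumor_row_min + tumor_row_max) %/% 2L
    band_start <- min(max(center - h0 %/% 2L, 1L), n_rows + 1L - h0)
    heights <- rep(h0 %/% t, t) + c(rep(1L, h0 %% t), rep(0L, t - h0 %% t))
    boundaries <- band_start + c(0L, cumsum(heights))
    boundaries[1L] <- 1L            # first region starts at the first row
    boundaries[t + 1L] <- n_rows + 1L  # last region ends at the last row
  }

  regions <- vector("list", t)
  for (i in seq_len(t)) {
    s <- boundaries[i]; e <- boundaries[i + 1L]
    top <- if (i > 1L) c(s, s + delta) else c(s, s)
    bottom <- if (i < t) c(e - delta, e) else c(e, e)
    regions[[i]] <- list(top = top, center = c(top[2L], bottom[1L]), bottom = bottom)
    if (regions[[i]]$center[2L] - regions[[i]]$center[1L] < delta)
      stop("initial region ", i, " has a center thinner than delta", call. = FALSE)
  }
  lists <- replicate(t, list(top = cells_matrix(), center = cells_matrix(),
                             bottom = cells_matrix()), simplify = FALSE)
  structure(list(regions = regions, lists = lists, n_rows = n_rows,
                 delta = delta, rho = as.numeric(rho), moves = list()),
            class = "tumor_partition")
}

#' @export
print.tumor_partition <- function(x, ...) {
  t <- length(x$regions)
  cat(sprintf("Tumor lattice partition: %d region(s) over %d rows, delta = %d, rho = %g%%\n",
              t, x$n_rows, x$delta, x$rho))
  sp <- region_spans(x)
  for (i in seq_len(t)) {
    r <- x$regions[[i]]
    cat(sprintf("  region %d rows [%d, %d): top %s center %s bottom %s\n",
                i, sp[i, 1L], sp[i, 2L], fmt_band(r$top), fmt_band(r$center),
                fmt_band(r$bottom)))
  }
  if (length(x$moves))
    for (m in x$moves)
      cat(sprintf("  active move: seam %d, shrinking region %d, phase %d\n",
                  m$seam, m$shrink, m$phase))
  invisible(x)
}

fmt_band <- function(b) {
  if (b[2L] <= b[1L]) "-" else sprintf("[%d,%d)", b[1L], b[2L])
}

#' Row span of each region
#'
#' @param partition A `tumor_partition`.
#' @return Integer matrix with columns `start`, `end` (half-open row
#'   bands), one row per region.
#' @export
region_spans <- function(partition) {
  t(vapply(partition$regions, function(r) {
    s <- if (r$top[2L] > r$top[1L]) r$top[1L] else r$center[1L]
    e <- if (r$bottom[2L] > r$bottom[1L]) r$bottom[2L] else r$center[2L]
    c(start = s, end = e)
  }, integer(2L)))
}

#' Seam boundary rows
#'
#' @param partition A `tumor_partition`.
#' @return Integer vector: for each seam, the first row of the lower
#'   region (length `t - 1`).
#' @export
seam_rows <- function(partition) {
  sp <- region_spans(partition)
  if (nrow(sp) < 2L) return(integer())
  sp[-1L, "start"]
}

#' Count live cells per region
#'
#' Counts are taken from the lattice census over each region's current
#' row span, not from the (possibly stale) subregion lists.
#'
#' @param partition A `tumor_partition`.
#' @param lattice Integer 0/1 occupancy matrix.
#' @return Integer vector of per-region live-cell counts.
#' @export
region_counts <- function(partition, lattice) {
  rc <- as.integer(rowSums(lattice))
  sp <- region_spans(partition)
  vapply(seq_len(nrow(sp)), function(i) {
    rows <- seq.int(sp[i, 1L], sp[i, 2L] - 1L)
    sum(rc[rows])
  }, integer(1L))
}

#' Decide which seam moves to start
#'
#' For each adjacent region pair the relative imbalance is
#' `100 * |c_i - c_{i+1}| / max(c_i, c_{i+1}, 1)` percent. Pairs above
#' the partition's threshold `rho` become candidate moves shrinking the
#' larger region. Candidates are taken in decreasing order of imbalance
#' (ties: lower seam first) and dropped when they touch a seam that is
#' active, adjacent to an active seam, or adjacent to an
#' already-selected one — two consecutive seams are never adjusted
#' together. A candidate whose shrinking region's center could not give
#' up `delta` rows and stay at least `delta` high is dropped too.
#'
#' @param partition A `tumor_partition`.
#' @param counts Per-region live-cell counts, as from [region_counts()].
#' @return List of seam moves (`seam`, `shrink` = region index to
#'   shrink, `phase = 0`), possibly empty. The moves are not yet applied;
#'   see [start_seam_moves()].
#' @export
needs_adjustment <- function(partition, counts) {
  t <- length(partition$regions)
  stopifnot(length(counts) == t)
  if (t < 2L) return(list())
  active <- vapply(partition$moves, `[[`, integer(1L), "seam")
  blocked <- unique(c(active, active - 1L, active + 1L))
  cand <- list()
  for (s in seq_len(t - 1L)) {
    a <- counts[s]; b <- counts[s + 1L]
    imb <- 100 * abs(a - b) / max(a, b, 1)
    if (imb > partition$rho)
      cand[[length(cand) + 1L]] <- list(seam = s, shrink = if (a > b) s else s + 1L,
                                        imbalance = imb)
  }
  if (!length(cand)) return(list())
  ord <- order(-vapply(cand, `[[`, numeric(1L), "imbalance"),
               vapply(cand, `[[`, integer(1L), "seam"))
  chosen <- list()
  taken <- integer()
  for (m in cand[ord]) {
    if (m$seam %in% blocked) next
    if (any(abs(taken - m$seam) <= 1L)) next
    ctr <- partition$regions[[m$shrink]]$center
    if (ctr[2L] - ctr[1L] < 2L * partition$delta) next
    chosen[[length(chosen) + 1L]] <- list(seam = m$seam, shrink = m$shrink,
                                          phase = 0L)
    taken <- c(taken, m$seam)
  }
  chosen
}

#' Register freshly started seam moves
#'
#' @param partition A `tumor_partition`.
#' @param moves Moves from [needs_adjustment()].
#' @return The partition with the moves added (still at phase 0; their
#'   first geometry change happens at the next [advance_seam_moves()]).
#' @export
start_seam_moves <- function(partition, moves) {
  partition$moves <- c(partition$moves, moves)
  partition
}

#' Advance every active seam move by one phase
#'
#' The three-phase displacement protocol shifts a region boundary by
#' `delta` rows without ever letting two workers write one subregion
#' list in the same phase:
#' phase 1 — the seam part on the shrinking side absorbs `delta` rows
#' from the shrinking region's center (that part is now `2*delta`
#' thick); phase 2 — those rows are handed across the boundary to the
#' other seam part (the boundary moves; total seam thickness is
#' conserved); phase 3 — the enlarged part releases `delta` rows into
#' the growing region's center, returning all parts to thickness
#' `delta`. Completed moves are removed. A move whose phase-1 shrink
#' would leave the center thinner than `delta` is aborted with the
#' geometry untouched. Subregion cell lists are NOT reassigned here;
#' stale membership is reconciled lazily when cells are next processed.
#'
#' @param partition A `tumor_partition`.
#' @return A list with `partition` (updated) and `completed` (number of
#'   moves that finished this call).
#' @export
advance_seam_moves <- function(partition) {
  keep <- list()
  completed <- 0L
  d <- partition$delta
  for (m in partition$moves) {
    m$phase <- m$phase + 1L
    upper <- m$shrink == m$seam  # shrinking the region above the seam?
    i <- m$seam; j <- m$seam + 1L
    if (m$phase == 1L) {
      ctr <- partition$regions[[m$shrink]]$center
      if (ctr[2L] - ctr[1L] < 2L * d) next  # abort; geometry untouched
      if (upper) {
        partition$regions[[i]]$bottom[1L] <- partition$regions[[i]]$bottom[1L] - d
        partition$regions[[i]]$center[2L] <- partition$regions[[i]]$center[2L] - d
      } else {
        partition$regions[[j]]$top[2L] <- partition$regions[[j]]$top[2L] + d
        partition$regions[[j]]$center[1L] <- partition$regions[[j]]$center[1L] + d
      }
      keep[[length(keep) + 1L]] <- m
    } else if (m$phase == 2L) {
      if (upper) {
        partition$regions[[i]]$bottom[2L] <- partition$regions[[i]]$bottom[2L] - d
        partition$regions[[j]]$top[1L] <- partition$regions[[j]]$top[1L] - d
      } else {
        partition$regions[[j]]$top[1L] <- partition$regions[[j]]$top[1L] + d
        partition$regions[[i]]$bottom[2L] <- partition$regions[[i]]$bottom[2L] + d
      }
      keep[[length(keep) + 1L]] <- m
    } else {
      if (upper) {
        partition$regions[[j]]$top[2L] <- partition$regions[[j]]$top[2L] - d
        partition$regions[[j]]$center[1L] <- partition$regions[[j]]$center[1L] - d
      } else {
        partition$regions[[i]]$bottom[1L] <- partition$regions[[i]]$bottom[1L] + d
        partition$regions[[i]]$center[2L] <- partition$regions[[i]]$center[2L] + d
      }
      completed <- completed + 1L
    }
  }
  partition$moves <- keep
  list(partition = partition, completed = completed)
}

#' Check all partition invariants
#'
#' Verifies: the parts tile every lattice row exactly once in order;
#' every existing center is at least `delta` high; every existing seam
#' part is `delta` or `2*delta` high, `2*delta` only while a move on
#' that seam is mid-flight; border regions lack their outward seam
#' parts; no two adjacent seams have simultaneously active moves; and
#' any two same-type parts are separated by at least `2*delta` rows.
#'
#' @param partition A `tumor_partition`.
#' @return `TRUE` invisibly, or an error describing the violated
#'   invariant.
#' @export
validate_partition <- function(partition) {
  t <- length(partition$regions)
  d <- partition$delta
  fail <- function(...) stop(sprintf(...), call. = FALSE)
  cover <- integer(0)
  active_seams <- vapply(partition$moves, `[[`, integer(1L), "seam")
  if (anyDuplicated(active_seams))
    fail("more than one active move on one seam")
  if (length(active_seams) > 1L && min(diff(sort(active_seams))) < 2L)
    fail("two adjacent seams have active moves")
  part_rows <- list(top = integer(), center = integer(), bottom = integer())
  for (i in seq_len(t)) {
    r <- partition$regions[[i]]
    for (nm in c("top", "center", "bottom")) {
      b <- r[[nm]]
      h <- b[2L] - b[1L]
      if (h < 0L) fail("region %d %s band is inverted", i, nm)
      if (h > 0L) {
        cover <- c(cover, seq.int(b[1L], b[2L] - 1L))
        part_rows[[nm]] <- c(part_rows[[nm]], seq.int(b[1L], b[2L] - 1L))
      }
      if (nm == "center" && h < d) fail("region %d center thinner than delta", i)
      if (nm != "center" && h > 0L && h != d && h != 2L * d)
        fail("region %d %s seam part height %d not in {delta, 2*delta}", i, nm, h)
      if (nm != "center" && h == 2L * d) {
        seam <- if (nm == "bottom") i else i - 1L
        if (!seam %in% active_seams)
          fail("region %d %s part is 2*delta thick with no active move", i, nm)
      }
    }
    if (i == 1L && r$top[2L] > r$top[1L]) fail("first region has a top seam part")
    if (i == t && r$bottom[2L] > r$bottom[1L]) fail("last region has a bottom seam part")
    if (i > 1L && i < t && (r$top[2L] == r$top[1L] || r$bottom[2L] == r$bottom[1L]))
      fail("interior region %d is missing a seam part", i)
  }
  if (!identical(sort(cover), seq_len(partition$n_rows)))
    fail("region parts do not tile the lattice rows exactly once")
  # same-type parts separated by >= 2*delta rows of other-type parts
  for (nm in c("top", "center", "bottom")) {
    rows <- sort(part_rows[[nm]])
    if (length(rows) > 1L) {
      gaps <- diff(rows)
      if (any(gaps > 1L & gaps < 2L * d + 1L))
        fail("two %s parts are closer than 2*delta rows", nm)
    }
  }
  invisible(TRUE)
}
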