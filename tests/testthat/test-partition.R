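test_that("a single worker owns the whole lattice with no seams", {
  p <- initial_partition(50, 50, 1, 1, 100)
  expect_identical(length(p$regions), 1L)
  expect_identical(p$regions[[1]]$center, c(1L, 101L))
  expect_identical(seam_rows(p), integer())
  validate_partition(p)
})

test_that("a thin seed mass is widened to the 3*delta*t minimum band", {
  # tumor height 5 < 3*1*4 = 12: internal boundaries must span a 12-row band
  p <- initial_partition(48, 53, 4, 1, 100)
  sp <- region_spans(p)
  internal <- sp[2:4, "start"]
  expect_identical(diff(internal), c(3L, 3L))       # three rows per region
  expect_identical(internal[3] - internal[1], 6L)   # interior of the 12-row band
  # band centered on the seed mass: equal regions above and below its center
  expect_true(internal[1] <= 50 && internal[3] >= 50)
  validate_partition(p)

  # delta scales the band: t = 2, delta = 3 -> 18-row minimum
  p2 <- initial_partition(30, 30, 2, 3, 60)
  sp2 <- region_spans(p2)
  expect_identical(as.integer(sp2[2, "start"] - max(30 - 9, 1)), 9L)
  validate_partition(p2)

  expect_error(initial_partition(5, 5, 4, 1, 11), "cannot hold")
})

test_that("two workers split at the tumor center with delta-thick seams", {
  p <- initial_partition(50, 50, 2, 1, 100)
  expect_identical(unname(seam_rows(p)), 50L)
  expect_identical(p$regions[[1]]$bottom, c(49L, 50L))
  expect_identical(p$regions[[2]]$top, c(50L, 51L))
  expect_identical(p$regions[[1]]$top, c(1L, 1L))      # border regions lack
  expect_identical(p$regions[[2]]$bottom, c(101L, 101L))  # outward seam parts
  validate_partition(p)
})

test_that("region counts come from the lattice census and sum to the total", {
  p <- initial_partition(50, 50, 3, 1, 90)
  lat <- matrix(0L, 90, 40)
  expect_identical(region_counts(p, lat), c(0L, 0L, 0L))
  lat[1:10, 1:3] <- 1L  # all inside region 1
  expect_identical(region_counts(p, lat), c(30L, 0L, 0L))
  set.seed(9)
  lat <- matrix(rbinom(90 * 40, 1, 0.2), 90, 40)
  expect_identical(sum(region_counts(p, lat)), sum(lat))
})

test_that("imbalance detection follows the relative-difference rule", {
  p <- initial_partition(50, 50, 2, 1, 100)
  expect_identical(needs_adjustment(p, c(100, 100)), list())
  expect_identical(needs_adjustment(p, c(100, 108)), list())  # 7.4% < 10%
  m <- needs_adjustment(p, c(100, 125))  # 25/125 = 20% > 10%
  expect_identical(length(m), 1L)
  expect_identical(m[[1]]$seam, 1L)
  expect_identical(m[[1]]$shrink, 2L)

  # empty regions: max(c_i, c_{i+1}, 1) keeps the ratio defined
  expect_identical(needs_adjustment(p, c(0, 0)), list())
  m0 <- needs_adjustment(p, c(0, 5))
  expect_identical(m0[[1]]$shrink, 2L)
})

test_that("adjacent seams are never adjusted together", {
  p <- initial_partition(30, 90, 3, 1, 120)  # roomy centers
  # both pairs at 33.3%: only one move may start; tie broken to seam 1
  m <- needs_adjustment(p, c(100, 150, 100))
  expect_identical(length(m), 1L)
  expect_identical(m[[1]]$seam, 1L)
  expect_identical(m[[1]]$shrink, 2L)

  # an active move blocks its own and neighboring seams
  p2 <- start_seam_moves(p, m)
  expect_identical(needs_adjustment(p2, c(100, 150, 100)), list())

  # four regions: seams 1 and 3 are not adjacent and may move together
  p4 <- initial_partition(20, 140, 4, 1, 160)
  m4 <- needs_adjustment(p4, c(100, 200, 100, 200))
  expect_identical(vapply(m4, `[[`, integer(1), "seam"), c(1L, 3L))
})

test_that("a move that would starve a center below delta is never started", {
  # interior regions of a minimum-height band have delta-thick centers
  p <- initial_partition(5, 5, 3, 1, 9)
  ctr <- p$regions[[2]]$center
  expect_identical(ctr[2] - ctr[1], 1L)
  expect_identical(needs_adjustment(p, c(0, 100, 0)), list())
  # but a border region with slack may still shrink
  m <- needs_adjustment(p, c(100, 0, 0))
  expect_identical(length(m), 1L)
  expect_identical(m[[1]]$shrink, 1L)
})

test_that("the three-phase protocol transfers exactly delta rows", {
  for (delta in c(1L, 2L)) {
    p <- initial_partition(20, 20, 2, delta, 40)
    b0 <- unname(seam_rows(p))
    p <- start_seam_moves(p, list(list(seam = 1L, shrink = 1L, phase = 0L)))
    heights <- function(q) vapply(q$regions, function(r)
      c(r$top[2] - r$top[1], r$center[2] - r$center[1],
        r$bottom[2] - r$bottom[1]), integer(3))

    a <- advance_seam_moves(p); p <- a$partition   # phase 1
    validate_partition(p)
    expect_identical(a$completed, 0L)
    expect_identical(unname(heights(p)[3, 1]), 2L * delta)  # shrink-side seam part doubled
    expect_identical(unname(seam_rows(p)), b0)              # boundary not yet moved

    a <- advance_seam_moves(p); p <- a$partition   # phase 2
    validate_partition(p)
    expect_identical(unname(seam_rows(p)), b0 - delta)      # boundary handed over
    expect_identical(unname(heights(p)[1, 2]), 2L * delta)

    a <- advance_seam_moves(p); p <- a$partition   # phase 3
    validate_partition(p)
    expect_identical(a$completed, 1L)
    expect_identical(length(p$moves), 0L)
    expect_identical(unname(seam_rows(p)), b0 - delta)
    expect_true(all(heights(p)[c(1, 3), ] %in% c(0L, delta)))
  }
})

test_that("non-adjacent moves advance independently", {
  p <- initial_partition(60, 60, 4, 1, 160)
  b0 <- unname(seam_rows(p))
  p <- start_seam_moves(p, list(list(seam = 1L, shrink = 1L, phase = 0L),
                                list(seam = 3L, shrink = 4L, phase = 0L)))
  for (k in 1:3) {
    a <- advance_seam_moves(p); p <- a$partition
    validate_partition(p)
  }
  expect_identical(unname(seam_rows(p)), c(b0[1] - 1L, b0[2], b0[3] + 1L))
})

test_that("an infeasible move aborts with the geometry untouched", {
  p <- initial_partition(3, 3, 2, 1, 6)
  # shrink region 1 once: its center drops to the delta minimum
  p <- start_seam_moves(p, list(list(seam = 1L, shrink = 1L, phase = 0L)))
  for (k in 1:3) p <- advance_seam_moves(p)$partition
  expect_identical(p$regions[[1]]$center[2] - p$regions[[1]]$center[1], 1L)
  spans <- region_spans(p)
  # a second shrink of region 1 must abort at phase 1
  p <- start_seam_moves(p, list(list(seam = 1L, shrink = 1L, phase = 0L)))
  a <- advance_seam_moves(p)
  expect_identical(a$completed, 0L)
  expect_identical(length(a$partition$moves), 0L)
  expect_identical(region_spans(a$partition), spans)
  validate_partition(a$partition)
})

test_that("randomized partitions keep all invariants through move walks", {
  completed <- vapply(1:100, partition_walk, integer(1), n_steps = 10)
  expect_gt(sum(completed), 50)  # the walk genuinely exercised seam moves
})
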