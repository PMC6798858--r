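test_that("parameter objects validate their fields", {
  expect_s3_class(model_params(), "tumor_params")
  expect_error(model_params(p_survive = 1.2), "p_survive")
  expect_error(model_params(p_signal = -0.1), "p_signal")
  expect_error(model_params(np_threshold = 0), "np_threshold")
  expect_error(model_params(delta = 0), "delta")
  expect_error(model_params(ph_init = -1), "ph_init")
})

one_cell_lattice <- function(n = 9, at = c(5, 5)) {
  lat <- matrix(0L, n, n)
  lat[at[1], at[2]] <- 1L
  lat
}

test_that("degenerate probabilities force their fate branch", {
  lat <- one_cell_lattice()
  cell <- cell_record(5, 5, 1)
  set.seed(1)
  for (k in 1:20)
    expect_identical(evaluate_cell(cell, lat, model_params(p_survive = 0))$kind, "die")
  p_div <- model_params(p_survive = 1, p_signal = 1)
  for (k in 1:20) {
    f <- evaluate_cell(cell, lat, p_div)
    expect_identical(f$kind, "proliferate")
    # axial target at Chebyshev distance 1
    expect_true(sum(abs(f$target - c(5, 5))) == 1)
    expect_identical(f$cell[["ph"]], 0L)  # PH reset on division
  }
  p_mig <- model_params(p_survive = 1, p_signal = 0, p_migrate = 1)
  for (k in 1:20) {
    f <- evaluate_cell(cell, lat, p_mig)
    expect_identical(f$kind, "migrate")
    expect_true(max(abs(f$target - c(5, 5))) <= p_mig$delta)
  }
})

test_that("a fully enclosed cell cannot divide or migrate", {
  lat <- matrix(1L, 3, 3)
  cell <- cell_record(2, 2, 1)
  set.seed(2)
  f <- evaluate_cell(cell, lat, model_params(p_survive = 1, p_signal = 1))
  expect_identical(f$kind, "quiescent")
  f <- evaluate_cell(cell, lat, model_params(p_survive = 1, p_signal = 0, p_migrate = 1))
  expect_identical(f$kind, "quiescent")
})

test_that("out-of-bounds sites are treated as occupied", {
  lat <- matrix(0L, 3, 3)
  lat[1, 1] <- 1L
  set.seed(3)
  for (k in 1:30) {
    f <- evaluate_cell(cell_record(1, 1, 1), lat,
                       model_params(p_survive = 1, p_signal = 1))
    expect_true(identical(unname(f$target), c(1L, 2L)) ||
                identical(unname(f$target), c(2L, 1L)))
  }
  # corner with both in-bounds neighbors occupied: nothing left
  lat[1, 2] <- lat[2, 1] <- 1L
  f <- evaluate_cell(cell_record(1, 1, 1), lat,
                     model_params(p_survive = 1, p_signal = 1))
  expect_identical(f$kind, "quiescent")
})

test_that("the Moore option widens the target set to diagonals", {
  lat <- matrix(1L, 3, 3)
  lat[1, 1] <- 0L  # only the diagonal neighbor of (2,2) is free
  set.seed(4)
  f4 <- evaluate_cell(cell_record(2, 2, 1), lat,
                      model_params(p_survive = 1, p_signal = 1))
  expect_identical(f4$kind, "quiescent")
  f8 <- evaluate_cell(cell_record(2, 2, 1), lat,
                      model_params(p_survive = 1, p_signal = 1,
                                   neighborhood = "moore"))
  expect_identical(f8$kind, "proliferate")
  expect_identical(unname(f8$target), c(1L, 1L))
})

test_that("PH accumulates signals and gates division at NP", {
  lat <- one_cell_lattice()
  p <- model_params(p_survive = 1, p_signal = 1, np_threshold = 3L, ph_init = 0L)
  set.seed(5)
  f1 <- evaluate_cell(cell_record(5, 5, 0), lat, p)
  expect_identical(f1$kind, "quiescent")
  expect_identical(f1$cell[["ph"]], 1L)
  f2 <- evaluate_cell(f1$cell, lat, p)
  expect_identical(f2$kind, "quiescent")
  expect_identical(f2$cell[["ph"]], 2L)
  f3 <- evaluate_cell(f2$cell, lat, p)  # third signal reaches NP
  expect_identical(f3$kind, "proliferate")
  expect_identical(f3$cell[["ph"]], 0L)
})

test_that("evaluate_cell rejects contract violations", {
  lat <- one_cell_lattice()
  expect_error(evaluate_cell(cell_record(99, 5, 0), lat, model_params()),
               "outside")
  expect_error(evaluate_cell(cell_record(1, 1, 0), lat, model_params()),
               "empty")
})

test_that("apply_fate writes each fate and conserves occupancy", {
  p <- model_params()
  lat <- one_cell_lattice()
  cell <- cell_record(5, 5, 2)

  res <- apply_fate(cell, list(kind = "die", target = NULL), lat, p)
  expect_identical(sum(res$lattice), 0L)
  expect_identical(nrow(res$cells), 0L)

  res <- apply_fate(cell, list(kind = "quiescent", target = NULL), lat, p)
  expect_identical(res$lattice, lat)
  expect_identical(res$cells[1, ], c(row = 5L, col = 5L, ph = 2L))

  res <- apply_fate(cell, list(kind = "migrate", target = c(row = 5, col = 6)), lat, p)
  expect_identical(res$lattice[5, 5], 0L)
  expect_identical(res$lattice[5, 6], 1L)
  expect_identical(res$cells[1, ], c(row = 5L, col = 6L, ph = 2L))

  res <- apply_fate(cell, list(kind = "proliferate", target = c(row = 4, col = 5)), lat, p)
  expect_identical(sum(res$lattice), sum(lat) + 1L)
  expect_identical(nrow(res$cells), 2L)
  expect_identical(res$cells[2, ], c(row = 4L, col = 5L, ph = p$ph_init))

  # a meanwhile-occupied target degrades to quiescence
  lat2 <- lat; lat2[5, 6] <- 1L
  res <- apply_fate(cell, list(kind = "migrate", target = c(row = 5, col = 6)), lat2, p)
  expect_identical(res$lattice, lat2)
  expect_identical(res$cells[1, ], c(row = 5L, col = 5L, ph = 2L))
  res <- apply_fate(cell, list(kind = "proliferate", target = c(row = 5, col = 6)), lat2, p)
  expect_identical(res$lattice, lat2)
  expect_identical(nrow(res$cells), 1L)
})

test_that("empirical fate frequencies match the analytic partition", {
  # single draw rr: die on [p_survive, 1), signal on [0, p_signal) with a
  # free site guaranteeing division, else migrate with p_migrate
  set.seed(6)
  n <- 2e5
  freq <- tally_fates(table1_params(), n) / n
  expect_lt(abs(freq[["DIE"]] - 0.20), 0.01)
  expect_lt(abs(freq[["PROLIFERATE"]] - 0.20), 0.01)
  expect_lt(abs(freq[["MIGRATE"]] - 0.15), 0.01)
  expect_lt(abs(freq[["QUIESCENT"]] - 0.45), 0.01)

  # and for a non-default parameter point
  p <- model_params(p_survive = 0.9, p_signal = 0.3, p_migrate = 0.5)
  freq <- tally_fates(p, n) / n
  expect_lt(abs(freq[["DIE"]] - 0.10), 0.01)
  expect_lt(abs(freq[["PROLIFERATE"]] - 0.30), 0.01)
  expect_lt(abs(freq[["MIGRATE"]] - 0.30), 0.01)  # (0.9 - 0.3) * 0.5
})
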