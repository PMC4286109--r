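test_that("complete_sw builds the lower-triangular wedge", {
  d <- complete_sw(2, 1, 7)
  expect_identical(unname(d$cells), rbind(c(0L, 1L, 1L), c(0L, 0L, 1L)))
  expect_true(d$stepped)
  expect_identical(total_observations(d), 2L * 3L * 7L)

  # number of exposed cells in an n-step wedge with one cluster per step
  for (n in 2:7) {
    d <- complete_sw(n, 1, 1)
    expect_identical(sum(d$cells), as.integer(n * (n + 1) / 2))
  }

  d <- complete_sw(5, 4, 3)
  expect_identical(d$n_clusters, 20L)
  expect_identical(d$n_periods, 6L)
  expect_true(all(apply(d$cells, 1, function(r) !is.unsorted(r))))

  d <- complete_sw(16, 1, 18, n_groups = 6)
  expect_identical(dim(d$cells), c(16L, 17L))
  expect_identical(total_observations(d), 16L * 17L * 18L * 6L)

  expect_error(complete_sw(0, 1, 1), "positive")
  expect_error(complete_sw(2, 1, 0), "positive")
})

test_that("sw_with_transition observes pre+post cells per cluster", {
  d <- sw_with_transition(c(0:7, 9, 10), 12, 1, 12, 12)
  expect_identical(d$n_clusters, 10L)
  expect_identical(d$n_periods, as.integer(10 + 12 + 1 + 12))
  expect_equal(unname(rowSums(!is.na(d$cells))), rep(24, 10))
  expect_identical(total_observations(d), 2880L)
  expect_true(d$stepped)

  # degenerate: single-cluster before/after, no transition gap
  d <- sw_with_transition(0, 3, 0, 2, 5)
  expect_identical(unname(d$cells), rbind(c(0L, 0L, 0L, 1L, 1L)))

  # observed-cell count is invariant to the offsets
  for (off in list(c(0, 0, 0), c(0, 2, 5), c(1, 1, 4))) {
    d <- sw_with_transition(off, 2, 1, 3, 1)
    expect_identical(sum(!is.na(d$cells)), 3L * 5L)
  }

  expect_error(sw_with_transition(integer(0), 1, 1, 1, 1), "at least one")
  expect_error(sw_with_transition(c(2, 1), 1, 1, 1, 1), "non-decreasing")
})

test_that("staggered_parallel builds block-diagonal parallel designs", {
  d <- staggered_parallel(3, 3, 3, TRUE, 15)
  expect_identical(d$n_clusters, 18L)
  expect_identical(d$n_periods, 6L)
  expect_identical(sum(!is.na(d$cells)), 36L)
  expect_identical(total_observations(d), 540L)
  # every block: baseline all control, follow-up split 3/3
  for (b in 1:3) {
    rows <- (b - 1) * 6 + 1:6
    expect_identical(unname(d$cells[rows, 2 * b - 1]), rep(0L, 6))
    expect_identical(unname(sort(d$cells[rows, 2 * b])),
                     c(rep(0L, 3), rep(1L, 3)))
  }

  # one block, no baseline: the plain parallel CRT (a single column)
  d <- staggered_parallel(1, 2, 2, FALSE, 9)
  expect_identical(d$n_periods, 1L)
  expect_identical(unname(sort(d$cells[, 1])), c(0L, 0L, 1L, 1L))

  # one block with baseline: classic before/after parallel CRT
  d <- staggered_parallel(1, 2, 2, TRUE, 9)
  expect_identical(d$n_periods, 2L)
  expect_identical(unname(d$cells[, 1]), rep(0L, 4))

  expect_error(staggered_parallel(1, 0, 0, TRUE, 1), "at least one cluster")
})

test_that("design_pattern validates grids and rejects bad input", {
  toy <- design_pattern(rbind(c(0, NA, 1, 1), c(0, 0, NA, 1)))
  expect_identical(sum(!is.na(toy$cells)), 6L)
  expect_true(toy$stepped)
  expect_identical(unname(toy$cell_sizes[1, ]), c(1L, 0L, 1L, 1L))

  expect_error(design_pattern(rbind(c("0", "x"))), "unknown design token")
  expect_error(design_pattern(rbind(c(NA, NA))), "at least one observed")
  expect_error(design_pattern(rbind(c(0, 2))), "cells must be")
  expect_error(design_pattern(rbind(c(0, 1)), cell_sizes = rbind(c(0, 1))),
               "exactly where")

  # non-monotone grids are representable but flagged as not stepped
  d <- design_pattern(rbind(c(1, 0)))
  expect_false(d$stepped)
})

test_that("validate_design reports findings without raising", {
  expect_identical(nrow(validate_design(complete_sw(4, 1, 5))), 0L)

  rep1 <- validate_design(design_pattern(rbind(c(1, 0), c(0, 1))))
  expect_true("non-monotone exposure" %in% rep1$type)

  # a period observed by a strict subset of clusters (informational)
  d <- sw_with_transition(c(0, 2), 2, 0, 2, 1)
  rep2 <- validate_design(d)
  expect_true("partially observed periods" %in% rep2$type)

  # cluster with no exposure contrast
  d <- design_pattern(rbind(c(0, 0), c(0, 1)))
  rep3 <- validate_design(d)
  expect_true("no exposure contrast" %in% rep3$type)
})

test_that("delete_cell removes exactly one observed cell", {
  d <- complete_sw(3, 1, 4)
  d2 <- delete_cell(d, 2, 3)
  expect_true(is.na(d2$cells[2, 3]))
  expect_identical(d2$cell_sizes[2, 3], 0L)
  expect_identical(sum(!is.na(d2$cells)), sum(!is.na(d$cells)) - 1L)
  expect_error(delete_cell(d2, 2, 3), "already unobserved")
})
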