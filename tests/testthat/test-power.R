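test_that("matrix route matches the closed-form complete-wedge variance", {
  # fixed grids first
  for (rho in c(0, 0.01, 0.1)) {
    cc <- one_level_from_icc(rho, 1)
    d <- complete_sw(6, 1, 10)
    expect_equal(treatment_variance(build_matrices(d, cc)),
                 hh_closed_form_variance(d, cc), tolerance = 1e-10)
  }
  # random instances
  set.seed(11)
  for (i in 1:50) {
    d <- random_complete_sw()
    cc <- random_one_level()
    expect_equal(treatment_variance(build_matrices(d, cc)),
                 hh_closed_form_variance(d, cc), tolerance = 1e-10)
  }
  expect_error(
    hh_closed_form_variance(sw_with_transition(c(0, 1), 1, 1, 1, 1),
                            one_level_from_icc(0.1, 1)),
    "complete")
})

test_that("with no cluster variance the GLS variance is the OLS variance", {
  d <- complete_sw(5, 1, 8)
  cc <- one_level_components(tau2 = 0, sigma_w2 = 2)
  m <- build_matrices(d, cc)
  ols <- (cc$sigma_w2 / 8) * solve(crossprod(m$X))[1, 1]
  expect_equal(treatment_variance(m), ols, tolerance = 1e-12)
})

test_that("wald_power follows the normal approximation", {
  eff <- effect_spec(delta = 0, sd = 1)
  expect_equal(wald_power(1, eff, test_spec(alpha = 0.05)), 0.025)

  # two arms of 270 individuals, delta 1, sd 2.2
  p <- wald_power(2 * 2.2^2 / 270, effect_spec(delta = 1, sd = 2.2),
                  test_spec())
  expect_equal(p, pnorm(1 / sqrt(2 * 2.2^2 / 270) - qnorm(0.975)))
  expect_lt(abs(p - 0.9995), 1e-4)
})

test_that("detectable difference inverts wald_power", {
  # at target power one half, delta_min is z_{alpha/2} * SE
  expect_equal(detectable_difference(4, test_spec(target_power = 0.5)),
               qnorm(0.975) * 2)
  set.seed(12)
  for (i in 1:1000) {
    v <- runif(1, 1e-4, 10)
    tp <- runif(1, 0.1, 0.99)
    ts <- test_spec(alpha = runif(1, 0.01, 0.2), target_power = tp)
    dmin <- detectable_difference(v, ts)
    expect_equal(wald_power(v, effect_spec(delta = dmin, sd = 1), ts), tp,
                 tolerance = 1e-10)
  }
  # monotone: higher target power needs a larger detectable difference
  powers <- seq(0.2, 0.95, by = 0.05)
  dmins <- vapply(powers, function(p)
    detectable_difference(1, test_spec(target_power = p)), numeric(1))
  expect_true(all(diff(dmins) > 0))
  expect_error(detectable_difference(1, test_spec(alpha = 0.2,
                                                  target_power = 0.05)),
               "target_power")
})

test_that("pooled binary SD and the parallel design effect evaluate", {
  expect_equal(pooled_binary_sd(0.4, 0.5), sqrt(0.245))
  expect_equal(pooled_binary_sd(0.5, 0.5), 0.5)
  expect_equal(pooled_binary_sd(0, 0), 0)
  expect_equal(design_effect_parallel(100, 0), 1)
  expect_equal(design_effect_parallel(1, 0.3), 1)
  expect_equal(design_effect_parallel(288, 0.01), 3.87)
})

test_that("parallel-CRT closed form equals the matrix route", {
  eff <- effect_spec(p0 = 0.4, p1 = 0.5)
  # rho = 0 reduces to individual randomisation of n*m per arm
  expect_equal(power_parallel_crt(5, 288, 0, eff),
               wald_power(2 * eff$sd^2 / (5 * 288), eff, test_spec()))
  expect_equal(round(power_parallel_crt(5, 288, 0.01, eff), 3), 0.787)

  set.seed(13)
  for (i in 1:30) {
    a <- sample(2:6, 1); m <- sample(c(3, 20, 80), 1)
    rho <- runif(1, 0, 0.4)
    eff <- random_effect()
    d <- staggered_parallel(1, a, a, FALSE, m)
    matrix_power <- sw_power(d, one_level_from_icc(rho, eff$sd^2),
                             eff)$power
    expect_equal(power_parallel_crt(a, m, rho, eff), matrix_power,
                 tolerance = 1e-10)
  }
})

test_that("baseline-adjusted design effect equals the matrix route", {
  expect_equal(ancova_correlation(15, 0.05), 0.75 / 1.7)
  expect_equal(round(ancova_correlation(15, 0.05), 2), 0.44)
  expect_equal(round(ancova_correlation(15, 0.5), 2), 0.94)
  expect_equal(ancova_correlation(20, 0), 0)
  # strictly increasing in m and rho
  expect_true(all(diff(vapply(1:50, ancova_correlation, numeric(1),
                              rho = 0.1)) > 0))
  expect_true(all(diff(vapply(seq(0.01, 0.9, 0.01), ancova_correlation,
                              numeric(1), m = 10)) > 0))

  # no clustering: pre and post both counted, design effect 2
  expect_equal(ancova_design_effect(30, 0), 2)

  set.seed(14)
  for (i in 1:30) {
    b <- sample(1:3, 1); a <- sample(1:4, 1); m <- sample(c(5, 15, 40), 1)
    rho <- runif(1, 0, 0.6)
    eff <- random_effect()
    d <- staggered_parallel(b, a, a, TRUE, m)
    matrix_power <- sw_power(d, one_level_from_icc(rho, eff$sd^2),
                             eff)$power
    expect_equal(power_ancova(b * a, m, rho, eff), matrix_power,
                 tolerance = 1e-10)
  }
})

test_that("power increases with effect size and uniform cell-size scaling", {
  set.seed(15)
  d <- random_incomplete_sw()
  cc <- one_level_from_icc(0.05, 1)
  p <- vapply(c(0.1, 0.2, 0.4), function(delta)
    sw_power(d, cc, effect_spec(delta = delta, sd = 1))$power, numeric(1))
  expect_true(all(diff(p) > 0))

  eff <- effect_spec(delta = 0.2, sd = 1)
  p <- vapply(c(1, 2, 4), function(scale) {
    d2 <- design_pattern(d$cells, d$cell_sizes * scale)
    sw_power(d2, cc, eff)$power
  }, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("two-level power collapses to one-level limits at rho_alpha 0 and 1", {
  set.seed(16)
  eff <- effect_spec(delta = 0.25, sd = 1)
  for (i in 1:10) {
    d <- complete_sw(sample(2:5, 1), 1, sample(c(4, 12), 1),
                     n_groups = sample(2:4, 1))
    rb <- runif(1, 0.02, 0.5)

    # rho_alpha = 1: groups merge into one cluster of cell size g*m
    p_two <- sw_power(d, two_level_from_iccs(1, rb, 1), eff)$power
    merged <- complete_sw(d$n_clusters, 1,
                          d$cell_sizes[1, 1] * d$n_groups)
    p_merged <- sw_power(merged, one_level_from_icc(rb, 1), eff)$power
    expect_equal(p_two, p_merged, tolerance = 1e-10)

    # rho_alpha = 0: k*g independent clusters inheriting the schedule
    p_zero <- sw_power(d, two_level_from_iccs(0, rb, 1), eff)$power
    split <- design_pattern(
      d$cells[rep(seq_len(d$n_clusters), each = d$n_groups), ],
      cell_sizes = d$cell_sizes[1, 1])
    p_split <- sw_power(split, one_level_from_icc(rb, 1), eff)$power
    expect_equal(p_zero, p_split, tolerance = 1e-10)
  }
})

test_that("deleting an observed cell never decreases the variance", {
  set.seed(17)
  for (i in 1:15) {
    d <- random_incomplete_sw()
    cc <- random_one_level()
    v0 <- treatment_variance(build_matrices(d, cc))
    obs <- which(!is.na(d$cells), arr.ind = TRUE)
    for (r in seq_len(nrow(obs))) {
      d2 <- try(delete_cell(d, obs[r, 1], obs[r, 2]), silent = TRUE)
      if (inherits(d2, "try-error")) next
      v2 <- try(treatment_variance(build_matrices(d2, cc)), silent = TRUE)
      if (inherits(v2, "try-error")) next  # deletion broke identifiability
      expect_gte(v2, v0 - 1e-12)
    }
  }
})

test_that("power_sweep tabulates grids and preserves known shapes", {
  d <- complete_sw(4, 1, 10)
  eff <- effect_spec(delta = 0.5, sd = 1)
  # a single-point grid is one wald_power call
  tab <- power_sweep(d, eff, test_spec(), icc_grid = 0.05)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$power,
               sw_power(d, one_level_from_icc(0.05, 1), eff)$power)

  # parallel-CRT power is monotone decreasing in rho_beta at rho_alpha = 1
  par <- staggered_parallel(1, 4, 4, FALSE, 20)
  tab <- power_sweep(par, eff, test_spec(),
                     icc_grid = c(0.01, 0.05, 0.1, 0.2, 0.4),
                     rho_alpha_grid = 1)
  expect_true(all(diff(tab$power) < 0))

  # two-level grid covers the full cross of values
  tab <- power_sweep(complete_sw(3, 1, 6, n_groups = 2), eff, test_spec(),
                     icc_grid = c(0.05, 0.1), rho_alpha_grid = c(0, 0.5, 1))
  expect_identical(nrow(tab), 6L)
  expect_identical(colnames(tab), c("rho_alpha", "rho_beta", "power"))
})
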