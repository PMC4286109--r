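#' Worked example fixtures
#'
#' Three ready-made study configurations used throughout the documentation
#' and tests, each returning the design pattern, variance components,
#' effect and test specification together with the derived power.
#'
#' * `sweeping_example()` — an incomplete stepped wedge with a transition
#'   week: 10 community midwifery teams, 12 pre-implementation control
#'   weeks, 1 unobserved training (transition) week and 12 exposed weeks
#'   per team, staggered by offsets 0–7, 9, 10 weeks; 12 births per team
#'   per week (2,880 observations in total); binary outcome improving from
#'   40\% to 50\%; ICC 0.01.  The stagger pattern is a synthetic
#'   reconstruction of the published schematic (the two long steps are
#'   placed before the last two clusters), so the power is quoted as
#'   "approximately 78\%" rather than to three decimals.
#' * `epoch_example()` — a complete stepped wedge with two levels of
#'   clustering: 16 regions (clusters) of 6 hospitals (groups), 17 monthly
#'   periods, 18 emergency laparotomies per hospital per month (29,376
#'   observations); mortality falling from 10\% by 2 percentage points.
#'   Returned with a default `rho_alpha = 1`, `rho_beta = 0.01`; intended
#'   for sensitivity sweeps over both ICCs via [power_sweep()].
#' * `nursery_example()` — a staggered parallel trial with baseline
#'   measures: 18 nurseries in three blocks of six (3 intervention, 3
#'   control per block), 15 children per cell at baseline and follow-up
#'   (540 observations); effect one portion of fruit/vegetables per day,
#'   SD 2.2; default ICC 0.05.
#'
#' @param rho intra-cluster correlation used by the bundle (defaults
#'   above).
#' @param rho_alpha,rho_beta two-level ICCs for `epoch_example()`.
#' @return a list of class `sw_example` with elements `name`, `pattern`,
#'   `components`, `effect`, `test` and `result` (an
#'   [sw_power_result][sw_power]).
#' @examples
#' sweeping_example()$result$power   # ~0.78
#' nursery_example()$result$power    # 0.891
#' @name paper_examples
NULL

.example_bundle <- function(name, pattern, components, effect,
                            test = test_spec()) {
  structure(list(name = name, pattern = pattern, components = components,
                 effect = effect, test = test,
                 result = sw_power(pattern, components, effect, test)),
            class = "sw_example")
}

#' @export
print.sw_example <- function(x, ...) {
  cat(sprintf("example %s: %s\n", dQuote(x$name), ""))
  print(x$pattern)
  print(x$effect)
  print(x$result)
  invisible(x)
}

#' @rdname paper_examples
#' @export
sweeping_example <- function(rho = 0.01) {
  pattern <- sw_with_transition(step_offsets = c(0:7, 9, 10),
                                pre_len = 12, transition_len = 1,
                                post_len = 12, cell_size = 12)
  effect <- effect_spec(p0 = 0.40, p1 = 0.50)
  .example_bundle("sweeping", pattern,
                  one_level_from_icc(rho, effect$sd^2), effect)
}

#' @rdname paper_examples
#' @export
epoch_example <- function(rho_alpha = 1, rho_beta = 0.01) {
  pattern <- complete_sw(n_steps = 16, clusters_per_step = 1,
                         cell_size = 18, n_groups = 6)
  effect <- effect_spec(p0 = 0.10, p1 = 0.08)
  .example_bundle("epoch", pattern,
                  two_level_from_iccs(rho_alpha, rho_beta, effect$sd^2),
                  effect)
}

#' @rdname paper_examples
#' @export
nursery_example <- function(rho = 0.05) {
  pattern <- staggered_parallel(n_blocks = 3, intervention_per_block = 3,
                                control_per_block = 3, with_baseline = TRUE,
                                cell_size = 15)
  effect <- effect_spec(delta = 1, sd = 2.2)
  .example_bundle("nursery", pattern,
                  one_level_from_icc(rho, effect$sd^2), effect)
}

#' Power of the nursery design across a grid of ICCs, by both routes
#'
#' For each ICC, evaluates the baseline-to-follow-up cluster-mean
#' correlation `r` ([ancova_correlation()]) and the power of the nursery
#' staggered parallel design by two independent routes — the
#' information-matrix route on the design pattern ([sw_power()]) and the
#' baseline-adjustment design-effect route ([power_ancova()]) — and checks
#' that they agree.  The power profile is non-monotone in the ICC: it
#' falls at first, reaches its minimum, then rises again as the growing
#' cluster-mean correlation makes the baseline adjustment increasingly
#' effective.
#'
#' @param icc_grid numeric vector of ICC values.
#' @param tol maximum tolerated relative disagreement between the two
#'   routes before an error is raised.
#' @return a data frame with columns `icc`, `r`, `power` (matrix route)
#'   and `power_ancova` (design-effect route).
#' @examples
#' nursery_power_table()
#' @export
nursery_power_table <- function(icc_grid = c(0.05, 0.1, 0.15, 0.2,
                                             0.3, 0.4, 0.5),
                                tol = 1e-10) {
  ex <- nursery_example()
  m <- 15
  out <- data.frame(
    icc = icc_grid,
    r = vapply(icc_grid, ancova_correlation, numeric(1), m = m),
    power = vapply(icc_grid, function(rho)
      sw_power(ex$pattern, one_level_from_icc(rho, ex$effect$sd^2),
               ex$effect, ex$test)$power, numeric(1)),
    power_ancova = vapply(icc_grid, function(rho)
      power_ancova(9, m, rho, ex$effect, ex$test), numeric(1)))
  disagree <- abs(out$power - out$power_ancova) / out$power
  if (any(disagree > tol))
    stop(sprintf("matrix and ANCOVA power routes disagree (max rel. %.3g)",
                 max(disagree)), call. = FALSE)
  out
}
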