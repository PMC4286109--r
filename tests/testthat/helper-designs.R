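# Random design generators used by the property-style tests.
# Callers are expected to set the seed; these draw from the current RNG.

random_complete_sw <- function() {
  complete_sw(n_steps = sample(2:8, 1),
              clusters_per_step = sample(1:3, 1),
              cell_size = sample(c(1, 5, 20, 100), 1))
}

random_one_level <- function(total_variance = NULL) {
  if (is.null(total_variance)) total_variance <- runif(1, 0.1, 10)
  one_level_from_icc(runif(1, 0, 0.5), total_variance)
}

random_baseline_parallel <- function() {
  list(n_blocks = sample(1:4, 1),
       per_arm = sample(1:5, 1),
       m = sample(c(2, 10, 50), 1))
}

# a valid incomplete design: start from a complete wedge, knock out cells
# while keeping every row observed and the design identifiable
random_incomplete_sw <- function() {
  pattern <- complete_sw(n_steps = sample(3:6, 1),
                         clusters_per_step = 1,
                         cell_size = sample(c(5, 12), 1))
  for (trial in seq_len(pattern$n_clusters)) {
    j <- sample(pattern$n_clusters, 1)
    t <- sample(pattern$n_periods, 1)
    if (is.na(pattern$cells[j, t])) next
    if (sum(!is.na(pattern$cells[j, ])) <= 2L) next
    candidate <- delete_cell(pattern, j, t)
    ok <- tryCatch({
      treatment_variance(build_matrices(candidate,
                                        one_level_from_icc(0.1, 1)))
      TRUE
    }, error = function(e) FALSE)
    if (ok) pattern <- candidate
  }
  pattern
}

random_effect <- function(sd = NULL) {
  if (is.null(sd)) sd <- runif(1, 0.5, 3)
  effect_spec(delta = runif(1, 0.1, 1) * sd, sd = sd)
}

# round half away from zero, as printed tables do (base round() is
# half-to-even: round(0.625, 2) gives 0.62, a table prints 0.63)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
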