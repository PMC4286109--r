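#' Monte-Carlo validation of analytic power
#'
#' The analytic framework treats the observed cell means as multivariate
#' normal with mean \eqn{X\beta} and covariance `V` (variance components
#' known).  These functions draw cell means from exactly that model,
#' estimate the intervention effect by generalised least squares with the
#' known `V`, and report the empirical rejection rate of the Wald test —
#' an end-to-end check of the analytic variance and power.
#'
#' @param model an [sw_model][build_matrices] object.
#' @param reps number of simulated replicates.
#' @param seed integer seed; the same seed reproduces the draws exactly.
#' @param true_delta the intervention effect used to generate the data.
#' @param period_effects numeric vector of period (time) effects, one per
#'   retained period column of the model; default all zero.
#' @return `simulate_cell_means()` returns a `reps` x N matrix of cell
#'   means (one replicate per row).
#' @name simulation
NULL

#' @rdname simulation
#' @export
simulate_cell_means <- function(model, reps, seed, true_delta = 0,
                                period_effects = NULL) {
  stopifnot(inherits(model, "sw_model"))
  if (reps < 1) stop("reps must be at least 1", call. = FALSE)
  p <- ncol(model$X) - 1L
  if (is.null(period_effects)) period_effects <- rep(0, p)
  if (length(period_effects) != p)
    stop(sprintf("period_effects has length %d but the model retains %d periods",
                 length(period_effects), p), call. = FALSE)
  mu <- as.vector(model$X %*% c(true_delta, period_effects))
  set.seed(seed)
  n <- nrow(model$X)
  Y <- matrix(stats::rnorm(reps * n), reps, n)
  # per-cluster Cholesky: rows of Y gain covariance V block by block
  at <- 0L
  for (B in model$blocks) {
    idx <- at + seq_len(nrow(B))
    Y[, idx] <- Y[, idx, drop = FALSE] %*% chol(B)
    at <- at + nrow(B)
  }
  sweep(Y, 2L, mu, `+`)
}

#' Generalised least squares estimate of the intervention effect
#'
#' Known-variance GLS: \eqn{\hat\beta = (X'V^{-1}X)^{-1} X'V^{-1} y}; the
#' reported standard error is the analytic
#' \eqn{\sqrt{[(X'V^{-1}X)^{-1}]_{1,1}}} (no re-estimation of variance
#' components, matching the assumptions of the power calculation).
#'
#' @param model an [sw_model][build_matrices] object.
#' @param y numeric vector of observed cell means (length `nrow(model$X)`),
#'   or a matrix with one replicate per row.
#' @return a list with `delta_hat` (scalar or vector) and `se` (scalar).
#' @export
gls_estimate <- function(model, y) {
  stopifnot(inherits(model, "sw_model"))
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  if (ncol(Y) != nrow(model$X))
    stop(sprintf("y has %d cells but the model has %d", ncol(Y),
                 nrow(model$X)), call. = FALSE)
  info <- information_matrix(model)
  # X' V^{-1} y accumulated per block
  xty <- matrix(0, ncol(model$X), nrow(Y))
  at <- 0L
  for (B in model$blocks) {
    idx <- at + seq_len(nrow(B))
    Xj <- model$X[idx, , drop = FALSE]
    xty <- xty + crossprod(Xj, solve(B, t(Y[, idx, drop = FALSE])))
    at <- at + nrow(B)
  }
  beta <- solve(info, xty)
  list(delta_hat = unname(drop(beta[1L, ])),
       se = sqrt(solve(info)[1L, 1L]))
}

#' @rdname simulation
#' @param effect an [effect_spec] object; `effect$delta` is the true
#'   effect used to simulate.
#' @param test a [test_spec] object.
#' @return `empirical_power()` returns the fraction of replicates in which
#'   the two-tailed Wald statistic exceeds \eqn{z_{\alpha/2}}.
#' @examples
#' m <- build_matrices(complete_sw(4, 1, 20), one_level_from_icc(0.05, 1))
#' empirical_power(m, effect_spec(delta = 0.4, sd = 1), test_spec(),
#'                 reps = 2000, seed = 1)
#' @export
empirical_power <- function(model, effect, test = test_spec(),
                            reps = 10000, seed = 1) {
  stopifnot(inherits(effect, "effect_spec"), inherits(test, "test_spec"))
  Y <- simulate_cell_means(model, reps, seed, true_delta = effect$delta)
  est <- gls_estimate(model, Y)
  mean(abs(est$delta_hat) / est$se > stats::qnorm(1 - test$alpha / 2))
}
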