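#' Specify the effect to be detected
#'
#' Either a continuous effect (`delta` with outcome standard deviation
#' `sd`) or a binary outcome given as the control and intervention arm
#' probabilities `p0`, `p1`.  Binary outcomes are handled on the
#' risk-difference scale: the effect is `p1 - p0` and the outcome SD is the
#' pooled binary standard deviation
#' \eqn{\sqrt{(p_0(1-p_0) + p_1(1-p_1))/2}} (see [pooled_binary_sd()]).
#'
#' @param delta continuous effect size (mean difference).
#' @param sd outcome standard deviation (> 0), required with `delta`.
#' @param p0,p1 control and intervention arm probabilities for a binary
#'   outcome.
#' @return an object of class `effect_spec` with fields `delta` and `sd`
#'   (plus `p0`, `p1` when binary).
#' @examples
#' effect_spec(delta = 1, sd = 2.2)
#' effect_spec(p0 = 0.4, p1 = 0.5)   # delta 0.1, sd sqrt(0.245)
#' @export
effect_spec <- function(delta = NULL, sd = NULL, p0 = NULL, p1 = NULL) {
  continuous <- !is.null(delta)
  binary <- !is.null(p0) || !is.null(p1)
  if (continuous == binary)
    stop("give exactly one of {delta, sd} or {p0, p1}", call. = FALSE)
  if (continuous) {
    if (is.null(sd) || sd <= 0)
      stop("a continuous effect needs sd > 0", call. = FALSE)
    out <- list(delta = delta, sd = sd)
  } else {
    if (is.null(p0) || is.null(p1) ||
        any(c(p0, p1) < 0) || any(c(p0, p1) > 1))
      stop("binary effects need both p0 and p1 in [0, 1]", call. = FALSE)
    out <- list(delta = p1 - p0, sd = pooled_binary_sd(p0, p1),
                p0 = p0, p1 = p1)
  }
  structure(out, class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  if (!is.null(x$p0))
    cat(sprintf("binary effect: p0 = %g, p1 = %g (delta %g, pooled sd %g)\n",
                x$p0, x$p1, x$delta, x$sd))
  else
    cat(sprintf("continuous effect: delta = %g, sd = %g\n", x$delta, x$sd))
  invisible(x)
}

#' Specify the hypothesis test
#'
#' @param alpha two-sided significance level, in `(0, 1)`; default 0.05.
#' @param target_power power used when inverting for the minimum
#'   detectable difference; default 0.8.
#' @return an object of class `test_spec`.
#' @export
test_spec <- function(alpha = 0.05, target_power = 0.8) {
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must lie in (0, 1)", call. = FALSE)
  structure(list(alpha = alpha, target_power = target_power),
            class = "test_spec")
}

#' Pooled binary standard deviation
#'
#' The pooled outcome standard deviation for a binary endpoint with arm
#' probabilities `p0` and `p1`:
#' \eqn{\sqrt{(p_0(1-p_0) + p_1(1-p_1))/2}}.
#'
#' @param p0,p1 probabilities in `[0, 1]`.
#' @return the pooled SD (non-negative).
#' @examples
#' pooled_binary_sd(0.4, 0.5)  # sqrt(0.245)
#' @export
pooled_binary_sd <- function(p0, p1) {
  if (any(c(p0, p1) < 0) || any(c(p0, p1) > 1))
    stop("p0 and p1 must lie in [0, 1]", call. = FALSE)
  sqrt((p0 * (1 - p0) + p1 * (1 - p1)) / 2)
}

#' Variance of the treatment effect estimator
#'
#' The generalised least squares variance of the estimated intervention
#' effect: the `[1, 1]` element of \eqn{(X' V^{-1} X)^{-1}}, computed via
#' per-block Cholesky solves (V is never inverted explicitly, and never
#' assembled densely).
#'
#' @param model an [sw_model][build_matrices] object.
#' @return the positive scalar \eqn{\mathrm{Var}(\hat\delta)}.
#' @examples
#' m <- build_matrices(complete_sw(4, 1, 10), one_level_from_icc(0.05, 1))
#' treatment_variance(m)
#' @export
treatment_variance <- function(model) {
  solve(information_matrix(model))[1, 1]
}

# X' V^{-1} X accumulated block-by-block, with rank and conditioning
# guards.  The rank check lives here rather than at build time so that
# structurally interesting but unidentifiable grids (every period
# homogeneous in exposure) can still be assembled and inspected.
information_matrix <- function(model) {
  stopifnot(inherits(model, "sw_model"))
  p <- ncol(model$X)
  qrX <- qr(model$X)
  if (qrX$rank < p) {
    dropped <- colnames(model$X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop(sprintf(
      "singular design: column(s) %s are collinear with the others %s",
      paste(dQuote(dropped), collapse = ", "),
      "(treatment effect is confounded with period effects)"),
      call. = FALSE)
  }
  info <- matrix(0, p, p)
  at <- 0L
  for (B in model$blocks) {
    idx <- at + seq_len(nrow(B))
    Xj <- model$X[idx, , drop = FALSE]
    R <- chol(B)
    W <- backsolve(R, Xj, transpose = TRUE)  # R^-T Xj
    info <- info + crossprod(W)
    at <- at + nrow(B)
  }
  cond <- kappa(info, exact = TRUE)
  if (!is.finite(cond) || cond > 1e12) {
    ev <- eigen(info, symmetric = TRUE)
    weights <- abs(ev$vectors[, p])
    worst <- colnames(model$X)[order(weights, decreasing = TRUE)[1:2]]
    stop(sprintf(
      paste0("singular or near-singular design (condition number %.3g): ",
             "columns %s are (nearly) collinear"),
      cond, paste(dQuote(worst), collapse = " and ")), call. = FALSE)
  }
  dimnames(info) <- list(colnames(model$X), colnames(model$X))
  info
}

#' Closed-form variance for the complete stepped wedge
#'
#' The published closed-form expression for the treatment-effect variance
#' in a complete cross-sectional stepped-wedge design with equal cell
#' sizes, used in the test suite as an oracle independent of the
#' information-matrix route.  With `I` clusters, `T` periods, cell-mean
#' residual variance \eqn{s^2 = \sigma_w^2/m}, treatment indicators
#' \eqn{X_{jt}}, and
#' \eqn{U = \sum X_{jt}}, \eqn{W = \sum_t (\sum_j X_{jt})^2},
#' \eqn{Q = \sum_j (\sum_t X_{jt})^2}:
#' \deqn{\mathrm{Var}(\hat\delta) =
#'   \frac{I s^2 (s^2 + T \tau^2)}
#'        {(IU - W) s^2 + (U^2 + ITU - TW - IQ)\tau^2}.}
#'
#' @param pattern a complete stepped-wedge [sw_design][design_pattern]
#'   (no unobserved cells, monotone rows, constant cell size).
#' @param components a [one_level_components] object.
#' @return the closed-form \eqn{\mathrm{Var}(\hat\delta)}.
#' @export
hh_closed_form_variance <- function(pattern, components) {
  stopifnot(inherits(pattern, "sw_design"),
            inherits(components, "one_level_components"))
  if (any(is.na(pattern$cells)) || !pattern$stepped)
    stop("closed form requires a complete stepped-wedge pattern",
         call. = FALSE)
  m <- unique(as.vector(pattern$cell_sizes))
  if (length(m) != 1L)
    stop("closed form requires a constant cell size", call. = FALSE)
  if (pattern$n_groups != 1L)
    stop("closed form covers a single level of clustering", call. = FALSE)
  I <- pattern$n_clusters
  Tn <- pattern$n_periods
  Xjt <- pattern$cells
  U <- sum(Xjt)
  W <- sum(colSums(Xjt)^2)
  Q <- sum(rowSums(Xjt)^2)
  s2 <- components$sigma_w2 / m
  tau2 <- components$tau2
  num <- I * s2 * (s2 + Tn * tau2)
  den <- (I * U - W) * s2 + (U^2 + I * Tn * U - Tn * W - I * Q) * tau2
  num / den
}

#' Wald-test power for a given effect-estimator variance
#'
#' The normal-approximation power of a two-sided Wald test:
#' \deqn{1 - \beta = \Phi\!\left(\frac{|\delta|}{\sqrt{\mathrm{Var}
#'   (\hat\delta)}} - z_{\alpha/2}\right).}
#' The opposite-tail rejection probability is deliberately ignored — it is
#' negligible except when \eqn{\delta} is close to 0 (at \eqn{\delta = 0}
#' the formula returns \eqn{\alpha/2}, half the two-tailed size).
#'
#' @param var_delta variance of the effect estimator (> 0).
#' @param effect an [effect_spec] object.
#' @param test a [test_spec] object.
#' @return the power, in `(0, 1)`.
#' @examples
#' wald_power(2 * 2.2^2 / 270, effect_spec(delta = 1, sd = 2.2), test_spec())
#' @export
wald_power <- function(var_delta, effect, test = test_spec()) {
  stopifnot(inherits(effect, "effect_spec"), inherits(test, "test_spec"))
  if (var_delta <= 0) stop("var_delta must be positive", call. = FALSE)
  stats::pnorm(abs(effect$delta) / sqrt(var_delta) -
                 stats::qnorm(1 - test$alpha / 2))
}

#' Minimum detectable difference
#'
#' Inverts the Wald power formula: the smallest absolute effect detectable
#' at `test$target_power` given the estimator variance,
#' \eqn{\delta_{min} = (z_{\alpha/2} + z_\beta)\sqrt{\mathrm{Var}
#' (\hat\delta)}}.
#'
#' @inheritParams wald_power
#' @return `delta_min > 0`; feeding it back through [wald_power()]
#'   reproduces `test$target_power` exactly.
#' @export
detectable_difference <- function(var_delta, test = test_spec()) {
  stopifnot(inherits(test, "test_spec"))
  if (var_delta <= 0) stop("var_delta must be positive", call. = FALSE)
  if (test$target_power <= test$alpha / 2)
    stop("target_power must exceed alpha/2 (the power at delta = 0)",
         call. = FALSE)
  (stats::qnorm(1 - test$alpha / 2) + stats::qnorm(test$target_power)) *
    sqrt(var_delta)
}

#' Design effect for a parallel cluster randomised trial
#'
#' The classical variance inflation for cluster randomisation with equal
#' cluster size `m` and intra-cluster correlation `rho`:
#' \eqn{1 + (m - 1)\rho}.
#'
#' @param m cluster (cell) size, a positive integer.
#' @param rho intra-cluster correlation, in `[0, 1)`.
#' @return the design effect, >= 1.
#' @export
design_effect_parallel <- function(m, rho) {
  if (m < 1) stop("m must be a positive integer", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  1 + (m - 1) * rho
}

#' Power of a parallel cluster randomised trial
#'
#' Closed-form route: the variance of the difference in arm means is
#' \eqn{2\sigma^2\,[1 + (m-1)\rho]/(n\,m)} with `n` clusters of size `m`
#' per arm; power then follows from [wald_power()].  Agrees exactly with
#' the information-matrix route applied to the single-period parallel
#' design pattern.
#'
#' @param n_per_arm_clusters clusters per arm.
#' @param m observations per cluster.
#' @param rho intra-cluster correlation.
#' @param effect an [effect_spec] object.
#' @param test a [test_spec] object.
#' @return the power.
#' @examples
#' power_parallel_crt(5, 288, 0.01, effect_spec(p0 = 0.4, p1 = 0.5))
#' @export
power_parallel_crt <- function(n_per_arm_clusters, m, rho, effect,
                               test = test_spec()) {
  if (n_per_arm_clusters < 1) stop("need at least one cluster per arm",
                                   call. = FALSE)
  de <- design_effect_parallel(m, rho)
  var_delta <- 2 * effect$sd^2 * de / (n_per_arm_clusters * m)
  wald_power(var_delta, effect, test)
}

#' Correlation between baseline and follow-up cluster means
#'
#' In a cross-sectional design with cell size `m` and intra-cluster
#' correlation `rho`, the correlation between the baseline and follow-up
#' means of the same cluster is
#' \deqn{r = \frac{m\rho}{1 + (m - 1)\rho}.}
#' Baseline adjustment in a parallel CRT reduces the effective variance by
#' the factor \eqn{1 - r^2}.
#'
#' @inheritParams design_effect_parallel
#' @return `r` in `[0, 1)`; 0 when `rho = 0`, increasing in both `m` and
#'   `rho`.
#' @examples
#' ancova_correlation(15, 0.05)  # 0.44 to 2 dp
#' @export
ancova_correlation <- function(m, rho) {
  if (m < 1) stop("m must be a positive integer", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  m * rho / (1 + (m - 1) * rho)
}

#' Design effect for a baseline-adjusted parallel cluster trial
#'
#' Relative to individual randomisation (counting both the `m` baseline
#' and `m` follow-up measurements per cluster), the cross-sectional
#' parallel CRT with baseline measures inflates the required sample size by
#' \deqn{2\,[1 + (m - 1)\rho]\,(1 - r^2)}
#' with `r` from [ancova_correlation()].  At `rho = 0` this is 2: the
#' baseline measurements carry no information about the follow-up means,
#' yet are counted in the sample size.
#'
#' @inheritParams design_effect_parallel
#' @return the design effect (positive).
#' @export
ancova_design_effect <- function(m, rho) {
  r <- ancova_correlation(m, rho)
  2 * design_effect_parallel(m, rho) * (1 - r^2)
}

#' Power of a parallel cluster trial with baseline measures
#'
#' Baseline-adjustment route: the variance of the adjusted difference in
#' arm means is \eqn{2\sigma^2[1+(m-1)\rho](1-r^2)/(n\,m)}, i.e. the
#' design effect of [ancova_design_effect()] applied to the `2 n m`
#' measurements per arm.  Identical to the information-matrix route on the
#' corresponding baseline + follow-up design pattern.
#'
#' @inheritParams power_parallel_crt
#' @return the power.
#' @examples
#' power_ancova(9, 15, 0.05, effect_spec(delta = 1, sd = 2.2))  # 0.891
#' @export
power_ancova <- function(n_per_arm_clusters, m, rho, effect,
                         test = test_spec()) {
  if (n_per_arm_clusters < 1) stop("need at least one cluster per arm",
                                   call. = FALSE)
  r <- ancova_correlation(m, rho)
  var_delta <- 2 * effect$sd^2 * design_effect_parallel(m, rho) *
    (1 - r^2) / (n_per_arm_clusters * m)
  wald_power(var_delta, effect, test)
}

#' Power and detectable difference for a design pattern
#'
#' The main entry point: builds the cell-means GLS model for the pattern
#' and variance components, extracts \eqn{\mathrm{Var}(\hat\delta)}, and
#' computes Wald power for the given effect together with the minimum
#' detectable difference at `test$target_power`.
#'
#' @param pattern an [sw_design][design_pattern] object.
#' @param components a [one_level_components] or [two_level_components]
#'   object.
#' @param effect an [effect_spec] object.
#' @param test a [test_spec] object.
#' @return an object of class `sw_power_result`: list with `var_delta`,
#'   `se`, `power`, `delta_min`, and the inputs.
#' @examples
#' sw_power(staggered_parallel(3, 3, 3, TRUE, 15),
#'          one_level_from_icc(0.05, 2.2^2),
#'          effect_spec(delta = 1, sd = 2.2))
#' @export
sw_power <- function(pattern, components, effect, test = test_spec()) {
  model <- build_matrices(pattern, components)
  var_delta <- treatment_variance(model)
  structure(list(var_delta = var_delta, se = sqrt(var_delta),
                 power = wald_power(var_delta, effect, test),
                 delta_min = detectable_difference(var_delta, test),
                 pattern = pattern, components = components,
                 effect = effect, test = test),
            class = "sw_power_result")
}

#' @export
print.sw_power_result <- function(x, ...) {
  cat(sprintf("Var(delta_hat) = %.6g  (SE %.6g)\n", x$var_delta, x$se))
  cat(sprintf("power          = %.4f  (delta %g, two-sided alpha %g)\n",
              x$power, x$effect$delta, x$test$alpha))
  cat(sprintf("delta_min      = %.6g  (at power %g)\n",
              x$delta_min, x$test$target_power))
  invisible(x)
}

#' Sweep power over a grid of intra-cluster correlations
#'
#' Evaluates the power of a design over a grid of ICC values.  With only
#' `icc_grid`, a one-level model is used (`rho` varies, total variance
#' fixed at `effect$sd^2`).  With `rho_alpha_grid` as well, a two-level
#' model is evaluated at every (rho_alpha, rho_beta) combination —
#' `icc_grid` is then interpreted as the grid of `rho_beta` values.
#'
#' @param pattern an [sw_design][design_pattern] object.
#' @param effect an [effect_spec] object; `effect$sd^2` is the total
#'   outcome variance.
#' @param test a [test_spec] object.
#' @param icc_grid numeric vector of ICC (or `rho_beta`) values.
#' @param rho_alpha_grid optional numeric vector of `rho_alpha` values.
#' @return a data frame with columns `rho_alpha` (NA for one-level),
#'   `rho_beta` and `power`, one row per grid point, in grid order.
#' @examples
#' power_sweep(complete_sw(4, 1, 10), effect_spec(delta = 0.5, sd = 1),
#'             test_spec(), icc_grid = c(0.01, 0.05, 0.1))
#' @export
power_sweep <- function(pattern, effect, test = test_spec(),
                        icc_grid, rho_alpha_grid = NULL) {
  stopifnot(inherits(pattern, "sw_design"), inherits(effect, "effect_spec"))
  sigma2 <- effect$sd^2
  if (is.null(rho_alpha_grid)) {
    grid <- data.frame(rho_alpha = NA_real_, rho_beta = icc_grid)
    comp <- lapply(icc_grid, one_level_from_icc, total_variance = sigma2)
  } else {
    grid <- expand.grid(rho_beta = icc_grid, rho_alpha = rho_alpha_grid)
    grid <- grid[, c("rho_alpha", "rho_beta")]
    comp <- Map(two_level_from_iccs, grid$rho_alpha, grid$rho_beta,
                total_variance = sigma2)
  }
  grid$power <- vapply(comp, function(cc)
    sw_power(pattern, cc, effect, test)$power, numeric(1))
  rownames(grid) <- NULL
  grid
}
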