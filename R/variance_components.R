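#' Variance components for one and two levels of clustering
#'
#' With a single level of clustering the individual outcome variance is
#' partitioned as \eqn{\sigma^2 = \tau^2 + \sigma_w^2}: between-cluster
#' plus within-cluster variance.  The intra-cluster correlation is
#' \eqn{\rho = \tau^2 / \sigma^2}.
#'
#' With two nested levels (groups within clusters, e.g. wards within a
#' hospital) the partition is \eqn{\sigma^2 = \tau^2 + b^2 + \sigma_w^2}:
#' between-cluster, between-group-within-cluster, and residual.  Two ICCs
#' describe the structure: \eqn{\rho_\alpha = \tau^2 / (\tau^2 + b^2)}, the
#' correlation between two groups within the same cluster, and
#' \eqn{\rho_\beta = (\tau^2 + b^2) / \sigma^2}, the correlation between
#' two observations within the same group.  Setting \eqn{\rho_\alpha = 1}
#' collapses the groups of a cluster into one entity; \eqn{\rho_\alpha = 0}
#' makes them mutually independent.
#'
#' @param tau2 between-cluster variance (>= 0).
#' @param sigma_w2 within-cluster (residual) variance (> 0).
#' @param b2 between-group-within-cluster variance (>= 0).
#' @return an object of class `one_level_components` or
#'   `two_level_components` with fields `tau2`, (`b2`,) `sigma_w2` and the
#'   derived `sigma2` total.
#' @seealso [one_level_from_icc()], [two_level_from_iccs()], [icc()]
#' @export
one_level_components <- function(tau2, sigma_w2) {
  if (tau2 < 0 || sigma_w2 <= 0)
    stop("need tau2 >= 0 and sigma_w2 > 0", call. = FALSE)
  structure(list(tau2 = tau2, sigma_w2 = sigma_w2,
                 sigma2 = tau2 + sigma_w2),
            class = "one_level_components")
}

#' @rdname one_level_components
#' @export
two_level_components <- function(tau2, b2, sigma_w2) {
  if (tau2 < 0 || b2 < 0 || sigma_w2 <= 0)
    stop("need tau2 >= 0, b2 >= 0 and sigma_w2 > 0", call. = FALSE)
  structure(list(tau2 = tau2, b2 = b2, sigma_w2 = sigma_w2,
                 sigma2 = tau2 + b2 + sigma_w2),
            class = "two_level_components")
}

#' Build one-level variance components from an ICC
#'
#' @param rho intra-cluster correlation, in `[0, 1)`.
#' @param total_variance total outcome variance \eqn{\sigma^2 > 0}.
#' @return a [one_level_components] object with `tau2 = rho * sigma2`.
#' @examples
#' one_level_from_icc(0.01, 0.245)
#' @export
one_level_from_icc <- function(rho, total_variance) {
  if (rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)", call. = FALSE)
  if (total_variance <= 0)
    stop("total_variance must be positive", call. = FALSE)
  one_level_components(tau2 = rho * total_variance,
                       sigma_w2 = (1 - rho) * total_variance)
}

#' Build two-level variance components from the two ICCs
#'
#' @param rho_alpha correlation between two groups within a cluster, in
#'   `[0, 1]`.
#' @param rho_beta correlation between two observations within a group, in
#'   `[0, 1)`.
#' @param total_variance total outcome variance \eqn{\sigma^2 > 0}.
#' @return a [two_level_components] object with
#'   `tau2 = rho_alpha * rho_beta * sigma2`,
#'   `b2 = (1 - rho_alpha) * rho_beta * sigma2`,
#'   `sigma_w2 = (1 - rho_beta) * sigma2`.
#' @examples
#' two_level_from_iccs(0.5, 0.1, 1)
#' @export
two_level_from_iccs <- function(rho_alpha, rho_beta, total_variance) {
  if (rho_alpha < 0 || rho_alpha > 1)
    stop("rho_alpha must lie in [0, 1]", call. = FALSE)
  if (rho_beta < 0 || rho_beta >= 1)
    stop("rho_beta must lie in [0, 1)", call. = FALSE)
  if (total_variance <= 0)
    stop("total_variance must be positive", call. = FALSE)
  two_level_components(tau2 = rho_alpha * rho_beta * total_variance,
                       b2 = (1 - rho_alpha) * rho_beta * total_variance,
                       sigma_w2 = (1 - rho_beta) * total_variance)
}

#' Intra-cluster correlations of a variance-component object
#'
#' For one-level components returns \eqn{\rho = \tau^2/\sigma^2}.  For
#' two-level components returns both ICCs,
#' `c(rho_alpha = tau2/(tau2+b2), rho_beta = (tau2+b2)/sigma2)`;
#' `rho_alpha` is defined as 0 by convention when `tau2 + b2 = 0` (there is
#' no between-unit variance to partition).
#'
#' @param components a [one_level_components] or [two_level_components]
#'   object.
#' @return a named numeric vector of ICC(s).
#' @export
icc <- function(components) UseMethod("icc")

#' @export
icc.one_level_components <- function(components)
  c(rho = components$tau2 / components$sigma2)

#' @export
icc.two_level_components <- function(components) {
  cluster_var <- components$tau2 + components$b2
  c(rho_alpha = if (cluster_var == 0) 0 else components$tau2 / cluster_var,
    rho_beta = cluster_var / components$sigma2)
}

#' @export
print.one_level_components <- function(x, ...) {
  cat(sprintf(
    "one-level variance components: tau2 = %g, sigma_w2 = %g (total %g, ICC %g)\n",
    x$tau2, x$sigma_w2, x$sigma2, icc(x)[["rho"]]))
  invisible(x)
}

#' @export
print.two_level_components <- function(x, ...) {
  r <- icc(x)
  cat(sprintf(
    "two-level variance components: tau2 = %g, b2 = %g, sigma_w2 = %g\n",
    x$tau2, x$b2, x$sigma_w2))
  cat(sprintf("  total %g, rho_alpha = %g, rho_beta = %g\n",
              x$sigma2, r[["rho_alpha"]], r[["rho_beta"]]))
  invisible(x)
}

#' Alternative between-group ICC parameterisation
#'
#' Some authors parameterise the between-group correlation as the fraction
#' of *total* variance at the cluster level, \eqn{\tau^2/\sigma^2}, rather
#' than as the fraction of the combined cluster-plus-group variance used
#' here.  This helper converts from that convention: given
#' `tau2_fraction` \eqn{= \tau^2/\sigma^2} and
#' `rho_beta` \eqn{= (\tau^2+b^2)/\sigma^2} it returns
#' \eqn{\rho_\alpha = } `tau2_fraction / rho_beta`.
#'
#' @param tau2_fraction cluster-level share of total variance, in
#'   `[0, rho_beta]`.
#' @param rho_beta within-group correlation, in `(0, 1)`.
#' @return `rho_alpha` on the convention used by [two_level_from_iccs()].
#' @export
rho_alpha_from_variance_fractions <- function(tau2_fraction, rho_beta) {
  if (rho_beta <= 0 || rho_beta >= 1)
    stop("rho_beta must lie in (0, 1)", call. = FALSE)
  if (tau2_fraction < 0 || tau2_fraction > rho_beta)
    stop("tau2_fraction must lie in [0, rho_beta]", call. = FALSE)
  tau2_fraction / rho_beta
}
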