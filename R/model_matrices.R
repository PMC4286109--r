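#' Build the cell-means design matrix and block-diagonal covariance
#'
#' Assembles the generalised least squares machinery for the cell-means
#' mixed model of a cluster trial.  Rows exist only for observed cells (one
#' per cluster-group-period combination with data), ordered by period
#' within group within cluster.  The fixed-effects matrix `X` has the
#' treatment (exposure) indicator in column 1 followed by one indicator per
#' period that retains at least one observed cell — no intercept, so with
#' a complete stepped wedge over `s` periods there are `s + 1` linear
#' parameters.  The covariance of the cell means, `V`, is block-diagonal
#' with one block per cluster:
#' \deqn{V_j = \tau^2 \mathbf{1}\mathbf{1}' + \mathrm{diag}(\sigma_w^2 / m)}
#' for a single clustering level, and for two levels
#' \deqn{V_j = \tau^2 \mathbf{1}\mathbf{1}' +
#'   \mathrm{blockdiag}_l\,[\,b^2 \mathbf{1}\mathbf{1}' +
#'   \mathrm{diag}(\sigma_w^2 / m)\,]}
#' over the cluster's `g` groups, which all share the cluster's exposure
#' row (groups cross over together).
#'
#' @param pattern an [sw_design][design_pattern] object.
#' @param components a [one_level_components] or [two_level_components]
#'   object.  One-level components on a multi-group pattern treat the
#'   groups as independent sub-clusters of the same schedule is *not*
#'   implied; use [two_level_from_iccs()] for multi-group patterns (a
#'   two-level build with `g = 1` coincides exactly with the one-level
#'   build using `tau2 + b2` as the cluster variance).
#' @return an object of class `sw_model`: list with `X` (N x (1+p)),
#'   `blocks` (per-cluster covariance matrices whose block-diagonal
#'   concatenation is V), `rows` (data frame mapping each row to cluster,
#'   group and period), `pattern` and `components`.
#' @examples
#' d <- complete_sw(3, 1, 10)
#' m <- build_matrices(d, one_level_from_icc(0.05, 1))
#' dim(m$X)
#' @export
build_matrices <- function(pattern, components) {
  stopifnot(inherits(pattern, "sw_design"))
  if (!inherits(components, c("one_level_components",
                              "two_level_components")))
    stop("components must be one_level_components or two_level_components",
         call. = FALSE)
  two_level <- inherits(components, "two_level_components")
  g <- pattern$n_groups
  cl <- pattern$cells
  msz <- pattern$cell_sizes

  periods_kept <- which(colSums(!is.na(cl)) > 0L)
  if (length(periods_kept) == 0L)
    stop("design has no observed cells", call. = FALSE)

  tau2 <- components$tau2
  b2 <- if (two_level) components$b2 else 0
  sigma_w2 <- components$sigma_w2
  if (!two_level && g > 1L)
    # one-level components carry no between-group variance: groups within a
    # cluster are then correlated only through tau2
    b2 <- 0

  rows <- list()
  blocks <- vector("list", nrow(cl))
  for (j in seq_len(nrow(cl))) {
    obs <- which(!is.na(cl[j, ]))
    p_j <- length(obs)
    n_j <- p_j * g
    within <- b2 + diag(sigma_w2 / msz[j, obs], nrow = p_j)
    Vj <- matrix(tau2, n_j, n_j)
    for (l in seq_len(g)) {
      idx <- (l - 1L) * p_j + seq_len(p_j)
      Vj[idx, idx] <- Vj[idx, idx] + within
    }
    blocks[[j]] <- Vj
    rows[[j]] <- data.frame(cluster = j,
                            group = rep(seq_len(g), each = p_j),
                            period = rep(obs, times = g),
                            exposed = rep(cl[j, obs], times = g),
                            m = rep(msz[j, obs], times = g))
  }
  rows <- do.call(rbind, rows)

  X <- cbind(treatment = rows$exposed,
             outer(rows$period, periods_kept, `==`) + 0)
  colnames(X) <- c("treatment", colnames(cl)[periods_kept])

  structure(list(X = X, blocks = blocks, rows = rows,
                 periods_kept = periods_kept,
                 pattern = pattern, components = components),
            class = "sw_model")
}

#' @export
print.sw_model <- function(x, ...) {
  cat(sprintf(
    "cell-means GLS model: %d observed cells, %d linear parameters, %d covariance blocks\n",
    nrow(x$X), ncol(x$X), length(x$blocks)))
  invisible(x)
}

#' Assemble the full block-diagonal covariance matrix V
#'
#' Mostly useful for inspection and simulation on small designs; all power
#' computations work block-by-block and never form V densely.
#'
#' @param model an [sw_model][build_matrices] object.
#' @return the N x N covariance matrix of the observed cell means.
#' @export
full_covariance <- function(model) {
  stopifnot(inherits(model, "sw_model"))
  n <- vapply(model$blocks, nrow, integer(1))
  V <- matrix(0, sum(n), sum(n))
  at <- 0L
  for (B in model$blocks) {
    idx <- at + seq_len(nrow(B))
    V[idx, idx] <- B
    at <- at + nrow(B)
  }
  V
}
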