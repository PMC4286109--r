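#' Design pattern matrices for cluster randomised trials
#'
#' A design pattern matrix is a clusters-by-periods grid that fully encodes
#' the shape of a cross-sectional cluster randomised trial.  Each cell is
#' either control (`0`), exposed to the intervention (`1`), or unobserved
#' (`.`, e.g. a transition/implementation period or a period in which no
#' data are collected).  Alongside the exposure grid sits a grid of cell
#' sizes: the number of individuals sampled in each cluster-period cell.
#'
#' `design_pattern()` builds a pattern from an arbitrary grid; the
#' constructors [complete_sw()], [sw_with_transition()] and
#' [staggered_parallel()] build the standard trial shapes.
#'
#' @param cells integer matrix (clusters x periods) with entries `0`
#'   (control), `1` (exposed) or `NA` (unobserved).  Character matrices with
#'   tokens `"0"`, `"1"`, `"."` are accepted.
#' @param cell_sizes cell sizes: either a single positive number recycled
#'   over all observed cells, or a matrix of the same shape as `cells`
#'   (entries must be 0 exactly where `cells` is unobserved).
#' @param n_groups number of groups per cluster (second clustering level,
#'   e.g. wards within a hospital).  All groups within a cluster share the
#'   cluster's exposure row.  Default 1 (a single level of clustering).
#' @param cluster_labels,period_labels optional character labels.
#'
#' @return An object of class `sw_design`: a list with elements
#'   `cells` (0/1/NA matrix), `cell_sizes` (integer matrix),
#'   `n_clusters`, `n_periods`, `n_groups`, and the logical `stepped`
#'   (TRUE iff every cluster's observed exposure sequence is monotone
#'   non-decreasing in time).
#'
#' @examples
#' # the smallest complete stepped wedge: 2 clusters, 3 periods
#' complete_sw(2, 1, 10)
#'
#' # an incomplete design given directly as a grid ('.' = unobserved)
#' design_pattern(rbind(c(0, NA, 1, 1),
#'                      c(0, 0, NA, 1)), cell_sizes = 12)
#' @export
design_pattern <- function(cells, cell_sizes = 1, n_groups = 1,
                           cluster_labels = NULL, period_labels = NULL) {
  if (is.character(cells)) {
    bad <- matrix(!(cells %in% c("0", "1", ".", NA)), nrow(cells))
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("unknown design token %s at row %d, column %d",
                   dQuote(cells[bad][1]), idx[1], idx[2]), call. = FALSE)
    }
    cells[cells == "."] <- NA
    cells <- matrix(as.integer(cells), nrow = nrow(cells))
  }
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (nrow(cells) < 1L || ncol(cells) < 1L)
    stop("design pattern must have at least one cluster and one period",
         call. = FALSE)
  if (any(!is.na(cells) & !(cells %in% c(0L, 1L))))
    stop("cells must be 0 (control), 1 (exposed) or NA (unobserved)",
         call. = FALSE)
  if (any(apply(cells, 1, function(r) all(is.na(r)))))
    stop("every cluster must have at least one observed cell", call. = FALSE)

  if (length(cell_sizes) == 1L) {
    m <- matrix(as.integer(cell_sizes), nrow(cells), ncol(cells))
    m[is.na(cells)] <- 0L
  } else {
    m <- as.matrix(cell_sizes)
    storage.mode(m) <- "integer"
    if (!identical(dim(m), dim(cells)))
      stop("cell_sizes must match the dimensions of cells", call. = FALSE)
  }
  if (any(is.na(m)) || any(m < 0L))
    stop("cell sizes must be non-negative integers", call. = FALSE)
  if (any((m == 0L) != is.na(cells)))
    stop("cell sizes must be 0 exactly where the cell is unobserved",
         call. = FALSE)
  n_groups <- as.integer(n_groups)
  if (length(n_groups) != 1L || is.na(n_groups) || n_groups < 1L)
    stop("n_groups must be a positive integer", call. = FALSE)

  if (is.null(cluster_labels))
    cluster_labels <- paste0("cluster", seq_len(nrow(cells)))
  if (is.null(period_labels))
    period_labels <- paste0("p", seq_len(ncol(cells)))
  dimnames(cells) <- dimnames(m) <- list(cluster_labels, period_labels)

  structure(
    list(cells = cells, cell_sizes = m,
         n_clusters = nrow(cells), n_periods = ncol(cells),
         n_groups = n_groups,
         stepped = all(apply(cells, 1, .is_monotone_row))),
    class = "sw_design")
}

.is_monotone_row <- function(row) {
  obs <- row[!is.na(row)]
  length(obs) == 0L || !is.unsorted(obs)
}

#' @export
print.sw_design <- function(x, ...) {
  kind <- if (any(is.na(x$cells))) "incomplete" else "complete"
  cat(sprintf("%s design pattern: %d cluster%s x %d period%s",
              kind, x$n_clusters, if (x$n_clusters > 1) "s" else "",
              x$n_periods, if (x$n_periods > 1) "s" else ""))
  if (x$n_groups > 1) cat(sprintf(", %d groups per cluster", x$n_groups))
  cat(sprintf(" (%s observations)\n", format(total_observations(x),
                                             big.mark = ",")))
  grid <- ifelse(is.na(x$cells), ".", as.character(x$cells))
  rownames(grid) <- rownames(x$cells)
  colnames(grid) <- colnames(x$cells)
  print(grid, quote = FALSE)
  invisible(x)
}

#' @export
`==.sw_design` <- function(e1, e2) {
  identical(unname(e1$cells), unname(e2$cells)) &&
    identical(unname(e1$cell_sizes), unname(e2$cell_sizes)) &&
    e1$n_groups == e2$n_groups
}

#' Total number of individual observations in a design
#'
#' The sum of all cell sizes, multiplied by the number of groups per
#' cluster (each group contributes a full set of cells).
#'
#' @param pattern an [sw_design][design_pattern] object.
#' @return integer count of individual observations.
#' @export
total_observations <- function(pattern) {
  stopifnot(inherits(pattern, "sw_design"))
  sum(pattern$cell_sizes) * pattern$n_groups
}

#' Construct a complete stepped-wedge design
#'
#' Builds the conventional complete cross-sectional stepped wedge: one
#' all-control baseline period, then clusters cross to the intervention in
#' blocks, one block per step, until all are exposed in the final period.
#' Every cluster-period cell is observed with the same cell size.
#'
#' @param n_steps number of randomisation steps (>= 1).
#' @param clusters_per_step number of clusters crossing over at each step.
#' @param cell_size observations per cluster-period cell (per group).
#' @param n_groups groups per cluster (second clustering level); default 1.
#' @return an [sw_design][design_pattern] with `n_steps * clusters_per_step`
#'   clusters and `n_steps + 1` periods.
#' @examples
#' complete_sw(5, 4, 10)  # 20 clusters, 6 periods
#' @export
complete_sw <- function(n_steps, clusters_per_step = 1, cell_size = 1,
                        n_groups = 1) {
  if (n_steps < 1 || clusters_per_step < 1 || cell_size < 1)
    stop("n_steps, clusters_per_step and cell_size must be positive",
         call. = FALSE)
  s <- n_steps + 1L
  one_block <- t(vapply(seq_len(n_steps), function(b)
    as.integer(seq_len(s) > b), integer(s)))
  cells <- one_block[rep(seq_len(n_steps), each = clusters_per_step), ,
                     drop = FALSE]
  design_pattern(cells, cell_sizes = cell_size, n_groups = n_groups)
}

#' Construct a stepped-wedge design with a transition period
#'
#' Each cluster contributes a fixed window of `pre_len` control periods,
#' then `transition_len` unobserved transition (implementation) periods,
#' then `post_len` exposed periods; the window of cluster `j` starts at
#' period `1 + step_offsets[j]`.  Periods outside a cluster's window are
#' unobserved, so the design is incomplete whenever offsets differ or a
#' transition period is present.
#'
#' @param step_offsets non-decreasing vector of non-negative integers, one
#'   per cluster: the delay (in periods) before the cluster's window opens.
#' @param pre_len number of pre-implementation (control) periods per cluster.
#' @param transition_len number of unobserved transition periods (may be 0).
#' @param post_len number of post-implementation (exposed) periods.
#' @param cell_size observations per observed cell (per group).
#' @param n_groups groups per cluster; default 1.
#' @return an [sw_design][design_pattern] with `length(step_offsets)`
#'   clusters and `max(step_offsets) + pre_len + transition_len + post_len`
#'   periods; every cluster has exactly `pre_len + post_len` observed cells.
#' @examples
#' # 10 clusters, 12 weeks before, 1-week transition, 12 weeks after
#' sw_with_transition(c(0:7, 9, 10), 12, 1, 12, 12)
#' @export
sw_with_transition <- function(step_offsets, pre_len, transition_len,
                               post_len, cell_size = 1, n_groups = 1) {
  if (length(step_offsets) == 0L)
    stop("step_offsets must contain at least one cluster", call. = FALSE)
  if (any(step_offsets < 0) || is.unsorted(step_offsets))
    stop("step_offsets must be non-negative and non-decreasing",
         call. = FALSE)
  if (pre_len < 1 || post_len < 1 || transition_len < 0 || cell_size < 1)
    stop("pre_len and post_len must be positive; transition_len >= 0",
         call. = FALSE)
  k <- length(step_offsets)
  s <- max(step_offsets) + pre_len + transition_len + post_len
  cells <- matrix(NA_integer_, k, s)
  for (j in seq_len(k)) {
    o <- step_offsets[j]
    cells[j, o + seq_len(pre_len)] <- 0L
    cells[j, o + pre_len + transition_len + seq_len(post_len)] <- 1L
  }
  design_pattern(cells, cell_sizes = cell_size, n_groups = n_groups)
}

#' Construct a staggered parallel cluster randomised trial
#'
#' Clusters are recruited in blocks; each block is randomised between the
#' intervention and control arms and observed only in its own follow-up
#' period (and, with `with_baseline = TRUE`, an immediately preceding
#' all-control baseline period).  With one block and no baseline this is
#' the plain parallel CRT; with one block and a baseline it is the
#' cross-sectional before/after parallel CRT (the cross-sectional analogue
#' of the ANCOVA design).
#'
#' @param n_blocks number of recruitment blocks.
#' @param intervention_per_block,control_per_block clusters randomised to
#'   each arm within every block (at least one cluster per block in total).
#' @param with_baseline if TRUE each block also contributes a baseline
#'   period in which all of its clusters are under control.
#' @param cell_size observations per observed cell (per group).
#' @param n_groups groups per cluster; default 1.
#' @return an [sw_design][design_pattern] with
#'   `n_blocks * (intervention_per_block + control_per_block)` clusters and
#'   `2 * n_blocks` periods (`n_blocks` without baseline).
#' @examples
#' staggered_parallel(3, 3, 3, with_baseline = TRUE, cell_size = 15)
#' @export
staggered_parallel <- function(n_blocks, intervention_per_block,
                               control_per_block, with_baseline = TRUE,
                               cell_size = 1, n_groups = 1) {
  if (n_blocks < 1 || intervention_per_block < 0 || control_per_block < 0 ||
      intervention_per_block + control_per_block < 1 || cell_size < 1)
    stop("need at least one cluster per block and positive cell_size",
         call. = FALSE)
  per_block <- intervention_per_block + control_per_block
  k <- n_blocks * per_block
  s <- if (with_baseline) 2L * n_blocks else n_blocks
  cells <- matrix(NA_integer_, k, s)
  for (b in seq_len(n_blocks)) {
    rows <- (b - 1L) * per_block + seq_len(per_block)
    arm <- rep(c(1L, 0L), c(intervention_per_block, control_per_block))
    if (with_baseline) {
      cells[rows, 2L * b - 1L] <- 0L
      cells[rows, 2L * b] <- arm
    } else {
      cells[rows, b] <- arm
    }
  }
  design_pattern(cells, cell_sizes = cell_size, n_groups = n_groups)
}

#' Validate a design pattern and report unusual features
#'
#' Inspects a pattern for features that are legitimate but worth flagging:
#' non-monotone exposure rows (a cluster reverting from intervention to
#' control, impossible under constructors but possible in a file), periods
#' with no observed cells (dropped from the model downstream), clusters
#' observed under only one exposure condition, and periods observed by only
#' a strict subset of clusters.  Never raises for merely unusual designs.
#'
#' @param pattern an [sw_design][design_pattern] object.
#' @return a data frame of findings with columns `type`, `where`,
#'   `message`; zero rows when nothing is noteworthy.
#' @examples
#' validate_design(complete_sw(3, 1, 10))           # empty
#' validate_design(design_pattern(rbind(c(1, 0))))  # non-monotone
#' @export
validate_design <- function(pattern) {
  stopifnot(inherits(pattern, "sw_design"))
  cl <- pattern$cells
  findings <- list()
  add <- function(type, where, message)
    findings[[length(findings) + 1L]] <<-
      data.frame(type = type, where = where, message = message)

  for (j in seq_len(nrow(cl)))
    if (!.is_monotone_row(cl[j, ]))
      add("non-monotone exposure", rownames(cl)[j],
          "cluster reverts from exposed to control")
  empty <- which(colSums(!is.na(cl)) == 0L)
  for (t in empty)
    add("empty period", colnames(cl)[t],
        "no cluster observed in this period; it will be dropped")
  for (j in seq_len(nrow(cl))) {
    obs <- cl[j, !is.na(cl[j, ])]
    if (length(unique(obs)) == 1L)
      add("no exposure contrast", rownames(cl)[j],
          sprintf("cluster observed only under %s",
                  if (obs[1] == 1L) "intervention" else "control"))
  }
  n_obs <- colSums(!is.na(cl))
  partial <- which(n_obs > 0L & n_obs < nrow(cl))
  if (length(partial))
    add("partially observed periods",
        paste(colnames(cl)[partial], collapse = ","),
        sprintf("%d period(s) observed by a strict subset of clusters",
                length(partial)))
  if (length(findings)) do.call(rbind, findings)
  else data.frame(type = character(), where = character(),
                  message = character())
}

# Remove one observed cell (set it unobserved); used by the information
# monotonicity property and by incomplete-design consistency checks.
#' Mark a single observed cell of a design as unobserved
#'
#' @param pattern an [sw_design][design_pattern] object.
#' @param cluster,period indices of the cell to delete.
#' @return the modified design.
#' @export
delete_cell <- function(pattern, cluster, period) {
  stopifnot(inherits(pattern, "sw_design"))
  if (is.na(pattern$cells[cluster, period]))
    stop("cell is already unobserved", call. = FALSE)
  cells <- pattern$cells
  sizes <- pattern$cell_sizes
  cells[cluster, period] <- NA_integer_
  sizes[cluster, period] <- 0L
  design_pattern(cells, sizes, n_groups = pattern$n_groups,
                 cluster_labels = rownames(cells),
                 period_labels = colnames(cells))
}
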