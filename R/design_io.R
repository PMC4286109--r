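#' Read and write design pattern CSV files
#'
#' The on-disk format is one row per cluster with comma-separated tokens
#' `0` (control), `1` (exposed) and `.` (unobserved).  An optional header
#' row `cluster,p1,...,ps` may be present, in which case the first column
#' carries cluster labels.  A companion CSV of identical shape may supply
#' per-cell sizes; otherwise a constant `cell_size` is used.
#'
#' @param path path of the design CSV.
#' @param sizes_path optional path of a cell-size CSV of identical shape.
#' @param cell_size constant cell size used when `sizes_path` is absent.
#' @param n_groups groups per cluster attached to the pattern.
#' @return `read_design()` returns an [sw_design][design_pattern];
#'   `write_design()` returns `path` invisibly.  Writing then reading a
#'   pattern reproduces it exactly (cell sizes via `sizes_path`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_design(complete_sw(2, 1, 10), f)
#' read_design(f, cell_size = 10)
#' @export
read_design <- function(path, sizes_path = NULL, cell_size = 1,
                        n_groups = 1) {
  if (!file.exists(path))
    stop(sprintf("design file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("empty design file: %s", path), call. = FALSE)
  rows <- strsplit(lines, ",", fixed = TRUE)
  rows <- lapply(rows, trimws)

  has_header <- !all(rows[[1]] %in% c("0", "1", "."))
  cluster_labels <- NULL
  if (has_header) {
    header <- rows[[1]]
    rows <- rows[-1]
    if (length(rows) == 0L)
      stop(sprintf("design file %s has a header but no data rows", path),
           call. = FALSE)
    # header row implies a leading label column
    rows <- lapply(rows, function(r) r)
    cluster_labels <- vapply(rows, `[`, character(1), 1L)
    rows <- lapply(rows, `[`, -1L)
    if (length(header) - 1L != length(rows[[1]]))
      stop(sprintf("header of %s names %d periods but row 1 has %d cells",
                   path, length(header) - 1L, length(rows[[1]])),
           call. = FALSE)
  }

  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged design file %s: row %d has %d cells, expected %d",
                 path, bad, widths[bad], widths[1]), call. = FALSE)
  }
  for (i in seq_along(rows)) {
    bad <- which(!(rows[[i]] %in% c("0", "1", ".")))
    if (length(bad))
      stop(sprintf("unknown token %s in %s at row %d, column %d",
                   dQuote(rows[[i]][bad[1]]), path, i, bad[1]),
           call. = FALSE)
  }
  cells <- do.call(rbind, rows)

  sizes <- cell_size
  if (!is.null(sizes_path)) {
    sz <- utils::read.csv(sizes_path, header = has_header,
                          row.names = if (has_header) 1 else NULL)
    sizes <- as.matrix(sz)
    if (!identical(dim(sizes), dim(cells)))
      stop(sprintf("cell-size file %s has shape %dx%d, design has %dx%d",
                   sizes_path, nrow(sizes), ncol(sizes),
                   nrow(cells), ncol(cells)), call. = FALSE)
  }
  design_pattern(cells, cell_sizes = sizes, n_groups = n_groups,
                 cluster_labels = cluster_labels)
}

#' @param pattern an [sw_design][design_pattern] to write.
#' @rdname read_design
#' @export
write_design <- function(pattern, path, sizes_path = NULL) {
  stopifnot(inherits(pattern, "sw_design"))
  grid <- ifelse(is.na(pattern$cells), ".", as.character(pattern$cells))
  header <- paste(c("cluster", colnames(pattern$cells)), collapse = ",")
  body <- vapply(seq_len(nrow(grid)), function(j)
    paste(c(rownames(pattern$cells)[j], grid[j, ]), collapse = ","),
    character(1))
  writeLines(c(header, body), path)
  if (!is.null(sizes_path)) {
    sz <- as.data.frame(pattern$cell_sizes)
    utils::write.csv(cbind(cluster = rownames(pattern$cells), sz),
                     sizes_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
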