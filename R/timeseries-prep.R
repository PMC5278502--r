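#' Normalize traces to their value at the start of imaging
#'
#' Divides every cell's intensities by its value at the first acquired
#' frame (t = 0 of the recording), so each trace starts at exactly 1 and
#' downstream values read as fold-change from the start. Cells whose
#' first value is not strictly positive cannot be normalized and are
#' excluded, with the reason recorded in the `qc_excluded` attribute.
#'
#' Normalization is idempotent and preserves peak times and periods.
#'
#' @param traces long data.frame with `cell_id`, `time_hr`, `intensity`
#'   (other columns pass through).
#' @return the normalized traces; excluded cells are dropped and listed
#'   in `attr(, "qc_excluded")`.
#' @export
normalize_to_start <- function(traces) {
  stopifnot(all(c("cell_id", "time_hr", "intensity") %in% names(traces)))
  excluded <- character(0)
  out <- lapply(split(traces, traces$cell_id), function(tr) {
    tr <- tr[order(tr$time_hr), ]
    if (nrow(tr) < 2L || tr$intensity[1] <= 0) {
      excluded <<- c(excluded, tr$cell_id[1])
      return(NULL)
    }
    tr$intensity <- tr$intensity / tr$intensity[1]
    tr
  })
  res <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                          make.row.names = FALSE))
  attr(res, "qc_excluded") <- excluded
  res
}

#' Build the heatmap matrix of normalized single-cell time courses
#'
#' One row per cell, one column per timepoint, rows ordered by the
#' highest intensity reached during the first `window_hr` hours
#' (descending; ties broken by cell id). All cells must share the same
#' sampling grid. Values above `ceiling` (when given) are flagged in the
#' `over_ceiling` attribute, mirroring the convention of marking values
#' that exceed the uppermost colour-scale bin.
#'
#' @param traces long data.frame of (normalized) traces.
#' @param window_hr row-ordering window in hours, default 24.
#' @param ceiling optional display ceiling.
#' @return numeric matrix of class `heatmap_matrix` with `row_order_key`
#'   and `over_ceiling` attributes; columns named by time in hours.
#' @export
build_heatmap <- function(traces, window_hr = 24, ceiling = NULL) {
  stopifnot(all(c("cell_id", "time_hr", "intensity") %in% names(traces)))
  cells <- split(traces, traces$cell_id)
  grids <- lapply(cells, function(tr) sort(tr$time_hr))
  grid <- grids[[1]]
  same <- vapply(grids, function(g) {
    length(g) == length(grid) && all(g == grid)
  }, logical(1))
  if (!all(same)) {
    stop("all traces must share one sampling grid (resampling is out of scope)")
  }
  ids <- names(cells)
  mat <- t(vapply(cells, function(tr) {
    tr$intensity[order(tr$time_hr)]
  }, numeric(length(grid))))
  rownames(mat) <- ids
  colnames(mat) <- format(grid, trim = TRUE)
  key <- apply(mat[, grid >= 0 & grid <= window_hr, drop = FALSE], 1, max)
  ord <- order(-key, ids)
  mat <- mat[ord, , drop = FALSE]
  structure(mat, row_order_key = key[ord],
            over_ceiling = if (is.null(ceiling)) NULL else mat > ceiling,
            time_hr = grid, class = c("heatmap_matrix", "matrix"))
}

#' Plot a heatmap matrix
#'
#' @param x a `heatmap_matrix`.
#' @param col colour palette.
#' @param ... passed to [graphics::image()].
#' @export
plot.heatmap_matrix <- function(x, col = grDevices::hcl.colors(64, "YlOrRd",
                                                               rev = TRUE),
                                ...) {
  m <- unclass(x)
  grid <- attr(x, "time_hr")
  graphics::image(x = grid, y = seq_len(nrow(m)), z = t(m[rev(seq_len(nrow(m))), ]),
                  col = col, xlab = "time (h)", ylab = "cell",
                  yaxt = "n", ...)
  invisible(x)
}

#' Read or write trace tables in the interchange CSV layout
#'
#' Columns: `cell_id`, `neuron_class`, `group`, `time_hr`, `intensity`.
#'
#' @param path CSV file path.
#' @return `read_traces`: a data.frame.
#' @export
read_traces <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_hr", "intensity")
  if (!all(need %in% names(tr))) {
    stop("trace CSV must contain columns: ", paste(need, collapse = ", "))
  }
  tr
}

#' @rdname read_traces
#' @param traces data.frame to write.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}
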