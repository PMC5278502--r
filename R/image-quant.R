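#' Sum-projection of a 3D volume
#'
#' Collapses a `[z, y, x]` intensity volume to a 2D image by summing over
#' z (a SUM-stack). Total intensity is conserved exactly; integer input
#' is widened to double before summation.
#'
#' @param volume 3D numeric or integer array, `[z, y, x]`.
#' @return 2D numeric matrix `[y, x]`.
#' @export
sum_project <- function(volume) {
  if (!is.array(volume) || length(dim(volume)) != 3L) {
    stop("volume must be a 3D array [z, y, x]")
  }
  if (any(dim(volume) == 0L)) stop("volume must be non-empty")
  storage.mode(volume) <- "double"
  colSums(volume, dims = 1)
}

#' Define a set of cell and background ROIs on a projected image
#'
#' Cell ROIs are named logical masks on the 2D projection; exactly three
#' background regions are required (the background estimate is the mean
#' of the three regions' mean intensities, mirroring the measurement of
#' three nearby areas per field). Cell and background regions must not
#' overlap.
#'
#' @param cell_rois named list of logical matrices.
#' @param background_rois list of exactly 3 logical matrices, same
#'   dimensions as the cell masks.
#' @return list of class `roi_set`.
#' @export
roi_set <- function(cell_rois, background_rois) {
  if (length(background_rois) != 3L) {
    stop("exactly 3 background regions are required")
  }
  if (is.null(names(cell_rois)) || any(!nzchar(names(cell_rois)))) {
    stop("cell_rois must be a named list")
  }
  dims <- unique(lapply(c(cell_rois, background_rois), dim))
  if (length(dims) != 1L) stop("all ROI masks must share dimensions")
  bg_any <- Reduce(`|`, background_rois)
  for (id in names(cell_rois)) {
    if (any(cell_rois[[id]] & bg_any)) {
      stop("cell ROI '", id, "' overlaps a background region")
    }
  }
  structure(list(cell_rois = cell_rois, background_rois = background_rois),
            class = "roi_set")
}

#' Background-corrected mean ROI intensity of one cell
#'
#' Mean intensity over the cell's ROI minus the mean of the three
#' background-region means. A negative value is returned as-is (with the
#' `negative` attribute set) rather than clipped: silently clipping would
#' bias downstream rhythm amplitudes.
#'
#' @param image 2D numeric matrix (typically a [sum_project()] output).
#' @param rois an `roi_set`.
#' @param cell_id name of the cell ROI to quantify.
#' @return numeric scalar with attribute `negative`.
#' @export
corrected_intensity <- function(image, rois, cell_id) {
  stopifnot(inherits(rois, "roi_set"))
  if (!cell_id %in% names(rois$cell_rois)) {
    stop("no ROI for cell '", cell_id, "'")
  }
  raw <- mean(image[rois$cell_rois[[cell_id]]])
  bg <- mean(vapply(rois$background_rois, function(m) mean(image[m]),
                    numeric(1)))
  out <- raw - bg
  attr(out, "negative") <- out < 0
  out
}

#' Quantify all cells of an ROI set on one image
#'
#' @param image 2D matrix.
#' @param rois an `roi_set`.
#' @param time_hr optional timepoint recorded in the output.
#' @return data.frame: `cell_id`, `time_hr`, `raw_mean`,
#'   `background_mean`, `corrected_intensity`, `qc_negative`.
#' @export
quantify_rois <- function(image, rois, time_hr = NA_real_) {
  stopifnot(inherits(rois, "roi_set"))
  bg <- mean(vapply(rois$background_rois, function(m) mean(image[m]),
                    numeric(1)))
  ids <- names(rois$cell_rois)
  raw <- vapply(ids, function(id) mean(image[rois$cell_rois[[id]]]),
                numeric(1))
  data.frame(cell_id = ids, time_hr = time_hr, raw_mean = unname(raw),
             background_mean = bg, corrected_intensity = unname(raw) - bg,
             qc_negative = unname(raw) - bg < 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 26-connected component labelling of a 3D logical mask
#'
#' Breadth-first labelling with 26-neighbourhood connectivity (faces,
#' edges and corners), the standard choice for blob-like somata.
#'
#' @param mask 3D logical array.
#' @return integer array of component labels (0 = background).
#' @export
label_components_3d <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  loff <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
  labels <- array(0L, pd)
  todo <- which(pm)
  lab <- 0L
  for (s in todo) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    labels[s] <- lab
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, loff, `+`)))
      nb <- nb[pm[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
  }
  labels[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

#' 3D-mask intensity sum after background subtraction
#'
#' Reproduces the 3D quantification scheme used for cultured neurons: the
#' background is subtracted voxelwise (floored at zero), voxels above
#' `threshold` form 26-connected components (one mask per cell body), and
#' the summed background-subtracted intensity of each component is
#' returned.
#'
#' @param volume 3D array `[z, y, x]`.
#' @param threshold mask threshold on the background-subtracted
#'   intensity, > 0.
#' @param background background level subtracted before thresholding.
#' @return list: `mask` (integer label array), `component_sums` (named
#'   numeric, one per component, descending), `total`, `empty` flag.
#' @export
mask_intensity_sum <- function(volume, threshold, background = 0) {
  if (threshold <= 0) stop("threshold must be positive")
  v <- pmax(volume - background, 0)
  dim(v) <- dim(volume)
  above <- v > threshold
  if (!any(above)) {
    return(list(mask = array(0L, dim(volume)),
                component_sums = numeric(0), total = 0, empty = TRUE))
  }
  labels <- label_components_3d(above)
  sums <- tapply(v[labels > 0], labels[labels > 0], sum)
  sums <- sort(as.numeric(sums), decreasing = TRUE)
  names(sums) <- sprintf("component_%d", seq_along(sums))
  list(mask = labels, component_sums = sums, total = sum(sums),
       empty = FALSE)
}

#' Nuclear/cytoplasmic fluorescence ratio
#'
#' Ratio of background-corrected mean intensities over disjoint nuclear
#' and cytoplasmic ROIs. Undefined (error) when the corrected cytoplasmic
#' mean is not positive.
#'
#' @param image 2D matrix.
#' @param nuclear_roi,cytoplasmic_roi disjoint logical masks.
#' @param background_mean background level subtracted from both means.
#' @return dimensionless ratio.
#' @export
nuclear_cytoplasmic_ratio <- function(image, nuclear_roi, cytoplasmic_roi,
                                      background_mean = 0) {
  if (any(nuclear_roi & cytoplasmic_roi)) {
    stop("nuclear and cytoplasmic ROIs must be disjoint")
  }
  nuc <- mean(image[nuclear_roi]) - background_mean
  cyt <- mean(image[cytoplasmic_roi]) - background_mean
  if (cyt <= 0) {
    stop("corrected cytoplasmic mean is not positive; ratio undefined")
  }
  nuc / cyt
}
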