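#' Specify a synthetic 3D image stack
#'
#' Describes a volume populated with blob-like cell bodies for validating
#' the image-quantification stage against known ground truth. Each cell is
#' a solid sphere of uniform intensity with a Gaussian rim: voxel value
#' `peak` for distance `d <= radius` from the centre, falling off as
#' `exp(-(d - radius)^2 / (2 * sigma_edge^2))` beyond. A filled soma with
#' a soft optical edge is both more realistic than a pure Gaussian blob
#' and keeps essentially all of a cell's integrated intensity above any
#' low threshold on its peak, so threshold-based 3D masks can be scored
#' against the full integral.
#'
#' @param shape integer `(z, y, x)` voxel counts.
#' @param cells data.frame with columns `cell_id`, `z`, `y`, `x` (centre,
#'   1-based voxel coordinates), `radius` (voxels), `peak` (AU),
#'   `neuron_class`.
#' @param background_level flat background, AU.
#' @param background_gradient additive AU per voxel along the x axis.
#' @param noise_model `list(type = "gaussian", sd = ...)`,
#'   `list(type = "poisson")`, or `list(type = "none")`.
#' @param sigma_edge rim width in voxels.
#' @param voxel_spacing microns per voxel, `(z, y, x)`.
#' @return list of class `stack_spec`.
#' @export
stack_spec <- function(shape, cells, background_level = 10,
                       background_gradient = 0,
                       noise_model = list(type = "none"),
                       sigma_edge = 1, voxel_spacing = c(2, 0.5, 0.5)) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  req <- c("cell_id", "z", "y", "x", "radius", "peak")
  if (!all(req %in% names(cells))) {
    stop("cells needs columns: ", paste(req, collapse = ", "))
  }
  if (!"neuron_class" %in% names(cells)) {
    cells$neuron_class <- rep("unknown", nrow(cells))
  }
  inside <- cells$z >= 1 & cells$z <= shape[1] &
    cells$y >= 1 & cells$y <= shape[2] &
    cells$x >= 1 & cells$x <= shape[3]
  if (!all(inside)) stop("all cell centres must lie inside the volume")
  if (any(cells$peak <= background_level)) {
    stop("every peak intensity must exceed the background level")
  }
  structure(list(shape = as.integer(shape), cells = cells,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 noise_model = noise_model, sigma_edge = sigma_edge,
                 voxel_spacing = voxel_spacing),
            class = "stack_spec")
}

# unit-peak blob volume for one cell (solid core + Gaussian rim)
blob_volume <- function(shape, center, radius, sigma_edge) {
  z <- slice.index(array(0, shape), 1)
  y <- slice.index(array(0, shape), 2)
  x <- slice.index(array(0, shape), 3)
  d <- sqrt((z - center[1])^2 + (y - center[2])^2 + (x - center[3])^2)
  exp(-pmax(d - radius, 0)^2 / (2 * sigma_edge^2))
}

#' Render a time series of 3D stacks from per-cell traces
#'
#' Builds one volume per timepoint: background plus gradient, plus each
#' cell's blob scaled so that its integrated intensity follows that
#' cell's trace (relative to the trace's first value), plus optional
#' noise. The exact integrated intensity contributed by every cell at
#' every timepoint is recorded as ground truth; cells whose blobs can
#' overlap are flagged.
#'
#' @param spec a [stack_spec()]; `spec$cells$cell_id` must match the cell
#'   ids present in `traces`.
#' @param traces long data.frame (`cell_id`, `time_hr`, `intensity`), one
#'   trace per cell on a shared grid.
#' @param seed RNG seed for the noise model.
#' @return list of class `stack_series`: `volumes` (list of 3D arrays,
#'   `[z, y, x]`), `time_hr`, `channel`, `voxel_spacing`, `ground_truth`
#'   (`cell_id`, `time_hr`, `integrated_intensity`, `overlapping`), and
#'   `spec`.
#' @export
render_stack_series <- function(spec, traces, seed = 1) {
  stopifnot(inherits(spec, "stack_spec"))
  ids <- spec$cells$cell_id
  if (!setequal(ids, unique(traces$cell_id))) {
    stop("traces must contain exactly one trace per cell in the spec")
  }
  grid <- sort(unique(traces$time_hr))
  if (!length(grid)) grid <- 0  # cell-free volume: single timepoint
  set.seed(seed)
  nz <- spec$shape[1]
  base <- array(spec$background_level, spec$shape)
  if (spec$background_gradient != 0) {
    xidx <- slice.index(base, 3)
    base <- base + spec$background_gradient * (xidx - 1)
  }
  blobs <- lapply(seq_along(ids), function(i) {
    ci <- spec$cells[i, ]
    blob_volume(spec$shape, c(ci$z, ci$y, ci$x), ci$radius, spec$sigma_edge)
  })
  blob_sums <- vapply(blobs, sum, numeric(1))
  # overlap flag: centre separation below the sum of effective radii
  n <- length(ids)
  overlapping <- rep(FALSE, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ci <- spec$cells[i, ]; cj <- spec$cells[j, ]
      sep <- sqrt((ci$z - cj$z)^2 + (ci$y - cj$y)^2 + (ci$x - cj$x)^2)
      if (sep < ci$radius + cj$radius + 4 * spec$sigma_edge) {
        overlapping[c(i, j)] <- TRUE
      }
    }
  }
  volumes <- vector("list", length(grid))
  gt <- list()
  for (ti in seq_along(grid)) {
    vol <- base
    for (i in seq_along(ids)) {
      tr <- traces[traces$cell_id == ids[i], ]
      tr <- tr[order(tr$time_hr), ]
      scale <- tr$intensity[ti] / tr$intensity[1]
      vol <- vol + blobs[[i]] * spec$cells$peak[i] * scale
      gt[[length(gt) + 1]] <- data.frame(
        cell_id = ids[i], time_hr = grid[ti],
        integrated_intensity = blob_sums[i] * spec$cells$peak[i] * scale,
        overlapping = overlapping[i], stringsAsFactors = FALSE)
    }
    nm <- spec$noise_model
    if (identical(nm$type, "gaussian") && nm$sd > 0) {
      vol <- vol + array(stats::rnorm(length(vol), 0, nm$sd), dim(vol))
    } else if (identical(nm$type, "poisson")) {
      vol <- array(stats::rpois(length(vol), pmax(vol, 0)), dim(vol))
    }
    volumes[[ti]] <- vol
  }
  structure(list(volumes = volumes, time_hr = grid, channel = "synthetic",
                 voxel_spacing = spec$voxel_spacing,
                 ground_truth = do.call(rbind, gt), spec = spec),
            class = "stack_series")
}

#' Write a stack series as multi-page TIFFs plus a JSON manifest
#'
#' One 32-bit float TIFF per timepoint (one page per z slice), intensities
#' divided by a global scale recorded in `manifest.json` together with
#' the time grid, channel and voxel spacing. Ground truth goes to
#' `ground_truth.csv` beside the images.
#'
#' @param series a `stack_series`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack_series <- function(series, dir) {
  stopifnot(inherits(series, "stack_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(vapply(series$volumes, max, numeric(1)), 1e-12)
  files <- sprintf("t%03d.tif", seq_along(series$volumes))
  for (i in seq_along(series$volumes)) {
    vol <- series$volumes[[i]] / scale
    pages <- lapply(seq_len(dim(vol)[1]), function(z) vol[z, , ])
    tiff::writeTIFF(pages, file.path(dir, files[i]), bits.per.sample = 32L)
  }
  manifest <- list(files = files, time_hr = series$time_hr,
                   channel = series$channel,
                   voxel_spacing = series$voxel_spacing,
                   intensity_scale = scale)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(series$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a stack series written by [write_stack_series()]
#'
#' @param dir directory containing the TIFFs and `manifest.json`.
#' @return a `stack_series` (without spec or ground truth unless
#'   `ground_truth.csv` is present).
#' @export
read_stack_series <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  volumes <- lapply(manifest$files, function(f) {
    pages <- tiff::readTIFF(file.path(dir, f), all = TRUE)
    vol <- array(0, c(length(pages), dim(pages[[1]])[1:2]))
    for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
    vol * manifest$intensity_scale
  })
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) {
    utils::read.csv(gt_path, stringsAsFactors = FALSE)
  } else NULL
  structure(list(volumes = volumes, time_hr = manifest$time_hr,
                 channel = manifest$channel,
                 voxel_spacing = manifest$voxel_spacing,
                 ground_truth = gt, spec = NULL),
            class = "stack_series")
}
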