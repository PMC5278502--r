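#' Configuration of the rhythmicity classifier
#'
#' Bundles the tunable choices of the dual-criterion call: the circadian
#' band, the AR order rule and spectrum grid of the MESA stage, the
#' minimum trace length, and the Burg taper.
#'
#' @param band_hr circadian period band in hours (inclusive).
#' @param order_rule AR order rule for [estimate_period()].
#' @param max_order AR order cap.
#' @param n_frequencies spectrum grid size.
#' @param min_points minimum usable trace length.
#' @param taper Burg taper.
#' @return list of class `rhythm_config`.
#' @export
rhythm_config <- function(band_hr = c(18, 36), order_rule = "n_over_3",
                          max_order = 20, n_frequencies = 2048,
                          min_points = 8, taper = "parabolic") {
  structure(list(band_hr = band_hr, order_rule = order_rule,
                 max_order = max_order, n_frequencies = n_frequencies,
                 min_points = min_points, taper = taper),
            class = "rhythm_config")
}

#' Classify one cell as circadian or not
#'
#' Applies both rhythmicity criteria to a single trace and scores the
#' cell as circadian only when both fire: (i) the degree-6 polynomial
#' trend shows at least one peak-to-peak interval inside the band, and
#' (ii) MESA finds a dominant spectral period inside the band. The
#' reported period is always the MESA period; the trend stage contributes
#' a boolean only, never a period estimate. Both criteria run on the raw
#' (non-normalized) intensities; the verdict is unchanged by positive
#' rescaling.
#'
#' Traces failing QC (too short, or a non-positive starting value that
#' precludes normalization downstream) are returned non-circadian with
#' the reason in `qc_flags` and can be excluded from cohort denominators.
#'
#' @param trace data.frame for one cell (`time_hr`, `intensity`, and
#'   optionally `cell_id`, `neuron_class`, `group`).
#' @param config a [rhythm_config()].
#' @return one-row data.frame (a rhythm call): `cell_id`, `neuron_class`,
#'   `trend_circadian`, `n_trend_peaks`, `mesa_period_hr`, `mesa_in_band`,
#'   `is_circadian`, `qc_flags`.
#' @export
classify_cell <- function(trace, config = rhythm_config()) {
  trace <- trace[order(trace$time_hr), ]
  id <- if ("cell_id" %in% names(trace)) trace$cell_id[1] else NA_character_
  cls <- if ("neuron_class" %in% names(trace)) trace$neuron_class[1] else
    NA_character_
  call0 <- data.frame(cell_id = id, neuron_class = cls,
                      trend_circadian = FALSE, n_trend_peaks = 0L,
                      mesa_period_hr = NA_real_, mesa_in_band = FALSE,
                      is_circadian = FALSE, qc_flags = "",
                      stringsAsFactors = FALSE)
  if (nrow(trace) < config$min_points) {
    call0$qc_flags <- "too_short"
    return(call0)
  }
  if (trace$intensity[1] <= 0) {
    call0$qc_flags <- "nonpositive_start"
    return(call0)
  }
  dt <- diff(trace$time_hr)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-8 * dt[1]) {
    call0$qc_flags <- "irregular_sampling"
    return(call0)
  }
  tf <- fit_trend(trace$time_hr, trace$intensity)
  iv <- peak_to_peak_intervals(tf)
  trend_ok <- trend_is_circadian(iv, config$band_hr)
  pe <- estimate_period(trace$intensity, dt[1],
                        order_rule = config$order_rule,
                        band_hr = config$band_hr,
                        n_frequencies = config$n_frequencies,
                        max_order = config$max_order, taper = config$taper)
  call0$trend_circadian <- trend_ok
  call0$n_trend_peaks <- length(tf$peak_times_hr)
  call0$mesa_period_hr <- pe$period_hr
  call0$mesa_in_band <- pe$in_band
  call0$is_circadian <- trend_ok && pe$in_band
  if (!is.na(pe$qc)) call0$qc_flags <- pe$qc
  call0
}

#' Classify every cell of a trace table
#'
#' @param traces long data.frame of traces.
#' @param config a [rhythm_config()].
#' @return data.frame of rhythm calls, one row per cell.
#' @export
classify_cohort <- function(traces, config = rhythm_config()) {
  calls <- lapply(split(traces, traces$cell_id), classify_cell,
                  config = config)
  do.call(rbind, c(calls, make.row.names = FALSE))
}

#' Summarize rhythm calls per neuron class
#'
#' Cells that passed QC form the denominator ("detected" cells); the
#' rhythmic fraction and the mean +/- SEM of the MESA periods are
#' computed over them. SEM is the sample standard deviation divided by
#' the square root of the number of rhythmic cells; with no rhythmic
#' cells the mean and SEM are `NA`.
#'
#' @param calls data.frame of rhythm calls from [classify_cohort()].
#' @param include_qc_failures count QC-failed cells in the denominator
#'   (default FALSE).
#' @return data.frame: `neuron_class`, `n_detected`, `n_rhythmic`,
#'   `fraction_rhythmic`, `mean_period_hr`, `sem_period_hr`.
#' @export
summarize_cohort <- function(calls, include_qc_failures = FALSE) {
  if (!include_qc_failures) calls <- calls[calls$qc_flags == "", ]
  if (!nrow(calls)) stop("no detected cells to summarize")
  out <- lapply(split(calls, calls$neuron_class), function(cc) {
    per <- cc$mesa_period_hr[cc$is_circadian]
    n_r <- sum(cc$is_circadian)
    data.frame(
      neuron_class = cc$neuron_class[1],
      n_detected = nrow(cc), n_rhythmic = n_r,
      fraction_rhythmic = n_r / nrow(cc),
      mean_period_hr = if (n_r) round(mean(per), 2) else NA_real_,
      sem_period_hr = if (n_r > 1) round(stats::sd(per) / sqrt(n_r), 2) else
        NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
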