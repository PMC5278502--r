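#' Fit a sixth-order polynomial trend to a trace
#'
#' The rhythmicity screen pairs the spectral estimate with a trend-based
#' criterion: a degree-6 polynomial is fitted to the intensity time course
#' by ordinary least squares and its interior maxima are read off as peak
#' times. Degree 6 accommodates up to five interior extrema, enough for the
#' one-to-two rhythm cycles visible in a 48-h recording. The abscissa is
#' shifted and scaled to \[-1, 1\] before fitting for numerical
#' conditioning; coefficients are reported both on that internal scale and
#' on the hour scale.
#'
#' Peaks are located by root-finding on the exact polynomial derivative
#' (not by argmax over a sampling grid), so the result does not depend on
#' any display grid density. Only maxima strictly inside the observed
#' window count: an extremum at or beyond either end of the recording
#' cannot anchor a measurable peak-to-peak interval.
#'
#' @param time_hr strictly increasing times in hours (>= 8 points).
#' @param intensity intensities, same length.
#' @return object of class `trend_fit`: `coefficients` (degree-6 polynomial
#'   in hours, constant term first), `coefficients_scaled`, `fitted_values`,
#'   `peak_times_hr` (sorted interior maxima), `time_range_hr`.
#' @export
fit_trend <- function(time_hr, intensity) {
  stopifnot(length(time_hr) == length(intensity))
  if (length(time_hr) < 8L) {
    stop("fit_trend needs at least 8 timepoints for a degree-6 fit")
  }
  if (any(diff(time_hr) <= 0)) stop("time_hr must be strictly increasing")
  ctr <- mean(range(time_hr))
  half <- diff(range(time_hr)) / 2
  u <- (time_hr - ctr) / half
  fit <- stats::lm(intensity ~ stats::poly(u, 6, raw = TRUE))
  cs <- unname(stats::coef(fit))
  cs[is.na(cs)] <- 0
  peaks_u <- polynomial_maxima(cs, -1, 1)
  structure(
    list(coefficients = rescale_poly(cs, ctr, half),
         coefficients_scaled = cs,
         fitted_values = unname(stats::fitted(fit)),
         peak_times_hr = sort(peaks_u * half + ctr),
         time_range_hr = range(time_hr)),
    class = "trend_fit")
}

# interior local maxima of sum(coef[j+1] * u^j) on (lo, hi), via roots of the
# derivative and the sign of the second derivative
polynomial_maxima <- function(coefs, lo, hi) {
  # coefficients negligible against the polynomial's scale are numerical
  # noise from the least-squares solve, not real curvature
  coefs[abs(coefs) < 1e-9 * max(abs(coefs))] <- 0
  dcoef <- coefs[-1] * seq_len(length(coefs) - 1)
  if (all(dcoef == 0)) return(numeric(0))
  while (length(dcoef) > 1 && dcoef[length(dcoef)] == 0) {
    dcoef <- dcoef[-length(dcoef)]
  }
  if (length(dcoef) < 2) return(numeric(0))  # constant, nonzero derivative
  rts <- polyroot(dcoef)
  re <- Re(rts)[abs(Im(rts)) < 1e-7 * (1 + abs(Re(rts)))]
  eps <- 1e-9 * (hi - lo)
  re <- re[re > lo + eps & re < hi - eps]
  if (!length(re)) return(numeric(0))
  d2 <- vapply(re, function(u0) {
    j <- seq_along(dcoef)[-1]  # powers >= 1 of the derivative polynomial
    sum(dcoef[-1] * (j - 1) * u0^(j - 2))
  }, numeric(1))
  re[d2 < 0]
}

# convert coefficients in u = (t - ctr)/half back to the t (hour) basis
rescale_poly <- function(cs, ctr, half) {
  deg <- length(cs) - 1
  out <- numeric(deg + 1)
  for (j in 0:deg) {
    if (cs[j + 1] == 0) next
    # cs_j * ((t - ctr)/half)^j  ->  binomial expansion in t
    for (i in 0:j) {
      out[i + 1] <- out[i + 1] +
        cs[j + 1] * choose(j, i) * (-ctr)^(j - i) / half^j
    }
  }
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("degree-6 trend fit on [%g, %g] h; %d interior peak(s)\n",
              x$time_range_hr[1], x$time_range_hr[2],
              length(x$peak_times_hr)))
  invisible(x)
}

#' Peak-to-peak intervals of a fitted trend
#'
#' Differences between consecutive interior maxima of the fitted
#' polynomial, in hours. Fewer than two peaks yields an empty vector: a
#' window showing at most one peak cannot exhibit a measurable cycle.
#'
#' @param fit a `trend_fit`.
#' @return numeric vector of intervals (possibly empty).
#' @export
peak_to_peak_intervals <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  if (length(fit$peak_times_hr) < 2L) return(numeric(0))
  diff(fit$peak_times_hr)
}

#' Trend-based circadian criterion
#'
#' TRUE when at least one peak-to-peak interval falls within the circadian
#' band, endpoints inclusive.
#'
#' @param intervals numeric vector of peak-to-peak intervals in hours.
#' @param band_hr length-2 band, default `c(18, 36)`.
#' @return logical scalar.
#' @export
trend_is_circadian <- function(intervals, band_hr = c(18, 36)) {
  any(intervals >= band_hr[1] & intervals <= band_hr[2])
}
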