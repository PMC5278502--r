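#' Two-way fixed-effects ANOVA for a drug-response stratum
#'
#' Treatment group and timepoint are crossed fixed factors; the response
#' is the normalized intensity of each cell at each timepoint. Sums of
#' squares are marginal (Type III, computed on sum-to-zero contrasts), so
#' unbalanced designs are handled; on balanced data the F ratios equal
#' the textbook mean-square ratios.
#'
#' Cells (not brains) are the unit of observation, and the repeated
#' measurement of a cell across timepoints is treated as independent --
#' a documented limitation matching the analysis convention the package
#' reproduces.
#'
#' @param data data.frame with the response and both factor columns.
#' @param response column name of the response (default `"intensity"`).
#' @param factor_a,factor_b factor column names (default `"group"` and
#'   `"time_hr"`).
#' @return data.frame of class `anova_table` (`term`, `df`, `F`,
#'   `p_value`, plus error df/MS rows as attributes `df_error` and
#'   `ms_error`); the fitted `lm` is attached as attribute `fit`.
#' @export
two_way_anova <- function(data, response = "intensity",
                          factor_a = "group", factor_b = "time_hr") {
  da <- data.frame(y = data[[response]],
                   A = factor(data[[factor_a]]),
                   B = factor(data[[factor_b]]))
  if (any(!is.finite(da$y))) stop("response contains non-finite values")
  if (nlevels(da$A) < 2 || nlevels(da$B) < 2) {
    stop("both factors need at least 2 levels")
  }
  tab <- table(da$A, da$B)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s", factor_a,
                 rownames(tab)[empty[1]], factor_b, colnames(tab)[empty[2]]))
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(y ~ A * B, data = da)
  an <- car::Anova(fit, type = 3)
  rows <- c("A", "B", "A:B")
  terms <- c(factor_a, factor_b, "interaction")
  out <- data.frame(term = terms,
                    df = an[rows, "Df"],
                    F = an[rows, "F value"],
                    p_value = an[rows, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  attr(out, "df_error") <- an["Residuals", "Df"]
  attr(out, "ms_error") <- an["Residuals", "Sum Sq"] / an["Residuals", "Df"]
  attr(out, "fit") <- fit
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Sidak correction for multiple comparisons
#'
#' \eqn{p_{adj} = 1 - (1 - p)^m}, computed on the log scale for accuracy
#' at small p and capped at 1. Monotone in both arguments and never below
#' the raw p-value.
#'
#' @param p_raw raw p-value(s) in \[0, 1\].
#' @param m family size, >= 1.
#' @return adjusted p-value(s).
#' @examples
#' sidak_adjust(0.02, 3)  # 0.058808
#' @export
sidak_adjust <- function(p_raw, m) {
  if (m < 1 || m != floor(m)) stop("m must be a positive integer")
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("p_raw must lie in [0, 1]")
  }
  pmin(1, pmax(p_raw, -expm1(m * log1p(-p_raw))))
}

#' Significance tier of an adjusted p-value
#'
#' Standard asterisk tiers: `****` < 0.0001, `***` < 0.001, `**` < 0.01,
#' `*` < 0.05, otherwise `ns`.
#'
#' @param p adjusted p-value(s).
#' @return character vector of tiers.
#' @export
significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = FALSE) |> as.character()
}

#' Per-timepoint treatment-vs-reference comparisons with Sidak correction
#'
#' For each neuron class, fits the two-way (group x time) ANOVA and then
#' compares every treatment group against the reference group at every
#' timepoint, using the pooled error mean square of the full model (the
#' per-timepoint mean comparison customary after a two-way ANOVA). The
#' Sidak family defaults to all (groups - 1) x timepoints comparisons
#' within a class panel; `family = "per_timepoint"` switches to
#' per-timepoint families.
#'
#' @param data long data.frame with `neuron_class`, `group`, `time_hr`,
#'   `intensity` (normalized).
#' @param reference_group label of the vehicle/control group.
#' @param family `"panel"` (default) or `"per_timepoint"`.
#' @return list of class `response_result`: `comparisons` (data.frame:
#'   `neuron_class`, `time_hr`, `group`, `mean_difference`, `t`, `df`,
#'   `p_raw`, `p_sidak`, `tier`), `anova` (per-class ANOVA tables),
#'   `family_size`.
#' @export
per_timepoint_comparisons <- function(data, reference_group,
                                      family = c("panel", "per_timepoint")) {
  family <- match.arg(family)
  if (!"neuron_class" %in% names(data)) data$neuron_class <- "all"
  if (!reference_group %in% data$group) {
    stop("reference group '", reference_group, "' not present")
  }
  res <- list()
  anovas <- list()
  fam_sizes <- integer(0)
  for (cl in unique(data$neuron_class)) {
    dc <- data[data$neuron_class == cl, ]
    an <- two_way_anova(dc)
    anovas[[cl]] <- an
    mse <- attr(an, "ms_error")
    dfe <- attr(an, "df_error")
    groups <- setdiff(unique(dc$group), reference_group)
    times <- sort(unique(dc$time_hr))
    m_panel <- length(groups) * length(times)
    m <- if (family == "panel") m_panel else length(groups)
    fam_sizes <- c(fam_sizes, m)
    for (tp in times) {
      ref <- dc$intensity[dc$group == reference_group & dc$time_hr == tp]
      if (!length(ref)) {
        warning(sprintf("class %s: reference missing at t = %g h; skipped",
                        cl, tp))
        next
      }
      for (g in groups) {
        trt <- dc$intensity[dc$group == g & dc$time_hr == tp]
        if (!length(trt)) next
        diff <- mean(trt) - mean(ref)
        se <- sqrt(mse * (1 / length(trt) + 1 / length(ref)))
        tval <- diff / se
        p_raw <- 2 * stats::pt(-abs(tval), dfe)
        p_adj <- sidak_adjust(p_raw, m)
        res[[length(res) + 1]] <- data.frame(
          neuron_class = cl, time_hr = tp, group = g,
          mean_difference = diff, t = tval, df = dfe,
          p_raw = p_raw, p_sidak = p_adj,
          tier = significance_tier(p_adj), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(comparisons = do.call(rbind, c(res, make.row.names = FALSE)),
                 anova = anovas,
                 family_size = fam_sizes, family = family,
                 reference_group = reference_group),
            class = "response_result")
}

#' @export
print.response_result <- function(x, ...) {
  cat(sprintf("per-timepoint comparisons vs '%s' (%s family)\n",
              x$reference_group, x$family))
  sig <- x$comparisons[x$comparisons$tier != "ns", ]
  cat(sprintf("  %d comparisons, %d significant\n", nrow(x$comparisons),
              nrow(sig)))
  invisible(x)
}

#' Plot response time courses with significance annotation
#'
#' Group-mean normalized intensity against time, one panel per neuron
#' class, with asterisk tiers of each treatment-vs-reference comparison
#' written above the corresponding timepoint.
#'
#' @param data long data.frame of normalized response traces.
#' @param result a `response_result` for the same data.
#' @param file optional PNG path; when given the plot is written there.
#' @export
plot_response <- function(data, result, file = NULL) {
  if (!"neuron_class" %in% names(data)) data$neuron_class <- "all"
  classes <- unique(data$neuron_class)
  if (!is.null(file)) {
    grDevices::png(file, width = 320 * length(classes), height = 340)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, length(classes)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old), add = TRUE)
  groups <- unique(data$group)
  cols <- stats::setNames(grDevices::palette.colors(length(groups)), groups)
  for (cl in classes) {
    dc <- data[data$neuron_class == cl, ]
    agg <- stats::aggregate(intensity ~ group + time_hr, dc, mean)
    graphics::plot(range(agg$time_hr), range(agg$intensity) * c(1, 1.15),
                   type = "n", xlab = "time (h)",
                   ylab = "normalized intensity", main = cl)
    for (g in groups) {
      ag <- agg[agg$group == g, ]
      graphics::lines(ag$time_hr, ag$intensity, col = cols[g], lwd = 2)
    }
    cmp <- result$comparisons
    cmp <- cmp[cmp$neuron_class == cl & cmp$tier != "ns", ]
    if (nrow(cmp)) {
      graphics::text(cmp$time_hr, max(agg$intensity) * 1.1, cmp$tier,
                     col = cols[cmp$group])
    }
    graphics::legend("topleft", legend = groups, col = cols[groups],
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(result)
}
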