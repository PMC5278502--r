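#' Parameters of the synthetic single-cell trace model
#'
#' The generator's trace model is a damped cosine riding on a mesor,
#' modulated by a multiplicative linear drift, with additive Gaussian
#' noise truncated at zero (fluorescence is non-negative):
#' \deqn{I(t) = \left[M + A e^{-\lambda t}
#'   \cos\!\frac{2\pi (t - \phi)}{T}\right](1 + \delta t) + \varepsilon(t)}
#' This is the minimal form exhibiting every phenomenon the analysis
#' pipeline must handle: ~29-h periods, amplitude damping over days in
#' culture, slow baseline drift, and shot-like measurement noise.
#'
#' Defaults emulate clock-reporter recordings from cultured brain
#' explants: images every 3 h for 48 h, periods near 29 h, signal-to-noise
#' (amplitude/noise_sd) of 5, and a phase a few hours after recording
#' onset (recordings begin close to the reporter's expression peak).
#'
#' @param mesor baseline intensity, arbitrary units (AU).
#' @param amplitude oscillation amplitude, AU (0 = arrhythmic).
#' @param period_hr period in hours, > 0.
#' @param phase_hr time of the first cosine maximum, hours.
#' @param damping_rate exponential amplitude decay, per hour, >= 0.
#' @param drift_rate fractional baseline drift per hour.
#' @param noise_sd additive Gaussian noise sd, AU, >= 0.
#' @param sampling_interval_hr hours between frames.
#' @param duration_hr total recording span; the trace has
#'   `floor(duration_hr / sampling_interval_hr) + 1` points.
#' @return a validated list of class `trace_params`.
#' @export
trace_params <- function(mesor = 100, amplitude = 50, period_hr = 29,
                         phase_hr = 4, damping_rate = 0.005,
                         drift_rate = 0.002, noise_sd = 10,
                         sampling_interval_hr = 3, duration_hr = 48) {
  p <- list(mesor = mesor, amplitude = amplitude, period_hr = period_hr,
            phase_hr = phase_hr, damping_rate = damping_rate,
            drift_rate = drift_rate, noise_sd = noise_sd,
            sampling_interval_hr = sampling_interval_hr,
            duration_hr = duration_hr)
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("trace parameters must be finite")
  if (period_hr <= 0) stop("period_hr must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (damping_rate < 0) stop("damping_rate must be non-negative")
  if (duration_hr < sampling_interval_hr) {
    stop("duration_hr must be at least one sampling interval")
  }
  structure(p, class = "trace_params")
}

#' Generate one synthetic single-cell trace
#'
#' Draws a trace from the model described in [trace_params()]. The same
#' seed always yields a bitwise-identical trace.
#'
#' @param params a `trace_params` object.
#' @param seed integer RNG seed.
#' @param cell_id,neuron_class,group metadata attached to the trace rows.
#' @return data.frame with columns `cell_id`, `neuron_class`, `group`,
#'   `time_hr`, `intensity`.
#' @examples
#' tr <- generate_trace(trace_params(noise_sd = 0), seed = 1)
#' head(tr)
#' @export
generate_trace <- function(params, seed, cell_id = "cell_01",
                           neuron_class = "LNv", group = "none") {
  stopifnot(inherits(params, "trace_params"))
  set.seed(seed)
  generate_trace_impl(params, cell_id, neuron_class, group)
}

# RNG-stream version used inside cohort/experiment generators (no re-seed)
generate_trace_impl <- function(params, cell_id, neuron_class, group) {
  t <- seq(0, params$duration_hr, by = params$sampling_interval_hr)
  clean <- (params$mesor +
              params$amplitude * exp(-params$damping_rate * t) *
              cos(2 * pi * (t - params$phase_hr) / params$period_hr)) *
    (1 + params$drift_rate * t)
  eps <- if (params$noise_sd > 0) {
    stats::rnorm(length(t), 0, params$noise_sd)
  } else {
    numeric(length(t))
  }
  data.frame(cell_id = cell_id, neuron_class = neuron_class, group = group,
             time_hr = t, intensity = pmax(clean + eps, 0),
             stringsAsFactors = FALSE)
}

# deterministic largest-remainder allocation of n among proportions
allocate_counts <- function(n, mix) {
  raw <- n * mix / sum(mix)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

draw_param <- function(dist, n) {
  if (is.function(dist)) return(dist(n))
  if (is.numeric(dist) && length(dist) == 2L) {
    return(stats::runif(n, dist[1], dist[2]))
  }
  if (is.numeric(dist) && length(dist) == 1L) return(rep(dist, n))
  stop("parameter distribution must be a range, a constant, or a function")
}

#' Default parameter distributions for explant-like cohorts
#'
#' Ranges (uniform unless a function is supplied) for per-cell parameter
#' draws in [generate_cohort()]. Rhythmic cells oscillate with mild
#' damping and drift; arrhythmic cells have amplitude 0 and a stronger
#' positive drift, emulating the steady non-rhythmic increase seen in
#' dissociated neurons.
#'
#' @return named list of distributions understood by [generate_cohort()].
#' @export
cohort_param_defaults <- function() {
  list(mesor = c(80, 120), amplitude = c(40, 60), period_hr = c(27, 31),
       phase_hr = c(2, 8), damping_rate = c(0.002, 0.01),
       drift_rate = c(0.001, 0.005), noise_sd = 10,
       nonrhythmic_drift_rate = c(0.005, 0.02))
}

#' Generate a cohort of synthetic single-cell traces with ground truth
#'
#' Rhythmic/arrhythmic status and neuron class are assigned
#' deterministically (largest-remainder counts; the first
#' `round(n_cells * rhythmic_fraction)` cells are rhythmic), so the
#' ground-truth composition is exact by construction, not sampled.
#' Per-cell model parameters are then drawn from `params_distribution`.
#'
#' @param n_cells number of cells, > 0.
#' @param class_mix named proportions over neuron classes (default: the
#'   LNv/DN1/DN2 mix of a larval explant recording, 11:15:8).
#' @param rhythmic_fraction proportion of rhythmic cells in \[0, 1\].
#' @param params_distribution list as in [cohort_param_defaults()]; each
#'   entry a `c(lo, hi)` range, a constant, or a `function(n)`.
#' @param seed integer RNG seed.
#' @param sampling_interval_hr,duration_hr sampling grid shared by all
#'   cells.
#' @return list of class `cohort`: `traces` (long data.frame) and `truth`
#'   (`cell_id`, `neuron_class`, `is_rhythmic`, `true_period_hr`).
#' @export
generate_cohort <- function(n_cells,
                            class_mix = c(LNv = 11, DN1 = 15, DN2 = 8) / 34,
                            rhythmic_fraction = 0.6,
                            params_distribution = cohort_param_defaults(),
                            seed = 1,
                            sampling_interval_hr = 3, duration_hr = 48) {
  if (n_cells < 1) stop("n_cells must be at least 1")
  if (rhythmic_fraction < 0 || rhythmic_fraction > 1) {
    stop("rhythmic_fraction must lie in [0, 1]")
  }
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  pd <- utils::modifyList(cohort_param_defaults(), params_distribution)
  counts <- allocate_counts(n_cells, class_mix)
  classes <- rep(names(class_mix), counts)
  # exactly round(n * fraction) rhythmic cells, stratified across classes
  n_r <- round(n_cells * rhythmic_fraction)
  r_counts <- pmin(allocate_counts(n_r, counts), counts)
  while (sum(r_counts) < n_r) {
    spare <- which(r_counts < counts)
    r_counts[spare[1]] <- r_counts[spare[1]] + 1
  }
  rhythmic <- unlist(mapply(function(k, tot) {
    rep(c(TRUE, FALSE), c(k, tot - k))
  }, r_counts, counts, SIMPLIFY = FALSE))
  set.seed(seed)
  ids <- sprintf("cell_%03d", seq_len(n_cells))
  traces <- vector("list", n_cells)
  true_period <- rep(NA_real_, n_cells)
  for (i in seq_len(n_cells)) {
    if (rhythmic[i]) {
      pars <- trace_params(
        mesor = draw_param(pd$mesor, 1),
        amplitude = draw_param(pd$amplitude, 1),
        period_hr = draw_param(pd$period_hr, 1),
        phase_hr = draw_param(pd$phase_hr, 1),
        damping_rate = draw_param(pd$damping_rate, 1),
        drift_rate = draw_param(pd$drift_rate, 1),
        noise_sd = draw_param(pd$noise_sd, 1),
        sampling_interval_hr = sampling_interval_hr,
        duration_hr = duration_hr)
      true_period[i] <- pars$period_hr
    } else {
      pars <- trace_params(
        mesor = draw_param(pd$mesor, 1),
        amplitude = 0, period_hr = 24, phase_hr = 0, damping_rate = 0,
        drift_rate = draw_param(pd$nonrhythmic_drift_rate, 1),
        noise_sd = draw_param(pd$noise_sd, 1),
        sampling_interval_hr = sampling_interval_hr,
        duration_hr = duration_hr)
    }
    traces[[i]] <- generate_trace_impl(pars, ids[i], classes[i], "none")
  }
  structure(
    list(traces = do.call(rbind, traces),
         truth = data.frame(cell_id = ids, neuron_class = classes,
                            is_rhythmic = rhythmic,
                            true_period_hr = true_period,
                            stringsAsFactors = FALSE)),
    class = "cohort")
}

#' Specify a drug effect for response-experiment generation
#'
#' Encodes which treatment groups and neuron classes respond to a bath-
#' applied drug, from when, and with what shape. Effects act
#' multiplicatively on the baseline (the analysis works on fold-change
#' from the start of imaging): a `step` of size s multiplies the baseline
#' by (1 + s) from `onset_hr` on; a `ramp` grows as s per hour after
#' onset. A group whose label contains a co-treatment named in
#' `blocked_by` (labels are "+"-separated, e.g. `"PDF+TTX"`) does not
#' respond.
#'
#' @param onset_hr effect onset, hours after recording start.
#' @param affected_groups character, treatment components that respond.
#' @param affected_classes character, neuron classes that respond.
#' @param effect_shape `"step"` or `"ramp"`.
#' @param effect_size total fractional increase (step) or fractional
#'   increase per hour (ramp).
#' @param blocked_by character, co-treatments that abolish the effect.
#' @return list of class `drug_effect_spec`.
#' @export
drug_effect_spec <- function(onset_hr, affected_groups, affected_classes,
                             effect_shape = c("step", "ramp"), effect_size,
                             blocked_by = character(0)) {
  effect_shape <- match.arg(effect_shape)
  if (!is.finite(onset_hr) || !is.finite(effect_size)) {
    stop("onset_hr and effect_size must be finite")
  }
  structure(list(onset_hr = onset_hr,
                 affected_groups = as.character(affected_groups),
                 affected_classes = as.character(affected_classes),
                 effect_shape = effect_shape, effect_size = effect_size,
                 blocked_by = as.character(blocked_by)),
            class = "drug_effect_spec")
}

group_components <- function(group) strsplit(group, "+", fixed = TRUE)[[1]]

group_is_affected <- function(group, spec) {
  comps <- group_components(group)
  any(comps %in% spec$affected_groups) && !any(comps %in% spec$blocked_by)
}

#' Generate a synthetic drug-response experiment
#'
#' Emulates the short pharmacology protocol: hourly imaging over a few
#' hours, a baseline period before drug addition, then a group-, class-
#' and time-of-day-specific response. Traces are flat (mesor) plus noise
#' before onset; affected (group, class) strata gain the specified
#' multiplicative effect afterwards; everything else is statistically
#' exchangeable with the vehicle group.
#'
#' @param spec a [drug_effect_spec()].
#' @param groups character vector of treatment labels (components
#'   separated by "+", e.g. `c("Vehicle", "PDF", "PDF+TTX")`).
#' @param classes neuron-class labels.
#' @param n_per_group_class cells per (group, class) stratum.
#' @param baseline_hr imaging time before drug onset (must be shorter than
#'   `duration_hr`); `spec$onset_hr` must lie in `[0, duration_hr]`.
#' @param duration_hr total imaging span in hours.
#' @param sampling_interval_hr frame spacing, hours.
#' @param seed integer RNG seed.
#' @param mesor_range,noise_sd per-cell baseline draw range and noise sd.
#' @return list of class `response_experiment`: `data` (long data.frame
#'   with `cell_id`, `neuron_class`, `group`, `time_hr`, `intensity`) and
#'   `truth` (per-stratum `affected` flag).
#' @export
generate_response_experiment <- function(spec, groups,
                                         classes = c("LNv", "DN1", "DN2"),
                                         n_per_group_class = 16,
                                         baseline_hr = 1, duration_hr = 8,
                                         sampling_interval_hr = 1, seed = 1,
                                         mesor_range = c(80, 120),
                                         noise_sd = 10) {
  stopifnot(inherits(spec, "drug_effect_spec"))
  if (baseline_hr >= duration_hr) stop("baseline_hr must be < duration_hr")
  if (spec$onset_hr < 0 || spec$onset_hr > duration_hr) {
    stop("effect onset lies outside the recording window")
  }
  all_comps <- unique(unlist(lapply(groups, group_components)))
  bad <- setdiff(spec$affected_groups, all_comps)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(spec$affected_classes, classes)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  t <- seq(0, duration_hr, by = sampling_interval_hr)
  rows <- list()
  truth <- list()
  idx <- 0
  for (g in groups) for (cl in classes) {
    affected <- group_is_affected(g, spec) && cl %in% spec$affected_classes
    eff <- rep(0, length(t))
    if (affected) {
      post <- t >= spec$onset_hr
      eff[post] <- if (spec$effect_shape == "step") spec$effect_size else
        spec$effect_size * (t[post] - spec$onset_hr)
    }
    for (j in seq_len(n_per_group_class)) {
      idx <- idx + 1
      base <- stats::runif(1, mesor_range[1], mesor_range[2])
      y <- pmax(base * (1 + eff) + stats::rnorm(length(t), 0, noise_sd), 0)
      rows[[idx]] <- data.frame(
        cell_id = sprintf("cell_%04d", idx), neuron_class = cl, group = g,
        time_hr = t, intensity = y, stringsAsFactors = FALSE)
    }
    truth[[paste(g, cl)]] <- data.frame(group = g, neuron_class = cl,
                                        affected = affected,
                                        stringsAsFactors = FALSE)
  }
  structure(list(data = do.call(rbind, rows),
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 spec = spec),
            class = "response_experiment")
}
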