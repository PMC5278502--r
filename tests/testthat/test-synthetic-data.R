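test_that("degenerate trace models behave analytically", {
  const <- generate_trace(trace_params(amplitude = 0, drift_rate = 0,
                                       noise_sd = 0, mesor = 100), 1)
  expect_true(all(const$intensity == 100))
  expect_equal(nrow(const), floor(48 / 3) + 1)
  clean <- generate_trace(trace_params(period_hr = 24, phase_hr = 0,
                                       damping_rate = 0, drift_rate = 0,
                                       noise_sd = 0, sampling_interval_hr = 1,
                                       duration_hr = 48), 1)
  peaks <- clean$time_hr[clean$intensity == max(clean$intensity)]
  expect_equal(peaks, c(0, 24, 48))
})

test_that("trace generation is seed-deterministic", {
  p <- trace_params()
  expect_identical(generate_trace(p, 7), generate_trace(p, 7))
  expect_false(identical(generate_trace(p, 7)$intensity,
                         generate_trace(p, 8)$intensity))
})

test_that("invalid trace parameters are rejected", {
  expect_error(trace_params(period_hr = 0), "positive")
  expect_error(trace_params(noise_sd = -1), "non-negative")
  expect_error(trace_params(mesor = Inf), "finite")
  expect_error(trace_params(duration_hr = 1, sampling_interval_hr = 3),
               "at least one sampling interval")
})

test_that("cohort ground-truth composition is exact by construction", {
  co <- generate_cohort(10, rhythmic_fraction = 1, seed = 1)
  expect_true(all(co$truth$is_rhythmic))
  co2 <- generate_cohort(100, rhythmic_fraction = 0.6, seed = 1)
  expect_equal(sum(co2$truth$is_rhythmic), 60)
  expect_true(all(is.na(co2$truth$true_period_hr[!co2$truth$is_rhythmic])))
  expect_true(all(!is.na(co2$truth$true_period_hr[co2$truth$is_rhythmic])))
  expect_error(generate_cohort(0), "at least 1")
})

test_that("non-rhythmic cells drift upward without oscillating", {
  co <- generate_cohort(30, rhythmic_fraction = 0, seed = 4,
                        params_distribution = list(noise_sd = 0))
  first <- tapply(co$traces$intensity, co$traces$cell_id, head, 1)
  last <- tapply(co$traces$intensity, co$traces$cell_id, tail, 1)
  expect_true(all(last > first))
})

test_that("response generator encodes effects, blocking and exchangeability", {
  sp <- drug_effect_spec(1, "PDF", "LNv", "ramp", 0.1, blocked_by = "TTX")
  ex <- generate_response_experiment(sp, c("Vehicle", "PDF", "PDF+TTX"),
                                     classes = c("LNv", "DN1"),
                                     n_per_group_class = 200, seed = 2,
                                     noise_sd = 10)
  norm <- normalize_to_start(ex$data)
  m8 <- aggregate(intensity ~ group + neuron_class,
                  norm[norm$time_hr == 8, ], mean)
  get <- function(g, cl) m8$intensity[m8$group == g & m8$neuron_class == cl]
  # ramp 0.1/h from t=1: expected +0.7 at t=8 in the affected stratum
  expect_equal(get("PDF", "LNv") - get("Vehicle", "LNv"), 0.7,
               tolerance = 0.08)
  # blocked co-treatment and unaffected class match vehicle in expectation
  expect_equal(get("PDF+TTX", "LNv"), get("Vehicle", "LNv"), tolerance = 0.05)
  expect_equal(get("PDF", "DN1"), get("Vehicle", "DN1"), tolerance = 0.05)
  # truth table marks exactly the affected stratum
  expect_identical(ex$truth$affected,
                   ex$truth$group == "PDF" & ex$truth$neuron_class == "LNv")
})

test_that("response generator validates labels and windows", {
  sp <- drug_effect_spec(1, "XXX", "LNv", "step", 0.5)
  expect_error(generate_response_experiment(sp, c("Vehicle", "PDF")),
               "unknown group")
  sp2 <- drug_effect_spec(1, "PDF", "Kenyon", "step", 0.5)
  expect_error(generate_response_experiment(sp2, c("Vehicle", "PDF")),
               "unknown class")
  sp3 <- drug_effect_spec(20, "PDF", "LNv", "step", 0.5)
  expect_error(generate_response_experiment(sp3, c("Vehicle", "PDF")),
               "outside the recording window")
  expect_error(generate_response_experiment(
    drug_effect_spec(1, "PDF", "LNv", "step", 0.5), c("Vehicle", "PDF"),
    baseline_hr = 8, duration_hr = 8), "baseline_hr")
})

test_that("rendered stacks honour background, scaling and determinism", {
  # no cells: background plus gradient only
  empty <- stack_spec(c(4, 6, 8),
                      cells = data.frame(cell_id = character(0),
                                         z = numeric(0), y = numeric(0),
                                         x = numeric(0), radius = numeric(0),
                                         peak = numeric(0)),
                      background_level = 10, background_gradient = 2)
  ss0 <- render_stack_series(empty, data.frame(cell_id = character(0),
                                               time_hr = numeric(0),
                                               intensity = numeric(0)))
  expect_equal(ss0$volumes[[1]][1, 1, 1], 10)
  expect_equal(ss0$volumes[[1]][4, 6, 8], 10 + 2 * 7)
  # one cell, noise-free: ground truth tracks the trace ratio
  cells <- data.frame(cell_id = "a", z = 8, y = 12, x = 12, radius = 4,
                      peak = 100)
  tr <- data.frame(cell_id = "a", time_hr = c(0, 3), intensity = c(100, 150))
  sp <- stack_spec(c(16, 24, 24), cells, background_level = 5)
  ss <- render_stack_series(sp, tr)
  gt <- ss$ground_truth
  expect_equal(gt$integrated_intensity[gt$time_hr == 3] /
                 gt$integrated_intensity[gt$time_hr == 0], 1.5)
  expect_false(any(gt$overlapping))
  # determinism under a noise model
  spn <- stack_spec(c(16, 24, 24), cells,
                    noise_model = list(type = "gaussian", sd = 2))
  s1 <- render_stack_series(spn, tr, seed = 3)
  s2 <- render_stack_series(spn, tr, seed = 3)
  expect_identical(s1$volumes, s2$volumes)
  # overlapping cells are flagged
  two <- data.frame(cell_id = c("a", "b"), z = c(8, 8), y = c(12, 14),
                    x = c(12, 14), radius = 4, peak = 100)
  tr2 <- rbind(tr, data.frame(cell_id = "b", time_hr = c(0, 3),
                              intensity = c(100, 100)))
  ssov <- render_stack_series(stack_spec(c(16, 24, 24), two), tr2)
  expect_true(all(ssov$ground_truth$overlapping))
})

test_that("stack specs are validated", {
  cells <- data.frame(cell_id = "a", z = 99, y = 1, x = 1, radius = 2,
                      peak = 100)
  expect_error(stack_spec(c(8, 8, 8), cells), "inside the volume")
  cells$z <- 4
  expect_error(stack_spec(c(8, 8, 8), cells, background_level = 200),
               "exceed the background")
})

test_that("stack series round-trip through TIFF plus manifest", {
  cells <- data.frame(cell_id = "a", z = 5, y = 8, x = 8, radius = 3,
                      peak = 50)
  tr <- data.frame(cell_id = "a", time_hr = c(0, 3), intensity = c(80, 120))
  ss <- render_stack_series(stack_spec(c(10, 16, 16), cells), tr)
  dir <- withr::local_tempdir()
  write_stack_series(ss, dir)
  back <- read_stack_series(dir)
  expect_equal(back$time_hr, ss$time_hr)
  expect_equal(back$volumes[[2]], ss$volumes[[2]], tolerance = 1e-6)
  expect_equal(back$ground_truth$integrated_intensity,
               ss$ground_truth$integrated_intensity, tolerance = 1e-6)
})
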