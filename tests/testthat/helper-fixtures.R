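# shared fixtures and independent oracles

# clean damped/drifting cosine on the explant sampling grid
cosine_trace <- function(period = 29, phase = 4, amplitude = 50, mesor = 100,
                         damping = 0, drift = 0, noise = 0, dt = 3,
                         duration = 48, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = dt)
  y <- (mesor + amplitude * exp(-damping * t) *
          cos(2 * pi * (t - phase) / period)) * (1 + drift * t)
  if (noise > 0) y <- y + rnorm(length(t), 0, noise)
  data.frame(cell_id = "c1", neuron_class = "LNv", group = "none",
             time_hr = t, intensity = pmax(y, 0))
}

# brute-force balanced two-way ANOVA from sums of squares
anova_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  gm <- mean(y)
  a <- nlevels(A); b <- nlevels(B); N <- length(y)
  mA <- ave(y, A); mB <- ave(y, B); mAB <- ave(y, A, B)
  ssA <- sum((mA - gm)^2)
  ssB <- sum((mB - gm)^2)
  ssAB <- sum((mAB - mA - mB + gm)^2)
  sse <- sum((y - mAB)^2)
  dfe <- N - a * b
  list(F_A = (ssA / (a - 1)) / (sse / dfe),
       F_B = (ssB / (b - 1)) / (sse / dfe),
       F_AB = (ssAB / ((a - 1) * (b - 1))) / (sse / dfe))
}

# FFT periodogram argmax frequency (cycles per hour)
periodogram_argmax <- function(y, dt) {
  y <- y - mean(y)
  n <- length(y)
  pg <- Mod(fft(y))^2
  freq <- (seq_len(n) - 1) / (n * dt)
  half <- 2:floor(n / 2)
  freq[half][which.max(pg[half])]
}
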