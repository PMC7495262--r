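# shared fixtures, built in code at test time

# one-segment EEG config with controllable band amplitudes
one_seg_cfg <- function(duration_s = 30, theta = 0, alpha = 0, beta = 0,
                        seed = 1, noise = 0, artifacts = 0,
                        carrier = "noise", ...) {
  synth_config(
    duration_s,
    list(segment_spec(0, duration_s, theta_amp = theta, alpha_amp = alpha,
                      beta_amp = beta, ...)),
    seed = seed, noise_scale = noise, artifact_rate = artifacts,
    carrier = carrier
  )
}

# pure sinusoid vector: peak amplitude A at frequency f, 256 Hz
sinusoid <- function(f, peak, duration_s = 8, rate = 256) {
  t <- (0:(duration_s * rate - 1)) / rate
  peak * sin(2 * pi * f * t)
}

# independent time-domain oracle for in-band RMS: brick-wall FFT filter of
# the whole signal (no windowing, no averaging) — used to cross-check the
# Welch path, never implemented in terms of it
inband_rms_oracle <- function(x, rate, low, high) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * rate / n
  ff <- pmin(f, rate - f)
  X[!(ff >= low & ff < high)] <- 0
  sqrt(mean(Re(stats::fft(X, inverse = TRUE) / n)^2))
}

# published per-group cells used across pipeline and acceptance tests
published_groups <- list(
  student = list(tbr = c(3.49, 3.23), alpha = c(7.77, 8.42),
                 hr = c(87, 86), eda = c(1.198, 4.097),
                 eda_sd = c(1.467, 2.79)),
  neurosurgeon = list(tbr = c(2.59, 2.90), alpha = c(7.03, 7.15),
                      hr = c(81, 83), eda = c(1.890, 5.407),
                      eda_sd = c(2.269, 5.391)),
  postgraduate = list(tbr = c(2.33, 2.56), alpha = c(11.84, 9.55),
                      hr = c(81, 77), eda = c(0.739, 2.498),
                      eda_sd = c(0.509, 1.72))
)

group_cell <- function(gs, grp, met, col) {
  gs[[col]][gs$group == grp & gs$metric == met]
}
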