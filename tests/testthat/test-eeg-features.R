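test_that("Welch band power matches the closed form for pure sinusoids", {
  x <- sinusoid(10, peak = 10, duration_s = 8)
  b <- default_bands()
  expect_equal(band_power(x, 256, b$alpha), 50, tolerance = 0.02)
  expect_equal(band_amplitude(x, 256, b$alpha), 10 / sqrt(2), tolerance = 0.02)
  expect_equal(band_amplitude(x, 256, b$alpha, convention = "peak_equivalent"),
               10, tolerance = 0.02)
  # out-of-band rejection
  expect_lt(band_power(x, 256, b$theta), 0.01 * band_power(x, 256, b$alpha))
  expect_lt(band_power(x, 256, b$beta), 0.01 * band_power(x, 256, b$alpha))
  # zero signal has zero amplitude
  expect_equal(band_amplitude(numeric(2048), 256, b$alpha), 0)
})

test_that("band power recovers the generator's band RMS within 5%", {
  cfg <- one_seg_cfg(60, theta = 4, alpha = 8.42, beta = 2, seed = 12)
  x <- generate_eeg(cfg)$stream$samples
  b <- default_bands()
  # Welch band power vs the time-domain mean square of the realized
  # band-limited component (independent brick-wall oracle); power carries
  # twice the relative error of amplitude, so 10% here vs 5% on RMS below
  expect_equal(band_power(x, 256, b$theta),
               inband_rms_oracle(x, 256, 4, 8)^2, tolerance = 0.10)
  expect_equal(band_power(x, 256, b$alpha),
               inband_rms_oracle(x, 256, 8, 12)^2, tolerance = 0.10)
  # the generator's nominal RMS targets are recovered within 5%
  expect_equal(band_amplitude(x, 256, b$theta), 4, tolerance = 0.05)
  expect_equal(band_amplitude(x, 256, b$alpha), 8.42, tolerance = 0.05)
  expect_equal(band_amplitude(x, 256, b$beta), 2, tolerance = 0.05)
})

test_that("theta/beta ratio behaves as a power ratio", {
  mk <- function(theta) {
    generate_eeg(one_seg_cfg(20, theta = theta, beta = 2, seed = 31,
                             carrier = "sinusoid"))$stream$samples
  }
  expect_equal(theta_beta_ratio(mk(4), 256), 4, tolerance = 0.02)
  expect_equal(theta_beta_ratio(mk(2), 256), 1, tolerance = 0.02)
  # doubling theta amplitude at fixed beta quadruples the ratio
  expect_equal(theta_beta_ratio(mk(8), 256) / theta_beta_ratio(mk(4), 256),
               4, tolerance = 0.02)
})

test_that("theta/beta ratio increases strictly with theta carrier RMS", {
  ratios <- vapply(c(2, 3, 4, 5), function(th) {
    x <- generate_eeg(one_seg_cfg(30, theta = th, beta = 2, seed = 17))$stream$samples
    theta_beta_ratio(x, 256)
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("band features are scale-equivariant and the ratio scale-invariant", {
  x <- generate_eeg(one_seg_cfg(20, theta = 3, alpha = 6, beta = 2,
                                seed = 13, noise = 0.5))$stream$samples
  b <- default_bands()
  for (c_scale in c(0.5, 3)) {
    expect_equal(band_power(c_scale * x, 256, b$alpha),
                 c_scale^2 * band_power(x, 256, b$alpha), tolerance = 1e-10)
    expect_equal(band_amplitude(c_scale * x, 256, b$theta),
                 abs(c_scale) * band_amplitude(x, 256, b$theta), tolerance = 1e-10)
    expect_equal(theta_beta_ratio(c_scale * x, 256),
                 theta_beta_ratio(x, 256), tolerance = 1e-10)
  }
})

test_that("epoch rejection flags exactly the epochs containing transients", {
  cfg <- one_seg_cfg(90, alpha = 8, seed = 21, noise = 0.5, artifacts = 2)
  g <- generate_eeg(cfg)
  rej <- reject_artifacts(g$stream, epoch_s = 1, threshold_uv = 100)
  # brute-force oracle: rebuild each epoch's peak artifact contribution from
  # the ground-truth half-sine transients (onset, width, amplitude)
  t <- stream_times(g$stream)
  contrib <- numeric(length(t))
  for (i in seq_len(nrow(g$artifacts))) {
    on <- g$artifacts$onset_utc[i]; w <- g$artifacts$width_s[i]
    idx <- which(t >= on & t < on + w)
    contrib[idx] <- pmax(contrib[idx],
                         abs(g$artifacts$amp_uv[i]) * sin(pi * (t[idx] - on) / w))
  }
  peak <- vapply(seq_len(rej$n_total), function(k) {
    i0 <- (k - 1) * 256 + 1
    max(contrib[i0:min(k * 256, length(contrib))])
  }, 0)
  # the clean trace never exceeds ~35 uV here, so the decision is forced
  # outside a +-35 uV band around the threshold
  expect_true(all(rej$rejected[peak > 135]))
  expect_false(any(rej$rejected[peak < 65]))
  expect_gt(rej$n_rejected, 0)
})

test_that("epoch rejection handles clean, short and degenerate input", {
  clean <- rep(c(-50, 50), 512)
  rej <- reject_artifacts(clean, rate = 256, threshold_uv = 100)
  expect_equal(rej$n_rejected, 0)
  expect_equal(rej$n_total, 4)

  short <- reject_artifacts(rnorm(64), rate = 256, epoch_s = 1)
  expect_equal(short$n_total, 1)
  expect_length(short$epochs[[1]], 64)

  expect_error(reject_artifacts(clean, rate = 256, threshold_uv = 0),
               class = "affectlytics_config_error")
  expect_error(reject_artifacts(clean, rate = 256, epoch_s = 0),
               class = "affectlytics_config_error")
})

test_that("rejection keeps contaminated features within 5% of clean ones", {
  base <- function(artifacts) {
    one_seg_cfg(120, theta = 4, alpha = 8, beta = 2, seed = 23,
                noise = 0.4, artifacts = artifacts)
  }
  # the artifact substream is drawn after carriers and noise, so the clean
  # portion of both streams is the identical realization
  clean <- generate_eeg(base(0))$stream
  dirty <- generate_eeg(base(3))$stream
  f_clean <- eeg_segment_features(clean)
  f_dirty <- eeg_segment_features(dirty)
  expect_gt(f_dirty$n_epochs_rejected, 0)
  for (col in c("alpha_amp", "theta_power", "beta_power", "theta_beta_ratio")) {
    expect_equal(f_dirty[[col]], f_clean[[col]], tolerance = 0.05)
  }
})

test_that("undefined features surface as NA with a classed warning", {
  # constant 200 uV exceeds the threshold everywhere: all epochs rejected
  sat <- biosignal_stream("EEG", rep(200, 256 * 5), 256, 0)
  expect_warning(f <- eeg_segment_features(sat),
                 class = "affectlytics_undefined_feature")
  expect_true(is.na(f$alpha_amp))
  expect_equal(f$n_epochs_rejected, f$n_epochs_total)

  # window with no samples
  s <- biosignal_stream("EEG", rnorm(256), 256, 0)
  expect_warning(f2 <- eeg_segment_features(s, 100, 200),
                 class = "affectlytics_undefined_feature")
  expect_true(is.na(f2$theta_beta_ratio))

  # beta power at the numeric floor
  th <- generate_eeg(one_seg_cfg(10, theta = 4, seed = 2))$stream$samples
  expect_warning(r <- theta_beta_ratio(th, 256),
                 class = "affectlytics_undefined_feature")
  expect_true(is.na(r))
})
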