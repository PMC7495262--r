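test_that("identical config and seed give byte-identical streams", {
  mk <- function() {
    cfg <- synth_config(15, list(segment_spec(0, 15, theta_amp = 3, alpha_amp = 6,
                                              beta_amp = 2, scr_count = 2)),
                        seed = 11, noise_scale = 1, artifact_rate = 4)
    list(eeg = generate_eeg(cfg), eda = generate_eda(cfg), hr = generate_hr(cfg))
  }
  a <- mk(); b <- mk()
  expect_identical(a$eeg$stream$samples, b$eeg$stream$samples)
  expect_identical(a$eeg$artifacts, b$eeg$artifacts)
  expect_identical(a$eda$samples, b$eda$samples)
  expect_identical(a$hr$samples, b$hr$samples)
})

test_that("a single active band stays confined to its band", {
  cfg <- one_seg_cfg(30, alpha = 10, seed = 2)
  x <- generate_eeg(cfg)$stream$samples
  a <- inband_rms_oracle(x, 256, 8, 12)
  expect_equal(a, 10, tolerance = 1e-6)
  expect_lt(inband_rms_oracle(x, 256, 4, 8), 0.01 * a)
  expect_lt(inband_rms_oracle(x, 256, 13, 21), 0.01 * a)
})

test_that("sinusoid carrier mode hits the target RMS analytically", {
  cfg <- one_seg_cfg(10, alpha = 10, seed = 3, carrier = "sinusoid")
  x <- generate_eeg(cfg)$stream$samples
  expect_equal(sqrt(mean(x^2)), 10, tolerance = 1e-3)
  expect_equal(inband_rms_oracle(x, 256, 8, 12), 10, tolerance = 1e-2)
})

test_that("theta 4 / beta 2 carriers imply a theta/beta power ratio of 4", {
  cfg <- one_seg_cfg(30, theta = 4, beta = 2, seed = 5)
  x <- generate_eeg(cfg)$stream$samples
  r <- inband_rms_oracle(x, 256, 4, 8)^2 / inband_rms_oracle(x, 256, 13, 21)^2
  expect_equal(r, 4, tolerance = 1e-6)
})

test_that("EEG artifacts are injected at the recorded ground-truth times", {
  cfg <- one_seg_cfg(90, alpha = 8, seed = 6, noise = 0.5, artifacts = 2)
  g <- generate_eeg(cfg)
  expect_equal(nrow(g$artifacts), 3)   # 2/min * 1.5 min
  for (i in seq_len(nrow(g$artifacts))) {
    sl <- slice_stream(g$stream, g$artifacts$onset_utc[i],
                       g$artifacts$onset_utc[i] + g$artifacts$width_s[i])
    expect_gt(max(abs(sl$samples)), 100)
  }
  # away from artifacts the trace stays at physiological scale
  quiet <- slice_stream(g$stream, g$artifacts$onset_utc[1] - 3,
                        g$artifacts$onset_utc[1] - 1)
  expect_lt(max(abs(quiet$samples)), 100)
})

test_that("EDA generator honors tonic level, phasic count and ordering", {
  cfg <- one_seg_cfg(60, eda_tonic = 2, scr_count = 0)
  e <- generate_eda(cfg)
  expect_true(all(e$samples == 2))
  expect_equal(e$rate, 4)

  cfg3 <- one_seg_cfg(60, eda_tonic = 1, scr_count = 3, seed = 5)
  x <- generate_eda(cfg3)$samples
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  expect_equal(sum(x[peaks] > 1 + 0.02), 3)

  two <- synth_config(120, list(
    segment_spec(0, 60, eda_tonic = 1), segment_spec(60, 120, eda_tonic = 5)
  ), seed = 7)
  e2 <- generate_eda(two)
  t <- stream_times(e2)
  m1 <- mean(e2$samples[t < 60]); m2 <- mean(e2$samples[t >= 60])
  expect_lt(m1, m2)
  expect_equal(m1, 1, tolerance = 0.3)
  expect_equal(m2, 5, tolerance = 0.3)

  zero <- one_seg_cfg(30, eda_tonic = 0, scr_count = 2, seed = 8)
  expect_true(all(generate_eda(zero)$samples >= 0))
})

test_that("HR generator honors level, jitter, drift and physiological clamp", {
  still <- synth_config(60, list(segment_spec(0, 60, hr_level = 80)),
                        seed = 2, hr_jitter_sd = 0, hr_drift_amp = 0)
  expect_true(all(generate_hr(still)$samples == 80))

  cfg <- one_seg_cfg(300, hr_level = 80, seed = 2)
  expect_equal(mean(generate_hr(cfg)$samples), 80, tolerance = 1)

  two <- synth_config(240, list(
    segment_spec(0, 120, hr_level = 70), segment_spec(120, 240, hr_level = 90)
  ), seed = 3)
  h <- generate_hr(two)
  t <- stream_times(h)
  expect_lt(mean(h$samples[t < 120]), mean(h$samples[t >= 120]))

  low <- synth_config(120, list(segment_spec(0, 120, hr_level = 30)), seed = 4)
  expect_true(all(generate_hr(low)$samples >= 30))
})

test_that("generate_session staggers streams and annotates internal boundaries", {
  cfg <- synth_config(30, list(
    segment_spec(0, 10, alpha_amp = 5), segment_spec(10, 20, alpha_amp = 5),
    segment_spec(20, 30, alpha_amp = 5)
  ), seed = 9)
  ses <- generate_session(cfg, "MR", "p1", "neurosurgeon", t0 = 5000)
  rec <- ses$recording
  expect_equal(get_stream(rec, "EEG")$start_utc, 5000)
  expect_equal(get_stream(rec, "EDA")$start_utc, 5000.5)
  expect_equal(get_stream(rec, "HR")$start_utc, 5001.2)
  # EEG covers the full duration at the acquisition rate
  expect_length(get_stream(rec, "EEG")$samples, 30 * 256)
  # 3 segments -> 2 internal boundaries, plus start/end marks
  expect_equal(sum(rec$annotations$kind == "gesture"), 2)
  expect_equal(rec$annotations$time_utc[rec$annotations$kind == "gesture"],
               c(5010, 5020))
  expect_setequal(c("session_start", "session_end"),
                  setdiff(unique(rec$annotations$kind), "gesture"))
  # ground truth emitted alongside
  expect_equal(nrow(ses$ground_truth$segments), 3)
  expect_equal(ses$ground_truth$segments$start_utc, c(5000, 5010, 5020))
})

test_that("invalid synthesis configurations are rejected", {
  expect_error(
    synth_config(20, list(segment_spec(0, 15), segment_spec(10, 20))),
    class = "affectlytics_config_error"
  )
  expect_error(
    synth_config(20, list(segment_spec(0, 10), segment_spec(12, 20))),
    class = "affectlytics_config_error"
  )
  expect_error(synth_config(0, list()), class = "affectlytics_config_error")
  expect_error(segment_spec(5, 5), class = "affectlytics_config_error")
  expect_error(segment_spec(0, 10, hr_level = 250), class = "affectlytics_config_error")
  expect_error(segment_spec(0, 10, theta_amp = -1), class = "affectlytics_config_error")
})
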