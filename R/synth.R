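#' Segment specification for synthetic recordings
#'
#' Ground truth for one contiguous stretch of a synthetic session: the RMS
#' amplitude of each EEG band carrier, the heart-rate level, the tonic skin
#' conductance level and the number of phasic skin-conductance responses.
#'
#' @param start_s,end_s Segment bounds in session-relative seconds,
#'   `start_s < end_s`.
#' @param theta_amp,alpha_amp,beta_amp Band carrier RMS in microvolts
#'   (theta 4-8 Hz, alpha 8-12 Hz, beta 13-21 Hz), all `>= 0`.
#' @param hr_level Heart-rate level in bpm, within the physiological range
#'   `[30, 220]`.
#' @param eda_tonic Tonic skin conductance in microsiemens, `>= 0`.
#' @param scr_count Number of phasic skin-conductance responses to place in
#'   the segment.
#' @return A list of class `segment_spec`.
#' @export
segment_spec <- function(start_s, end_s, theta_amp = 0, alpha_amp = 0, beta_amp = 0,
                         hr_level = 75, eda_tonic = 1, scr_count = 0) {
  if (start_s >= end_s) abort_config("segment_spec needs start_s < end_s")
  if (any(c(theta_amp, alpha_amp, beta_amp) < 0)) abort_config("band amplitudes must be >= 0")
  if (hr_level < 30 || hr_level > 220) abort_config("hr_level must lie in [30, 220] bpm")
  if (eda_tonic < 0) abort_config("eda_tonic must be >= 0")
  structure(
    list(start_s = start_s, end_s = end_s,
         theta_amp = theta_amp, alpha_amp = alpha_amp, beta_amp = beta_amp,
         hr_level = hr_level, eda_tonic = eda_tonic,
         scr_count = as.integer(scr_count)),
    class = "segment_spec"
  )
}

#' Synthetic-recording configuration
#'
#' Defines a session to synthesize: duration, acquisition rates (the rig's
#' defaults: EEG 256 Hz, HR 1 Hz, EDA 4 Hz), the ground-truth segment specs
#' (which must tile `[0, duration_s)` without gaps or overlap), the 1/f
#' background level, the artifact injection rate and the carrier model.
#'
#' All randomness flows from `seed` through one named substream per modality,
#' so e.g. the EDA trace is reproducible independently of how many EEG
#' samples were drawn.
#'
#' @param duration_s Session duration in seconds.
#' @param segments List of [segment_spec()]s tiling `[0, duration_s)`.
#' @param seed Integer master seed.
#' @param eeg_rate,hr_rate,eda_rate Sampling rates in samples/s.
#' @param artifact_rate High-amplitude EEG transients per minute.
#' @param noise_scale RMS of the 1/f EEG background, microvolts.
#' @param carrier `"noise"` (white noise band-passed to the band, rescaled to
#'   the target RMS — exercises spectral integration over the whole band) or
#'   `"sinusoid"` (pure tone at the band center — analytic oracle mode).
#' @param hr_jitter_sd Per-sample Gaussian HR jitter SD in bpm.
#' @param hr_drift_amp,hr_drift_period_s Slow sinusoidal HR drift (bpm, s).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_s, segments, seed = 1L,
                         eeg_rate = 256, hr_rate = 1, eda_rate = 4,
                         artifact_rate = 0, noise_scale = 1,
                         carrier = c("noise", "sinusoid"),
                         hr_jitter_sd = 2, hr_drift_amp = 1, hr_drift_period_s = 120) {
  carrier <- match.arg(carrier)
  if (duration_s <= 0) abort_config("duration_s must be > 0")
  if (any(c(eeg_rate, hr_rate, eda_rate) <= 0)) abort_config("all rates must be > 0")
  segments <- lapply(segments, function(s) {
    if (!inherits(s, "segment_spec")) abort_config("segments must be segment_spec objects")
    s
  })
  o <- order(vapply(segments, `[[`, 0, "start_s"))
  segments <- segments[o]
  starts <- vapply(segments, `[[`, 0, "start_s")
  ends <- vapply(segments, `[[`, 0, "end_s")
  tol <- 1e-9
  if (abs(starts[1]) > tol || abs(ends[length(ends)] - duration_s) > tol ||
      (length(segments) > 1 && any(abs(ends[-length(ends)] - starts[-1]) > tol))) {
    abort_config("segment specs must tile [0, duration_s) without gaps or overlap")
  }
  # one named substream per modality, all derived from the master seed
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  subs <- sample.int(2147483646L, 4L)
  names(subs) <- c("eeg", "eda", "hr", "session")
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(
    list(duration_s = duration_s, segments = segments, seed = seed, substreams = subs,
         eeg_rate = eeg_rate, hr_rate = hr_rate, eda_rate = eda_rate,
         artifact_rate = artifact_rate, noise_scale = noise_scale, carrier = carrier,
         hr_jitter_sd = hr_jitter_sd, hr_drift_amp = hr_drift_amp,
         hr_drift_period_s = hr_drift_period_s),
    class = "synth_config"
  )
}

with_substream <- function(config, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$substreams[[name]])
  force(code)
}

# white noise confined to [low_hz, high_hz) by brick-wall FFT shaping, then
# rescaled so its RMS is exactly `rms` — keeps the ground-truth band power
# fully inside the integration window
bandlimited_noise <- function(n, rate, low_hz, high_hz, rms) {
  if (rms == 0 || n < 4) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * rate / n
  f_fold <- pmin(f, rate - f)              # frequency of each bin, folded
  keep <- f_fold >= low_hz & f_fold < high_hz
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  cur <- sqrt(mean(y^2))
  if (cur == 0) return(numeric(n))
  y * (rms / cur)
}

# 1/f ("pink") background of target RMS via spectral shaping
pink_noise <- function(n, rms) {
  if (rms == 0 || n < 4) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1)
  f_fold <- pmin(f, n - f)
  scale <- ifelse(f_fold == 0, 0, 1 / sqrt(f_fold))
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y * (rms / sqrt(mean(y^2)))
}

band_centers <- c(theta = 6, alpha = 10, beta = 17)
band_edges <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(13, 21))

#' Generate a synthetic EEG stream
#'
#' Per segment, each band with nonzero ground-truth amplitude contributes a
#' carrier of exactly that RMS (band-limited noise or a center-frequency
#' sinusoid, per `config$carrier`), superposed on a 1/f background of RMS
#' `noise_scale`. `artifact_rate`/min rectangular-windowed half-sine
#' transients (width 0.2-0.5 s, amplitude at least 5x the largest band
#' amplitude and at least 600 microvolts) are injected at seeded random
#' times; their ground-truth onsets are returned alongside the stream so
#' artifact-rejection tests have an oracle.
#'
#' @param config A [synth_config()].
#' @param t0 UTC epoch seconds of session time zero.
#' @param offset_s Stream start stagger relative to `t0` (seconds).
#' @param channel EEG channel label.
#' @return List with elements `stream` (a [biosignal_stream()]) and
#'   `artifacts` (tibble of `onset_utc`, `width_s`, `amp_uv`).
#' @export
generate_eeg <- function(config, t0 = 0, offset_s = 0, channel = "Cz") {
  rate <- config$eeg_rate
  n <- floor((config$duration_s - offset_s) * rate + 1e-9)
  t <- offset_s + (seq_len(n) - 1) / rate
  res <- with_substream(config, "eeg", {
    arts <- tibble::tibble(onset_utc = numeric(), width_s = numeric(), amp_uv = numeric())
    x <- pink_noise(n, config$noise_scale)
    for (seg in config$segments) {
      idx <- which(t >= seg$start_s - 1e-9 & t < seg$end_s - 1e-9)
      if (length(idx) == 0) next
      for (band in names(band_centers)) {
        amp <- seg[[paste0(band, "_amp")]]
        if (amp <= 0) next
        if (config$carrier == "sinusoid") {
          fc <- band_centers[[band]]
          ph <- stats::runif(1, 0, 2 * pi)
          x[idx] <- x[idx] + amp * sqrt(2) * sin(2 * pi * fc * t[idx] + ph)
        } else {
          e <- band_edges[[band]]
          x[idx] <- x[idx] + bandlimited_noise(length(idx), rate, e[1], e[2], amp)
        }
      }
    }
    # artifact transients
    n_art <- round(config$artifact_rate * config$duration_s / 60)
    if (n_art > 0) {
      max_amp <- max(vapply(config$segments, function(s) {
        max(s$theta_amp, s$alpha_amp, s$beta_amp)
      }, 0))
      amp_art <- max(5 * max_amp, 600)
      onsets <- sort(stats::runif(n_art, offset_s + 0.5, config$duration_s - 1))
      widths <- stats::runif(n_art, 0.2, 0.5)
      signs <- sample(c(-1, 1), n_art, replace = TRUE)
      for (j in seq_len(n_art)) {
        idx <- which(t >= onsets[j] & t < onsets[j] + widths[j])
        x[idx] <- x[idx] + signs[j] * amp_art * sin(pi * (t[idx] - onsets[j]) / widths[j])
      }
      arts <- tibble::tibble(onset_utc = t0 + onsets, width_s = widths,
                             amp_uv = signs * amp_art)
    }
    list(x = x, arts = arts)
  })
  list(
    stream = biosignal_stream("EEG", res$x, rate, t0 + offset_s, channel),
    artifacts = res$arts
  )
}

# peak-normalized bi-exponential skin-conductance response, rise 1 s, decay 4 s
scr_pulse <- function(t_rel, amp, rise = 1, decay = 4) {
  g <- exp(-t_rel / decay) - exp(-t_rel / rise)
  g[t_rel < 0] <- 0
  t_peak <- rise * decay / (decay - rise) * log(decay / rise)
  amp * g / (exp(-t_peak / decay) - exp(-t_peak / rise))
}

#' Generate a synthetic electrodermal activity stream
#'
#' Tonic level is piecewise constant at each segment's `eda_tonic`, with a
#' 5-s linear ramp at segment boundaries (a full-segment ramp would destroy
#' the segment-mean ground truth). Each segment carries `scr_count` phasic
#' responses — bi-exponential pulses with 1-s rise and 4-s decay, peak
#' amplitude drawn uniformly in \[0.1, 0.5\] microsiemens — at seeded onsets
#' spread across the segment. All samples are non-negative.
#'
#' @inheritParams generate_eeg
#' @return A [biosignal_stream()] at `config$eda_rate`.
#' @export
generate_eda <- function(config, t0 = 0, offset_s = 0) {
  rate <- config$eda_rate
  n <- floor((config$duration_s - offset_s) * rate + 1e-9)
  t <- offset_s + (seq_len(n) - 1) / rate
  ramp_s <- 5
  x <- with_substream(config, "eda", {
    x <- numeric(n)
    prev_tonic <- config$segments[[1]]$eda_tonic
    for (i in seq_along(config$segments)) {
      seg <- config$segments[[i]]
      idx <- which(t >= seg$start_s - 1e-9 & t < seg$end_s - 1e-9)
      if (length(idx) > 0) {
        tonic <- rep(seg$eda_tonic, length(idx))
        if (i > 1) {
          r <- t[idx] < seg$start_s + ramp_s
          frac <- (t[idx][r] - seg$start_s) / ramp_s
          tonic[r] <- prev_tonic + frac * (seg$eda_tonic - prev_tonic)
        }
        x[idx] <- tonic
      }
      prev_tonic <- seg$eda_tonic
      if (seg$scr_count > 0) {
        len <- seg$end_s - seg$start_s
        # stratified onsets: one per equal-width bin so peaks stay distinct
        bins <- seq(seg$start_s, seg$end_s - 8, length.out = seg$scr_count + 1)
        if (length(bins) < seg$scr_count + 1 || any(diff(bins) <= 0)) {
          abort_config("segment too short for requested scr_count")
        }
        onsets <- bins[-length(bins)] + stats::runif(seg$scr_count, 0.5, pmax(0.6, diff(bins) * 0.5))
        amps <- stats::runif(seg$scr_count, 0.1, 0.5)
        for (j in seq_len(seg$scr_count)) {
          x <- x + scr_pulse(t - onsets[j], amps[j])
        }
      }
    }
    x
  })
  biosignal_stream("EDA", pmax(x, 0), rate, t0 + offset_s)
}

#' Generate a synthetic heart-rate stream
#'
#' Per-segment level plus seeded Gaussian jitter (`hr_jitter_sd`, default
#' 2 bpm) plus a slow sinusoidal drift (default 1 bpm amplitude, 120-s
#' period), clamped to the physiological range \[30, 220\] bpm.
#'
#' @inheritParams generate_eeg
#' @return A [biosignal_stream()] at `config$hr_rate`.
#' @export
generate_hr <- function(config, t0 = 0, offset_s = 0) {
  rate <- config$hr_rate
  n <- floor((config$duration_s - offset_s) * rate + 1e-9)
  t <- offset_s + (seq_len(n) - 1) / rate
  x <- with_substream(config, "hr", {
    x <- numeric(n)
    for (seg in config$segments) {
      idx <- which(t >= seg$start_s - 1e-9 & t < seg$end_s - 1e-9)
      x[idx] <- seg$hr_level
    }
    x + stats::rnorm(n, 0, config$hr_jitter_sd) +
      config$hr_drift_amp * sin(2 * pi * t / config$hr_drift_period_s)
  })
  biosignal_stream("HR", pmin(pmax(x, 30), 220), rate, t0 + offset_s)
}

# fixed start staggers (s) per modality, chosen so that naive index alignment
# fails while timestamp alignment succeeds
session_staggers <- c(EEG = 0, EDA = 0.5, HR = 1.2)

#' Generate a full synthetic session
#'
#' Produces the three modality streams with staggered UTC start times (EEG at
#' `t0`, EDA at `t0 + 0.5` s, HR at `t0 + 1.2` s) plus one event annotation
#' per internal segment boundary (node transitions for the baseline session,
#' gestures for the mixed-reality session) and session start/end marks. The
#' ground-truth segment table and artifact onsets are returned alongside for
#' parameter-recovery tests.
#'
#' @param config A [synth_config()].
#' @param session_kind `"VP_baseline"` or `"MR"`.
#' @param participant_id,group Manifest fields for the recording.
#' @param t0 UTC epoch seconds of session time zero.
#' @return List with `recording` (a [session_recording()]) and
#'   `ground_truth` (list of `segments` tibble and `artifacts` tibble).
#' @export
generate_session <- function(config, session_kind = c("VP_baseline", "MR"),
                             participant_id = "synthetic-1", group = "student",
                             t0 = 0) {
  session_kind <- match.arg(session_kind)
  eeg <- generate_eeg(config, t0, session_staggers[["EEG"]])
  eda <- generate_eda(config, t0, session_staggers[["EDA"]])
  hr <- generate_hr(config, t0, session_staggers[["HR"]])
  bounds <- vapply(config$segments, `[[`, 0, "start_s")[-1]
  mark_kind <- if (session_kind == "VP_baseline") "node_transition" else "gesture"
  ann <- event_annotations(
    time_utc = c(t0, t0 + bounds, t0 + config$duration_s),
    label = c("start", sprintf("%s_%d", mark_kind, seq_along(bounds)), "end"),
    kind = c("session_start", rep(mark_kind, length(bounds)), "session_end")
  )
  gt_seg <- dplyr::bind_rows(lapply(seq_along(config$segments), function(i) {
    s <- config$segments[[i]]
    tibble::tibble(
      segment = i, start_utc = t0 + s$start_s, end_utc = t0 + s$end_s,
      theta_amp = s$theta_amp, alpha_amp = s$alpha_amp, beta_amp = s$beta_amp,
      hr_level = s$hr_level, eda_tonic = s$eda_tonic, scr_count = s$scr_count
    )
  }))
  list(
    recording = session_recording(participant_id, group, session_kind,
                                  list(eeg$stream, eda, hr), ann),
    ground_truth = list(segments = gt_seg, artifacts = eeg$artifacts)
  )
}
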