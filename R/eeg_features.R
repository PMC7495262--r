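#' Frequency band definition
#'
#' @param name Band name.
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`. Bands are
#'   half-open `[low_hz, high_hz)` so adjacent bands (theta/alpha at 8 Hz)
#'   never double-count a spectral bin.
#' @return A list of class `band_definition`.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && low_hz < high_hz)) abort_config("need 0 < low_hz < high_hz")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' Default EEG bands
#'
#' Theta 4-8 Hz, alpha 8-12 Hz, beta 13-21 Hz — the rhythm definitions the
#' acquisition rig generates in real time.
#'
#' @return Named list of [band_definition()]s.
#' @export
default_bands <- function() {
  list(
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 12),
    beta = band_definition("beta", 13, 21)
  )
}

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: the signal is cut into Hann-windowed
#' segments of `window_s` seconds with fractional `overlap`, each segment is
#' mean-detrended, and the modified periodograms are averaged. The density is
#' normalized so that `sum(psd) * df` equals the signal variance (Parseval),
#' which makes band power an integral of the PSD.
#'
#' @param x Numeric samples.
#' @param rate Sampling rate, samples/s.
#' @param window_s Window length in seconds; truncated to the signal length
#'   when the signal is shorter than one window.
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return List with `freq` (Hz), `psd` (units^2/Hz) and `df` (bin width).
#' @export
welch_psd <- function(x, rate, window_s = 2, overlap = 0.5) {
  n <- length(x)
  L <- min(n, max(4L, round(window_s * rate)))
  hop <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = hop)
  # flush window so the tail of the signal is never left uncovered
  if (starts[length(starts)] + L - 1L < n) starts <- c(starts, n - L + 1L)
  k <- 0:(L - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / L))          # periodic Hann
  wnorm <- sum(w^2)
  nfreq <- floor(L / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    P <- (Mod(X)^2) / (rate * wnorm)
    # one-sided: double everything except DC (and Nyquist when L is even)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (L %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + P * dbl
  }
  list(freq = (seq_len(nfreq) - 1) * rate / L,
       psd = acc / length(starts),
       df = rate / L)
}

#' Band power of a set of epochs
#'
#' Integrates the Welch PSD of each epoch over the half-open band
#' `[low_hz, high_hz)` and averages across epochs (weighted by epoch length,
#' which reduces to the plain mean for equal-length epochs). For a stationary
#' signal this equals the mean squared value of the band-limited component;
#' for a pure sinusoid of peak amplitude A inside the band it equals A^2/2.
#'
#' @param epochs List of numeric vectors (surviving epochs from
#'   [reject_artifacts()]), or a single numeric vector.
#' @param rate Sampling rate, samples/s.
#' @param band A [band_definition()].
#' @param window_s,overlap Welch parameters, see [welch_psd()].
#' @return Band power in squared signal units (microvolts^2 for EEG), or
#'   `NA` with an `affectlytics_undefined_feature` warning when no epochs
#'   survive.
#' @export
band_power <- function(epochs, rate, band, window_s = 2, overlap = 0.5) {
  if (is.numeric(epochs)) epochs <- list(epochs)
  epochs <- Filter(function(e) length(e) >= 4L, epochs)
  if (length(epochs) == 0L) return(undefined_feature("band power with zero surviving epochs"))
  if (band$high_hz > rate / 2) abort_config("band extends beyond the Nyquist frequency")
  pw <- vapply(epochs, function(e) {
    sp <- welch_psd(e, rate, window_s, overlap)
    sel <- sp$freq >= band$low_hz & sp$freq < band$high_hz
    sum(sp$psd[sel]) * sp$df
  }, 0)
  wts <- vapply(epochs, length, 0L)
  sum(pw * wts) / sum(wts)
}

#' Band amplitude (RMS convention)
#'
#' Reported band "amplitude" in microvolts is the RMS of the band-limited
#' component, i.e. `sqrt(band power)`. A `peak_equivalent` convention
#' (RMS x sqrt(2), the peak of the sinusoid with the same power) is available
#' because absolute comparability with instrument-internal amplitude metrics
#' is not claimed.
#'
#' @inheritParams band_power
#' @param convention `"rms"` (default) or `"peak_equivalent"`.
#' @return Amplitude in signal units.
#' @export
band_amplitude <- function(epochs, rate, band, window_s = 2, overlap = 0.5,
                           convention = c("rms", "peak_equivalent")) {
  convention <- match.arg(convention)
  p <- band_power(epochs, rate, band, window_s, overlap)
  a <- sqrt(p)
  if (convention == "peak_equivalent") a * sqrt(2) else a
}

#' Theta/beta power ratio
#'
#' Ratio of mean theta-band power to mean beta-band power across the
#' surviving epochs; the engagement index (higher under working-memory load
#' and sustained attention). Invariant to rescaling of the signal.
#'
#' @inheritParams band_power
#' @param bands Named list with `theta` and `beta` [band_definition()]s.
#' @return Dimensionless ratio, or `NA` (with warning) when beta power is at
#'   or below the numeric floor.
#' @export
theta_beta_ratio <- function(epochs, rate, bands = default_bands(),
                             window_s = 2, overlap = 0.5) {
  th <- band_power(epochs, rate, bands$theta, window_s, overlap)
  be <- band_power(epochs, rate, bands$beta, window_s, overlap)
  if (is.na(th) || is.na(be)) return(NA_real_)
  if (ratio_undefined(th, be)) {
    return(undefined_feature("theta/beta ratio with beta power at the numeric floor"))
  }
  th / be
}

# the ratio is not estimable when beta power sits at spectral-leakage level:
# below machine precision or under 1e-6 of theta power (a scale-invariant
# floor, orders of magnitude beneath any physiological beta level)
ratio_undefined <- function(theta_power, beta_power) {
  beta_power <= .Machine$double.eps || beta_power < 1e-6 * theta_power
}

#' Amplitude-threshold artifact rejection
#'
#' Splits a segment into consecutive non-overlapping epochs of `epoch_s`
#' seconds (a segment shorter than one epoch yields a single truncated epoch;
#' a trailing partial epoch is kept and evaluated as-is) and rejects an epoch
#' iff any absolute sample value exceeds `threshold_uv` — the simplest
#' defensible automatic artifact-removal rule, with the threshold exposed.
#'
#' @param x A [biosignal_stream()] or a numeric vector.
#' @param rate Sampling rate; taken from the stream when `x` is one.
#' @param epoch_s Epoch length in seconds, `> 0`.
#' @param threshold_uv Rejection threshold in microvolts, `> 0`.
#' @return List with `epochs` (surviving epochs, in order), `rejected`
#'   (logical mask over all epochs), `n_total`, `n_rejected`.
#' @export
reject_artifacts <- function(x, rate = NULL, epoch_s = 1, threshold_uv = 100) {
  if (inherits(x, "biosignal_stream")) {
    rate <- x$rate
    x <- x$samples
  }
  if (is.null(rate)) abort_config("rate required when x is a bare vector")
  if (epoch_s <= 0) abort_config("epoch_s must be > 0")
  if (threshold_uv <= 0) abort_config("threshold_uv must be > 0")
  n <- length(x)
  ep_len <- max(1L, round(epoch_s * rate))
  starts <- seq(1L, n, by = ep_len)
  epochs <- lapply(starts, function(s) x[s:min(s + ep_len - 1L, n)])
  rejected <- vapply(epochs, function(e) any(abs(e) > threshold_uv), FALSE)
  list(epochs = epochs[!rejected], rejected = rejected,
       n_total = length(epochs), n_rejected = sum(rejected))
}

#' EEG feature-extraction configuration
#'
#' @param bands Named list of [band_definition()]s (needs `theta`, `alpha`,
#'   `beta`).
#' @param reject_epoch_s Artifact-rejection epoch length, seconds.
#' @param threshold_uv Absolute-amplitude rejection threshold, microvolts.
#' @param welch_window_s,welch_overlap Welch estimator parameters.
#' @param amplitude_convention `"rms"` or `"peak_equivalent"`, see
#'   [band_amplitude()].
#' @return A list of class `eeg_config`.
#' @export
eeg_config <- function(bands = default_bands(), reject_epoch_s = 1,
                       threshold_uv = 100,
                       welch_window_s = 4, welch_overlap = 0.5,
                       amplitude_convention = c("rms", "peak_equivalent")) {
  structure(
    list(bands = bands, reject_epoch_s = reject_epoch_s,
         threshold_uv = threshold_uv,
         welch_window_s = welch_window_s, welch_overlap = welch_overlap,
         amplitude_convention = match.arg(amplitude_convention)),
    class = "eeg_config"
  )
}

# surviving epochs are concatenated into one sequence before spectral
# estimation: the Hann taper makes the splice discontinuities negligible for
# band-integrated power, whereas analyzing each artifact-free run separately
# would underweight every run's tapered edges
clean_concat <- function(rej) {
  if (length(rej$epochs) == 0L) return(list())
  list(unlist(rej$epochs, use.names = FALSE))
}

#' EEG features of one segment
#'
#' Runs the full single-segment EEG chain: amplitude-threshold artifact
#' rejection on `reject_epoch_s` epochs, concatenation of the surviving
#' epochs, Welch band powers over the concatenated clean signal, and the
#' derived metrics: alpha amplitude (microvolts) and the theta/beta power
#' ratio.
#'
#' @param stream An EEG [biosignal_stream()].
#' @param start_utc,end_utc Optional segment bounds (UTC epoch seconds); the
#'   whole stream is used when omitted.
#' @param config An [eeg_config()].
#' @return One-row tibble: `alpha_amp`, `theta_power`, `alpha_power`,
#'   `beta_power`, `theta_beta_ratio`, `n_epochs_total`, `n_epochs_rejected`.
#'   Features are `NA` (with an `affectlytics_undefined_feature` warning)
#'   when no epoch survives rejection or the segment holds no samples.
#' @export
eeg_segment_features <- function(stream, start_utc = NULL, end_utc = NULL,
                                 config = eeg_config()) {
  if (!is.null(start_utc)) {
    stream <- slice_stream(stream, start_utc, end_utc)
  }
  na_row <- tibble::tibble(
    alpha_amp = NA_real_, theta_power = NA_real_, alpha_power = NA_real_,
    beta_power = NA_real_, theta_beta_ratio = NA_real_,
    n_epochs_total = 0L, n_epochs_rejected = 0L
  )
  if (is.null(stream)) {
    undefined_feature("EEG segment contains no samples")
    return(na_row)
  }
  rej <- reject_artifacts(stream, epoch_s = config$reject_epoch_s,
                          threshold_uv = config$threshold_uv)
  runs <- clean_concat(rej)
  if (length(runs) == 0L) {
    undefined_feature("all EEG epochs rejected in segment")
    na_row$n_epochs_total <- rej$n_total
    na_row$n_epochs_rejected <- rej$n_rejected
    return(na_row)
  }
  bp <- function(band) band_power(runs, stream$rate, band,
                                  config$welch_window_s, config$welch_overlap)
  theta <- bp(config$bands$theta)
  alpha <- bp(config$bands$alpha)
  beta <- bp(config$bands$beta)
  ratio <- if (!ratio_undefined(theta, beta)) theta / beta else {
    undefined_feature("theta/beta ratio with beta power at the numeric floor")
  }
  amp <- sqrt(alpha)
  if (config$amplitude_convention == "peak_equivalent") amp <- amp * sqrt(2)
  tibble::tibble(
    alpha_amp = amp, theta_power = theta, alpha_power = alpha,
    beta_power = beta, theta_beta_ratio = ratio,
    n_epochs_total = rej$n_total, n_epochs_rejected = rej$n_rejected
  )
}
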