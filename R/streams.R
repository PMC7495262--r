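#' Biosignal stream container
#'
#' A uniformly sampled single-channel time series on a shared UTC clock.
#' Sample `k` (0-based) is stamped `start_utc + k / rate`; all alignment in
#' the package is timestamp arithmetic, never index arithmetic, because the
#' modalities start at different instants.
#'
#' @param modality One of `"EEG"`, `"HR"`, `"EDA"`.
#' @param samples Numeric vector in the modality's units
#'   (EEG in microvolts, HR in beats per minute, EDA in microsiemens).
#' @param rate Sampling rate in samples per second.
#' @param start_utc Start time, seconds since the UTC epoch (fractional ok).
#' @param channel Channel label; EEG defaults to `"Cz"` (10-20 system),
#'   peripheral channels to the modality name.
#' @return An object of class `biosignal_stream`.
#' @export
biosignal_stream <- function(modality, samples, rate, start_utc, channel = NULL) {
  modality <- match.arg(modality, c("EEG", "HR", "EDA"))
  if (is.null(channel)) channel <- if (modality == "EEG") "Cz" else modality
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort_format("rate must be a single positive number")
  }
  if (length(samples) == 0L) abort_format("samples must be non-empty")
  if (!is.numeric(start_utc) || length(start_utc) != 1L) {
    abort_format("start_utc must be a single number (UTC epoch seconds)")
  }
  structure(
    list(
      modality = modality, channel = channel,
      rate = as.numeric(rate), start_utc = as.numeric(start_utc),
      samples = as.numeric(samples)
    ),
    class = "biosignal_stream"
  )
}

#' @export
print.biosignal_stream <- function(x, ...) {
  cat(sprintf(
    "<biosignal_stream> %s [%s]  %g Hz, %d samples, %.3f s, start_utc=%.3f\n",
    x$modality, x$channel, x$rate, length(x$samples),
    length(x$samples) / x$rate, x$start_utc
  ))
  invisible(x)
}

stream_units <- c(EEG = "uV", HR = "bpm", EDA = "uS")

#' Timestamps of every sample in a stream
#' @param stream A [biosignal_stream()].
#' @return Numeric vector of UTC epoch seconds, one per sample.
#' @export
stream_times <- function(stream) {
  stream$start_utc + (seq_along(stream$samples) - 1) / stream$rate
}

#' End of a stream's span (exclusive)
#' @param stream A [biosignal_stream()].
#' @return `start_utc + n / rate`: the first instant no longer covered.
#' @export
stream_end_utc <- function(stream) {
  stream$start_utc + length(stream$samples) / stream$rate
}

#' Slice a stream by UTC time
#'
#' Returns the samples whose timestamps fall in the half-open interval
#' `[start_utc, end_utc)`. Half-open intervals make slicing a partition:
#' cutting a stream at any ordered set of boundaries and concatenating the
#' pieces reproduces the original sample sequence exactly.
#'
#' @param stream A [biosignal_stream()].
#' @param start_utc,end_utc Window bounds in UTC epoch seconds,
#'   `start_utc < end_utc`.
#' @return A `biosignal_stream` covering the intersection, or `NULL` when the
#'   window contains no samples (the caller decides what an empty segment
#'   means).
#' @export
slice_stream <- function(stream, start_utc, end_utc) {
  if (start_utc >= end_utc) abort_config("slice window must have start_utc < end_utc")
  n <- length(stream$samples)
  # sample k (0-based) is at start + k/rate; tolerate float fuzz at bounds
  eps <- 1e-9
  k_lo <- ceiling((start_utc - stream$start_utc) * stream$rate - eps)
  k_hi <- ceiling((end_utc - stream$start_utc) * stream$rate - eps) - 1
  k_lo <- max(k_lo, 0)
  k_hi <- min(k_hi, n - 1)
  if (k_hi < k_lo) return(NULL)
  biosignal_stream(
    modality = stream$modality,
    samples = stream$samples[(k_lo + 1):(k_hi + 1)],
    rate = stream$rate,
    start_utc = stream$start_utc + k_lo / stream$rate,
    channel = stream$channel
  )
}

#' Session recording container
#'
#' One participant's recording of one session: the three modality streams
#' plus the event annotations used for segmentation.
#'
#' @param participant_id Participant identifier.
#' @param group One of `"student"`, `"postgraduate"`, `"neurosurgeon"`.
#' @param session_kind `"VP_baseline"` (web-based virtual-patient case, the
#'   personal baseline) or `"MR"` (mixed-reality session).
#' @param streams List of [biosignal_stream()] objects, at most one per
#'   modality/channel pair.
#' @param annotations Event annotation tibble as returned by
#'   [event_annotations()].
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(participant_id, group, session_kind, streams, annotations) {
  group <- match.arg(group, c("student", "postgraduate", "neurosurgeon"))
  session_kind <- match.arg(session_kind, c("VP_baseline", "MR"))
  keys <- vapply(streams, function(s) paste(s$modality, s$channel), "")
  if (anyDuplicated(keys)) abort_integrity("duplicate modality/channel stream in session")
  structure(
    list(
      participant_id = as.character(participant_id), group = group,
      session_kind = session_kind, streams = streams,
      annotations = annotations
    ),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> participant %s (%s), %s: %d streams, %d annotations\n",
    x$participant_id, x$group, x$session_kind,
    length(x$streams), nrow(x$annotations)
  ))
  invisible(x)
}

#' Fetch one stream from a session recording
#' @param recording A [session_recording()].
#' @param modality Modality to fetch.
#' @param channel Optional channel label; defaults to the first stream of the
#'   modality.
#' @return A [biosignal_stream()].
#' @export
get_stream <- function(recording, modality, channel = NULL) {
  hits <- Filter(
    function(s) s$modality == modality && (is.null(channel) || s$channel == channel),
    recording$streams
  )
  if (length(hits) == 0L) {
    abort_integrity(sprintf("no %s stream%s in session", modality,
                            if (is.null(channel)) "" else paste0(" [", channel, "]")))
  }
  hits[[1]]
}

#' Common span of a session's streams
#'
#' The intersection of all stream spans — the only window over which every
#' modality has data, used as the segmentation span.
#'
#' @param recording A [session_recording()].
#' @return `c(start_utc, end_utc)` of the intersection.
#' @export
session_span <- function(recording) {
  starts <- vapply(recording$streams, function(s) s$start_utc, 0)
  ends <- vapply(recording$streams, stream_end_utc, 0)
  span <- c(max(starts), min(ends))
  if (span[1] >= span[2]) abort_integrity("streams share no common time span")
  span
}
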