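#' Per-segment heart-rate summary
#'
#' Arithmetic mean and population SD (divisor n) of the HR samples whose
#' timestamps fall in the half-open window `[start_utc, end_utc)`.
#'
#' @param stream An HR [biosignal_stream()] (bpm).
#' @param start_utc,end_utc Window bounds, UTC epoch seconds; the whole
#'   stream is used when omitted.
#' @return One-row tibble `hr_mean`, `hr_sd`, `n_samples_hr`. Both summary
#'   values are `NA` (with an `affectlytics_undefined_feature` warning) when
#'   the window holds no samples.
#' @export
segment_hr <- function(stream, start_utc = NULL, end_utc = NULL) {
  peripheral_segment(stream, start_utc, end_utc, "hr")
}

#' Per-segment electrodermal-activity summary
#'
#' As [segment_hr()], for skin conductance in microsiemens. EDA is
#' summarized as the raw mean conductance — no tonic/phasic decomposition,
#' matching the descriptive analysis this pipeline reproduces.
#'
#' @inheritParams segment_hr
#' @param stream An EDA [biosignal_stream()] (microsiemens).
#' @return One-row tibble `eda_mean`, `eda_sd`, `n_samples_eda`.
#' @export
segment_eda <- function(stream, start_utc = NULL, end_utc = NULL) {
  peripheral_segment(stream, start_utc, end_utc, "eda")
}

peripheral_segment <- function(stream, start_utc, end_utc, prefix) {
  if (!is.null(start_utc)) {
    stream <- slice_stream(stream, start_utc, end_utc)
  }
  out <- tibble::tibble(mean = NA_real_, sd = NA_real_, n = 0L)
  if (is.null(stream) || length(stream$samples) == 0L) {
    undefined_feature(paste0(prefix, " segment contains no samples"))
  } else {
    out$mean <- mean(stream$samples)
    out$sd <- pop_sd(stream$samples)
    out$n <- length(stream$samples)
  }
  names(out) <- c(paste0(prefix, "_mean"), paste0(prefix, "_sd"),
                  paste0("n_samples_", prefix))
  out
}
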