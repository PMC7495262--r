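#' Build analysis segments from event annotations
#'
#' Segments are the half-open intervals between consecutive scenario events
#' (node transitions or gestures) inside the session span, plus a final
#' segment from the last event to the session end. The interval from session
#' start to the first event is excluded as the orientation period. A
#' zero-length final segment (event exactly at session end) is dropped with
#' a warning.
#'
#' @param annotations Annotation tibble ([event_annotations()]).
#' @param session_span `c(start_utc, end_utc)`, e.g. from [session_span()].
#' @return Tibble with `index`, `start_utc`, `end_utc`, `source_annotation`.
#' @export
build_segments <- function(annotations, session_span) {
  marks <- annotations[annotations$kind %in% c("node_transition", "gesture"), ]
  marks <- marks[marks$time_utc >= session_span[1] & marks$time_utc <= session_span[2], ]
  if (nrow(marks) == 0L) {
    abort_integrity("cannot segment: no node_transition/gesture annotations in span")
  }
  starts <- marks$time_utc
  ends <- c(marks$time_utc[-1], session_span[2])
  labels <- marks$label
  keep <- ends > starts
  if (!all(keep)) {
    warning("dropping zero-length segment(s) at session end", call. = FALSE)
  }
  tibble::tibble(
    index = seq_len(sum(keep)),
    start_utc = starts[keep], end_utc = ends[keep],
    source_annotation = labels[keep]
  )
}

pipeline_metrics <- c("theta_beta", "alpha_amp", "hr", "eda")

#' Per-segment metrics for one session
#'
#' Segments the session by its annotations and computes, per segment, the
#' four pipeline metrics: theta/beta power ratio and alpha amplitude from
#' the EEG (default channel Cz, the reporting channel), mean HR and mean
#' EDA from the peripheral streams.
#'
#' @param recording A [session_recording()].
#' @param config An [eeg_config()].
#' @param channel EEG reporting channel.
#' @return Tibble, one row per segment, with the segment bounds, EEG feature
#'   columns, and the HR/EDA summaries.
#' @export
session_metrics <- function(recording, config = eeg_config(), channel = "Cz") {
  span <- session_span(recording)
  segs <- build_segments(recording$annotations, span)
  eeg <- get_stream(recording, "EEG", channel)
  hr <- get_stream(recording, "HR")
  eda <- get_stream(recording, "EDA")
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    dplyr::bind_cols(
      s,
      eeg_segment_features(eeg, s$start_utc, s$end_utc, config),
      segment_hr(hr, s$start_utc, s$end_utc),
      segment_eda(eda, s$start_utc, s$end_utc)
    )
  })
  dplyr::bind_rows(rows)
}

#' Global baseline averages of a session
#'
#' The baseline is the unweighted arithmetic mean over segment means, per
#' metric — segments count equally regardless of duration, because the
#' comparison is performed on a per-segment basis.
#'
#' @param metrics Per-segment metrics from [session_metrics()], or a tibble
#'   with columns `theta_beta_ratio`/`theta_beta`, `alpha_amp`, `hr_mean`/
#'   `hr`, `eda_mean`/`eda`.
#' @param duration_weighted Use duration-weighted averaging instead
#'   (requires `start_utc`/`end_utc` columns); off by default.
#' @return Named list with `theta_beta`, `alpha_amp`, `hr`, `eda`.
#' @export
baseline_summary <- function(metrics, duration_weighted = FALSE) {
  col <- function(...) {
    for (nm in c(...)) if (nm %in% names(metrics)) return(metrics[[nm]])
    rep(NA_real_, nrow(metrics))
  }
  vals <- list(
    theta_beta = col("theta_beta_ratio", "theta_beta"),
    alpha_amp = col("alpha_amp", "alpha"),
    hr = col("hr_mean", "hr"),
    eda = col("eda_mean", "eda")
  )
  if (duration_weighted) {
    w <- metrics$end_utc - metrics$start_utc
    lapply(vals, function(v) {
      ok <- is.finite(v)
      if (!any(ok)) NA_real_ else sum(v[ok] * w[ok]) / sum(w[ok])
    })
  } else {
    lapply(vals, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
}

#' Baseline-vs-MR summary for one participant
#'
#' Combines the per-segment metrics of the baseline virtual-patient session
#' and the mixed-reality session into one long row set: per metric, the
#' baseline global average, the MR session average (both unweighted means
#' over segment means) and their difference `delta = mr - vp`.
#'
#' @param vp_metrics,mr_metrics Per-segment metric tibbles
#'   ([session_metrics()]) of the two sessions.
#' @param participant_id,group Identifiers for the output rows.
#' @return Tibble with columns `participant_id`, `group`, `metric`, `vp`,
#'   `mr`, `delta`; metrics whose features were undefined carry `NA`.
#' @export
participant_summary <- function(vp_metrics, mr_metrics, participant_id, group) {
  vp <- baseline_summary(vp_metrics)
  mr <- baseline_summary(mr_metrics)
  vp_v <- unname(unlist(vp[pipeline_metrics]))
  mr_v <- unname(unlist(mr[pipeline_metrics]))
  tibble::tibble(
    participant_id = as.character(participant_id),
    group = group,
    metric = pipeline_metrics,
    vp = vp_v,
    mr = mr_v,
    delta = mr_v - vp_v
  )
}

#' Run both sessions of a participant through the pipeline
#'
#' @param vp_recording,mr_recording The two [session_recording()]s
#'   (`VP_baseline` and `MR`).
#' @param config An [eeg_config()].
#' @param channel EEG reporting channel.
#' @return A [participant_summary()] tibble.
#' @export
summarize_participant <- function(vp_recording, mr_recording,
                                  config = eeg_config(), channel = "Cz") {
  stopifnot(vp_recording$session_kind == "VP_baseline",
            mr_recording$session_kind == "MR")
  participant_summary(
    session_metrics(vp_recording, config, channel),
    session_metrics(mr_recording, config, channel),
    vp_recording$participant_id, vp_recording$group
  )
}

#' Group-level aggregation
#'
#' Per group, condition and metric: arithmetic mean and population SD
#' (divisor n) over the participant means, with the count of participants
#' whose metric is defined.
#'
#' @param participants Row-bound [participant_summary()] tibbles.
#' @return Tibble with `group`, `metric`, `vp_mean`, `vp_sd`, `mr_mean`,
#'   `mr_sd`, `n`.
#' @export
group_summary <- function(participants) {
  participants |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      vp_mean = mean(.data$vp[is.finite(.data$vp)]),
      vp_sd = pop_sd(.data$vp),
      mr_mean = mean(.data$mr[is.finite(.data$mr)]),
      mr_sd = pop_sd(.data$mr),
      n = sum(is.finite(.data$vp) & is.finite(.data$mr)),
      .groups = "drop"
    )
}

#' Directional shift counts
#'
#' Counts, per group and in total, the participants whose MR-vs-baseline
#' delta moved in the direction of interest: increased theta/beta ratio,
#' decreased alpha amplitude, increased HR, increased EDA. Comparisons use
#' strict inequalities on unrounded deltas; a zero delta counts as neither
#' an increase nor a decrease. The `Total` row is the column sum over
#' groups.
#'
#' @param participants Row-bound [participant_summary()] tibbles.
#' @return Tibble with `group` (including `"Total"`), `n`, and the four
#'   shift-count columns.
#' @export
shift_table <- function(participants) {
  wide <- tidyr_pivot(participants)
  per_group <- wide |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      increased_theta_beta = sum(.data$delta_theta_beta > 0, na.rm = TRUE),
      decreased_alpha = sum(.data$delta_alpha_amp < 0, na.rm = TRUE),
      increased_hr = sum(.data$delta_hr > 0, na.rm = TRUE),
      increased_eda = sum(.data$delta_eda > 0, na.rm = TRUE),
      .groups = "drop"
    )
  total <- dplyr::summarise(
    per_group, group = "Total",
    dplyr::across(c("n", "increased_theta_beta", "decreased_alpha",
                    "increased_hr", "increased_eda"), sum)
  )
  dplyr::bind_rows(total, per_group)
}

# minimal long->wide for the delta columns (avoids a tidyr dependency)
tidyr_pivot <- function(participants) {
  sp <- split(participants, participants$participant_id)
  dplyr::bind_rows(lapply(sp, function(p) {
    out <- tibble::tibble(participant_id = p$participant_id[1], group = p$group[1])
    for (m in pipeline_metrics) {
      out[[paste0("delta_", m)]] <- p$delta[match(m, p$metric)]
    }
    out
  }))
}
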