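#' Affect-rule configuration
#'
#' Dead-zones per metric: an absolute delta at or below the dead-zone counts
#' as "no change". Defaults are 0 (pure sign logic), matching a qualitative
#' reading of group-level shifts; nonzero dead-zones are recommended for
#' noisy single-participant use.
#'
#' @param theta_beta,alpha_amp,hr,eda Non-negative dead-zone per metric, in
#'   the metric's units (ratio, microvolts, bpm, microsiemens).
#' @return A list of class `affect_rules`.
#' @export
affect_rules <- function(theta_beta = 0, alpha_amp = 0, hr = 0, eda = 0) {
  dz <- c(theta_beta = theta_beta, alpha_amp = alpha_amp, hr = hr, eda = eda)
  if (any(dz < 0)) abort_config("dead-zones must be >= 0")
  structure(list(dead_zone = dz), class = "affect_rules")
}

sign_dz <- function(delta, dz) {
  if (!is.finite(delta)) return(NA_integer_)
  if (delta > dz) 1L else if (delta < -dz) -1L else 0L
}

#' Rule-based affective interpretation of metric deltas
#'
#' Maps the signs of the MR-minus-baseline deltas (after dead-zoning) to the
#' engagement reading established for these EEG indices:
#'
#' * theta/beta up, alpha down -> `full_cognitive_engagement` (working-memory
#'   load with attention-driven alpha suppression);
#' * theta/beta down, alpha up -> `guided_disengagement` (judgement calls
#'   suppressed, e.g. a fully guided learner);
#' * theta/beta up, alpha up -> `ambivalent_engagement` (task commitment
#'   without full cognitive challenge);
#' * any other pattern (including no-change and theta/beta down with alpha
#'   down, for which no established reading exists) -> `indeterminate`.
#'
#' `arousal_elevated` is true when the EDA or HR delta exceeds its dead-zone
#' (sympathetic arousal, independent of valence).
#'
#' @param deltas Named numeric vector (or single-row list/tibble) with
#'   elements `theta_beta`, `alpha_amp`, `hr`, `eda` — e.g. one
#'   participant's `delta` column from [participant_summary()], or group
#'   deltas `mr_mean - vp_mean`.
#' @param rules An [affect_rules()].
#' @return One-row tibble: `engagement`, `arousal_elevated`, `rationale`.
#' @export
classify_affect <- function(deltas, rules = affect_rules()) {
  deltas <- unlist(deltas)[c("theta_beta", "alpha_amp", "hr", "eda")]
  dz <- rules$dead_zone
  s_tbr <- sign_dz(deltas[["theta_beta"]], dz[["theta_beta"]])
  s_alpha <- sign_dz(deltas[["alpha_amp"]], dz[["alpha_amp"]])
  s_hr <- sign_dz(deltas[["hr"]], dz[["hr"]])
  s_eda <- sign_dz(deltas[["eda"]], dz[["eda"]])
  if (is.na(s_tbr) || is.na(s_alpha)) {
    engagement <- "indeterminate"
    why <- "EEG deltas undefined"
  } else if (s_tbr > 0 && s_alpha < 0) {
    engagement <- "full_cognitive_engagement"
    why <- "theta/beta ratio increased and alpha amplitude decreased"
  } else if (s_tbr < 0 && s_alpha > 0) {
    engagement <- "guided_disengagement"
    why <- "theta/beta ratio decreased and alpha amplitude increased"
  } else if (s_tbr > 0 && s_alpha > 0) {
    engagement <- "ambivalent_engagement"
    why <- "theta/beta ratio and alpha amplitude both increased"
  } else {
    engagement <- "indeterminate"
    why <- sprintf("no established reading for sign pattern (theta/beta %+d, alpha %+d)",
                   s_tbr, s_alpha)
  }
  arousal <- isTRUE(s_eda > 0) || isTRUE(s_hr > 0)
  why_ar <- if (arousal) {
    paste0("elevated ", paste(c("EDA", "HR")[c(isTRUE(s_eda > 0), isTRUE(s_hr > 0))],
                              collapse = " and "))
  } else "no HR/EDA elevation"
  tibble::tibble(
    engagement = engagement,
    arousal_elevated = arousal,
    rationale = paste0(why, "; ", why_ar)
  )
}

#' Classify every group of a cohort
#'
#' Derives group-level deltas (`mr_mean - vp_mean` per metric) from a
#' [group_summary()] table and applies [classify_affect()] to each group.
#'
#' @param groups A [group_summary()] tibble.
#' @param rules An [affect_rules()].
#' @return Tibble with `group`, `engagement`, `arousal_elevated`,
#'   `rationale`.
#' @export
classify_groups <- function(groups, rules = affect_rules()) {
  dplyr::bind_rows(lapply(split(groups, groups$group), function(g) {
    deltas <- stats::setNames(g$mr_mean - g$vp_mean, g$metric)
    dplyr::bind_cols(tibble::tibble(group = g$group[1]),
                     classify_affect(deltas, rules))
  }))
}
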