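#' Reference cohort: per-participant session means
#'
#' Published per-participant biosignal averages from an 11-participant
#' affective-learning cohort (4 medical students, 4 neurosurgeons, 3
#' postgraduate medical students) who each completed a web-based
#' virtual-patient baseline session and a mixed-reality neuroanatomy
#' session, transcribed as plain CSV. These summary values are the input to
#' the aggregation stage ([group_summary()], [shift_table()],
#' [classify_groups()]); the study deposited no raw signal data.
#'
#' Known internal inconsistencies of the source tables (the neurosurgeon-1
#' alpha cells disagree with that participant's own session summaries, and
#' some printed group/total cells do not equal the aggregate of the
#' per-participant rows) are preserved as printed — this accessor returns
#' the per-participant table verbatim and the pipeline recomputes all
#' aggregates from it.
#'
#' @return Long tibble with `participant_id`, `group`, `metric`
#'   (`theta_beta`, `alpha_amp`, `hr`, `eda`), `vp`, `mr`, `delta`.
#' @export
reference_cohort <- function() {
  path <- system.file("extdata", "reference_cohort_means.csv",
                      package = "affectlytics", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df) |>
    dplyr::mutate(delta = .data$mr - .data$vp)
}

#' Reference baseline segment table
#'
#' Per-segment baseline averages of a representative participant
#' (neurosurgeon) during the virtual-patient session: four segments with
#' alpha amplitude (microvolts), theta/beta power ratio, HR (bpm) and EDA
#' (microsiemens). Used to check that [baseline_summary()]'s unweighted
#' segment averaging reproduces the published global baseline values.
#'
#' @return Tibble with `segment`, `alpha_amp`, `theta_beta`, `hr`, `eda`.
#' @export
reference_baseline_segments <- function() {
  path <- system.file("extdata", "reference_baseline_segments.csv",
                      package = "affectlytics", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
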