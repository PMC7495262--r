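#' Synthetic two-session cohort with known ground truth
#'
#' Builds a cohort of participants who each completed a baseline
#' virtual-patient session and a mixed-reality session, with per-participant
#' session levels (band carrier RMS, HR level, tonic EDA) chosen so that the
#' direction of every baseline-to-MR shift is known by construction. Shift
#' patterns cycle through the three engagement archetypes (theta/beta up
#' with alpha down, down/up, up/up) with varied HR/EDA directions, so a
#' recovered [shift_table()] can be compared cell-by-cell against the
#' ground-truth direction table.
#'
#' Within a session all segments share the session's levels (the first
#' segment is an orientation period and is excluded from analysis, so
#' constant levels keep the session ground truth unbiased); the per-segment
#' ground-truth tables are returned for band-RMS recovery checks.
#'
#' @param seed Master seed; every participant and session derives a
#'   substream from it.
#' @param n_participants Number of participants (default 6).
#' @param n_segments Segments per session (default 4, 120 s each; the first
#'   is the orientation period).
#' @param segment_s Segment duration in seconds.
#' @param noise_frac 1/f background RMS as a fraction of the beta carrier
#'   RMS (default 0.1, i.e. noise at 10 percent of the weakest band).
#' @param artifact_rate Injected EEG transients per minute.
#' @return List with `participants` (per participant: `vp`/`mr`
#'   [session_recording()]s plus their ground-truth tables) and `truth`
#'   (tibble of per-participant true session levels, deltas and shift
#'   directions per metric).
#' @export
synthetic_cohort <- function(seed = 1L, n_participants = 6L, n_segments = 4L,
                             segment_s = 120, noise_frac = 0.1,
                             artifact_rate = 2) {
  groups <- rep(c("student", "postgraduate", "neurosurgeon"),
                length.out = n_participants)
  # shift archetypes, recycled over participants: signs of (tbr, alpha, hr, eda)
  patterns <- list(
    c(1, -1, 1, 1), c(-1, 1, -1, 1), c(1, 1, 1, -1),
    c(1, -1, -1, 1), c(-1, 1, 1, 1), c(1, 1, 1, 1)
  )
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  sub_seeds <- matrix(sample.int(2147483646L, 2L * n_participants), ncol = 2L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  duration <- n_segments * segment_s
  participants <- list()
  truth_rows <- list()
  for (p in seq_len(n_participants)) {
    pat <- patterns[[(p - 1L) %% length(patterns) + 1L]]
    # baseline levels with a deterministic per-participant offset
    theta_vp <- 4 + 0.15 * p
    alpha_vp <- 8 + 0.3 * p
    beta_vp <- 2
    hr_vp <- 76 + p
    eda_vp <- 1.2 + 0.1 * p
    # MR levels: multiplicative/additive effects well above estimation error
    theta_mr <- theta_vp * ifelse(pat[1] > 0, 1.4, 0.7)
    alpha_mr <- alpha_vp * ifelse(pat[2] > 0, 1.3, 0.75)
    beta_mr <- beta_vp
    hr_mr <- hr_vp + 8 * pat[3]
    eda_mr <- max(eda_vp + 0.8 * pat[4], 0.1)
    noise <- noise_frac * beta_vp

    mk_cfg <- function(theta, alpha, beta, hr, eda, sd_seed) {
      segs <- lapply(seq_len(n_segments), function(i) {
        segment_spec((i - 1) * segment_s, i * segment_s,
                     theta_amp = theta, alpha_amp = alpha, beta_amp = beta,
                     hr_level = hr, eda_tonic = eda, scr_count = 1L)
      })
      synth_config(duration, segs, seed = sd_seed,
                   noise_scale = noise, artifact_rate = artifact_rate)
    }
    pid <- sprintf("synthetic-%02d", p)
    vp <- generate_session(mk_cfg(theta_vp, alpha_vp, beta_vp, hr_vp, eda_vp,
                                  sub_seeds[p, 1]),
                           "VP_baseline", pid, groups[p], t0 = 1000)
    mr <- generate_session(mk_cfg(theta_mr, alpha_mr, beta_mr, hr_mr, eda_mr,
                                  sub_seeds[p, 2]),
                           "MR", pid, groups[p], t0 = 100000)
    participants[[p]] <- list(
      participant_id = pid, group = groups[p],
      vp = vp$recording, mr = mr$recording,
      vp_truth = vp$ground_truth, mr_truth = mr$ground_truth
    )
    tbr_vp <- theta_vp^2 / beta_vp^2
    tbr_mr <- theta_mr^2 / beta_mr^2
    truth_rows[[p]] <- tibble::tibble(
      participant_id = pid, group = groups[p],
      metric = c("theta_beta", "alpha_amp", "hr", "eda"),
      vp_true = c(tbr_vp, alpha_vp, hr_vp, eda_vp),
      mr_true = c(tbr_mr, alpha_mr, hr_mr, eda_mr),
      direction = c(sign(tbr_mr - tbr_vp), sign(alpha_mr - alpha_vp),
                    pat[3], pat[4])
    )
  }
  list(participants = participants, truth = dplyr::bind_rows(truth_rows))
}
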