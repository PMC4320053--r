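# Seeded generators for synthetic experimental cohorts with the
# statistical structure the analysis functions assume: Gaussian
# localization noise around a midline-biased latent hand position,
# group-dependent injected drift, ordinal ownership ratings coupled to
# drift, and tonic skin-conductance traces with event-locked responses
# scaled by group and coupled to ownership.

#' Configuration for a synthetic Experiment 1 cohort
#'
#' Defaults mirror the magnitudes observed in the behavioral experiment:
#' 21 subjects per group, a true hand azimuth of 320 mm, a 31.5 mm baseline
#' localization bias toward the midline, a 13 mm within-subject
#' localization SD over the 40 repeated responses, and group drift means
#' ordered sync > async > no_stroke > no_hand with magnitudes that put the
#' sync standardized effect near 1. Ownership ratings arise from a latent
#' Gaussian coupled to the subject's drift, rounded and clipped to the
#' integer scale -3..3.
#'
#' @param n_per_group Subjects per group.
#' @param true_hand_position True hand azimuth, mm from midline.
#' @param baseline_bias Mean localization bias toward the midline, mm.
#' @param within_subject_sd SD of repeated localizations within a subject,
#'   mm.
#' @param between_subject_sd SD of the latent localization mean across
#'   subjects, mm.
#' @param n_localizations Repeated responses per phase.
#' @param drift_means Named vector of mean injected drifts toward the
#'   rubber hand, mm, for groups sync, async, no_stroke, no_hand.
#' @param subject_drift_sd Between-subject SD of the injected drift, mm.
#' @param ownership_baseline Named vector of latent ownership baselines per
#'   group (rating-scale units).
#' @param ownership_post_shift Named vector added to the latent baseline in
#'   the post-test.
#' @param coupling_slope Latent rating units per mm of drift.
#' @param rating_noise SD of the latent rating noise.
#' @param seed Integer seed.
#' @return A list of class `exp1_gen_config`.
#' @export
exp1_gen_config <- function(n_per_group = 21,
                            true_hand_position = 320,
                            baseline_bias = 31.5,
                            within_subject_sd = 13,
                            between_subject_sd = 20,
                            n_localizations = 40,
                            drift_means = c(sync = 10, async = 5.5,
                                            no_stroke = 4.5, no_hand = 2.5),
                            subject_drift_sd = 9,
                            ownership_baseline = c(sync = 1.2, async = 1.2,
                                                   no_stroke = 1.2,
                                                   no_hand = -2.5),
                            ownership_post_shift = c(sync = 1.0,
                                                     async = -0.6,
                                                     no_stroke = -0.2,
                                                     no_hand = 0),
                            coupling_slope = 0.08,
                            rating_noise = 2.0,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_per_group >= 2, within_subject_sd > 0, between_subject_sd > 0,
            subject_drift_sd > 0, rating_noise > 0, n_localizations >= 1)
  for (field in c("drift_means", "ownership_baseline", "ownership_post_shift")) {
    bad <- setdiff(EXP1_GROUPS, names(cfg[[field]]))
    if (length(bad))
      stop_input(field, " must name group(s): ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "exp1_gen_config")
}

clip_rating <- function(latent) pmin(3, pmax(-3, round(latent)))

#' Generate a synthetic Experiment 1 cohort
#'
#' Per subject: a latent localization mean equal to the true hand position
#' minus the midline bias plus between-subject noise; repeated pre-test
#' draws around that mean; post-test draws additionally shifted toward the
#' rubber hand (i.e. toward the midline, negative on the stored axis) by
#' the subject's injected drift; and ownership ratings discretized from a
#' latent Gaussian coupled to the drift. Output is bit-reproducible for a
#' fixed seed.
#'
#' @param config An [exp1_gen_config()].
#' @param seed Overrides `config$seed` when supplied.
#' @return An [exp1_records()] object with the generating config attached
#'   as attribute `gen_config`.
#' @export
generate_exp1 <- function(config = exp1_gen_config(), seed = NULL) {
  if (!inherits(config, "exp1_gen_config"))
    stop_input("config must be an exp1_gen_config")
  seed <- if (is.null(seed)) config$seed else seed
  with_seed(seed, {
    n <- config$n_per_group
    groups <- rep(EXP1_GROUPS, each = n)
    n_tot <- length(groups)
    mu <- config$true_hand_position - config$baseline_bias +
      stats::rnorm(n_tot, 0, config$between_subject_sd)
    delta <- config$drift_means[groups] +
      stats::rnorm(n_tot, 0, config$subject_drift_sd)
    k <- config$n_localizations
    pre <- matrix(stats::rnorm(n_tot * k, mu, config$within_subject_sd),
                  n_tot, k)
    post <- matrix(stats::rnorm(n_tot * k, mu - delta,
                                config$within_subject_sd), n_tot, k)
    own_pre <- clip_rating(config$ownership_baseline[groups] +
                             config$coupling_slope * delta +
                             stats::rnorm(n_tot, 0, config$rating_noise))
    own_post <- clip_rating(config$ownership_baseline[groups] +
                              config$ownership_post_shift[groups] +
                              config$coupling_slope * delta +
                              stats::rnorm(n_tot, 0, config$rating_noise))
    subjects <- data.frame(
      subject = sprintf("s%03d", seq_len(n_tot)),
      group = groups,
      ownership_pre = as.integer(own_pre),
      ownership_post = as.integer(own_post),
      true_x = config$true_hand_position,
      stringsAsFactors = FALSE
    )
    rec <- exp1_records(subjects, pre, post)
    attr(rec, "gen_config") <- config
    attr(rec, "seed") <- seed
    rec
  })
}

#' Write an Experiment 1 record set to CSV
#'
#' Emits the one-row-per-subject dialect that [load_exp1()] reads with its
#' default column map.
#'
#' @param records An `exp1_records` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exp1_csv <- function(records, path) {
  k_pre <- ncol(records$pre); k_post <- ncol(records$post)
  df <- data.frame(
    subject = records$subjects$subject,
    group = records$subjects$group,
    ownership_pre = records$subjects$ownership_pre,
    ownership_post = records$subjects$ownership_post,
    true_x_mm = records$subjects$true_x,
    stringsAsFactors = FALSE
  )
  pre <- as.data.frame(records$pre)
  names(pre) <- sprintf("pre_%02d", seq_len(k_pre))
  post <- as.data.frame(records$post)
  names(post) <- sprintf("post_%02d", seq_len(k_post))
  utils::write.csv(cbind(df, pre, post), path, row.names = FALSE)
  invisible(path)
}

#' Configuration for a synthetic Experiment 2 cohort
#'
#' Defaults: 17 subjects per group; a 420 s conductance trace sampled at
#' 10 Hz with a tonic level, slow drift and measurement noise; eye-opening
#' at 240 s and threat at 300 s; event-locked response amplitudes drawn per
#' group, large for the plausible-arm group and small for both controls;
#' and ownership ratings (plausible-arm and hanging-arm only) discretized
#' from a latent Gaussian coupled to the subject's response amplitude.
#'
#' @param n_per_group Subjects per group.
#' @param duration_s Trace duration, s (sampling is fixed at 10 Hz).
#' @param baseline_uS Tonic conductance level, microsiemens.
#' @param drift_per_s Linear tonic drift, microsiemens per second.
#' @param noise_sd Measurement noise SD, microsiemens.
#' @param eye_opening_s,threat_s Event onsets, s.
#' @param amp_mean Named vector of mean eye-opening response amplitudes per
#'   group, microsiemens.
#' @param amp_sd SD of response amplitudes.
#' @param threat_scale Threat amplitude as a fraction of the eye-opening
#'   amplitude.
#' @param rise_s,decay_tau_s Response morphology: linear rise time and
#'   exponential decay constant, s.
#' @param ownership_baseline Named latent baselines for the two rated
#'   groups.
#' @param coupling_slope Latent rating units per microsiemens of response
#'   amplitude.
#' @param rating_noise SD of the latent rating noise.
#' @param seed Integer seed.
#' @return A list of class `exp2_gen_config`.
#' @export
exp2_gen_config <- function(n_per_group = 17,
                            duration_s = 420,
                            baseline_uS = 5,
                            drift_per_s = 5e-4,
                            noise_sd = 0.01,
                            eye_opening_s = 240,
                            threat_s = 300,
                            amp_mean = c(plausible_arm = 0.8,
                                         hanging_arm = 0.25,
                                         no_arm = 0.25),
                            amp_sd = 0.3,
                            threat_scale = 0.8,
                            rise_s = 0.5,
                            decay_tau_s = 2,
                            ownership_baseline = c(plausible_arm = 0.2,
                                                   hanging_arm = -3.5),
                            coupling_slope = 2.5,
                            rating_noise = 1.2,
                            seed = 1) {
  stopifnot(n_per_group >= 2, duration_s > 0, noise_sd > 0, amp_sd > 0,
            rating_noise > 0)
  if (eye_opening_s + 5 > duration_s || threat_s + 5 > duration_s ||
      eye_opening_s < 0 || threat_s < 0)
    stop_input("event times (plus the 5 s response window) must fall ",
               "inside the trace")
  structure(as.list(environment()), class = "exp2_gen_config")
}

scr_bump <- function(time_s, onset, amp, rise_s, tau) {
  dt <- time_s - onset
  out <- numeric(length(dt))
  rising <- dt >= 0 & dt < rise_s
  falling <- dt >= rise_s
  out[rising] <- amp * dt[rising] / rise_s
  out[falling] <- amp * exp(-(dt[falling] - rise_s) / tau)
  out
}

#' Generate a synthetic Experiment 2 cohort
#'
#' Per subject: a tonic conductance trace (baseline, slow linear drift,
#' Gaussian measurement noise) with rise-and-decay responses inserted at
#' the eye-opening and threat onsets, whose amplitudes follow the group's
#' distribution; plus an ownership rating (rated groups only) discretized
#' from a latent Gaussian coupled to the eye-opening amplitude. Output is
#' bit-reproducible for a fixed seed.
#'
#' @param config An [exp2_gen_config()].
#' @param seed Overrides `config$seed` when supplied.
#' @return An [exp2_records()] object with attribute `gen_config`.
#' @export
generate_exp2 <- function(config = exp2_gen_config(), seed = NULL) {
  if (!inherits(config, "exp2_gen_config"))
    stop_input("config must be an exp2_gen_config")
  seed <- if (is.null(seed)) config$seed else seed
  with_seed(seed, {
    groups <- rep(EXP2_GROUPS, each = config$n_per_group)
    n_tot <- length(groups)
    time_s <- seq(0, config$duration_s, by = 0.1)
    amp_eye <- pmax(0.01, stats::rnorm(n_tot, config$amp_mean[groups],
                                       config$amp_sd))
    amp_threat <- pmax(0.01, config$threat_scale * amp_eye +
                         stats::rnorm(n_tot, 0, config$amp_sd / 4))
    traces <- lapply(seq_len(n_tot), function(i) {
      tonic <- config$baseline_uS + config$drift_per_s * time_s +
        stats::rnorm(length(time_s), 0, config$noise_sd)
      y <- tonic +
        scr_bump(time_s, config$eye_opening_s, amp_eye[i], config$rise_s,
                 config$decay_tau_s) +
        scr_bump(time_s, config$threat_s, amp_threat[i], config$rise_s,
                 config$decay_tau_s)
      data.frame(time_s = time_s, conductance_uS = y)
    })
    rated <- groups %in% EXP2_RATED_GROUPS
    own <- rep(NA_integer_, n_tot)
    own[rated] <- as.integer(clip_rating(
      config$ownership_baseline[groups[rated]] +
        config$coupling_slope * amp_eye[rated] +
        stats::rnorm(sum(rated), 0, config$rating_noise)))
    subjects <- data.frame(
      subject = sprintf("s%03d", seq_len(n_tot)),
      group = groups,
      ownership = own,
      eye_opening_s = config$eye_opening_s,
      threat_s = config$threat_s,
      stringsAsFactors = FALSE
    )
    rec <- exp2_records(subjects, traces)
    attr(rec, "gen_config") <- config
    attr(rec, "seed") <- seed
    rec
  })
}

#' Write an Experiment 2 record set to a directory of CSV files
#'
#' Emits the dialect [load_exp2()] reads: `subjects.csv` plus one
#' `traces/<subject>.csv` per subject.
#'
#' @param records An `exp2_records` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_exp2_csv <- function(records, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (id in records$subjects$subject)
    utils::write.csv(records$traces[[id]],
                     file.path(dir, "traces", paste0(id, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
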