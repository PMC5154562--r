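#' Synthetic-cohort configuration
#'
#' Study conditions for the cohort generator. The demographic defaults are
#' the validation cohort's characteristics: 81 subjects, 63 of them male;
#' per-sex truncated normals for age, height and weight with the cohort's
#' means, SDs and observed ranges. Feature distributions (start-of-recovery
#' HR and RDI) and their correlation are modelling choices documented in
#' the methods vignette; measured VO2max is generated from one of the three
#' published equations plus Gaussian residual noise whose SD defaults to
#' that model's published RMSE.
#'
#' @param n Number of subjects.
#' @param male_fraction Probability of drawing a male subject (default
#'   63/81).
#' @param age_male,age_female,height_male,height_female,weight_male,weight_female
#'   Length-4 numeric vectors `c(mean, sd, min, max)`.
#' @param start_hr_rec Length-2 `c(mean, sd)` of the start-of-recovery HR,
#'   bpm.
#' @param rdi Length-2 `c(mean, sd)` of the Ruffier-Dickson Index.
#' @param feature_cor Correlation between start-of-recovery HR and RDI.
#' @param dgp_model Which published equation generates VO2max (1, 2 or 3).
#' @param residual_sd Residual SD of generated VO2max, L/min (default: the
#'   chosen model's published RMSE).
#' @param seed Integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 81,
                          male_fraction = 63 / 81,
                          age_male = c(29, 8, 18, 67),
                          age_female = c(27, 9, 19, 46),
                          height_male = c(1.76, 0.06, 1.66, 1.88),
                          height_female = c(1.70, 0.05, 1.61, 1.76),
                          weight_male = c(74.5, 9.8, 58, 100),
                          weight_female = c(68.0, 10.7, 52.5, 86.95),
                          start_hr_rec = c(110, 15),
                          rdi = c(8, 3),
                          feature_cor = 0.6,
                          dgp_model = 3,
                          residual_sd = NULL,
                          seed = 1) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (is.null(residual_sd)) residual_sd <- builtin_model_rmse(dgp_model)
  cfg <- list(n = n, male_fraction = male_fraction,
              age_male = age_male, age_female = age_female,
              height_male = height_male, height_female = height_female,
              weight_male = weight_male, weight_female = weight_female,
              start_hr_rec = start_hr_rec, rdi = rdi,
              feature_cor = feature_cor, dgp_model = dgp_model,
              residual_sd = residual_sd, seed = seed)
  sds <- c(age_male[2], age_female[2], height_male[2], height_female[2],
           weight_male[2], weight_female[2], start_hr_rec[2], rdi[2])
  if (any(sds <= 0)) stop("all SDs must be positive", call. = FALSE)
  if (residual_sd < 0) stop("residual_sd must be non-negative", call. = FALSE)
  if (abs(feature_cor) >= 1) stop("feature_cor must be in (-1, 1)", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic validation cohort
#'
#' Draws demographics from per-sex truncated normals, features from a
#' correlated bivariate normal, and measured VO2max from the configured
#' published equation plus Gaussian residual noise. Fully reproducible
#' from the config's seed; the caller's RNG state is untouched.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `subject_id`, `sex` (1 male / 0
#'   female), `age` (years), `height` (m), `weight` (kg), `start_hr_rec`
#'   (bpm), `rdi`, `start_hr_rec_over_h2`, `start_hr_rec_over_age2`, and
#'   `vo2max_measured` (L/min).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  rng <- new_rng(config$seed)
  n <- config$n
  sex <- rng$rbinom(n, 1, config$male_fraction)
  draw_by_sex <- function(par_m, par_f) {
    out <- numeric(n)
    for (s in c(1, 0)) {
      par <- if (s == 1) par_m else par_f
      idx <- which(sex == s)
      if (length(idx)) out[idx] <- rtruncnorm(rng, length(idx), par[1], par[2],
                                              par[3], par[4])
    }
    out
  }
  age <- draw_by_sex(config$age_male, config$age_female)
  height <- draw_by_sex(config$height_male, config$height_female)
  weight <- draw_by_sex(config$weight_male, config$weight_female)
  z1 <- rng$rnorm(n)
  z2 <- config$feature_cor * z1 + sqrt(1 - config$feature_cor^2) * rng$rnorm(n)
  start_hr_rec <- config$start_hr_rec[1] + config$start_hr_rec[2] * z1
  rdi <- config$rdi[1] + config$rdi[2] * z2
  d <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sex, age = age, height = height, weight = weight,
    start_hr_rec = start_hr_rec, rdi = rdi,
    start_hr_rec_over_h2 = start_hr_rec / height^2,
    start_hr_rec_over_age2 = start_hr_rec / age^2
  )
  d$vo2max_measured <- predict(builtin_model(config$dgp_model), d) +
    rng$rnorm(n, 0, config$residual_sd)
  d
}

#' Synthetic heart-rate trace configuration
#'
#' Generating parameters for one squat-test recording: a resting plateau,
#' a saturating HR rise over the squat phase that reaches `squat_peak` at
#' the phase's end, and an exponential recovery decay d * exp(f x). White
#' HR jitter and isolated artifact beats are injectable.
#'
#' @param rest_hr Resting plateau HR, bpm.
#' @param squat_peak HR at the end of the squat phase, bpm (> rest_hr).
#' @param recovery_d Exponential-decay coefficient d, bpm (HR at recovery
#'   onset). Default `NULL` uses `squat_peak`, making the trace continuous
#'   at recovery onset; a lower value models an abrupt postural HR drop,
#'   at the cost of an interpolation kink at the boundary grid sample.
#' @param recovery_f Decay rate f, 1/s (negative). Ignored when
#'   `recovery_end_target` is set, in which case f is solved so the curve
#'   passes through the target at the end of recovery.
#' @param recovery_end_target Optional HR at the end of recovery, bpm.
#' @param squat_tau Time constant of the squat-phase rise, s (default 20).
#' @param hr_jitter_sd SD of white per-beat HR jitter, bpm (default 0).
#' @param spike_count Number of isolated artifact beats (default 0). They
#'   are placed within the rest plateau, pairwise at least 21 s apart: the
#'   short/long-variation despiking rule can only separate artifact from
#'   physiology on quasi-stationary segments.
#' @param spike_magnitude HR excursion of an artifact beat, bpm.
#' @param seed Integer seed.
#' @return List of class `trace_config`.
#' @export
trace_config <- function(rest_hr = 66, squat_peak = 128,
                         recovery_d = NULL, recovery_f = -0.004,
                         recovery_end_target = NULL, squat_tau = 20,
                         hr_jitter_sd = 0, spike_count = 0,
                         spike_magnitude = 60, seed = 1) {
  if (rest_hr >= squat_peak) stop("rest_hr must be below squat_peak", call. = FALSE)
  if (is.null(recovery_d)) recovery_d <- squat_peak
  if (is.null(recovery_end_target) && recovery_f >= 0) {
    stop("recovery_f must be negative", call. = FALSE)
  }
  if (hr_jitter_sd < 0 || spike_count < 0) stop("invalid jitter/spike config",
                                                call. = FALSE)
  structure(list(rest_hr = rest_hr, squat_peak = squat_peak,
                 recovery_d = recovery_d, recovery_f = recovery_f,
                 recovery_end_target = recovery_end_target,
                 squat_tau = squat_tau, hr_jitter_sd = hr_jitter_sd,
                 spike_count = spike_count, spike_magnitude = spike_magnitude,
                 seed = seed), class = "trace_config")
}

# continuous HR curve of a trace config over given phases
trace_hr_curve <- function(trace, phases) {
  sq_dur <- phases$squat_end_s - phases$squat_start_s
  rec_dur <- phases$recovery_end_s - phases$recovery_start_s
  f <- if (!is.null(trace$recovery_end_target)) {
    log(trace$recovery_end_target / trace$recovery_d) / rec_dur
  } else trace$recovery_f
  rise_scale <- 1 - exp(-sq_dur / trace$squat_tau)
  function(t) {
    ifelse(t < phases$squat_start_s, trace$rest_hr,
      ifelse(t <= phases$squat_end_s,
        trace$rest_hr + (trace$squat_peak - trace$rest_hr) *
          (1 - exp(-(t - phases$squat_start_s) / trace$squat_tau)) / rise_scale,
        ifelse(t < phases$recovery_start_s, trace$squat_peak,
          trace$recovery_d * exp(f * (t - phases$recovery_start_s)))))
  }
}

#' Generate a synthetic inter-beat-interval recording
#'
#' Builds the continuous HR curve of the configured test, inverts it beat
#' by beat into inter-beat intervals (each interval is 60000 over the
#' instantaneous HR at the accumulating beat time, rounded to 1 ms), adds
#' optional per-beat HR jitter, and injects the configured number of
#' isolated artifact beats at seeded positions within the rest plateau.
#'
#' @param trace A [trace_config()].
#' @param phases A [phase_markers()].
#' @return List with `ibi` (an [ibi_series()]), `phases`, and `truth` - the
#'   generating parameters (`rest_hr`, `squat_peak`, `recovery_d`,
#'   `recovery_f`, `recovery_hr_end`, `rdi` implied by the noiseless curve,
#'   and `spike_times_s`).
#' @export
generate_trace <- function(trace, phases = phase_markers()) {
  stopifnot(inherits(trace, "trace_config"), inherits(phases, "phase_markers"))
  rng <- new_rng(trace$seed)
  curve <- trace_hr_curve(trace, phases)
  duration <- phases$recovery_end_s
  hl <- 10  # half of the default despike long window
  spike_times <- numeric(0)
  if (trace$spike_count > 0) {
    lo <- phases$rest_start_s + hl + 2
    hi <- phases$rest_end_s - hl - 2
    if (hi - lo < (trace$spike_count - 1) * 21) {
      stop("rest phase too short for the requested isolated spikes", call. = FALSE)
    }
    # greedy rejection from shuffled candidate seconds, >= 21 s apart
    cand <- lo:hi
    cand <- cand[rng$sample(length(cand))]
    for (s in cand) {
      if (all(abs(s - spike_times) >= 21)) spike_times <- c(spike_times, s)
      if (length(spike_times) == trace$spike_count) break
    }
    spike_times <- sort(spike_times)
  }
  intervals <- numeric(0)
  t <- 0
  pending <- spike_times
  while (t < duration) {
    h <- curve(t)
    if (trace$hr_jitter_sd > 0) h <- h + rng$rnorm(1, 0, trace$hr_jitter_sd)
    iv <- 60000 / h
    if (length(pending) && pending[1] >= t && pending[1] < t + iv / 1000) {
      iv <- 60000 / (h + trace$spike_magnitude)
      pending <- pending[-1]
    }
    iv <- round(iv)
    intervals <- c(intervals, iv)
    t <- t + iv / 1000
  }
  rec_dur <- phases$recovery_end_s - phases$recovery_start_s
  f <- if (!is.null(trace$recovery_end_target)) {
    log(trace$recovery_end_target / trace$recovery_d) / rec_dur
  } else trace$recovery_f
  xs <- 60:74
  truth <- list(
    rest_hr = trace$rest_hr,
    squat_peak = trace$squat_peak,
    recovery_d = trace$recovery_d,
    recovery_f = f,
    recovery_hr_end = trace$recovery_d * exp(f * rec_dur),
    rdi = ((trace$recovery_d - 70) +
             2 * (mean(trace$recovery_d * exp(f * xs)) - trace$rest_hr)) / 10,
    spike_times_s = spike_times
  )
  list(ibi = ibi_series(intervals), phases = phases, truth = truth)
}

#' Generate paired test-retest feature tables
#'
#' Second-occasion scores are the first occasion's plus Gaussian
#' within-subject noise, so the expected ICC of each feature is
#' analytically var_between / (var_between + sd^2), enabling calibration
#' tests of the reliability statistics.
#'
#' @param features Data frame of first-occasion scores.
#' @param within_subject_sd Named numeric vector of within-subject SDs;
#'   names select the feature columns to perturb.
#' @param seed Integer seed.
#' @return List with data frames `test1` and `test2`.
#' @export
generate_test_retest <- function(features, within_subject_sd, seed = 1) {
  if (any(within_subject_sd < 0)) stop("within_subject_sd must be >= 0", call. = FALSE)
  if (is.null(names(within_subject_sd)) || !all(names(within_subject_sd) %in% names(features))) {
    stop("within_subject_sd must be named after feature columns", call. = FALSE)
  }
  rng <- new_rng(seed)
  test2 <- features
  for (nm in names(within_subject_sd)) {
    test2[[nm]] <- features[[nm]] +
      rng$rnorm(nrow(features), 0, within_subject_sd[[nm]])
  }
  list(test1 = features, test2 = test2)
}
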