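# HR samples of a half-open absolute window [from_s, to_s) on the 1 Hz grid
window_hr <- function(hr, from_s, to_s, what = "window") {
  sel <- hr$time_s >= from_s & hr$time_s < to_s
  if (!any(sel)) stop(sprintf("%s window [%g, %g) is empty", what, from_s, to_s),
                      call. = FALSE)
  hr$hr_bpm[sel]
}

need_phases <- function(hr) {
  if (is.null(hr$phases)) stop("hr_series carries no phase markers", call. = FALSE)
  hr$phases
}

#' Resting heart-rate mode
#'
#' The mode of the HR over the supine rest phase, excluding its first and
#' last minute. HR is rounded to the nearest integer bpm before counting
#' (the mode of a real-valued signal is otherwise ill-defined); ties are
#' broken towards the smallest value so the statistic is reproducible.
#'
#' @param hr An [hr_series()] with phase markers.
#' @return Mode resting HR, bpm (integer-valued).
#' @export
rest_hr_mode <- function(hr) {
  p <- need_phases(hr)
  from <- p$rest_start_s + 60
  to <- p$rest_end_s - 60
  if (to - from < 60) stop("rest phase too short after excluding first/last minute",
                           call. = FALSE)
  v <- round(window_hr(hr, from, to, "rest"))
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])  # which.max takes the first (smallest) tie
}

#' Peak heart rate during the squat phase
#'
#' @param hr An [hr_series()] with phase markers.
#' @return Maximum HR over the squat phase, bpm.
#' @export
squat_peak <- function(hr) {
  p <- need_phases(hr)
  max(window_hr(hr, p$squat_start_s, p$squat_end_s + 1, "squat"))
}

#' Linear fit of the heart-rate recovery phase
#'
#' Ordinary least squares of HR on time since recovery onset (x = 0 at the
#' first recovery grid sample). The intercept is the fitted HR at the start
#' of recovery ("start HR_rec"), the single most predictive HR feature of
#' the test.
#'
#' @param hr An [hr_series()] with phase markers; recovery phase >= 30 s.
#' @return List with `slope_m` (bpm/s) and `intercept_b` (bpm), class
#'   `recovery_linear_fit`.
#' @export
fit_recovery_linear <- function(hr) {
  p <- need_phases(hr)
  sel <- hr$time_s >= p$recovery_start_s & hr$time_s <= p$recovery_end_s
  if (sum(sel) < 30) stop("recovery phase shorter than 30 s", call. = FALSE)
  x <- hr$time_s[sel] - p$recovery_start_s
  y <- hr$hr_bpm[sel]
  co <- stats::coef(stats::lm.fit(cbind(1, x), y))
  structure(list(slope_m = unname(co[2]), intercept_b = unname(co[1])),
            class = "recovery_linear_fit")
}

#' Exponential fit of the heart-rate recovery decay
#'
#' Nonlinear least squares of the two-parameter model y = d * exp(f * x),
#' x in seconds since recovery onset, with no asymptote term. Start values
#' come from the log-linear fit; the Levenberg-Marquardt solver is capped
#' at 200 iterations with relative tolerance 1e-8. A constant recovery
#' trace is the degenerate case d = mean HR, f = 0 and is returned without
#' invoking the solver. On non-convergence the error carries the log-linear
#' fallback estimates in its `fallback` field.
#'
#' @param hr An [hr_series()] with phase markers; recovery phase >= 30 s,
#'   all HR positive.
#' @return List with `coef_d` (bpm) and `rate_f` (1/s), class
#'   `recovery_exp_fit`.
#' @export
fit_recovery_exponential <- function(hr) {
  p <- need_phases(hr)
  sel <- hr$time_s >= p$recovery_start_s & hr$time_s <= p$recovery_end_s
  if (sum(sel) < 30) stop("recovery phase shorter than 30 s", call. = FALSE)
  x <- hr$time_s[sel] - p$recovery_start_s
  y <- hr$hr_bpm[sel]
  if (stats::sd(y) == 0) {
    return(structure(list(coef_d = mean(y), rate_f = 0), class = "recovery_exp_fit"))
  }
  ll <- stats::coef(stats::lm.fit(cbind(1, x), log(y)))
  start <- list(d = exp(unname(ll[1])), f = unname(ll[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ d * exp(f * x), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-8)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    err <- simpleError("exponential recovery fit did not converge")
    err$fallback <- list(coef_d = start$d, rate_f = start$f)
    stop(err)
  }
  co <- stats::coef(fit)
  structure(list(coef_d = unname(co["d"]), rate_f = unname(co["f"])),
            class = "recovery_exp_fit")
}

#' Final heart rate of the recovery phase
#'
#' @param hr An [hr_series()] with phase markers.
#' @return HR at the last grid second of the recovery phase, bpm.
#' @export
recovery_end <- function(hr) {
  p <- need_phases(hr)
  sel <- hr$time_s >= p$recovery_start_s & hr$time_s <= p$recovery_end_s
  if (!any(sel)) stop("recovery window is empty", call. = FALSE)
  hr$hr_bpm[max(which(sel))]
}

#' Ruffier-Dickson Index from a phase-annotated heart-rate series
#'
#' The classic squat-test index, RDI = ((P1 - 70) + 2 (P2 - P0)) / 10,
#' built from three 15-second HR windows:
#' \itemize{
#'   \item P0 - mean resting HR over rest seconds [225, 240) (i.e. from
#'     3 min 45 s to 4 min into the 5-minute rest);
#'   \item P1 - maximum HR over the first 15 s of recovery;
#'   \item P2 - mean HR over recovery seconds [60, 75) (the 15 s after the
#'     first minute of recovery).
#' }
#' All windows are half-open on the 1 Hz grid.
#'
#' @param hr An [hr_series()] with phase markers; rest phase >= 240 s and
#'   recovery >= 75 s.
#' @return List with elements `p0`, `p1`, `p2` (bpm) and `rdi`.
#' @export
compute_rdi <- function(hr) {
  p <- need_phases(hr)
  if (p$rest_end_s - p$rest_start_s < 240) stop("P0 window incomplete: rest phase < 240 s",
                                                call. = FALSE)
  if (p$recovery_end_s - p$recovery_start_s < 75) stop("P2 window incomplete: recovery < 75 s",
                                                       call. = FALSE)
  p0 <- mean(window_hr(hr, p$rest_start_s + 225, p$rest_start_s + 240, "P0"))
  p1 <- max(window_hr(hr, p$recovery_start_s, p$recovery_start_s + 15, "P1"))
  p2 <- mean(window_hr(hr, p$recovery_start_s + 60, p$recovery_start_s + 75, "P2"))
  list(p0 = p0, p1 = p1, p2 = p2, rdi = ((p1 - 70) + 2 * (p2 - p0)) / 10)
}

#' Anthropometry-normalised recovery features
#'
#' The start-of-recovery HR (the linear-fit intercept) divided by height
#' squared and by age squared. Height scaling removes the larger exercise
#' dose taller individuals incur from displacing their centre of mass over
#' a longer path; age scaling absorbs the known negative age-fitness
#' relation.
#'
#' @param start_hr_rec Start-of-recovery HR, bpm.
#' @param height_m Height in meters (> 0).
#' @param age_y Age in years (> 0).
#' @return List with `start_hr_rec_over_h2` (bpm/m^2) and
#'   `start_hr_rec_over_age2` (bpm/y^2).
#' @export
normalize_features <- function(start_hr_rec, height_m, age_y) {
  if (!is.finite(height_m) || height_m <= 0) stop("height must be positive", call. = FALSE)
  if (!is.finite(age_y) || age_y <= 0) stop("age must be positive", call. = FALSE)
  list(start_hr_rec_over_h2 = start_hr_rec / height_m^2,
       start_hr_rec_over_age2 = start_hr_rec / age_y^2)
}

#' Extract all squat-test heart-rate features
#'
#' Runs every feature extractor on one cleaned, phase-annotated series and
#' returns a single flat record. When subject demographics are supplied the
#' height- and age-normalised recovery features are included too.
#' Physiologically odd traces (squat peak below the rest mode, or P2 above
#' P1) raise warnings, not errors.
#'
#' @param hr An [hr_series()] with phase markers.
#' @param subject Optional single-row data frame (or list) with `age`
#'   (years) and `height` (m); enables the normalised features.
#' @return One-row data frame with columns `rest_hr_mode`, `squat_hr_peak`,
#'   `slope_m`, `start_hr_rec`, `coef_d`, `rate_f`, `recovery_hr_end`,
#'   `p0`, `p1`, `p2`, `rdi` and, with a subject, `start_hr_rec_over_h2`
#'   and `start_hr_rec_over_age2`.
#' @export
extract_all <- function(hr, subject = NULL) {
  grab <- function(name, f) {
    tryCatch(f(hr), error = function(e) {
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  mode_ <- grab("rest_hr_mode", rest_hr_mode)
  peak <- grab("squat_peak", squat_peak)
  lin <- grab("recovery_linear", fit_recovery_linear)
  ex <- grab("recovery_exponential", fit_recovery_exponential)
  rend <- grab("recovery_end", recovery_end)
  rdi <- grab("rdi", compute_rdi)
  if (peak < mode_) warning("squat peak below resting mode: check phase markers",
                            call. = FALSE)
  if (rdi$p2 > rdi$p1) warning("P2 exceeds P1: recovery does not decay", call. = FALSE)
  out <- data.frame(
    rest_hr_mode = mode_, squat_hr_peak = peak,
    slope_m = lin$slope_m, start_hr_rec = lin$intercept_b,
    coef_d = ex$coef_d, rate_f = ex$rate_f,
    recovery_hr_end = rend,
    p0 = rdi$p0, p1 = rdi$p1, p2 = rdi$p2, rdi = rdi$rdi
  )
  if (!is.null(subject)) {
    nf <- normalize_features(lin$intercept_b, subject$height, subject$age)
    out$start_hr_rec_over_h2 <- nf$start_hr_rec_over_h2
    out$start_hr_rec_over_age2 <- nf$start_hr_rec_over_age2
  }
  out
}
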