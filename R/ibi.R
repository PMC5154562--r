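#' Beat-to-beat inter-beat-interval series
#'
#' Container for raw RR / inter-beat intervals as recorded by a chest-strap
#' heart-rate monitor. Intervals are in milliseconds; beat times are their
#' cumulative sum, offset by `t0_s` seconds.
#'
#' @param intervals_ms Numeric vector of positive inter-beat intervals (ms).
#'   Each interval must lie in (0, 5000) ms; values outside this
#'   physiological range are rejected.
#' @param t0_s Time offset of the first beat, seconds (default 0).
#' @return An object of class `ibi_series` with elements `intervals_ms`,
#'   `t0_s` and `beat_time_s` (cumulative end-of-interval times, seconds).
#' @examples
#' ibi <- ibi_series(c(800, 800, 750))
#' ibi$beat_time_s
#' @export
ibi_series <- function(intervals_ms, t0_s = 0) {
  intervals_ms <- as.numeric(intervals_ms)
  if (length(intervals_ms) == 0L) stop("no beats", call. = FALSE)
  if (anyNA(intervals_ms)) stop("intervals contain missing values", call. = FALSE)
  bad <- which(intervals_ms <= 0 | intervals_ms >= 5000)
  if (length(bad)) {
    stop(sprintf("interval out of physiological range (0, 5000) ms at position %d: %g",
                 bad[1], intervals_ms[bad[1]]), call. = FALSE)
  }
  structure(list(
    intervals_ms = intervals_ms,
    t0_s = as.numeric(t0_s),
    beat_time_s = t0_s + cumsum(intervals_ms) / 1000
  ), class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d beats, %.1f s, mean interval %.0f ms\n",
              length(x$intervals_ms),
              x$beat_time_s[length(x$beat_time_s)] - x$t0_s,
              mean(x$intervals_ms)))
  invisible(x)
}

#' Convert inter-beat intervals to instantaneous heart-rate samples
#'
#' Each interval yields one HR sample, 60000 / interval (beats per minute),
#' located at the interval's end beat time.
#'
#' @param ibi An [ibi_series()].
#' @return Data frame with columns `time_s` and `hr_bpm`, one row per beat.
#' @examples
#' ibi_to_hr(ibi_series(c(1000, 600)))  # 60 bpm, then 100 bpm
#' @export
ibi_to_hr <- function(ibi) {
  stopifnot(inherits(ibi, "ibi_series"))
  data.frame(time_s = ibi$beat_time_s, hr_bpm = 60000 / ibi$intervals_ms)
}

#' Phase markers for one squat test
#'
#' Locates the rest, squat and recovery phases on the 1 Hz grid. The nominal
#' protocol is 300 s supine rest, 30 squats in 45 s, and 180 s supine
#' recovery; a warning (not an error) is raised when any phase deviates from
#' its nominal duration by more than 10%.
#'
#' @param rest_start_s,rest_end_s,squat_start_s,squat_end_s,recovery_start_s,recovery_end_s
#'   Phase boundaries in seconds from the start of the recording.
#' @return An object of class `phase_markers`.
#' @export
phase_markers <- function(rest_start_s = 0, rest_end_s = 300,
                          squat_start_s = 300, squat_end_s = 345,
                          recovery_start_s = 345, recovery_end_s = 525) {
  p <- list(rest_start_s = rest_start_s, rest_end_s = rest_end_s,
            squat_start_s = squat_start_s, squat_end_s = squat_end_s,
            recovery_start_s = recovery_start_s, recovery_end_s = recovery_end_s)
  v <- unlist(p)
  if (anyNA(v)) stop("phase markers contain missing values", call. = FALSE)
  ok <- rest_start_s <= rest_end_s && rest_end_s <= squat_start_s &&
    squat_start_s < squat_end_s && squat_end_s <= recovery_start_s &&
    recovery_start_s < recovery_end_s
  if (!ok) stop("phase markers must be ordered rest <= squat < recovery", call. = FALSE)
  nominal <- c(rest = 300, squat = 45, recovery = 180)
  durs <- c(rest = rest_end_s - rest_start_s,
            squat = squat_end_s - squat_start_s,
            recovery = recovery_end_s - recovery_start_s)
  off <- abs(durs - nominal) / nominal > 0.10
  if (any(off)) {
    warning(sprintf("phase duration(s) deviate >10%% from nominal: %s",
                    paste(names(durs)[off], collapse = ", ")), call. = FALSE)
  }
  structure(p, class = "phase_markers")
}

#' Uniform 1 Hz heart-rate series
#'
#' The cleaned working signal of the pipeline: heart rate sampled on an
#' integer-second grid, with phase annotations.
#'
#' @param time_s Integer-second grid (must be consecutive, step 1 s).
#' @param hr_bpm Heart rate per grid sample, beats per minute. All values
#'   must lie in the physiological band (20, 250).
#' @param phases A [phase_markers()] object, or `NULL`.
#' @return Object of class `hr_series`.
#' @export
hr_series <- function(time_s, hr_bpm, phases = NULL) {
  time_s <- as.numeric(time_s)
  hr_bpm <- as.numeric(hr_bpm)
  if (length(time_s) != length(hr_bpm)) stop("time and HR lengths differ", call. = FALSE)
  if (length(time_s) >= 2 && any(diff(time_s) != 1)) {
    stop("hr_series grid must be consecutive integer seconds", call. = FALSE)
  }
  if (any(!is.finite(hr_bpm)) || any(hr_bpm <= 20 | hr_bpm >= 250)) {
    stop("hr_bpm outside physiological band (20, 250)", call. = FALSE)
  }
  if (!is.null(phases)) stopifnot(inherits(phases, "phase_markers"))
  structure(list(time_s = time_s, hr_bpm = hr_bpm, phases = phases),
            class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %d s at 1 Hz, HR %.0f-%.0f bpm%s\n",
              length(x$time_s), min(x$hr_bpm), max(x$hr_bpm),
              if (is.null(x$phases)) "" else ", phases set"))
  invisible(x)
}

#' @export
as.data.frame.hr_series <- function(x, ...) {
  data.frame(time_s = x$time_s, hr_bpm = x$hr_bpm,
             phase = phase_label(x$time_s, x$phases))
}

# vector of phase labels ("rest"/"squat"/"recovery"/"") for grid seconds
phase_label <- function(time_s, phases) {
  if (is.null(phases)) return(rep("", length(time_s)))
  lab <- rep("", length(time_s))
  lab[time_s >= phases$rest_start_s & time_s < phases$rest_end_s] <- "rest"
  lab[time_s >= phases$squat_start_s & time_s < phases$squat_end_s] <- "squat"
  lab[time_s >= phases$recovery_start_s & time_s <= phases$recovery_end_s] <- "recovery"
  lab
}

#' Resample irregular heart-rate samples onto a 1 Hz grid
#'
#' Linear interpolation of beatwise HR onto integer seconds 0..`duration_s`.
#' Grid seconds before the first beat or after the last one are held at the
#' nearest sample's value.
#'
#' @param samples Data frame with `time_s` and `hr_bpm` (e.g. from
#'   [ibi_to_hr()]).
#' @param duration_s Last grid second (the grid is `0:duration_s`).
#' @param phases Optional [phase_markers()] attached to the result.
#' @return An [hr_series()].
#' @export
resample_1hz <- function(samples, duration_s, phases = NULL) {
  if (nrow(samples) < 2) stop("need at least 2 HR samples to resample", call. = FALSE)
  grid <- 0:floor(duration_s)
  hr <- stats::approx(samples$time_s, samples$hr_bpm, xout = grid, rule = 2,
                      ties = "ordered")$y
  hr_series(grid, hr, phases)
}
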