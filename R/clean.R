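#' Remove artifact spikes from a 1 Hz heart-rate series
#'
#' For every interior sample the short-term variation (sample SD over a
#' centred `short_win`-sample window) is compared with the long-term
#' variation (sample SD over the centred `long_win`-sample window with the
#' `short_win` central samples excluded). A sample is replaced by the mean
#' of its previous and following samples when its short-term SD is at least
#' `ratio` times the long-term SD (or when the long-term SD is zero while
#' the short-term SD is not) and the sample itself carries the largest
#' absolute deviation from the long-window median within its short window.
#' The deviation condition pins the replacement to the artifact beat rather
#' than to its neighbours, whose short windows also see the spike.
#'
#' The first and last `floor(long_win / 2)` samples are never evaluated:
#' the phases of interest are interior to the recording. Consecutive flagged
#' samples are replaced from the nearest non-flagged neighbours, and a run
#' of more than `short_win` flagged samples triggers a warning that the
#' cleaning may be altering signal morphology.
#'
#' @param hr An [hr_series()].
#' @param short_win Short window length in samples (odd, default 3).
#' @param long_win Long window length in samples (odd, default 21).
#' @param ratio Firing threshold on short SD / long SD (default 10).
#' @return The input `hr_series` with spikes replaced, carrying attribute
#'   `n_replaced` (count of replaced samples) and `replaced_idx` (their
#'   1-based indices).
#' @export
despike <- function(hr, short_win = 3, long_win = 21, ratio = 10) {
  stopifnot(inherits(hr, "hr_series"))
  if (short_win %% 2 != 1 || long_win %% 2 != 1 || long_win <= short_win) {
    stop("windows must be odd with long_win > short_win", call. = FALSE)
  }
  x <- hr$hr_bpm
  n <- length(x)
  if (n < long_win) stop("series shorter than the long window", call. = FALSE)
  hs <- (short_win - 1) / 2
  hl <- (long_win - 1) / 2
  flagged <- logical(n)
  for (i in (hl + 1):(n - hl)) {
    short_idx <- (i - hs):(i + hs)
    long_idx <- setdiff((i - hl):(i + hl), short_idx)
    sd_short <- stats::sd(x[short_idx])
    sd_long <- stats::sd(x[long_idx])
    fires <- if (sd_long == 0) sd_short > 0 else sd_short >= ratio * sd_long
    if (!fires) next
    dev <- abs(x[short_idx] - stats::median(x[long_idx]))
    if (dev[hs + 1] >= max(dev)) flagged[i] <- TRUE
  }
  runs <- rle(flagged)
  if (any(runs$lengths[runs$values] > short_win)) {
    warning("run of more than short_win flagged samples: cleaning may alter signal morphology",
            call. = FALSE)
  }
  y <- x
  for (i in which(flagged)) {
    lo <- i - 1
    while (lo >= 1 && flagged[lo]) lo <- lo - 1
    hi <- i + 1
    while (hi <= n && flagged[hi]) hi <- hi + 1
    nb <- x[c(lo, hi)[c(lo >= 1, hi <= n)]]
    y[i] <- mean(nb)
  }
  out <- hr_series(hr$time_s, y, hr$phases)
  attr(out, "n_replaced") <- sum(flagged)
  attr(out, "replaced_idx") <- which(flagged)
  out
}

#' Low-pass filter a heart-rate series with a 5-sample moving average
#'
#' Centred 5-sample mean; at the series edges the window shrinks
#' symmetrically (1, 3, then 5 samples) so no samples are dropped and no
#' values are invented. Phase markers are preserved.
#'
#' @param hr An [hr_series()] of length >= 5.
#' @return The smoothed `hr_series`.
#' @export
smooth_ma5 <- function(hr) {
  stopifnot(inherits(hr, "hr_series"))
  x <- hr$hr_bpm
  n <- length(x)
  if (n < 5) stop("series shorter than 5 samples", call. = FALSE)
  y <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(2, i - 1, n - i)
    y[i] <- mean(x[(i - h):(i + h)])
  }
  hr_series(hr$time_s, y, hr$phases)
}

#' Full signal-cleaning step: despike then smooth
#'
#' Convenience wrapper applying [despike()] followed (optionally) by
#' [smooth_ma5()]. The replaced-sample count of the despiking pass is
#' carried through on the result.
#'
#' @param hr An [hr_series()].
#' @param smooth Apply the 5-sample moving average after despiking
#'   (default `TRUE`).
#' @inheritParams despike
#' @return Cleaned `hr_series` with attributes `n_replaced`, `replaced_idx`.
#' @export
clean_hr <- function(hr, short_win = 3, long_win = 21, ratio = 10, smooth = TRUE) {
  d <- despike(hr, short_win = short_win, long_win = long_win, ratio = ratio)
  if (!smooth) return(d)
  out <- smooth_ma5(d)
  attr(out, "n_replaced") <- attr(d, "n_replaced")
  attr(out, "replaced_idx") <- attr(d, "replaced_idx")
  out
}
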