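# shared fixture builders; everything is generated in code

# hr_series on the grid 0..(length-1)
make_hr <- function(values, phases = NULL) {
  hr_series(seq_along(values) - 1, values, phases)
}

nominal_phases <- function() phase_markers()

# full-protocol series (526 samples, grid 0..525) with chosen window values:
# rest plateau `base`, P0 window [225, 240), first 15 s of recovery, and
# recovery seconds [60, 75) settable independently
protocol_hr <- function(base = 80, p0 = base, p1 = base, p2 = base) {
  v <- rep(base, 526)
  v[(225:239) + 1] <- p0
  v[(345:359) + 1] <- p1
  v[(405:419) + 1] <- p2
  make_hr(v, nominal_phases())
}

# synthetic 3-class norms table (NOT the copyrighted reference norms)
fixture_norms <- function() {
  norms_table(data.frame(
    sex = c(1, 1, 0, 0),
    age_low = c(18, 30, 18, 30),
    age_high = c(30, 70, 30, 70),
    poor_below_ml_kg_min = c(38, 35, 30, 28),
    good_at_or_above_ml_kg_min = c(45, 42, 38, 35)
  ))
}

# independent naive LOOCV oracle via the formula interface of lm()
naive_loocv <- function(terms, data) {
  n <- nrow(data)
  fml <- if (length(terms)) {
    stats::as.formula(paste("vo2max_measured ~", paste(terms, collapse = " + ")))
  } else stats::as.formula("vo2max_measured ~ 1")
  err <- numeric(n)
  for (i in seq_len(n)) {
    fit <- stats::lm(fml, data = data[-i, , drop = FALSE])
    err[i] <- data$vo2max_measured[i] -
      stats::predict(fit, newdata = data[i, , drop = FALSE])
  }
  sqrt(mean(err^2))
}

# exhaustive best-subset oracle by adjusted r-squared
best_subset_adj_r2 <- function(candidates, data) {
  best <- character(0)
  best_adj <- fit_ols(character(0), data)$report$adj_r2
  idx <- seq_along(candidates)
  for (k in idx) {
    for (comb in utils::combn(idx, k, simplify = FALSE)) {
      terms <- candidates[comb]
      X <- cbind(1, as.matrix(data[terms]))
      if (qr(X)$rank < ncol(X)) next
      adj <- fit_ols(terms, data)$report$adj_r2
      if (adj > best_adj + 1e-12) {
        best <- terms
        best_adj <- adj
      }
    }
  }
  best
}

# mean of a normal truncated to [lo, hi] (closed form)
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}
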