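# canonical term vocabulary for prediction models
MODEL_TERMS <- c("rdi", "sex", "age", "height", "start_hr_rec_over_age2",
                 "start_hr_rec_over_h2")

#' Linear VO2max prediction model
#'
#' A flat set of named coefficients: a mandatory `constant` plus any of
#' `rdi`, `sex`, `age`, `height`, `start_hr_rec_over_age2`,
#' `start_hr_rec_over_h2`. Units: predictions are absolute VO2max in
#' L/min; `sex` is coded male = 1, female = 0; `height` is in meters.
#'
#' @param coefficients Named numeric vector including `constant`.
#' @return Object of class `vo2_model`.
#' @export
vo2_model <- function(coefficients) {
  coefficients <- unlist(coefficients)
  if (!("constant" %in% names(coefficients))) {
    stop("model must include a constant term", call. = FALSE)
  }
  if (anyDuplicated(names(coefficients))) stop("duplicate model terms", call. = FALSE)
  unknown <- setdiff(names(coefficients), c("constant", MODEL_TERMS))
  if (length(unknown)) stop(sprintf("unknown model term(s): %s",
                                    paste(unknown, collapse = ", ")), call. = FALSE)
  structure(list(coefficients = coefficients), class = "vo2_model")
}

#' @export
print.vo2_model <- function(x, ...) {
  cat("<vo2_model> VO2max (L/min) =\n")
  co <- x$coefficients
  cat(sprintf("  %+.4g", co[["constant"]]))
  for (nm in setdiff(names(co), "constant")) cat(sprintf(" %+.4g*%s", co[[nm]], nm))
  cat("\n")
  invisible(x)
}

#' The three published squat-test prediction equations
#'
#' Returns the fixed coefficient sets of the published multiple-regression
#' models for absolute VO2max (L/min):
#' \itemize{
#'   \item Model 1: RDI only.
#'   \item Model 2: sex, age (years), height (m) and RDI.
#'   \item Model 3: sex plus the start-of-recovery HR normalised by age
#'     squared and by height squared.
#' }
#' Sex is coded male = 1, female = 0.
#'
#' @param which Model number, 1, 2 or 3.
#' @return A [vo2_model()].
#' @examples
#' predict(builtin_model(1), data.frame(rdi = 0))  # 3.867 L/min
#' @export
builtin_model <- function(which) {
  if (!(length(which) == 1 && which %in% 1:3)) {
    stop("which must be 1, 2 or 3", call. = FALSE)
  }
  co <- switch(as.character(which),
    "1" = c(constant = 3.867, rdi = -0.110),
    "2" = c(constant = -3.788, sex = 0.560, age = -0.0309, height = 4.533,
            rdi = -0.0864),
    "3" = c(constant = 4.121, sex = 0.787, start_hr_rec_over_age2 = 4.235,
            start_hr_rec_over_h2 = -0.0673)
  )
  vo2_model(co)
}

#' In-sample RMSE of a builtin model as published
#'
#' The residual error scale reported alongside each published equation,
#' L/min. Used as the default residual SD of the synthetic-cohort
#' generator.
#'
#' @param which Model number, 1, 2 or 3.
#' @return RMSE in L/min.
#' @export
builtin_model_rmse <- function(which) {
  if (!(length(which) == 1 && which %in% 1:3)) {
    stop("which must be 1, 2 or 3", call. = FALSE)
  }
  c(0.707, 0.523, 0.502)[which]
}

#' Predict absolute VO2max from a fitted or builtin model
#'
#' Evaluates constant + sum(coef * term) on each row of `newdata`. Every
#' non-constant model term must be present as a column; a missing column is
#' an error naming the term.
#'
#' @param object A [vo2_model()].
#' @param newdata Data frame with one column per model term (e.g. `rdi`,
#'   `sex`, `age`, `height`, `start_hr_rec_over_age2`,
#'   `start_hr_rec_over_h2`).
#' @param ... Unused.
#' @return Numeric vector of predicted VO2max, L/min.
#' @export
predict.vo2_model <- function(object, newdata, ...) {
  co <- object$coefficients
  terms <- setdiff(names(co), "constant")
  missing <- setdiff(terms, names(newdata))
  if (length(missing)) stop(sprintf("missing model term value(s): %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  out <- rep(co[["constant"]], nrow(as.data.frame(newdata)))
  for (nm in terms) {
    v <- newdata[[nm]]
    if (anyNA(v)) stop(sprintf("missing model term value(s): %s", nm), call. = FALSE)
    out <- out + co[[nm]] * v
  }
  unname(out)
}

# design matrix (with intercept) for a term set; errors on missing columns
model_matrix_terms <- function(terms, data) {
  missing <- setdiff(terms, names(data))
  if (length(missing)) stop(sprintf("missing model term value(s): %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  X <- cbind(constant = rep(1, nrow(data)))
  for (nm in terms) X <- cbind(X, data[[nm]])
  colnames(X) <- c("constant", terms)
  X
}

#' Fit an ordinary-least-squares VO2max model
#'
#' Regresses measured VO2max on the given feature terms and reports
#' in-sample accuracy: Pearson r between fitted and measured values,
#' adjusted r-squared, and RMSE (root mean squared residual, L/min).
#'
#' @param terms Character vector of term names (columns of `data`).
#' @param data Cohort data frame with a `vo2max_measured` column (L/min)
#'   and the term columns; no missing values.
#' @return List with `model` (a [vo2_model()]) and `report` (list with
#'   `r`, `adj_r2`, `rmse`, `n`).
#' @export
fit_ols <- function(terms, data) {
  y <- data$vo2max_measured
  if (is.null(y)) stop("data lacks vo2max_measured", call. = FALSE)
  if (anyNA(y)) stop("missing vo2max_measured values", call. = FALSE)
  X <- model_matrix_terms(terms, data)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("not enough rows to fit the requested terms", call. = FALSE)
  if (qr(X)$rank < p) stop("rank-deficient design", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  co <- stats::coef(fit)
  fitted <- X %*% co
  res <- y - fitted
  rmse <- sqrt(mean(res^2))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  r <- if (stats::sd(fitted) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(as.vector(fitted), y)
  list(model = vo2_model(co),
       report = list(r = r, adj_r2 = adj, rmse = rmse, n = n))
}

#' Standard errors of an OLS fit's coefficients
#'
#' Classical standard errors (sigma^2 (X'X)^-1 diagonal), matching the
#' coefficient order of [fit_ols()].
#'
#' @inheritParams fit_ols
#' @return Named numeric vector of standard errors.
#' @export
fit_ols_se <- function(terms, data) {
  y <- data$vo2max_measured
  X <- model_matrix_terms(terms, data)
  n <- nrow(X)
  p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  sigma2 <- sum(fit$residuals^2) / (n - p)
  se <- sqrt(diag(chol2inv(qr.R(fit$qr))) * sigma2)
  names(se) <- colnames(X)
  se
}

#' Greedy forward stepwise term selection
#'
#' At each step fits every remaining candidate on top of the current term
#' set and adds the one with the smallest partial-F p-value, provided it is
#' below `p_enter`; stops when no candidate qualifies. With a single added
#' coefficient the partial F test equals the squared-t test on that
#' coefficient. Ties are broken by candidate order, so selection is
#' deterministic. A candidate that makes the design rank-deficient
#' (e.g. a duplicate of a selected term) is skipped.
#'
#' @param candidates Character vector of candidate term names.
#' @param data Cohort data frame with `vo2max_measured` and all candidates.
#' @param p_enter Entry threshold on the partial-F p-value (default 0.05).
#' @return List with `terms` (selected, in entry order) and `model`
#'   (the [vo2_model()] fitted on them; constant-only if none entered).
#' @export
fit_stepwise_forward <- function(candidates, data, p_enter = 0.05) {
  if (length(candidates) == 0) stop("need at least one candidate", call. = FALSE)
  y <- data$vo2max_measured
  selected <- character(0)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    best <- NULL
    best_p <- Inf
    rss0 <- {
      X0 <- model_matrix_terms(selected, data)
      sum(stats::lm.fit(X0, y)$residuals^2)
    }
    df0 <- nrow(data) - (length(selected) + 1)
    for (cand in remaining) {
      X1 <- model_matrix_terms(c(selected, cand), data)
      if (qr(X1)$rank < ncol(X1)) next
      rss1 <- sum(stats::lm.fit(X1, y)$residuals^2)
      df1 <- nrow(data) - ncol(X1)
      if (df1 <= 0 || rss1 <= 0) {
        pval <- if (rss1 < rss0) 0 else 1
      } else {
        Fstat <- (rss0 - rss1) / (rss1 / df1)
        pval <- stats::pf(Fstat, 1, df1, lower.tail = FALSE)
      }
      if (pval < best_p) {  # strict <: ties keep the earlier candidate
        best <- cand
        best_p <- pval
      }
    }
    if (is.null(best) || best_p >= p_enter) break
    selected <- c(selected, best)
  }
  fit <- fit_ols(selected, data)
  list(terms = selected, model = fit$model)
}

#' Leave-one-out cross-validation RMSE
#'
#' For each row, the model is refitted on the remaining n - 1 rows and used
#' to predict the held-out row; returns the root mean squared prediction
#' error. The refit is explicit (one least-squares solve per fold), not the
#' hat-matrix shortcut, so each fold can fail independently and be named in
#' the error.
#'
#' @inheritParams fit_ols
#' @return LOOCV RMSE, L/min.
#' @export
loocv_rmse <- function(terms, data) {
  y <- data$vo2max_measured
  X <- model_matrix_terms(terms, data)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows for LOOCV", call. = FALSE)
  err <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(stats::lm.fit(X[-i, , drop = FALSE], y[-i]),
                    error = function(e) e)
    if (inherits(fit, "error") || anyNA(stats::coef(fit))) {
      stop(sprintf("LOOCV fit failed on fold %d", i), call. = FALSE)
    }
    err[i] <- y[i] - sum(X[i, ] * stats::coef(fit))
  }
  sqrt(mean(err^2))
}

#' Bland-Altman agreement between predicted and measured values
#'
#' Differences are predicted minus measured. Bias is their mean; the limits
#' of agreement are bias +/- `k` sample standard deviations (default
#' k = 1.96). A proportional-error check is included: the slope (and its
#' p-value) of the regression of the differences on the pairwise means,
#' reported but never used as a gate. A significantly negative slope is the
#' classic signature of overestimating low values and underestimating high
#' ones.
#'
#' @param predicted,measured Equal-length numeric vectors, n >= 2.
#' @param k LoA multiplier (default 1.96).
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `prop_bias_slope`, `prop_bias_p`, `n`.
#' @export
bland_altman <- function(predicted, measured, k = 1.96) {
  if (length(predicted) != length(measured)) stop("paired vectors differ in length",
                                                  call. = FALSE)
  n <- length(predicted)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- predicted - measured
  m <- (predicted + measured) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  slope <- NA_real_
  pval <- NA_real_
  if (stats::sd(m) > 0 && s > 0 && n >= 3) {
    sl <- stats::summary.lm(stats::lm(d ~ m))$coefficients
    if (nrow(sl) == 2) {
      slope <- sl[2, 1]
      pval <- sl[2, 4]
    }
  }
  list(bias = bias, loa_low = bias - k * s, loa_high = bias + k * s,
       sd_diff = s, prop_bias_slope = slope, prop_bias_p = pval, n = n)
}

#' Convert absolute VO2 to metabolic equivalents
#'
#' One MET is an oxygen uptake of 3.5 mL per kg per minute.
#'
#' @param vo2_l_min Absolute oxygen uptake, L/min.
#' @param weight_kg Body weight, kg (> 0).
#' @return METs.
#' @export
mets_from_vo2 <- function(vo2_l_min, weight_kg) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("weight must be positive", call. = FALSE)
  }
  (vo2_l_min * 1000 / weight_kg) / 3.5
}

#' Full accuracy report of a model on a measured cohort
#'
#' Combines the in-sample statistics of [fit_ols()] (when `refit = TRUE`)
#' or of fixed published coefficients with Bland-Altman agreement and the
#' LOOCV error, mirroring the per-model accuracy panel of the validation
#' study.
#'
#' @param terms Character vector of term names.
#' @param data Cohort data frame with `vo2max_measured` and term columns.
#' @param model Optional fixed [vo2_model()]; when `NULL` the model is
#'   refitted on `data` (LOOCV always refits).
#' @param loa_k LoA multiplier passed to [bland_altman()].
#' @return List of class `validation_report`: `r`, `adj_r2`, `rmse`,
#'   `bias`, `loa_low`, `loa_high`, `loocv_rmse`, `n`.
#' @export
validation_report <- function(terms, data, model = NULL, loa_k = 1.96) {
  if (is.null(model)) {
    fit <- fit_ols(terms, data)
    model <- fit$model
    rep_ <- fit$report
  } else {
    pred0 <- predict(model, data)
    res <- data$vo2max_measured - pred0
    sst <- sum((data$vo2max_measured - mean(data$vo2max_measured))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
    n <- nrow(data)
    p <- length(model$coefficients)
    rep_ <- list(r = stats::cor(pred0, data$vo2max_measured),
                 adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
                 rmse = sqrt(mean(res^2)), n = n)
  }
  pred <- predict(model, data)
  ba <- bland_altman(pred, data$vo2max_measured, k = loa_k)
  structure(list(r = rep_$r, adj_r2 = rep_$adj_r2, rmse = rep_$rmse,
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 loocv_rmse = loocv_rmse(terms, data), n = rep_$n),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report> n=%d r=%.3f adj.r2=%.3f ",
                     "RMSE=%.3f bias=%.3f LoA=[%.3f, %.3f] LOOCV=%.3f L/min\n"),
              x$n, x$r, x$adj_r2, x$rmse, x$bias, x$loa_low, x$loa_high,
              x$loocv_rmse))
  invisible(x)
}
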