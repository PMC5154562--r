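#' Intraclass correlation coefficient for test-retest scores
#'
#' ICC = (MSr - MSe) / MSr, where MSr is the between-subject mean square
#' and MSe the error mean square. The default dialect is a two-way ANOVA
#' without interaction (subject and occasion effects removed), a
#' consistency-type ICC under which a constant shift between occasions is
#' absorbed by the occasion effect and does not lower repeatability. Set
#' `dialect = "oneway"` to leave the occasion effect in the error term.
#'
#' @param test1,test2 Paired per-subject scores, n >= 2.
#' @param dialect `"twoway"` (default) or `"oneway"`.
#' @return List with `ms_r`, `ms_e`, `icc`.
#' @export
icc <- function(test1, test2, dialect = c("twoway", "oneway")) {
  dialect <- match.arg(dialect)
  if (length(test1) != length(test2)) stop("paired scores differ in length", call. = FALSE)
  n <- length(test1)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  scores <- cbind(test1, test2)
  k <- 2
  grand <- mean(scores)
  subj_means <- rowMeans(scores)
  occ_means <- colMeans(scores)
  ss_subj <- k * sum((subj_means - grand)^2)
  ms_r <- ss_subj / (n - 1)
  if (ms_r == 0) stop("no between-subject variance", call. = FALSE)
  if (dialect == "twoway") {
    ss_occ <- n * sum((occ_means - grand)^2)
    ss_tot <- sum((scores - grand)^2)
    ms_e <- (ss_tot - ss_subj - ss_occ) / ((n - 1) * (k - 1))
  } else {
    ms_e <- sum((scores - subj_means)^2) / (n * (k - 1))
  }
  list(ms_r = ms_r, ms_e = ms_e, icc = (ms_r - ms_e) / ms_r)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper with the pipeline's error contract: at least 3 pairs and
#' nonzero variance on both sides.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance", call. = FALSE)
  stats::cor(x, y)
}

# ordered fitness classes, worst first
CRF_LEVELS <- c("poor", "fair", "good")

#' Classify cardiorespiratory fitness from the Ruffier-Dickson Index
#'
#' The classic bands: RDI <= 5 is good, RDI >= 11 is poor, anything
#' between is fair. The published bands are stated on integers, leaving
#' (5, 6) and (10, 11) unassigned for continuous scores; both fall in
#' fair so the three bands are exhaustive.
#'
#' @param rdi Numeric vector of RDI scores (finite).
#' @return Factor with ordered levels poor < fair < good.
#' @export
classify_rdi <- function(rdi) {
  if (any(!is.finite(rdi))) stop("RDI must be finite", call. = FALSE)
  out <- ifelse(rdi <= 5, "good", ifelse(rdi >= 11, "poor", "fair"))
  factor(out, levels = CRF_LEVELS, ordered = TRUE)
}

#' Build a 3-class relative-VO2max norms table
#'
#' Validates a user-supplied norms table mapping sex and age band to the
#' pooled poor/fair/good classification of relative VO2max. For each sex,
#' age bands `[age_low, age_high)` must not overlap, and each row's two
#' thresholds must be strictly increasing. Reference norms (e.g. the ACSM
#' tables) are not shipped with the package; users supply their own CSV.
#'
#' @param df Data frame with columns `sex` (1 male / 0 female), `age_low`,
#'   `age_high`, `poor_below_ml_kg_min`, `good_at_or_above_ml_kg_min`.
#' @return The validated data frame, class `norms_table`.
#' @export
norms_table <- function(df) {
  req <- c("sex", "age_low", "age_high", "poor_below_ml_kg_min",
           "good_at_or_above_ml_kg_min")
  missing <- setdiff(req, names(df))
  if (length(missing)) stop(sprintf("norms table lacks column(s): %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  if (any(df$age_low >= df$age_high)) stop("age bands must have age_low < age_high",
                                           call. = FALSE)
  if (any(df$poor_below_ml_kg_min >= df$good_at_or_above_ml_kg_min)) {
    stop("norms thresholds must be strictly increasing", call. = FALSE)
  }
  for (s in unique(df$sex)) {
    b <- df[df$sex == s, ]
    b <- b[order(b$age_low), ]
    if (nrow(b) > 1 && any(b$age_high[-nrow(b)] > b$age_low[-1])) {
      stop("overlapping age bands in norms table", call. = FALSE)
    }
  }
  structure(as.data.frame(df), class = c("norms_table", "data.frame"))
}

#' Classify fitness from absolute VO2max against a norms table
#'
#' Converts absolute VO2max (L/min) to relative (mL/kg/min) using body
#' weight, finds the subject's sex and age band, and returns the pooled
#' 3-class label. Values exactly at a threshold take the upper class
#' (half-open bands).
#'
#' @param vo2max_l_min Absolute VO2max, L/min.
#' @param sex Sex code, 1 male / 0 female.
#' @param age Age, years.
#' @param weight_kg Body weight, kg.
#' @param norms A [norms_table()].
#' @return Factor with ordered levels poor < fair < good.
#' @export
classify_norms <- function(vo2max_l_min, sex, age, weight_kg, norms) {
  stopifnot(inherits(norms, "norms_table"))
  n <- length(vo2max_l_min)
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  weight_kg <- rep_len(weight_kg, n)
  rel <- vo2max_l_min * 1000 / weight_kg
  out <- character(n)
  for (i in seq_len(n)) {
    row <- norms[norms$sex == sex[i] & norms$age_low <= age[i] &
                   age[i] < norms$age_high, ]
    if (nrow(row) != 1) {
      stop(sprintf("norms table does not cover sex=%g age=%g", sex[i], age[i]),
           call. = FALSE)
    }
    out[i] <- if (rel[i] < row$poor_below_ml_kg_min) "poor"
      else if (rel[i] >= row$good_at_or_above_ml_kg_min) "good"
      else "fair"
  }
  factor(out, levels = CRF_LEVELS, ordered = TRUE)
}

#' Classification agreement summary against reference fitness classes
#'
#' Applies the squat-test study's operating definitions on the ordered
#' 3-class scale poor < fair < good:
#' \itemize{
#'   \item true positives - predicted class equals the reference class and
#'     that class is good or fair;
#'   \item true negatives - both classifications say poor;
#'   \item false negatives - the prediction underestimates the reference;
#'   \item false positives - the prediction overestimates the reference.
#' }
#' Sensitivity is nTP/(nTP+nFN), specificity nTN/(nTN+nFP), and the false
#' positive rate 1 - specificity. Cohen's kappa is computed on the full
#' 3 x 3 table, and the two-category miss rate is the fraction of pairs
#' confusing poor with good (ordinal distance 2).
#'
#' @param predicted,reference Vectors of labels in poor/fair/good (factors
#'   or characters), equal length.
#' @return List with counts `n_tp`, `n_fn`, `n_tn`, `n_fp`, rates
#'   `sensitivity`, `specificity`, `false_positive_rate`, `kappa`,
#'   `two_class_miss_rate`, and the full `table`.
#' @export
confusion_summary <- function(predicted, reference) {
  to_ord <- function(v, what) {
    v <- as.character(v)
    if (!all(v %in% CRF_LEVELS)) stop(sprintf("unknown %s label", what), call. = FALSE)
    factor(v, levels = CRF_LEVELS, ordered = TRUE)
  }
  predicted <- to_ord(predicted, "predicted")
  reference <- to_ord(reference, "reference")
  if (length(predicted) != length(reference)) stop("label vectors differ in length",
                                                   call. = FALSE)
  pi_ <- as.integer(predicted)
  ri <- as.integer(reference)
  n_tp <- sum(pi_ == ri & reference %in% c("fair", "good"))
  n_tn <- sum(pi_ == ri & reference == "poor")
  n_fn <- sum(pi_ < ri)
  n_fp <- sum(pi_ > ri)
  tab <- table(predicted = predicted, reference = reference)
  n <- length(predicted)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  list(n_tp = n_tp, n_fn = n_fn, n_tn = n_tn, n_fp = n_fp,
       sensitivity = n_tp / (n_tp + n_fn),
       specificity = n_tn / (n_tn + n_fp),
       false_positive_rate = 1 - n_tn / (n_tn + n_fp),
       kappa = kappa,
       two_class_miss_rate = mean(abs(pi_ - ri) == 2),
       table = tab)
}

#' Training-size stability simulation
#'
#' Quantifies how the out-of-sample error of a term set stabilises as the
#' training cohort grows. For each training size 1..`max_train`, repeat
#' `iterations` times: draw a random disjoint test subset (10% of the
#' cohort by default), draw a training subset of the given size from the
#' remainder (fresh shuffle each iteration, removing any order effect),
#' fit OLS, and score RMSE on the test subset; then average. Training
#' sizes too small to identify the model (fewer rows than coefficients,
#' or a degenerate design, e.g. single-sex draws) yield `NA` for the
#' affected iterations and `NaN` for a point where no iteration succeeded.
#'
#' @param data Cohort data frame with `vo2max_measured` and term columns.
#' @param terms Character vector of term names.
#' @param iterations Iterations per training size (default 100).
#' @param test_fraction Held-out fraction (default 0.10; test size is its
#'   ceiling).
#' @param max_train Largest training size (default n minus the test size).
#' @param seed Integer seed; the whole curve is reproducible from it.
#' @return Data frame with columns `n_train` and `mean_rmse`.
#' @export
stability_simulation <- function(data, terms, iterations = 100,
                                 test_fraction = 0.10, max_train = NULL,
                                 seed = 1) {
  n <- nrow(data)
  n_test <- ceiling(test_fraction * n)
  if (is.null(max_train)) max_train <- n - n_test
  if (max_train + n_test > n) stop("max_train leaves no room for the test subset",
                                   call. = FALSE)
  rng <- new_rng(seed)
  p <- length(terms) + 1
  out <- data.frame(n_train = seq_len(max_train), mean_rmse = NA_real_)
  for (nt in seq_len(max_train)) {
    rmse <- rep(NA_real_, iterations)
    for (it in seq_len(iterations)) {
      perm <- rng$sample(n)
      test_idx <- perm[seq_len(n_test)]
      train_idx <- perm[n_test + seq_len(nt)]
      if (nt < p) next
      X <- model_matrix_terms(terms, data[train_idx, , drop = FALSE])
      if (qr(X)$rank < ncol(X)) next
      fit <- stats::lm.fit(X, data$vo2max_measured[train_idx])
      Xt <- model_matrix_terms(terms, data[test_idx, , drop = FALSE])
      pred <- as.vector(Xt %*% stats::coef(fit))
      rmse[it] <- sqrt(mean((data$vo2max_measured[test_idx] - pred)^2))
    }
    out$mean_rmse[nt] <- mean(rmse, na.rm = TRUE)
  }
  out
}
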