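test_that("ICC matches the hand-worked two-way ANOVA example", {
  r <- icc(c(1, 4), c(2, 3))
  expect_equal(r$ms_r, 4)
  expect_equal(r$ms_e, 1)
  expect_equal(r$icc, 0.75)
})

test_that("perfect repeatability gives ICC 1; occasion shifts are absorbed", {
  t1 <- c(2.1, 3.4, 2.8, 3.9)
  r <- icc(t1, t1)
  expect_equal(r$ms_e, 0)
  expect_equal(r$icc, 1)
  shifted <- icc(t1, t1 + 0.7)
  expect_equal(shifted$icc, 1)
  # the one-way dialect charges the shift to error
  expect_lt(icc(t1, t1 + 0.7, dialect = "oneway")$icc, 1)
  expect_error(icc(c(2, 2), c(2, 2)), "between-subject")
})

test_that("ICC is invariant to location shifts and positive scaling", {
  set.seed(2)
  t1 <- stats::rnorm(30, 100, 10)
  t2 <- t1 + stats::rnorm(30, 0, 5)
  base <- icc(t1, t2)$icc
  expect_equal(icc(t1 + 50, t2 + 50)$icc, base)
  expect_equal(icc(3 * t1, 3 * t2)$icc, base)
})

test_that("pearson_r reproduces hand fixtures and enforces its contract", {
  x <- c(0.5, 1.8, 2.2, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "3")
  expect_error(pearson_r(c(1, 2, 3), c(2, 2, 2)), "variance")
})

test_that("RDI classification uses the published bands, exhaustively", {
  expect_equal(as.character(classify_rdi(c(0, 9, 14))), c("good", "fair", "poor"))
  expect_equal(as.character(classify_rdi(c(5, 5.5, 10.5, 11))),
               c("good", "fair", "fair", "poor"))
  expect_error(classify_rdi(NA_real_), "finite")
})

test_that("norms classification converts units and respects half-open bands", {
  nt <- fixture_norms()
  # male, 25 y, 70 kg: 3.15 L/min = 45.0 mL/kg/min, exactly at the good threshold
  expect_equal(as.character(classify_norms(3.15, 1, 25, 70, nt)), "good")
  expect_equal(as.character(classify_norms(2.0, 1, 25, 70, nt)), "poor")
  expect_equal(as.character(classify_norms(2.9, 1, 25, 70, nt)), "fair")
  # value exactly at the poor threshold takes the upper class
  expect_equal(as.character(classify_norms(38 * 70 / 1000, 1, 25, 70, nt)), "fair")
  expect_error(classify_norms(3, 1, 80, 70, nt), "cover")
})

test_that("norms tables reject overlapping bands and inverted thresholds", {
  bad <- data.frame(sex = c(1, 1), age_low = c(18, 25), age_high = c(30, 40),
                    poor_below_ml_kg_min = c(38, 35),
                    good_at_or_above_ml_kg_min = c(45, 42))
  expect_error(norms_table(bad), "overlapping")
  bad2 <- fixture_norms()
  bad2$good_at_or_above_ml_kg_min[1] <- 30
  expect_error(norms_table(as.data.frame(bad2)), "increasing")
})

test_that("confusion summary matches the study's operating definitions", {
  reference <- c("good", "good", "fair", "fair", "poor", "poor")
  predicted <- c("good", "fair", "fair", "good", "poor", "fair")
  cs <- confusion_summary(predicted, reference)
  expect_equal(c(cs$n_tp, cs$n_fn, cs$n_tn, cs$n_fp), c(2, 1, 1, 2))
  expect_equal(cs$sensitivity, 2 / 3)
  expect_equal(cs$specificity, 1 / 3)
  expect_equal(cs$false_positive_rate, 2 / 3)
})

test_that("kappa is 1 on perfect agreement and 0 on chance tables", {
  labs <- c("poor", "fair", "good", "fair", "poor", "good", "fair")
  perfect <- confusion_summary(labs, labs)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$two_class_miss_rate, 0)

  # product-of-marginals 2x2: predicted and reference independent
  predicted <- rep(c("poor", "poor", "good", "good"), each = 5)
  reference <- rep(c("poor", "good", "poor", "good"), each = 5)
  expect_equal(confusion_summary(predicted, reference)$kappa, 0)
  expect_error(confusion_summary("excellent", "good"), "unknown")
})

test_that("the four counts partition every pair exactly once (property)", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    predicted <- sample(c("poor", "fair", "good"), n, replace = TRUE)
    reference <- sample(c("poor", "fair", "good"), n, replace = TRUE)
    cs <- confusion_summary(predicted, reference)
    expect_equal(cs$n_tp + cs$n_fn + cs$n_tn + cs$n_fp, n)
  }
})

test_that("stability curve collapses to zero error for a noiseless generating process", {
  d <- generate_cohort(cohort_config(n = 40, dgp_model = 1, residual_sd = 1e-9,
                                     seed = 5))
  curve <- stability_simulation(d, "rdi", iterations = 10, seed = 2)
  expect_equal(nrow(curve), 40 - ceiling(0.1 * 40))
  expect_true(all(curve$mean_rmse[curve$n_train >= 3] < 1e-6, na.rm = TRUE))
})

test_that("stability curve decreases toward the residual noise floor", {
  d <- generate_cohort(cohort_config(n = 60, dgp_model = 1, residual_sd = 0.5,
                                     seed = 7))
  curve <- stability_simulation(d, "rdi", iterations = 30, seed = 3)
  head_err <- mean(curve$mean_rmse[curve$n_train %in% 3:6])
  tail_err <- mean(curve$mean_rmse[curve$n_train >= 40])
  expect_gt(head_err, tail_err)
  expect_lt(abs(tail_err - 0.5), 0.25)
})

test_that("averaging over more iterations stabilises the curve (resampling property)", {
  d <- generate_cohort(cohort_config(n = 40, dgp_model = 1, residual_sd = 0.7,
                                     seed = 9))
  point <- function(iters, seed) {
    stability_simulation(d, "rdi", iterations = iters, max_train = 10,
                         seed = seed)$mean_rmse[10]
  }
  one <- vapply(1:8, function(s) point(1, s), numeric(1))
  many <- vapply(1:8, function(s) point(25, s), numeric(1))
  expect_lt(stats::var(many), stats::var(one))
})
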