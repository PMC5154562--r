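test_that("builtin equations reproduce the published worked examples", {
  expect_equal(predict(builtin_model(1), data.frame(rdi = 0)), 3.867)
  expect_equal(predict(builtin_model(1), data.frame(rdi = 10)), 3.867 - 1.10)
  m3 <- predict(builtin_model(3),
                data.frame(sex = 1, start_hr_rec_over_age2 = 105 / 900,
                           start_hr_rec_over_h2 = 105 / 1.75^2))
  expect_equal(m3, 4.121 + 0.787 + 4.235 * (105 / 900) - 0.0673 * (105 / 1.75^2))
  expect_equal(m3, 3.0947, tolerance = 1e-4)
  expect_error(builtin_model(4), "1, 2 or 3")
  expect_equal(builtin_model(2)$coefficients[["constant"]], -3.788)
})

test_that("prediction is linear in the features and errors on missing terms", {
  m <- builtin_model(2)
  f1 <- data.frame(sex = 1, age = 25, height = 1.80, rdi = 4)
  f2 <- data.frame(sex = 1, age = 25, height = 1.70, rdi = 12)
  for (a in c(0.25, 0.5, 0.9)) {
    mix <- f1 * a + f2 * (1 - a)
    expect_equal(predict(m, mix),
                 a * predict(m, f1) + (1 - a) * predict(m, f2))
  }
  expect_error(predict(builtin_model(3), data.frame(sex = 1)),
               "start_hr_rec_over_age2")
})

test_that("OLS fitting is exact on noiseless data and matches hand arithmetic", {
  d <- data.frame(rdi = 0:9, vo2max_measured = 2 + 3 * (0:9))
  fit <- fit_ols("rdi", d)
  expect_equal(unname(fit$model$coefficients), c(2, 3))
  expect_equal(fit$report$rmse, 0, tolerance = 1e-10)

  d2 <- data.frame(rdi = c(3, 1, 4, 1, 5), vo2max_measured = rep(5, 5))
  fit2 <- fit_ols("rdi", d2)
  expect_equal(unname(fit2$model$coefficients), c(5, 0))

  # hand OLS on the 5-row fixture: slope = 20.2 / 10 = 2.02
  d3 <- data.frame(rdi = 0:4, vo2max_measured = c(1, 3, 5, 7, 9.1))
  expect_equal(fit_ols("rdi", d3)$model$coefficients[["rdi"]], 2.02)

  dup <- data.frame(rdi = 1:9, sex = 1:9, vo2max_measured = stats::rnorm(9))
  expect_error(fit_ols(c("rdi", "sex"), dup), "rank-deficient")
})

test_that("coefficient standard errors match the reference linear-model summary", {
  set.seed(11)
  d <- data.frame(rdi = stats::rnorm(40, 8, 3), age = stats::rnorm(40, 30, 7))
  d$vo2max_measured <- 3 - 0.1 * d$rdi - 0.02 * d$age + stats::rnorm(40, 0, 0.4)
  se <- fit_ols_se(c("rdi", "age"), d)
  ref <- summary(stats::lm(vo2max_measured ~ rdi + age, d))$coefficients[, 2]
  expect_equal(unname(se), unname(ref))
})

test_that("forward stepwise selects true predictors and agrees with the subset oracle", {
  set.seed(21)
  n <- 60
  d <- data.frame(rdi = stats::rnorm(n), age = stats::rnorm(n))
  d$vo2max_measured <- 2 * d$rdi + stats::rnorm(n, 0, 0.1)
  sel <- fit_stepwise_forward(c("rdi", "age"), d)
  expect_equal(sel$terms, "rdi")
  expect_equal(best_subset_adj_r2(c("rdi", "age"), d), "rdi")

  # pure noise response: constant-only model
  d$vo2max_measured <- stats::rnorm(n)
  expect_length(fit_stepwise_forward(c("rdi", "age"), d, p_enter = 0.01)$terms, 0)

  # exact collinearity: exactly one of the pair enters
  d$rdi2 <- d$rdi
  d$vo2max_measured <- 2 * d$rdi + stats::rnorm(n, 0, 0.1)
  sel2 <- fit_stepwise_forward(c("rdi", "rdi2"), d)
  expect_length(sel2$terms, 1)
  expect_true(sel2$terms %in% c("rdi", "rdi2"))
})

test_that("stepwise matches the exhaustive oracle on a multi-candidate cohort", {
  set.seed(33)
  n <- 120
  d <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n), x3 = stats::rnorm(n),
                  x4 = stats::rnorm(n), x5 = stats::rnorm(n))
  names(d) <- c("rdi", "age", "height", "sex", "start_hr_rec_over_h2")
  d$vo2max_measured <- 1 + 0.8 * d$rdi - 0.6 * d$age + stats::rnorm(n, 0, 0.3)
  cand <- names(d)[1:5]
  sel <- fit_stepwise_forward(cand, d)
  expect_setequal(sel$terms, c("rdi", "age"))
  # the adjusted-r2 oracle must find the true terms; it may add weak noise
  # terms (adjusted r2 rewards any F > 1), so containment is the check
  expect_true(all(c("rdi", "age") %in% best_subset_adj_r2(cand, d)))
})

test_that("LOOCV equals hand computation and the naive refit oracle", {
  d <- data.frame(vo2max_measured = c(1, 2, 3))
  expect_equal(loocv_rmse(character(0), d), sqrt(1.5))

  exact <- data.frame(rdi = 1:10, vo2max_measured = 4 - 0.2 * (1:10))
  expect_equal(loocv_rmse("rdi", exact), 0, tolerance = 1e-10)

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:25, 1)
    d <- data.frame(rdi = stats::rnorm(n, 8, 3), sex = stats::rbinom(n, 1, 0.7))
    d$vo2max_measured <- 3.8 - 0.1 * d$rdi + 0.5 * d$sex + stats::rnorm(n, 0, 1)
    expect_equal(loocv_rmse(c("rdi", "sex"), d), naive_loocv(c("rdi", "sex"), d),
                 tolerance = 1e-12)
  }

  set.seed(9)
  d10 <- data.frame(vo2max_measured = stats::rnorm(10, 0, 1))
  expect_gt(loocv_rmse(character(0), d10), 0.7)
  expect_lt(loocv_rmse(character(0), d10), 1.5)
})

test_that("Bland-Altman reproduces hand cases", {
  ba <- bland_altman(c(0.1, -0.1) + 3, c(3, 3))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * stats::sd(c(0.1, -0.1)))
  expect_equal(ba$loa_high, 0.2772, tolerance = 1e-3)

  same <- bland_altman(c(2.5, 3.1, 2.8), c(2.5, 3.1, 2.8))
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))

  shift <- bland_altman(c(3, 4, 5), c(2, 3, 4))
  expect_equal(c(shift$bias, shift$loa_low, shift$loa_high), c(1, 1, 1))
  expect_error(bland_altman(1, numeric(0)), "length")
})

test_that("the proportional-bias slope flags over/under-estimation across the range", {
  set.seed(5)
  measured <- seq(2, 5, length.out = 40)
  predicted <- 3.5 + 0.2 * (measured - 3.5) + stats::rnorm(40, 0, 0.05)
  ba <- bland_altman(predicted, measured)
  expect_lt(ba$prop_bias_slope, 0)
  expect_lt(ba$prop_bias_p, 0.01)
})

test_that("MET conversion follows the 3.5 mL/kg/min definition", {
  expect_equal(mets_from_vo2(0.245, 70), 1)
  expect_equal(mets_from_vo2(2.45, 70), 10)
  expect_equal(mets_from_vo2(2.205, 70), 9)
  expect_error(mets_from_vo2(2, 0), "weight")
})

test_that("adjusted r-squared never exceeds r-squared", {
  set.seed(14)
  for (i in 1:5) {
    n <- sample(15:60, 1)
    d <- data.frame(rdi = stats::rnorm(n), age = stats::rnorm(n))
    d$vo2max_measured <- 3 - 0.2 * d$rdi + stats::rnorm(n)
    rep_ <- fit_ols(c("rdi", "age"), d)$report
    expect_lte(rep_$adj_r2, rep_$r^2 + 1e-12)
  }
})

test_that("validation_report combines accuracy, agreement and LOOCV coherently", {
  set.seed(8)
  d <- generate_cohort(cohort_config(n = 60, dgp_model = 1, seed = 4))
  rep_ <- validation_report("rdi", d)
  expect_true(rep_$loa_low <= rep_$bias && rep_$bias <= rep_$loa_high)
  expect_gte(rep_$rmse, 0)
  expect_gt(rep_$loocv_rmse, rep_$rmse * 0.9)  # LOOCV never flatters the fit
  # fixed published coefficients instead of refit
  rep2 <- validation_report("rdi", d, model = builtin_model(1))
  expect_true(is.finite(rep2$bias))
})
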