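test_that("generated cohorts have the requested composition and valid records", {
  coh <- generate_cohort(generator_params(n_normal = 113, n_abnormal = 191, seed = 1))
  expect_equal(nrow(coh), 304)
  expect_equal(sum(coh$label == "normal"), 113)
  expect_false(anyDuplicated(coh$id) > 0)
  expect_true(all(as.matrix(coh[fpcitbench:::SBR_COLUMNS]) > 0))
  expect_true(all(coh$age > 0))
  expect_silent(validate_cohort(coh, require_both_classes = TRUE))

  one_class <- generate_cohort(generator_params(n_normal = 0, n_abnormal = 5, seed = 2))
  expect_equal(nrow(one_class), 5)
  expect_true(all(one_class$label == "abnormal"))
  expect_true(all(as.matrix(one_class[fpcitbench:::SBR_COLUMNS]) > 0))
})

test_that("identical parameters and seed reproduce the cohort bit for bit", {
  p <- preset_params("clinical", 25, 40, seed = 77)
  expect_identical(generate_cohort(p), generate_cohort(p))
  p2 <- preset_params("clinical", 25, 40, seed = 78)
  expect_false(identical(generate_cohort(p), generate_cohort(p2)))
})

test_that("invalid generator parameters raise classed errors", {
  expect_error(generator_params(-1, 10), class = "fpcit_invalid_parameter")
  expect_error(generator_params(10, 10, age_sd = c(normal = -1, abnormal = 1)),
               class = "fpcit_invalid_parameter")
  expect_error(generator_params(10, 10, disease_putamen_drop = 1.2),
               class = "fpcit_invalid_parameter")
  expect_error(generator_params(10, 10, disease_putamen_drop = 0.2,
                                disease_caudate_drop = 0.4),
               class = "fpcit_invalid_parameter")
  expect_error(generator_params(10, 10, age_slope = 0.01),
               class = "fpcit_invalid_parameter")
})

test_that("large cohorts match the generating moments within 3 standard errors", {
  p <- preset_params("research", 1500, 1500, seed = 42)
  coh <- generate_cohort(p)
  for (cl in c("normal", "abnormal")) {
    ages <- coh$age[coh$label == cl]
    se <- p$age_sd[[cl]] / sqrt(length(ages))
    expect_lt(abs(mean(ages) - p$age_mean[[cl]]), 3 * se)
    expect_lt(abs(sd(ages) - p$age_sd[[cl]]), 3 * se)
  }
  # normal-class SBR regression slope recovers the generating age slope
  normals <- coh[coh$label == "normal", ]
  fit <- summary(lm(sbr_l_putamen ~ age, data = normals))
  expect_lt(abs(fit$coefficients["age", "Estimate"] - p$age_slope),
            3 * fit$coefficients["age", "Std. Error"])
})

test_that("zero disease effect leaves class SBR means indistinguishable", {
  coh <- generate_cohort(zero_effect_params(2000, 2000, seed = 5))
  put <- pmin(coh$sbr_l_putamen, coh$sbr_r_putamen)
  d <- mean(put[coh$label == "abnormal"]) - mean(put[coh$label == "normal"])
  se <- sqrt(var(put[coh$label == "abnormal"]) / 2000 +
             var(put[coh$label == "normal"]) / 2000)
  expect_lt(abs(d), 3 * se)
})

test_that("Bayes-rate estimate hits the degenerate limits", {
  expect_error(estimate_bayes_rate(zero_effect_params(10, 10), n_mc = 100),
               class = "fpcit_invalid_parameter")
  r0 <- estimate_bayes_rate(zero_effect_params(100, 100, seed = 1),
                            n_mc = 4000, seed = 3)
  expect_lt(abs(as.numeric(r0) - 0.5), 4 * sqrt(0.25 / 4000))
  huge <- generator_params(100, 100, disease_putamen_drop = 0.9,
                           disease_caudate_drop = 0.9, asymmetry_sd = 0,
                           noise_sd = c(putamen = 0.05, caudate = 0.05), seed = 1)
  r1 <- estimate_bayes_rate(huge, n_mc = 4000, seed = 4)
  expect_gt(as.numeric(r1), 0.999)
})

test_that("Bayes-rate estimate matches a closed-form quadrature oracle", {
  # Symmetric case: equal priors and age distributions, no asymmetry, equal
  # noise in both classes. Given age a, the log-likelihood ratio of the
  # four-region Gaussian is itself Gaussian, so P(correct | a) = Phi(d(a)/2)
  # with d(a)^2 = sum_r (drop_r * mu_r(a) / s_r)^2; integrate over the age
  # density numerically.
  p <- generator_params(
    n_normal = 100, n_abnormal = 100,
    age_mean = c(normal = 65, abnormal = 65),
    age_sd = c(normal = 10, abnormal = 10),
    disease_putamen_drop = 0.40, disease_caudate_drop = 0.25,
    asymmetry_sd = 0, noise_sd = c(putamen = 0.3, caudate = 0.3), seed = 1
  )
  oracle <- integrate(function(a) {
    mu_put <- 3.0 - 0.005 * a
    mu_cau <- 3.5 - 0.005 * a
    d2 <- 2 * (0.40 * mu_put / 0.3)^2 + 2 * (0.25 * mu_cau / 0.3)^2
    dnorm(a, 65, 10) * pnorm(sqrt(d2) / 2)
  }, lower = 65 - 80, upper = 65 + 80)$value
  est <- estimate_bayes_rate(p, n_mc = 20000, seed = 11)
  expect_lt(abs(as.numeric(est) - oracle), 2 * attr(est, "se"))
})
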