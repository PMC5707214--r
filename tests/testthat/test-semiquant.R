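test_that("age matching includes both window bounds and errors when empty", {
  train <- sbr_cohort(c(54, 55, 60, 65, 66, 50),
                      c(rep("normal", 5), "abnormal"), lp = 2)
  got <- age_matched_normals(train, 60, window = 5)
  expect_setequal(got$age, c(55, 60, 65))
  expect_error(age_matched_normals(sbr_cohort(40, "normal", 2), 70, window = 5),
               class = "fpcit_insufficient_comparators")
  all_norm <- sbr_cohort(c(20, 40, 90), "normal", 2)
  expect_equal(nrow(age_matched_normals(all_norm, 60, window = Inf)), 3)
  expect_error(age_matched_normals(all_norm, 60, window = 0),
               class = "fpcit_invalid_parameter")
})

test_that("normal-limit estimators match hand calculations", {
  expect_equal(limit_mean_minus_ksd(c(2.0, 2.2, 2.4), 2), 1.8)  # sample SD 0.2
  expect_equal(limit_mean_minus_ksd(c(2.0, 2.2, 2.4), 0), 2.2)
  expect_equal(limit_mean_minus_ksd(rep(1.7, 4), 2), 1.7)
  expect_error(limit_mean_minus_ksd(2.0, 2), class = "fpcit_insufficient_comparators")

  expect_equal(limit_minimum(c(2.0, 2.2, 2.4)), 2.0)
  expect_equal(limit_minimum(1.5), 1.5)
  expect_equal(limit_minimum(c(2.4, 2.0, 2.2)), limit_minimum(c(2.0, 2.2, 2.4)))
  expect_error(limit_minimum(numeric(0)), class = "fpcit_insufficient_comparators")
})

test_that("regression band matches an independent normal-equations oracle", {
  ages <- c(40, 50, 60); sbrs <- c(2.45, 2.15, 2.00)
  # closed-form least squares from sums, independent of the implementation
  b <- sum((ages - mean(ages)) * (sbrs - mean(sbrs))) / sum((ages - mean(ages))^2)
  a <- mean(sbrs) - b * mean(ages)
  rss <- sum((sbrs - a - b * ages)^2)
  oracle <- (a + b * 50) - 1 * sqrt(rss / (length(ages) - 2))
  expect_equal(limit_regression_minus_kse(ages, sbrs, 50, 1), oracle)

  # exact line: residual SE is 0 for any k
  on_line <- 3 - 0.01 * c(40, 55, 70)
  expect_equal(limit_regression_minus_kse(c(40, 55, 70), on_line, 62, 2),
               3 - 0.01 * 62, tolerance = 1e-12)
  expect_equal(limit_regression_minus_kse(ages, sbrs, 50, 0), a + b * 50)
  expect_error(limit_regression_minus_kse(c(50, 50, 50), sbrs, 50, 1),
               class = "fpcit_degenerate_regression")
})

test_that("ROC cut-off maximises training accuracy with the stated tie rule", {
  c1 <- roc_optimal_cutoff(c(2.0, 2.5, 3.0), c(1.0, 1.5))
  expect_equal(as.numeric(c1), 1.75)
  expect_equal(attr(c1, "accuracy"), 1.0)
  # competing optimum at 2.3 also scores 5/6; tie rule takes the smaller
  c2 <- roc_optimal_cutoff(c(2.0, 2.5, 3.0), c(1.0, 1.5, 2.1))
  expect_equal(as.numeric(c2), 1.75)
  expect_equal(attr(c2, "accuracy"), 5 / 6)
  # indistinguishable singletons: sentinel below the value, accuracy 1/2
  c3 <- roc_optimal_cutoff(2.0, 2.0)
  expect_lt(as.numeric(c3), 2.0)
  expect_equal(attr(c3, "accuracy"), 0.5)
  expect_error(roc_optimal_cutoff(numeric(0), 1),
               class = "fpcit_insufficient_comparators")
})

test_that("the rigid any-below rule treats the cut-off itself as normal", {
  cutoffs <- c(l = 1.5, r = 1.6)
  expect_equal(classify_sq(c(l = 1.6, r = 1.7), cutoffs), "normal")
  expect_equal(classify_sq(c(l = 1.4, r = 1.7), cutoffs), "abnormal")
  expect_equal(classify_sq(c(l = 1.5, r = 1.7), cutoffs), "normal")  # boundary
  expect_error(classify_sq(c(l = 1.4, x = 1.7), cutoffs),
               class = "fpcit_configuration")
})

test_that("the built-in catalogue reproduces the published method layout", {
  tab <- sq_methods()
  expect_equal(nrow(tab), 18)
  expect_equal(tab$rule[1:6], rep("mean_minus_ksd", 6))
  expect_equal(tab$k[c(1, 3, 5)], c(2, 1.5, 1))
  expect_equal(tab$rule[7:8], rep("minimum", 2))
  expect_equal(tab$rule[9:14], rep("regression_minus_kse", 6))
  expect_equal(tab$rule[15:18], rep("roc_optimal", 4))
  expect_equal(tab$comparison[15:18],
               c("all_both", "all_both", "age_matched_both", "age_matched_both"))
  expect_equal(tab$regions[c(15, 16)], c("lowest_putamen", "lowest_putamen_caudate"))
})

test_that("looser k never loses abnormal calls (SQ1 subset of SQ5)", {
  coh <- make_cohort(40, 40, seed = 21, preset = "clinical")
  train <- coh[seq(1, 80, by = 2), ]
  test <- coh[seq(2, 80, by = 2), ]
  p1 <- run_sq_method("SQ1", train, test)   # mean - 2SD
  p5 <- run_sq_method("SQ5", train, test)   # mean - 1SD
  expect_true(all(which(p1 == "abnormal") %in% which(p5 == "abnormal")))
})

test_that("adding the caudate to the ROC rule can only add abnormal flags", {
  coh <- make_cohort(40, 40, seed = 22, preset = "clinical")
  train <- coh[seq(1, 80, by = 2), ]
  test <- coh[seq(2, 80, by = 2), ]
  p15 <- run_sq_method("SQ15", train, test)
  p16 <- run_sq_method("SQ16", train, test)
  expect_true(all(which(p15 == "abnormal") %in% which(p16 == "abnormal")))
  m15 <- confusion_metrics(p15, test$label)
  m16 <- confusion_metrics(p16, test$label)
  expect_gte(m16[["sensitivity"]], m15[["sensitivity"]])
  expect_lte(m16[["specificity"]], m15[["specificity"]])
})

test_that("the age window widens rather than failing mid-experiment", {
  # only 3 normals near the test age, min_support 5 forces widening
  train <- sbr_cohort(c(40, 41, 42, 60, 61, 62, 70, 70),
                      c(rep("normal", 6), "abnormal", "abnormal"), lp = 2.2)
  train$sbr_l_putamen <- c(2.0, 2.1, 2.2, 2.3, 2.4, 2.5, 1.0, 1.1)
  test <- sbr_cohort(60, "normal", lp = 2.35)
  expect_s3_class(run_sq_method("SQ1", train, test), "factor")
  det <- run_sq_method("SQ7", train, test, details = TRUE)
  expect_true(all(attr(det, "details")$flagged %in% c(TRUE, FALSE)))
})

test_that("predictions come back in test order with per-region details", {
  coh <- make_cohort(30, 30, seed = 23)
  train <- coh[1:40, ]; test <- coh[41:60, ]
  pred <- run_sq_method("SQ9", train, test, details = TRUE)
  expect_length(pred, 20)
  d <- attr(pred, "details")
  expect_equal(unique(d$id), test$id)
  expect_equal(nrow(d), 20 * 2)  # two putamen regions per subject
})
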