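test_that("standardization centres and scales training columns exactly", {
  set.seed(1)
  x <- cbind(rnorm(20, 5, 2), runif(20), rep(3, 20))
  expect_warning(std <- standardize_fit(x), "zero-variance")
  z <- standardize_apply(std, x)
  expect_equal(unname(colMeans(z)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_true(all(z[, 3] == 0))                        # constant column guard
  centre_row <- matrix(std$mean, nrow = 1)
  expect_equal(unname(as.vector(standardize_apply(std, centre_row))), c(0, 0, 0))
  expect_error(standardize_fit(x[1, , drop = FALSE]),
               class = "fpcit_insufficient_data")
})

test_that("PCA components are orthonormal, variance-ordered and reconstructive", {
  set.seed(2)
  x <- matrix(rnorm(30 * 6), 30, 6) %*% diag(c(4, 3, 2, 1, 0.5, 0.2))
  pca <- pca_fit(x, 6)
  expect_equal(crossprod(pca$rotation), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$sdev) <= 1e-9))
  proj <- pca_apply(pca, x)
  recon <- proj %*% t(pca$rotation) + rep(1, 30) %o% pca$center
  expect_equal(recon, x, tolerance = 1e-6, ignore_attr = TRUE)
  # projected training coordinates are uncorrelated
  cc <- cov(proj)
  expect_equal(cc - diag(diag(cc)), matrix(0, 6, 6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_fit(x, 7), class = "fpcit_invalid_parameter")

  # rank-deficient data: the extra component carries ~no variance
  r2 <- cbind(x[, 1], x[, 2], x[, 1] + x[, 2])
  p3 <- pca_fit(r2, 3)
  expect_lt(p3$sdev[3], 1e-8)

  # Gram-matrix path (p >> n) agrees with the thin-SVD path
  set.seed(3)
  wide <- matrix(rnorm(12 * 200), 12, 200)
  pw <- pca_fit(wide, 4)
  ps <- svd(sweep(wide, 2, colMeans(wide)), nu = 0, nv = 4)
  expect_equal(abs(diag(crossprod(pw$rotation, ps$v))), rep(1, 4),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("F-score follows the harmonic-mean definition", {
  lab <- c(rep("abnormal", 10), rep("normal", 10))
  expect_equal(f_score(lab, lab), 1.0)
  pred <- c(rep("abnormal", 8), rep("normal", 2),  # TP 8, FN 2
            rep("abnormal", 2), rep("normal", 8))  # FP 2
  expect_equal(f_score(pred, lab), 0.8)
  expect_equal(f_score(rep("normal", 20), lab), 0)
  expect_error(f_score(lab[1:3], lab), class = "fpcit_invalid_input")
  expect_error(f_score(rep("normal", 3), rep("normal", 3)),
               class = "fpcit_invalid_input")
})

test_that("the default grid spans the coarse powers of two", {
  g <- grid_spec()
  expect_equal(g$c_values, 2^(-3:8))
  expect_equal(g$gamma_values, 2^(-8:3))
  expect_error(grid_spec(c_values = numeric(0)), class = "fpcit_invalid_parameter")
})

test_that("grid search returns the singleton grid point and nails separable data", {
  set.seed(4)
  n <- 40
  x <- cbind(c(rnorm(n, -4), rnorm(n, 4)), rnorm(2 * n), age = rnorm(2 * n, 65, 5))
  y <- factor(rep(c("abnormal", "normal"), each = n),
              levels = c("normal", "abnormal"))
  spec <- ml_spec("sbrs", "linear")
  one <- grid_search(x, y, spec, grid_spec(c_values = 2, gamma_values = 1),
                     inner_k = 4, seed = 1)
  expect_equal(one$C, 2)
  full <- grid_search(x, y, spec, inner_k = 5, seed = 1)
  expect_equal(full$mean_f, 1.0)
  # tie-break: on clean separable data many C values tie at F = 1;
  # the smallest C in the grid must win
  ties <- full$table$C[full$table$mean_f == max(full$table$mean_f)]
  expect_equal(full$C, min(ties))
})

test_that("the method catalogue encodes the kernel and component ladder", {
  tab <- ml_methods()
  expect_equal(nrow(tab), 13)
  expect_equal(tab$n_components[1:5], c(3, 5, 10, 15, 20))
  expect_equal(tab$kernel[11:13], c("linear", "linear", "rbf"))
  expect_error(ml_spec("voxels", "rbf"), class = "fpcit_invalid_parameter")
})

test_that("fit_predict is consistent, leak-free and order-equivariant", {
  coh <- make_cohort(25, 25, seed = 31)
  fs <- extract_features(coh, kind = "sbrs")
  y <- factor(coh$label, levels = c("normal", "abnormal"))
  pred <- fit_predict("ML12", fs$matrix, y, fs$matrix, inner_k = 5, seed = 2)
  # deep training points are reproduced
  expect_gt(mean(pred == y), 0.85)
  # permuting test rows permutes predictions correspondingly
  perm <- sample(nrow(fs$matrix))
  pred_perm <- fit_predict("ML12", fs$matrix, y, fs$matrix[perm, ],
                           inner_k = 5, seed = 2)
  expect_equal(as.character(pred_perm), as.character(pred)[perm])
})

test_that("PC pipelines classify phantom-derived features", {
  coh <- make_cohort(20, 20, seed = 32)
  vols <- cohort_volumes(coh, geom32, noise_sd = 0.05)
  fv <- extract_features(coh, vols, kind = "voxels")
  y <- factor(coh$label, levels = c("normal", "abnormal"))
  tr <- rep(c(TRUE, FALSE), 20)
  pred <- fit_predict("ML1", fv$matrix[tr, ], y[tr], fv$matrix[!tr, ],
                      grid = grid_spec(c_values = 2^(-3:4)),
                      inner_k = 5, seed = 3)
  expect_gt(confusion_metrics(pred, y[!tr])[["accuracy"]], 0.8)
})
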