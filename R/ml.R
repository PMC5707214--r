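#' Catalogue of the thirteen SVM pipelines
#'
#' Ten principal-component pipelines (3, 5, 10, 15 or 20 components, linear or
#' radial-basis kernel), one voxel-intensity pipeline (linear only — with
#' thousands of voxel inputs a kernel adds nothing and invites overfitting),
#' and two SBR pipelines (linear and RBF). Age is an input feature of every
#' pipeline.
#'
#' @return Data frame: `ml_id`, `feature_kind`, `n_components`, `kernel`,
#'   `label`.
#' @export
ml_methods <- function() {
  data.frame(
    ml_id = paste0("ML", 1:13),
    feature_kind = c(rep("pcs", 10), "voxels", "sbrs", "sbrs"),
    n_components = c(rep(c(3, 5, 10, 15, 20), 2), NA, NA, NA),
    kernel = c(rep("linear", 5), rep("rbf", 5), "linear", "linear", "rbf"),
    label = c(paste0(rep(c(3, 5, 10, 15, 20), 2), " PCs, ",
                     rep(c("linear", "RBF"), each = 5)),
              "Voxels, linear", "SBRs, linear", "SBRs, RBF"),
    stringsAsFactors = FALSE
  )
}

#' Construct/validate an SVM pipeline specification
#'
#' @param feature_kind `"pcs"`, `"voxels"` or `"sbrs"`.
#' @param kernel `"linear"` or `"rbf"`; voxel features admit only a linear
#'   kernel.
#' @param n_components Number of principal components for `"pcs"`.
#' @param ml_id Optional identifier.
#' @return A validated `ml_spec` list.
#' @export
ml_spec <- function(feature_kind = c("pcs", "voxels", "sbrs"),
                    kernel = c("linear", "rbf"), n_components = NA,
                    ml_id = NA_character_) {
  feature_kind <- match.arg(feature_kind)
  kernel <- match.arg(kernel)
  if (feature_kind == "voxels" && kernel != "linear")
    stop_invalid_parameter("voxel features admit only a linear kernel")
  if (feature_kind == "pcs" && (is.na(n_components) || n_components < 1))
    stop_invalid_parameter("pcs features require a positive n_components")
  structure(list(ml_id = ml_id, feature_kind = feature_kind,
                 n_components = n_components, kernel = kernel),
            class = "ml_spec")
}

resolve_ml_spec <- function(spec) {
  if (inherits(spec, "ml_spec")) return(spec)
  if (is.character(spec)) {
    tab <- ml_methods()
    row <- tab[tab$ml_id == spec, ]
    if (nrow(row) != 1L) stop_configuration(paste("unknown ML method:", spec))
    return(ml_spec(row$feature_kind, row$kernel, row$n_components, row$ml_id))
  }
  ml_spec(spec$feature_kind, spec$kernel,
          spec$n_components %||% NA, spec$ml_id %||% NA_character_)
}

#' Hyperparameter grid for the SVM search
#'
#' The coarse grid: `C` in `2^-3 .. 2^8` and `gamma` in `2^-8 .. 2^3`, both in
#' steps of a factor of 2. The gamma grid is ignored for linear kernels.
#'
#' @param c_values,gamma_values Override vectors (kept sorted ascending).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(c_values = 2^(-3:8), gamma_values = 2^(-8:3)) {
  if (!length(c_values) || !length(gamma_values))
    stop_invalid_parameter("hyperparameter grids must be non-empty")
  structure(list(c_values = sort(c_values), gamma_values = sort(gamma_values)),
            class = "grid_spec")
}

#' Per-feature standardization fitted on training rows
#'
#' Stores the per-column mean and sample SD of the training matrix; applying
#' the transform yields training columns with mean 0 and SD 1. Zero-variance
#' columns are mapped to 0 everywhere (with a warning at fit time).
#'
#' @param x Training matrix (rows = subjects).
#' @return A `standardizer`; apply with [standardize_apply()].
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_insufficient_data("standardization needs >= 2 training rows")
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  degenerate <- sd_ == 0 | !is.finite(sd_)
  if (any(degenerate))
    warning(sprintf("%d zero-variance column(s) mapped to 0", sum(degenerate)))
  structure(list(mean = mu, sd = ifelse(degenerate, 1, sd_),
                 degenerate = degenerate), class = "standardizer")
}

#' @rdname standardize_fit
#' @param std A fitted `standardizer`.
#' @export
standardize_apply <- function(std, x) {
  x <- as.matrix(x)
  z <- sweep(sweep(x, 2L, std$mean, `-`), 2L, std$sd, `/`)
  if (any(std$degenerate)) z[, std$degenerate] <- 0
  z
}

#' Principal-component projection fitted on training rows
#'
#' Centred (not scaled) PCA with orthonormal components ordered by decreasing
#' explained variance. When there are many more features than subjects the
#' decomposition goes through the n x n Gram matrix, which is exact and much
#' faster for voxel features.
#'
#' @param x Training matrix.
#' @param n_components Number of components, at most `min(nrow - 1, ncol)`.
#' @return A `pca_projection` with `center`, `rotation`, `sdev`.
#' @export
pca_fit <- function(x, n_components) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n_components > min(n - 1L, p))
    stop_invalid_parameter(sprintf(
      "n_components = %d exceeds min(rows - 1, cols) = %d", n_components,
      min(n - 1L, p)))
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, `-`)
  if (p > 3L * n) {
    eg <- eigen(tcrossprod(xc), symmetric = TRUE)
    keep <- seq_len(n_components)
    ev <- pmax(eg$values[keep], 0)
    rot <- crossprod(xc, eg$vectors[, keep, drop = FALSE])
    nz <- ev > 0
    rot[, nz] <- sweep(rot[, nz, drop = FALSE], 2L, sqrt(ev[nz]), `/`)
    sdev <- sqrt(ev / (n - 1L))
  } else {
    sv <- svd(xc, nu = 0, nv = n_components)
    rot <- sv$v
    sdev <- sv$d[seq_len(n_components)] / sqrt(n - 1L)
  }
  colnames(rot) <- paste0("PC", seq_len(n_components))
  structure(list(center = ctr, rotation = rot, sdev = sdev),
            class = "pca_projection")
}

#' @rdname pca_fit
#' @param pca A fitted `pca_projection`.
#' @export
pca_apply <- function(pca, x) {
  sweep(as.matrix(x), 2L, pca$center, `-`) %*% pca$rotation
}

#' F-score of the abnormal class
#'
#' Harmonic mean of precision and recall with `abnormal` as the positive
#' class; defined as 0 when there are no positive predictions or no true
#' positives.
#'
#' @param predictions,labels Vectors/factors of `normal`/`abnormal` calls of
#'   equal length.
#' @param positive The positive class.
#' @return A value in `[0, 1]`.
#' @export
f_score <- function(predictions, labels, positive = "abnormal") {
  if (length(predictions) != length(labels))
    stop_invalid_input("predictions and labels must have equal length")
  if (!any(labels == positive))
    stop_invalid_input("labels must contain at least one positive case")
  tp <- sum(predictions == positive & labels == positive)
  fp <- sum(predictions == positive & labels != positive)
  fn <- sum(predictions != positive & labels == positive)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

# Transform chain (standardize, or PCA then standardize) fitted on training
# rows only. Hyperparameter-free, so a grid search fits it once per fold.
fit_transform <- function(spec, x_train, age_col) {
  if (spec$feature_kind == "pcs") {
    vox <- x_train[, -age_col, drop = FALSE]
    pca <- pca_fit(vox, spec$n_components)
    proj <- cbind(pca_apply(pca, vox), age = x_train[, age_col])
    std <- standardize_fit(proj)
    list(pca = pca, std = std, age_col = age_col)
  } else {
    list(pca = NULL, std = standardize_fit(x_train), age_col = age_col)
  }
}

apply_transform <- function(tf, x) {
  if (!is.null(tf$pca)) {
    proj <- cbind(pca_apply(tf$pca, x[, -tf$age_col, drop = FALSE]),
                  age = x[, tf$age_col])
    standardize_apply(tf$std, proj)
  } else {
    standardize_apply(tf$std, x)
  }
}

fit_svm <- function(z, y, spec, C, gamma) {
  e1071::svm(x = z, y = y, type = "C-classification", scale = FALSE,
             kernel = if (spec$kernel == "rbf") "radial" else "linear",
             cost = C,
             gamma = if (spec$kernel == "rbf") gamma else 1 / ncol(z))
}

#' Inner-loop grid search for the SVM hyperparameters
#'
#' For every grid point, a full pipeline (standardize, optional PCA fitted on
#' the inner-fold training part, then the SVM) is trained on each inner fold
#' and scored by the F-score of the abnormal class on the held-out part. The
#' grid point with the highest mean F wins; ties break toward the smaller `C`,
#' then the smaller `gamma`. The feature transform has no hyperparameters, so
#' it is fitted once per inner fold and shared across the grid.
#'
#' @param x Feature matrix (training split), age as last column.
#' @param y Factor of labels.
#' @param spec An `ml_spec` or method id.
#' @param grid A `grid_spec`.
#' @param inner_k Number of stratified inner folds (single repetition).
#' @param seed Seed for the inner fold assignment.
#' @return List `C`, `gamma` (NA for linear kernels), `mean_f`, and the full
#'   score `table`.
#' @export
grid_search <- function(x, y, spec, grid = grid_spec(), inner_k = 10L, seed = 1L) {
  spec <- resolve_ml_spec(spec)
  x <- as.matrix(x); y <- factor(y, levels = CLASS_LEVELS)
  if (nlevels(droplevels(y)) < 2L)
    stop_invalid_input("training data must contain both classes")
  pts <- if (spec$kernel == "rbf") {
    expand.grid(gamma = grid$gamma_values, C = grid$c_values)[, c("C", "gamma")]
  } else {
    data.frame(C = grid$c_values, gamma = NA_real_)
  }
  pts <- pts[order(pts$C, pts$gamma), , drop = FALSE]  # lexicographic tie order
  folds <- stratified_folds(y, inner_k, seed)
  fmat <- matrix(NA_real_, nrow = nrow(pts), ncol = inner_k)
  for (f in seq_len(inner_k)) {
    tr <- folds != f
    tf <- fit_transform(spec, x[tr, , drop = FALSE], ncol(x))
    ztr <- apply_transform(tf, x[tr, , drop = FALSE])
    zte <- apply_transform(tf, x[!tr, , drop = FALSE])
    ytr <- y[tr]; yte <- y[!tr]
    for (j in seq_len(nrow(pts))) {
      m <- fit_svm(ztr, ytr, spec, pts$C[j], pts$gamma[j])
      fmat[j, f] <- f_score(as.character(stats::predict(m, zte)), as.character(yte))
    }
  }
  mean_f <- rowMeans(fmat)
  best <- which.max(mean_f)  # first maximum = smallest C then gamma
  list(C = pts$C[best], gamma = pts$gamma[best], mean_f = mean_f[best],
       table = cbind(pts, mean_f = mean_f))
}

#' Fit an SVM pipeline on a training split and predict a test split
#'
#' Runs the nested [grid_search()] on the training rows, refits the
#' standardizer, optional PCA and SVM on the full training split with the
#' selected hyperparameters, and predicts the test rows. Every fitted
#' statistic derives from training rows only.
#'
#' @param spec An `ml_spec` or method id (`"ML1"`..`"ML13"`).
#' @param x_train,y_train Training feature matrix (age last column) and
#'   labels.
#' @param x_test Test feature matrix with the same columns.
#' @param grid A `grid_spec`.
#' @param inner_k Inner folds for the grid search.
#' @param seed Seed for the inner fold assignment.
#' @return Factor of predicted test labels with the chosen hyperparameters as
#'   attribute `"hyperparams"`.
#' @export
fit_predict <- function(spec, x_train, y_train, x_test, grid = grid_spec(),
                        inner_k = 10L, seed = 1L) {
  spec <- resolve_ml_spec(spec)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- factor(y_train, levels = CLASS_LEVELS)
  gs <- grid_search(x_train, y_train, spec, grid, inner_k, seed)
  tf <- fit_transform(spec, x_train, ncol(x_train))
  m <- fit_svm(apply_transform(tf, x_train), y_train, spec, gs$C, gs$gamma)
  pred <- stats::predict(m, apply_transform(tf, x_test))
  structure(factor(as.character(pred), levels = CLASS_LEVELS),
            hyperparams = gs[c("C", "gamma", "mean_f")])
}
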