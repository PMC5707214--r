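#' Seeded stratified fold assignment
#'
#' Partitions subjects into `k` folds preserving class proportions: each fold
#' receives the floor or ceiling of `n_class / k` members of every class, and
#' which folds carry the remainders is randomised. Deterministic given
#' `labels`, `k` and `seed`.
#'
#' @param labels Factor/vector of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices (1..k), one per subject.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(k)
  counts <- table(labels)
  if (any(counts < k))
    stop_stratification(sprintf(
      "class '%s' has %d members, fewer than k = %d folds",
      names(counts)[which.min(counts)], min(counts), k))
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    perm <- sample(k)  # randomise which folds take the remainder
    fold[idx] <- perm[rep_len(seq_len(k), length(idx))]
  }
  fold
}

#' Confusion-matrix metrics with abnormal as the positive class
#'
#' @param predictions,labels Vectors/factors of `normal`/`abnormal` calls.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(predictions, labels) {
  predictions <- as.character(predictions); labels <- as.character(labels)
  if (length(predictions) != length(labels))
    stop_invalid_input("predictions and labels must have equal length")
  if (length(unique(labels)) < 2L)
    stop_undefined_metric("both classes must be present in the labels")
  tp <- sum(predictions == "abnormal" & labels == "abnormal")
  tn <- sum(predictions == "normal" & labels == "normal")
  fp <- sum(predictions == "abnormal" & labels == "normal")
  fn <- sum(predictions == "normal" & labels == "abnormal")
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

resolve_method <- function(id) {
  if (inherits(id, "ml_spec")) return(list(type = "ml", id = id$ml_id, spec = id))
  if (grepl("^SQ", id)) list(type = "sq", id = id, spec = sq_spec(id))
  else if (grepl("^ML", id)) list(type = "ml", id = id, spec = resolve_ml_spec(id))
  else stop_configuration(paste("unknown method id:", id))
}

#' Repeated, nested, stratified k-fold comparison of classifiers
#'
#' The benchmark harness: for each of `repeats` repetitions a fresh seeded
#' stratified partition into `k` folds is drawn, and every method is trained
#' on each training split (semi-quantification limits re-estimated; SVM
#' hyperparameters re-selected by the nested inner grid search) and evaluated
#' on the held-out fold. All methods share the identical fold assignments
#' within a repetition, so comparisons between methods are paired. Volumes are
#' turned into voxel features once per cohort (flipping, occipital scaling and
#' loose masking are per-subject operations that use no label information);
#' PCA and standardization remain per-fold.
#'
#' @param methods Character vector of method ids (`"SQ1"`..`"SQ18"`,
#'   `"ML1"`..`"ML13"`) and/or `ml_spec` objects.
#' @param cohort A cohort data frame with both classes.
#' @param volumes Optional list of `phantom_volume`s (named by id or in cohort
#'   order); required when any method uses voxel or PC features unless
#'   `voxel_features` is given.
#' @param voxel_features Optional precomputed `feature_set` of kind
#'   `"voxels"`.
#' @param k,repeats Outer folds and repetitions (defaults 10 and 10).
#' @param seed Master seed; per-repeat fold seeds and per-cell grid-search
#'   seeds are derived from it by a fixed counter scheme.
#' @param grid,inner_k Hyperparameter grid and inner folds for ML methods.
#' @param window,min_support Age-matching controls for SQ methods.
#' @param verbose Emit one progress line per repeat to stderr.
#' @return An `fpcit_cv` object: `cells` (one row per method, repeat and fold
#'   with accuracy/sensitivity/specificity) plus the run configuration.
#'   `summary()` aggregates to per-method means and SDs.
#' @export
run_experiment <- function(methods, cohort, volumes = NULL,
                           voxel_features = NULL, k = 10L, repeats = 10L,
                           seed = 1L, grid = grid_spec(), inner_k = 10L,
                           window = 5, min_support = 5L, verbose = FALSE) {
  validate_cohort(cohort, require_both_classes = TRUE)
  specs <- lapply(methods, resolve_method)
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_configuration("duplicate method ids")
  labels <- cohort_labels(cohort)
  needs_vox <- any(vapply(specs, function(m)
    m$type == "ml" && m$spec$feature_kind %in% c("voxels", "pcs"), logical(1)))
  needs_sbr <- any(vapply(specs, function(m)
    m$type == "ml" && m$spec$feature_kind == "sbrs", logical(1)))
  if (needs_vox && is.null(voxel_features)) {
    if (is.null(volumes))
      stop_missing_input("voxel/PC methods need volumes or voxel_features")
    voxel_features <- extract_features(cohort, volumes, "voxels")
  }
  sbr_features <- if (needs_sbr) extract_features(cohort, kind = "sbrs") else NULL

  set.seed(as.integer(seed))
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  cells <- vector("list", repeats * k * length(specs))
  ci <- 0L
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(labels, k, repeat_seeds[r])
    if (verbose) message(sprintf("repeat %d/%d", r, repeats))
    for (f in seq_len(k)) {
      te <- folds == f
      train <- cohort[!te, , drop = FALSE]
      test <- cohort[te, , drop = FALSE]
      for (mi in seq_along(specs)) {
        m <- specs[[mi]]
        pred <- if (m$type == "sq") {
          run_sq_method(m$spec, train, test, window = window,
                        min_support = min_support)
        } else {
          fs <- if (m$spec$feature_kind == "sbrs") sbr_features else voxel_features
          gs_seed <- (repeat_seeds[r] + 7919L * f + 131L * mi) %% .Machine$integer.max
          fit_predict(m$spec, fs$matrix[!te, , drop = FALSE], labels[!te],
                      fs$matrix[te, , drop = FALSE], grid = grid,
                      inner_k = inner_k, seed = gs_seed)
        }
        met <- confusion_metrics(pred, labels[te])
        ci <- ci + 1L
        cells[[ci]] <- data.frame(method = m$id, repeat_index = r,
                                  fold_index = f, accuracy = met[["accuracy"]],
                                  sensitivity = met[["sensitivity"]],
                                  specificity = met[["specificity"]])
      }
    }
  }
  structure(
    list(cells = do.call(rbind, cells), methods = ids, k = k,
         repeats = repeats, seed = as.integer(seed),
         repeat_seeds = repeat_seeds),
    class = "fpcit_cv"
  )
}

#' @export
summary.fpcit_cv <- function(object, ...) {
  cells <- object$cells
  agg <- lapply(split(cells, factor(cells$method, levels = object$methods)),
                function(d) {
    data.frame(
      method = d$method[1], n_cells = nrow(d),
      accuracy = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
      sensitivity = mean(d$sensitivity), sensitivity_sd = stats::sd(d$sensitivity),
      specificity = mean(d$specificity), specificity_sd = stats::sd(d$specificity))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' @export
print.fpcit_cv <- function(x, ...) {
  cat(sprintf("FP-CIT benchmark: %d method(s), %d repeat(s) x %d fold(s), seed %d\n",
              length(x$methods), x$repeats, x$k, x$seed))
  s <- summary(x)
  s[, -(1:2)] <- round(s[, -(1:2)], 3)
  print(s, row.names = FALSE)
  invisible(x)
}

method_descriptor <- function(id) {
  sq <- sq_methods(); ml <- ml_methods()
  if (id %in% sq$sq_id) sq$label[sq$sq_id == id]
  else if (id %in% ml$ml_id) ml$label[ml$ml_id == id]
  else id
}

#' Write benchmark report tables
#'
#' One row per method with mean and SD of accuracy, sensitivity and
#' specificity: a CSV rounded to two decimals for reading, and a JSON twin at
#' full precision for machines. Re-running with the same results yields
#' byte-identical files.
#'
#' @param cv An `fpcit_cv` object (or its `summary()` data frame).
#' @param dir Output directory (created if needed).
#' @param name File stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(cv, dir, name = "report") {
  s <- if (inherits(cv, "fpcit_cv")) summary(cv) else cv
  if (!nrow(s)) stop_invalid_input("no summaries to report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- cbind(method = s$method,
             descriptor = vapply(s$method, method_descriptor, character(1)),
             s[, setdiff(names(s), "method"), drop = FALSE])
  csv <- s
  num <- vapply(csv, is.numeric, logical(1)) & names(csv) != "n_cells"
  csv[num] <- lapply(csv[num], function(v) sprintf("%.2f", v))
  csv_path <- file.path(dir, paste0(name, ".csv"))
  json_path <- file.path(dir, paste0(name, ".json"))
  utils::write.csv(csv, csv_path, row.names = FALSE)
  jsonlite::write_json(s, json_path, dataframe = "rows", digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' Run a benchmark described by a YAML configuration
#'
#' The configuration names the cohort source (a CSV path, or a generator
#' preset with counts and seed), the methods, the fold scheme and the output
#' directory, e.g.:
#' \preformatted{
#' cohort:
#'   preset: research   # or csv: path/to/cohort.csv
#'   n_normal: 50
#'   n_abnormal: 100
#'   seed: 7
#' volumes: false        # true generates phantoms for voxel/PC methods
#' geometry: {dim: 48}
#' methods: [SQ15, ML12]
#' k: 10
#' repeats: 3
#' seed: 1
#' out_dir: results
#' name: report
#' }
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @return The `fpcit_cv` object, invisibly; reports are written to
#'   `out_dir`.
#' @export
run_benchmark <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cs <- cfg$cohort %||% stop_configuration("config must name a cohort source")
  cohort <- if (!is.null(cs$csv)) {
    read_cohort_csv(cs$csv)
  } else {
    generate_cohort(preset_params(cs$preset %||% "research",
                                  n_normal = cs$n_normal,
                                  n_abnormal = cs$n_abnormal,
                                  seed = cs$seed %||% 1L))
  }
  volumes <- NULL
  if (isTRUE(cfg$volumes)) {
    geom <- do.call(phantom_geometry, cfg$geometry %||% list())
    volumes <- cohort_volumes(cohort, geom,
                              noise_sd = cfg$volume_noise_sd %||% 0.05)
  }
  cv <- run_experiment(cfg$methods %||% stop_configuration("config must list methods"),
                       cohort, volumes = volumes,
                       k = cfg$k %||% 10L, repeats = cfg$repeats %||% 10L,
                       seed = cfg$seed %||% 1L,
                       inner_k = cfg$inner_k %||% 10L,
                       verbose = isTRUE(cfg$verbose))
  if (!is.null(cfg$out_dir)) write_report(cv, cfg$out_dir, cfg$name %||% "report")
  invisible(cv)
}

#' Generate one phantom volume per cohort subject
#'
#' Seeds are derived from the cohort generator seed (or 0) plus the row
#' index, so the set of volumes is reproducible.
#'
#' @param cohort A cohort data frame.
#' @param geometry A `phantom_geometry`.
#' @param noise_sd Voxel noise SD as a fraction of background.
#' @param seed_base Base added to each row index to form the per-subject seed.
#' @return Named list of `phantom_volume`s in cohort order.
#' @export
cohort_volumes <- function(cohort, geometry, noise_sd = 0.05,
                           seed_base = NULL) {
  validate_cohort(cohort)
  if (is.null(seed_base)) {
    p <- attr(cohort, "params")
    seed_base <- if (!is.null(p)) p$seed * 10000L else 0L
  }
  vols <- lapply(seq_len(nrow(cohort)), function(i)
    generate_volume(cohort[i, ], geometry, noise_sd = noise_sd,
                    seed = (seed_base + i) %% .Machine$integer.max))
  names(vols) <- cohort$id
  vols
}
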