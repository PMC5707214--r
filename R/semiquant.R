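#' Catalogue of the eighteen semi-quantification classifiers
#'
#' Each method combines a comparison set (age-matched or whole-cohort, normals
#' only or both classes), a set of regional SBRs or per-patient "lowest"
#' discriminants, and a cut-off rule. A patient is called abnormal as soon as
#' any considered SBR falls strictly below its cut-off; a value exactly on the
#' cut-off counts as within normal limits.
#'
#' @return A data frame with one row per method: `sq_id`, `comparison`,
#'   `regions`, `rule`, `k`, `label`.
#' @export
sq_methods <- function() {
  put  <- "putamen"; pc <- "putamen_caudate"
  lput <- "lowest_putamen"; lpc <- "lowest_putamen_caudate"
  data.frame(
    sq_id = paste0("SQ", 1:18),
    comparison = c(rep("age_matched_normals", 8), rep("all_normals", 6),
                   "all_both", "all_both", "age_matched_both", "age_matched_both"),
    regions = c(rep(c(put, pc), 7), lput, lpc, lput, lpc),
    rule = c(rep("mean_minus_ksd", 6), rep("minimum", 2),
             rep("regression_minus_kse", 6), rep("roc_optimal", 4)),
    k = c(2, 2, 1.5, 1.5, 1, 1, 0, 0, 2, 2, 1.5, 1.5, 1, 1, 0, 0, 0, 0),
    label = c(
      "Mean - 2SD, L+R putamen", "Mean - 2SD, L+R putamen + caudate",
      "Mean - 1.5SD, L+R putamen", "Mean - 1.5SD, L+R putamen + caudate",
      "Mean - 1SD, L+R putamen", "Mean - 1SD, L+R putamen + caudate",
      "Minimum, L+R putamen", "Minimum, L+R putamen + caudate",
      "Regression - 2SE, L+R putamen", "Regression - 2SE, L+R putamen + caudate",
      "Regression - 1.5SE, L+R putamen", "Regression - 1.5SE, L+R putamen + caudate",
      "Regression - 1SE, L+R putamen", "Regression - 1SE, L+R putamen + caudate",
      "ROC optimal, lowest putamen", "ROC optimal, lowest putamen + caudate",
      "ROC optimal (age-matched), lowest putamen",
      "ROC optimal (age-matched), lowest putamen + caudate"
    ),
    stringsAsFactors = FALSE
  )
}

sq_spec <- function(id) {
  tab <- sq_methods()
  row <- tab[tab$sq_id == id, ]
  if (nrow(row) != 1L) stop_configuration(paste("unknown semi-quantification method:", id))
  as.list(row)
}

region_columns <- function(regions) {
  switch(regions,
    putamen = c("sbr_l_putamen", "sbr_r_putamen"),
    putamen_caudate = SBR_COLUMNS,
    stop_configuration(paste("unknown region set:", regions))
  )
}

# per-patient "lowest side" discriminants for the ROC family
discriminants <- function(cohort, regions) {
  d <- list(lowest_putamen = pmin(cohort$sbr_l_putamen, cohort$sbr_r_putamen))
  if (regions == "lowest_putamen_caudate")
    d$lowest_caudate <- pmin(cohort$sbr_l_caudate, cohort$sbr_r_caudate)
  else if (regions != "lowest_putamen")
    stop_configuration(paste("unknown discriminant set:", regions))
  d
}

#' Age-matched normal comparators
#'
#' Selects the normal-labelled training records whose age lies within
#' `test_age +/- window` years, inclusive at both bounds.
#'
#' @param train Training cohort data frame.
#' @param test_age Test subject age in years.
#' @param window Half-width of the age window in years (default 5).
#' @param min_support Minimum number of matches below which a classed
#'   `insufficient_comparators` error is raised.
#' @return The matching rows of `train`.
#' @export
age_matched_normals <- function(train, test_age, window = 5, min_support = 1L) {
  if (window <= 0) stop_invalid_parameter("window must be > 0")
  sel <- train[train$label == "normal" & abs(train$age - test_age) <= window, ,
               drop = FALSE]
  if (nrow(sel) < min_support)
    stop_insufficient_comparators(sprintf(
      "only %d normal comparator(s) within %.1f years of age %.1f",
      nrow(sel), window, test_age))
  sel
}

# Widen the window symmetrically in 1-year steps until the predicate holds.
widened_subset <- function(train, test_age, window, enough, max_extra = 200) {
  for (extra in 0:max_extra) {
    sel <- train[abs(train$age - test_age) <= window + extra, , drop = FALSE]
    if (enough(sel)) return(sel)
  }
  stop_insufficient_comparators(sprintf(
    "no adequate comparator set near age %.1f even after widening", test_age))
}

#' Normal-limit estimators
#'
#' `limit_mean_minus_ksd` returns `mean(values) - k * sd(values)` using the
#' sample (n-1) standard deviation. `limit_minimum` returns the smallest
#' value. `limit_regression_minus_kse` fits an ordinary least-squares line of
#' SBR against age and returns the fitted value at `test_age` minus `k` times
#' the residual standard error `sqrt(RSS / (n - 2))` — the width of the normal
#' band, not the standard error of the predicted mean.
#'
#' @param values Numeric SBR values from the comparison set.
#' @param k Multiplier of the spread term.
#' @param ages,sbrs Paired normal-population observations for the regression
#'   form.
#' @param test_age Age at which the regression band is evaluated.
#' @return The lower cut-off as a plain number.
#' @export
limit_mean_minus_ksd <- function(values, k) {
  if (length(values) < 2L)
    stop_insufficient_comparators("mean - kSD needs at least 2 comparators")
  mean(values) - k * stats::sd(values)
}

#' @rdname limit_mean_minus_ksd
#' @export
limit_minimum <- function(values) {
  if (length(values) < 1L)
    stop_insufficient_comparators("minimum rule needs at least 1 comparator")
  min(values)
}

#' @rdname limit_mean_minus_ksd
#' @export
limit_regression_minus_kse <- function(ages, sbrs, test_age, k) {
  if (length(ages) != length(sbrs)) stop_invalid_input("ages and sbrs must pair up")
  if (length(ages) < 3L)
    stop_insufficient_comparators("regression band needs at least 3 comparators")
  if (length(unique(ages)) < 2L)
    stop_degenerate_regression("all comparator ages are identical")
  fit <- stats::lm.fit(cbind(1, ages), sbrs)
  rse <- sqrt(sum(fit$residuals^2) / (length(ages) - 2L))
  sum(fit$coefficients * c(1, test_age)) - k * rse
}

#' Accuracy-optimal ROC threshold
#'
#' Finds the cut-off `c` maximising training accuracy of the rule "abnormal
#' iff value < c". Candidates are the midpoints between consecutive distinct
#' pooled values plus one sentinel below the pooled minimum and one above the
#' pooled maximum; ties are broken toward the smallest candidate, which
#' favours specificity.
#'
#' @param normal_values,abnormal_values SBR discriminant values per class.
#' @return The selected threshold, with the achieved training accuracy as
#'   attribute `"accuracy"`.
#' @export
roc_optimal_cutoff <- function(normal_values, abnormal_values) {
  if (length(normal_values) == 0L || length(abnormal_values) == 0L)
    stop_insufficient_comparators("both classes must be represented for a ROC cut-off")
  pooled <- sort(unique(c(normal_values, abnormal_values)))
  cand <- c(pooled[1] - 1,
            if (length(pooled) > 1L) (pooled[-1] + pooled[-length(pooled)]) / 2,
            pooled[length(pooled)] + 1)
  n_total <- length(normal_values) + length(abnormal_values)
  acc <- vapply(cand, function(cc) {
    (sum(abnormal_values < cc) + sum(normal_values >= cc)) / n_total
  }, numeric(1))
  best <- which.max(acc)  # first maximum = smallest candidate
  structure(cand[best], accuracy = acc[best])
}

#' Classify one record against fitted normal limits
#'
#' The rigid rule: the record is abnormal as soon as any considered value
#' falls strictly below its cut-off; all values at or above their cut-offs
#' give an overall classification of normal.
#'
#' @param values Named numeric vector of the record's SBRs/discriminants.
#' @param cutoffs Named numeric vector of cut-offs covering every name in
#'   `values`.
#' @return `"normal"` or `"abnormal"`.
#' @export
classify_sq <- function(values, cutoffs) {
  if (!all(names(values) %in% names(cutoffs)))
    stop_configuration("missing cut-off for one or more considered regions")
  if (any(values < cutoffs[names(values)])) "abnormal" else "normal"
}

#' Run one semi-quantification method on a train/test split
#'
#' Dispatches the method's comparison set, regions and cut-off rule:
#' \itemize{
#'   \item mean - kSD and minimum rules re-estimate per-region cut-offs from
#'     the age-matched normal comparators of each test subject (window
#'     `+/- window` years, widened symmetrically in 1-year steps until at
#'     least `min_support` comparators are found);
#'   \item regression bands are fitted once per region on all normal training
#'     records and evaluated at each test subject's age;
#'   \item ROC methods reduce each region pair to the per-patient lowest SBR
#'     and fit one accuracy-optimal threshold per discriminant from both
#'     classes of the training data — on the whole training set, or on the
#'     test subject's age window for the age-matched variants (widened until
#'     both classes reach `min_support`).
#' }
#'
#' @param spec A method id (`"SQ1"`..`"SQ18"`) or a one-row list in the
#'   [sq_methods()] schema.
#' @param train,test Cohort data frames.
#' @param window Age-matching half-width in years.
#' @param min_support Minimum comparators per (class and) window.
#' @param details If `TRUE`, attach a per-subject data frame of values,
#'   cut-offs and flags.
#' @return Factor of predicted labels in test order (levels normal,
#'   abnormal); with `details`, an attribute `"details"`.
#' @export
run_sq_method <- function(spec, train, test, window = 5, min_support = 5L,
                          details = FALSE) {
  if (is.character(spec)) spec <- sq_spec(spec)
  validate_cohort(train)
  validate_cohort(test)
  n_test <- nrow(test)
  det <- if (details) vector("list", n_test) else NULL

  if (spec$rule %in% c("mean_minus_ksd", "minimum", "regression_minus_kse")) {
    cols <- region_columns(spec$regions)
    normals <- train[train$label == "normal", , drop = FALSE]
    if (spec$rule == "regression_minus_kse") {
      cut_fun <- lapply(cols, function(cn) {
        ages <- normals$age; sbrs <- normals[[cn]]
        if (length(ages) < 3L)
          stop_insufficient_comparators("regression band needs at least 3 normal records")
        if (length(unique(ages)) < 2L)
          stop_degenerate_regression("normal training ages are all identical")
        fit <- stats::lm.fit(cbind(1, ages), sbrs)
        rse <- sqrt(sum(fit$residuals^2) / (length(ages) - 2L))
        co <- fit$coefficients
        function(a) co[1] + co[2] * a - spec$k * rse
      })
      names(cut_fun) <- cols
      pred <- character(n_test)
      for (i in seq_len(n_test)) {
        cutoffs <- vapply(cols, function(cn) cut_fun[[cn]](test$age[i]), numeric(1))
        values <- vapply(cols, function(cn) test[[cn]][i], numeric(1))
        pred[i] <- classify_sq(values, cutoffs)
        if (details) det[[i]] <- data.frame(id = test$id[i], region = cols,
                                            value = values, cutoff = cutoffs,
                                            flagged = values < cutoffs)
      }
    } else {
      need <- if (spec$rule == "mean_minus_ksd") max(min_support, 2L) else min_support
      pred <- character(n_test)
      for (i in seq_len(n_test)) {
        comp <- widened_subset(normals, test$age[i], window,
                               function(s) nrow(s) >= need)
        cutoffs <- vapply(cols, function(cn) {
          if (spec$rule == "minimum") limit_minimum(comp[[cn]])
          else limit_mean_minus_ksd(comp[[cn]], spec$k)
        }, numeric(1))
        values <- vapply(cols, function(cn) test[[cn]][i], numeric(1))
        pred[i] <- classify_sq(values, cutoffs)
        if (details) det[[i]] <- data.frame(id = test$id[i], region = cols,
                                            value = values, cutoff = cutoffs,
                                            flagged = values < cutoffs)
      }
    }
  } else if (spec$rule == "roc_optimal") {
    validate_cohort(train, require_both_classes = TRUE)
    disc_test <- discriminants(test, spec$regions)
    dnames <- names(disc_test)
    fit_cutoffs <- function(sub) {
      disc_tr <- discriminants(sub, spec$regions)
      isn <- sub$label == "normal"
      vapply(dnames, function(dn)
        as.numeric(roc_optimal_cutoff(disc_tr[[dn]][isn], disc_tr[[dn]][!isn])),
        numeric(1))
    }
    pred <- character(n_test)
    if (spec$comparison == "all_both") {
      cutoffs <- fit_cutoffs(train)
      for (i in seq_len(n_test)) {
        values <- vapply(dnames, function(dn) disc_test[[dn]][i], numeric(1))
        pred[i] <- classify_sq(values, cutoffs)
        if (details) det[[i]] <- data.frame(id = test$id[i], region = dnames,
                                            value = values, cutoff = cutoffs,
                                            flagged = values < cutoffs)
      }
    } else {
      for (i in seq_len(n_test)) {
        sub <- widened_subset(train, test$age[i], window, function(s)
          sum(s$label == "normal") >= min_support &&
            sum(s$label == "abnormal") >= min_support)
        cutoffs <- fit_cutoffs(sub)
        values <- vapply(dnames, function(dn) disc_test[[dn]][i], numeric(1))
        pred[i] <- classify_sq(values, cutoffs)
        if (details) det[[i]] <- data.frame(id = test$id[i], region = dnames,
                                            value = values, cutoff = cutoffs,
                                            flagged = values < cutoffs)
      }
    }
  } else {
    stop_configuration(paste("unknown rule:", spec$rule))
  }
  out <- factor(pred, levels = CLASS_LEVELS)
  if (details) attr(out, "details") <- do.call(rbind, det)
  out
}
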