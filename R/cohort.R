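#' Regions of the striatal SBR table
#'
#' Column order used throughout the package for the four regional striatal
#' binding ratios (SBRs).
#' @keywords internal
SBR_COLUMNS <- c("sbr_l_putamen", "sbr_r_putamen", "sbr_l_caudate", "sbr_r_caudate")

CLASS_LEVELS <- c("normal", "abnormal")

#' Parameters of the synthetic FP-CIT cohort generator
#'
#' Defines the generative model for a two-class cohort of striatal binding
#' ratios (SBRs). For a subject of class \eqn{y} with age \eqn{a}, the
#' noise-free SBR in region \eqn{r} (putamen or caudate, either side) is
#' \deqn{\mu_r(a) = \beta_{0,r} + \beta_1 a}
#' for normal subjects, reflecting the gradual age-related decline of striatal
#' dopamine transporter density. Abnormal (pre-synaptic dopaminergic deficit,
#' PDD) subjects lose a fraction of that mean: the left/right drops are
#' \eqn{d_r (1 \pm q)} where \eqn{q \sim N(0, \code{asymmetry_sd})} is a single
#' per-subject laterality factor shared by putamen and caudate, so disease is
#' asymmetric but consistently lateralised within a subject. Drops are clamped
#' to \eqn{[0, 0.95]}. Independent Gaussian noise with region-specific SD is
#' then added and values are truncated to stay positive. The putamen drop must
#' be at least as large as the caudate drop (putamen-dominant degeneration).
#'
#' @param n_normal,n_abnormal Subject counts per class.
#' @param age_mean,age_sd Length-2 named numeric vectors (`normal`,
#'   `abnormal`), years.
#' @param p_male Length-2 named numeric vector of male proportions per class.
#'   Sex is generated for demographic fidelity only; no classifier uses it.
#' @param sbr_intercept Length-2 named numeric vector (`putamen`, `caudate`):
#'   SBR of a normal subject extrapolated to age 0.
#' @param age_slope SBR change per year of age (non-positive).
#' @param disease_putamen_drop,disease_caudate_drop Fractional reduction of the
#'   age-specific normal mean in the abnormal class, in `[0, 1)`.
#' @param asymmetry_sd SD of the per-subject disease laterality factor.
#' @param noise_sd Length-2 named numeric vector (`putamen`, `caudate`):
#'   between-subject SD of SBRs about their class/age mean.
#' @param seed Integer seed; identical parameters and seed reproduce the cohort
#'   bit for bit.
#' @return An object of class `generator_params` (a validated list).
#' @seealso [preset_params()] for the two bundled difficulty presets,
#'   [generate_cohort()].
#' @export
generator_params <- function(n_normal,
                             n_abnormal,
                             age_mean = c(normal = 60.8, abnormal = 61.6),
                             age_sd = c(normal = 11.3, abnormal = 9.8),
                             p_male = c(normal = 0.35, abnormal = 0.65),
                             sbr_intercept = c(putamen = 3.0, caudate = 3.5),
                             age_slope = -0.005,
                             disease_putamen_drop = 0.55,
                             disease_caudate_drop = 0.35,
                             asymmetry_sd = 0.05,
                             noise_sd = c(putamen = 0.5, caudate = 0.5),
                             seed = 1L) {
  p <- list(
    n_normal = as.integer(n_normal), n_abnormal = as.integer(n_abnormal),
    age_mean = take2(age_mean, CLASS_LEVELS), age_sd = take2(age_sd, CLASS_LEVELS),
    p_male = take2(p_male, CLASS_LEVELS),
    sbr_intercept = take2(sbr_intercept, c("putamen", "caudate")),
    age_slope = age_slope,
    disease_putamen_drop = disease_putamen_drop,
    disease_caudate_drop = disease_caudate_drop,
    asymmetry_sd = asymmetry_sd,
    noise_sd = take2(noise_sd, c("putamen", "caudate")),
    seed = as.integer(seed)
  )
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

take2 <- function(x, names2) {
  if (length(x) == 1L) x <- rep(x, 2L)
  if (is.null(names(x))) names(x) <- names2
  x[names2]
}

validate_generator_params <- function(p) {
  if (is.na(p$n_normal) || is.na(p$n_abnormal) || p$n_normal < 0 || p$n_abnormal < 0)
    stop_invalid_parameter("subject counts must be non-negative integers")
  if (p$n_normal + p$n_abnormal == 0)
    stop_invalid_parameter("at least one subject must be requested")
  if (any(p$age_sd < 0) || any(p$noise_sd < 0) || p$asymmetry_sd < 0)
    stop_invalid_parameter("all SD parameters must be >= 0")
  if (any(p$p_male < 0 | p$p_male > 1))
    stop_invalid_parameter("p_male must lie in [0, 1]")
  if (p$age_slope > 0)
    stop_invalid_parameter("age_slope must be <= 0 (SBRs decline with age)")
  drops <- c(p$disease_putamen_drop, p$disease_caudate_drop)
  if (any(drops < 0 | drops >= 1))
    stop_invalid_parameter("disease drops must lie in [0, 1)")
  if (p$disease_caudate_drop > p$disease_putamen_drop)
    stop_invalid_parameter("caudate drop must not exceed putamen drop")
  invisible(p)
}

#' Bundled generator presets bracketing research- and clinical-grade difficulty
#'
#' `"research"` emulates a screened research cohort (PPMI-like shape: 209
#' healthy controls vs 448 Parkinson's disease by default, ages about 60.8
#' (11.3) and 61.6 (9.8) years) with a strong, well-separated disease effect.
#' `"clinical"` emulates a heterogeneous clinical archive (113 non-PDD vs 191
#' PDD, ages 68.7 (12.4) and 68.7 (13.3)) with smaller drops, doubled noise
#' and stronger asymmetry, so every classifier scores lower than on the
#' research preset. Effect and noise magnitudes are package defaults chosen to
#' bracket that difficulty ordering, not measured clinical values.
#'
#' @param preset `"research"` or `"clinical"`.
#' @param n_normal,n_abnormal Optional count overrides.
#' @param seed Integer seed.
#' @return A `generator_params` object.
#' @export
preset_params <- function(preset = c("research", "clinical"),
                          n_normal = NULL, n_abnormal = NULL, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "research") {
    generator_params(
      n_normal = n_normal %||% 209L, n_abnormal = n_abnormal %||% 448L,
      age_mean = c(normal = 60.8, abnormal = 61.6),
      age_sd = c(normal = 11.3, abnormal = 9.8),
      p_male = c(normal = 73 / 209, abnormal = 289 / 448),
      disease_putamen_drop = 0.55, disease_caudate_drop = 0.35,
      asymmetry_sd = 0.05,
      noise_sd = c(putamen = 0.5, caudate = 0.5),
      seed = seed
    )
  } else {
    generator_params(
      n_normal = n_normal %||% 113L, n_abnormal = n_abnormal %||% 191L,
      age_mean = c(normal = 68.7, abnormal = 68.7),
      age_sd = c(normal = 12.4, abnormal = 13.3),
      p_male = c(normal = 61 / 113, abnormal = 132 / 191),
      disease_putamen_drop = 0.45, disease_caudate_drop = 0.25,
      asymmetry_sd = 0.10,
      noise_sd = c(putamen = 1.0, caudate = 1.0),
      seed = seed
    )
  }
}

#' Noise-free regional SBR means under a generator model
#'
#' @param params A `generator_params` object.
#' @param age Vector of ages.
#' @param label `"normal"` or `"abnormal"`.
#' @param q Disease laterality factor(s) (ignored for normals).
#' @return Matrix with one row per age and columns [SBR_COLUMNS].
#' @keywords internal
sbr_means <- function(params, age, label, q = 0) {
  base_put <- params$sbr_intercept[["putamen"]] + params$age_slope * age
  base_cau <- params$sbr_intercept[["caudate"]] + params$age_slope * age
  m <- cbind(base_put, base_put, base_cau, base_cau)
  colnames(m) <- SBR_COLUMNS
  if (label == "abnormal") {
    drop_l <- pmin(pmax(cbind(params$disease_putamen_drop * (1 + q),
                              params$disease_caudate_drop * (1 + q)), 0), 0.95)
    drop_r <- pmin(pmax(cbind(params$disease_putamen_drop * (1 - q),
                              params$disease_caudate_drop * (1 - q)), 0), 0.95)
    m[, "sbr_l_putamen"] <- m[, "sbr_l_putamen"] * (1 - drop_l[, 1])
    m[, "sbr_l_caudate"] <- m[, "sbr_l_caudate"] * (1 - drop_l[, 2])
    m[, "sbr_r_putamen"] <- m[, "sbr_r_putamen"] * (1 - drop_r[, 1])
    m[, "sbr_r_caudate"] <- m[, "sbr_r_caudate"] * (1 - drop_r[, 2])
  }
  m
}

#' Generate a synthetic two-class SBR cohort
#'
#' Draws `n_normal + n_abnormal` subjects from the generative model described
#' in [generator_params()]: ages are Gaussian per class (truncated at 1 year),
#' sex is Bernoulli per class, and the four regional SBRs are the age-dependent
#' class means plus independent Gaussian noise, truncated to stay strictly
#' positive. Normal subjects are listed first. The same parameters and seed
#' always reproduce the identical cohort.
#'
#' @param params A `generator_params` object.
#' @return A `fpcit_cohort`: a data frame with columns `id`, `age`, `sex`,
#'   `label` and the four `sbr_*` columns, with the generator parameters
#'   attached as attribute `"params"`.
#' @examples
#' coh <- generate_cohort(generator_params(n_normal = 5, n_abnormal = 5, seed = 1))
#' table(coh$label)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  validate_generator_params(params)
  set.seed(params$seed)
  n <- c(normal = params$n_normal, abnormal = params$n_abnormal)
  rows <- lapply(CLASS_LEVELS, function(cl) {
    k <- n[[cl]]
    if (k == 0L) return(NULL)
    age <- pmax(stats::rnorm(k, params$age_mean[[cl]], params$age_sd[[cl]]), 1)
    sex <- ifelse(stats::runif(k) < params$p_male[[cl]], "M", "F")
    q <- if (cl == "abnormal") stats::rnorm(k, 0, params$asymmetry_sd) else rep(0, k)
    mu <- sbr_means(params, age, cl, q)
    sds <- c(params$noise_sd[["putamen"]], params$noise_sd[["putamen"]],
             params$noise_sd[["caudate"]], params$noise_sd[["caudate"]])
    noise <- matrix(stats::rnorm(k * 4L, 0, rep(sds, each = k)), nrow = k)
    sbr <- pmax(mu + noise, 1e-6)
    data.frame(age = age, sex = sex, label = cl, sbr, stringsAsFactors = FALSE)
  })
  coh <- do.call(rbind, rows)
  coh <- cbind(id = sprintf("S%04d", seq_len(nrow(coh))), coh)
  rownames(coh) <- NULL
  structure(coh, params = params, class = c("fpcit_cohort", "data.frame"))
}

#' Validate the structural invariants of a cohort table
#' @param cohort A data frame in the cohort schema.
#' @param require_both_classes Require at least one record per label.
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort, require_both_classes = FALSE) {
  needed <- c("id", "age", "sex", "label", SBR_COLUMNS)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop_invalid_input(paste("cohort lacks columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(cohort$id))
    stop_invalid_input("cohort ids must be unique")
  if (any(cohort$age <= 0)) stop_invalid_input("ages must be > 0")
  if (!all(cohort$label %in% CLASS_LEVELS))
    stop_invalid_input("labels must be 'normal' or 'abnormal'")
  if (any(as.matrix(cohort[SBR_COLUMNS]) <= 0))
    stop_invalid_input("all SBRs must be > 0")
  if (require_both_classes && length(unique(cohort$label)) < 2L)
    stop_invalid_input("cohort must contain both classes")
  invisible(cohort)
}

cohort_labels <- function(cohort) factor(cohort$label, levels = CLASS_LEVELS)

#' Read/write a cohort CSV
#'
#' Schema: `id,age,sex,label,sbr_l_putamen,sbr_r_putamen,sbr_l_caudate,
#' sbr_r_caudate` with `label` in `{normal, abnormal}`.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns a validated `fpcit_cohort`;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(as.data.frame(cohort)[, c("id", "age", "sex", "label", SBR_COLUMNS)],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(coh)
  structure(coh, class = c("fpcit_cohort", "data.frame"), provenance = path)
}
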