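# Log-density of a subject (age + four SBRs) under one class of the
# generative model. For abnormal subjects the per-subject laterality factor q
# is integrated out by Gauss-Hermite quadrature. Truncation of SBRs at zero is
# ignored: under sensible parameters its probability mass is negligible.
class_loglik <- function(params, age, sbr, label, gh = NULL) {
  n <- length(age)
  sds <- c(params$noise_sd[["putamen"]], params$noise_sd[["putamen"]],
           params$noise_sd[["caudate"]], params$noise_sd[["caudate"]])
  ll_age <- stats::dnorm(age, params$age_mean[[label]], params$age_sd[[label]],
                         log = TRUE)
  if (label == "normal" || params$asymmetry_sd == 0 ||
      (params$disease_putamen_drop == 0 && params$disease_caudate_drop == 0)) {
    mu <- sbr_means(params, age, label, q = 0)
    ll_sbr <- rowSums(stats::dnorm(sbr, mu, rep(sds, each = n), log = TRUE))
  } else {
    # E_q[ prod_r phi(x_r; mu_r(a, q), s_r) ] via Gauss-Hermite
    nodes <- sqrt(2) * params$asymmetry_sd * gh$x
    w <- gh$w / sqrt(pi)
    acc <- matrix(0, nrow = n, ncol = length(nodes))
    for (j in seq_along(nodes)) {
      mu <- sbr_means(params, age, label, q = nodes[j])
      acc[, j] <- rowSums(stats::dnorm(sbr, mu, rep(sds, each = n), log = TRUE))
    }
    mx <- apply(acc, 1L, max)
    ll_sbr <- mx + log(as.vector(exp(acc - mx) %*% w))
  }
  ll_age + ll_sbr
}

#' Monte-Carlo estimate of the best achievable classification accuracy
#'
#' Draws `n_mc` subjects from the generative model (class priors proportional
#' to the requested class counts), classifies each with the Bayes rule
#' computed directly from the known generating densities — age density times
#' the SBR density with the disease-laterality factor integrated out — and
#' returns the proportion classified correctly. This is the ceiling no
#' classifier trained on cohorts from the same parameters can beat (up to
#' Monte-Carlo error), and serves as the reference for the recovery checks.
#' Posterior ties are resolved to `normal`.
#'
#' @param params A `generator_params` object.
#' @param n_mc Number of Monte-Carlo subjects (at least 1000).
#' @param seed Integer seed.
#' @return The estimated accuracy, with its binomial standard error as
#'   attribute `"se"` and `n_mc` as attribute `"n_mc"`.
#' @export
estimate_bayes_rate <- function(params, n_mc = 20000L, seed = 1L) {
  stopifnot(inherits(params, "generator_params"))
  validate_generator_params(params)
  if (n_mc < 1000L) stop_invalid_parameter("n_mc must be >= 1000")
  total <- params$n_normal + params$n_abnormal
  p_ab <- params$n_abnormal / total
  set.seed(as.integer(seed))
  lab <- ifelse(stats::runif(n_mc) < p_ab, "abnormal", "normal")
  age <- numeric(n_mc)
  sbr <- matrix(0, nrow = n_mc, ncol = 4L, dimnames = list(NULL, SBR_COLUMNS))
  sds <- c(params$noise_sd[["putamen"]], params$noise_sd[["putamen"]],
           params$noise_sd[["caudate"]], params$noise_sd[["caudate"]])
  for (cl in CLASS_LEVELS) {
    idx <- which(lab == cl)
    if (!length(idx)) next
    a <- pmax(stats::rnorm(length(idx), params$age_mean[[cl]],
                           params$age_sd[[cl]]), 1)
    q <- if (cl == "abnormal") stats::rnorm(length(idx), 0, params$asymmetry_sd)
         else rep(0, length(idx))
    mu <- sbr_means(params, a, cl, q)
    noise <- matrix(stats::rnorm(length(idx) * 4L, 0,
                                 rep(sds, each = length(idx))),
                    nrow = length(idx))
    age[idx] <- a
    sbr[idx, ] <- pmax(mu + noise, 1e-6)
  }
  gh <- if (params$asymmetry_sd > 0) pracma::gaussHermite(21) else NULL
  ll_n <- class_loglik(params, age, sbr, "normal", gh)
  ll_a <- class_loglik(params, age, sbr, "abnormal", gh)
  post_ab <- ll_a + log(p_ab) > ll_n + log1p(-p_ab)  # tie -> normal
  rate <- mean((lab == "abnormal") == post_ab)
  structure(rate, se = sqrt(rate * (1 - rate) / n_mc), n_mc = n_mc)
}
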