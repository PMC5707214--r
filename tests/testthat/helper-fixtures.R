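# Shared fixtures; everything is generated in code at test time.

geom32 <- phantom_geometry(32)

make_cohort <- function(n_normal = 30, n_abnormal = 30, seed = 1,
                        preset = "research") {
  generate_cohort(preset_params(preset, n_normal, n_abnormal, seed = seed))
}

# Two statistically identical classes: equal age distributions, no disease
# effect, no asymmetry. Bayes accuracy is exactly the majority-class rate.
zero_effect_params <- function(n_normal, n_abnormal, seed = 1) {
  generator_params(
    n_normal = n_normal, n_abnormal = n_abnormal,
    age_mean = c(normal = 65, abnormal = 65),
    age_sd = c(normal = 10, abnormal = 10),
    disease_putamen_drop = 0, disease_caudate_drop = 0,
    asymmetry_sd = 0, noise_sd = c(putamen = 0.5, caudate = 0.5),
    seed = seed
  )
}

# Hand-crafted cohort rows for the semi-quantification unit tests.
sbr_cohort <- function(age, label, lp, rp = lp, lc = lp, rc = lc) {
  n <- length(age)
  data.frame(
    id = sprintf("H%03d", seq_len(n)), age = age,
    sex = rep("F", n), label = label,
    sbr_l_putamen = rep_len(lp, n), sbr_r_putamen = rep_len(rp, n),
    sbr_l_caudate = rep_len(lc, n), sbr_r_caudate = rep_len(rc, n),
    stringsAsFactors = FALSE
  )
}

mirror3 <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
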