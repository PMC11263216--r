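# Fixture builders shared across the suite. All fixtures are generated in
# code; p-values are made consistent with beta/se to avoid validation
# warnings unless a test wants them.

consistent_p <- function(beta, se) pmax(2 * pnorm(-abs(beta / se)), 1e-300)

make_records <- function(n = 5, snp = sprintf("rs%03d", seq_len(n)),
                         chr = "1", pos = seq_len(n) * 1e6,
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, beta = 0.1, se = 0.02,
                         pval = NULL, n_samples = 10000) {
  beta <- rep_len(beta, n); se <- rep_len(se, n)
  data.frame(snp = snp, chr = chr, pos = rep_len(pos, n),
             effect_allele = rep_len(effect_allele, n),
             other_allele = rep_len(other_allele, n),
             eaf = rep_len(eaf, n), beta = beta, se = se,
             pval = if (is.null(pval)) consistent_p(beta, se) else rep_len(pval, n),
             n = rep_len(n_samples, n), stringsAsFactors = FALSE)
}

make_dataset <- function(..., trait_id = "trait",
                         trait_type = "quantitative") {
  summary_dataset(make_records(...), trait_id, trait_type)
}

# Harmonized-instruments data.frame straight from numeric vectors, for
# estimator/sensitivity tests that do not need the allele machinery.
make_instruments <- function(beta_exp, beta_out, se_out,
                             se_exp = rep(0.01, length(beta_exp)),
                             eaf = rep(0.3, length(beta_exp)),
                             n_exp = 8000, n_out = 100000) {
  j <- length(beta_exp)
  data.frame(snp = sprintf("rs%03d", seq_len(j)),
             chr = "1", pos = seq_len(j) * 1e6,
             effect_allele = "A", other_allele = "G",
             beta_exp = beta_exp, se_exp = rep_len(se_exp, j),
             eaf_exp = rep_len(eaf, j),
             beta_out = beta_out, se_out = rep_len(se_out, j),
             eaf_out = rep_len(eaf, j),
             n_exp = n_exp, n_out = n_out,
             action = "unchanged", stringsAsFactors = FALSE)
}

# A fully-specified five-method result table for verdict tests.
make_methods_df <- function(betas, ivw_p) {
  data.frame(method = c("IVW", "MR-Egger", "weighted_median", "simple_mode",
                        "weighted_mode"),
             n_snp = 10, beta = betas, se = 0.1,
             ci_low = betas - 0.196, ci_high = betas + 0.196,
             or = exp(betas), or_low = exp(betas - 0.196),
             or_high = exp(betas + 0.196),
             pval = c(ivw_p, 0.2, 0.1, 0.3, 0.2),
             egger_intercept = NA, egger_intercept_se = NA,
             egger_intercept_pval = NA, stringsAsFactors = FALSE)
}

fake_sens <- function(pass) structure(list(pass = pass),
                                      class = "sensitivity_report")

ratio_df <- function(theta, se) {
  data.frame(snp = sprintf("rs%03d", seq_along(theta)),
             theta = theta, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}
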