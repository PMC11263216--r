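# Sensitivity battery: Cochran's Q, Egger intercept, MR-PRESSO,
# leave-one-out, Steiger directionality.

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum w_j (theta_j - theta_IVW_fixed)^2 over the Wald ratios, with
#' J - 1 degrees of freedom and an upper-tail chi-square p-value.
#'
#' @param x an `mr_harmonized` object or Wald-ratio data.frame.
#' @return list with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(x) {
  r <- as_ratios(x)
  j <- nrow(r)
  if (j < 2) stop("Cochran's Q requires at least 2 instruments")
  w <- r$weight
  beta <- sum(w * r$theta) / sum(w)
  q <- sum(w * (r$theta - beta)^2)
  df <- j - 1
  list(q_stat = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exposes the intercept of [mr_egger()]: a two-sided t-test of the
#' average directional pleiotropy being zero. p > 0.05 is conventionally
#' read as no significant horizontal pleiotropy.
#'
#' @param h an `mr_harmonized` object or instruments data.frame.
#' @return list with `alpha`, `alpha_se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  list(alpha = fit$egger_intercept, alpha_se = fit$egger_intercept_se,
       pval = fit$egger_intercept_pval)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed residual sum of squares, with each SNP's
#' prediction from the leave-one-out IVW slope, is compared against a null
#' distribution from parametric simulations (beta_exp* ~ N(beta_exp, se_exp),
#' beta_out* ~ N(slope_(-j) beta_exp, se_out), RSS recomputed identically).
#' Outlier test: per-SNP observed squared residual against its simulated
#' distribution, Bonferroni-corrected across instruments. Distortion test:
#' the shift in the IVW estimate after removing flagged outliers against the
#' distribution of shifts from removing equally many random SNPs. Empirical
#' p-values use the (1 + #exceed)/(K + 1) convention, so the global p is
#' bounded below by 1/(n_sim + 1).
#'
#' @param h an `mr_harmonized` object or instruments data.frame.
#' @param n_sim parametric simulations (default 1000).
#' @param outlier_alpha per-test outlier level before Bonferroni (default
#'   0.05; a SNP is flagged when its empirical p < outlier_alpha / J).
#' @param seed RNG seed.
#' @return list with `global_pval`, `outliers` (data.frame of snp, pval,
#'   flagged), `distortion_pval`, `corrected_result` (IVW on the retained
#'   set when outliers were flagged, else NULL).
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  d <- if (inherits(h, "mr_harmonized")) h$instruments else h
  j <- nrow(d)
  if (j < 4) stop("MR-PRESSO requires at least 4 instruments")
  x <- d$beta_exp; y <- d$beta_out
  sx <- d$se_exp; sy <- d$se_out
  w <- 1 / sy^2

  loo_slope <- function(xm, ym) {
    # weighted through-origin slopes leaving each SNP out, via sums
    sxy <- sum(w * xm * ym); sxx <- sum(w * xm^2)
    (sxy - w * xm * ym) / (sxx - w * xm^2)
  }
  sl <- loo_slope(x, y)
  resid_obs <- y - sl * x
  rss_obs <- sum(resid_obs^2)

  with_seed(seed, {
    rss_sim <- numeric(n_sim)
    resid2_sim <- matrix(0, n_sim, j)
    for (s in seq_len(n_sim)) {
      xs <- stats::rnorm(j, x, sx)
      ys <- stats::rnorm(j, sl * x, sy)
      sls <- loo_slope(xs, ys)
      rs <- ys - sls * xs
      rss_sim[s] <- sum(rs^2)
      resid2_sim[s, ] <- rs^2
    }
    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    out_p <- vapply(seq_len(j), function(k) {
      (1 + sum(resid2_sim[, k] >= resid_obs[k]^2)) / (n_sim + 1)
    }, numeric(1))
    flagged <- out_p < outlier_alpha / j
    outliers <- data.frame(snp = d$snp, pval = out_p, flagged = flagged,
                           stringsAsFactors = FALSE)

    distortion_pval <- NA_real_
    corrected <- NULL
    if (any(flagged) && sum(!flagged) >= 1) {
      slope_of <- function(idx) sum(w[idx] * x[idx] * y[idx]) / sum(w[idx] * x[idx]^2)
      b_all <- slope_of(seq_len(j))
      b_corr <- slope_of(which(!flagged))
      d_obs <- b_corr - b_all
      n_rm <- sum(flagged)
      d_rand <- vapply(seq_len(n_sim), function(s) {
        keep <- setdiff(seq_len(j), sample.int(j, n_rm))
        slope_of(keep) - b_all
      }, numeric(1))
      distortion_pval <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_sim + 1)
      corrected <- mr_ivw(d[!flagged, , drop = FALSE])
    }
    list(global_pval = global_pval, outliers = outliers,
         distortion_pval = distortion_pval, corrected_result = corrected)
  })
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate excluding each instrument in turn; flags any
#' exclusion that changes the sign of the estimate or moves its p-value
#' across 0.05.
#'
#' @param h an `mr_harmonized` object or instruments data.frame.
#' @param variance_model IVW variance model, see [mr_ivw()].
#' @return data.frame with `excluded_snp`, `beta`, `se`, `pval`, `flagged`.
#' @export
leave_one_out <- function(h, variance_model = "multiplicative_random") {
  d <- if (inherits(h, "mr_harmonized")) h$instruments else h
  j <- nrow(d)
  if (j < 2) stop("leave-one-out requires at least 2 instruments")
  full <- mr_ivw(d, variance_model = variance_model)
  rows <- lapply(seq_len(j), function(k) {
    fit <- mr_ivw(d[-k, , drop = FALSE], variance_model = variance_model)
    data.frame(excluded_snp = d$snp[k], beta = fit$beta, se = fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$flagged <- sign(tab$beta) != sign(full$beta) |
    (tab$pval < 0.05) != (full$pval < 0.05)
  tab
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against the
#' outcome (per-trait summed R^2 = 2 beta^2 eaf (1 - eaf)); the implied
#' correlations sqrt(R^2) are compared with a Fisher-z test using the two
#' sample sizes. Orientation exposure -> outcome is supported when the
#' exposure R^2 is larger and p < 0.05.
#'
#' @param h an `mr_harmonized` object or instruments data.frame with
#'   `beta_exp`, `eaf_exp`, `beta_out`, `eaf_out` (and `n_exp`, `n_out`
#'   unless supplied).
#' @param n_exp,n_out per-trait sample sizes; default median of the
#'   per-SNP columns.
#' @return list with `direction` (TRUE when exposure explains more),
#'   `pval`, `r2_exposure`, `r2_outcome`.
#' @export
steiger <- function(h, n_exp = NULL, n_out = NULL) {
  d <- if (inherits(h, "mr_harmonized")) h$instruments else h
  if (anyNA(d$eaf_exp) || anyNA(d$eaf_out)) {
    stop("Steiger test needs EAF for both traits; missing for: ",
         paste(d$snp[is.na(d$eaf_exp) | is.na(d$eaf_out)], collapse = ", "))
  }
  n_exp <- n_exp %||% stats::median(d$n_exp)
  n_out <- n_out %||% stats::median(d$n_out)
  r2_exp <- min(sum(2 * d$beta_exp^2 * d$eaf_exp * (1 - d$eaf_exp)), 1 - 1e-12)
  r2_out <- min(sum(2 * d$beta_out^2 * d$eaf_out * (1 - d$eaf_out)), 1 - 1e-12)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(direction = r2_exp > r2_out, pval = z_pval(z),
       r2_exposure = r2_exp, r2_outcome = r2_out)
}

#' Full sensitivity report
#'
#' Runs Cochran's Q, the Egger intercept test, MR-PRESSO, leave-one-out and
#' the Steiger test on one harmonized instrument set and derives the overall
#' pass flag used by the screening verdict: no significant heterogeneity
#' (Q p > 0.05), no significant directional pleiotropy (intercept p > 0.05),
#' no global PRESSO signal (p > 0.05), and a supported causal orientation
#' (Steiger p < 0.05 with the exposure explaining more variance). Components
#' that cannot run for too few instruments are recorded as NA and excluded
#' from the conjunction.
#'
#' @param h an `mr_harmonized` object.
#' @param n_sim MR-PRESSO simulations.
#' @param seed RNG seed for MR-PRESSO.
#' @param alpha significance level for the pass definition (default 0.05).
#' @return object of class `sensitivity_report`.
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed = NULL, alpha = 0.05) {
  d <- if (inherits(h, "mr_harmonized")) h$instruments else h
  j <- nrow(d)
  q <- if (j >= 2) cochran_q(h) else list(q_stat = NA, q_df = NA, q_pval = NA)
  eg <- if (j >= 3) egger_intercept_test(h)
        else list(alpha = NA, alpha_se = NA, pval = NA)
  pr <- if (j >= 4) mr_presso(h, n_sim = n_sim, seed = seed)
        else list(global_pval = NA, outliers = NULL, distortion_pval = NA,
                  corrected_result = NULL)
  loo <- if (j >= 2) leave_one_out(h) else NULL
  st <- steiger(h)
  checks <- c(q_ok = if (is.na(q$q_pval)) NA else q$q_pval > alpha,
              egger_ok = if (is.na(eg$pval)) NA else eg$pval > alpha,
              presso_ok = if (is.na(pr$global_pval)) NA else pr$global_pval > alpha,
              steiger_ok = st$direction && st$pval < alpha)
  structure(list(
    q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
    egger_intercept = eg$alpha, egger_intercept_se = eg$alpha_se,
    egger_intercept_pval = eg$pval,
    presso_global_pval = pr$global_pval,
    presso_outliers = pr$outliers,
    presso_distortion_pval = pr$distortion_pval,
    presso_corrected = pr$corrected_result,
    loo_table = loo,
    steiger_direction = st$direction, steiger_pval = st$pval,
    r2_exposure = st$r2_exposure, r2_outcome = st$r2_outcome,
    checks = checks,
    pass = all(checks[!is.na(checks)])),
    class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  cat(sprintf("  Cochran Q = %.3f (df %s), p = %.3g\n",
              x$q_stat, format(x$q_df), x$q_pval))
  cat(sprintf("  Egger intercept = %.4f (p = %.3g)\n",
              x$egger_intercept, x$egger_intercept_pval))
  cat(sprintf("  MR-PRESSO global p = %.3g; %d outlier(s)\n",
              x$presso_global_pval,
              if (is.null(x$presso_outliers)) 0L
              else sum(x$presso_outliers$flagged)))
  cat(sprintf("  Steiger: direction %s, p = %.3g\n",
              x$steiger_direction, x$steiger_pval))
  cat(sprintf("  overall pass: %s\n", x$pass))
  invisible(x)
}
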