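# The five causal estimators: IVW (primary), MR-Egger, weighted median,
# simple mode and weighted mode, built from per-SNP Wald ratios.

#' Per-SNP Wald ratios
#'
#' The Wald ratio for one instrument is beta_out / beta_exp with first-order
#' SE se_out / |beta_exp|; its inverse-variance weight is se^-2.
#'
#' @param h an `mr_harmonized` object (or its `instruments` data.frame).
#' @return data.frame with columns `snp`, `theta`, `se`, `weight`.
#' @export
wald_ratios <- function(h) {
  d <- if (inherits(h, "mr_harmonized")) h$instruments else h
  if (any(d$beta_exp == 0)) {
    stop("degenerate instrument (beta_exp = 0): ",
         paste(d$snp[d$beta_exp == 0], collapse = ", "))
  }
  theta <- d$beta_out / d$beta_exp
  se <- d$se_out / abs(d$beta_exp)
  data.frame(snp = d$snp, theta = theta, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

#' Wald ratio for a single instrument
#' @param beta_exp,beta_out,se_out exposure beta, outcome beta and its SE.
#' @return list with `theta`, `se`, `weight`.
#' @export
wald_ratio <- function(beta_exp, beta_out, se_out) {
  if (beta_exp == 0) stop("degenerate instrument (beta_exp = 0)")
  se <- se_out / abs(beta_exp)
  list(theta = beta_out / beta_exp, se = se, weight = 1 / se^2)
}

# Assemble one MRResult row. 95% Wald CI on the beta (log-odds) scale, then
# exponentiated to an odds ratio.
mr_result <- function(method, beta, se, pval, n_snp,
                      egger_intercept = NA_real_,
                      egger_intercept_se = NA_real_,
                      egger_intercept_pval = NA_real_) {
  ci_low <- beta - stats::qnorm(0.975) * se
  ci_high <- beta + stats::qnorm(0.975) * se
  data.frame(method = method, n_snp = n_snp, beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high,
             or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
             pval = pval,
             egger_intercept = egger_intercept,
             egger_intercept_se = egger_intercept_se,
             egger_intercept_pval = egger_intercept_pval,
             stringsAsFactors = FALSE)
}

as_ratios <- function(x) {
  if (inherits(x, "mr_harmonized")) return(wald_ratios(x))
  if (is.data.frame(x) && all(c("beta_exp", "beta_out", "se_out") %in% names(x)))
    return(wald_ratios(x))
  if (!all(c("theta", "se") %in% names(x))) {
    stop("expected an mr_harmonized object, instruments or ratio data.frame")
  }
  if (is.null(x$weight)) x$weight <- 1 / x$se^2
  x
}

#' Inverse-variance-weighted estimate
#'
#' Precision-weighted mean of the Wald ratios, equivalently weighted least
#' squares of outcome betas on exposure betas through the origin with
#' weights se_out^-2. The default multiplicative random-effects model scales
#' the fixed-effect SE by sqrt(max(1, Q/(J-1))), Q being Cochran's Q; the
#' fixed-effect SE is (sum of weights)^-1/2.
#'
#' @param x an `mr_harmonized` object or a Wald-ratio data.frame.
#' @param variance_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return a one-row MRResult data.frame.
#' @export
mr_ivw <- function(x, variance_model = c("multiplicative_random", "fixed")) {
  variance_model <- match.arg(variance_model)
  r <- as_ratios(x)
  j <- nrow(r)
  if (j < 1) stop("IVW requires at least one instrument")
  w <- r$weight
  beta <- sum(w * r$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (variance_model == "multiplicative_random" && j >= 2) {
    q <- sum(w * (r$theta - beta)^2)
    se <- se * sqrt(max(1, q / (j - 1)))
  }
  mr_result("IVW", beta, se, z_pval(beta / se), j)
}

# Closed-form weighted regression of y on (1, x); returns coefficients,
# their SEs under a residual scale floored at 1, RSS and df.
weighted_lm <- function(x, y, w, floor_sigma2 = TRUE) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 1e-10 * sum(w * x^2)) {
    stop("zero spread in the regressor: singular design")
  }
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  rss <- sum(w * resid^2)
  df <- length(x) - 2
  sigma2 <- if (df > 0) rss / df else 0
  if (floor_sigma2) sigma2 <- max(1, sigma2)
  se_slope <- sqrt(sigma2 / sxx)
  se_intercept <- sqrt(sigma2 * (1 / sw + xb^2 / sxx))
  list(slope = slope, intercept = intercept,
       se_slope = se_slope, se_intercept = se_intercept,
       rss = rss, df = df)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' unconstrained intercept (weights se_out^-2), after orienting every
#' instrument so that its exposure beta is positive. The slope is the causal
#' estimate; the intercept estimates average directional pleiotropy.
#' Standard errors use a residual scale floored at 1 and p-values are
#' two-sided t on J - 2 degrees of freedom.
#'
#' @param h an `mr_harmonized` object or instruments data.frame with
#'   `beta_exp`, `beta_out`, `se_out`.
#' @return a one-row MRResult data.frame carrying the intercept estimate,
#'   SE and p-value in the `egger_*` columns.
#' @export
mr_egger <- function(h) {
  d <- if (inherits(h, "mr_harmonized")) h$instruments else h
  j <- nrow(d)
  if (j < 3) stop("MR-Egger requires at least 3 instruments")
  s <- ifelse(d$beta_exp < 0, -1, 1)
  x <- s * d$beta_exp
  y <- s * d$beta_out
  w <- 1 / d$se_out^2
  fit <- weighted_lm(x, y, w)
  p_slope <- 2 * stats::pt(-abs(fit$slope / fit$se_slope), df = fit$df)
  p_int <- 2 * stats::pt(-abs(fit$intercept / fit$se_intercept), df = fit$df)
  res <- mr_result("MR-Egger", fit$slope, fit$se_slope, p_slope, j,
                   egger_intercept = fit$intercept,
                   egger_intercept_se = fit$se_intercept,
                   egger_intercept_pval = p_int)
  attr(res, "rss") <- fit$rss
  res
}

# Weighted-median point estimate: linear interpolation of the ordered
# ratios against standardized cumulative weights, evaluated at 0.5.
weighted_median_point <- function(theta, weight) {
  ord <- order(theta)
  th <- theta[ord]
  w <- weight[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(s)])
  stats::approx(s, th, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Consistent when instruments carrying more than half of the total weight
#' are valid. The SE is the standard deviation of the point estimate over
#' parametric-bootstrap resamples theta_j* ~ N(theta_j, se_j) (weights held
#' fixed).
#'
#' @param x an `mr_harmonized` object or a Wald-ratio data.frame.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return a one-row MRResult data.frame.
#' @export
mr_weighted_median <- function(x, n_boot = 1000, seed = NULL) {
  r <- as_ratios(x)
  j <- nrow(r)
  if (j < 3) stop("weighted median requires at least 3 instruments")
  beta <- weighted_median_point(r$theta, r$weight)
  se <- with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      weighted_median_point(stats::rnorm(j, r$theta, r$se), r$weight)
    }, numeric(1))
    stats::sd(est)
  })
  mr_result("weighted_median", beta, se, z_pval(beta / se), j)
}

# Mode of a weighted Gaussian kernel density over the ratios, argmax on a
# 512-point grid spanning the ratio range plus 3 bandwidths each side.
mode_point <- function(theta, rel_weight, phi) {
  j <- length(theta)
  bw <- phi * 0.9 * min(stats::sd(theta), stats::IQR(theta) / 1.349) * j^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) {
    bw <- phi * 0.9 * stats::sd(theta) * j^(-1 / 5)
  }
  if (!is.finite(bw) || bw <= 0) return(theta[1])  # all ratios identical
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw, length.out = 512)
  dens <- colSums(rel_weight * stats::dnorm(outer(theta, grid, "-") / bw))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' Gaussian kernel density over the Wald ratios (uniform kernel weights for
#' the simple mode, inverse-variance weights for the weighted mode);
#' bandwidth phi * 0.9 min(sd, IQR/1.349) J^(-1/5); the estimate is the
#' density argmax. SE by the same parametric bootstrap as the weighted
#' median. With all ratios identical the estimate is the common value and
#' the SE is 0.
#'
#' @param x an `mr_harmonized` object or a Wald-ratio data.frame.
#' @param weighted use inverse-variance kernel weights (weighted mode).
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return a one-row MRResult data.frame.
#' @export
mr_mode <- function(x, weighted = FALSE, phi = 1, n_boot = 1000, seed = NULL) {
  r <- as_ratios(x)
  j <- nrow(r)
  if (j < 3) stop("mode estimators require at least 3 instruments")
  rel_w <- if (weighted) r$weight / sum(r$weight) else rep(1 / j, j)
  beta <- mode_point(r$theta, rel_w, phi)
  if (stats::sd(r$theta) == 0) {
    return(mr_result(if (weighted) "weighted_mode" else "simple_mode",
                     beta, 0, if (beta == 0) 1 else 0, j))
  }
  se <- with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      mode_point(stats::rnorm(j, r$theta, r$se), rel_w, phi)
    }, numeric(1))
    stats::sd(est)
  })
  mr_result(if (weighted) "weighted_mode" else "simple_mode",
            beta, se, z_pval(beta / se), j)
}

#' Run the five MR methods
#'
#' IVW, MR-Egger, weighted median, simple mode and weighted mode on one
#' harmonized instrument set. Methods whose minimum instrument count is not
#' met are skipped with a logged notice. Fully deterministic given `seed`.
#'
#' @param h an `mr_harmonized` object (or instruments data.frame).
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param seed RNG seed; sub-seeds are derived per method.
#' @param variance_model IVW variance model, see [mr_ivw()].
#' @param phi mode bandwidth multiplier.
#' @return data.frame of MRResult rows, one per applicable method.
#' @export
run_all_methods <- function(h, n_boot = 1000, seed = NULL,
                            variance_model = "multiplicative_random",
                            phi = 1) {
  d <- if (inherits(h, "mr_harmonized")) h$instruments else h
  j <- nrow(d)
  if (j < 1) stop("no instruments")
  out <- list(mr_ivw(h, variance_model = variance_model))
  if (j >= 3) {
    sub <- function(k) if (is.null(seed)) NULL else seed + k
    out <- c(out, list(
      mr_egger(h),
      mr_weighted_median(h, n_boot = n_boot, seed = sub(1L)),
      mr_mode(h, weighted = FALSE, phi = phi, n_boot = n_boot, seed = sub(2L)),
      mr_mode(h, weighted = TRUE, phi = phi, n_boot = n_boot, seed = sub(3L))))
  } else {
    message("Fewer than 3 instruments: skipping MR-Egger, weighted median ",
            "and mode estimators")
  }
  do.call(rbind, out)
}
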