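# Replication meta-analysis, OR/CI conversions, the screening verdict, and
# pathway over-representation.

#' Combine study estimates by common- and random-effects meta-analysis
#'
#' Fixed (common) effect: inverse-variance weighted mean. Random effects:
#' DerSimonian-Laird, tau^2 = max(0, (Q - df)/(sum w - sum w^2 / sum w)) with
#' re-weighting 1/(se^2 + tau^2). Both p-values are two-sided normal. When
#' tau^2 = 0 the two models coincide.
#'
#' @param beta study estimates on the log-odds scale (or a data.frame with
#'   `beta` and `se` columns).
#' @param se study standard errors.
#' @return object of class `meta_result` with fixed and random estimates,
#'   `tau2`, `i2`, between-study Q and its p-value, and the study inputs.
#' @export
meta_combine <- function(beta, se = NULL) {
  if (is.data.frame(beta)) { se <- beta$se; beta <- beta$beta }
  k <- length(beta)
  if (k < 2) stop("meta-analysis requires at least 2 studies")
  if (any(!is.finite(se) | se <= 0)) stop("nonpositive study standard error")
  w <- 1 / se^2
  bf <- sum(w * beta) / sum(w)
  sef <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - bf)^2)
  df <- k - 1
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  br <- sum(wr * beta) / sum(wr)
  ser <- 1 / sqrt(sum(wr))
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  structure(list(
    beta_fixed = bf, se_fixed = sef, pval_fixed = z_pval(bf / sef),
    beta_random = br, se_random = ser, pval_random = z_pval(br / ser),
    tau2 = tau2, i2 = i2,
    q_between = q, q_between_pval = stats::pchisq(q, df, lower.tail = FALSE),
    studies = data.frame(beta = beta, se = se)),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d studies\n", nrow(x$studies)))
  cat(sprintf("  common:  OR = %.3f [%.3f, %.3f], p = %.3g\n",
              exp(x$beta_fixed), exp(x$beta_fixed - 1.96 * x$se_fixed),
              exp(x$beta_fixed + 1.96 * x$se_fixed), x$pval_fixed))
  cat(sprintf("  random:  OR = %.3f [%.3f, %.3f], p = %.3g (tau2 = %.4f, I2 = %.1f%%)\n",
              exp(x$beta_random), exp(x$beta_random - 1.96 * x$se_random),
              exp(x$beta_random + 1.96 * x$se_random), x$pval_random,
              x$tau2, 100 * x$i2))
  invisible(x)
}

#' Convert a published odds ratio with 95% CI to beta and SE
#'
#' beta = ln(OR); se = (ln(hi) - ln(lo)) / (2 * 1.96). Warns when the
#' log-scale CI is asymmetric about beta by more than 5% of its half-width.
#'
#' @param or_ odds ratio.
#' @param ci_low,ci_high 95% confidence limits (0 < lo <= OR <= hi).
#' @return list with `beta` and `se`.
#' @export
or_ci_to_beta_se <- function(or_, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_low > or_) || any(or_ > ci_high)) {
    stop("require 0 < ci_low <= or <= ci_high")
  }
  beta <- log(or_)
  se <- (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
  half <- (log(ci_high) - log(ci_low)) / 2
  mid <- (log(ci_high) + log(ci_low)) / 2
  asym <- half > 0 & abs(mid - beta) > 0.05 * half
  if (any(asym)) {
    warning("log-scale CI asymmetric about ln(OR) by > 5% of its half-width",
            call. = FALSE)
  }
  list(beta = beta, se = se)
}

#' Convert beta and SE to an odds ratio with 95% CI
#' @param beta log-odds estimate.
#' @param se its standard error.
#' @return list with `or_`, `ci_low`, `ci_high`.
#' @export
beta_se_to_or_ci <- function(beta, se) {
  z <- stats::qnorm(0.975)
  list(or_ = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se))
}

#' Classify one exposure's screening outcome
#'
#' Gate order: an exposure is `not_significant` unless the IVW p-value is
#' below `alpha`; it is a `false_positive_direction` when the five method
#' estimates disagree in sign or the sensitivity battery fails; when a
#' replication meta-analysis is supplied it must be significant
#' (random-effects p < alpha) or the call is `not_replicated`; what remains
#' is `pathogenic` (beta > 0) or `protective` (beta < 0).
#'
#' @param methods MRResult data.frame from [run_all_methods()].
#' @param sensitivity a [sensitivity_report()] (or NULL when unavailable).
#' @param meta a [meta_combine()] result, or NULL when no replication was
#'   run (the replication gate is then skipped).
#' @param alpha significance level (default 0.05).
#' @return object of class `mr_verdict`: list of the four booleans, the IVW
#'   beta and the `classification`.
#' @export
verdict <- function(methods, sensitivity = NULL, meta = NULL, alpha = 0.05) {
  if (is.null(methods) || !"IVW" %in% methods$method) {
    stop("verdict requires an IVW result")
  }
  ivw <- methods[methods$method == "IVW", ][1, ]
  ivw_significant <- ivw$pval < alpha
  signs <- sign(methods$beta)
  directions_consistent <- length(unique(signs[signs != 0])) <= 1
  sensitivity_pass <- if (is.null(sensitivity)) NA else isTRUE(sensitivity$pass)
  replication_meta_significant <-
    if (is.null(meta)) NA else meta$pval_random < alpha
  classification <-
    if (!ivw_significant) "not_significant"
    else if (!directions_consistent) "false_positive_direction"
    else if (isFALSE(sensitivity_pass)) "false_positive_direction"
    else if (isFALSE(replication_meta_significant)) "not_replicated"
    else if (ivw$beta > 0) "pathogenic"
    else "protective"
  structure(list(ivw_significant = ivw_significant,
                 directions_consistent = directions_consistent,
                 sensitivity_pass = sensitivity_pass,
                 replication_meta_significant = replication_meta_significant,
                 ivw_beta = ivw$beta, ivw_pval = ivw$pval,
                 classification = classification),
            class = "mr_verdict")
}

#' @export
print.mr_verdict <- function(x, ...) {
  cat(sprintf("<mr_verdict> %s (IVW beta %.3f, p %.3g)\n",
              x$classification, x$ivw_beta, x$ivw_pval))
  invisible(x)
}

#' Pathway over-representation analysis
#'
#' For each pathway (members intersected with the universe first), tests
#' whether the selected compounds are enriched by the hypergeometric upper
#' tail P(X >= k | M, K, s): M universe size, K pathway size, s selected,
#' k hits. Results are sorted by p ascending; the significance flag uses
#' p < alpha (default 0.1, the usual exploratory threshold for small
#' metabolite panels).
#'
#' @param selected character vector of selected compound IDs (subset of
#'   `universe`).
#' @param universe character vector of all analyzed compound IDs.
#' @param pathways list of `pathway_set` objects from [read_pathways()].
#' @param alpha significance threshold (default 0.1).
#' @return data.frame with `pathway_id`, `name`, `M`, `K`, `s`, `k`, `pval`,
#'   `significant`.
#' @export
pathway_ora <- function(selected, universe, pathways, alpha = 0.1) {
  selected <- unique(selected)
  universe <- unique(universe)
  stray <- setdiff(selected, universe)
  if (length(stray) > 0) {
    stop("selected compounds not in universe: ", paste(stray, collapse = ", "))
  }
  m <- length(universe)
  s <- length(selected)
  rows <- lapply(pathways, function(p) {
    members <- intersect(p$members, universe)
    k_size <- length(members)
    k_hit <- length(intersect(members, selected))
    pval <- stats::phyper(k_hit - 1, k_size, m - k_size, s, lower.tail = FALSE)
    data.frame(pathway_id = p$pathway_id, name = p$name,
               M = m, K = k_size, s = s, k = k_hit, pval = pval,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$pval, tab$pathway_id), , drop = FALSE]
  tab$significant <- tab$pval < alpha
  rownames(tab) <- NULL
  tab
}
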