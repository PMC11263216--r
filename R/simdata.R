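# Synthetic GWAS summary statistics with known ground truth.
#
# Summary-level simulation only: per-SNP standard errors follow the
# unit-variance approximation se = 1/sqrt(2 n eaf (1 - eaf)) and observed
# betas are drawn around their true values, which is sufficient for every
# statistic the pipeline computes. Binary-outcome betas are generated
# directly on the log-odds scale.

#' Simulation configuration
#'
#' Defines the generative regime for a synthetic exposure/outcome GWAS pair:
#' J SNPs with effect-allele frequencies from `eaf_range`, per-SNP exposure
#' effects (fixed magnitudes with random sign, or centred normal), a causal
#' effect `theta` of exposure on outcome, an optional pleiotropy regime
#' applied to a fraction of invalid instruments, palindromic allele coding
#' for a fraction of SNPs, outcome rows with swapped or strand-flipped
#' coding that harmonization must undo, and optional LD blocks.
#'
#' @param n_snp number of SNPs J (default 26, a typical metabolite
#'   instrument count).
#' @param theta true causal effect of exposure on outcome (log-odds per SD).
#' @param n_exp,n_out exposure and outcome GWAS sample sizes (defaults 7824
#'   and 113238, typical of a metabolomics GWAS and a large case-control
#'   meta-analysis).
#' @param eaf_range uniform range for effect-allele frequencies.
#' @param beta_exp_dist `"magnitude"` (|beta| uniform over `beta_exp_par`
#'   with random sign; default) or `"normal"` (centred, sd
#'   `beta_exp_par[1]`).
#' @param beta_exp_par parameters of the exposure-effect distribution;
#'   default `c(0.15, 0.45)` SD units, the strong-instrument regime of
#'   metabolite lead variants.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean mean direct effect for the directional regime.
#' @param pleiotropy_sd sd of direct effects (balanced and directional).
#' @param prop_invalid fraction of SNPs receiving a direct (pleiotropic)
#'   outcome effect.
#' @param palindrome_frac fraction of SNPs given palindromic (A/T or C/G)
#'   coding.
#' @param allele_scramble_frac fraction of non-palindromic outcome rows
#'   whose allele coding is swapped or strand-flipped (with beta/EAF
#'   adjusted so that harmonization must undo it).
#' @param ld_blocks optional list of blocks, each `list(size =, r2 =)`;
#'   block members share a chromosome neighbourhood, tag the lead SNP's
#'   effect, and are written to the LD table at the declared r-squared.
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_snp = 26, theta = 0,
                       n_exp = 7824, n_out = 113238,
                       eaf_range = c(0.05, 0.95),
                       beta_exp_dist = c("magnitude", "normal"),
                       beta_exp_par = c(0.15, 0.45),
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0.1, pleiotropy_sd = 0.05,
                       prop_invalid = 0,
                       palindrome_frac = 0.2,
                       allele_scramble_frac = 0.3,
                       ld_blocks = NULL, seed = NULL) {
  beta_exp_dist <- match.arg(beta_exp_dist)
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(n_snp >= 1, n_exp > 0, n_out > 0,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            prop_invalid >= 0, prop_invalid <= 1,
            palindrome_frac >= 0, palindrome_frac <= 1,
            allele_scramble_frac >= 0, allele_scramble_frac <= 1)
  structure(list(n_snp = n_snp, theta = theta, n_exp = n_exp, n_out = n_out,
                 eaf_range = eaf_range, beta_exp_dist = beta_exp_dist,
                 beta_exp_par = beta_exp_par, pleiotropy = pleiotropy,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 prop_invalid = prop_invalid,
                 palindrome_frac = palindrome_frac,
                 allele_scramble_frac = allele_scramble_frac,
                 ld_blocks = ld_blocks, seed = seed),
            class = "sim_config")
}

# Ordered non-palindromic allele pairs (second base is not the complement
# of the first) and palindromic pairs.
NONPAL_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                         "G","A", "G","T", "T","C", "T","G"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                    ncol = 2, byrow = TRUE)

#' Simulate one exposure/outcome GWAS summary-statistic pair
#'
#' Per SNP: draw eaf, a true exposure effect, sampling noise at
#' se = 1/sqrt(2 n eaf (1-eaf)) for both traits, a direct outcome effect for
#' invalid SNPs per the pleiotropy regime, two-sided normal p-values, allele
#' coding (palindromic for the configured fraction), and — last in the
#' random stream, so twin datasets differing only in scrambling share all
#' other draws — swapped or strand-flipped outcome coding for the scramble
#' fraction.
#'
#' @param config a [sim_config()].
#' @param id_prefix prefix for synthetic SNP ids.
#' @param chrom chromosome label for the simulated region.
#' @param trait_id trait label for the exposure dataset.
#' @return list with `exposure` and `outcome` ([summary_dataset()]s), `ld`
#'   (an [ld_table()]) and `truth` (class `sim_truth`: theta, per-SNP
#'   pleiotropy, invalid/palindromic/scrambled ids, true exposure betas).
#' @export
simulate_pair <- function(config, id_prefix = "snp", chrom = "1",
                          trait_id = "exposure") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_pair_impl(config, id_prefix, chrom, trait_id))
}

simulate_pair_impl <- function(config, id_prefix, chrom, trait_id) {
  j <- config$n_snp
  snp <- sprintf("%s%04d", id_prefix, seq_len(j))

  # positions: independent SNPs 1 Mb apart; LD-block members 10 kb apart
  pos <- seq_len(j) * 1e6
  block_id <- rep(0L, j)
  if (!is.null(config$ld_blocks)) {
    cursor <- 1L
    for (b in seq_along(config$ld_blocks)) {
      size <- config$ld_blocks[[b]]$size
      idx <- cursor:(cursor + size - 1L)
      if (max(idx) > j) stop("ld_blocks exceed n_snp")
      pos[idx] <- pos[cursor] + (seq_len(size) - 1L) * 1e4
      block_id[idx] <- b
      cursor <- cursor + size
    }
  }

  eaf <- stats::runif(j, config$eaf_range[1], config$eaf_range[2])
  true_bx <- switch(config$beta_exp_dist,
    magnitude = sample(c(-1, 1), j, replace = TRUE) *
      stats::runif(j, config$beta_exp_par[1], config$beta_exp_par[2]),
    normal = stats::rnorm(j, 0, config$beta_exp_par[1]))
  # block members tag the lead SNP's effect at the declared correlation
  if (!is.null(config$ld_blocks)) {
    for (b in seq_along(config$ld_blocks)) {
      idx <- which(block_id == b)
      r <- sqrt(config$ld_blocks[[b]]$r2)
      true_bx[idx[-1]] <- r * true_bx[idx[1]]
    }
  }

  se_x <- 1 / sqrt(2 * config$n_exp * eaf * (1 - eaf))
  obs_bx <- stats::rnorm(j, true_bx, se_x)
  p_x <- pmax(z_pval(obs_bx / se_x), .Machine$double.xmin)

  n_invalid <- round(config$prop_invalid * j)
  invalid <- if (n_invalid > 0) sort(sample.int(j, n_invalid)) else integer(0)
  alpha <- numeric(j)
  if (length(invalid) > 0 && config$pleiotropy != "none") {
    mu <- if (config$pleiotropy == "directional") config$pleiotropy_mean else 0
    # direct effects are oriented to the exposure-raising allele, so a
    # "directional" regime stays directional under the estimators'
    # beta_exp > 0 orientation
    alpha[invalid] <- sign(true_bx[invalid]) *
      stats::rnorm(length(invalid), mu, config$pleiotropy_sd)
  }

  true_by <- config$theta * true_bx + alpha
  se_y <- 1 / sqrt(2 * config$n_out * eaf * (1 - eaf))
  obs_by <- stats::rnorm(j, true_by, se_y)
  p_y <- pmax(z_pval(obs_by / se_y), .Machine$double.xmin)

  n_pal <- round(config$palindrome_frac * j)
  pal_idx <- if (n_pal > 0) sort(sample.int(j, n_pal)) else integer(0)
  ea <- oa <- character(j)
  pal_pick <- sample.int(nrow(PAL_PAIRS), j, replace = TRUE)
  nonpal_pick <- sample.int(nrow(NONPAL_PAIRS), j, replace = TRUE)
  is_pal <- seq_len(j) %in% pal_idx
  ea[is_pal] <- PAL_PAIRS[pal_pick[is_pal], 1]
  oa[is_pal] <- PAL_PAIRS[pal_pick[is_pal], 2]
  ea[!is_pal] <- NONPAL_PAIRS[nonpal_pick[!is_pal], 1]
  oa[!is_pal] <- NONPAL_PAIRS[nonpal_pick[!is_pal], 2]

  # outcome coding starts identical to the exposure's, then a fraction of
  # non-palindromic rows is scrambled (drawn last in the random stream)
  o_ea <- ea; o_oa <- oa
  o_beta <- obs_by; o_eaf <- eaf
  nonpal_idx <- which(!is_pal)
  n_scramble <- round(config$allele_scramble_frac * length(nonpal_idx))
  scramble <- if (n_scramble > 0) sort(sample(nonpal_idx, n_scramble)) else integer(0)
  if (length(scramble) > 0) {
    mode <- sample(c("swap", "flip"), length(scramble), replace = TRUE)
    for (k in seq_along(scramble)) {
      i <- scramble[k]
      if (mode[k] == "swap") {
        tmp <- o_ea[i]; o_ea[i] <- o_oa[i]; o_oa[i] <- tmp
        o_beta[i] <- -o_beta[i]
        o_eaf[i] <- 1 - o_eaf[i]
      } else {
        o_ea[i] <- flip_strand(o_ea[i])
        o_oa[i] <- flip_strand(o_oa[i])
      }
    }
  }

  exposure <- summary_dataset(data.frame(
    snp = snp, chr = chrom, pos = pos, effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = obs_bx, se = se_x, pval = p_x, n = config$n_exp,
    stringsAsFactors = FALSE), trait_id, "quantitative", validate = FALSE)
  outcome <- summary_dataset(data.frame(
    snp = snp, chr = chrom, pos = pos, effect_allele = o_ea,
    other_allele = o_oa, eaf = o_eaf, beta = o_beta, se = se_y, pval = p_y,
    n = config$n_out, stringsAsFactors = FALSE),
    "outcome", "binary", validate = FALSE)

  ld_a <- character(0); ld_b <- character(0); ld_r2 <- numeric(0)
  if (!is.null(config$ld_blocks)) {
    for (b in seq_along(config$ld_blocks)) {
      idx <- which(block_id == b)
      prs <- utils::combn(idx, 2)
      ld_a <- c(ld_a, snp[prs[1, ]])
      ld_b <- c(ld_b, snp[prs[2, ]])
      ld_r2 <- c(ld_r2, rep(config$ld_blocks[[b]]$r2, ncol(prs)))
    }
  }

  truth <- structure(list(
    theta = config$theta,
    alpha = stats::setNames(alpha, snp),
    invalid_ids = snp[invalid],
    palindromic_ids = snp[pal_idx],
    scrambled_ids = snp[scramble],
    true_beta_exp = stats::setNames(true_bx, snp)),
    class = "sim_truth")

  list(exposure = exposure, outcome = outcome,
       ld = ld_table(ld_a, ld_b, ld_r2), truth = truth)
}

#' Simulate a replication outcome study for an existing pair
#'
#' Draws a second, independent outcome GWAS of the same underlying per-SNP
#' effects (theta times the true exposure betas plus any planted
#' pleiotropy), with sampling noise at the replication study's sample size.
#' Allele coding matches the exposure's.
#'
#' @param pair result of [simulate_pair()].
#' @param exposure the exposure dataset of that pair.
#' @param n_out replication sample size (default 141355, a typical large
#'   biobank disease GWAS).
#' @param seed RNG seed.
#' @return a binary-trait [summary_dataset()] labelled
#'   `outcome_replication`.
#' @export
simulate_replication <- function(pair, exposure = pair$exposure,
                                 n_out = 141355, seed = NULL) {
  rec <- exposure$records
  truth <- pair$truth
  true_by <- truth$theta * unname(truth$true_beta_exp[rec$snp]) +
    unname(truth$alpha[rec$snp])
  se_y <- 1 / sqrt(2 * n_out * rec$eaf * (1 - rec$eaf))
  with_seed(seed, {
    beta <- stats::rnorm(nrow(rec), true_by, se_y)
    out <- data.frame(snp = rec$snp, chr = rec$chr, pos = rec$pos,
                      effect_allele = rec$effect_allele,
                      other_allele = rec$other_allele,
                      eaf = rec$eaf, beta = beta, se = se_y,
                      pval = pmax(z_pval(beta / se_y), .Machine$double.xmin),
                      n = n_out, stringsAsFactors = FALSE)
    summary_dataset(out, "outcome_replication", "binary", validate = FALSE)
  })
}

#' Simulate a multi-exposure screening panel
#'
#' Emulates a metabolite screen against one shared outcome: `n_causal`
#' exposures get the causal effect `theta` from `base`, the rest are null,
#' and one additional non-causal exposure is built with SNP ids absent from
#' the outcome so the pipeline exercises its zero-overlap skip path. Each
#' exposure occupies its own chromosome.
#'
#' @param n_exposures number of exposures (excluding skip behaviour: the
#'   drop-out exposure is one of these when `n_exposures > n_causal`).
#' @param n_causal number of exposures with a true causal effect.
#' @param base a [sim_config()]; `base$theta` is the causal effect assigned
#'   to causal exposures (must be nonzero when `n_causal > 0`).
#' @return list with `exposures` (named list of datasets), `outcome` (one
#'   shared dataset), `ld`, and `truth` (causal ids, drop-out id, per-
#'   exposure `sim_truth`).
#' @export
simulate_panel <- function(n_exposures, n_causal, base = sim_config()) {
  stopifnot(n_causal <= n_exposures, n_exposures >= 1)
  if (n_causal > 0 && base$theta == 0) {
    stop("base$theta must be nonzero when n_causal > 0")
  }
  dropout <- if (n_exposures > n_causal) n_exposures else 0L
  exposures <- list()
  truths <- list()
  out_records <- list()
  ld_parts <- list()
  for (i in seq_len(n_exposures)) {
    cfg <- base
    cfg$theta <- if (i <= n_causal) base$theta else 0
    cfg$seed <- if (is.null(base$seed)) NULL else base$seed + i
    name <- sprintf("metabolite_%02d", i)
    pair <- simulate_pair(cfg, id_prefix = sprintf("e%02d_snp", i),
                          chrom = as.character(i), trait_id = name)
    exposures[[name]] <- pair$exposure
    truths[[name]] <- pair$truth
    ld_parts[[i]] <- pair$ld
    if (i != dropout) out_records[[length(out_records) + 1]] <- pair$outcome$records
  }
  outcome <- summary_dataset(do.call(rbind, out_records), "outcome", "binary",
                             validate = FALSE)
  ld <- do.call(rbind, ld_parts)
  list(exposures = exposures, outcome = outcome,
       ld = ld_table(ld$snp_a, ld$snp_b, ld$r2),
       truth = list(causal_ids = names(exposures)[seq_len(n_causal)],
                    dropout_id = if (dropout > 0) names(exposures)[dropout] else NA,
                    per_exposure = truths))
}
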