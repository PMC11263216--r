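# Instrument selection and exposure/outcome allele harmonization.

#' Filter a dataset to genome-wide-suggestive associations
#'
#' Retains records with p strictly below the threshold (the conventional
#' instrument screen keeps p < 1e-5 when too few variants reach 5e-8).
#'
#' @param dataset a [summary_dataset()].
#' @param threshold p-value cutoff in (0, 1]; default `1e-5`.
#' @return the filtered [summary_dataset()] (order preserved); may be empty
#'   at the record level, in which case a message is logged and a dataset
#'   with zero rows is returned unclassed-safe via `validate = FALSE`.
#' @export
select_by_pvalue <- function(dataset, threshold = 1e-5) {
  stopifnot(inherits(dataset, "summary_dataset"),
            threshold >= 0, threshold <= 1)
  keep <- dataset$records$pval < threshold
  if (!any(keep)) {
    message("No SNPs pass p < ", format(threshold), " for ", dataset$trait_id)
  }
  out <- dataset
  out$records <- dataset$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Pairwise linkage-disequilibrium table
#'
#' Sparse symmetric map of pairwise r-squared values. Pairs absent from the
#' table are treated as r-squared 0 (a one-time warning is emitted when an
#' absent in-window pair is encountered during clumping).
#'
#' @param snp_a,snp_b character vectors of SNP ids.
#' @param r2 numeric r-squared values in \[0, 1\].
#' @return an `ld_table` data.frame.
#' @export
ld_table <- function(snp_a = character(), snp_b = character(), r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(r2) == length(snp_a),
            all(r2 >= 0 & r2 <= 1))
  structure(data.frame(snp_a = as.character(snp_a),
                       snp_b = as.character(snp_b),
                       r2 = as.numeric(r2), stringsAsFactors = FALSE),
            class = c("ld_table", "data.frame"))
}

#' Read an LD table from a three-column TSV (snp_a, snp_b, r2)
#' @param path file path.
#' @export
read_ld <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ld_table(tab$snp_a, tab$snp_b, tab$r2)
}

#' Write an LD table as TSV
#' @param ld an [ld_table()].
#' @param path output path.
#' @export
write_ld <- function(ld, path) {
  utils::write.table(ld, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Symmetric lookup environment keyed "a|b" for O(1) pair queries.
ld_env <- function(ld) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (!is.null(ld) && nrow(ld) > 0) {
    for (i in seq_len(nrow(ld))) {
      assign(paste(ld$snp_a[i], ld$snp_b[i], sep = "|"), ld$r2[i], envir = env)
      assign(paste(ld$snp_b[i], ld$snp_a[i], sep = "|"), ld$r2[i], envir = env)
    }
  }
  env
}

#' Greedy LD clumping
#'
#' Sorts records by p-value ascending (ties broken by smaller SE, then
#' lexicographic SNP id), repeatedly keeps the best remaining SNP and removes
#' all others on the same chromosome within `window_bp` whose r-squared with
#' it exceeds `r2_max`. Defaults match the common instrument-independence
#' criterion of r-squared 0.01 within 500 kb.
#'
#' @param dataset a [summary_dataset()] whose records carry `chr`/`pos`.
#' @param ld an [ld_table()] of pairwise r-squared values; pairs absent from
#'   the table count as r-squared 0.
#' @param r2_max maximum tolerated pairwise r-squared (default 0.01; strictly
#'   greater values are pruned).
#' @param window_bp window in basepairs (default 500000).
#' @return the clumped [summary_dataset()].
#' @export
clump <- function(dataset, ld = NULL, r2_max = 0.01, window_bp = 500000) {
  stopifnot(inherits(dataset, "summary_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0) return(dataset)
  if (anyNA(rec$pos) || anyNA(rec$chr)) {
    stop("clumping requires chromosome and position for every SNP")
  }
  ord <- order(rec$pval, rec$se, rec$snp)
  rec <- rec[ord, , drop = FALSE]
  env <- ld_env(ld)
  keep <- logical(nrow(rec))
  alive <- rep(TRUE, nrow(rec))
  warned_absent <- FALSE
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == nrow(rec)) break
    later <- which(alive & seq_len(nrow(rec)) > i)
    for (j in later) {
      if (rec$chr[j] != rec$chr[i]) next
      if (abs(rec$pos[j] - rec$pos[i]) > window_bp) next
      key <- paste(rec$snp[i], rec$snp[j], sep = "|")
      r2 <- if (exists(key, envir = env, inherits = FALSE)) {
        get(key, envir = env)
      } else {
        if (!warned_absent) {
          warning("LD for at least one in-window pair not supplied; ",
                  "treating absent pairs as r2 = 0", call. = FALSE)
          warned_absent <- TRUE
        }
        0
      }
      if (r2 > r2_max) alive[j] <- FALSE
    }
  }
  out <- dataset
  kept_ids <- rec$snp[keep]
  out$records <- dataset$records[dataset$records$snp %in% kept_ids, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Per-instrument strength (R-squared and F-statistic)
#'
#' Instrument R-squared is computed on the unit-variance trait scale as
#' 2 beta^2 eaf (1 - eaf); the F-statistic follows
#' F = (n - k - 1) R^2 / (k (1 - R^2)). In `per_snp` mode each SNP is its own
#' instrument set (k = 1); in `joint` mode k is the number of instruments and
#' the per-SNP R-squared values are summed.
#'
#' @param dataset a [summary_dataset()] with `eaf` and `n` present.
#' @param k_mode `"per_snp"` (default) or `"joint"`.
#' @param r2_method `"eaf_beta"` (default, 2 beta^2 eaf(1-eaf)) or `"z"`
#'   (t^2/(t^2 + n - 2)).
#' @return data.frame with columns `snp`, `r2`, `f_stat`, `n`, `k`.
#' @export
compute_f <- function(dataset, k_mode = c("per_snp", "joint"),
                      r2_method = c("eaf_beta", "z")) {
  stopifnot(inherits(dataset, "summary_dataset"))
  k_mode <- match.arg(k_mode)
  r2_method <- match.arg(r2_method)
  rec <- dataset$records
  r2 <- switch(r2_method,
    eaf_beta = 2 * rec$beta^2 * rec$eaf * (1 - rec$eaf),
    z = {
      t2 <- (rec$beta / rec$se)^2
      t2 / (t2 + rec$n - 2)
    })
  if (any(r2 >= 1)) {
    stop("per-SNP R2 >= 1 for: ",
         paste(rec$snp[r2 >= 1], collapse = ", "))
  }
  if (k_mode == "per_snp") {
    k <- 1
    f <- (rec$n - k - 1) * r2 / (k * (1 - r2))
  } else {
    k <- nrow(rec)
    r2_joint <- sum(r2)
    if (r2_joint >= 1) stop("joint R2 >= 1 across instruments")
    f <- rep((median(rec$n) - k - 1) * r2_joint / (k * (1 - r2_joint)), k)
  }
  data.frame(snp = rec$snp, r2 = r2, f_stat = f, n = rec$n, k = k,
             stringsAsFactors = FALSE)
}

#' Drop weak instruments
#'
#' Removes instruments with F-statistic strictly below `f_min` (the usual
#' weak-instrument rule removes F < 10).
#'
#' @param dataset a [summary_dataset()].
#' @param strengths output of [compute_f()] for the same dataset.
#' @param f_min minimum F retained (default 10; F exactly 10 is kept).
#' @return the filtered [summary_dataset()].
#' @export
filter_weak <- function(dataset, strengths, f_min = 10) {
  stopifnot(inherits(dataset, "summary_dataset"))
  weak <- strengths$snp[strengths$f_stat < f_min]
  out <- dataset
  out$records <- dataset$records[!dataset$records$snp %in% weak, , drop = FALSE]
  rownames(out$records) <- NULL
  if (nrow(out$records) == 0) {
    message("All instruments weak (F < ", f_min, ") for ", dataset$trait_id)
  }
  out
}

#' Harmonize exposure and outcome alleles
#'
#' Intersects the two datasets on SNP id and aligns the outcome association
#' to the exposure's effect allele. Identical alleles pass unchanged; swapped
#' labels negate the outcome beta and reflect its EAF; complementary-strand
#' coding is relabelled first. Palindromic SNPs (A/T or C/G) cannot be
#' resolved by labels: when either trait's EAF lies strictly inside the
#' intermediate window they are excluded, otherwise alignment uses EAF
#' concordance (frequencies on opposite sides of 0.5 indicate a swap).
#' Irreconcilable allele pairs are excluded. Every exclusion carries a
#' reason code.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param palindrome_window numeric length-2: the intermediate-EAF exclusion
#'   window, default `c(0.42, 0.58)` (the symmetric reading of the usual
#'   "EAF > 0.42" palindrome rule).
#' @return an object of class `mr_harmonized`: list with `instruments` (one
#'   row per aligned SNP: exposure and outcome beta/se/eaf on the shared
#'   effect allele, per-trait sample sizes, and the `action` taken) and
#'   `exclusions` (snp, stage, reason).
#' @export
harmonize <- function(exposure, outcome, palindrome_window = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"),
            length(palindrome_window) == 2,
            palindrome_window[1] < palindrome_window[2])
  ex <- exposure$records
  out <- outcome$records
  shared <- intersect(ex$snp, out$snp)
  ex <- ex[match(shared, ex$snp), , drop = FALSE]
  ou <- out[match(shared, out$snp), , drop = FALSE]

  n <- length(shared)
  action <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  o_ea <- ou$effect_allele
  o_oa <- ou$other_allele

  pal <- is_palindromic_pair(ex$effect_allele, ex$other_allele)
  same_set <- (o_ea == ex$effect_allele & o_oa == ex$other_allele) |
              (o_ea == ex$other_allele & o_oa == ex$effect_allele)
  flip_set <- (flip_strand(o_ea) == ex$effect_allele & flip_strand(o_oa) == ex$other_allele) |
              (flip_strand(o_ea) == ex$other_allele & flip_strand(o_oa) == ex$effect_allele)

  for (i in seq_len(n)) {
    if (pal[i]) {
      if (!same_set[i]) { reason[i] <- "allele_mismatch"; next }
      inter <- function(f) f > palindrome_window[1] & f < palindrome_window[2]
      if (inter(ex$eaf[i]) || inter(eaf_out[i])) {
        reason[i] <- "palindromic_intermediate_eaf"
        next
      }
      swapped <- o_ea[i] == ex$other_allele[i]
      if (swapped) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      discordant <- (ex$eaf[i] - 0.5) * (eaf_out[i] - 0.5) < 0
      if (discordant) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      action[i] <- if (swapped && discordant) "swapped_and_flipped"
                   else if (swapped) "swapped"
                   else if (discordant) "strand_flipped"
                   else "unchanged"
    } else {
      if (same_set[i]) {
        if (o_ea[i] == ex$effect_allele[i]) {
          action[i] <- "unchanged"
        } else {
          action[i] <- "swapped"
          beta_out[i] <- -beta_out[i]
          eaf_out[i] <- 1 - eaf_out[i]
        }
      } else if (flip_set[i]) {
        if (flip_strand(o_ea[i]) == ex$effect_allele[i]) {
          action[i] <- "strand_flipped"
        } else {
          action[i] <- "swapped_and_flipped"
          beta_out[i] <- -beta_out[i]
          eaf_out[i] <- 1 - eaf_out[i]
        }
      } else {
        reason[i] <- "allele_mismatch"
      }
    }
  }

  kept <- is.na(reason)
  instruments <- data.frame(
    snp = shared[kept],
    chr = ex$chr[kept], pos = ex$pos[kept],
    effect_allele = ex$effect_allele[kept],
    other_allele = ex$other_allele[kept],
    beta_exp = ex$beta[kept], se_exp = ex$se[kept], eaf_exp = ex$eaf[kept],
    beta_out = beta_out[kept], se_out = ou$se[kept], eaf_out = eaf_out[kept],
    n_exp = ex$n[kept], n_out = ou$n[kept],
    action = action[kept],
    stringsAsFactors = FALSE)
  exclusions <- data.frame(snp = shared[!kept],
                           stage = rep("harmonize", sum(!kept)),
                           reason = reason[!kept], stringsAsFactors = FALSE)
  structure(list(instruments = instruments, exclusions = exclusions,
                 exposure_id = exposure$trait_id,
                 outcome_id = outcome$trait_id),
            class = "mr_harmonized")
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("<mr_harmonized> %s -> %s: %d instruments, %d excluded\n",
              x$exposure_id, x$outcome_id,
              nrow(x$instruments), nrow(x$exclusions)))
  invisible(x)
}

#' @export
as.data.frame.mr_harmonized <- function(x, ...) x$instruments
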