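# Orchestration: per-exposure analysis chain, forward/reverse screens,
# output tables and the run manifest.

#' Pipeline run configuration
#'
#' Thresholds and method settings for a screening run. Defaults follow the
#' conventional instrument-selection criteria for metabolite exposures:
#' p < 1e-5, LD r-squared 0.01 within 500 kb, F >= 10, IVW significance at
#' 0.05 and pathway significance at 0.1.
#'
#' @param p_threshold instrument p-value cutoff.
#' @param clump_r2 maximum pairwise LD r-squared.
#' @param clump_kb clumping window in kilobases.
#' @param f_min minimum instrument F-statistic retained.
#' @param alpha significance level for IVW, sensitivity and meta gates.
#' @param pathway_alpha significance threshold for pathway ORA.
#' @param palindrome_window intermediate-EAF window for palindrome
#'   exclusion.
#' @param variance_model IVW variance model.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param presso_n_sim MR-PRESSO simulations.
#' @param seed integer seed; required for reproducible stochastic steps.
#' @return object of class `run_config`.
#' @export
run_config <- function(p_threshold = 1e-5, clump_r2 = 0.01, clump_kb = 500,
                       f_min = 10, alpha = 0.05, pathway_alpha = 0.1,
                       palindrome_window = c(0.42, 0.58),
                       variance_model = "multiplicative_random",
                       n_boot = 1000, presso_n_sim = 1000, seed = 1L) {
  stopifnot(p_threshold >= 0, p_threshold <= 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_kb > 0, f_min >= 0,
            alpha > 0, alpha < 1, pathway_alpha > 0, pathway_alpha < 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min, alpha = alpha,
                 pathway_alpha = pathway_alpha,
                 palindrome_window = palindrome_window,
                 variance_model = variance_model, n_boot = n_boot,
                 presso_n_sim = presso_n_sim, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  do.call(run_config, vals[intersect(names(vals), known)])
}

#' Single exposure-outcome MR analysis
#'
#' The full per-pair chain: p-value selection, LD clumping, F filter, allele
#' harmonization, the five estimators and the sensitivity battery. Stage
#' counts are monotone non-increasing; a stage that empties the instrument
#' set short-circuits with a skip reason instead of failing.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param config a [run_config()].
#' @param ld optional [ld_table()].
#' @param seed seed for the stochastic steps (default `config$seed`).
#' @return list with `results` (MRResult rows), `sensitivity`, `loo`,
#'   `harmonized`, `counts`, `exclusions` and `skip` (NULL, or the reason
#'   the pair produced no instruments).
#' @export
mr_analysis <- function(exposure, outcome, config = run_config(), ld = NULL,
                        seed = config$seed) {
  counts <- c(input = n_records(exposure), threshold = 0L, clump = 0L,
              f_filter = 0L, harmonized = 0L)
  skip <- function(reason) {
    list(results = NULL, sensitivity = NULL, loo = NULL, harmonized = NULL,
         counts = counts, exclusions = NULL, skip = reason)
  }
  sel <- select_by_pvalue(exposure, config$p_threshold)
  counts["threshold"] <- n_records(sel)
  if (n_records(sel) == 0) return(skip("no_snp_passing_p_threshold"))
  cl <- clump(sel, ld = ld, r2_max = config$clump_r2,
              window_bp = config$clump_kb * 1000)
  counts["clump"] <- n_records(cl)
  strengths <- compute_f(cl)
  fs <- filter_weak(cl, strengths, f_min = config$f_min)
  counts["f_filter"] <- n_records(fs)
  if (n_records(fs) == 0) return(skip("all_instruments_weak"))
  h <- harmonize(fs, outcome, palindrome_window = config$palindrome_window)
  counts["harmonized"] <- nrow(h$instruments)
  if (nrow(h$instruments) == 0) return(skip("no_harmonizable_snps"))
  res <- run_all_methods(h, n_boot = config$n_boot, seed = seed,
                         variance_model = config$variance_model)
  sens <- if (nrow(h$instruments) >= 2) {
    sensitivity_report(h, n_sim = config$presso_n_sim,
                       seed = if (is.null(seed)) NULL else seed + 11L,
                       alpha = config$alpha)
  } else NULL
  loo <- if (nrow(h$instruments) >= 2) leave_one_out(h) else NULL
  list(results = res, sensitivity = sens, loo = loo, harmonized = h,
       counts = counts, exclusions = h$exclusions, skip = NULL)
}

# One verdict-table row for an exposure.
verdict_row <- function(name, v, ivw) {
  data.frame(exposure = name,
             n_snp = ivw$n_snp, beta = ivw$beta, se = ivw$se, or = ivw$or,
             ci_low = ivw$or_low, ci_high = ivw$or_high, pval = ivw$pval,
             ivw_significant = v$ivw_significant,
             directions_consistent = v$directions_consistent,
             sensitivity_pass = v$sensitivity_pass,
             replication_meta_significant = v$replication_meta_significant,
             classification = v$classification,
             stringsAsFactors = FALSE)
}

sensitivity_row <- function(exposure, outcome, s) {
  data.frame(exposure = exposure, outcome = outcome,
             egger_intercept = s$egger_intercept,
             egger_intercept_pval = s$egger_intercept_pval,
             q_stat = s$q_stat, q_pval = s$q_pval,
             presso_global_pval = s$presso_global_pval,
             steiger_direction = s$steiger_direction,
             steiger_pval = s$steiger_pval,
             stringsAsFactors = FALSE)
}

#' Run the forward screen: many exposures against one outcome
#'
#' For each exposure: select, clump, F-filter, harmonize, run the five
#' estimators and the sensitivity battery; optionally repeat the IVW
#' analysis against a replication outcome and meta-analyse the two IVW
#' estimates; classify each exposure with [verdict()]; optionally run
#' pathway over-representation on the surviving exposures. Exposures with
#' no harmonizable SNPs are skipped with a recorded reason. Deterministic
#' under `config$seed`. A Benjamini-Hochberg column is added to the verdict
#' table for transparency but does not drive the classification (the screen
#' is gated on raw IVW p-values).
#'
#' @param exposures a [summary_dataset()] or a named list of them.
#' @param outcome the outcome [summary_dataset()].
#' @param config a [run_config()].
#' @param ld optional [ld_table()].
#' @param replication optional replication outcome dataset; triggers the
#'   meta-analysis gate.
#' @param pathways optional pathway sets from [read_pathways()].
#' @param compound_map optional named character vector mapping exposure
#'   names to compound IDs for the pathway universe; defaults to the
#'   exposure names themselves.
#' @param out_dir optional output directory; when given, all tables plus a
#'   `manifest.json` are written there.
#' @param direction label recorded on every results row.
#' @return object of class `mr_screen` with `results`, `sensitivity`,
#'   `loo`, `meta`, `verdicts`, `pathway`, `exclusions` and `manifest`.
#' @export
run_forward <- function(exposures, outcome, config = run_config(), ld = NULL,
                        replication = NULL, pathways = NULL,
                        compound_map = NULL, out_dir = NULL,
                        direction = "forward") {
  if (inherits(exposures, "summary_dataset")) {
    exposures <- stats::setNames(list(exposures), exposures$trait_id)
  }
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, function(e) e$trait_id, character(1))
  }
  results <- list(); sens_tab <- list(); loo_tab <- list()
  meta_tab <- list(); verd_tab <- list(); excl_tab <- list()
  stage_counts <- list(); skips <- list()

  for (i in seq_along(exposures)) {
    name <- names(exposures)[i]
    seed_i <- if (is.null(config$seed)) NULL else config$seed + 100L * i
    ana <- mr_analysis(exposures[[i]], outcome, config, ld, seed = seed_i)
    stage_counts[[name]] <- ana$counts
    if (!is.null(ana$skip)) {
      skips[[name]] <- ana$skip
      message("Skipping ", name, ": ", ana$skip)
      next
    }
    res <- cbind(exposure = name, outcome = outcome$trait_id,
                 direction = direction, ana$results,
                 stringsAsFactors = FALSE)
    results[[name]] <- res
    if (!is.null(ana$sensitivity)) {
      sens_tab[[name]] <- sensitivity_row(name, outcome$trait_id,
                                          ana$sensitivity)
    }
    if (!is.null(ana$loo)) {
      loo_tab[[name]] <- cbind(exposure = name, ana$loo,
                               stringsAsFactors = FALSE)
    }
    if (!is.null(ana$exclusions) && nrow(ana$exclusions) > 0) {
      excl_tab[[name]] <- cbind(exposure = name, ana$exclusions,
                                stringsAsFactors = FALSE)
    }

    meta <- NULL
    if (!is.null(replication)) {
      rep_ana <- mr_analysis(exposures[[i]], replication, config, ld,
                             seed = if (is.null(seed_i)) NULL else seed_i + 17L)
      if (is.null(rep_ana$skip)) {
        ivw_main <- ana$results[ana$results$method == "IVW", ]
        ivw_rep <- rep_ana$results[rep_ana$results$method == "IVW", ]
        meta <- meta_combine(c(ivw_main$beta, ivw_rep$beta),
                             c(ivw_main$se, ivw_rep$se))
        meta_tab[[name]] <- data.frame(
          exposure = name,
          beta_primary = ivw_main$beta, se_primary = ivw_main$se,
          beta_replication = ivw_rep$beta, se_replication = ivw_rep$se,
          beta_fixed = meta$beta_fixed, se_fixed = meta$se_fixed,
          pval_fixed = meta$pval_fixed,
          beta_random = meta$beta_random, se_random = meta$se_random,
          pval_random = meta$pval_random,
          tau2 = meta$tau2, i2 = meta$i2,
          stringsAsFactors = FALSE)
      } else {
        skips[[paste0(name, "_replication")]] <- rep_ana$skip
      }
    }

    v <- verdict(ana$results, ana$sensitivity, meta, alpha = config$alpha)
    verd_tab[[name]] <- verdict_row(name, v,
                                    ana$results[ana$results$method == "IVW", ])
  }

  verdicts <- if (length(verd_tab) > 0) do.call(rbind, verd_tab) else NULL
  if (!is.null(verdicts)) {
    verdicts$pval_bh <- stats::p.adjust(verdicts$pval, method = "BH")
    rownames(verdicts) <- NULL
  }

  pathway <- NULL
  if (!is.null(pathways) && !is.null(verdicts)) {
    map <- compound_map %||% stats::setNames(verdicts$exposure,
                                             verdicts$exposure)
    hit <- !verdicts$classification %in% c("not_significant",
                                           "false_positive_direction")
    selected <- unname(map[verdicts$exposure[hit]])
    universe <- unname(map[verdicts$exposure])
    if (length(selected) > 0) {
      pathway <- pathway_ora(selected, universe, pathways,
                             alpha = config$pathway_alpha)
    }
  }

  bind_or_null <- function(x) if (length(x) > 0) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  } else NULL
  manifest <- list(direction = direction,
                   config = unclass(config),
                   n_exposures = length(exposures),
                   stage_counts = stage_counts,
                   skips = skips)
  screen <- structure(list(results = bind_or_null(results),
                           sensitivity = bind_or_null(sens_tab),
                           loo = bind_or_null(loo_tab),
                           meta = bind_or_null(meta_tab),
                           verdicts = verdicts,
                           pathway = pathway,
                           exclusions = bind_or_null(excl_tab),
                           manifest = manifest),
                      class = "mr_screen")
  if (!is.null(out_dir)) write_screen(screen, out_dir)
  screen
}

#' Run the reverse analysis: the disease as exposure
#'
#' Identical instrument criteria and stage sequence as [run_forward()], with
#' the disease dataset as the exposure and each metabolite as an outcome;
#' results are labelled `direction = "reverse"`.
#'
#' @param exposure the disease [summary_dataset()] (the forward screen's
#'   outcome).
#' @param outcomes a [summary_dataset()] or named list of them (the forward
#'   screen's exposures).
#' @param config,ld,out_dir as in [run_forward()].
#' @return an `mr_screen` object (one row set per outcome; the `exposure`
#'   column of the verdict table carries the outcome trait labels prefixed
#'   by the disease, so forward and reverse outputs never collide).
#' @export
run_reverse <- function(exposure, outcomes, config = run_config(), ld = NULL,
                        out_dir = NULL) {
  if (inherits(outcomes, "summary_dataset")) {
    outcomes <- stats::setNames(list(outcomes), outcomes$trait_id)
  }
  screens <- lapply(seq_along(outcomes), function(i) {
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + 1000L * i
    run_forward(stats::setNames(list(exposure), exposure$trait_id),
                outcomes[[i]], cfg, ld = ld, direction = "reverse")
  })
  merge_field <- function(field) {
    parts <- Filter(Negate(is.null), lapply(seq_along(screens), function(i) {
      x <- screens[[i]][[field]]
      if (!is.null(x) && "outcome" %in% names(x) == FALSE && is.data.frame(x)) {
        x$outcome <- names(outcomes)[i]
      }
      x
    }))
    if (length(parts) > 0) { out <- do.call(rbind, parts); rownames(out) <- NULL; out } else NULL
  }
  manifest <- list(direction = "reverse", config = unclass(config),
                   stage_counts = lapply(screens, function(s) s$manifest$stage_counts),
                   skips = lapply(screens, function(s) s$manifest$skips))
  names(manifest$stage_counts) <- names(outcomes)
  names(manifest$skips) <- names(outcomes)
  screen <- structure(list(results = merge_field("results"),
                           sensitivity = merge_field("sensitivity"),
                           loo = merge_field("loo"),
                           meta = NULL,
                           verdicts = merge_field("verdicts"),
                           pathway = NULL,
                           exclusions = merge_field("exclusions"),
                           manifest = manifest),
                      class = "mr_screen")
  if (!is.null(out_dir)) write_screen(screen, out_dir)
  screen
}

#' Write every table of a screen to a directory
#'
#' Emits `results.tsv`, `sensitivity.tsv`, `loo.tsv`, `meta.tsv`,
#' `verdict.tsv`, `pathway.tsv`, `exclusions.tsv` (those that exist) and
#' `manifest.json`. Reruns under the same seed are byte-identical.
#'
#' @param screen an `mr_screen` object.
#' @param out_dir output directory, created if missing.
#' @export
write_screen <- function(screen, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c(results = "results.tsv", sensitivity = "sensitivity.tsv",
            loo = "loo.tsv", meta = "meta.tsv", verdicts = "verdict.tsv",
            pathway = "pathway.tsv", exclusions = "exclusions.tsv")
  written <- character(0)
  for (nm in names(tabs)) {
    if (!is.null(screen[[nm]])) {
      path <- file.path(out_dir, tabs[[nm]])
      utils::write.table(screen[[nm]], path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, tabs[[nm]])
    }
  }
  manifest <- screen$manifest
  manifest$files <- written
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mr_screen <- function(x, ...) {
  n_run <- if (is.null(x$verdicts)) 0L else nrow(x$verdicts)
  cat(sprintf("<mr_screen> %s: %d exposure(s) analysed, %d skipped\n",
              x$manifest$direction, n_run, length(x$manifest$skips)))
  if (!is.null(x$verdicts)) {
    print(x$verdicts[, c("exposure", "n_snp", "or", "pval", "classification")])
  }
  invisible(x)
}
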