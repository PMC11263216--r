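# Instrument selection, clumping, F-statistics and harmonization.

test_that("p-value selection is strict and order-preserving", {
  ds <- make_dataset(n = 3, beta = c(0.5, 0.1, 0.2), se = c(0.1, 0.025, 0.02))
  p <- ds$records$pval  # ~ {5.7e-7, 6.3e-5, 1e-23}
  sel <- select_by_pvalue(ds, 1e-5)
  expect_equal(sel$records$snp, ds$records$snp[p < 1e-5])
  expect_equal(select_by_pvalue(ds, 1)$records, ds$records)
  # boundary: p exactly at the threshold is excluded
  thr <- p[1]
  expect_false(ds$records$snp[1] %in% select_by_pvalue(ds, thr)$records$snp)
})

test_that("clumping keeps the best SNP and prunes in-window correlated ones", {
  rec <- make_records(n = 3, pos = c(1e6, 1.01e6, 200e6),
                      beta = c(0.5, 0.3, 0.3), se = c(0.05, 0.05, 0.05))
  ds <- summary_dataset(rec, "x")
  ld <- ld_table("rs001", "rs002", 0.5)
  kept <- clump(ds, ld)$records$snp
  expect_setequal(kept, c("rs001", "rs003"))
  # independent SNPs all survive (absent pairs count as r2 = 0)
  expect_equal(nrow(suppressWarnings(clump(ds, ld_table()))$records), 3)
  # missing positions are a configuration error
  rec$pos <- NA
  ds2 <- summary_dataset(rec, "x")
  expect_error(clump(ds2, ld), "position")
})

test_that("clumped set matches brute-force admissibility on a 5-SNP chain", {
  # chain with a known LD matrix: each dropped SNP must have r2 > 0.01 with
  # a better-p kept SNP in-window; every kept pair must be admissible
  rec <- make_records(n = 5, pos = c(1, 1.1, 1.2, 1.3, 20) * 1e6,
                      beta = c(0.50, 0.45, 0.40, 0.35, 0.30),
                      se = 0.05)
  ds <- summary_dataset(rec, "x")
  pairs <- t(combn(5, 2))
  r2 <- c(0.8, 0.005, 0.2, 0, 0.6, 0.003, 0, 0.9, 0, 0)  # (1,2)(1,3)...(4,5)
  ld <- ld_table(rec$snp[pairs[, 1]], rec$snp[pairs[, 2]], r2)
  kept <- clump(ds, ld)$records$snp
  lookup <- function(a, b) {
    i <- which((ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a))
    if (length(i) == 0) 0 else ld$r2[i]
  }
  in_window <- function(a, b) {
    abs(rec$pos[rec$snp == a] - rec$pos[rec$snp == b]) <= 5e5
  }
  dropped <- setdiff(rec$snp, kept)
  for (d in dropped) {
    better_kept <- kept[rec$pval[match(kept, rec$snp)] <= rec$pval[rec$snp == d]]
    expect_true(any(vapply(better_kept, function(k)
      in_window(k, d) && lookup(k, d) > 0.01, logical(1))),
      label = paste("dropped", d, "is justified"))
  }
  for (i in seq_along(kept)) for (j in seq_along(kept)) {
    if (i < j) {
      expect_false(in_window(kept[i], kept[j]) && lookup(kept[i], kept[j]) > 0.01)
    }
  }
})

test_that("absent in-window LD pairs warn once and count as r2 = 0", {
  rec <- make_records(n = 2, pos = c(1e6, 1.05e6), beta = c(0.5, 0.3),
                      se = 0.05)
  ds <- summary_dataset(rec, "x")
  expect_warning(kept <- clump(ds, ld_table()), "r2 = 0")
  expect_equal(nrow(kept$records), 2)
})

test_that("F-statistics follow (n-k-1) R2 / (k (1-R2))", {
  # beta=0.05, eaf=0.5, n=7824: R2 = 2*0.0025*0.25 = 0.00125,
  # F = 7822*0.00125/0.99875 ~ 9.79
  ds <- make_dataset(n = 1, beta = 0.05, eaf = 0.5, se = 0.011,
                     n_samples = 7824)
  f <- compute_f(ds)
  expect_equal(f$r2, 0.00125)
  expect_equal(f$f_stat, 7822 * 0.00125 / 0.99875, tolerance = 1e-12)
  expect_equal(round(f$f_stat, 2), 9.79)
  # n=1000, R2=0.01 -> F = 998*0.01/0.99
  ds2 <- make_dataset(n = 1, beta = sqrt(0.01 / (2 * 0.25)), eaf = 0.5,
                      se = 0.03, n_samples = 1000)
  expect_equal(compute_f(ds2)$f_stat, 998 * 0.01 / 0.99, tolerance = 1e-12)
  expect_equal(round(compute_f(ds2)$f_stat, 3), 10.081)
})

test_that("F is monotone in R2 and in n, and beta=0 gives F=0", {
  base <- function(beta, n) {
    compute_f(make_dataset(n = 1, beta = beta, eaf = 0.3, se = 0.02,
                           n_samples = n))$f_stat
  }
  betas <- seq(0.02, 0.4, length.out = 10)
  expect_true(all(diff(vapply(betas, base, numeric(1), n = 5000)) > 0))
  ns <- seq(1000, 50000, length.out = 10)
  expect_true(all(diff(vapply(ns, function(n) base(0.1, n), numeric(1))) > 0))
  suppressWarnings(
    expect_equal(base(0, 5000), 0))
})

test_that("weak-instrument filter drops F < 10 strictly", {
  ds <- make_dataset(n = 3, beta = c(0.04, 0.08, 0.2), eaf = 0.5,
                     se = 0.02, n_samples = 7000)
  f <- compute_f(ds)
  # engineer strengths around the boundary explicitly
  f$f_stat <- c(9.99, 10, 12)
  kept <- filter_weak(ds, f, f_min = 10)
  expect_setequal(kept$records$snp, ds$records$snp[2:3])
  f$f_stat <- rep(5, 3)
  expect_message(out <- filter_weak(ds, f), "weak")
  expect_equal(n_records(out), 0)
})

make_pair_datasets <- function(exp_rec, out_rec) {
  list(exposure = summary_dataset(exp_rec, "exp"),
       outcome = summary_dataset(out_rec, "out", "binary"))
}

test_that("harmonization handles identical, swapped and flipped alleles", {
  exp_rec <- make_records(n = 4, effect_allele = c("A", "A", "A", "C"),
                          other_allele = c("G", "G", "G", "A"),
                          eaf = 0.3, beta = 0.1, se = 0.02)
  out_rec <- make_records(n = 4,
                          effect_allele = c("A", "G", "T", "T"),
                          other_allele  = c("G", "A", "C", "G"),
                          eaf = c(0.3, 0.7, 0.3, 0.3),
                          beta = 0.05, se = 0.01)
  d <- make_pair_datasets(exp_rec, out_rec)
  h <- harmonize(d$exposure, d$outcome)
  expect_equal(h$instruments$action,
               c("unchanged", "swapped", "strand_flipped", "swapped_and_flipped"))
  expect_equal(h$instruments$beta_out, c(0.05, -0.05, 0.05, -0.05))
  expect_equal(h$instruments$eaf_out, c(0.3, 0.3, 0.3, 0.7))
})

test_that("palindromic SNPs with intermediate EAF are excluded with a reason", {
  exp_rec <- make_records(n = 3, effect_allele = "A", other_allele = "T",
                          eaf = c(0.50, 0.30, 0.43), beta = 0.1, se = 0.02)
  out_rec <- make_records(n = 3, effect_allele = "A", other_allele = "T",
                          eaf = c(0.50, 0.30, 0.43), beta = 0.05, se = 0.01)
  d <- make_pair_datasets(exp_rec, out_rec)
  h <- harmonize(d$exposure, d$outcome)
  expect_setequal(h$exclusions$snp, c("rs001", "rs003"))
  expect_true(all(h$exclusions$reason == "palindromic_intermediate_eaf"))
  expect_equal(h$instruments$snp, "rs002")
  expect_equal(h$instruments$action, "unchanged")
})

test_that("palindromic SNPs align by EAF concordance outside the window", {
  # outcome EAF on the opposite side of 0.5: treated as swapped
  exp_rec <- make_records(n = 1, effect_allele = "C", other_allele = "G",
                          eaf = 0.2, beta = 0.1, se = 0.02)
  out_rec <- make_records(n = 1, effect_allele = "C", other_allele = "G",
                          eaf = 0.8, beta = 0.05, se = 0.01)
  d <- make_pair_datasets(exp_rec, out_rec)
  h <- harmonize(d$exposure, d$outcome)
  expect_equal(h$instruments$beta_out, -0.05)
  expect_equal(h$instruments$eaf_out, 0.2)
})

test_that("irreconcilable alleles are excluded with reason allele_mismatch", {
  exp_rec <- make_records(n = 1, effect_allele = "A", other_allele = "G")
  out_rec <- make_records(n = 1, effect_allele = "A", other_allele = "C",
                          beta = 0.05, se = 0.01)
  d <- make_pair_datasets(exp_rec, out_rec)
  h <- harmonize(d$exposure, d$outcome)
  expect_equal(nrow(h$instruments), 0)
  expect_equal(h$exclusions$reason, "allele_mismatch")
})

test_that("harmonization is idempotent and invariant to outcome recoding", {
  cfg <- sim_config(n_snp = 30, theta = 0.2, allele_scramble_frac = 0.5,
                    seed = 11)
  pair <- simulate_pair(cfg)
  h1 <- harmonize(pair$exposure, pair$outcome)
  # rebuild the outcome from the harmonized columns and harmonize again
  out2 <- pair$outcome
  idx <- match(h1$instruments$snp, out2$records$snp)
  out2$records <- out2$records[idx, ]
  out2$records$effect_allele <- h1$instruments$effect_allele
  out2$records$other_allele <- h1$instruments$other_allele
  out2$records$beta <- h1$instruments$beta_out
  out2$records$eaf <- h1$instruments$eaf_out
  h2 <- harmonize(pair$exposure, out2)
  expect_true(all(h2$instruments$action == "unchanged"))
  keep <- setdiff(names(h1$instruments), "action")
  expect_equal(h2$instruments[keep], h1$instruments[keep])
  # flipping every outcome allele label and beta sign changes nothing
  out3 <- pair$outcome
  out3$records <- within(out3$records, {
    tmp <- effect_allele; effect_allele <- other_allele; other_allele <- tmp
    beta <- -beta; eaf <- 1 - eaf; rm(tmp)
  })
  out3$records <- out3$records[names(pair$outcome$records)]
  h3 <- harmonize(pair$exposure, out3)
  expect_equal(h3$instruments$snp, h1$instruments$snp)
  expect_equal(h3$instruments$beta_out, h1$instruments$beta_out)
  expect_equal(h3$instruments$eaf_out, h1$instruments$eaf_out, tolerance = 1e-12)
})
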