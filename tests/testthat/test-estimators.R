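# The five causal estimators and their oracle equivalences.

test_that("Wald ratios follow the first-order delta method", {
  r <- wald_ratio(beta_exp = 0.1, beta_out = 0.05, se_out = 0.02)
  expect_equal(r$theta, 0.5)
  expect_equal(r$se, 0.2)
  expect_equal(r$weight, 25)
  expect_equal(wald_ratio(0.1, 0, 0.02)$theta, 0)
  expect_error(wald_ratio(0, 0.05, 0.02), "degenerate")
})

test_that("IVW reduces to the symmetric mean and the single-ratio identity", {
  r <- ratio_df(c(0.4, 0.6), c(0.1, 0.1))
  fit <- mr_ivw(r, variance_model = "fixed")
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$se, sqrt(1 / 200))
  single <- ratio_df(0.37, 0.12)
  fit1 <- mr_ivw(single)
  expect_equal(fit1$beta, 0.37)
  expect_equal(fit1$se, 0.12)
  expect_error(mr_ivw(ratio_df(numeric(0), numeric(0))), "at least one")
})

test_that("IVW equals weighted least squares through the origin (oracle)", {
  set.seed(101)
  for (i in 1:100) {
    j <- sample(5:40, 1)
    d <- make_instruments(beta_exp = rnorm(j, 0, 0.3) + 0.2,
                          beta_out = rnorm(j, 0, 0.1),
                          se_out = runif(j, 0.01, 0.1))
    fit <- mr_ivw(d, variance_model = "fixed")
    oracle <- lm(beta_out ~ 0 + beta_exp, data = d, weights = 1 / d$se_out^2)
    expect_equal(fit$beta, unname(coef(oracle)), tolerance = 1e-10)
  }
})

test_that("multiplicative random-effects SE is the fixed SE scaled by Q", {
  r <- ratio_df(c(0.1, 0.9, 0.5, 0.2), rep(0.05, 4))
  q <- cochran_q(r)
  fixed <- mr_ivw(r, variance_model = "fixed")
  mre <- mr_ivw(r, variance_model = "multiplicative_random")
  expect_equal(mre$se, fixed$se * sqrt(max(1, q$q_stat / 3)))
  expect_equal(mre$beta, fixed$beta)
})

test_that("Egger interpolates exactly through collinear points", {
  d <- make_instruments(beta_exp = c(0.1, 0.2, 0.3),
                        beta_out = 0.3 * c(0.1, 0.2, 0.3) + 0.01,
                        se_out = c(0.01, 0.02, 0.03))
  fit <- mr_egger(d)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$egger_intercept, 0.01, tolerance = 1e-12)
  expect_equal(attr(fit, "rss"), 0, tolerance = 1e-20)
  expect_error(mr_egger(d[1:2, ]), "at least 3")
  d$beta_exp <- 0.2
  expect_error(mr_egger(d), "singular")
})

test_that("Egger slope and intercept match the weighted-regression oracle", {
  set.seed(202)
  for (i in 1:100) {
    j <- sample(5:40, 1)
    d <- make_instruments(beta_exp = runif(j, 0.05, 0.5),
                          beta_out = rnorm(j, 0, 0.1),
                          se_out = runif(j, 0.01, 0.1))
    fit <- mr_egger(d)
    oracle <- lm(beta_out ~ beta_exp, data = d, weights = 1 / d$se_out^2)
    expect_equal(fit$beta, unname(coef(oracle)[2]), tolerance = 1e-10)
    expect_equal(fit$egger_intercept, unname(coef(oracle)[1]), tolerance = 1e-10)
    sm <- summary(oracle)
    infl <- max(1, sm$sigma^2) / sm$sigma^2
    expect_equal(fit$se, sm$coefficients[2, 2] * sqrt(infl), tolerance = 1e-8)
  }
})

test_that("Egger orients instruments to positive exposure betas", {
  set.seed(7)
  d <- make_instruments(beta_exp = c(-0.2, 0.3, -0.4, 0.25),
                        beta_out = rnorm(4, 0, 0.05),
                        se_out = rep(0.02, 4))
  d2 <- d
  d2$beta_exp <- abs(d$beta_exp)
  d2$beta_out <- d$beta_out * sign(d$beta_exp)
  expect_equal(mr_egger(d)$beta, mr_egger(d2)$beta)
  expect_equal(mr_egger(d)$egger_intercept, mr_egger(d2)$egger_intercept)
})

test_that("Egger recovers planted directional pleiotropy", {
  set.seed(303)
  j <- 100
  bx <- runif(j, 0.2, 0.5)
  by <- 0.3 * bx + rnorm(j, 0.05, 0.01)  # directional pleiotropy mean 0.05
  d <- make_instruments(bx, by, se_out = rep(0.01, j))
  fit <- mr_egger(d)
  expect_lt(abs(fit$egger_intercept - 0.05), 3 * fit$egger_intercept_se)
})

test_that("weighted median matches the sample median and the weight-share limit", {
  r <- ratio_df(c(0.1, 0.5, 0.9), rep(0.1, 3))
  expect_equal(mr_weighted_median(r, n_boot = 50, seed = 1)$beta, 0.5)
  # one ratio carries >50% of the weight: estimate approaches it
  r2 <- ratio_df(c(0.1, 0.5, 2), c(0.4, 0.4, 0.01))
  expect_equal(mr_weighted_median(r2, n_boot = 50, seed = 1)$beta, 2,
               tolerance = 0.01)
  expect_error(mr_weighted_median(r[1:2, ]), "at least 3")
})

test_that("weighted median equals a brute-force weighted quantile oracle", {
  # oracle: evaluate the interpolated quantile function at q = 0.5 directly
  wq_oracle <- function(theta, w) {
    ord <- order(theta)
    th <- theta[ord]; w <- w[ord]
    s <- (cumsum(w) - w / 2) / sum(w)
    if (0.5 <= s[1]) return(th[1])
    if (0.5 >= s[length(s)]) return(th[length(th)])
    i <- max(which(s <= 0.5))
    th[i] + (th[i + 1] - th[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
  }
  set.seed(404)
  for (i in 1:50) {
    j <- sample(3:30, 1)
    theta <- rnorm(j)
    se <- runif(j, 0.05, 1)
    r <- ratio_df(theta, se)
    expect_equal(mr_weighted_median(r, n_boot = 2, seed = 1)$beta,
                 wq_oracle(theta, 1 / se^2), tolerance = 1e-12)
  }
})

test_that("mode estimators find the taller mode and handle degeneracy", {
  r <- ratio_df(rep(0.7, 4), rep(0.1, 4))
  fit <- mr_mode(r, n_boot = 10, seed = 1)
  expect_equal(fit$beta, 0.7)
  expect_equal(fit$se, 0)
  r2 <- ratio_df(c(0, 0, 0, 1), rep(0.05, 4))
  expect_lt(abs(mr_mode(r2, n_boot = 10, seed = 1)$beta), 0.1)
})

test_that("mode grid argmax matches a 10x finer grid within one coarse step", {
  set.seed(505)
  for (i in 1:20) {
    j <- sample(5:30, 1)
    theta <- rnorm(j)
    se <- runif(j, 0.05, 0.5)
    r <- ratio_df(theta, se)
    fit <- mr_mode(r, weighted = TRUE, n_boot = 2, seed = 1)
    bw <- 0.9 * min(sd(theta), IQR(theta) / 1.349) * j^(-1 / 5)
    grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw,
                length.out = 5120)
    w <- (1 / se^2); w <- w / sum(w)
    dens <- colSums(w * dnorm(outer(theta, grid, "-") / bw))
    coarse_step <- (max(theta) - min(theta) + 6 * bw) / 511
    expect_lt(abs(fit$beta - grid[which.max(dens)]), coarse_step + 1e-12)
  }
})

test_that("run_all_methods yields five results, skips below minimums, and is deterministic", {
  cfg <- sim_config(n_snp = 26, theta = 0.2, palindrome_frac = 0, seed = 21)
  pair <- simulate_pair(cfg)
  h <- harmonize(pair$exposure, pair$outcome)
  res <- run_all_methods(h, n_boot = 100, seed = 9)
  expect_equal(res$method,
               c("IVW", "MR-Egger", "weighted_median", "simple_mode",
                 "weighted_mode"))
  expect_true(all(res$n_snp == 26))
  res2 <- run_all_methods(h, n_boot = 100, seed = 9)
  expect_identical(res, res2)
  two <- h$instruments[1:2, ]
  expect_message(res3 <- run_all_methods(two, n_boot = 10, seed = 1),
                 "skipping")
  expect_equal(res3$method, "IVW")
})

test_that("estimates are scale- and sign-equivariant", {
  cfg <- sim_config(n_snp = 20, theta = 0.25, palindrome_frac = 0,
                    allele_scramble_frac = 0, seed = 31)
  pair <- simulate_pair(cfg)
  d <- harmonize(pair$exposure, pair$outcome)$instruments
  base <- run_all_methods(d, n_boot = 50, seed = 4)
  scaled <- d
  scaled$beta_exp <- 2 * d$beta_exp
  scaled$se_exp <- 2 * d$se_exp
  res_scaled <- run_all_methods(scaled, n_boot = 50, seed = 4)
  expect_equal(res_scaled$beta, base$beta / 2, tolerance = 1e-8)
  neg <- d
  neg$beta_out <- -d$beta_out
  res_neg <- run_all_methods(neg, n_boot = 50, seed = 4)
  expect_equal(res_neg$beta, -base$beta, tolerance = 1e-8)
})

test_that("all five estimators recover the causal effect without pleiotropy", {
  set.seed(606)
  reps <- 60
  ests <- matrix(NA_real_, reps, 5)
  for (k in seq_len(reps)) {
    cfg <- sim_config(n_snp = 50, theta = 0.3, n_exp = 8000, n_out = 1e5,
                      palindrome_frac = 0, allele_scramble_frac = 0,
                      seed = 7000 + k)
    pair <- simulate_pair(cfg)
    h <- harmonize(pair$exposure, pair$outcome)
    res <- run_all_methods(h, n_boot = 30, seed = k)
    ests[k, ] <- res$beta
  }
  for (m in 1:5) {
    mc_sd <- sd(ests[, m])
    expect_lt(abs(mean(ests[, m]) - 0.3), 3 * mc_sd)
  }
})
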