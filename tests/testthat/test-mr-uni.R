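# Univariable estimators against independent oracles and known truth.

test_that("Wald ratios follow the delta method", {
  wr <- wald_ratio(0.4, 0.02, 0.2, 0.1)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$ratio_se, 0.25)
  expect_equal(wald_ratio(1, 0.01, 0, 0.1)$ratio, 0)
  expect_equal(wald_ratio(1, 0.01, 0, 0.1)$ratio_se, 0.1)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.1), "degenerate")
  # simulation oracle: Monte-Carlo SD of the ratio matches se_y/|beta_x|
  set.seed(1)
  n <- 1e5
  ratios <- rnorm(n, 0.2, 0.1) / rnorm(n, 0.4, 0.02)
  expect_lt(abs(sd(ratios) - 0.25) / 0.25, 0.03)
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(2)
  h <- make_h(bx = c(0.1, 0.2, 0.15, 0.3, 0.25),
              by = c(0.05, 0.11, 0.07, 0.14, 0.13),
              sx = rep(0.01, 5), sy = c(0.05, 0.04, 0.06, 0.05, 0.03))
  est <- mr_ivw(h)
  v <- h$variants
  ora <- wls_oracle(matrix(v$beta_x), v$beta_y, 1 / v$se_y^2)
  expect_equal(est$estimate, ora$coef, tolerance = 1e-10)
  phi <- max(1, ora$rss / 4)
  expect_equal(est$se, sqrt(ora$cov[1, 1] * phi), tolerance = 1e-10)
  expect_equal(est$Q, ora$rss, tolerance = 1e-10)
})

test_that("two identical ratios give a degenerate, dispersion-free IVW", {
  h <- make_h(bx = c(0.1, 0.2), by = c(0.05, 0.10))
  est <- mr_ivw(h)
  expect_equal(est$estimate, 0.5)
  expect_equal(est$Q, 0)
  expect_equal(est$dispersion, 1)
  expect_error(mr_ivw(make_h(0.1, 0.05)), "at least 2")
})

test_that("the dispersion floor keeps the IVW SE at or above fixed effects", {
  for (i in 1:20) {
    s <- simulate_harmonized(m_snps = 15, theta = 0.1, pi_invalid = 0.2,
                             pleio_mean = 0, pleio_sd = 0.05,
                             seed = 300 + i)
    est <- mr_ivw(s$h)
    se_fixed <- 1 / sqrt(sum(s$h$variants$beta_x^2 / s$h$variants$se_y^2))
    expect_gte(est$se, se_fixed - 1e-12)
  }
})

test_that("MR-Egger matches closed-form weighted regression and exact fits", {
  # exact-fit case: data on beta_y = 0.1 + 0.5 * beta_x
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3, 0.35)
  h <- make_h(bx, 0.1 + 0.5 * bx)
  est <- mr_egger(h)
  expect_equal(est$estimate, 0.5, tolerance = 1e-9)
  expect_equal(est$intercept, 0.1, tolerance = 1e-9)
  expect_equal(est$Q, 0, tolerance = 1e-12)

  # closed-form oracle on a noisy 6-variant fixture
  set.seed(3)
  by <- 0.1 + 0.5 * bx + rnorm(6, 0, 0.05)
  h2 <- make_h(bx, by)
  est2 <- mr_egger(h2)
  ora <- wls_oracle(cbind(1, bx), by, rep(1 / 0.05^2, 6))
  expect_equal(est2$estimate, ora$coef[2], tolerance = 1e-10)
  expect_equal(est2$intercept, ora$coef[1], tolerance = 1e-10)
  scale <- max(1, sqrt(ora$rss / 4))
  expect_equal(est2$se, sqrt(ora$cov[2, 2]) * scale, tolerance = 1e-10)
  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("the Egger intercept recovers planted directional pleiotropy", {
  # instruments restricted to genome-wide significance, as in the real
  # pipeline: borderline variants whose observed effect sign could flip
  # would otherwise dilute the intercept
  reps <- 500
  ints <- vapply(seq_len(reps), function(i) {
    s <- simulate_harmonized(m_snps = 40, theta = 0.2, pi_invalid = 1,
                             pleio_mean = 0.05, pleio_sd = 0.02,
                             seed = 400 + i, exposure_increasing = TRUE)
    h <- s$h
    keep <- 2 * pnorm(-abs(h$variants$beta_x / h$variants$se_x)) < 5e-8
    h$variants <- h$variants[keep, , drop = FALSE]
    mr_egger(h)$intercept
  }, 0)
  mc_se <- sd(ints) / sqrt(reps)
  expect_lt(abs(mean(ints) - 0.05), 2 * mc_se)
})

test_that("weighted median handles symmetric and constant-ratio cases", {
  h <- make_h(bx = c(1, 1, 1), by = c(1, 2, 3))
  expect_equal(mr_weighted_median(h, 50, seed = 1)$estimate, 2)
  # all ratios equal c: estimate c regardless of weights
  h2 <- make_h(bx = c(0.1, 0.2, 0.4), by = 0.7 * c(0.1, 0.2, 0.4),
               sy = c(0.02, 0.05, 0.08))
  expect_equal(mr_weighted_median(h2, 50, seed = 1)$estimate, 0.7)
})

test_that("weighted median equals a brute-force breakpoint search", {
  set.seed(4)
  bx <- runif(7, 0.1, 0.4)
  by <- 0.3 * bx + rnorm(7, 0, 0.04)
  sy <- runif(7, 0.03, 0.08)
  h <- make_h(bx, by, sy = sy)
  est <- mr_weighted_median(h, 50, seed = 1)$estimate
  # oracle: scan the weighted empirical CDF of ratios on a fine grid of
  # candidate breakpoints and interpolate where it crosses one half
  r <- by / bx; w <- (bx / sy)^2; w <- w / sum(w)
  ord <- order(r); r <- r[ord]; w <- w[ord]
  s <- cumsum(w) - w / 2
  j <- max(which(s < 0.5))
  oracle <- r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
  expect_equal(est, oracle, tolerance = 1e-12)
})

test_that("weighted median stays consistent under 40% invalid instruments", {
  # direct effects drawn directional on the outcome scale; with effect
  # alleles in their natural (sign-random) orientation the contamination
  # of the ratio estimates is sign-symmetric, so the median is
  # mean-unbiased while each realized IVW is dragged by its own draw of
  # invalid instruments
  reps <- 400
  out <- vapply(seq_len(reps), function(i) {
    s <- simulate_harmonized(m_snps = 40, theta = 0.3, pi_invalid = 0.4,
                             pleio_mean = 0.1, pleio_sd = 0.03,
                             seed = 500 + i)
    c(wm = mr_weighted_median(s$h, 100, seed = i)$estimate,
      ivw = mr_ivw(s$h)$estimate)
  }, c(wm = 0, ivw = 0))
  wm_mc_se <- sd(out["wm", ]) / sqrt(reps)
  expect_lt(abs(mean(out["wm", ]) - 0.3), 2 * wm_mc_se)
  # per-replicate IVW error clearly exceeds the weighted median's
  expect_gt(mean(abs(out["ivw", ] - 0.3)),
            2 * mean(abs(out["wm", ] - 0.3)))
})

test_that("contamination mixture agrees with a per-grid-point oracle", {
  set.seed(5)
  bx <- runif(5, 0.2, 0.4)
  by <- 0.4 * bx + rnorm(5, 0, 0.01)
  h <- make_h(bx, by, sy = rep(0.02, 5))
  grid <- seq(-0.5, 1.5, by = 0.005)
  est <- mr_conmix(h, psi = 0.3, grid = grid)
  # brute-force profile recomputation (second-order delta-method SEs)
  r <- by / bx
  rs <- sqrt(0.02^2 / bx^2 + by^2 * 0.01^2 / bx^4)
  prof <- vapply(grid, function(th) {
    sum(pmax(dnorm(r, th, rs, log = TRUE),
             dnorm(r, 0, sqrt(rs^2 + 0.3^2), log = TRUE)))
  }, 0)
  expect_equal(est$estimate, grid[which.max(prof)])
  inside <- prof >= max(prof) - qchisq(0.95, 1) / 2
  # reported bounds sit half a grid step beyond the inside region
  expect_equal(est$ci_low, min(grid[inside]) - 0.0025)
  expect_equal(est$ci_high, max(grid[inside]) + 0.0025)
  expect_equal(est$valid_fraction, 1)
})

test_that("a tight consensus yields that value with a single interval", {
  bx <- rep(0.3, 4)
  h <- make_h(bx, 0.4 * bx, sy = rep(0.003, 4))
  est <- mr_conmix(h)
  expect_equal(est$estimate, 0.4, tolerance = 0.01)
  expect_equal(est$valid_fraction, 1)
  expect_false(est$ci_disjoint)
})

test_that("two tight clusters produce a disjoint confidence set", {
  bx <- rep(0.3, 6)
  by <- c(rep(0, 3), rep(0.3, 3)) + c(-1, 0, 1, -1, 0, 1) * 1e-4
  h <- make_h(bx, by, sx = rep(1e-4, 6), sy = rep(0.003, 6))
  est <- mr_conmix(h, psi = 1, grid = seq(-0.5, 1.5, by = 0.002))
  expect_true(est$ci_disjoint)
  expect_gte(nrow(est$ci_intervals), 2)
})

test_that("MR-PRESSO flags a planted outlier and applies the p-value floor", {
  s <- simulate_harmonized(m_snps = 20, theta = 0.2, seed = 61)
  h <- s$h
  # plant one variant whose ratio is 10x the causal effect
  h$variants$beta_y[7] <- 2.0 * h$variants$beta_x[7]
  est <- mr_presso(h, n_sim = 500, seed = 9)
  expect_equal(est$outlier_ids, h$variants$variant_id[7])
  expect_equal(est$n_variants, 19)  # outlier-corrected IVW
  expect_lt(est$global_pval, 0.05)
  # clean data: the global p respects the 1/(n_sim+1) floor and is large
  est2 <- mr_presso(s$h, n_sim = 200, seed = 9)
  expect_gte(est2$global_pval, 1 / 201)
  expect_gt(est2$global_pval, 0.05)
  expect_length(est2$outlier_ids, 0)
  expect_error(mr_presso(make_h(c(1, 1, 1), c(1, 1, 1)), 100),
               "at least 4")
})

test_that("instrument strength follows its closed form and sums per variant", {
  # t = 2, n = 1000: F = 4, r2 = 4 / (4 + 998)
  h <- make_h(bx = 0.02 * 2, by = 0.01, sx = 0.02, sy = 0.05, n_x = 1000)
  st <- instrument_strength(h)
  expect_equal(st$per_variant$F, 4)
  expect_equal(st$per_variant$r2, 4 / (4 + 998))
  # k = 1: overall F reduces to r2 (n-2) / (1 - r2)
  r2 <- st$total_r2
  expect_equal(st$overall_F, r2 * (1000 - 2) / (1 - r2))

  s <- simulate_harmonized(m_snps = 10, theta = 0.1, seed = 71)
  st2 <- instrument_strength(s$h)
  t <- s$h$variants$beta_x / s$h$variants$se_x
  expect_equal(st2$total_r2, sum(t^2 / (t^2 + s$h$n_exposure - 2)),
               tolerance = 1e-12)
  expect_equal(st2$mean_F, mean(t^2), tolerance = 1e-12)
})

test_that("the Steiger filter flags outcome-first variants only", {
  # equal correlations: z = 0, never flagged
  h <- make_h(bx = 0.1, by = 0.1, sx = 0.01, sy = 0.01,
              n_x = 1e5, n_y = 1e5)
  st <- steiger_filter(h)
  expect_equal(st$result$z, 0, tolerance = 1e-12)
  expect_false(st$result$flagged)

  # outcome explains far more variance: flagged and removed
  h2 <- make_h(bx = c(0.004, 0.1), by = c(0.04, 0.01),
               sx = 0.003, sy = 0.003, n_x = 1e5, n_y = 1e5)
  st2 <- steiger_filter(h2)
  expect_true(st2$result$flagged[1])
  expect_false(st2$result$flagged[2])
  expect_equal(st2$h$variants$variant_id, "rs2")
  expect_true("steiger" %in% st2$h$dropped$reason)

  # z matches a direct Fisher-transform recomputation
  s <- simulate_harmonized(m_snps = 5, theta = 0.2, seed = 81)
  v <- s$h$variants
  res <- steiger_filter(s$h)$result
  tx <- v$beta_x / v$se_x; ty <- v$beta_y / v$se_y
  rx <- abs(tx) / sqrt(tx^2 + s$h$n_exposure - 2)
  ry <- abs(ty) / sqrt(ty^2 + s$h$n_outcome - 2)
  z <- (atanh(rx) - atanh(ry)) /
    sqrt(1 / (s$h$n_exposure - 3) + 1 / (s$h$n_outcome - 3))
  expect_equal(res$z, z, tolerance = 1e-12)
})

test_that("reverse MR equals the manually chained pipeline and recovers truth", {
  sim <- simulate_two_sample_gwas(gwas_sim_config(
    m_snps = 35, theta = 0.2, hx2 = 0.1, n_exposure = 32860,
    n_outcome = 115000, outcome_type = "continuous", seed = 91))
  est <- reverse_mr(sim$exposure, sim$outcome, sim$ld)
  ins <- substitute_proxies(select_instruments(sim$exposure, sim$ld),
                            sim$outcome, sim$ld)
  manual <- mr_ivw(harmonize(sim$exposure, sim$outcome, ins))
  expect_equal(est$estimate, manual$estimate)
  expect_equal(est$se, manual$se)
  expect_lt(abs(est$estimate - 0.2), 2 * est$se)
})

test_that("estimators are scale- and sign-equivariant", {
  s <- simulate_harmonized(m_snps = 25, theta = 0.25, seed = 101)
  h <- s$h
  # outcome rescaling by c rescales estimate and SE by c
  c_scale <- 3.7
  h_scaled <- h
  h_scaled$variants$beta_y <- h$variants$beta_y * c_scale
  h_scaled$variants$se_y <- h$variants$se_y * c_scale
  for (f in list(mr_ivw, mr_egger,
                 function(x) mr_weighted_median(x, 200, seed = 2))) {
    a <- f(h); b <- f(h_scaled)
    expect_equal(b$estimate, c_scale * a$estimate, tolerance = 1e-8)
    expect_equal(b$se, c_scale * a$se, tolerance = 0.2 * c_scale * a$se)
  }
  cm_a <- mr_conmix(h); cm_b <- mr_conmix(h_scaled)
  expect_equal(cm_b$estimate, c_scale * cm_a$estimate,
               tolerance = 2 * c_scale * cm_a$se)

  # flipping every exposure effect allele leaves estimates unchanged
  h_flip <- h
  h_flip$variants$beta_x <- -h$variants$beta_x
  h_flip$variants$beta_y <- -h$variants$beta_y
  h_flip$variants$eaf_x <- 1 - h$variants$eaf_x
  h_flip$variants$eaf_y <- 1 - h$variants$eaf_y
  expect_equal(mr_ivw(h_flip)$estimate, mr_ivw(h)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(h_flip)$estimate, mr_egger(h)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(h_flip, 200, seed = 2)$estimate,
               mr_weighted_median(h, 200, seed = 2)$estimate,
               tolerance = 1e-12)
})

test_that("all five estimators cover the truth on pleiotropy-free data", {
  # nominal 95% intervals from each estimator should cover a true effect
  # of 0.25 in at least 93% of clean replicates
  reps <- 1000
  cover <- matrix(FALSE, reps, 5,
                  dimnames = list(NULL, c("ivw", "egger", "median",
                                          "conmix", "presso")))
  for (i in seq_len(reps)) {
    s <- simulate_harmonized(m_snps = 25, theta = 0.25, seed = 60000 + i)
    ests <- list(
      ivw = mr_ivw(s$h),
      egger = mr_egger(s$h),
      median = mr_weighted_median(s$h, n_boot = 200, seed = i),
      conmix = mr_conmix(s$h),
      presso = mr_presso(s$h, n_sim = 200, seed = i))
    cover[i, ] <- vapply(ests, function(e) {
      e$ci_low <= 0.25 && 0.25 <= e$ci_high
    }, TRUE)
  }
  for (nm in colnames(cover)) {
    expect_gte(mean(cover[, nm]), 0.93)
  }
})
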