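# Multivariable estimators: closed-form oracles, univariable reductions,
# robustness, and conditional instrument strength.

sim_mvmr <- function(m = 30, theta = c(0.3, 0.4), pi_invalid = 0,
                     pleio_mean = 0, pleio_sd = 0, seed = 1,
                     oriented = FALSE, n1 = 115000, n2 = 462166) {
  # two exposures with independent variant effects; outcome combines both
  set.seed(seed)
  p <- runif(m, 0.05, 0.95)
  var_g <- 2 * p * (1 - p)
  b1 <- rnorm(m); b2 <- rnorm(m)
  if (oriented) b1 <- abs(b1)
  b1 <- b1 * sqrt(0.04 / sum(var_g * b1^2))
  b2 <- b2 * sqrt(0.02 / sum(var_g * b2^2))
  sx1 <- 1 / sqrt(var_g * n1)
  sx2 <- 1 / sqrt(var_g * n2)
  sy <- 1 / sqrt(var_g * 778614)
  n_inv <- ceiling(pi_invalid * m)
  alpha <- numeric(m)
  if (n_inv > 0) alpha[sample.int(m, n_inv)] <- rnorm(n_inv, pleio_mean,
                                                      pleio_sd)
  bx <- cbind(e1 = rnorm(m, b1, sx1), e2 = rnorm(m, b2, sx2))
  by <- rnorm(m, theta[1] * b1 + theta[2] * b2 + alpha, sy)
  list(m = mvmr_set(bx, cbind(e1 = sx1, e2 = sx2), by, sy,
                    sprintf("rs%d", 1:m),
                    n_exposure = c(e1 = 115000, e2 = 462166),
                    n_outcome = 778614, outcome_type = "binary"),
       truth = list(b1 = b1, b2 = b2, alpha = alpha))
}

test_that("multivariable IVW equals closed-form weighted least squares", {
  set.seed(10)
  bx <- cbind(runif(8, 0.1, 0.3), runif(8, -0.2, 0.2))
  by <- 0.3 * bx[, 1] + 0.5 * bx[, 2] + rnorm(8, 0, 0.03)
  sy <- runif(8, 0.03, 0.07)
  m <- make_m(bx, by, sy = sy)
  est <- mvmr_ivw(m)
  ora <- wls_oracle(bx, by, 1 / sy^2)
  expect_equal(unname(est$estimate), ora$coef, tolerance = 1e-10)
  scale <- max(1, sqrt(ora$rss / 6))
  expect_equal(unname(est$se), sqrt(diag(ora$cov)) * scale,
               tolerance = 1e-10)
  expect_equal(est$Q, ora$rss, tolerance = 1e-10)
})

test_that("single-exposure multivariable IVW reduces to univariable IVW", {
  s <- simulate_harmonized(m_snps = 15, theta = 0.3, seed = 12)
  v <- s$h$variants
  m1 <- mvmr_set(matrix(v$beta_x, ncol = 1), matrix(v$se_x, ncol = 1),
                 v$beta_y, v$se_y, v$variant_id,
                 n_exposure = s$h$n_exposure, n_outcome = s$h$n_outcome)
  uni <- mr_ivw(s$h)
  mv <- mvmr_ivw(m1)
  expect_equal(unname(mv$estimate), uni$estimate, tolerance = 1e-12)
  # dispersion scaling differs only through the k-1 vs k-p denominator
  se_fixed <- 1 / sqrt(sum(v$beta_x^2 / v$se_y^2))
  expect_equal(unname(mv$se),
               se_fixed * max(1, sqrt(mv$Q / (nrow(v) - 1))),
               tolerance = 1e-12)
})

test_that("multivariable IVW recovers both direct effects", {
  s <- sim_mvmr(m = 40, theta = c(0.3, 0), seed = 14)
  est <- mvmr_ivw(s$m)
  expect_lt(abs(est$estimate["e1"] - 0.3), 2 * est$se["e1"])
  expect_lt(abs(est$estimate["e2"] - 0), 2 * est$se["e2"])
})

test_that("multivariable Egger recovers an exact fit with planted intercept", {
  bx <- cbind(seq(0.1, 0.45, by = 0.05), c(0.2, -0.1, 0.15, 0.05, -0.2,
                                           0.1, 0, 0.25))
  by <- 0.05 + 0.3 * bx[, 1] + 0.5 * bx[, 2]
  m <- make_m(bx, by)
  est <- mvmr_egger(m)
  expect_equal(est$intercept, 0.05, tolerance = 1e-9)
  expect_equal(unname(est$estimate), c(0.3, 0.5), tolerance = 1e-9)
  expect_equal(est$Q, 0, tolerance = 1e-10)
})

test_that("Egger orientation does not change which slopes are found", {
  s <- sim_mvmr(m = 25, seed = 16)
  est1 <- mvmr_egger(s$m, primary = 1)
  # flipping rows by hand before fitting must give identical slopes
  sgn <- ifelse(s$m$beta_x[, 1] < 0, -1, 1)
  m2 <- mvmr_set(s$m$beta_x * sgn, s$m$se_x, s$m$beta_y * sgn, s$m$se_y,
                 s$m$variant_ids, s$m$n_exposure, s$m$n_outcome,
                 s$m$outcome_type)
  est2 <- mvmr_egger(m2, primary = 1)
  expect_equal(est1$estimate, est2$estimate, tolerance = 1e-12)
  expect_equal(est1$intercept, est2$intercept, tolerance = 1e-12)
})

test_that("the multivariable Egger intercept test is calibrated under no pleiotropy", {
  reps <- 400
  pv <- vapply(seq_len(reps), function(i) {
    s <- sim_mvmr(m = 30, seed = 2000 + i, oriented = TRUE)
    mvmr_egger(s$m)$intercept_pval
  }, 0)
  rej <- mean(pv < 0.05)
  expect_gte(rej, 0.028)
  expect_lte(rej, 0.072)
})

test_that("multivariable median solves exact-fit data and matches L1 geometry", {
  bx <- cbind(c(0.1, 0.2, 0.3, 0.4, 0.5), c(0.2, -0.1, 0.1, -0.2, 0.3))
  by <- 0.3 * bx[, 1] + 0.6 * bx[, 2]
  m <- make_m(bx, by)
  est <- mvmr_median(m, n_boot = 50, seed = 1)
  expect_equal(unname(est$estimate), c(0.3, 0.6), tolerance = 1e-6)
})

test_that("single-exposure multivariable median agrees with the weighted median", {
  s <- simulate_harmonized(m_snps = 25, theta = 0.3, seed = 18)
  v <- s$h$variants
  m1 <- mvmr_set(matrix(v$beta_x, ncol = 1), matrix(v$se_x, ncol = 1),
                 v$beta_y, v$se_y, v$variant_id,
                 n_exposure = s$h$n_exposure, n_outcome = s$h$n_outcome)
  mv <- mvmr_median(m1, n_boot = 200, seed = 3)
  uni <- mr_weighted_median(s$h, n_boot = 200, seed = 3)
  # different weighting conventions: agreement within bootstrap error
  expect_lt(abs(unname(mv$estimate) - uni$estimate),
            2 * sqrt(mv$se^2 + uni$se^2))
})

test_that("the Lasso limit of no penalty activity equals multivariable IVW", {
  s <- sim_mvmr(m = 20, seed = 20)
  est <- mvmr_lasso(s$m, lambda_grid = 1e6)  # huge penalty: all valid
  ivw <- mvmr_ivw(s$m)
  expect_equal(est$estimate, ivw$estimate, tolerance = 1e-10)
  expect_length(est$retained_variant_ids, 20)
})

test_that("the Lasso excludes a planted outlier and keeps the rest", {
  s <- sim_mvmr(m = 20, seed = 22)
  m <- s$m
  m$beta_y[5] <- m$beta_y[5] + 0.05  # ~30 outcome-SEs of direct effect
  est <- mvmr_lasso(m)
  expect_false("rs5" %in% est$retained_variant_ids)
  expect_gte(est$n_valid, 15)
  ivw_clean <- mvmr_ivw(mvmr_set(
    m$beta_x[-5, ], m$se_x[-5, ], m$beta_y[-5], m$se_y[-5],
    m$variant_ids[-5], m$n_exposure, m$n_outcome, m$outcome_type))
  expect_lt(abs(est$estimate["e1"] - ivw_clean$estimate["e1"]),
            2 * ivw_clean$se["e1"])
})

test_that("the Lasso recovers truth under 30% invalid instruments where IVW drifts", {
  # precise instruments isolate the contamination effect from
  # weak-instrument attenuation; direct effects are well separated from
  # the outcome noise so the penalty can identify them
  reps <- 200
  out <- vapply(seq_len(reps), function(i) {
    s <- sim_mvmr(m = 30, theta = c(0.3, 0.4), pi_invalid = 0.3,
                  pleio_mean = 0.08, pleio_sd = 0.02,
                  seed = 3000 + i, n1 = 1e6, n2 = 2e6)
    las <- tryCatch(mvmr_lasso(s$m), error = function(e) NULL)
    c(lasso = if (is.null(las)) NA_real_ else unname(las$estimate["e1"]),
      ivw = unname(mvmr_ivw(s$m)$estimate["e1"]))
  }, c(lasso = 0, ivw = 0))
  lasso_est <- out["lasso", !is.na(out["lasso", ])]
  mc_se <- sd(lasso_est) / sqrt(length(lasso_est))
  expect_lt(abs(mean(lasso_est) - 0.3), 2 * mc_se)
  # each realized IVW is dragged by its own draw of invalid instruments
  expect_gt(mean(abs(out["ivw", ] - 0.3)),
            3 * mean(abs(lasso_est - 0.3)))
})

test_that("conditional F behaves like marginal strength when exposures are orthogonal", {
  s <- sim_mvmr(m = 40, seed = 24)
  cf <- conditional_f(s$m)
  marg <- colMeans((s$m$beta_x / s$m$se_x)^2)
  expect_lt(abs(cf["e1"] - marg["e1"]) / marg["e1"], 0.15)
  expect_lt(abs(cf["e2"] - marg["e2"]) / marg["e2"], 0.15)
})

test_that("conditional F collapses for duplicated exposures and scales with n", {
  s <- sim_mvmr(m = 20, seed = 26)
  dup <- mvmr_set(cbind(a = s$m$beta_x[, 1], b = s$m$beta_x[, 1]),
                  cbind(a = s$m$se_x[, 1], b = s$m$se_x[, 1]),
                  s$m$beta_y, s$m$se_y, s$m$variant_ids,
                  s$m$n_exposure, s$m$n_outcome, s$m$outcome_type)
  cf_dup <- conditional_f(dup)
  expect_lt(max(cf_dup), 1e-10)

  # halving the exposure-side variance doubles the statistic
  half <- mvmr_set(s$m$beta_x, s$m$se_x / sqrt(2), s$m$beta_y, s$m$se_y,
                   s$m$variant_ids, s$m$n_exposure, s$m$n_outcome,
                   s$m$outcome_type)
  expect_equal(unname(conditional_f(half)),
               unname(2 * conditional_f(s$m)), tolerance = 1e-10)
})

test_that("adding a null exposure leaves the primary estimate essentially unchanged", {
  s <- sim_mvmr(m = 40, theta = c(0.3, 0), seed = 28)
  est2 <- mvmr_ivw(s$m)
  m1 <- mvmr_set(s$m$beta_x[, 1, drop = FALSE],
                 s$m$se_x[, 1, drop = FALSE], s$m$beta_y, s$m$se_y,
                 s$m$variant_ids, s$m$n_exposure[1], s$m$n_outcome,
                 s$m$outcome_type)
  est1 <- mvmr_ivw(m1)
  joint_se <- sqrt(est1$se^2 + est2$se["e1"]^2)
  expect_lt(abs(unname(est2$estimate["e1"]) - unname(est1$estimate)),
            2 * joint_se)
})
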