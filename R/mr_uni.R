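# Univariable two-sample MR: per-variant Wald ratios, the IVW primary
# analysis with a multiplicative random-effects dispersion floor, four
# robust estimators, instrument-strength and directionality diagnostics.

new_mr_estimate <- function(method, estimate, se, pval, n_variants,
                            outcome_type = "binary", ...) {
  ci <- z_ci(estimate, se)
  structure(c(list(method = method, estimate = estimate, se = se,
                   ci_low = ci[1], ci_high = ci[2], pval = pval,
                   n_variants = n_variants, outcome_type = outcome_type,
                   or = if (outcome_type == "binary") exp(estimate)
                        else NA_real_),
              list(...)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: estimate %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pval))
  if (!is.na(x$or)) cat(sprintf(", OR %.3f", x$or))
  cat(sprintf(" [k = %d]\n", x$n_variants))
  invisible(x)
}

#' Per-variant Wald ratio and first-order standard error
#'
#' The causal-effect estimate contributed by a single instrument:
#' `ratio = beta_y / beta_x`, with delta-method standard error
#' `se_y / |beta_x|` (exposure-side uncertainty ignored at first order, the
#' convention for strong instruments).
#'
#' @param beta_x,se_x Exposure effect and SE.
#' @param beta_y,se_y Outcome effect and SE.
#' @return List with `ratio` and `ratio_se` (vectorized).
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (any(beta_x == 0)) stop("degenerate instrument: beta_x == 0")
  list(ratio = beta_y / beta_x, ratio_se = se_y / abs(beta_x))
}

h_parts <- function(h) {
  v <- h$variants
  wr <- wald_ratio(v$beta_x, v$se_x, v$beta_y, v$se_y)
  list(bx = v$beta_x, sx = v$se_x, by = v$beta_y, sy = v$se_y,
       ratio = wr$ratio, ratio_se = wr$ratio_se,
       w = v$beta_x^2 / v$se_y^2, k = nrow(v), ids = v$variant_id)
}

#' Inverse-variance-weighted MR (primary analysis)
#'
#' Multiplicative random-effects IVW with an under-dispersion correction:
#' with weights `w_j = beta_x^2 / se_y^2` and Wald ratios `theta_j`, the
#' estimate is the weighted mean; Cochran's Q measures heterogeneity and
#' the dispersion `phi = max(1, Q / (k - 1))` scales the fixed-effect
#' standard error, never below it.
#'
#' @param h A [harmonized_set()].
#' @return An `mr_estimate` with `Q`, `Q_pval` and `dispersion`.
#' @export
mr_ivw <- function(h) {
  p <- h_parts(h)
  if (p$k < 2) stop("IVW needs at least 2 instruments")
  est <- sum(p$w * p$ratio) / sum(p$w)
  se_fixed <- 1 / sqrt(sum(p$w))
  Q <- sum(p$w * (p$ratio - est)^2)
  phi <- max(1, Q / (p$k - 1))
  se <- se_fixed * sqrt(phi)
  new_mr_estimate("ivw", est, se, z_pval(est, se), p$k, h$outcome_type,
                  Q = Q, Q_pval = stats::pchisq(Q, p$k - 1,
                                                lower.tail = FALSE),
                  dispersion = phi)
}

# weighted least squares with explicit design matrix; returns coef, cov
# (unscaled), weighted RSS
wls_fit <- function(X, y, w) {
  sw <- sqrt(w)
  Xs <- X * sw
  ys <- y * sw
  qr_x <- qr(Xs)
  if (qr_x$rank < ncol(X)) stop("collinear design in weighted regression")
  coef <- qr.coef(qr_x, ys)
  res <- ys - Xs %*% coef
  xtx_inv <- chol2inv(qr.R(qr_x))
  list(coef = as.numeric(coef), cov = xtx_inv,
       rss = sum(res^2))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept,
#' after orienting every variant so its exposure effect is non-negative
#' (required for the intercept to measure directional pleiotropy). Weights
#' are `1 / se_y^2`; standard errors are scaled by
#' `max(1, sqrt(RSS_w / (k - 2)))`. The intercept test probes horizontal
#' pleiotropy; the slope is the pleiotropy-adjusted causal effect.
#'
#' @param h A [harmonized_set()].
#' @return An `mr_estimate` with `intercept`, `intercept_se`,
#'   `intercept_pval`, `Q`, `Q_pval`.
#' @export
mr_egger <- function(h) {
  p <- h_parts(h)
  if (p$k < 3) stop("MR-Egger needs at least 3 instruments")
  s <- ifelse(p$bx < 0, -1, 1)
  bx <- p$bx * s; by <- p$by * s
  if (stats::sd(bx) < 1e-12) stop("no spread in exposure effects")
  w <- 1 / p$sy^2
  fit <- wls_fit(cbind(1, bx), by, w)
  scale <- max(1, sqrt(fit$rss / (p$k - 2)))
  ses <- sqrt(diag(fit$cov)) * scale
  est <- fit$coef[2]; se <- ses[2]
  new_mr_estimate("mr_egger", est, se, z_pval(est, se), p$k,
                  h$outcome_type,
                  intercept = fit$coef[1], intercept_se = ses[1],
                  intercept_pval = z_pval(fit$coef[1], ses[1]),
                  Q = fit$rss,
                  Q_pval = stats::pchisq(fit$rss, p$k - 2,
                                         lower.tail = FALSE))
}

# weighted median of values x with weights w: order x ascending, cumulative
# midpoint positions s_j = cumsum(w_norm) - w_norm/2, linear interpolation
# at probability 0.5
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] <= 0.5) return(x[length(s)])
  j <- max(which(s < 0.5))
  x[j] + (x[j + 1] - x[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median MR
#'
#' Median of the Wald ratios under inverse-variance weights; consistent
#' when at least half the weight comes from valid instruments. The
#' standard error is a seeded parametric bootstrap, resampling exposure
#' and outcome effects from their normal sampling distributions.
#'
#' @param h A [harmonized_set()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  p <- h_parts(h)
  if (p$k < 3) stop("weighted median needs at least 3 instruments")
  w <- 1 / p$ratio_se^2
  est <- weighted_median_point(p$ratio, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(p$k, p$bx, p$sx)
      by <- stats::rnorm(p$k, p$by, p$sy)
      bx[bx == 0] <- 1e-12
      r <- by / bx
      rs <- p$sy / abs(bx)
      weighted_median_point(r, 1 / rs^2)
    }, 0)
  })
  se <- stats::sd(boots)
  new_mr_estimate("weighted_median", est, se, z_pval(est, se), p$k,
                  h$outcome_type, n_boot = n_boot)
}

conmix_profile <- function(ratio, ratio_se, psi, grid) {
  vapply(grid, function(theta) {
    lv <- stats::dnorm(ratio, theta, ratio_se, log = TRUE)
    li <- stats::dnorm(ratio, 0, sqrt(ratio_se^2 + psi^2), log = TRUE)
    sum(pmax(lv, li))
  }, 0)
}

#' Contamination-mixture MR
#'
#' Models each Wald ratio as coming from either a valid instrument
#' (`N(theta, ratio_se^2)`) or an invalid one (`N(0, ratio_se^2 + psi^2)`),
#' assigning each variant to the component with the larger likelihood, and
#' profiles the resulting log-likelihood over a grid of candidate causal
#' effects. The 95% confidence set is the grid region within
#' `qchisq(0.95, 1) / 2` of the maximum and may be a union of disjoint
#' intervals (multimodality is reported, not hidden).
#'
#' @param h A [harmonized_set()].
#' @param psi Scale of invalid effects; default `1.5 * sd(ratios)`.
#' @param grid Optional grid of causal-effect values; by default centred
#'   on the IVW estimate with half-width `6 * se`, widened until the
#'   maximum is interior, step `se / 10`.
#' @return An `mr_estimate` with `valid_fraction`, `ci_intervals` (matrix
#'   of disjoint interval bounds) and `ci_disjoint`.
#' @export
mr_conmix <- function(h, psi = NULL, grid = NULL) {
  p <- h_parts(h)
  if (p$k < 2) stop("contamination mixture needs at least 2 instruments")
  # the profile likelihood treats the ratio SE as the full uncertainty,
  # so the exposure-side noise term of the delta method cannot be
  # neglected here (it can in the weighting schemes): second-order SE
  p$ratio_se <- sqrt(p$sy^2 / p$bx^2 + p$by^2 * p$sx^2 / p$bx^4)
  psi <- psi %||% (1.5 * stats::sd(p$ratio))
  if (psi <= 0) psi <- max(p$ratio_se)  # degenerate consensus case
  if (is.null(grid)) {
    ivw <- mr_ivw(h)
    step <- ivw$se / 10
    width <- 6 * ivw$se
    for (tries in 1:12) {
      grid <- seq(ivw$estimate - width, ivw$estimate + width, by = step)
      prof <- conmix_profile(p$ratio, p$ratio_se, psi, grid)
      amax <- which.max(prof)
      if (amax > 1 && amax < length(grid)) break
      width <- width * 2
    }
    if (amax == 1 || amax == length(grid)) {
      stop("contamination-mixture maximum at grid boundary")
    }
  } else {
    prof <- conmix_profile(p$ratio, p$ratio_se, psi, grid)
    amax <- which.max(prof)
    if (amax == 1 || amax == length(grid)) {
      warning("contamination-mixture maximum at grid boundary")
    }
  }
  est <- grid[amax]
  inside <- prof >= prof[amax] - stats::qchisq(0.95, 1) / 2
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # widen each interval by half a grid step: the true crossing of the
  # chi-square cutoff lies between the last inside and first outside
  # grid points
  half_step <- if (length(grid) > 1) (grid[2] - grid[1]) / 2 else 0
  iv <- cbind(grid[starts[runs$values]] - half_step,
              grid[ends[runs$values]] + half_step)
  ci_low <- min(iv[, 1]); ci_high <- max(iv[, 2])
  se <- (ci_high - ci_low) / (2 * stats::qnorm(0.975))
  lv <- stats::dnorm(p$ratio, est, p$ratio_se, log = TRUE)
  li <- stats::dnorm(p$ratio, 0, sqrt(p$ratio_se^2 + psi^2), log = TRUE)
  valid_fraction <- mean(lv >= li)
  # likelihood-ratio p against theta = 0
  ll0 <- conmix_profile(p$ratio, p$ratio_se, psi, 0)
  lr <- max(0, 2 * (prof[amax] - ll0))
  out <- new_mr_estimate("conmix", est, se,
                         stats::pchisq(lr, 1, lower.tail = FALSE), p$k,
                         h$outcome_type,
                         valid_fraction = valid_fraction, psi = psi,
                         ci_intervals = iv, ci_disjoint = nrow(iv) > 1)
  out$ci_low <- ci_low; out$ci_high <- ci_high
  out
}

presso_loo_theta <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  th <- by / bx
  s1 <- sum(w * th); s2 <- sum(w)
  (s1 - w * th) / (s2 - w)
}

#' MR-PRESSO global and outlier tests
#'
#' The observed residual sum of squares is
#' `sum_j (beta_y_j - theta_loo_j * beta_x_j)^2 / se_y_j^2`, each variant
#' measured against the leave-one-out IVW prediction. The null
#' distribution comes from `n_sim` parametric simulations
#' (`beta_x* ~ N(beta_x, se_x^2)`, `beta_y* ~ N(theta_loo * beta_x,
#' se_y^2)`); the global p-value is the empirical proportion of simulated
#' RSS at or above the observed one, floored at `1 / (n_sim + 1)`.
#' Per-variant outlier p-values are Bonferroni-adjusted across variants;
#' when outliers are flagged, the reported estimate is the IVW on the
#' remaining variants (outlier-corrected), otherwise the raw IVW.
#'
#' @param h A [harmonized_set()].
#' @param n_sim Parametric simulations (default 1000).
#' @param seed Seed.
#' @param outlier_alpha Significance level for flagging outliers
#'   (default 0.05, applied to the Bonferroni-adjusted p).
#' @return An `mr_estimate` with `global_rss`, `global_pval`,
#'   `outlier_ids`, `outlier_pvals`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = NULL, outlier_alpha = 0.05) {
  p <- h_parts(h)
  if (p$k < 4) stop("MR-PRESSO needs at least 4 instruments")
  th_loo <- presso_loo_theta(p$bx, p$by, p$sy)
  resid_obs <- (p$by - th_loo * p$bx)^2 / p$sy^2
  rss_obs <- sum(resid_obs)

  sims <- with_seed(seed, {
    bx_s <- matrix(stats::rnorm(p$k * n_sim, p$bx, p$sx), p$k, n_sim)
    by_s <- matrix(stats::rnorm(p$k * n_sim, th_loo * p$bx, p$sy),
                   p$k, n_sim)
    w_s <- bx_s^2 / p$sy^2
    th_s <- by_s / bx_s
    s1 <- colSums(w_s * th_s)
    s2 <- colSums(w_s)
    th_loo_s <- (rep(s1, each = p$k) - w_s * th_s) /
      (rep(s2, each = p$k) - w_s)
    resid_s <- (by_s - th_loo_s * bx_s)^2 / p$sy^2
    list(rss = colSums(resid_s), resid = resid_s)
  })
  global_pval <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  p_var <- (1 + rowSums(sims$resid >= resid_obs)) / (n_sim + 1)
  p_var_adj <- pmin(1, p_var * p$k)
  outliers <- p$ids[p_var_adj < outlier_alpha]

  if (length(outliers) > 0 && (p$k - length(outliers)) >= 2) {
    keep <- !(p$ids %in% outliers)
    h2 <- h
    h2$variants <- h$variants[keep, , drop = FALSE]
    base <- mr_ivw(h2)
  } else {
    base <- mr_ivw(h)
  }
  new_mr_estimate("mr_presso", base$estimate, base$se, base$pval,
                  base$n_variants, h$outcome_type,
                  Q = base$Q, Q_pval = base$Q_pval,
                  global_rss = rss_obs, global_pval = global_pval,
                  outlier_ids = outliers,
                  outlier_pvals = stats::setNames(p_var_adj, p$ids),
                  n_sim = n_sim)
}

#' Instrument strength: per-variant and overall F, variance explained
#'
#' `F_j = (beta_x_j / se_x_j)^2`; per-variant variance explained
#' `r2_j = t_j^2 / (t_j^2 + n - 2)`; total `r2` is their sum and the
#' overall F-statistic is `r2 (n - k - 1) / ((1 - r2) k)`.
#'
#' @param h A [harmonized_set()].
#' @return A `strength_summary`: list with `per_variant` (data frame of
#'   `variant_id`, `F`, `r2`), `mean_F`, `total_r2`, `overall_F`.
#' @export
instrument_strength <- function(h) {
  v <- h$variants
  n <- h$n_exposure
  k <- nrow(v)
  if (n <= k + 1) stop("exposure sample size too small for ", k,
                       " instruments")
  t <- v$beta_x / v$se_x
  Fj <- t^2
  r2j <- t^2 / (t^2 + n - 2)
  r2 <- sum(r2j)
  structure(list(per_variant = data.frame(variant_id = v$variant_id,
                                          F = Fj, r2 = r2j,
                                          stringsAsFactors = FALSE),
                 mean_F = mean(Fj), total_r2 = r2,
                 overall_F = r2 * (n - k - 1) / ((1 - r2) * k),
                 n_exposure = n, n_variants = k),
            class = "strength_summary")
}

#' @export
print.strength_summary <- function(x, ...) {
  cat(sprintf(
    "Instrument strength: k = %d, mean F = %.1f, r2 = %.3g%%, overall F = %.1f\n",
    x$n_variants, x$mean_F, 100 * x$total_r2, x$overall_F))
  invisible(x)
}

#' Steiger directionality filter
#'
#' Per variant, compares the variance explained in the exposure and the
#' outcome through the Fisher-transformed correlations implied by the
#' t-statistics (`r = t / sqrt(t^2 + n - 2)`); the two-sample z-statistic
#' `(atanh(r_x) - atanh(r_y)) / sqrt(1/(n_x - 3) + 1/(n_y - 3))` tests the
#' null of equal variance explained. Variants explaining significantly
#' more outcome than exposure variance (one-sided p < `alpha`) are flagged
#' and removed — a guard against reverse causation. For a binary outcome
#' the log-odds t-statistic is used directly (an approximation).
#'
#' @param h A [harmonized_set()].
#' @param alpha One-sided significance level (default 0.05).
#' @return List with `result` (per-variant data frame: `r2_exposure`,
#'   `r2_outcome`, `z`, `pval`, `flagged`; plus totals as attributes) and
#'   `h` (the filtered [harmonized_set()], flagged variants moved to
#'   `dropped` with reason `"steiger"`).
#' @export
steiger_filter <- function(h, alpha = 0.05) {
  v <- h$variants
  n_x <- h$n_exposure; n_y <- h$n_outcome
  if (n_x <= 3 || n_y <= 3) stop("sample sizes too small for Steiger test")
  t_x <- v$beta_x / v$se_x
  t_y <- v$beta_y / v$se_y
  r_x <- abs(t_x) / sqrt(t_x^2 + n_x - 2)
  r_y <- abs(t_y) / sqrt(t_y^2 + n_y - 2)
  z <- (atanh(r_x) - atanh(r_y)) /
    sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  pval <- stats::pnorm(z)  # one-sided: small when outcome r2 dominates
  flagged <- (r_y^2 > r_x^2) & (pval < alpha)
  result <- data.frame(variant_id = v$variant_id, r2_exposure = r_x^2,
                       r2_outcome = r_y^2, z = z, pval = pval,
                       flagged = flagged, stringsAsFactors = FALSE)
  h2 <- h
  h2$variants <- v[!flagged, , drop = FALSE]
  if (any(flagged)) {
    h2$dropped <- rbind(h2$dropped,
                        data.frame(variant_id = v$variant_id[flagged],
                                   reason = "steiger",
                                   stringsAsFactors = FALSE))
  }
  if (nrow(h2$variants) == 0) stop("Steiger filtering removed every variant")
  list(result = result, h = h2, n_flagged = sum(flagged))
}

#' Run all five univariable MR estimators
#'
#' @param h A [harmonized_set()].
#' @param n_boot Bootstrap resamples for the weighted median.
#' @param n_sim Simulations for MR-PRESSO.
#' @param seed Seed shared by the stochastic estimators.
#' @return Named list of `mr_estimate`s: `ivw`, `mr_egger`,
#'   `weighted_median`, `conmix`, `mr_presso`; estimators whose
#'   instrument-count preconditions fail are omitted.
#' @export
mr_all <- function(h, n_boot = 1000, n_sim = 1000, seed = NULL) {
  out <- list(ivw = mr_ivw(h))
  if (nrow(h$variants) >= 3) {
    out$mr_egger <- mr_egger(h)
    out$weighted_median <- mr_weighted_median(h, n_boot, seed)
  }
  out$conmix <- tryCatch(mr_conmix(h), error = function(e) NULL)
  if (nrow(h$variants) >= 4) {
    out$mr_presso <- mr_presso(h, n_sim, seed)
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Reverse MR: liver fat as exposure, a metabolite as outcome
#'
#' Full univariable pipeline — instrument selection, proxy substitution,
#' harmonization, IVW — with the continuous liver-fat trait as exposure.
#' Testing the reverse direction on the continuous trait avoids using a
#' binary diagnosis as an MR exposure.
#'
#' @param liver_fat [sumstat_table()] for liver fat (exposure side).
#' @param metabolite [sumstat_table()] for the metabolite (outcome side).
#' @param ld An [ld_matrix()].
#' @param p_threshold,clump_r2,clump_window_bp,exclude_regions Passed to
#'   [select_instruments()].
#' @param palindrome_eaf_limit Passed to [harmonize()].
#' @param proxy_r2 Passed to [substitute_proxies()].
#' @return The IVW `mr_estimate` with diagnostics.
#' @export
reverse_mr <- function(liver_fat, metabolite, ld, p_threshold = 5e-8,
                       clump_r2 = 0.01, clump_window_bp = 1e6,
                       exclude_regions = NULL,
                       palindrome_eaf_limit = 0.42, proxy_r2 = 0.8) {
  ins <- select_instruments(liver_fat, ld, p_threshold, clump_r2,
                            clump_window_bp, exclude_regions)
  ins <- substitute_proxies(ins, metabolite, ld, proxy_r2)
  h <- harmonize(liver_fat, metabolite, ins, palindrome_eaf_limit)
  mr_ivw(h)
}
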