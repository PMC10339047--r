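# Multivariable MR: direct effects of each exposure conditional on the
# others (here: a metabolic measure adjusted for waist circumference),
# with conditional instrument strength and robust variants.

new_mvmr_estimate <- function(method, m, coef, se, ...) {
  nm <- m$exposure_names
  ci_l <- coef - stats::qnorm(0.975) * se
  ci_h <- coef + stats::qnorm(0.975) * se
  structure(c(list(method = method,
                   exposures = nm,
                   estimate = stats::setNames(coef, nm),
                   se = stats::setNames(se, nm),
                   ci_low = stats::setNames(ci_l, nm),
                   ci_high = stats::setNames(ci_h, nm),
                   pval = stats::setNames(z_pval(coef, se), nm),
                   n_variants = length(m$beta_y),
                   outcome_type = m$outcome_type,
                   or = if (m$outcome_type == "binary")
                     stats::setNames(exp(coef), nm) else NULL),
              list(...)),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("%s (k = %d):\n", x$method, x$n_variants))
  for (nm in x$exposures) {
    cat(sprintf("  %s: %.4f (se %.4f), p = %.3g\n", nm, x$estimate[nm],
                x$se[nm], x$pval[nm]))
  }
  invisible(x)
}

#' Multivariable IVW (primary multivariable analysis)
#'
#' Weighted regression of the outcome effects on the matrix of exposure
#' effects, no intercept, weights `1 / se_y^2`. Standard errors are scaled
#' by `max(1, sqrt(Q / (k - p)))`, the multivariable analogue of the
#' multiplicative random-effects dispersion floor; Q is reported with its
#' chi-square p-value on `k - p` degrees of freedom.
#'
#' @param m An [mvmr_set()].
#' @return An `mvmr_estimate` with per-exposure estimates, `Q`, `Q_pval`.
#' @export
mvmr_ivw <- function(m) {
  stopifnot(inherits(m, "mvmr_set"))
  k <- length(m$beta_y); p <- ncol(m$beta_x)
  if (k <= p) stop("need more instruments than exposures")
  w <- 1 / m$se_y^2
  fit <- wls_fit(m$beta_x, m$beta_y, w)
  scale <- max(1, sqrt(fit$rss / (k - p)))
  se <- sqrt(diag(fit$cov)) * scale
  new_mvmr_estimate("mvmr_ivw", m, fit$coef, se,
                    Q = fit$rss,
                    Q_pval = stats::pchisq(fit$rss, k - p,
                                           lower.tail = FALSE),
                    dispersion = max(1, fit$rss / (k - p)))
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] plus an intercept, after orienting every variant so its
#' effect on the designated primary exposure is non-negative (the
#' orientation that makes the intercept interpretable as directional
#' pleiotropy). The intercept test is reported alongside the slopes.
#'
#' @param m An [mvmr_set()].
#' @param primary Column index or name of the primary exposure
#'   (default 1).
#' @return An `mvmr_estimate` with `intercept`, `intercept_se`,
#'   `intercept_pval`.
#' @export
mvmr_egger <- function(m, primary = 1) {
  stopifnot(inherits(m, "mvmr_set"))
  k <- length(m$beta_y); p <- ncol(m$beta_x)
  if (k <= p + 1) stop("need more instruments than exposures plus one")
  if (is.character(primary)) primary <- match(primary, m$exposure_names)
  s <- ifelse(m$beta_x[, primary] < 0, -1, 1)
  X <- cbind(1, m$beta_x * s)
  y <- m$beta_y * s
  w <- 1 / m$se_y^2
  fit <- wls_fit(X, y, w)
  scale <- max(1, sqrt(fit$rss / (k - p - 1)))
  ses <- sqrt(diag(fit$cov)) * scale
  new_mvmr_estimate("mvmr_egger", m, fit$coef[-1], ses[-1],
                    intercept = fit$coef[1], intercept_se = ses[1],
                    intercept_pval = z_pval(fit$coef[1], ses[1]),
                    Q = fit$rss,
                    Q_pval = stats::pchisq(fit$rss, k - p - 1,
                                           lower.tail = FALSE))
}

# weighted L1 regression through the origin by iteratively reweighted
# least squares
l1_wls <- function(X, y, w, max_iter = 300, tol = 1e-10) {
  fit <- wls_fit(X, y, w)
  coef <- fit$coef
  for (i in seq_len(max_iter)) {
    r <- as.numeric(y - X %*% coef)
    wi <- w / pmax(abs(r), 1e-8)
    new_fit <- wls_fit(X, y, wi)
    if (max(abs(new_fit$coef - coef)) < tol) { coef <- new_fit$coef; break }
    coef <- new_fit$coef
  }
  coef
}

#' Multivariable median MR
#'
#' Minimizes the weighted sum of absolute residuals
#' `sum_j w_j |beta_y_j - sum_p theta_p beta_x_pj|` with weights
#' `1 / se_y^2` (weighted L1 regression through the origin), robust to a
#' minority of invalid instruments. Standard errors come from a seeded
#' parametric bootstrap.
#'
#' @param m An [mvmr_set()].
#' @param n_boot Bootstrap resamples (default 500).
#' @param seed Seed.
#' @return An `mvmr_estimate`.
#' @export
mvmr_median <- function(m, n_boot = 500, seed = NULL) {
  stopifnot(inherits(m, "mvmr_set"))
  k <- length(m$beta_y); p <- ncol(m$beta_x)
  if (k <= p) stop("need more instruments than exposures")
  w <- 1 / m$se_y^2
  coef <- l1_wls(m$beta_x, m$beta_y, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- m$beta_x + m$se_x * matrix(stats::rnorm(k * p), k, p)
      by <- stats::rnorm(k, m$beta_y, m$se_y)
      l1_wls(bx, by, w)
    }, numeric(p))
  })
  se <- if (p == 1) stats::sd(boots) else apply(boots, 1, stats::sd)
  new_mvmr_estimate("mvmr_median", m, coef, se, n_boot = n_boot)
}

#' Multivariable MR-Lasso
#'
#' Augments the multivariable IVW model with one intercept per variant,
#' penalized by `lambda * sum_j |alpha_j|`: variants whose intercept is
#' shrunk to zero are treated as valid, the others as pleiotropic. The
#' path is solved by coordinate descent over a log-spaced lambda grid; the
#' selected lambda is the largest one whose valid (zero-intercept) subset
#' is homogeneous (Cochran's Q at or below the 95% chi-square quantile on
#' `k_valid - p` degrees of freedom) — the heterogeneity stopping rule.
#' The reported estimate is the multivariable IVW on that valid subset.
#'
#' @param m An [mvmr_set()].
#' @param lambda_grid Optional decreasing penalty grid; by default 61
#'   log-spaced values from the smallest lambda shrinking every intercept
#'   to zero down to 1e-6 of it.
#' @return An `mvmr_estimate` with `retained_variant_ids`, `lambda`.
#' @export
mvmr_lasso <- function(m, lambda_grid = NULL) {
  stopifnot(inherits(m, "mvmr_set"))
  k <- length(m$beta_y); p <- ncol(m$beta_x)
  if (k <= p) stop("need more instruments than exposures")
  w <- 1 / m$se_y^2
  base <- wls_fit(m$beta_x, m$beta_y, w)
  r0 <- as.numeric(m$beta_y - m$beta_x %*% base$coef)
  lambda_max <- max(2 * w * abs(r0)) * 1.0001
  lambda_grid <- lambda_grid %||%
    (lambda_max * 10^seq(0, -6, length.out = 61))
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  solve_at <- function(lambda, coef_init, alpha_init) {
    coef <- coef_init; alpha <- alpha_init
    for (it in 1:500) {
      r <- as.numeric(m$beta_y - m$beta_x %*% coef)
      alpha_new <- sign(r) * pmax(abs(r) - lambda / (2 * w), 0)
      fit <- wls_fit(m$beta_x, m$beta_y - alpha_new, w)
      delta <- max(abs(fit$coef - coef), abs(alpha_new - alpha))
      coef <- fit$coef; alpha <- alpha_new
      if (delta < 1e-8) break
    }
    list(coef = coef, alpha = alpha)
  }

  coef <- base$coef; alpha <- numeric(k)
  chosen <- NULL
  for (lambda in lambda_grid) {
    sol <- solve_at(lambda, coef, alpha)
    coef <- sol$coef; alpha <- sol$alpha
    valid <- abs(alpha) < 1e-10
    k_valid <- sum(valid)
    if (k_valid <= p) next
    sub <- mvmr_subset(m, valid)
    fit_v <- wls_fit(sub$beta_x, sub$beta_y, 1 / sub$se_y^2)
    if (fit_v$rss <= stats::qchisq(0.95, k_valid - p)) {
      chosen <- list(lambda = lambda, valid = valid)
      break
    }
  }
  if (is.null(chosen)) stop("no valid instrument subset at any lambda")
  sub <- mvmr_subset(m, chosen$valid)
  est <- mvmr_ivw(sub)
  new_mvmr_estimate("mvmr_lasso", m, unname(est$estimate),
                    unname(est$se),
                    Q = est$Q, Q_pval = est$Q_pval,
                    retained_variant_ids = m$variant_ids[chosen$valid],
                    lambda = chosen$lambda,
                    n_valid = sum(chosen$valid))
}

mvmr_subset <- function(m, keep) {
  mvmr_set(m$beta_x[keep, , drop = FALSE], m$se_x[keep, , drop = FALSE],
           m$beta_y[keep], m$se_y[keep], m$variant_ids[keep],
           m$n_exposure, m$n_outcome, m$outcome_type)
}

#' Conditional F-statistics for instrument strength in multivariable MR
#'
#' For each exposure, its effects are regressed (weights
#' `1 / se_x_e^2`) on the other exposures' effects; the weighted residual
#' sum of squares `Q_x_e`, standardized by the exposure's own GWAS
#' variances, measures the instrument signal not explained by the other
#' exposures, and the conditional F is `Q_x_e / (k - p)`. Cross-exposure
#' GWAS error covariances are treated as zero.
#'
#' @param m An [mvmr_set()].
#' @return Named numeric vector of conditional F-statistics.
#' @export
conditional_f <- function(m) {
  stopifnot(inherits(m, "mvmr_set"))
  k <- length(m$beta_y); p <- ncol(m$beta_x)
  if (k <= p) stop("need more instruments than exposures")
  out <- numeric(p)
  for (e in seq_len(p)) {
    y <- m$beta_x[, e]
    w <- 1 / m$se_x[, e]^2
    others <- m$beta_x[, -e, drop = FALSE]
    if (ncol(others) == 0) {
      q <- sum(w * y^2)
    } else {
      fit <- tryCatch(wls_fit(others, y, w), error = function(e2) NULL)
      q <- if (is.null(fit)) 0 else fit$rss
    }
    out[e] <- q / (k - p)
  }
  stats::setNames(out, m$exposure_names)
}

#' Run the multivariable MR battery
#'
#' @param m An [mvmr_set()].
#' @param n_boot Bootstrap resamples for the multivariable median.
#' @param seed Seed.
#' @return Named list: `ivw`, `egger`, `median`, `lasso`
#'   (`mvmr_estimate`s; `lasso` may be `NULL` if no homogeneous subset
#'   exists) and `conditional_F`.
#' @export
mvmr_all <- function(m, n_boot = 500, seed = NULL) {
  list(ivw = mvmr_ivw(m),
       egger = mvmr_egger(m),
       median = mvmr_median(m, n_boot, seed),
       lasso = tryCatch(mvmr_lasso(m), error = function(e) NULL),
       conditional_F = conditional_f(m))
}
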