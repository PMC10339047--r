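# Shared fixture builders. Everything is generated in code; no files.

# a minimal well-formed summary-statistic data frame
make_records <- function(n = 3, chrom = "1", pos = NULL, ea = "A",
                         oa = "G", eaf = 0.3, beta = 0.1, se = 0.02,
                         n_samp = 1e5, ids = NULL) {
  pos <- pos %||% seq(1e6, by = 1e4, length.out = n)
  beta <- rep_len(beta, n); se <- rep_len(se, n)
  data.frame(
    variant_id = ids %||% sprintf("rs%d", seq_len(n)),
    chrom = rep_len(chrom, n), pos = pos,
    effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
    eaf = rep_len(eaf, n), beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n = rep_len(n_samp, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# harmonized set straight from numbers (for estimator fixtures)
make_h <- function(bx, by, sx = NULL, sy = NULL, n_x = 1e5, n_y = 5e5,
                   outcome_type = "binary") {
  k <- length(bx)
  harmonized_set(
    data.frame(variant_id = sprintf("rs%d", seq_len(k)),
               beta_x = bx, se_x = sx %||% rep(0.01, k), eaf_x = 0.3,
               beta_y = by, se_y = sy %||% rep(0.05, k), eaf_y = 0.3,
               stringsAsFactors = FALSE),
    exposure_name = "exp", outcome_name = "out",
    n_exposure = n_x, n_outcome = n_y, outcome_type = outcome_type)
}

# mvmr set from matrices
make_m <- function(bx, by, sx = NULL, sy = NULL) {
  bx <- as.matrix(bx)
  k <- nrow(bx); p <- ncol(bx)
  mvmr_set(bx, sx %||% matrix(0.01, k, p), by, sy %||% rep(0.05, k),
           sprintf("rs%d", seq_len(k)),
           n_exposure = rep(1e5, p), n_outcome = 5e5,
           outcome_type = "binary")
}

# closed-form weighted least squares (independent oracle for IVW/Egger/
# MVMR-IVW): solve (X'WX) b = X'Wy by explicit matrix algebra
wls_oracle <- function(X, y, w) {
  X <- as.matrix(X)
  XtW <- t(X * w)
  coef <- solve(XtW %*% X, XtW %*% y)
  cov_unscaled <- solve(XtW %*% X)
  rss <- sum(w * (y - X %*% coef)^2)
  list(coef = as.numeric(coef), cov = cov_unscaled, rss = rss)
}
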