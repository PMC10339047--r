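# Multiplicity correction via principal components, clustering of
# correlated exposures, the causal-call triage, and consolidated reports.

#' Effective number of tests from principal components
#'
#' With a panel of highly correlated exposures, Bonferroni correction over
#' the raw count is far too severe; instead the number of tests is taken
#' as the smallest number of principal components of the exposure
#' correlation matrix jointly accounting for at least
#' `variance_threshold` of the variance, and the corrected significance
#' threshold is `base_alpha` divided by that count.
#'
#' @param cor_mat Symmetric positive semi-definite correlation matrix with
#'   unit diagonal.
#' @param variance_threshold Cumulative variance fraction (default 0.9).
#' @param base_alpha Family-wise level (default 0.05).
#' @return A `multiplicity_result`: list with `n_components`,
#'   `cumulative_variance`, `alpha_corrected` and `alpha_display`
#'   (rounded half-up to 4 decimals, the conventional presentation).
#' @export
pc_effective_tests <- function(cor_mat, variance_threshold = 0.9,
                               base_alpha = 0.05) {
  cor_mat <- as.matrix(cor_mat)
  stopifnot(nrow(cor_mat) == ncol(cor_mat))
  if (max(abs(cor_mat - t(cor_mat))) > 1e-8) {
    stop("correlation matrix is not symmetric")
  }
  if (max(abs(diag(cor_mat) - 1)) > 1e-6) {
    stop("correlation matrix diagonal must be 1")
  }
  ev <- eigen(cor_mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(ev)) {
    stop("correlation matrix is not positive semi-definite")
  }
  ev <- pmax(ev, 0)
  cumfrac <- cumsum(ev) / ncol(cor_mat)
  m <- which(cumfrac >= variance_threshold - 1e-12)[1]
  structure(list(n_components = m, cumulative_variance = cumfrac,
                 alpha_corrected = base_alpha / m,
                 alpha_display = round_half_up(base_alpha / m, 4),
                 variance_threshold = variance_threshold,
                 base_alpha = base_alpha),
            class = "multiplicity_result")
}

#' @export
print.multiplicity_result <- function(x, ...) {
  cat(sprintf(
    "Effective tests: %d components reach %.0f%% variance; alpha = %s/%d = %.4g\n",
    x$n_components, 100 * x$variance_threshold, format(x$base_alpha),
    x$n_components, x$alpha_display))
  invisible(x)
}

#' K-means clustering of exposures on their correlation profiles
#'
#' Clusters the rows of the phenotypic correlation matrix (each exposure's
#' correlation profile is its feature vector) with `stats::kmeans`, best
#' of `n_restarts` starts, and reports each cluster's minimum pairwise
#' correlation — the descriptor used to summarize how tight a block of
#' metabolic measures is.
#'
#' @param cor_mat Exposure correlation matrix with named rows.
#' @param k Number of clusters (default 3).
#' @param n_restarts Random restarts (default 25).
#' @param seed Seed.
#' @return A `cluster_assignment`: list with `cluster` (named integer
#'   vector), `min_correlation` (per cluster), `k`, `seed`.
#' @export
kmeans_correlation_clusters <- function(cor_mat, k = 3, n_restarts = 25,
                                        seed = NULL) {
  cor_mat <- as.matrix(cor_mat)
  p <- nrow(cor_mat)
  if (k < 1 || k > p) stop("k must be between 1 and the number of exposures")
  if (is.null(rownames(cor_mat))) {
    rownames(cor_mat) <- colnames(cor_mat) <- paste0("x", seq_len(p))
  }
  km <- with_seed(seed, stats::kmeans(cor_mat, centers = k,
                                      nstart = n_restarts))
  assign <- stats::setNames(km$cluster, rownames(cor_mat))
  min_cor <- vapply(seq_len(k), function(ci) {
    idx <- which(km$cluster == ci)
    if (length(idx) < 2) return(NA_real_)
    sub <- cor_mat[idx, idx]
    min(sub[upper.tri(sub)])
  }, 0)
  structure(list(cluster = assign, min_correlation = min_cor, k = k,
                 seed = seed, withinss = km$tot.withinss),
            class = "cluster_assignment")
}

#' Causal-call triage for one exposure
#'
#' An exposure is called a causal candidate only when every criterion
#' holds:
#' \itemize{
#'   \item `primary_significant`: IVW p below the multiplicity-corrected
#'     threshold;
#'   \item `robust_majority`: strictly more than half of the available
#'     robust estimators significant at 0.05;
#'   \item `directionally_consistent`: all available estimates share the
#'     IVW sign;
#'   \item `egger_intercept_ok`: MR-Egger intercept p above 0.05 (no
#'     evidence of directional pleiotropy);
#'   \item `mvmr_robust`: multivariable IVW significant at 0.05 with the
#'     IVW sign, multivariable median and Lasso significant at 0.05, and
#'     multivariable Egger intercept p above 0.05 — robustness to the
#'     inclusion of waist circumference;
#'   \item `no_reverse_causality`: reverse-MR p at or above 0.05;
#'   \item `steiger_clean`: Steiger filtering was applied (flagged
#'     variants removed before estimation).
#' }
#'
#' @param primary IVW `mr_estimate`.
#' @param robust Named list of robust `mr_estimate`s (any of `mr_egger`,
#'   `weighted_median`, `conmix`, `mr_presso`); at least two required.
#' @param mvmr Output of [mvmr_all()] (or `NULL`, failing the MVMR flag).
#' @param steiger Output of [steiger_filter()] (or `NULL` when not
#'   applied).
#' @param reverse Reverse-MR `mr_estimate` (or `NULL`, failing the flag).
#' @param alpha_corrected Multiplicity-corrected threshold for the
#'   primary analysis.
#' @param mvmr_exposure Name or index of the exposure of interest within
#'   the multivariable estimates (default 1).
#' @return A `triage_result`: list with `flags` (named logical) and
#'   `verdict` (`"causal-candidate"` or `"not-supported"`).
#' @export
triage <- function(primary, robust, mvmr, steiger, reverse,
                   alpha_corrected, mvmr_exposure = 1) {
  if (is.null(primary)) stop("primary IVW estimate is required")
  if (length(robust) < 2) stop("at least two robust estimates required")
  sgn <- sign(primary$estimate)
  robust_p <- vapply(robust, function(e) e$pval, 0)
  robust_est <- vapply(robust, function(e) e$estimate, 0)

  flags <- c(
    primary_significant = primary$pval < alpha_corrected,
    robust_majority = sum(robust_p < 0.05) > length(robust_p) / 2,
    directionally_consistent = all(sign(robust_est) == sgn),
    egger_intercept_ok = if ("mr_egger" %in% names(robust))
      robust$mr_egger$intercept_pval > 0.05 else NA,
    mvmr_robust = if (!is.null(mvmr) && !is.null(mvmr$lasso)) {
      e <- mvmr_exposure
      unname(mvmr$ivw$pval[e] < 0.05 &&
               sign(mvmr$ivw$estimate[e]) == sgn &&
               mvmr$median$pval[e] < 0.05 &&
               mvmr$egger$intercept_pval > 0.05 &&
               mvmr$lasso$pval[e] < 0.05)
    } else FALSE,
    no_reverse_causality = if (!is.null(reverse)) reverse$pval >= 0.05
                           else FALSE,
    steiger_clean = !is.null(steiger))
  verdict <- if (isTRUE(all(flags[!is.na(flags)])) && !any(is.na(flags)))
    "causal-candidate" else "not-supported"
  structure(list(flags = flags, verdict = verdict,
                 alpha_corrected = alpha_corrected),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat("Triage verdict:", x$verdict, "\n")
  for (nm in names(x$flags)) {
    cat(sprintf("  %-25s %s\n", nm, x$flags[[nm]]))
  }
  invisible(x)
}

#' Consolidated forest-style report table
#'
#' One row per exposure and method, with the estimate on both the model
#' scale and the odds/hazard-ratio scale, confidence limits, p-value and
#' optional cluster and verdict annotations; deterministic column order,
#' suitable for forest or volcano plotting.
#'
#' @param results Named list (by exposure) of lists with elements
#'   `estimates` (named list of `mr_estimate`s) and optionally `verdict`
#'   and `cluster`.
#' @return Data frame with columns `exposure`, `method`, `n_variants`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pval`, `or`,
#'   `neg_log10_pval`, `cluster`, `verdict`.
#' @export
build_report <- function(results) {
  stopifnot(length(results) > 0)
  rows <- list()
  for (exp_name in names(results)) {
    res <- results[[exp_name]]
    for (mth in names(res$estimates)) {
      e <- res$estimates[[mth]]
      rows[[length(rows) + 1]] <- data.frame(
        exposure = exp_name, method = mth,
        n_variants = e$n_variants, estimate = e$estimate, se = e$se,
        ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
        or = exp(e$estimate), neg_log10_pval = -log10(e$pval),
        cluster = res$cluster %||% NA_integer_,
        verdict = res$verdict %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a report table as TSV
#' @param report Data frame from [build_report()].
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_report <- function(report, path) {
  data.table::fwrite(report, path, sep = "\t")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
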