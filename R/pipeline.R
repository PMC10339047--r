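# End-to-end orchestration: the univariable pipeline for one exposure,
# and a synthetic benchmark suite with known causal truth that exercises
# selection, harmonization, all estimators, MVMR, reverse MR, multiplicity
# correction and triage.

#' Univariable MR pipeline for one exposure
#'
#' Chains instrument selection, proxy substitution, harmonization, Steiger
#' filtering and the five univariable estimators.
#'
#' @param exposure,outcome [sumstat_table()] objects.
#' @param ld An [ld_matrix()].
#' @param p_threshold,clump_r2,clump_window_bp,exclude_regions Passed to
#'   [select_instruments()].
#' @param proxy_r2 Passed to [substitute_proxies()].
#' @param palindrome_eaf_limit Passed to [harmonize()].
#' @param steiger_alpha Passed to [steiger_filter()].
#' @param n_boot,n_sim,seed Passed to [mr_all()].
#' @return List with `instruments`, `h` (post-Steiger
#'   [harmonized_set()]), `steiger`, `strength`, `estimates` (from
#'   [mr_all()]).
#' @export
mr_pipeline <- function(exposure, outcome, ld, p_threshold = 5e-8,
                        clump_r2 = 0.01, clump_window_bp = 1e6,
                        exclude_regions = NULL, proxy_r2 = 0.8,
                        palindrome_eaf_limit = 0.42, steiger_alpha = 0.05,
                        n_boot = 1000, n_sim = 1000, seed = NULL) {
  ins <- select_instruments(exposure, ld, p_threshold, clump_r2,
                            clump_window_bp, exclude_regions)
  ins <- substitute_proxies(ins, outcome, ld, proxy_r2)
  h <- harmonize(exposure, outcome, ins, palindrome_eaf_limit)
  st <- steiger_filter(h, steiger_alpha)
  h <- st$h
  list(instruments = ins, h = h, steiger = st,
       strength = instrument_strength(h),
       estimates = mr_all(h, n_boot = n_boot, n_sim = n_sim, seed = seed))
}

#' Simulate the benchmark exposure suite with known causal truth
#'
#' Twenty metabolic exposures against one binary liver-disease outcome:
#' five truly causal (log-odds effects 0.3, -0.3, 0.5, -0.5, 0.4 per SD),
#' fifteen null, five of the nulls contaminated with directional
#' pleiotropy (30% invalid instruments, mean direct effect 0.08). Study
#' sizes mirror the real designs (exposure GWAS n = 115,000; binary
#' outcome GWAS with effective n = 33,462, i.e. 8,434 cases and 770,180
#' controls; waist-circumference GWAS n = 462,166; liver-fat GWAS
#' n = 32,860). Each exposure gets 80 candidate variants in 40 LD blocks
#' of two (within-block r = 0.9) so clumping has real work, plus a
#' matching waist-covariate GWAS for MVMR and a liver-fat GWAS (35
#' independent variants, no true reverse effect) for reverse MR. A
#' phenotypic correlation matrix for the multiplicity correction comes
#' from a simulated cohort panel with three correlated blocks.
#'
#' @param seed Integer seed; every per-exposure simulation derives its own
#'   sub-seed from it.
#' @param n_exposures Number of exposures (default 20; the first quarter,
#'   rounded, are causal).
#' @return List with `exposures` (per-exposure list: `name`, `theta`,
#'   `sim` from [simulate_mvmr_gwas()], `reverse_sim`), `truth` (data
#'   frame `exposure`, `theta`, `pleiotropy`), `cor_mat` (phenotypic
#'   correlation matrix of the panel).
#' @export
simulate_benchmark_suite <- function(seed = 1, n_exposures = 20) {
  theta_causal <- c(0.3, -0.3, 0.5, -0.5, 0.4)
  n_causal <- length(theta_causal)
  stopifnot(n_exposures >= n_causal + 10)
  theta <- c(theta_causal, rep(0, n_exposures - n_causal))
  pleio <- rep(FALSE, n_exposures)
  pleio[(n_causal + 1):(n_causal + 5)] <- TRUE
  names <- sprintf("met_%02d", seq_len(n_exposures))

  exposures <- vector("list", n_exposures)
  for (i in seq_len(n_exposures)) {
    cfg <- gwas_sim_config(
      m_snps = 80, theta = theta[i],
      pi_invalid = if (pleio[i]) 0.3 else 0,
      pleio_mean = if (pleio[i]) 0.08 else 0,
      pleio_sd = if (pleio[i]) 0.04 else 0,
      hx2 = 0.04, n_exposure = 115000, n_outcome = 33462,
      ld_blocks = list(size = 2, r = 0.9),
      outcome_type = "binary", seed = seed * 1000L + i)
    sim <- simulate_mvmr_gwas(cfg, theta_cov = 0.4, hcov2 = 0.02,
                              n_covariate = 462166)
    rev_cfg <- gwas_sim_config(
      m_snps = 35, theta = 0, pi_invalid = 0, hx2 = 0.1,
      n_exposure = 32860, n_outcome = 115000,
      outcome_type = "continuous", seed = seed * 1000L + 500L + i)
    rev_sim <- simulate_two_sample_gwas(rev_cfg)
    rev_sim$exposure$trait_name <- "liver_fat"
    rev_sim$outcome$trait_name <- names[i]
    exposures[[i]] <- list(name = names[i], theta = theta[i],
                           sim = sim, reverse_sim = rev_sim)
  }

  panel <- simulate_cohort(cohort_sim_config(
    n = 2000, k_metabolites = n_exposures,
    cluster_spec = list(list(size = 7, loading = sqrt(0.8)),
                        list(size = 7, loading = sqrt(0.8)),
                        list(size = 6, loading = sqrt(0.8))),
    seed = seed * 1000L + 999L))
  met_cols <- grep("^met_", names(panel$subjects), value = TRUE)
  cor_mat <- stats::cor(panel$subjects[met_cols])

  list(exposures = stats::setNames(exposures, names),
       truth = data.frame(exposure = names, theta = theta,
                          pleiotropy = pleio, stringsAsFactors = FALSE),
       cor_mat = cor_mat)
}

#' Run the full pipeline and triage over the benchmark suite
#'
#' For every exposure: univariable pipeline (selection, harmonization,
#' Steiger filter, five estimators), multivariable MR against the waist
#' covariate, reverse MR from liver fat, then the causal-call triage at
#' the principal-component-corrected threshold derived from the panel's
#' phenotypic correlation matrix.
#'
#' @param suite Output of [simulate_benchmark_suite()].
#' @param n_boot,n_sim Monte-Carlo sizes for the stochastic estimators.
#' @param seed Seed for the stochastic estimators.
#' @return List with `multiplicity` ([pc_effective_tests()] result),
#'   `clusters` ([kmeans_correlation_clusters()]), `results` (per-exposure
#'   list: `estimates`, `mvmr`, `reverse`, `steiger`, `triage`,
#'   `verdict`, `cluster`), `report` (from [build_report()]), `summary`
#'   (data frame with truth and verdict), `sensitivity`,
#'   `false_positives`.
#' @export
run_benchmark <- function(suite, n_boot = 500, n_sim = 1000, seed = 1) {
  mult <- pc_effective_tests(suite$cor_mat, 0.9, 0.05)
  clus <- kmeans_correlation_clusters(suite$cor_mat, k = 3,
                                      n_restarts = 25, seed = seed)
  results <- list()
  for (nm in names(suite$exposures)) {
    ex <- suite$exposures[[nm]]
    sim <- ex$sim
    pipe <- mr_pipeline(sim$exposure, sim$outcome, sim$ld,
                        n_boot = n_boot, n_sim = n_sim, seed = seed)
    mv_ins <- pipe$instruments
    m <- mvmr_harmonize(list(exposure = sim$exposure,
                             waist = sim$covariate),
                        sim$outcome, mv_ins)
    mv <- mvmr_all(m, n_boot = n_boot, seed = seed)
    rev <- reverse_mr(ex$reverse_sim$exposure, ex$reverse_sim$outcome,
                      ex$reverse_sim$ld)
    robust <- pipe$estimates[setdiff(names(pipe$estimates), "ivw")]
    tri <- triage(pipe$estimates$ivw, robust, mv, pipe$steiger, rev,
                  mult$alpha_corrected, mvmr_exposure = 1)
    results[[nm]] <- list(estimates = pipe$estimates, mvmr = mv,
                          reverse = rev, steiger = pipe$steiger,
                          strength = pipe$strength, triage = tri,
                          verdict = tri$verdict,
                          cluster = unname(clus$cluster[nm]))
  }
  verdicts <- vapply(results, function(r) r$verdict, "")
  summary <- suite$truth
  summary$verdict <- verdicts[summary$exposure]
  summary$called <- summary$verdict == "causal-candidate"
  sens <- sum(summary$called & summary$theta != 0)
  fp <- sum(summary$called & summary$theta == 0)
  list(multiplicity = mult, clusters = clus, results = results,
       report = build_report(results), summary = summary,
       sensitivity = sens, n_causal = sum(summary$theta != 0),
       false_positives = fp)
}
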