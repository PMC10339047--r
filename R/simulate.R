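# Synthetic-data generators: two-sample GWAS summary statistics with known
# causal effect and pleiotropy structure, and survival cohorts with a
# factor-correlated metabolite panel. Every downstream stage is validated
# against the ground truth these emit.

#' Configuration for the two-sample GWAS simulator
#'
#' Defaults mirror the study design the pipeline targets: an exposure GWAS
#' of rank-inverse-normalized circulating metabolites in roughly 115,000
#' individuals and a binary liver-disease outcome GWAS on the log-odds
#' scale. For a binary trait the standard-error formula takes the
#' effective sample size `4 / (1/n_cases + 1/n_controls)` — about 33,500
#' for a case-control imbalance of 8,434 cases versus 770,180 controls —
#' not the total count, which is why `n_outcome` defaults to 33,462.
#' Instrument counts and heritability are chosen so single-variant
#' F-statistics land in the 50-150 range typical of metabolite
#' instruments.
#'
#' @param m_snps Number of variants.
#' @param theta True causal effect (outcome units per SD exposure;
#'   log-odds for a binary outcome).
#' @param pi_invalid Fraction of variants with a direct (pleiotropic)
#'   outcome effect.
#' @param pleio_mean,pleio_sd Mean and SD of the direct effects alpha_j of
#'   invalid variants (nonzero mean = directional pleiotropy).
#' @param hx2 Exposure variance explained jointly by the variants.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param ld_blocks Optional LD structure: `list(size =, r =)` giving
#'   compound-symmetric blocks of `size` variants with within-block
#'   correlation `r` (zero between blocks).
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param seed Integer seed.
#' @return A `gwas_sim_config` list.
#' @export
gwas_sim_config <- function(m_snps = 80, theta = 0, pi_invalid = 0,
                            pleio_mean = 0, pleio_sd = 0, hx2 = 0.04,
                            n_exposure = 115000, n_outcome = 33462,
                            ld_blocks = NULL,
                            outcome_type = c("binary", "continuous"),
                            seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(m_snps >= 1, pi_invalid >= 0, pi_invalid <= 1,
            hx2 > 0, hx2 < 1, n_exposure >= 100, n_outcome >= 100,
            pleio_sd >= 0)
  if (!is.null(ld_blocks)) {
    stopifnot(is.list(ld_blocks), ld_blocks$size >= 1,
              abs(ld_blocks$r) < 1)
  }
  structure(list(m_snps = m_snps, theta = theta, pi_invalid = pi_invalid,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd, hx2 = hx2,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 ld_blocks = ld_blocks, outcome_type = outcome_type,
                 seed = seed),
            class = "gwas_sim_config")
}

# non-palindromic allele pairs keep simulated harmonization deterministic;
# palindromic behaviour is exercised by dedicated fixtures
NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                 "G", "A", "C", "A", "G", "T", "C", "T"),
                               ncol = 2, byrow = TRUE)

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Per-variant true exposure effects `b_j` are drawn standard normal and
#' rescaled so that `sum(2 p_j (1 - p_j) b_j^2) = hx2`, with effect-allele
#' frequencies `p_j ~ Uniform(0.05, 0.95)`. Standard errors use the
#' standardized-trait approximation `se = 1 / sqrt(2 p (1 - p) n)`.
#' Observed effects are independent draws
#' `beta_x ~ N(b_j, se_x^2)` and `beta_y ~ N(theta * b_j + alpha_j,
#' se_y^2)` (two-sample independence); `alpha_j = 0` for valid variants
#' and `alpha_j ~ N(pleio_mean, pleio_sd^2)` for the `ceiling(pi * m)`
#' invalid ones. When `ld_blocks` is given, additional variants within
#' each compound-symmetric block share attenuated marginal effects
#' (`r` times the index effect) and correlated estimation noise, so that
#' clumping has real work to do.
#'
#' @param cfg A [gwas_sim_config()].
#' @return List with `exposure` and `outcome` ([sumstat_table()]s), `ld`
#'   (an [ld_matrix()]), and `truth` (data frame of `variant_id`, `b`,
#'   `alpha`, `valid`).
#' @export
simulate_two_sample_gwas <- function(cfg) {
  stopifnot(inherits(cfg, "gwas_sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$m_snps
    if (is.null(cfg$ld_blocks)) {
      blocks <- as.list(seq_len(m))
      r_within <- 0
    } else {
      size <- cfg$ld_blocks$size
      r_within <- cfg$ld_blocks$r
      starts <- seq(1, m, by = size)
      blocks <- lapply(starts, function(s) s:min(s + size - 1, m))
    }
    ids <- sprintf("rs%06d", seq_len(m))
    chrom <- rep("1", m)
    pos <- numeric(m)
    # blocks spaced 2 Mb apart (beyond the clump window); 5 kb inside
    for (bi in seq_along(blocks)) {
      pos[blocks[[bi]]] <- bi * 2e6 + (seq_along(blocks[[bi]]) - 1) * 5000
    }

    p <- stats::runif(m, 0.05, 0.95)
    var_g <- 2 * p * (1 - p)
    # index variant of each block carries the causal signal; followers are
    # LD shadows with marginal effect r * b_index
    b_raw <- stats::rnorm(m)
    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      if (length(blk) > 1) b_raw[blk[-1]] <- r_within * b_raw[blk[1]]
    }
    b <- b_raw * sqrt(cfg$hx2 / sum(var_g * b_raw^2))

    n_invalid <- ceiling(cfg$pi_invalid * m)
    invalid <- rep(FALSE, m)
    if (n_invalid > 0) {
      invalid[sample.int(m, n_invalid)] <- TRUE
    }
    alpha <- numeric(m)
    alpha[invalid] <- stats::rnorm(n_invalid, cfg$pleio_mean, cfg$pleio_sd)

    se_x <- 1 / sqrt(var_g * cfg$n_exposure)
    se_y <- 1 / sqrt(var_g * cfg$n_outcome)
    ex <- stats::rnorm(m); ey <- stats::rnorm(m)
    if (r_within != 0) {
      # share estimation noise within blocks (same samples, correlated
      # genotypes) at correlation r_within
      for (bi in seq_along(blocks)) {
        blk <- blocks[[bi]]
        if (length(blk) > 1) {
          ex[blk[-1]] <- r_within * ex[blk[1]] +
            sqrt(1 - r_within^2) * ex[blk[-1]]
          ey[blk[-1]] <- r_within * ey[blk[1]] +
            sqrt(1 - r_within^2) * ey[blk[-1]]
        }
      }
    }
    beta_x <- b + se_x * ex
    beta_y <- cfg$theta * b + alpha + se_y * ey

    alleles <- NONPALINDROMIC_PAIRS[
      sample.int(nrow(NONPALINDROMIC_PAIRS), m, replace = TRUE), ,
      drop = FALSE]

    mk <- function(beta, se, n, trait, type) {
      sumstat_table(data.frame(
        variant_id = ids, chrom = chrom, pos = pos,
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        eaf = p, beta = beta, se = se,
        pval = pmax(z_pval(beta, se), 1e-300), n = n,
        stringsAsFactors = FALSE), trait, type)
    }

    r_mat <- diag(m)
    for (blk in blocks) {
      if (length(blk) > 1) {
        r_mat[blk, blk] <- r_within
        diag(r_mat)[blk] <- 1
      }
    }

    list(exposure = mk(beta_x, se_x, cfg$n_exposure, "exposure",
                       "continuous"),
         outcome = mk(beta_y, se_y, cfg$n_outcome, "outcome",
                      cfg$outcome_type),
         ld = ld_matrix(r_mat, ids),
         truth = data.frame(variant_id = ids, b = b, alpha = alpha,
                            valid = !invalid, stringsAsFactors = FALSE))
  })
}

#' Simulate a harmonized set directly (no tables, no clumping)
#'
#' Convenience wrapper around the same generative model as
#' [simulate_two_sample_gwas()] for estimator calibration loops, returning
#' a ready [harmonized_set()] of independent variants.
#'
#' @inheritParams gwas_sim_config
#' @param exposure_increasing When `TRUE`, true exposure effects are
#'   oriented positive (instruments reported on the exposure-increasing
#'   allele, the convention under which directional pleiotropy is
#'   directional rather than sign-balanced).
#' @return List with `h` (a [harmonized_set()]) and `truth`.
#' @export
simulate_harmonized <- function(m_snps = 50, theta = 0, pi_invalid = 0,
                                pleio_mean = 0, pleio_sd = 0, hx2 = 0.04,
                                n_exposure = 115000, n_outcome = 33462,
                                outcome_type = "binary", seed = NULL,
                                exposure_increasing = FALSE) {
  with_seed(seed, {
    m <- m_snps
    p <- stats::runif(m, 0.05, 0.95)
    var_g <- 2 * p * (1 - p)
    b_raw <- stats::rnorm(m)
    if (exposure_increasing) b_raw <- abs(b_raw)
    b <- b_raw * sqrt(hx2 / sum(var_g * b_raw^2))
    n_invalid <- ceiling(pi_invalid * m)
    invalid <- rep(FALSE, m)
    if (n_invalid > 0) invalid[sample.int(m, n_invalid)] <- TRUE
    alpha <- numeric(m)
    alpha[invalid] <- stats::rnorm(n_invalid, pleio_mean, pleio_sd)
    se_x <- 1 / sqrt(var_g * n_exposure)
    se_y <- 1 / sqrt(var_g * n_outcome)
    beta_x <- stats::rnorm(m, b, se_x)
    beta_y <- stats::rnorm(m, theta * b + alpha, se_y)
    ids <- sprintf("rs%06d", seq_len(m))
    h <- harmonized_set(
      data.frame(variant_id = ids, beta_x = beta_x, se_x = se_x,
                 eaf_x = p, beta_y = beta_y, se_y = se_y, eaf_y = p,
                 stringsAsFactors = FALSE),
      exposure_name = "exposure", outcome_name = "outcome",
      n_exposure = n_exposure, n_outcome = n_outcome,
      outcome_type = outcome_type)
    list(h = h,
         truth = data.frame(variant_id = ids, b = b, alpha = alpha,
                            valid = !invalid, stringsAsFactors = FALSE))
  })
}

#' Simulate summary statistics for one exposure, a covariate, and the outcome
#'
#' Generative model for the multivariable analyses: each variant affects
#' the primary exposure (`b_j`, scaled to `hx2`) and, independently, the
#' covariate (`c_j`, scaled to `hcov2`); the outcome effect is
#' `theta * b_j + theta_cov * c_j + alpha_j` plus estimation noise. All
#' three studies draw independent noise (two-sample independence; the
#' covariate GWAS has its own sample size).
#'
#' @param cfg A [gwas_sim_config()] for the exposure/outcome pair.
#' @param theta_cov True causal effect of the covariate on the outcome.
#' @param hcov2 Covariate variance explained by the variants.
#' @param n_covariate Covariate GWAS sample size.
#' @return List with `exposure`, `covariate`, `outcome`
#'   ([sumstat_table()]s), `ld`, and `truth` (including `c`, the
#'   per-variant covariate effects).
#' @export
simulate_mvmr_gwas <- function(cfg, theta_cov = 0.4, hcov2 = 0.02,
                               n_covariate = 462166) {
  stopifnot(inherits(cfg, "gwas_sim_config"))
  base <- simulate_two_sample_gwas(cfg)
  with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L, {
    m <- cfg$m_snps
    rec <- base$exposure$records
    p <- rec$eaf
    var_g <- 2 * p * (1 - p)
    c_raw <- stats::rnorm(m)
    cc <- c_raw * sqrt(hcov2 / sum(var_g * c_raw^2))
    se_c <- 1 / sqrt(var_g * n_covariate)
    beta_c <- stats::rnorm(m, cc, se_c)
    cov_tab <- sumstat_table(data.frame(
      variant_id = rec$variant_id, chrom = rec$chrom, pos = rec$pos,
      effect_allele = rec$effect_allele, other_allele = rec$other_allele,
      eaf = p, beta = beta_c, se = se_c,
      pval = pmax(z_pval(beta_c, se_c), 1e-300), n = n_covariate,
      stringsAsFactors = FALSE), "covariate", "continuous")
    # outcome re-drawn so it reflects both causal paths
    se_y <- base$outcome$records$se
    beta_y <- stats::rnorm(m, cfg$theta * base$truth$b + theta_cov * cc +
                             base$truth$alpha, se_y)
    out_rec <- base$outcome$records
    out_rec$beta <- beta_y
    out_rec$pval <- pmax(z_pval(beta_y, se_y), 1e-300)
    outcome <- sumstat_table(out_rec, "outcome", cfg$outcome_type)
    truth <- base$truth
    truth$c <- cc
    list(exposure = base$exposure, covariate = cov_tab, outcome = outcome,
         ld = base$ld, truth = truth)
  })
}

#' Configuration for the survival-cohort simulator
#'
#' Defaults emulate a middle-aged population cohort: enrollment ages
#' 40-69, ~46% male, a metabolite panel organized in three highly
#' correlated blocks (within-block Pearson r about 0.8, matching the
#' cluster structure of lipoprotein panels), Weibull baseline hazard with
#' administrative censoring after 12.6 years of median follow-up.
#'
#' @param n Number of individuals.
#' @param k_metabolites Panel size.
#' @param cluster_spec List of blocks, each `list(size =, loading =)`;
#'   metabolites in a block load on a shared latent factor with the given
#'   loading (pairwise correlation = loading^2). Sizes must sum to at most
#'   `k_metabolites`; leftover metabolites are independent.
#' @param log_hr_per_sd True log hazard ratios per SD, one per metabolite
#'   (recycled).
#' @param baseline_shape,baseline_scale Weibull baseline hazard shape and
#'   scale (scale in years).
#' @param admin_censor_years Administrative censoring horizon (years).
#' @param frac_prevalent Fraction of cases whose diagnosis is back-dated
#'   before enrollment (exercises the prevalent-case exclusion).
#' @param frac_other_liver Fraction of individuals given a non-target
#'   liver code (exercises the exclusion-code filter).
#' @param covariate_log_hr Named log-HRs for `age` (per year), `male`,
#'   `waist` (per cm), `smoking`.
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n = 10000, k_metabolites = 20,
                              cluster_spec = list(
                                list(size = 7, loading = sqrt(0.8)),
                                list(size = 7, loading = sqrt(0.8)),
                                list(size = 6, loading = sqrt(0.8))),
                              log_hr_per_sd = 0,
                              baseline_shape = 1.3,
                              baseline_scale = 80,
                              admin_censor_years = 12.6,
                              frac_prevalent = 0.01,
                              frac_other_liver = 0.01,
                              covariate_log_hr = c(age = 0.02,
                                                   male = 0.15,
                                                   waist = 0.03,
                                                   smoking = 0.1),
                              seed = NULL) {
  stopifnot(n >= 10, k_metabolites >= 1,
            sum(vapply(cluster_spec, function(b) b$size, 0)) <=
              k_metabolites,
            baseline_shape > 0, baseline_scale > 0,
            admin_censor_years > 0,
            frac_prevalent >= 0, frac_prevalent < 1,
            frac_other_liver >= 0, frac_other_liver < 1)
  structure(list(n = n, k_metabolites = k_metabolites,
                 cluster_spec = cluster_spec,
                 log_hr_per_sd = rep_len(log_hr_per_sd, k_metabolites),
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 admin_censor_years = admin_censor_years,
                 frac_prevalent = frac_prevalent,
                 frac_other_liver = frac_other_liver,
                 covariate_log_hr = covariate_log_hr, seed = seed),
            class = "cohort_sim_config")
}

#' Simulate an individual-level survival cohort with a metabolite panel
#'
#' Metabolites arise from block latent factors plus independent noise
#' (within-block pairwise correlation = loading^2). Event times follow a
#' Weibull proportional-hazards model whose linear predictor combines the
#' standardized metabolites (per-SD log-HRs from the configuration) and
#' the covariates; administrative censoring is applied at the follow-up
#' horizon. Diagnosis records carry ICD-10-style codes: incident cases
#' receive a target liver code dated at their event time, a configurable
#' fraction of diagnoses are back-dated before enrollment, and a fraction
#' of individuals receive a non-target liver code, so the phenotype filter
#' has realistic work.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A `cohort_table`: list with `subjects` (covariates, lipids,
#'   metabolite columns `met_*`, enrollment and censor dates),
#'   `diagnoses` (`id`, `code`, `date`), and `truth` (per-subject latent
#'   event time and event indicator before record assembly).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n; k <- cfg$k_metabolites
    met <- matrix(stats::rnorm(n * k), n, k)
    col <- 1
    for (blk in cfg$cluster_spec) {
      f <- stats::rnorm(n)
      idx <- col:(col + blk$size - 1)
      met[, idx] <- blk$loading * f +
        sqrt(1 - blk$loading^2) * met[, idx]
      col <- col + blk$size
    }
    colnames(met) <- sprintf("met_%02d", seq_len(k))

    age <- stats::runif(n, 40, 69)
    male <- stats::rbinom(n, 1, 0.46)
    waist <- stats::rnorm(n, 90 + 8 * male, 12)
    smoking <- stats::rbinom(n, 1, 0.45)
    alcohol <- sample(1:6, n, replace = TRUE)
    deprivation <- stats::rnorm(n, -1.3, 3.1)
    ethnicity_white <- stats::rbinom(n, 1, 0.94)
    medication <- stats::rbinom(n, 1, 0.27)
    tg <- exp(stats::rnorm(n, log(1.5), 0.45))
    hdl <- pmax(stats::rnorm(n, 1.45 - 0.25 * male, 0.35), 0.3)

    chr <- cfg$covariate_log_hr
    eta <- scale(met) %*% cfg$log_hr_per_sd +
      chr[["age"]] * (age - mean(age)) + chr[["male"]] * male +
      chr[["waist"]] * (waist - mean(waist)) +
      chr[["smoking"]] * smoking
    eta <- as.numeric(eta)
    # Weibull PH: S(t) = exp(-(t/scale)^shape * exp(eta))
    u <- stats::runif(n)
    t_event <- cfg$baseline_scale *
      (-log(u) / exp(eta))^(1 / cfg$baseline_shape)
    event <- t_event <= cfg$admin_censor_years
    t_obs <- pmin(t_event, cfg$admin_censor_years)

    enroll <- as.Date("2008-01-01") + sample.int(1000, n, replace = TRUE)
    censor <- enroll + round(cfg$admin_censor_years * 365.25)

    include_pool <- nafld_codes()$include
    diag_list <- list()
    case_ids <- which(event)
    if (length(case_ids) > 0) {
      codes <- sample(include_pool, length(case_ids), replace = TRUE)
      dates <- enroll[case_ids] + round(t_event[case_ids] * 365.25)
      back <- stats::runif(length(case_ids)) < cfg$frac_prevalent
      dates[back] <- enroll[case_ids][back] -
        sample.int(1500, sum(back), replace = TRUE)
      diag_list[[1]] <- data.frame(id = case_ids, code = codes,
                                   date = dates, stringsAsFactors = FALSE)
    }
    n_other <- round(cfg$frac_other_liver * n)
    if (n_other > 0) {
      oid <- sample.int(n, n_other)
      diag_list[[length(diag_list) + 1]] <- data.frame(
        id = oid,
        code = sample(c("K74.6", "K75.0", "K76.1"), n_other,
                      replace = TRUE),
        date = enroll[oid] + sample.int(3000, n_other, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    diagnoses <- if (length(diag_list)) do.call(rbind, diag_list) else
      data.frame(id = integer(0), code = character(0),
                 date = as.Date(character(0)), stringsAsFactors = FALSE)
    diagnoses <- diagnoses[order(diagnoses$id, diagnoses$date), ,
                           drop = FALSE]
    rownames(diagnoses) <- NULL

    subjects <- data.frame(
      id = seq_len(n), age = age, sex = ifelse(male == 1, "male",
                                               "female"),
      ethnicity_white = ethnicity_white, smoking = smoking,
      alcohol = alcohol, deprivation = deprivation, waist = waist,
      medication = medication, tg = tg, hdl = hdl,
      enroll_date = enroll, censor_date = censor,
      stringsAsFactors = FALSE)
    subjects <- cbind(subjects, as.data.frame(met))

    structure(list(subjects = subjects, diagnoses = diagnoses,
                   truth = data.frame(id = seq_len(n), t_event = t_event,
                                      event = event, t_obs = t_obs)),
              class = "cohort_table")
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort: %d subjects, %d diagnosis records\n",
              nrow(x$subjects), nrow(x$diagnoses)))
  invisible(x)
}
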