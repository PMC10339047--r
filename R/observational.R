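# Cohort arm: incident-phenotype derivation from diagnosis codes, Cox
# per-SD hazard ratios, Kaplan-Meier curves, quintile and dyslipidemia
# groupings, and baseline characteristic tables.

#' Diagnosis codes defining the fatty-liver phenotype
#'
#' The incident phenotype is the first occurrence of a target liver code:
#' K74.0 and K74.2 (hepatic fibrosis), K75.8 (non-alcoholic
#' steatohepatitis), K76.0 (fatty liver) and K76.9 (other specified liver
#' disease). Any other K74/K75/K76 code marks liver disease of another
#' etiology (alcoholic, viral, ...) and excludes the participant from the
#' analysis entirely.
#'
#' @return List with `include` (target codes) and `exclude_prefix`
#'   (chapter prefixes whose non-target codes exclude a participant).
#' @export
nafld_codes <- function() {
  list(include = c("K74.0", "K74.2", "K75.8", "K76.0", "K76.9"),
       exclude_prefix = c("K74", "K75", "K76"))
}

check_codes <- function(codes) {
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9X]+)?$", codes)
  if (any(bad)) {
    stop("malformed diagnosis code(s): ",
         paste(utils::head(unique(codes[bad]), 5), collapse = ", "))
  }
}

#' Derive the incident fatty-liver phenotype from diagnosis records
#'
#' A participant is a case at the earliest date of an included code.
#' Participants carrying any excluded liver code (a code starting with one
#' of the exclusion prefixes but not in the include list) are removed
#' entirely; participants whose earliest included code predates enrollment
#' (prevalent cases) are removed from the incident analysis. Everyone else
#' is censored at their censor date.
#'
#' @param cohort A `cohort_table` (see [simulate_cohort()]) or a list with
#'   `subjects` (`id`, `enroll_date`, `censor_date`) and `diagnoses`
#'   (`id`, `code`, `date`).
#' @param include_codes Target codes (default [nafld_codes()]`$include`).
#' @param exclude_codes Codes or chapter prefixes whose carriers are
#'   removed (default [nafld_codes()]`$exclude_prefix`; a code is excluded
#'   when it equals an entry or extends a prefix entry, and is not in
#'   `include_codes`).
#' @return List with `data` (data frame `id`, `event`, `time_years`),
#'   `excluded` (data frame `id`, `reason`:
#'   `"excluded_code"`/`"prevalent"`), `n_cases`.
#' @export
derive_nafld_phenotype <- function(cohort,
                                   include_codes = nafld_codes()$include,
                                   exclude_codes =
                                     nafld_codes()$exclude_prefix) {
  stopifnot(length(include_codes) > 0, length(exclude_codes) > 0)
  sub <- cohort$subjects
  dg <- cohort$diagnoses
  check_codes(include_codes)
  if (nrow(dg) > 0) check_codes(dg$code)

  is_excluded_code <- function(code) {
    !(code %in% include_codes) &
      Reduce(`|`, lapply(exclude_codes, function(p) startsWith(code, p)))
  }

  excl_ids <- if (nrow(dg) > 0) unique(dg$id[is_excluded_code(dg$code)])
              else integer(0)
  inc <- dg[dg$code %in% include_codes & !(dg$id %in% excl_ids), ,
            drop = FALSE]
  first_date <- if (nrow(inc) > 0) {
    stats::aggregate(date ~ id, data = inc, FUN = min)
  } else data.frame(id = integer(0), date = as.Date(character(0)))

  enroll <- sub$enroll_date[match(first_date$id, sub$id)]
  prevalent_ids <- first_date$id[first_date$date <= enroll]

  keep <- !(sub$id %in% excl_ids) & !(sub$id %in% prevalent_ids)
  kept <- sub[keep, , drop = FALSE]
  ev_date <- first_date$date[match(kept$id, first_date$id)]
  event <- !is.na(ev_date)
  end_date <- as.Date(ifelse(event, ev_date, kept$censor_date),
                      origin = "1970-01-01")
  time_years <- as.numeric(end_date - kept$enroll_date) / 365.25
  excluded <- rbind(
    data.frame(id = excl_ids,
               reason = rep("excluded_code", length(excl_ids))),
    data.frame(id = prevalent_ids,
               reason = rep("prevalent", length(prevalent_ids))))
  list(data = data.frame(id = kept$id, event = as.integer(event),
                         time_years = time_years),
       excluded = excluded, n_cases = sum(event))
}

#' Cox proportional-hazards fit with per-SD hazard ratios
#'
#' Fits `survival::coxph` (partial likelihood, Efron tie correction by
#' default, Newton-Raphson) of the derived event data on the requested
#' covariates; covariates flagged for standardization are divided by the
#' analysis sample's SD so their hazard ratios are per SD.
#'
#' @param cohort A `cohort_table`.
#' @param pheno Output of [derive_nafld_phenotype()] (or any list with
#'   `data` containing `id`, `event`, `time_years`).
#' @param covariates Character vector of `subjects` column names to adjust
#'   for; `sex` is entered as an indicator for male.
#' @param standardize Character vector of covariates to standardize to the
#'   analysis sample's SD (typically the metabolite columns).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `survival_fit`: list with `coefficients` (data frame: `term`,
#'   `beta`, `se`, `hr`, `ci_low`, `ci_high`, `pval`), `n`, `n_events`,
#'   and the underlying `coxph` fit.
#' @export
cox_fit <- function(cohort, pheno, covariates, standardize = character(0),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  dat <- pheno$data
  if (sum(dat$event) < 1) stop("no events in the analysis sample")
  sub <- cohort$subjects[match(dat$id, cohort$subjects$id), , drop = FALSE]
  X <- data.frame(row.names = seq_len(nrow(sub)))
  for (cv in covariates) {
    v <- sub[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv)
    if (cv == "sex") v <- as.numeric(v == "male")
    if (is.character(v)) v <- as.numeric(as.factor(v))
    if (cv %in% standardize) v <- v / stats::sd(v)
    X[[cv]] <- as.numeric(v)
  }
  df <- cbind(data.frame(time = dat$time_years, event = dat$event), X)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0)) {
    stop("Cox model failed to converge")
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(se)) || any(abs(beta) > 20)) {
    stop("Cox fit degenerate (possible complete separation)")
  }
  coefs <- data.frame(term = names(beta), beta = unname(beta),
                      se = unname(se), hr = exp(unname(beta)),
                      ci_low = exp(unname(beta - 1.96 * se)),
                      ci_high = exp(unname(beta + 1.96 * se)),
                      pval = z_pval(unname(beta), unname(se)),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, n = nrow(df),
                 n_events = sum(df$event), fit = fit, ties = ties),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): %d subjects, %d events\n", x$ties, x$n,
              x$n_events))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Kaplan-Meier curves by group
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` per
#' group, via `survival::survfit`.
#'
#' @param time,event Follow-up times and event indicators.
#' @param groups Group labels (one curve per level); default one group.
#' @param at_times Optional times at which to report numbers at risk.
#' @return A `km_curve`: list with `curves` (data frame: `group`, `time`,
#'   `surv`, `n_risk`, `n_event`) and optionally `at_risk`.
#' @export
km_curve <- function(time, event, groups = NULL, at_times = NULL) {
  groups <- groups %||% rep("all", length(time))
  df <- data.frame(time = time, event = event, group = as.factor(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(df$group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, surv = sm$surv,
                       n_risk = sm$n.risk, n_event = sm$n.event,
                       stringsAsFactors = FALSE)
  out <- list(curves = curves)
  if (!is.null(at_times)) {
    sa <- summary(fit, times = at_times, extend = TRUE)
    ga <- if (is.null(sa$strata)) rep(levels(df$group)[1], length(sa$time))
          else sub("^group=", "", as.character(sa$strata))
    out$at_risk <- data.frame(group = ga, time = sa$time,
                              n_risk = sa$n.risk, surv = sa$surv,
                              stringsAsFactors = FALSE)
  }
  structure(out, class = "km_curve")
}

#' Quintile group labels
#'
#' Cut points at the empirical 20/40/60/80 percentiles; values equal to a
#' cut point go to the lower group (deterministic tie handling).
#'
#' @param values Numeric vector with at least 5 distinct values.
#' @return Integer labels 1-5.
#' @export
quintile_groups <- function(values) {
  if (length(unique(values)) < 5) {
    stop("need at least 5 distinct values for quintiles")
  }
  q <- stats::quantile(values, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  1L + (values > q[1]) + (values > q[2]) + (values > q[3]) +
    (values > q[4])
}

#' Metabolic-dyslipidemia groups from clinical lipid cut-offs
#'
#' NCEP-ATPIII cut-offs: high triglycerides at or above 1.7 mmol/L for
#' both sexes; low HDL-cholesterol below 1.0 mmol/L for men and below
#' 1.3 mmol/L for women. The high-TG/low-HDL combination is the
#' metabolic-dyslipidemia phenotype.
#'
#' @param tg Triglycerides (mmol/L, > 0).
#' @param hdl HDL-cholesterol (mmol/L, > 0).
#' @param sex `"male"` / `"female"`.
#' @return Factor with levels `lowTG_highHDL`, `highTG_highHDL`,
#'   `lowTG_lowHDL`, `highTG_lowHDL`.
#' @export
dyslipidemia_groups <- function(tg, hdl, sex) {
  stopifnot(all(tg > 0), all(hdl > 0))
  if (!all(sex %in% c("male", "female"))) {
    stop("unknown sex code; expected 'male'/'female'")
  }
  high_tg <- tg >= 1.7
  low_hdl <- hdl < ifelse(sex == "male", 1.0, 1.3)
  factor(paste0(ifelse(high_tg, "highTG", "lowTG"), "_",
                ifelse(low_hdl, "lowHDL", "highHDL")),
         levels = c("lowTG_highHDL", "highTG_highHDL", "lowTG_lowHDL",
                    "highTG_lowHDL"))
}

#' Baseline characteristics table
#'
#' Per variable and stratum: mean and SD for continuous variables; count
#' and percentage (one decimal, half-up) for categorical/indicator
#' variables.
#'
#' @param cohort A `cohort_table`.
#' @param strata Factor-like vector aligned with `subjects` rows (e.g.
#'   case/control); `NULL` for a single stratum.
#' @param continuous,categorical Column names of `subjects` to summarize.
#' @return Data frame with `variable`, `stratum`, `n`, `mean`, `sd`,
#'   `count`, `pct`, `display`.
#' @export
baseline_table <- function(cohort, strata = NULL,
                           continuous = c("age", "waist", "tg", "hdl"),
                           categorical = c("sex", "smoking",
                                           "medication")) {
  sub <- cohort$subjects
  stopifnot(nrow(sub) > 0)
  strata <- strata %||% rep("all", nrow(sub))
  rows <- list()
  for (s in unique(strata)) {
    grp <- sub[strata == s, , drop = FALSE]
    n_s <- nrow(grp)
    for (v in continuous) {
      x <- grp[[v]]
      m <- mean(x); sdv <- if (n_s > 1) stats::sd(x) else 0
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, stratum = as.character(s), n = n_s, mean = m,
        sd = sdv, count = NA_real_, pct = NA_real_,
        display = sprintf("%.1f (%.1f)", m, sdv),
        stringsAsFactors = FALSE)
    }
    for (v in categorical) {
      x <- grp[[v]]
      if (v == "sex") x <- as.numeric(x == "male")
      cnt <- sum(x == 1)
      pc <- pct(cnt, n_s)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, stratum = as.character(s), n = n_s,
        mean = NA_real_, sd = NA_real_, count = cnt, pct = pc,
        display = sprintf("%d (%.1f)", cnt, pc),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
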