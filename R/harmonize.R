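# Effect-allele harmonization of exposure and outcome summary statistics.

ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

#' Construct a harmonized exposure-outcome variant set
#'
#' Low-level constructor for the container the MR estimators consume: one
#' row per variant with exposure and outcome effects expressed on a common
#' effect allele. Usually produced by [harmonize()]; exposed directly so
#' that simulation studies can feed estimators without file round-trips.
#'
#' @param variants Data frame with columns `variant_id`, `beta_x`, `se_x`,
#'   `eaf_x`, `beta_y`, `se_y`, `eaf_y`.
#' @param exposure_name,outcome_name Trait labels.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param outcome_type `"binary"` (betas on the log-odds scale, estimates
#'   reported as odds ratios) or `"continuous"`.
#' @param dropped Data frame (`variant_id`, `reason`) of variants excluded
#'   during harmonization.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(variants, exposure_name, outcome_name,
                           n_exposure, n_outcome,
                           outcome_type = c("binary", "continuous"),
                           dropped = data.frame(variant_id = character(0),
                                                reason = character(0),
                                                stringsAsFactors = FALSE)) {
  outcome_type <- match.arg(outcome_type)
  need <- c("variant_id", "beta_x", "se_x", "eaf_x", "beta_y", "se_y",
            "eaf_y")
  stopifnot(all(need %in% names(variants)))
  variants <- as.data.frame(variants)[need]
  stopifnot(all(variants$se_x > 0), all(variants$se_y > 0))
  if (any(variants$variant_id %in% dropped$variant_id)) {
    stop("a variant appears both retained and dropped")
  }
  structure(list(variants = variants, dropped = dropped,
                 exposure_name = exposure_name,
                 outcome_name = outcome_name,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 outcome_type = outcome_type),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf(
    "Harmonized set %s -> %s: %d variants (%d dropped), n_x=%d, n_y=%d\n",
    x$exposure_name, x$outcome_name, nrow(x$variants), nrow(x$dropped),
    round(x$n_exposure), round(x$n_outcome)))
  invisible(x)
}

#' Harmonize exposure and outcome effects onto a common effect allele
#'
#' Aligns, per instrument, the outcome association to the exposure's
#' effect allele. Both studies are assumed reported on the forward strand;
#' complementary-strand notation is resolved by complementing before
#' matching. Rules per variant:
#' \itemize{
#'   \item same allele pair, same order: kept as-is;
#'   \item same pair, swapped order: outcome beta negated, outcome
#'     frequency reflected (`eaf -> 1 - eaf`);
#'   \item complementary-strand pair: alleles complemented, then as above;
#'   \item palindromic pair (A/T or G/C): orientation inferred from
#'     allele-frequency concordance (frequencies on the same side of 0.5
#'     mean same orientation); dropped as `palindromic_ambiguous` when
#'     either trait's minor-allele frequency exceeds
#'     `palindrome_eaf_limit`, where frequency is uninformative;
#'   \item incompatible allele pairs dropped.
#' }
#' Proxy instruments (see [substitute_proxies()]) inherit the original
#' variant's exposure record; the proxy's outcome effect is aligned through
#' the sign of the LD correlation instead of allele matching.
#'
#' @param exposure,outcome [sumstat_table()] objects.
#' @param instruments An `instrument_set` from [select_instruments()].
#' @param palindrome_eaf_limit Minor-allele-frequency ceiling above which a
#'   palindromic variant is considered unresolvable (default 0.42).
#' @return A [harmonized_set()].
#' @export
harmonize <- function(exposure, outcome, instruments,
                      palindrome_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "sumstat_table"),
            inherits(outcome, "sumstat_table"),
            inherits(instruments, "instrument_set"))
  if (length(instruments$variant_ids) == 0) stop("empty instrument set")
  exp_rec <- exposure$records
  out_rec <- outcome$records
  rownames(exp_rec) <- exp_rec$variant_id
  rownames(out_rec) <- out_rec$variant_id

  rows <- list()
  dropped <- list()
  drop <- function(id, why) {
    dropped[[length(dropped) + 1]] <<- data.frame(
      variant_id = id, reason = why, stringsAsFactors = FALSE)
  }
  n_x <- numeric(0); n_y <- numeric(0)

  for (id in instruments$variant_ids) {
    pxi <- match(id, instruments$proxies$variant_id)
    src <- if (is.na(pxi)) id else instruments$proxies$source_id[pxi]
    if (!(src %in% rownames(exp_rec))) { drop(id, "missing_in_exposure"); next }
    if (!(id %in% rownames(out_rec))) { drop(id, "missing_in_outcome"); next }
    ex <- exp_rec[src, ]
    ou <- out_rec[id, ]

    if (!is.na(pxi)) {
      # proxy: align outcome effect through the LD correlation sign
      s <- sign(instruments$proxies$r[pxi])
      beta_y <- s * ou$beta
      eaf_y <- if (s < 0) 1 - ou$eaf else ou$eaf
    } else {
      ea_x <- ex$effect_allele; oa_x <- ex$other_allele
      ea_y <- ou$effect_allele; oa_y <- ou$other_allele
      if (is_palindromic(ea_x, oa_x)) {
        maf_x <- min(ex$eaf, 1 - ex$eaf)
        maf_y <- min(ou$eaf, 1 - ou$eaf)
        same_pair <- (ea_y == ea_x & oa_y == oa_x) |
          (ea_y == oa_x & oa_y == ea_x)
        if (!same_pair) { drop(id, "incompatible_alleles"); next }
        if (maf_x > palindrome_eaf_limit || maf_y > palindrome_eaf_limit) {
          drop(id, "palindromic_ambiguous"); next
        }
        concordant <- (ex$eaf < 0.5) == (ou$eaf < 0.5)
        if (concordant) {
          beta_y <- ou$beta; eaf_y <- ou$eaf
        } else {
          beta_y <- -ou$beta; eaf_y <- 1 - ou$eaf
        }
      } else {
        # try direct match, then complementary-strand match
        flip <- NA
        if (ea_y == ea_x && oa_y == oa_x) flip <- FALSE
        else if (ea_y == oa_x && oa_y == ea_x) flip <- TRUE
        else {
          ea_c <- ALLELE_COMPLEMENT[[ea_y]]
          oa_c <- ALLELE_COMPLEMENT[[oa_y]]
          if (ea_c == ea_x && oa_c == oa_x) flip <- FALSE
          else if (ea_c == oa_x && oa_c == ea_x) flip <- TRUE
        }
        if (is.na(flip)) { drop(id, "incompatible_alleles"); next }
        beta_y <- if (flip) -ou$beta else ou$beta
        eaf_y <- if (flip) 1 - ou$eaf else ou$eaf
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = id, beta_x = ex$beta, se_x = ex$se, eaf_x = ex$eaf,
      beta_y = beta_y, se_y = ou$se, eaf_y = eaf_y,
      stringsAsFactors = FALSE)
    n_x <- c(n_x, ex$n); n_y <- c(n_y, ou$n)
  }

  if (length(rows) == 0) {
    stop("harmonization dropped every instrument for exposure '",
         exposure$trait_name, "'")
  }
  harmonized_set(
    do.call(rbind, rows),
    exposure_name = exposure$trait_name,
    outcome_name = outcome$trait_name,
    n_exposure = stats::median(n_x), n_outcome = stats::median(n_y),
    outcome_type = outcome$trait_type,
    dropped = if (length(dropped)) do.call(rbind, dropped) else
      data.frame(variant_id = character(0), reason = character(0),
                 stringsAsFactors = FALSE))
}

#' Construct a multi-exposure harmonized set
#'
#' Container for multivariable MR: per variant, a row of exposure effects
#' (one column per exposure) plus the outcome effect, all on a common
#' effect allele.
#'
#' @param beta_x,se_x Numeric matrices, variants by exposures, with column
#'   names naming the exposures.
#' @param beta_y,se_y Outcome effect and standard error vectors.
#' @param variant_ids Variant identifiers.
#' @param n_exposure Named vector of exposure GWAS sample sizes.
#' @param n_outcome Outcome GWAS sample size.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @return An `mvmr_set`.
#' @export
mvmr_set <- function(beta_x, se_x, beta_y, se_y, variant_ids,
                     n_exposure, n_outcome,
                     outcome_type = c("binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  beta_x <- as.matrix(beta_x); se_x <- as.matrix(se_x)
  stopifnot(nrow(beta_x) == length(beta_y),
            all(dim(beta_x) == dim(se_x)),
            length(se_y) == length(beta_y),
            length(variant_ids) == length(beta_y))
  if (is.null(colnames(beta_x))) {
    colnames(beta_x) <- paste0("exposure_", seq_len(ncol(beta_x)))
  }
  colnames(se_x) <- colnames(beta_x)
  structure(list(beta_x = beta_x, se_x = se_x,
                 beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
                 variant_ids = as.character(variant_ids),
                 exposure_names = colnames(beta_x),
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 outcome_type = outcome_type),
            class = "mvmr_set")
}

#' Harmonize several exposures and one outcome onto shared instruments
#'
#' Runs [harmonize()] for each exposure against the outcome on the same
#' instrument set (the univariable instruments of the primary exposure,
#' possibly after proxy substitution) and intersects the retained
#' variants.
#'
#' @param exposures Named list of [sumstat_table()] objects; the first is
#'   the primary exposure.
#' @param outcome A [sumstat_table()].
#' @param instruments An `instrument_set`.
#' @param palindrome_eaf_limit Passed to [harmonize()].
#' @return An [mvmr_set()].
#' @export
mvmr_harmonize <- function(exposures, outcome, instruments,
                           palindrome_eaf_limit = 0.42) {
  stopifnot(length(exposures) >= 2)
  hs <- lapply(exposures, harmonize, outcome = outcome,
               instruments = instruments,
               palindrome_eaf_limit = palindrome_eaf_limit)
  ids <- Reduce(intersect, lapply(hs, function(h) h$variants$variant_id))
  if (length(ids) == 0) stop("no variant harmonized across all exposures")
  rowsel <- lapply(hs, function(h) {
    h$variants[match(ids, h$variants$variant_id), ]
  })
  beta_x <- vapply(rowsel, function(v) v$beta_x, numeric(length(ids)))
  se_x <- vapply(rowsel, function(v) v$se_x, numeric(length(ids)))
  nm <- names(exposures) %||% vapply(hs, function(h) h$exposure_name, "")
  colnames(beta_x) <- nm; colnames(se_x) <- nm
  mvmr_set(beta_x, se_x,
           beta_y = rowsel[[1]]$beta_y, se_y = rowsel[[1]]$se_y,
           variant_ids = ids,
           n_exposure = stats::setNames(
             vapply(hs, function(h) h$n_exposure, 0), nm),
           n_outcome = hs[[1]]$n_outcome,
           outcome_type = hs[[1]]$outcome_type)
}
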