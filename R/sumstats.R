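# GWAS summary-statistic tables and LD matrices: containers, validation, I/O.

SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                  "other_allele", "eaf", "beta", "se", "pval", "n")

#' Construct a validated GWAS summary-statistic table
#'
#' The central container consumed by every MR stage: one association record
#' per variant for a single trait. Rows violating the record invariants are
#' dropped (not repaired) and tallied by reason, mirroring how a careful
#' analyst treats a malformed public summary-statistics file.
#'
#' Invariants enforced per record: alleles are single A/C/G/T bases and
#' differ; `se > 0`; `0 < eaf < 1`; `pval` in (0, 1] and consistent with the
#' two-sided normal p-value implied by `beta/se` (within 10% on the log-p
#' scale, or equal after rounding to one significant digit); `variant_id`
#' unique.
#'
#' @param records Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_name Trait label.
#' @param trait_type `"continuous"` (beta per SD) or `"binary"` (log-odds).
#' @return A `sumstat_table`: list with `trait_name`, `trait_type`,
#'   `records` (validated data frame) and `drops` (data frame of
#'   `variant_id`, `reason` for discarded rows).
#' @export
sumstat_table <- function(records, trait_name,
                          trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTAT_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("summary-statistic table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[SUMSTAT_COLS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- why
  }
  num_ok <- stats::complete.cases(records[c("pos", "eaf", "beta", "se",
                                            "pval", "n")])
  flag(!num_ok, "missing_values")
  flag(!(records$effect_allele %in% c("A", "C", "G", "T")) |
         !(records$other_allele %in% c("A", "C", "G", "T")),
       "invalid_alleles")
  flag(records$effect_allele == records$other_allele, "degenerate_alleles")
  flag(records$se <= 0, "nonpositive_se")
  flag(records$eaf <= 0 | records$eaf >= 1, "eaf_out_of_range")
  flag(records$pval <= 0 | records$pval > 1, "pval_out_of_range")
  ok_now <- is.na(reason)
  if (any(ok_now)) {
    incons <- !pval_consistent(records$beta[ok_now], records$se[ok_now],
                               records$pval[ok_now])
    idx <- which(ok_now)[incons]
    reason[idx] <- "pval_inconsistent"
  }
  flag(duplicated(records$variant_id), "duplicate_variant")

  drops <- data.frame(variant_id = records$variant_id[!is.na(reason)],
                      reason = reason[!is.na(reason)],
                      stringsAsFactors = FALSE)
  kept <- records[is.na(reason), , drop = FALSE]
  if (nrow(kept) == 0) {
    stop("no valid summary-statistic rows for trait '", trait_name, "'")
  }
  rownames(kept) <- NULL
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 records = kept, drops = drops),
            class = "sumstat_table")
}

# stored p agrees with 2*pnorm(-|beta/se|): within 10% on the p scale
# (compared as |delta log p| <= log(1/0.9)) or identical at 1 significant
# digit, which absorbs the rounding used in published files
pval_consistent <- function(beta, se, pval) {
  logp <- log(2) + stats::pnorm(-abs(beta / se), log.p = TRUE)
  close <- abs(logp - log(pval)) <= -log(0.9) + 1e-12
  rounded <- signif(exp(logp), 1) == signif(pval, 1)
  close | rounded | (pval <= 1e-300 & logp <= log(1e-300))
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants (%d dropped)\n",
              x$trait_name, x$trait_type, nrow(x$records), nrow(x$drops)))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited file
#'
#' @param path Tab-separated file with a header row.
#' @param column_map Optional named character vector mapping the standard
#'   column names (`variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the file's column
#'   names, for files using a different dialect.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_name Trait label; defaults to the file name.
#' @return A [sumstat_table()]; invalid rows are dropped with reasons
#'   recorded in `$drops`.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_type = c("continuous", "binary"),
                          trait_name = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(dat))
    if (length(missing_src) > 0) {
      stop("mapped column(s) absent from file: ",
           paste(missing_src, collapse = ", "))
    }
    dat <- dat[unname(column_map)]
    names(dat) <- names(column_map)
  }
  sumstat_table(dat, trait_name %||% basename(path), trait_type)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' @param x A `sumstat_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstat_table"))
  data.table::fwrite(x$records, path, sep = "\t")
  invisible(path)
}

#' Construct an LD matrix
#'
#' @param r Square numeric matrix of pairwise LD correlations, unit
#'   diagonal, entries in \[-1, 1\].
#' @param variant_ids Variant identifiers, one per row/column.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(variant_ids)) stop("LD matrix needs variant identifiers")
  variant_ids <- as.character(variant_ids)
  stopifnot(nrow(r) == ncol(r), length(variant_ids) == nrow(r))
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix is not symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-8) stop("LD correlations must lie in [-1, 1]")
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r = r), class = "ld_matrix")
}

#' Read an LD matrix from a square TSV with id header row and column
#' @param path File path.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  dat <- as.data.frame(data.table::fread(path, sep = "\t"))
  ids <- as.character(dat[[1]])
  m <- as.matrix(dat[, -1, drop = FALSE])
  ld_matrix(m, ids)
}

#' Write an LD matrix as a square TSV
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  out <- data.frame(variant_id = ld$variant_ids, ld$r,
                    check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

# squared LD correlation between two variants (error when absent)
ld_r <- function(ld, a, b) {
  if (!(a %in% ld$variant_ids)) stop("variant absent from LD matrix: ", a)
  if (!(b %in% ld$variant_ids)) stop("variant absent from LD matrix: ", b)
  ld$r[a, b]
}
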