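# Instrument selection: p-value thresholding, greedy LD clumping, region
# exclusion, and proxy substitution for variants missing from the outcome.

#' Pleiotropic glucokinase-regulator region, widened by flanks
#'
#' The GCKR locus (chromosome 2) has a primary hepatic effect and
#' influences a wide range of circulating metabolites, violating the
#' exclusion restriction; sensitivity analyses drop all instruments in the
#' region plus a flank on each side.
#'
#' @param flank_bp Flank added up- and downstream (default 500 kb).
#' @return One-row data frame with `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @export
gckr_region <- function(flank_bp = 5e5) {
  data.frame(chrom = "2", start = 27219709 - flank_bp,
             end = 28246554 + flank_bp, stringsAsFactors = FALSE)
}

parse_regions <- function(regions) {
  if (is.null(regions)) return(NULL)
  if (is.character(regions)) {
    parts <- regmatches(regions,
                        regexec("^([^:]+):([0-9]+)-([0-9]+)$", regions))
    bad <- vapply(parts, length, 1L) != 4L
    if (any(bad)) stop("malformed region string: ", regions[bad][1])
    regions <- data.frame(
      chrom = vapply(parts, `[`, "", 2L),
      start = as.numeric(vapply(parts, `[`, "", 3L)),
      end = as.numeric(vapply(parts, `[`, "", 4L)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  regions
}

in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos >= regions$start[i] & pos <= regions$end[i])
  }
  hit
}

#' Select genetic instruments by significance and greedy LD clumping
#'
#' Candidates are the variants with `pval < p_threshold` (strict). Variants
#' falling inside any excluded span are removed first. The remainder are
#' clumped greedily: candidates are scanned in order of ascending p-value
#' (ties broken by chromosome, position, then identifier); each retained
#' index variant removes every remaining candidate on the same chromosome
#' within `clump_window_bp` whose squared LD correlation with it exceeds
#' `clump_r2`.
#'
#' @param exposure A [sumstat_table()] for the exposure trait.
#' @param ld An [ld_matrix()] covering all candidate variants.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param clump_r2 LD r-squared bound (default 0.01).
#' @param clump_window_bp Clumping window in base pairs (default 1 Mb).
#' @param exclude_regions Optional regions to blacklist: a data frame with
#'   `chrom`, `start`, `end`, or strings `"chrom:start-end"` (1-based,
#'   inclusive); see [gckr_region()]. Flank widening is the caller's
#'   responsibility.
#' @return An `instrument_set`: list with `exposure_name`, `variant_ids`
#'   (retained, in retention order) and `provenance` (data frame tagging
#'   every candidate `direct`, `removed:clumped` or
#'   `removed:region_excluded`).
#' @export
select_instruments <- function(exposure, ld, p_threshold = 5e-8,
                               clump_r2 = 0.01, clump_window_bp = 1e6,
                               exclude_regions = NULL) {
  stopifnot(inherits(exposure, "sumstat_table"), inherits(ld, "ld_matrix"))
  stopifnot(p_threshold > 0, p_threshold < 1, clump_r2 > 0, clump_r2 < 1)
  rec <- exposure$records
  cand <- rec[rec$pval < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no variant passes the p-value threshold ", p_threshold,
         " for exposure '", exposure$trait_name, "'")
  }
  prov <- data.frame(variant_id = cand$variant_id,
                     tag = "direct", stringsAsFactors = FALSE)

  regions <- parse_regions(exclude_regions)
  if (!is.null(regions)) {
    excluded <- in_regions(cand$chrom, cand$pos, regions)
    prov$tag[excluded] <- "removed:region_excluded"
    cand <- cand[!excluded, , drop = FALSE]
  }

  missing_ld <- setdiff(cand$variant_id, ld$variant_ids)
  if (length(missing_ld) > 0) {
    stop("LD matrix does not cover candidate variant(s): ",
         paste(utils::head(missing_ld, 5), collapse = ", "))
  }

  # deterministic greedy clumping: ascending p, ties by (chrom, pos, id)
  ord <- order(cand$pval, cand$chrom, cand$pos, cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  retained <- character(0)
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    retained <- c(retained, cand$variant_id[i])
    if (i == nrow(cand)) break
    rest <- which(alive)
    rest <- rest[rest > i]
    if (length(rest) == 0) break
    near <- cand$chrom[rest] == cand$chrom[i] &
      abs(cand$pos[rest] - cand$pos[i]) <= clump_window_bp
    if (!any(near)) next
    r2 <- ld$r[cand$variant_id[i], cand$variant_id[rest[near]]]^2
    drop_ids <- cand$variant_id[rest[near]][r2 > clump_r2]
    alive[cand$variant_id %in% drop_ids] <- FALSE
    prov$tag[prov$variant_id %in% drop_ids] <- "removed:clumped"
  }

  structure(list(exposure_name = exposure$trait_name,
                 variant_ids = retained,
                 provenance = prov,
                 proxies = data.frame(variant_id = character(0),
                                      source_id = character(0),
                                      r = numeric(0),
                                      stringsAsFactors = FALSE)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d retained of %d candidates\n",
              x$exposure_name, length(x$variant_ids), nrow(x$provenance)))
  invisible(x)
}

#' Find a proxy variant present in the outcome data
#'
#' Among outcome variants covered by the LD matrix, returns the one with
#' the highest squared LD correlation to `variant_id`, provided that
#' r-squared is strictly greater than `min_r2`; otherwise `NULL`.
#'
#' @param variant_id Variant to be proxied (must be in the LD matrix).
#' @param outcome A [sumstat_table()] for the outcome trait.
#' @param ld An [ld_matrix()].
#' @param min_r2 Strict lower bound on the proxy r-squared (default 0.8).
#' @return The proxy identifier with attributes `r` (signed LD correlation
#'   with the proxied variant) and `r2`, or `NULL` when no variant
#'   qualifies.
#' @export
find_proxy <- function(variant_id, outcome, ld, min_r2 = 0.8) {
  stopifnot(min_r2 > 0, min_r2 < 1)
  if (!(variant_id %in% ld$variant_ids)) {
    stop("variant absent from LD matrix: ", variant_id)
  }
  cands <- setdiff(intersect(outcome$records$variant_id, ld$variant_ids),
                   variant_id)
  if (length(cands) == 0) return(NULL)
  r <- ld$r[variant_id, cands]
  r2 <- r^2
  ok <- r2 > min_r2
  if (!any(ok)) return(NULL)
  # argmax by r2; ties broken by identifier for determinism
  cands <- cands[ok]; r <- r[ok]; r2 <- r2[ok]
  best <- order(-r2, cands)[1]
  structure(cands[best], r = unname(r[best]), r2 = unname(r2[best]))
}

#' Substitute proxies for instruments missing from the outcome data
#'
#' Retained instruments absent from the outcome table are replaced by their
#' best LD proxy (see [find_proxy()]); instruments with no qualifying proxy
#' are dropped. Proxy provenance (`proxy:<original_id>`) and the signed LD
#' correlation are recorded so that harmonization can align the proxy's
#' outcome effect to the original variant's effect allele.
#'
#' @param instruments An `instrument_set`.
#' @param outcome A [sumstat_table()].
#' @param ld An [ld_matrix()].
#' @param min_r2 Strict proxy r-squared bound (default 0.8).
#' @return The updated `instrument_set`.
#' @export
substitute_proxies <- function(instruments, outcome, ld, min_r2 = 0.8) {
  stopifnot(inherits(instruments, "instrument_set"))
  out_ids <- outcome$records$variant_id
  ids <- instruments$variant_ids
  for (id in ids[!(ids %in% out_ids)]) {
    px <- find_proxy(id, outcome, ld, min_r2)
    i <- match(id, instruments$variant_ids)
    j <- match(id, instruments$provenance$variant_id)
    if (is.null(px)) {
      instruments$variant_ids <- instruments$variant_ids[-i]
      instruments$provenance$tag[j] <- "removed:no_proxy"
    } else {
      instruments$variant_ids[i] <- as.character(px)
      instruments$provenance$tag[j] <- paste0("proxy:", id)
      instruments$proxies <- rbind(
        instruments$proxies,
        data.frame(variant_id = as.character(px), source_id = id,
                   r = attr(px, "r"), stringsAsFactors = FALSE))
    }
  }
  instruments
}
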