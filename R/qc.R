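# Locus-level quality/length filters and genotype-matrix filters.
#
# Thresholds are strict (">"): a DEL at exactly QUAL 200 is removed, a locus
# at exactly 90% call rate is removed, a locus at exactly 5% MAF is removed.

#' QC configuration
#'
#' @param min_qual quality that DEL/DUP/INV loci must strictly exceed
#'   (default 200).
#' @param mei_filter_token filter token MEI loci must carry (default
#'   `"PASS"`).
#' @param min_len,max_len inclusive length bounds in bp (defaults 50 and
#'   1e6; loci above 1 Mb are unreliable at short-read scale).
#' @param sample_call_rate,locus_call_rate call-rate fractions that samples
#'   and loci must strictly exceed (default 0.90).
#' @param min_maf minor-allele frequency loci must strictly exceed
#'   (default 0.05), computed on non-missing dosages.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(min_qual = 200, mei_filter_token = "PASS",
                      min_len = 50, max_len = 1e6,
                      sample_call_rate = 0.90, locus_call_rate = 0.90,
                      min_maf = 0.05) {
  stopifnot(min_len > 0, min_len < max_len,
            sample_call_rate > 0, sample_call_rate < 1,
            locus_call_rate > 0, locus_call_rate < 1,
            min_maf > 0, min_maf < 1)
  structure(list(min_qual = min_qual, mei_filter_token = mei_filter_token,
                 min_len = min_len, max_len = max_len,
                 sample_call_rate = sample_call_rate,
                 locus_call_rate = locus_call_rate, min_maf = min_maf),
            class = "qc_config")
}

#' Filter merged loci on quality and length
#'
#' DEL/DUP/INV loci are kept iff `qual > min_qual` and
#' `min_len <= length <= max_len`; MEI loci iff their filter token equals
#' `mei_filter_token`.  Every removed locus carries a reason.
#'
#' @param loci merged-locus data frame with `qual`, `filter`, `length`.
#' @param config a [qc_config()].
#' @return list with `kept` (locus data frame) and `removed` (locus data
#'   frame with a `reason` column).
#' @export
filter_loci <- function(loci, config = qc_config()) {
  mei <- loci$svtype == "MEI"
  reason <- rep(NA_character_, nrow(loci))

  no_qual <- !mei & is.na(loci$qual)
  if (any(no_qual)) {
    warning(sum(no_qual), " DEL/DUP/INV locus/loci without QUAL removed")
    reason[no_qual] <- "no-qual"
  }
  low_qual <- !mei & !is.na(loci$qual) & loci$qual <= config$min_qual
  reason[low_qual & is.na(reason)] <- "low-qual"
  under <- !mei & loci$length < config$min_len
  reason[under & is.na(reason)] <- "under-length"
  over <- !mei & loci$length > config$max_len
  reason[over & is.na(reason)] <- "over-length"
  mei_fail <- mei & loci$filter != config$mei_filter_token
  reason[mei_fail & is.na(reason)] <- "mei-filter"

  removed <- loci[!is.na(reason), , drop = FALSE]
  if (nrow(removed) > 0) removed$reason <- reason[!is.na(reason)]
  else removed$reason <- character(0)
  list(kept = loci[is.na(reason), , drop = FALSE], removed = removed)
}

#' Filter a genotype matrix on call rates and MAF
#'
#' Three stages, in fixed order: (1) drop samples whose call rate does not
#' exceed `sample_call_rate`; (2) drop loci whose call rate (over the
#' remaining samples) does not exceed `locus_call_rate`; (3) drop loci whose
#' minor-allele frequency (over non-missing dosages of remaining samples)
#' does not exceed `min_maf`.
#'
#' @param gm an [sv_geno()] object or dosage matrix.
#' @param config a [qc_config()].
#' @return list with `gm` (filtered [sv_geno()]) and `report` (counts
#'   dropped per stage).
#' @export
filter_genotype_matrix <- function(gm, config = qc_config()) {
  g <- if (inherits(gm, "sv_geno")) gm else sv_geno(gm)
  d <- g$dosages

  sample_cr <- colMeans(!is.na(d))
  keep_s <- sample_cr > config$sample_call_rate
  d <- d[, keep_s, drop = FALSE]

  locus_cr <- rowMeans(!is.na(d))
  keep_cr <- locus_cr > config$locus_call_rate
  d <- d[keep_cr, , drop = FALSE]

  p <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf > config$min_maf
  d <- d[keep_maf, , drop = FALSE]

  if (nrow(d) == 0 || ncol(d) == 0) stop("no loci survive genotype QC")
  report <- list(samples_dropped = sum(!keep_s),
                 loci_dropped_call_rate = sum(!keep_cr),
                 loci_dropped_maf = sum(!keep_maf),
                 n_loci = nrow(d), n_samples = ncol(d))
  samples <- if (!is.null(g$samples)) {
    g$samples[g$samples$sample %in% colnames(d), , drop = FALSE]
  } else NULL
  loci <- if (!is.null(g$loci)) {
    g$loci[g$loci$locus_id %in% rownames(d), , drop = FALSE]
  } else NULL
  list(gm = sv_geno(d, samples, loci), report = report)
}
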