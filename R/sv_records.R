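#' Construct a table of SV call records
#'
#' An SV record is the atom of merging: one call from one caller on one
#' sample.  Records are stored as an ordinary data frame with one row per
#' call; all pipeline functions accept and return this representation.
#'
#' Coordinates are 1-based inclusive (VCF convention).  For `DEL`, `DUP` and
#' `INV` the length is `end - start + 1`.  Mobile element insertions (`MEI`)
#' are point events: `end == start` and `length` is the length of the
#' inserted element.
#'
#' @param chrom chromosome names.
#' @param start 1-based left breakpoint positions.
#' @param end 1-based right breakpoint positions (equal to `start` for MEI).
#' @param svtype one of `"DEL"`, `"DUP"`, `"INV"`, `"MEI"` per record.
#' @param mei_family `"ERV"`, `"LINE"` or `"SINE"` for MEI records, `"none"`
#'   otherwise.
#' @param length event length in bp; recomputed from breakpoints for
#'   `DEL`/`DUP`/`INV` when `NULL`.
#' @param qual caller quality score.
#' @param filter caller filter token, e.g. `"PASS"`.
#' @param orientation breakpoint strand-configuration token; defaults to a
#'   per-type token.
#' @param caller,sample source caller and sample labels.
#' @return a data frame of class `sv_records`.
#' @export
sv_records <- function(chrom, start, end, svtype,
                       mei_family = "none", length = NULL,
                       qual = NA_real_, filter = "PASS",
                       orientation = NULL, caller = "caller", sample = "sample") {
  n <- max(lengths(list(chrom, start, end, svtype)))
  rec <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    svtype = rep_len(as.character(svtype), n),
    mei_family = rep_len(as.character(mei_family), n),
    qual = rep_len(as.numeric(qual), n),
    filter = rep_len(as.character(filter), n),
    caller = rep_len(as.character(caller), n),
    sample = rep_len(as.character(sample), n),
    stringsAsFactors = FALSE
  )
  rec$orientation <- if (is.null(orientation)) {
    unname(DEFAULT_ORIENTATION[rec$svtype])
  } else {
    rep_len(as.character(orientation), n)
  }
  rec$length <- if (is.null(length)) {
    ifelse(rec$svtype == "MEI", 0L, rec$end - rec$start + 1L)
  } else {
    rep_len(as.integer(length), n)
  }
  rec <- rec[, c("chrom", "start", "end", "svtype", "mei_family", "length",
                 "qual", "filter", "orientation", "caller", "sample")]
  class(rec) <- c("sv_records", "data.frame")
  validate_sv_records(rec)
}

#' Validate SV record invariants
#'
#' Checks start >= 1, end >= start for span types, end == start for MEI,
#' non-negative lengths, and that `mei_family` is set exactly for MEI records.
#'
#' @param rec a data frame of SV records.
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_sv_records <- function(rec) {
  stopifnot(is.data.frame(rec))
  needed <- c("chrom", "start", "end", "svtype", "mei_family", "length",
              "qual", "filter", "orientation", "caller", "sample")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols) > 0) {
    stop("sv_records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(rec) == 0) return(rec)
  bad_type <- !rec$svtype %in% SV_TYPES
  if (any(bad_type)) {
    stop("unknown svtype token(s): ",
         paste(unique(rec$svtype[bad_type]), collapse = ", "))
  }
  if (any(rec$start < 1)) stop("start must be >= 1")
  span <- rec$svtype != "MEI"
  if (any(rec$end[span] < rec$start[span])) {
    stop("end < start for a DEL/DUP/INV record")
  }
  if (any(rec$end[!span] != rec$start[!span])) {
    stop("MEI records must have end == start")
  }
  if (any(rec$length < 0)) stop("negative length")
  fam_ok <- ifelse(rec$svtype == "MEI",
                   rec$mei_family %in% MEI_FAMILIES,
                   rec$mei_family == "none")
  if (!all(fam_ok)) {
    stop("mei_family must be ERV/LINE/SINE for MEI and 'none' otherwise")
  }
  rec
}

#' Construct a sample-information table
#'
#' @param sample sample identifiers.
#' @param breed breed label per sample.
#' @param generation `"F0"` or `"F2"`.
#' @param sex sample sex (required for F2 samples).
#' @param batch slaughter batch (required for F2 samples).
#' @return a data frame with one row per sample.
#' @export
sample_info <- function(sample, breed, generation, sex = NA, batch = NA) {
  df <- data.frame(sample = as.character(sample),
                   breed = as.character(breed),
                   generation = as.character(generation),
                   sex = as.character(sex),
                   batch = as.character(batch),
                   stringsAsFactors = FALSE)
  if (!all(df$generation %in% c("F0", "F2"))) {
    stop("generation must be F0 or F2")
  }
  f2 <- df$generation == "F2"
  if (any(is.na(df$sex[f2])) || any(is.na(df$batch[f2]))) {
    stop("every F2 sample needs sex and batch")
  }
  df
}

#' Bundle a dosage matrix with its sample metadata
#'
#' The genotype container used across QC, popgen, screening and GWAS:
#' an integer matrix of alternate-allele dosages (loci in rows, samples in
#' columns, `NA` for missing calls) plus a sample-information table and,
#' optionally, the merged-locus table the rows refer to.
#'
#' @param dosages numeric matrix in \{0, 1, 2, NA\}, loci x samples, with
#'   rownames (locus ids) and colnames (sample ids).
#' @param samples data frame as returned by [sample_info()]; matched to
#'   `colnames(dosages)`.
#' @param loci optional merged-locus table matched to `rownames(dosages)`.
#' @return a list of class `sv_geno` with elements `dosages`, `samples`,
#'   `loci`.
#' @export
sv_geno <- function(dosages, samples = NULL, loci = NULL) {
  stopifnot(is.matrix(dosages))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) > 0 && !all(vals %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (is.null(colnames(dosages))) stop("dosages needs sample colnames")
  if (!is.null(samples)) {
    if (!setequal(samples$sample, colnames(dosages))) {
      stop("sample metadata does not match dosage columns")
    }
    samples <- samples[match(colnames(dosages), samples$sample), , drop = FALSE]
  }
  if (!is.null(loci) && !is.null(rownames(dosages))) {
    if (!all(rownames(dosages) %in% loci$locus_id)) {
      stop("dosage rownames not all present in locus table")
    }
    loci <- loci[match(rownames(dosages), loci$locus_id), , drop = FALSE]
  }
  structure(list(dosages = dosages, samples = samples, loci = loci),
            class = "sv_geno")
}

#' @export
print.sv_geno <- function(x, ...) {
  cat("sv_geno:", nrow(x$dosages), "loci x", ncol(x$dosages), "samples;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.sv_geno <- function(x) dim(x$dosages)

# natural-order rank for chromosome names: "chr2" < "chr10"; non-numeric
# names fall back to lexicographic order after the numeric ones.
chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(sub("^(chr|Chr|CHR)?", "", u)))
  u_sorted <- u[order(is.na(num), num, u)]
  match(chrom, u_sorted)
}
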