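# VCF input/output for SV records and merged loci.
#
# Reading goes through vcfR; writing is a small deterministic formatter so
# that identical inputs always produce byte-identical files (a property the
# merge and round-trip contracts rely on).

VCF_INFO_HEADER <- c(
  '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
  '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
  '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of the variant; negative for deletions">',
  '##INFO=<ID=MEINFO,Number=4,Type=String,Description="Mobile element info of the form NAME,START,END,POLARITY">',
  '##INFO=<ID=ORIENT,Number=1,Type=String,Description="Breakpoint strand configuration">',
  '##INFO=<ID=CALLER,Number=1,Type=String,Description="Source caller label(s), |-separated">',
  '##INFO=<ID=SRCSAMPLE,Number=1,Type=String,Description="Source sample label(s), |-separated">'
)

# deterministic, idempotent numeric formatting (no padding, no scientific)
vcf_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "." else format(v, trim = TRUE, scientific = FALSE, digits = 15)
  }, character(1))
}

join_bar <- function(x) {
  vapply(x, function(v) paste(sort(unique(as.character(v))), collapse = "|"),
         character(1))
}

#' Write SV records or merged loci as VCF 4.2
#'
#' Records are sorted deterministically by chromosome (natural order), start
#' position and type; two calls on the same input produce byte-identical
#' files.  When a genotype matrix is supplied a `GT` FORMAT column is written
#' per sample (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param records an `sv_records` data frame or a merged-locus table.
#' @param path output file path.
#' @param genotypes optional [sv_geno()] object or dosage matrix whose
#'   rownames match `records$locus_id`.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path, genotypes = NULL) {
  rec <- as.data.frame(records)
  if (is.null(rec$qual)) rec$qual <- NA_real_
  if (is.null(rec$filter)) rec$filter <- "."
  if (is.null(rec$orientation)) {
    rec$orientation <- unname(DEFAULT_ORIENTATION[rec$svtype])
  }
  if (is.null(rec$caller) && is.null(rec$callers)) rec$caller <- "."
  if (is.null(rec$sample) && is.null(rec$samples)) rec$sample <- "."
  if (is.null(rec$mei_family)) rec$mei_family <- "none"
  rec$filter[is.na(rec$filter)] <- "."
  if (nrow(rec) > 0 &&
      any(is.na(suppressWarnings(as.numeric(sub("^(chr|Chr|CHR)?", "",
                                                unique(rec$chrom))))))) {
    warning("non-numeric chromosome names: falling back to lexicographic order")
  }
  ord <- order(chrom_rank(rec$chrom), rec$start, rec$svtype)
  rec <- rec[ord, , drop = FALSE]

  dos <- NULL
  if (!is.null(genotypes)) {
    dos <- if (inherits(genotypes, "sv_geno")) genotypes$dosages else genotypes
    if (is.null(rec$locus_id) || !all(rec$locus_id %in% rownames(dos))) {
      stop("genotype rownames must cover records$locus_id")
    }
    dos <- dos[rec$locus_id, , drop = FALSE]
  }

  caller <- if (!is.null(rec$callers)) join_bar(rec$callers) else rec$caller
  smp <- if (!is.null(rec$samples)) join_bar(rec$samples) else rec$sample
  svlen <- ifelse(rec$svtype == "DEL", -rec$length, rec$length)
  info <- paste0("SVTYPE=", rec$svtype,
                 ";END=", rec$end,
                 ";SVLEN=", svlen,
                 ";ORIENT=", rec$orientation,
                 ";CALLER=", caller,
                 ";SRCSAMPLE=", smp)
  is_mei <- rec$svtype == "MEI"
  info[is_mei] <- paste0(info[is_mei], ";MEINFO=", rec$mei_family[is_mei],
                         ",1,", rec$length[is_mei], ",+")

  id <- if (!is.null(rec$locus_id)) rec$locus_id else rep(".", nrow(rec))
  body <- if (nrow(rec) == 0) character(0) else
    paste(rec$chrom, rec$start, id, "N",
          paste0("<", rec$svtype, ">"),
          vcf_num(rec$qual), rec$filter, info, sep = "\t")

  contigs <- unique(rec$chrom[order(chrom_rank(rec$chrom))])
  header <- c("##fileformat=VCFv4.2", "##source=svforge",
              if (length(contigs) > 0) paste0("##contig=<ID=", contigs, ">"),
              VCF_INFO_HEADER)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(dos)) {
    header <- c(header,
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
    cols <- c(cols, "FORMAT", colnames(dos))
    gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow = nrow(dos))
    gt[is.na(gt)] <- "./."
    body <- paste(body, "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  }
  con <- file(path, open = "wb")  # binary mode: stable LF endings
  on.exit(close(con))
  writeLines(c(header, paste(cols, collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}

#' Read an SV VCF into a record table
#'
#' Parses `SVTYPE`, `END`, `SVLEN`, `MEINFO`, `ORIENT`, `CALLER` and
#' `SRCSAMPLE` INFO keys.  Records without a recognised `SVTYPE` are skipped;
#' the number skipped is reported in a message and stored in the
#' `n_skipped` attribute.  Lengths of span-type records are recomputed as
#' `END - POS + 1`; the number of records whose stated `SVLEN` disagrees is
#' stored in the `n_svlen_discrepant` attribute.  If the file carries a `GT`
#' FORMAT column the dosage matrix is attached as the `genotypes` attribute.
#'
#' @param path VCF file path.
#' @param caller_label,sample_label optional labels overriding the INFO
#'   fields (useful when reading one caller's output for one sample).
#' @return an `sv_records` data frame.
#' @export
read_sv_vcf <- function(path, caller_label = NULL, sample_label = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^##fileformat=VCF", lines[1])) {
    stop("malformed VCF header in ", path)
  }
  n_data <- sum(!startsWith(lines, "#"))
  if (n_data == 0) {
    return(sv_records(character(0), integer(0), integer(0), character(0)))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix

  svtype <- unname(vcfR::extract.info(vcf, element = "SVTYPE"))
  n_missing <- sum(is.na(svtype))
  n_unknown <- sum(!is.na(svtype) & !svtype %in% SV_TYPES)
  n_skipped <- n_missing + n_unknown
  if (n_skipped > 0) {
    message(n_missing, " record(s) lacking SVTYPE and ", n_unknown,
            " with unknown SVTYPE skipped")
  }
  keep <- !is.na(svtype) & svtype %in% SV_TYPES

  pos <- as.integer(fix[, "POS"])
  endv <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "END")))
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "SVLEN")))
  meinfo <- vcfR::extract.info(vcf, element = "MEINFO")
  orient <- vcfR::extract.info(vcf, element = "ORIENT")
  caller <- vcfR::extract.info(vcf, element = "CALLER")
  smp <- vcfR::extract.info(vcf, element = "SRCSAMPLE")

  is_mei <- svtype == "MEI"
  end_use <- ifelse(is_mei, pos, endv)
  # span records with no END fall back to POS + |SVLEN| - 1; else skipped
  fallback <- keep & !is_mei & is.na(end_use) & !is.na(svlen)
  end_use[fallback] <- pos[fallback] + abs(svlen[fallback]) - 1L
  no_end <- keep & is.na(end_use)
  if (any(no_end)) {
    message(sum(no_end), " record(s) lacking END/SVLEN skipped")
    keep <- keep & !no_end
    n_skipped <- n_skipped + sum(no_end)
  }

  mei_fam <- rep("none", length(svtype))
  mei_len <- rep(NA_integer_, length(svtype))
  if (any(is_mei & keep)) {
    parts <- strsplit(ifelse(is.na(meinfo), ",,,", meinfo), ",", fixed = TRUE)
    fam <- vapply(parts, `[`, character(1), 1)
    el_start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
    el_end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
    mei_fam[is_mei] <- fam[is_mei]
    mei_len[is_mei] <- ifelse(!is.na(svlen[is_mei]), abs(svlen[is_mei]),
                              el_end[is_mei] - el_start[is_mei] + 1L)
    bad_fam <- keep & is_mei & !mei_fam %in% MEI_FAMILIES
    if (any(bad_fam)) {
      message(sum(bad_fam), " MEI record(s) without a recognised family skipped")
      keep <- keep & !bad_fam
      n_skipped <- n_skipped + sum(bad_fam)
    }
  }

  length_use <- ifelse(is_mei, mei_len, end_use - pos + 1L)
  n_discrepant <- sum(keep & !is_mei & !is.na(svlen) &
                        abs(svlen) != length_use, na.rm = TRUE)

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."

  rec <- sv_records(
    chrom = fix[keep, "CHROM"],
    start = pos[keep],
    end = end_use[keep],
    svtype = svtype[keep],
    mei_family = mei_fam[keep],
    length = length_use[keep],
    qual = qual[keep],
    filter = filt[keep],
    orientation = ifelse(is.na(orient[keep]),
                         unname(DEFAULT_ORIENTATION[svtype[keep]]),
                         orient[keep]),
    caller = if (!is.null(caller_label)) caller_label else
      ifelse(is.na(caller[keep]), "caller", caller[keep]),
    sample = if (!is.null(sample_label)) sample_label else
      ifelse(is.na(smp[keep]), "sample", smp[keep])
  )
  ids <- fix[keep, "ID"]
  if (any(!is.na(ids) & ids != ".")) rec$locus_id <- ids

  if (ncol(vcf@gt %||% matrix(nrow = 0, ncol = 0)) > 1) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
    dos[gt %in% c("0/0", "0|0")] <- 0L
    dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    dos[gt %in% c("1/1", "1|1")] <- 2L
    attr(rec, "genotypes") <- dos[keep, , drop = FALSE]
  }
  attr(rec, "n_skipped") <- n_skipped
  attr(rec, "n_svlen_discrepant") <- n_discrepant
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert BED (0-based half-open) coordinates to 1-based inclusive
#'
#' @param start0,end0 BED chromStart/chromEnd.
#' @return data frame with 1-based inclusive `start`, `end`.
#' @export
bed_to_vcf_coords <- function(start0, end0) {
  data.frame(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' Convert 1-based inclusive coordinates to BED (0-based half-open)
#'
#' Exact inverse of [bed_to_vcf_coords()].
#'
#' @param start,end 1-based inclusive coordinates.
#' @return data frame with BED `start0`, `end0`.
#' @export
vcf_to_bed_coords <- function(start, end) {
  data.frame(start0 = as.integer(start) - 1L, end0 = as.integer(end))
}
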