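# Positional annotation of SV loci against a gene model, and an explicit
# impact-class rule table.
#
# Category precedence when a locus touches several features:
#   coverage > exon > UTR5/UTR3 > intron > gene_upstream > gene_downstream
#   > intergenic.
# DEL/DUP are annotated on their full span; INV on its two breakpoints only
# (the inverted interior is neither gained nor lost); MEI on its insertion
# point.  "coverage" marks a span-type locus that contains at least one
# entire gene.  Upstream/downstream are strand-aware within a flank
# (default 1 kb).

SV_CATEGORIES <- c("coverage", "exon", "UTR5", "UTR3", "intron",
                   "gene_upstream", "gene_downstream", "intergenic")

#' Locate SV loci relative to a gene model
#'
#' @param loci merged-locus data frame (`chrom`, `start`, `end`, `svtype`).
#' @param gm a [gene_model()] object.
#' @param flank upstream/downstream window in bp (default 1000).
#' @return data frame with `locus_id` (if present), `category`, and a
#'   comma-separated `genes` column of overlapped gene ids.
#' @export
locate_sv <- function(loci, gm, flank = 1000) {
  n <- nrow(loci)
  category <- rep("intergenic", n)
  genes_hit <- character(n)
  if (n == 0 || nrow(gm$genes) == 0) {
    out <- data.frame(category = category, genes = genes_hit,
                      stringsAsFactors = FALSE)
    if (!is.null(loci$locus_id)) out <- cbind(locus_id = loci$locus_id, out)
    if (!is.null(loci$svtype)) out$svtype <- loci$svtype
    return(out)
  }
  missing_chr <- !loci$chrom %in% gm$genes$chrom
  if (any(missing_chr)) {
    warning(sum(missing_chr),
            " locus/loci on chromosome(s) absent from the gene model: intergenic")
  }

  # query intervals: spans for DEL/DUP, breakpoints for INV, point for MEI
  qs <- list()
  for (i in seq_len(n)) {
    qs[[i]] <- switch(loci$svtype[i],
      DEL = , DUP = cbind(loci$start[i], loci$end[i]),
      INV = cbind(c(loci$start[i], loci$end[i]),
                  c(loci$start[i], loci$end[i])),
      MEI = cbind(loci$start[i], loci$start[i]))
  }
  qidx <- rep(seq_len(n), vapply(qs, nrow, 1L))
  qmat <- do.call(rbind, qs)
  query <- GenomicRanges::GRanges(loci$chrom[qidx],
                                  IRanges::IRanges(qmat[, 1], qmat[, 2]))

  feat_gr <- function(f) GenomicRanges::GRanges(
    f$chrom, IRanges::IRanges(f$start, f$end))
  g <- gm$genes
  gene_ranges <- feat_gr(g)
  up_start <- ifelse(g$strand == "-", g$end + 1L, pmax(1L, g$start - flank))
  up_end <- ifelse(g$strand == "-", g$end + flank, g$start - 1L)
  dn_start <- ifelse(g$strand == "-", pmax(1L, g$start - flank), g$end + 1L)
  dn_end <- ifelse(g$strand == "-", g$start - 1L, g$end + flank)
  up_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(up_start, up_end))
  dn_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(dn_start, dn_end))

  # seqlevel-mismatch warnings are expected when a locus chromosome is
  # absent from the model; they are handled above
  fo <- function(q, s, ...) suppressWarnings(GenomicRanges::findOverlaps(q, s, ...))
  hit_loci <- function(subject) {
    h <- fo(query, subject)
    list(loci = unique(qidx[S4Vectors::queryHits(h)]), hits = h)
  }
  # coverage: full-span types containing an entire gene
  span_type <- loci$svtype %in% c("DEL", "DUP")
  cov_hits <- fo(gene_ranges, query, type = "within")
  cov_loci <- unique(qidx[S4Vectors::subjectHits(cov_hits)])
  cov_loci <- cov_loci[span_type[cov_loci]]

  assign_cat <- function(current, idx, cat) {
    pr <- match(cat, SV_CATEGORIES)
    sel <- idx[match(current[idx], SV_CATEGORIES) > pr]
    current[sel] <- cat
    current
  }
  category <- assign_cat(category, hit_loci(feat_gr(gm$introns))$loci, "intron")
  category <- assign_cat(category, hit_loci(dn_gr)$loci, "gene_downstream")
  category <- assign_cat(category, hit_loci(up_gr)$loci, "gene_upstream")
  # re-apply in precedence-increasing order so higher classes win
  category <- assign_cat(category, hit_loci(feat_gr(gm$utr3))$loci, "UTR3")
  category <- assign_cat(category, hit_loci(feat_gr(gm$utr5))$loci, "UTR5")
  category <- assign_cat(category, hit_loci(feat_gr(gm$exons))$loci, "exon")
  category <- assign_cat(category, cov_loci, "coverage")

  # overlapped gene ids: gene spans touched by the query (plus the flanked
  # gene for upstream/downstream categories)
  gh <- fo(query, gene_ranges)
  by_locus <- split(g$gene_id[S4Vectors::subjectHits(gh)],
                    qidx[S4Vectors::queryHits(gh)])
  uh <- fo(query, up_gr)
  dh <- fo(query, dn_gr)
  flank_by_locus <- split(
    g$gene_id[c(S4Vectors::subjectHits(uh), S4Vectors::subjectHits(dh))],
    qidx[c(S4Vectors::queryHits(uh), S4Vectors::queryHits(dh))])
  for (i in seq_len(n)) {
    ids <- by_locus[[as.character(i)]]
    if (category[i] %in% c("gene_upstream", "gene_downstream")) {
      ids <- c(ids, flank_by_locus[[as.character(i)]])
    }
    genes_hit[i] <- paste(sort(unique(ids)), collapse = ",")
  }
  genes_hit[category == "intergenic"] <- ""

  out <- data.frame(category = category, genes = genes_hit,
                    stringsAsFactors = FALSE)
  if (!is.null(loci$locus_id)) out <- cbind(locus_id = loci$locus_id, out,
                                            stringsAsFactors = FALSE)
  out$svtype <- loci$svtype
  out
}

#' Impact class from positional category and SV type
#'
#' Fixed rule table: `exon`/`coverage` are HIGH; UTRs are MODERATE for
#' DEL/DUP and LOW for INV/MEI; intron, flanks and intergenic are MODIFIER.
#'
#' @param category positional categories (see [locate_sv()]).
#' @param svtype SV types.
#' @return character vector of impact classes.
#' @export
classify_effect <- function(category, svtype) {
  bad <- !category %in% SV_CATEGORIES
  if (any(bad)) stop("unknown category: ", unique(category[bad])[1])
  ifelse(category %in% c("exon", "coverage"), "HIGH",
    ifelse(category %in% c("UTR5", "UTR3"),
           ifelse(svtype %in% c("DEL", "DUP"), "MODERATE", "LOW"),
           "MODIFIER"))
}

#' Annotate loci: position category plus impact class
#'
#' @inheritParams locate_sv
#' @return the [locate_sv()] table with an `impact` column added.
#' @export
annotate_loci <- function(loci, gm, flank = 1000) {
  ann <- locate_sv(loci, gm, flank)
  ann$impact <- classify_effect(ann$category, ann$svtype)
  ann
}

#' Per-type category fractions
#'
#' @param annotations output of [locate_sv()] or [annotate_loci()].
#' @return data frame of fractions; rows are SV types, columns categories,
#'   each row summing to 1.
#' @export
summarize_positions <- function(annotations) {
  if (nrow(annotations) == 0) {
    return(data.frame(matrix(numeric(0), nrow = 0,
                             ncol = length(SV_CATEGORIES),
                             dimnames = list(NULL, SV_CATEGORIES))))
  }
  tab <- table(annotations$svtype,
               factor(annotations$category, levels = SV_CATEGORIES))
  as.data.frame.matrix(prop.table(tab, margin = 1))
}
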