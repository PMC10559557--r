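# Gene-model construction and readers (GFF3 / BED12), plus TSV readers for
# sample metadata and phenotypes.
#
# Internally all intervals are 1-based inclusive.  Exon intervals hold the
# coding portions of exons; UTR5/UTR3 are kept as separate intervals so that
# the positional-annotation precedence (exon over UTR) is meaningful.
# Introns are derived as the gene span minus all exon and UTR intervals.

#' Construct a gene model
#'
#' @param genes data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param exons,utr5,utr3 data frames with `gene_id`, `chrom`, `start`,
#'   `end`; coordinates 1-based inclusive, within the gene span.
#' @return a list of class `gene_model` with elements `genes`, `exons`,
#'   `utr5`, `utr3` and derived `introns`.
#' @export
gene_model <- function(genes, exons, utr5 = NULL, utr3 = NULL) {
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0))
  utr5 <- utr5 %||% empty
  utr3 <- utr3 %||% empty
  feats <- rbind(exons[, names(empty)], utr5[, names(empty)],
                 utr3[, names(empty)])
  if (nrow(feats) > 0) {
    span <- genes[match(feats$gene_id, genes$gene_id), ]
    if (any(is.na(span$start))) {
      stop("feature references unknown gene: ",
           feats$gene_id[which(is.na(span$start))[1]])
    }
    outside <- feats$start < span$start | feats$end > span$end
    if (any(outside)) {
      stop("exon/UTR outside its gene span for gene ",
           feats$gene_id[which(outside)[1]])
    }
  }
  # no overlapping exons within a gene
  if (nrow(exons) > 1) {
    for (g in unique(exons$gene_id)) {
      e <- exons[exons$gene_id == g, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)])) {
        stop("overlapping exons within gene ", g)
      }
    }
  }
  introns <- derive_introns(genes, feats)
  structure(list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3,
                 introns = introns),
            class = "gene_model")
}

# gene span minus the union of its features
derive_introns <- function(genes, feats) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    f <- feats[feats$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(f) == 0) {
      return(data.frame(gene_id = g$gene_id, chrom = g$chrom,
                        start = g$start, end = g$end))
    }
    ir <- IRanges::reduce(IRanges::IRanges(f$start, f$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(g$start, g$end), ir)
    if (length(gaps) == 0) return(NULL)
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = IRanges::start(gaps), end = IRanges::end(gaps))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0))
  }
  out
}

#' Read a gene model from GFF3 or BED12
#'
#' GFF3 files must carry `gene` and `exon` features (optionally
#' `five_prime_UTR`/`three_prime_UTR`, and an mRNA level between genes and
#' exons).  BED12 blocks become exons; the thick region splits blocks into
#' coding exon parts and UTRs (5'/3' assigned by strand).  BED coordinates
#' (0-based half-open) are converted to 1-based inclusive at the boundary.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @return a [gene_model()] object.
#' @export
read_gene_model <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    read_gene_model_bed12(path)
  } else {
    read_gene_model_gff3(path)
  }
}

read_gene_model_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  if (length(gr) == 0) {
    e <- data.frame(gene_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0))
    return(gene_model(cbind(e, strand = character(0)), e, e, e))
  }
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  id <- as.character(md$ID)
  parent <- vapply(as.list(md$Parent), function(p)
    if (length(p) == 0) NA_character_ else p[1], character(1))
  # resolve exon parents through an mRNA/transcript level when present
  tx <- type %in% c("mRNA", "transcript")
  tx_map <- setNames(parent[tx], id[tx])
  resolve <- function(p) ifelse(p %in% names(tx_map), unname(tx_map[p]), p)

  pick <- function(sel, gene_id) {
    data.frame(gene_id = gene_id,
               chrom = as.character(GenomicRanges::seqnames(gr)[sel]),
               start = GenomicRanges::start(gr)[sel],
               end = GenomicRanges::end(gr)[sel])
  }
  gsel <- type == "gene"
  genes <- cbind(pick(gsel, id[gsel]),
                 strand = as.character(GenomicRanges::strand(gr)[gsel]))
  esel <- type == "exon"
  u5sel <- type == "five_prime_UTR"
  u3sel <- type == "three_prime_UTR"
  gene_model(genes,
             exons = pick(esel, resolve(parent[esel])),
             utr5 = pick(u5sel, resolve(parent[u5sel])),
             utr3 = pick(u3sel, resolve(parent[u3sel])))
}

read_gene_model_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    e <- data.frame(gene_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0))
    return(gene_model(cbind(e, strand = character(0)), e, e, e))
  }
  md <- S4Vectors::mcols(gr)
  genes <- data.frame(gene_id = as.character(md$name),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)))
  exs <- list(); u5s <- list(); u3s <- list()
  for (i in seq_along(gr)) {
    blocks <- md$blocks[[i]]  # 1-based, relative to the range start
    abs_blocks <- IRanges::shift(blocks, GenomicRanges::start(gr)[i] - 1L)
    thick <- IRanges::IRanges(IRanges::start(md$thick[i]),
                              IRanges::end(md$thick[i]))
    coding <- IRanges::intersect(abs_blocks, thick)
    noncoding <- IRanges::setdiff(abs_blocks, thick)
    mk <- function(ir) if (length(ir) == 0) NULL else
      data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                 start = IRanges::start(ir), end = IRanges::end(ir))
    exs[[i]] <- mk(coding)
    if (length(noncoding) > 0) {
      left <- noncoding[IRanges::end(noncoding) < min(IRanges::start(thick))]
      right <- noncoding[IRanges::start(noncoding) > max(IRanges::end(thick))]
      if (genes$strand[i] == "-") {
        u5s[[i]] <- mk(right); u3s[[i]] <- mk(left)
      } else {
        u5s[[i]] <- mk(left); u3s[[i]] <- mk(right)
      }
    }
  }
  bind <- function(l) {
    l <- Filter(Negate(is.null), l)
    if (length(l) == 0) {
      data.frame(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0))
    } else do.call(rbind, l)
  }
  gene_model(genes, bind(exs), bind(u5s), bind(u3s))
}

#' Write a gene model as GFF3
#'
#' @param gm a [gene_model()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gff3 <- function(gm, path) {
  line <- function(chrom, type, start, end, strand, attrs) {
    paste(chrom, "svforge", type, start, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  g <- gm$genes
  out <- c("##gff-version 3",
           line(g$chrom, "gene", g$start, g$end, g$strand,
                paste0("ID=", g$gene_id)))
  feat_lines <- function(f, type) {
    if (nrow(f) == 0) return(character(0))
    st <- g$strand[match(f$gene_id, g$gene_id)]
    line(f$chrom, type, f$start, f$end, st, paste0("Parent=", f$gene_id))
  }
  out <- c(out, feat_lines(gm$exons, "exon"),
           feat_lines(gm$utr5, "five_prime_UTR"),
           feat_lines(gm$utr3, "three_prime_UTR"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample`, `breed`, `generation`, `sex`, `batch`.
#'
#' @param path TSV file path.
#' @return a validated sample-information data frame.
#' @export
read_sample_info <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  sample_info(df$sample, df$breed, df$generation, df$sex, df$batch)
}

#' Read a phenotype table from TSV
#'
#' One row per F2 sample; a `sample` column plus one numeric column per
#' trait.  Traits with fewer than two distinct non-missing values are
#' rejected.
#'
#' @param path TSV file path.
#' @return data frame with `sample` first, trait columns numeric.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stop("phenotype table needs a 'sample' column")
  traits <- setdiff(names(df), c("sample", "sex", "batch"))
  for (tr in traits) {
    v <- df[[tr]]
    if (length(unique(v[!is.na(v)])) < 2) {
      stop("trait '", tr, "' has fewer than 2 distinct values")
    }
  }
  df
}
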