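# Union merge of multi-caller SV callsets.
#
# DEL/DUP/MEI calls are clustered by single-linkage transitive closure with a
# breakpoint-distance rule: two same-type, same-orientation calls link iff
# |start1 - start2| <= d AND |end1 - end2| <= d (d = 1000 bp by default).
# MEIs additionally require the same element family.  INV calls, whose
# breakpoints may be reported in reverse order by different callers, are
# instead merged by reciprocal overlap (> 0.75), separately within two
# length strata (<= 100 kb and > 100 kb) so that large inversions cannot
# absorb small ones.  Merging is union semantics: every input call belongs
# to exactly one output locus.

#' Merge configuration
#'
#' @param breakpoint_distance maximum breakpoint offset (bp) for
#'   DEL/DUP/MEI clustering.  Default 1000.
#' @param inv_overlap_fraction reciprocal-overlap fraction that must be
#'   exceeded (strictly) for two inversions to link.  Default 0.75.
#' @param size_split inversion length (bp) separating the two merge strata;
#'   the boundary itself falls in the lower stratum.  Default 100000.
#' @param db_overlap_fraction reciprocal-overlap fraction at or above which
#'   a locus matches a reference-database interval.  Default 0.75.
#' @param link_mode `"both"` (default) requires both breakpoint offsets
#'   within distance; `"start"` only the left breakpoint.
#' @return a list of class `merge_config`.
#' @export
merge_config <- function(breakpoint_distance = 1000,
                         inv_overlap_fraction = 0.75,
                         size_split = 100000,
                         db_overlap_fraction = 0.75,
                         link_mode = c("both", "start")) {
  stopifnot(breakpoint_distance >= 0,
            inv_overlap_fraction > 0, inv_overlap_fraction <= 1,
            db_overlap_fraction > 0, db_overlap_fraction <= 1,
            size_split > 0)
  structure(list(breakpoint_distance = breakpoint_distance,
                 inv_overlap_fraction = inv_overlap_fraction,
                 size_split = size_split,
                 db_overlap_fraction = db_overlap_fraction,
                 link_mode = match.arg(link_mode)),
            class = "merge_config")
}

#' Reciprocal overlap of two inclusive intervals
#'
#' `min(overlap/len(a), overlap/len(b))` with inclusive lengths; 0 when the
#' intervals are disjoint.  Vectorised.
#'
#' @param a_start,a_end,b_start,b_end 1-based inclusive interval bounds.
#' @return overlap fractions in \[0, 1\].
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  la <- a_end - a_start + 1
  lb <- b_end - b_start + 1
  if (any(la <= 0) || any(lb <= 0)) stop("zero-length interval")
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
  pmin(ov / la, ov / lb)
}

# --- union-find ------------------------------------------------------------

uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), 1L)
  match(roots, unique(roots))
}

# lower median: for even counts, the smaller of the two middle values
lower_median <- function(x) sort(x)[(length(x) + 1L) %/% 2L]

# ensure records carry list-columns for multi-stage support tracking
as_merge_input <- function(rec) {
  rec <- as.data.frame(rec)
  if (is.null(rec$callers)) rec$callers <- as.list(rec$caller)
  if (is.null(rec$samples)) rec$samples <- as.list(rec$sample)
  if (is.null(rec$member_ids)) rec$member_ids <- as.list(seq_len(nrow(rec)))
  rec
}

# build one merged locus row from member records
build_locus <- function(members) {
  span <- members$svtype[1] != "MEI"
  rep_start <- lower_median(members$start)
  rep_end <- lower_median(members$end)
  filt <- if (any(members$filter == "PASS")) "PASS" else sort(members$filter)[1]
  data.frame(
    chrom = members$chrom[1],
    start = rep_start,
    end = if (span) rep_end else rep_start,
    svtype = members$svtype[1],
    mei_family = members$mei_family[1],
    length = if (span) rep_end - rep_start + 1L else lower_median(members$length),
    qual = if (all(is.na(members$qual))) NA_real_ else
      max(members$qual, na.rm = TRUE),
    filter = filt,
    orientation = members$orientation[1],
    n_members = sum(lengths(members$member_ids)),
    callers = I(list(sort(unique(unlist(members$callers))))),
    samples = I(list(sort(unique(unlist(members$samples))))),
    member_ids = I(list(sort(unlist(members$member_ids)))),
    stringsAsFactors = FALSE
  )
}

finalize_loci <- function(groups, rec) {
  loci <- do.call(rbind, lapply(split(seq_len(nrow(rec)), groups),
                                function(idx) build_locus(rec[idx, , drop = FALSE])))
  # deterministic order, independent of input permutation
  loci <- loci[order(chrom_rank(loci$chrom), loci$start, loci$svtype,
                     loci$end, loci$orientation, loci$mei_family), ,
               drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Cluster DEL/DUP/MEI calls by breakpoint distance
#'
#' Single-linkage transitive clustering on one chromosome: two calls link
#' iff same type, same orientation (and same MEI family), and their start
#' and end breakpoints each differ by at most `breakpoint_distance`.
#' Representative breakpoints are the lower medians of the member
#' breakpoints, so the output is invariant to input order.
#'
#' @param records `sv_records` on a single chromosome, types DEL/DUP/MEI.
#' @param config a [merge_config()].
#' @return merged-locus data frame (one row per cluster) with member
#'   bookkeeping columns `n_members`, `callers`, `samples`, `member_ids`.
#' @export
cluster_calls <- function(records, config = merge_config()) {
  rec <- as_merge_input(records)
  if (nrow(rec) == 0) return(NULL)
  if (length(unique(rec$chrom)) > 1) {
    stop("cluster_calls expects records from a single chromosome")
  }
  if (any(rec$svtype == "INV")) {
    stop("INV records must be merged with merge_inversions()")
  }
  d <- config$breakpoint_distance
  strata <- paste(rec$svtype, rec$orientation,
                  ifelse(rec$svtype == "MEI", rec$mei_family, "."))
  groups <- integer(nrow(rec))
  g_off <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    ord <- idx[order(rec$start[idx], rec$end[idx])]
    starts <- rec$start[ord]
    ends <- rec$end[ord]
    parent <- uf_new(length(ord))
    lo <- 1L
    for (j in seq_along(ord)) {
      while (starts[j] - starts[lo] > d) lo <- lo + 1L
      if (lo < j) {
        for (i in lo:(j - 1L)) {
          if (config$link_mode == "start" || abs(ends[j] - ends[i]) <= d) {
            parent <- uf_union(parent, i, j)
          }
        }
      }
    }
    groups[ord] <- uf_components(parent) + g_off
    g_off <- max(groups)
  }
  finalize_loci(groups, rec)
}

#' Merge inversion calls by reciprocal overlap within length strata
#'
#' Records are partitioned by recomputed length into `(0, size_split]` and
#' `(size_split, Inf)` strata; within a stratum, single-linkage clustering
#' links two inversions iff their reciprocal overlap strictly exceeds
#' `inv_overlap_fraction`.  Loci from different strata never merge, which
#' prevents large inversions from swallowing small ones.
#'
#' @param records `sv_records`, all of type INV, one chromosome.
#' @param config a [merge_config()].
#' @return merged-locus data frame as in [cluster_calls()].
#' @export
merge_inversions <- function(records, config = merge_config()) {
  rec <- as_merge_input(records)
  if (nrow(rec) == 0) return(NULL)
  if (!all(rec$svtype == "INV")) stop("merge_inversions expects INV records")
  if (length(unique(rec$chrom)) > 1) {
    stop("merge_inversions expects records from a single chromosome")
  }
  len <- rec$end - rec$start + 1L
  strata <- ifelse(len <= config$size_split, "small", "large")
  groups <- integer(nrow(rec))
  g_off <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    ord <- idx[order(rec$start[idx], rec$end[idx])]
    starts <- rec$start[ord]
    ends <- rec$end[ord]
    parent <- uf_new(length(ord))
    active <- integer(0)
    for (j in seq_along(ord)) {
      active <- active[ends[active] >= starts[j]]
      if (length(active) > 0) {
        ro <- reciprocal_overlap(starts[active], ends[active],
                                 starts[j], ends[j])
        for (i in active[ro > config$inv_overlap_fraction]) {
          parent <- uf_union(parent, i, j)
        }
      }
      active <- c(active, j)
    }
    groups[ord] <- uf_components(parent) + g_off
    g_off <- max(groups)
  }
  finalize_loci(groups, rec)
}

# merge a mixed record set: split by chromosome and dispatch by type
merge_records <- function(records, config = merge_config()) {
  rec <- as_merge_input(records)
  if (nrow(rec) == 0) stop("no records to merge")
  out <- list()
  for (chr in unique(rec$chrom)) {
    sub <- rec[rec$chrom == chr, , drop = FALSE]
    inv <- sub$svtype == "INV"
    if (any(!inv)) out[[length(out) + 1L]] <-
      cluster_calls(sub[!inv, , drop = FALSE], config)
    if (any(inv)) out[[length(out) + 1L]] <-
      merge_inversions(sub[inv, , drop = FALSE], config)
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(chrom_rank(loci$chrom), loci$start, loci$svtype,
                     loci$end), , drop = FALSE]
  loci$locus_id <- sprintf("SV_%05d", seq_len(nrow(loci)))
  rownames(loci) <- NULL
  loci[, c("locus_id", setdiff(names(loci), "locus_id"))]
}

#' Union-merge per-caller callsets within samples, then across samples
#'
#' Stage one merges each sample's calls across callers; stage two merges the
#' per-sample loci across samples.  Union semantics: every input call ends
#' up in exactly one output locus, and calls seen by a single caller are
#' retained.  Exact duplicates of (caller, sample, position, type) are
#' collapsed first with a warning.
#'
#' @param records `sv_records` holding all calls (caller and sample columns
#'   identify the source callsets).
#' @param config a [merge_config()].
#' @return merged-locus data frame with `locus_id`, representative
#'   breakpoints, and `callers`/`samples` support sets.
#' @export
merge_callsets <- function(records, config = merge_config()) {
  rec <- as.data.frame(records)
  # [[ ]]: `$` would partial-match the `callers`/`samples` list columns of
  # already-merged loci
  if (is.null(rec[["caller"]])) rec[["caller"]] <- "."
  if (is.null(rec[["sample"]])) rec[["sample"]] <- "."
  key <- paste(rec[["caller"]], rec[["sample"]], rec$chrom, rec$start,
               rec$end, rec$svtype)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate (caller, sample, position, type) record(s) collapsed")
    rec <- rec[!duplicated(key), , drop = FALSE]
  }
  rec <- as_merge_input(rec)
  # stage 1: within sample, across callers
  stage1 <- do.call(rbind, lapply(split(rec, rec[["sample"]]), function(sub) {
    loci <- merge_records(sub, config)
    loci$locus_id <- NULL
    loci
  }))
  stage1$caller <- NA_character_
  stage1$sample <- NA_character_
  # stage 2: across samples
  merge_records(stage1, config)
}

#' Label merged loci as known or novel against a reference SV set
#'
#' A DEL/DUP/INV locus is "known" iff some same-type reference interval on
#' the same chromosome reaches `db_overlap_fraction` reciprocal overlap; an
#' MEI locus iff a reference MEI insertion point lies within
#' `breakpoint_distance`.  Everything else is "novel".
#'
#' @param loci merged-locus data frame.
#' @param reference data frame with `chrom`, `start`, `end`, `svtype`.
#' @param config a [merge_config()].
#' @return `loci` with a logical `known` column; per-type novel counts in
#'   the `novel_by_type` attribute.
#' @export
compare_to_database <- function(loci, reference, config = merge_config()) {
  if (is.null(reference) || nrow(reference) == 0) {
    warning("empty reference set: all loci labelled novel")
    loci$known <- FALSE
  } else {
    loci$known <- vapply(seq_len(nrow(loci)), function(i) {
      ref <- reference[reference$chrom == loci$chrom[i] &
                         reference$svtype == loci$svtype[i], , drop = FALSE]
      if (nrow(ref) == 0) return(FALSE)
      if (loci$svtype[i] == "MEI") {
        any(abs(ref$start - loci$start[i]) <= config$breakpoint_distance)
      } else {
        any(reciprocal_overlap(ref$start, ref$end, loci$start[i],
                               loci$end[i]) >= config$db_overlap_fraction)
      }
    }, logical(1))
  }
  novel <- table(factor(loci$svtype[!loci$known], levels = SV_TYPES))
  attr(loci, "novel_by_type") <- as.integer(novel)
  names(attr(loci, "novel_by_type")) <- SV_TYPES
  loci
}
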