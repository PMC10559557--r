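# Breed-differential genotype screening on founders, and position-based
# candidate genotyping in offspring.
#
# A locus passes the screen iff some genotype class g and some breed
# assignment (g to breed X, the remaining two classes jointly to breed Y)
# satisfy both frequency conditions: the count of g among X's founders
# strictly exceeds freq_X * |X| and the count of the complement classes
# among Y's founders strictly exceeds freq_Y * |Y|.  Thresholds use the
# nominal breed sizes; missing founder genotypes count toward neither side.

#' Screening configuration
#'
#' @param breed_a_samples,breed_b_samples disjoint founder sample id sets
#'   (defaults mirror the study design: 6 purebred founders of breed A and
#'   15 of breed B).
#' @param freq_a,freq_b genotype-frequency fractions that must be strictly
#'   exceeded in breeds A and B (defaults 0.80 and 0.50).
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(breed_a_samples, breed_b_samples,
                          freq_a = 0.80, freq_b = 0.50) {
  if (length(intersect(breed_a_samples, breed_b_samples)) > 0) {
    stop("breed sample sets must be disjoint")
  }
  stopifnot(freq_a > 0, freq_a <= 1, freq_b > 0, freq_b <= 1)
  structure(list(breed_a_samples = breed_a_samples,
                 breed_b_samples = breed_b_samples,
                 freq_a = freq_a, freq_b = freq_b),
            class = "screen_config")
}

#' Minimum count satisfying a strict frequency condition
#'
#' The smallest integer k with `k > n * freq`.  With n = 6 founders at
#' freq = 0.8 this is 5; with n = 15 at freq = 0.5 it is 8.
#'
#' @param n nominal group size.
#' @param freq frequency fraction.
#' @return integer count.
#' @export
min_passing_count <- function(n, freq) {
  as.integer(floor(round(n * freq, 9)) + 1L)
}

#' Screen founder loci for breed-differential genotypes
#'
#' @param gm an [sv_geno()] object or dosage matrix over the founders.
#' @param config a [screen_config()].
#' @return data frame of passing loci: `locus_id`, the specific genotype
#'   class, which breed carries it (`direction`), and the supporting
#'   counts.
#' @export
screen_differential_loci <- function(gm, config) {
  d <- if (inherits(gm, "sv_geno")) gm$dosages else gm
  missing_s <- setdiff(c(config$breed_a_samples, config$breed_b_samples),
                       colnames(d))
  if (length(missing_s) > 0) {
    stop("founder sample(s) absent from genotype matrix: ",
         paste(missing_s, collapse = ", "))
  }
  da <- d[, config$breed_a_samples, drop = FALSE]
  db <- d[, config$breed_b_samples, drop = FALSE]
  na <- length(config$breed_a_samples)
  nb <- length(config$breed_b_samples)
  ta <- na * config$freq_a
  tb <- nb * config$freq_b

  count_g <- function(m, g) rowSums(m == g, na.rm = TRUE)
  ca <- cbind(count_g(da, 0), count_g(da, 1), count_g(da, 2))  # loci x 3
  cb <- cbind(count_g(db, 0), count_g(db, 1), count_g(db, 2))
  nm_a <- rowSums(!is.na(da))
  nm_b <- rowSums(!is.na(db))

  hits <- list()
  for (g in 0:2) {
    # direction 1: class g specific to breed A, complement classes in B
    p1 <- ca[, g + 1] > ta & (nm_b - cb[, g + 1]) > tb
    # direction 2: class g specific to breed B, complement classes in A
    p2 <- cb[, g + 1] > tb & (nm_a - ca[, g + 1]) > ta
    for (dir in c("A", "B")) {
      pass <- if (dir == "A") p1 else p2
      if (any(pass)) {
        hits[[length(hits) + 1L]] <- data.frame(
          row = which(pass), genotype = g, direction = dir,
          count_specific = if (dir == "A") ca[pass, g + 1] else cb[pass, g + 1],
          count_complement = if (dir == "A") (nm_b - cb[, g + 1])[pass]
                             else (nm_a - ca[, g + 1])[pass])
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(locus_id = character(0), genotype = integer(0),
                      direction = character(0), count_specific = integer(0),
                      count_complement = integer(0)))
  }
  res <- do.call(rbind, hits)
  res <- res[!duplicated(res$row), , drop = FALSE]  # one record per locus
  res <- res[order(res$row), , drop = FALSE]
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  out <- data.frame(locus_id = ids[res$row], genotype = res$genotype,
                    direction = res$direction,
                    count_specific = res$count_specific,
                    count_complement = res$count_complement,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genotype candidate loci in offspring from positional evidence
#'
#' Matches each candidate locus to per-sample genotype evidence keyed by
#' (chromosome, position within `distance`, SV type); the nearest evidence
#' position wins.  Unmatched (locus, sample) cells are missing.  When a
#' cell has duplicate evidence rows the highest-confidence one is kept.
#'
#' @param candidates locus data frame (`locus_id`, `chrom`, `start`,
#'   `svtype`).
#' @param evidence data frame with `chrom`, `pos`, `svtype`, `sample`,
#'   `dosage` and optionally `conf`.
#' @param samples sample ids to genotype (default: all in `evidence`).
#' @param distance matching tolerance in bp (default 1000, the merge
#'   breakpoint distance).
#' @return list with `gm` (an [sv_geno()]), `success_rate` (percent of
#'   non-missing cells, 2 decimals) and `n_matched` loci.
#' @export
genotype_candidates_in_offspring <- function(candidates, evidence,
                                             samples = NULL, distance = 1000) {
  if (is.null(samples)) samples <- sort(unique(evidence$sample))
  n_loci <- nrow(candidates)
  dos <- matrix(NA_integer_, n_loci, length(samples),
                dimnames = list(candidates$locus_id, samples))
  if (is.null(evidence$conf)) evidence$conf <- 1

  ev_key <- paste(evidence$chrom, evidence$svtype, evidence$pos)
  ev_rows_by_key <- split(seq_len(nrow(evidence)), ev_key)
  ev_pos_tab <- unique(data.frame(chrom = evidence$chrom,
                                  svtype = evidence$svtype,
                                  pos = evidence$pos, key = ev_key,
                                  stringsAsFactors = FALSE))
  pos_by_stratum <- split(ev_pos_tab,
                          paste(ev_pos_tab$chrom, ev_pos_tab$svtype))
  n_dup <- 0L
  for (i in seq_len(n_loci)) {
    cand <- pos_by_stratum[[paste(candidates$chrom[i], candidates$svtype[i])]]
    if (is.null(cand)) next
    off <- abs(cand$pos - candidates$start[i])
    if (min(off) > distance) next
    key <- cand$key[which.min(off)]
    rows <- evidence[ev_rows_by_key[[key]], , drop = FALSE]
    rows <- rows[order(rows$sample, -rows$conf), , drop = FALSE]
    dup <- duplicated(rows$sample)
    n_dup <- n_dup + sum(dup)
    rows <- rows[!dup, , drop = FALSE]
    rows <- rows[rows$sample %in% samples, , drop = FALSE]
    dos[i, rows$sample] <- as.integer(rows$dosage)
  }
  if (n_dup > 0) {
    message(n_dup, " duplicate evidence record(s): highest confidence kept")
  }
  success <- round(100 * mean(!is.na(dos)), 2)
  list(gm = sv_geno(dos, loci = if (!is.null(candidates$locus_id)) candidates),
       success_rate = success,
       n_matched = sum(rowSums(!is.na(dos)) > 0))
}
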