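# Population-genetic summaries on the SV genotype matrix: per-locus
# Weir & Cockerham (1984) F_ST between two groups, top-quantile selection of
# stratified loci, genomic-relationship PCA, and an allele-sharing
# neighbour-joining tree.

#' Per-locus Weir-Cockerham F_ST between two groups
#'
#' The standard two-allele, r-population variance-component estimator with
#' r = 2: among-population (a), among-individual-within-population (b) and
#' within-individual (c) components, theta = a/(a+b+c).  Missing genotypes
#' are excluded per locus per group.  Negative estimates are retained.
#' A locus is undefined when a group has fewer than two non-missing
#' genotypes or when the locus is monomorphic (a+b+c == 0).
#'
#' @param gm an [sv_geno()] object or dosage matrix (loci x samples).
#' @param groups two-level factor/character vector over the samples.
#' @return data frame with per-group sizes/frequencies, the components
#'   `a`, `b`, `c`, `theta`, and `reason` for undefined loci.
#' @export
weir_cockerham_fst <- function(gm, groups) {
  d <- if (inherits(gm, "sv_geno")) gm$dosages else gm
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (length(groups) != ncol(d)) stop("one group label per sample required")
  g1 <- d[, groups == levels(groups)[1], drop = FALSE]
  g2 <- d[, groups == levels(groups)[2], drop = FALSE]

  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1, na.rm = TRUE) / n2

  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2

  denom <- a + b + cc
  theta <- ifelse(abs(denom) > 0, a / denom, NA_real_)
  reason <- rep(NA_character_, nrow(d))
  too_few <- n1 < 2 | n2 < 2
  reason[too_few] <- "fewer than 2 genotypes in a group"
  mono <- !too_few & !is.na(denom) & denom == 0
  reason[mono] <- "monomorphic"
  theta[!is.na(reason)] <- NA_real_
  a[too_few] <- NA_real_; b[too_few] <- NA_real_; cc[too_few] <- NA_real_

  out <- data.frame(n1 = n1, n2 = n2, p1 = p1, p2 = p2, h1 = h1, h2 = h2,
                    a = a, b = b, c = cc, theta = theta, reason = reason,
                    stringsAsFactors = FALSE)
  if (!is.null(rownames(d))) out <- cbind(locus_id = rownames(d), out,
                                          stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select loci in the top quantile of F_ST
#'
#' The threshold is the `ceiling(q * n)`-th largest defined theta; every
#' locus with theta at or above the threshold is included, so ties at the
#' boundary all enter the selection.
#'
#' @param fst output of [weir_cockerham_fst()] (optionally with an `svtype`
#'   column for per-type counts).
#' @param q upper tail fraction (default 0.05).
#' @return the selected rows; threshold in the `threshold` attribute,
#'   per-type counts (when `svtype` present) in `counts_by_type`.
#' @export
top_quantile_loci <- function(fst, q = 0.05) {
  def <- fst[!is.na(fst$theta), , drop = FALSE]
  n <- nrow(def)
  if (n == 0) stop("no defined theta values")
  if (n < 1 / q) {
    warning("fewer than 1/q defined loci: returning all")
    sel <- def
    attr(sel, "threshold") <- min(def$theta)
  } else {
    k <- ceiling(q * n)
    thr <- sort(def$theta, decreasing = TRUE)[k]
    sel <- def[def$theta >= thr, , drop = FALSE]
    attr(sel, "threshold") <- thr
  }
  if (!is.null(sel$svtype)) {
    attr(sel, "counts_by_type") <-
      table(factor(sel$svtype, levels = SV_TYPES))
  }
  sel
}

#' Genomic-relationship PCA of the samples
#'
#' Missing dosages are mean-imputed per locus; dosages are centred by
#' `2*p` and scaled by `sqrt(2*p*(1-p))` (monomorphic loci skipped); the
#' eigendecomposition of the resulting relationship matrix gives the sample
#' coordinates (eigenvectors scaled by the square roots of their
#' eigenvalues).
#'
#' @param gm an [sv_geno()] object or dosage matrix.
#' @param k_axes number of axes to return (default 10, capped at n).
#' @return list with `grm`, `values`, `vectors`, and `coords`
#'   (samples x axes).
#' @export
grm_pca <- function(gm, k_axes = 10) {
  d <- if (inherits(gm, "sv_geno")) gm$dosages else gm
  if (ncol(d) < 2) stop("at least 2 samples required")
  d <- impute_row_means(d)
  p <- rowMeans(d) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("no informative loci (all monomorphic)")
  z <- (d[keep, , drop = FALSE] - 2 * p[keep]) / sqrt(2 * p[keep] * (1 - p[keep]))
  grm <- crossprod(z) / sum(keep)
  ev <- eigen(grm, symmetric = TRUE)
  k <- min(k_axes, ncol(grm))
  coords <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  rownames(coords) <- colnames(d)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(grm = grm, values = ev$values, vectors = ev$vectors, coords = coords)
}

impute_row_means <- function(d) {
  if (!anyNA(d)) return(d)
  mu <- rowMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 1]]
  d
}

#' Allele-sharing distances between samples
#'
#' For each pair, the mean over loci non-missing in both of
#' `1 - |d_i - d_j| / 2`; the distance is one minus that sharing
#' proportion.
#'
#' @param gm an [sv_geno()] object or dosage matrix.
#' @return a `dist` object over samples.
#' @export
allele_sharing_dist <- function(gm) {
  d <- if (inherits(gm, "sv_geno")) gm$dosages else gm
  n <- ncol(d)
  dm <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      if (!any(ok)) {
        stop("samples ", colnames(d)[i], " and ", colnames(d)[j],
             " share no non-missing loci")
      }
      share <- mean(1 - abs(d[ok, i] - d[ok, j]) / 2)
      dm[i, j] <- dm[j, i] <- 1 - share
    }
  }
  stats::as.dist(dm)
}

#' Neighbour-joining tree on allele-sharing distances
#'
#' Classical neighbour joining (via \pkg{ape}) on
#' [allele_sharing_dist()]; the Newick string carries branch lengths.
#'
#' @param gm an [sv_geno()] object or dosage matrix with >= 3 samples.
#' @return list with `tree` (an `ape::phylo`) and `newick` (string).
#' @export
nj_tree <- function(gm) {
  d <- if (inherits(gm, "sv_geno")) gm$dosages else gm
  if (ncol(d) < 3) stop("at least 3 samples required")
  tree <- ape::nj(allele_sharing_dist(d))
  list(tree = tree, newick = ape::write.tree(tree))
}
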