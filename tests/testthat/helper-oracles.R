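# Independent oracles used across the test suite.  These deliberately take
# the slow, direct route (all-pairs comparisons, scalar per-locus formulas,
# dense matrix algebra) and never share code with the package paths they
# check.

# all-pairs transitive-closure clustering via adjacency matrix + igraph
# components; returns a membership vector over the rows of `rec`
oracle_cluster_membership <- function(rec, d, link_mode = "both") {
  same <- outer(rec$chrom, rec$chrom, "==") &
    outer(rec$svtype, rec$svtype, "==") &
    outer(rec$orientation, rec$orientation, "==") &
    outer(rec$mei_family, rec$mei_family, "==")
  adj <- same & abs(outer(rec$start, rec$start, "-")) <= d
  if (link_mode == "both") {
    adj <- adj & abs(outer(rec$end, rec$end, "-")) <= d
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# all-pairs INV clustering: strict reciprocal-overlap links within length
# strata, overlap computed from scratch
oracle_inv_membership <- function(rec, frac, size_split) {
  n <- nrow(rec)
  len <- rec$end - rec$start + 1
  stratum <- ifelse(len <= size_split, 1, 2)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || rec$chrom[i] != rec$chrom[j] ||
          stratum[i] != stratum[j]) next
      ov <- min(rec$end[i], rec$end[j]) - max(rec$start[i], rec$start[j]) + 1
      if (ov > 0 && min(ov / len[i], ov / len[j]) > frac) adj[i, j] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# canonical form of a partition: sorted list of sorted member index sets
partition_sets <- function(membership) {
  unname(lapply(split(seq_along(membership), membership), sort))[
    order(vapply(split(seq_along(membership), membership), min, 1L))]
}

# membership implied by a merged-locus table's member_ids over n input rows
loci_membership <- function(loci, n) {
  m <- integer(n)
  for (i in seq_len(nrow(loci))) m[loci$member_ids[[i]]] <- i
  m
}

# scalar Weir & Cockerham (1984) two-population evaluation from dosages
oracle_wc84 <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  n <- c(length(d1), length(d2))
  p <- c(sum(d1) / (2 * n[1]), sum(d2) / (2 * n[2]))
  h <- c(mean(d1 == 1), mean(d2 == 1))
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc,
    theta = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# dense generalized least squares of y on [X, g] with covariance V (up to a
# scale re-estimated from the residuals), explicit matrix inversion
oracle_gls <- function(y, X, g, V) {
  W <- cbind(X, g)
  Vi <- solve(V)
  A <- solve(t(W) %*% Vi %*% W)
  b <- A %*% t(W) %*% Vi %*% y
  res <- y - W %*% b
  df <- length(y) - ncol(W)
  s2 <- as.numeric(t(res) %*% Vi %*% res) / df
  k <- ncol(W)
  se <- sqrt(s2 * A[k, k])
  tt <- b[k] / se
  list(beta = b[k], se = se, p = 2 * pt(-abs(tt), df))
}

# small random record set: jittered copies of well-separated true loci
make_jittered_records <- function(n_true = 5, copies = 10, jitter = 400,
                                  gap = 5000, svtype = "DEL",
                                  chrom = "chr1", len = 2000) {
  true_start <- cumsum(rep(gap + len, n_true)) + 10000
  idx <- rep(seq_len(n_true), each = copies)
  js <- sample(-jitter:jitter, n_true * copies, replace = TRUE)
  je <- sample(-jitter:jitter, n_true * copies, replace = TRUE)
  sv_records(chrom = chrom,
             start = true_start[idx] + js,
             end = true_start[idx] + len + je,
             svtype = svtype,
             qual = 500, caller = "c1",
             sample = paste0("s", seq_along(idx) %% 3))
}

# reduced study configuration used by end-to-end tests: the full founder
# and F2 cohort over a smaller multi-chromosome genome
small_study_config <- function(seed, n_f2 = 513,
                               traits = list(body_length =
                                               list(n_causal = 1,
                                                    causal_var = 0.15))) {
  sim_config(seed = seed, n_chrom = 6, chrom_length = 3.3e6,
             n_sv = c(DEL = 150, DUP = 30, INV = 40, MEI = 50),
             n_f2 = n_f2, traits = traits)
}
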