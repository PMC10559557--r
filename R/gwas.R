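# EMMAX-style mixed-linear-model association.
#
# Model: y = X beta + u + e, u ~ N(0, sigma2_g K), e ~ N(0, sigma2_e I).
# Variance components are estimated once by REML on the null model via the
# spectral decomposition of K and a 1-D search over delta = sigma2_e /
# sigma2_g; each marker is then tested by generalized least squares with
# the covariance fixed, using a Wald t-test on the marker coefficient.

#' Kinship matrix from a dosage matrix
#'
#' `IBS`: mean allele-sharing fraction per pair, `1 - |d_i - d_j| / 2`
#' averaged over loci (missing dosages mean-imputed first).  `GRM`:
#' VanRaden standardization `Z'Z / (2 * sum p(1-p))`.  A ridge of 1e-6 is
#' added to the diagonal.
#'
#' @param gm an [sv_geno()] object or dosage matrix (loci x samples).
#' @param method `"IBS"` (default) or `"GRM"`.
#' @return an n x n kinship matrix with a `method` attribute.
#' @export
kinship <- function(gm, method = c("IBS", "GRM")) {
  method <- match.arg(method)
  d <- if (inherits(gm, "sv_geno")) gm$dosages else gm
  if (ncol(d) < 3) stop("at least 3 samples required")
  d <- impute_row_means(d)
  if (method == "IBS") {
    manhattan <- as.matrix(dist(t(d), method = "manhattan"))
    k <- 1 - manhattan / (2 * nrow(d))
  } else {
    p <- rowMeans(d) / 2
    z <- d - 2 * p
    denom <- 2 * sum(p * (1 - p))
    if (denom == 0) stop("no polymorphic loci for GRM")
    k <- crossprod(z) / denom
  }
  diag(k) <- diag(k) + 1e-6
  attr(k, "method") <- method
  k
}

#' REML variance components of the null model
#'
#' Maximizes the restricted likelihood over `delta = sigma2_e / sigma2_g`
#' using the eigendecomposition of K: a fixed grid on log10(delta) in
#' [-5, 5] followed by local refinement with [stats::optimize()].
#' Deterministic given its inputs.
#'
#' @param y numeric response (no missing values).
#' @param X fixed-effect design matrix including the intercept.
#' @param K kinship matrix from [kinship()].
#' @return list of class `sv_vc`: `sigma2_g`, `sigma2_e`, `delta`, `h2`
#'   (`sigma2_g / (sigma2_g + sigma2_e)`), `loglik`, `boundary` flag, and
#'   the reusable spectral pieces (`U`, `S`).
#' @export
fit_null_reml <- function(y, X, K) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, !anyNA(y))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  p <- ncol(X)
  ev <- eigen(K, symmetric = TRUE)
  U <- ev$vectors
  S <- pmax(ev$values, 0)
  ty <- crossprod(U, y)
  tX <- crossprod(U, X)

  neg_restricted_ll <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- 1 / (S + delta)
    sw <- sqrt(w)
    Xw <- tX * sw
    yw <- ty * sw
    fit <- qr(Xw)
    res <- qr.resid(fit, yw)
    rss <- sum(res^2)
    ldet_xwx <- 2 * sum(log(abs(diag(qr.R(fit)))))
    0.5 * ((n - p) * log(rss) + sum(log(S + delta)) + ldet_xwx)
  }
  grid <- seq(-5, 5, by = 0.1)
  vals <- vapply(grid, neg_restricted_ll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(neg_restricted_ll, c(lo, hi), tol = 1e-8)
  delta <- 10^opt$minimum

  w <- 1 / (S + delta)
  sw <- sqrt(w)
  fit <- qr(tX * sw)
  rss <- sum(qr.resid(fit, ty * sw)^2)
  sigma2_g <- rss / (n - p)
  sigma2_e <- delta * sigma2_g
  loglik <- -opt$objective -
    0.5 * (n - p) * (1 + log(2 * pi) - log(n - p))
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, delta = delta,
                 h2 = 1 / (1 + delta), loglik = loglik,
                 boundary = i %in% c(1L, length(grid)),
                 U = U, S = S, n = n, p = p),
            class = "sv_vc")
}

#' Per-marker mixed-model association (EMMAX approximation)
#'
#' With variance components fixed from [fit_null_reml()], each marker is
#' tested by generalized least squares of `y` on `[X, dosage]` under
#' covariance `sigma2_g K + sigma2_e I`, using the precomputed spectral
#' decomposition.  Missing dosages are mean-imputed per marker; markers
#' monomorphic after imputation get `p_value = NA`.
#'
#' @param gm an [sv_geno()] object or dosage matrix (loci x samples, in the
#'   same sample order as `y`).
#' @param y numeric response.
#' @param X fixed-effect design matrix (intercept, sex/batch indicators,
#'   PC covariates).
#' @param vc output of [fit_null_reml()].
#' @param alpha family-wise error rate for the Bonferroni flag
#'   (default 0.05).
#' @return data frame with `locus_id`, `beta`, `se`, `p_value`, `n_used`,
#'   `significant`, and `reason` for untestable markers.
#' @export
mlm_association <- function(gm, y, X, vc, alpha = 0.05) {
  d <- if (inherits(gm, "sv_geno")) gm$dosages else gm
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(ncol(d) == n, nrow(X) == n)
  G <- t(impute_row_means(d))            # n x m
  mono <- apply(G, 2, function(g) var(g) == 0)

  sw <- sqrt(1 / (vc$S + vc$delta))
  ystar <- crossprod(vc$U, y) * sw
  Xstar <- crossprod(vc$U, X) * sw
  Gstar <- crossprod(vc$U, G) * sw

  fit <- qr(Xstar)
  yres <- qr.resid(fit, ystar)
  Gres <- qr.resid(fit, Gstar)

  gg <- colSums(Gres^2)
  gy <- colSums(Gres * as.vector(yres))
  beta <- gy / gg
  df <- n - ncol(X) - 1
  rss <- sum(yres^2) - beta^2 * gg
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)

  beta[mono] <- NA; se[mono] <- NA; p[mono] <- NA
  n_tested <- sum(!mono)
  thr <- if (n_tested > 0) bonferroni_threshold(alpha, n_tested) else NA
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  out <- data.frame(locus_id = ids, beta = beta, se = se, p_value = p,
                    n_used = n,
                    significant = !is.na(p) & p < thr,
                    reason = ifelse(mono, "monomorphic after imputation",
                                    NA_character_),
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni") <- thr
  attr(out, "n_tested") <- n_tested
  rownames(out) <- NULL
  out
}

#' Bonferroni significance threshold
#'
#' `alpha / n_markers`.
#'
#' @param alpha family-wise error rate.
#' @param n_markers number of tested markers (>= 1).
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_markers) {
  if (n_markers < 1) stop("n_markers must be >= 1")
  alpha / n_markers
}

#' Genomic-control lambda from a p-value vector
#'
#' Median chi-square statistic over its null median.
#'
#' @param p p-values.
#' @return lambda.
#' @export
gc_lambda <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
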