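# End-to-end pipeline driver: merge -> QC -> founder genotyping -> F_ST ->
# founder screen -> offspring genotyping -> matrix QC -> mixed-model GWAS.

#' Run the full SV analysis pipeline on a simulated study
#'
#' @param study output of [simulate_study()].
#' @param merge_cfg a [merge_config()].
#' @param qc_cfg a [qc_config()].
#' @param freq_a,freq_b founder-screen genotype-frequency thresholds.
#' @param n_pcs number of PCA covariates in the association model
#'   (default 3).
#' @param fst_q upper tail fraction for stratified-locus selection.
#' @param alpha family-wise error rate for Bonferroni significance.
#' @return a list with every intermediate: merged loci, QC results,
#'   founder genotypes, `fst` table and `fst_top` selection, screen
#'   `candidates`, offspring genotyping (`f2_genotyping`), filtered matrix,
#'   kinship/PCA, per-trait association tables, and summary counts.
#' @export
run_sv_pipeline <- function(study,
                            merge_cfg = merge_config(),
                            qc_cfg = qc_config(),
                            freq_a = 0.80, freq_b = 0.50,
                            n_pcs = 3, fst_q = 0.05, alpha = 0.05) {
  cfg <- study$config

  merged <- merge_callsets(study$callsets, merge_cfg)
  qc <- filter_loci(merged, qc_cfg)
  loci <- qc$kept

  novelty <- compare_to_database(loci, study$reference_db, merge_cfg)

  founders <- study$truth$founder_samples
  fg <- genotype_candidates_in_offspring(
    loci, study$founder_evidence, samples = founders$sample,
    distance = merge_cfg$breakpoint_distance)
  founder_gm <- fg$gm

  groups <- founders$breed[match(colnames(founder_gm$dosages),
                                 founders$sample)]
  fst <- weir_cockerham_fst(founder_gm, groups)
  fst$svtype <- loci$svtype[match(fst$locus_id, loci$locus_id)]
  fst_top <- top_quantile_loci(fst, q = fst_q)

  scr_cfg <- screen_config(
    breed_a_samples = founders$sample[founders$breed == "A" &
                                        founders$purebred],
    breed_b_samples = founders$sample[founders$breed == "B"],
    freq_a = freq_a, freq_b = freq_b)
  screen_hits <- screen_differential_loci(founder_gm, scr_cfg)
  candidates <- loci[loci$locus_id %in% screen_hits$locus_id, , drop = FALSE]

  f2g <- genotype_candidates_in_offspring(
    candidates, study$f2_evidence, samples = study$f2$samples$sample,
    distance = merge_cfg$breakpoint_distance)
  gm_f2 <- sv_geno(f2g$gm$dosages, samples = study$f2$samples,
                   loci = candidates)
  filt <- filter_genotype_matrix(gm_f2, qc_cfg)

  K <- kinship(filt$gm, method = "IBS")
  pca <- grm_pca(filt$gm, k_axes = max(n_pcs, 2))

  samples <- filt$gm$samples
  X <- stats::model.matrix(~ sex + batch, data = samples)
  X <- cbind(X, pca$coords[, seq_len(n_pcs), drop = FALSE])

  ph <- study$phenotypes[match(samples$sample, study$phenotypes$sample), ]
  assoc <- list()
  vcs <- list()
  for (tr in names(cfg$traits)) {
    y <- ph[[tr]]
    vc <- fit_null_reml(y, X, K)
    res <- mlm_association(filt$gm, y, X, vc, alpha = alpha)
    li <- filt$gm$loci[match(res$locus_id, filt$gm$loci$locus_id), ]
    res$chrom <- li$chrom
    res$pos <- li$start
    res$svtype <- li$svtype
    res$length <- li$length
    res <- res[order(chrom_rank(res$chrom), res$pos), , drop = FALSE]
    assoc[[tr]] <- res
    vcs[[tr]] <- vc
  }

  list(merged = merged, qc = qc, loci = loci, novelty = novelty,
       founder_gm = founder_gm, founder_genotyping_rate = fg$success_rate,
       fst = fst, fst_top = fst_top,
       screen_hits = screen_hits, candidates = candidates,
       f2_genotyping_rate = f2g$success_rate, gm_filtered = filt$gm,
       filter_report = filt$report, K = K, pca = pca,
       variance_components = vcs, associations = assoc,
       summary = list(
         n_calls = nrow(study$callsets),
         n_merged = nrow(merged),
         n_after_qc = nrow(loci),
         pct_novel = round(100 * mean(!novelty$known), 2),
         n_fst_defined = sum(!is.na(fst$theta)),
         n_fst_top = nrow(fst_top),
         n_candidates = nrow(candidates),
         f2_genotyping_rate = f2g$success_rate,
         n_loci_tested = nrow(filt$gm$dosages)))
}

#' Match analysis loci back to true loci
#'
#' Nearest same-type true locus within `distance` bp of the representative
#' start.
#'
#' @param loci locus data frame with `chrom`, `start`, `svtype`.
#' @param truth_loci truth table from [simulate_truth()].
#' @param distance matching tolerance in bp.
#' @return character vector of truth ids (`NA` where unmatched).
#' @export
match_loci_to_truth <- function(loci, truth_loci, distance = 1000) {
  vapply(seq_len(nrow(loci)), function(i) {
    cand <- truth_loci[truth_loci$chrom == loci$chrom[i] &
                         truth_loci$svtype == loci$svtype[i], , drop = FALSE]
    if (nrow(cand) == 0) return(NA_character_)
    off <- abs(cand$start - loci$start[i])
    if (min(off) > distance) return(NA_character_)
    cand$truth_id[which.min(off)]
  }, character(1))
}

#' Did each trait's top association hit its planted causal SV?
#'
#' @param result output of [run_sv_pipeline()].
#' @param study the [simulate_study()] object it was run on.
#' @return named logical vector over traits.
#' @export
evaluate_causal_recovery <- function(result, study) {
  out <- logical(0)
  for (tr in names(study$config$traits)) {
    res <- result$associations[[tr]]
    res <- res[!is.na(res$p_value), , drop = FALSE]
    top <- res[which.min(res$p_value), , drop = FALSE]
    tid <- match_loci_to_truth(
      data.frame(chrom = top$chrom, start = top$pos, svtype = top$svtype),
      study$truth$loci)
    out[tr] <- !is.na(tid) &&
      tid %in% study$phenotype_truth[[tr]]$causal_ids
  }
  out
}
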