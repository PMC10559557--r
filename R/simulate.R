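# Synthetic two-breed study generator.
#
# Generates every input the pipeline consumes, with known ground truth:
# a gene model on a desk-scale genome, true SV loci placed with
# configurable positional-category weights, per-breed allele frequencies
# with Balding-Nichols-style divergence, founder genotypes for two breeds,
# noisy per-caller callsets (sensitivity, breakpoint jitter, false
# positives, quality failures), an F2 intercross with Haldane
# recombination, per-sample genotype evidence degraded by dropout and
# error, a partial reference SV database, and phenotypes with planted
# causal SVs plus polygenic background.
#
# All randomness flows from the single config seed; sub-steps use fixed
# small offsets from it so each stage is independently reproducible.

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: 15 + 15 founders
#' of two diverged breeds (with 4 + 15 of them the F0 parents of the
#' cross and the first 6 of breed A treated as purebred for screening),
#' 513 F2 offspring, four SV types with realistic type mix and length
#' distributions, four span-SV callers plus one MEI caller, and a 3%
#' genotyping dropout.
#'
#' @param seed integer seed driving all randomness.
#' @param n_chrom,chrom_length genome shape (default 9 chromosomes of
#'   10 Mb).  Several shortish chromosomes, rather than few long ones,
#'   mirror a multi-chromosome livestock genome: no single chromosome
#'   dominates the kinship matrix, which keeps the mixed model's
#'   marker-in-kinship contamination at realistic levels.
#' @param genes_per_mb gene density (default 9).
#' @param n_sv named vector of true locus counts per type.
#' @param placement_weights category weights for SV placement.
#' @param divergence_f Balding-Nichols F parameter for breed divergence.
#' @param n_founders_a,n_founders_b founders per breed.
#' @param n_purebred_a breed-A founders tagged purebred for the screen.
#' @param n_parents_a,n_parents_b founders that actually parent the cross.
#' @param n_f1,n_f2 intercross sizes.
#' @param recomb_cm_per_mb recombination rate.  The default (25 cM/Mb)
#'   compensates for the compressed physical genome: 3 x 30 Mb at 25 cM/Mb
#'   gives ~22.5 Morgans, the genome-wide map length of a real livestock
#'   genome, so F2 linkage disequilibrium decays over a realistic number of
#'   independently segregating blocks.
#' @param callers list of caller profiles (name, types, per-type
#'   sensitivity, jitter sd and truncation in bp, false positives per Mb,
#'   fraction of calls failing the quality filter).
#' @param genotype_dropout,genotype_error per-cell missingness and
#'   miscall probabilities of the positional genotyper.
#' @param db_known_fraction fraction of true loci present in the simulated
#'   reference SV database.
#' @param traits named list: per trait, `n_causal` and `causal_var` (the
#'   phenotypic variance fraction each causal SV explains).
#' @param h2_polygenic polygenic heritability of each trait.
#' @param trait_base_var total phenotypic variance scale; causal and
#'   polygenic shares are fractions of it (0 gives a constant phenotype
#'   when the fixed effects are also 0).
#' @param sex_effect,batch_sd,n_batches fixed-effect structure.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 9, chrom_length = 1e7,
                       genes_per_mb = 9,
                       n_sv = c(DEL = 600, DUP = 110, INV = 170, MEI = 220),
                       placement_weights = c(intergenic = 0.62, intron = 0.345,
                                             exon = 0.01, utr = 0.005,
                                             upstream = 0.01, downstream = 0.01),
                       divergence_f = 0.2,
                       n_founders_a = 15, n_founders_b = 15,
                       n_purebred_a = 6,
                       n_parents_a = 15, n_parents_b = 4,
                       n_f1 = 20, n_f2 = 513,
                       recomb_cm_per_mb = 25,
                       callers = default_caller_profiles(),
                       genotype_dropout = 0.03, genotype_error = 0.005,
                       db_known_fraction = 0.46,
                       traits = list(body_length = list(n_causal = 1,
                                                        causal_var = 0.15),
                                     carcass_length = list(n_causal = 1,
                                                           causal_var = 0.15)),
                       h2_polygenic = 0.3, trait_base_var = 1,
                       sex_effect = 0.3, batch_sd = 0.2, n_batches = 5) {
  stopifnot(all(placement_weights >= 0), abs(sum(placement_weights) - 1) < 1e-6,
            divergence_f >= 0, divergence_f < 1,
            genotype_dropout >= 0, genotype_dropout < 1,
            n_founders_a >= 2, n_founders_b >= 2)
  structure(as.list(environment()), class = "sim_config")
}

#' Default caller observation profiles
#'
#' Four span-SV callers with complementary per-type sensitivities plus one
#' MEI caller, each with its own breakpoint jitter scale, false-positive
#' rate and quality-failure fraction.  Jitter is truncated at 400 bp,
#' below half the 1000-bp merge distance, so calls of one true locus
#' always cluster together.
#'
#' @return list of caller profile lists.
#' @export
default_caller_profiles <- function() {
  list(
    list(name = "splitread", types = c("DEL", "DUP", "INV"),
         sensitivity = c(DEL = 0.80, DUP = 0.70, INV = 0.75),
         jitter_sd = 60, jitter_max = 400, fp_per_mb = 0.05,
         qual_fail_frac = 0.10),
    list(name = "pairedend", types = c("DEL", "DUP", "INV"),
         sensitivity = c(DEL = 0.75, DUP = 0.65, INV = 0.70),
         jitter_sd = 100, jitter_max = 400, fp_per_mb = 0.06,
         qual_fail_frac = 0.12),
    list(name = "assembly", types = c("DEL", "DUP", "INV"),
         sensitivity = c(DEL = 0.85, DUP = 0.70, INV = 0.65),
         jitter_sd = 30, jitter_max = 400, fp_per_mb = 0.03,
         qual_fail_frac = 0.08),
    list(name = "readdepth", types = c("DEL", "DUP", "INV"),
         sensitivity = c(DEL = 0.60, DUP = 0.80, INV = 0.50),
         jitter_sd = 150, jitter_max = 400, fp_per_mb = 0.08,
         qual_fail_frac = 0.15),
    list(name = "meiscan", types = "MEI",
         sensitivity = c(MEI = 0.85),
         jitter_sd = 50, jitter_max = 400, fp_per_mb = 0.02,
         qual_fail_frac = 0.08)
  )
}

MEI_FAMILY_PROBS <- c(ERV = 0.05, LINE = 0.15, SINE = 0.80)
MEI_FAMILY_LEN <- c(ERV = 8000, LINE = 6000, SINE = 300)

sv_length_draw <- function(svtype, n) {
  len <- switch(svtype,
    DEL = round(rlnorm(n, log(300), 0.8)),
    DUP = round(rlnorm(n, log(8000), 1.0)),
    INV = round(rlnorm(n, log(400), 1.0)),
    MEI = {
      fam <- sample(names(MEI_FAMILY_PROBS), n, replace = TRUE,
                    prob = MEI_FAMILY_PROBS)
      round(MEI_FAMILY_LEN[fam] * runif(n, 0.8, 1.2))
    })
  pmin(pmax(len, 50), 40000)
}

#' Simulate ground truth: gene model, SV loci, founder genotypes
#'
#' @param config a [sim_config()].
#' @return list with `gene_model`, `loci` (truth table with per-breed
#'   allele frequencies and causal flags), founder haplotypes `hap1`/`hap2`,
#'   `founder_geno` and `founder_samples`.
#' @export
simulate_truth <- function(config = sim_config()) {
  set.seed(config$seed)
  gm <- sim_gene_model(config)
  loci <- sim_sv_placement(config, gm)

  # breed allele frequencies: Balding-Nichols divergence around p0
  p0 <- runif(nrow(loci), 0.1, 0.9)
  f <- config$divergence_f
  if (f > 0) {
    loci$p_a <- rbeta(nrow(loci), p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    loci$p_b <- rbeta(nrow(loci), p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  } else {
    loci$p_a <- p0
    loci$p_b <- p0
  }

  # planted causal loci: fixed differences between the breeds, one or more
  # per trait, drawn from DEL loci at isolated positions (no same-type
  # neighbour within 2.5 kb) so the 1000-bp merge rule cannot chain a
  # causal locus into a neighbouring cluster and lose its identity
  loci$causal <- FALSE
  loci$trait <- NA_character_
  loci$causal_var <- NA_real_
  isolated <- vapply(seq_len(nrow(loci)), function(i) {
    same <- loci$svtype == loci$svtype[i] & loci$chrom == loci$chrom[i]
    same[i] <- FALSE
    !any(same & abs(loci$start - loci$start[i]) < 2500)
  }, logical(1))
  pool <- which(loci$svtype == "DEL" & loci$length >= 100 &
                  loci$length <= 2000 & isolated)
  for (tr in names(config$traits)) {
    spec <- config$traits[[tr]]
    pick <- sample(pool, spec$n_causal)
    pool <- setdiff(pool, pick)
    loci$causal[pick] <- TRUE
    loci$trait[pick] <- tr
    loci$causal_var[pick] <- spec$causal_var
    loci$p_a[pick] <- 1
    loci$p_b[pick] <- 0
  }

  n_a <- config$n_founders_a
  n_b <- config$n_founders_b
  samples <- sample_info(
    sample = c(paste0("M", seq_len(n_a)), paste0("LW", seq_len(n_b))),
    breed = c(rep("A", n_a), rep("B", n_b)),
    generation = "F0")
  samples$purebred <- c(seq_len(n_a) <= config$n_purebred_a,
                        rep(FALSE, n_b))
  p_mat <- cbind(matrix(loci$p_a, nrow(loci), n_a),
                 matrix(loci$p_b, nrow(loci), n_b))
  hap1 <- matrix(rbinom(length(p_mat), 1, p_mat), nrow(loci),
                 dimnames = list(loci$truth_id, samples$sample))
  hap2 <- matrix(rbinom(length(p_mat), 1, p_mat), nrow(loci),
                 dimnames = list(loci$truth_id, samples$sample))
  list(config = config, gene_model = gm, loci = loci,
       hap1 = hap1, hap2 = hap2,
       founder_geno = hap1 + hap2, founder_samples = samples)
}

# non-overlapping genes in regular slots; exon/intron structure with
# terminal UTRs carved out of the first/last exon
sim_gene_model <- function(config) {
  genes <- list(); exons <- list(); u5 <- list(); u3 <- list()
  gi <- 0L
  for (ch in seq_len(config$n_chrom)) {
    chrom <- paste0("chr", ch)
    n_genes <- max(1, round(config$chrom_length / 1e6 * config$genes_per_mb))
    slot <- config$chrom_length / n_genes
    for (s in seq_len(n_genes)) {
      gi <- gi + 1L
      span <- round(slot * runif(1, 0.05, 0.45))
      gstart <- round((s - 1) * slot + runif(1) * (slot - span)) + 1L
      gend <- gstart + span - 1L
      strand <- sample(c("+", "-"), 1)
      id <- sprintf("G%04d", gi)
      genes[[gi]] <- data.frame(gene_id = id, chrom = chrom,
                                start = gstart, end = gend, strand = strand)
      k <- sample(3:8, 1)
      w <- numeric(2 * k - 1)
      w[seq(1, 2 * k - 1, by = 2)] <- runif(k, 0.4, 1.0)     # exons
      w[seq(2, 2 * k - 2, by = 2)] <- runif(k - 1, 1.5, 4.0) # introns
      bounds <- gstart + round(cumsum(w) / sum(w) * (span - 1))
      seg_start <- c(gstart, head(bounds, -1) + 1L)
      seg_end <- c(head(bounds, -1), gend)
      ex_i <- seq(1, 2 * k - 1, by = 2)
      es <- seg_start[ex_i]; ee <- seg_end[ex_i]
      ok <- ee >= es
      es <- es[ok]; ee <- ee[ok]
      # terminal UTRs: left end of the leftmost exon, right end of the
      # rightmost; 5'/3' by strand
      nl <- length(es)
      u_left <- NULL; u_right <- NULL
      if (ee[1] - es[1] + 1 >= 20) {
        ul_end <- es[1] + max(1L, round(0.3 * (ee[1] - es[1]))) - 1L
        u_left <- c(es[1], ul_end); es[1] <- ul_end + 1L
      }
      if (ee[nl] - es[nl] + 1 >= 20) {
        ur_start <- ee[nl] - max(1L, round(0.3 * (ee[nl] - es[nl]))) + 1L
        u_right <- c(ur_start, ee[nl]); ee[nl] <- ur_start - 1L
      }
      exons[[gi]] <- data.frame(gene_id = id, chrom = chrom,
                                start = es, end = ee)
      mku <- function(u) if (is.null(u)) NULL else
        data.frame(gene_id = id, chrom = chrom, start = u[1], end = u[2])
      if (strand == "+") {
        u5[[gi]] <- mku(u_left); u3[[gi]] <- mku(u_right)
      } else {
        u5[[gi]] <- mku(u_right); u3[[gi]] <- mku(u_left)
      }
    }
  }
  bindf <- function(l) do.call(rbind, Filter(Negate(is.null), l))
  gene_model(bindf(genes), bindf(exons), bindf(u5), bindf(u3))
}

# place SV loci with the configured category weights
sim_sv_placement <- function(config, gm, flank = 1000) {
  g <- gm$genes
  # intergenic gaps shrunk by flank + 100 bp margins so placements are
  # unambiguously intergenic
  gaps <- list()
  for (chrom in unique(g$chrom)) {
    gc <- g[g$chrom == chrom, ]
    gc <- gc[order(gc$start), ]
    bounds <- c(1L, gc$end + flank + 100L)
    ends <- c(gc$start - flank - 100L, config$chrom_length)
    ok <- ends - bounds > 1000
    gaps[[chrom]] <- data.frame(chrom = chrom, start = bounds[ok],
                                end = ends[ok])
  }
  gaps <- do.call(rbind, gaps)
  feats <- list(intron = gm$introns,
                exon = gm$exons,
                utr = rbind(gm$utr5, gm$utr3))
  # upstream/downstream flank windows, strand-aware
  up <- data.frame(chrom = g$chrom,
                   start = ifelse(g$strand == "-", g$end + 1L,
                                  pmax(1L, g$start - flank)),
                   end = ifelse(g$strand == "-", g$end + flank, g$start - 1L))
  dn <- data.frame(chrom = g$chrom,
                   start = ifelse(g$strand == "-", pmax(1L, g$start - flank),
                                  g$end + 1L),
                   end = ifelse(g$strand == "-", g$start - 1L, g$end + flank))
  feats$upstream <- up
  feats$downstream <- dn
  feats$intergenic <- gaps

  out <- list()
  ti <- 0L
  for (svtype in names(config$n_sv)) {
    n <- config$n_sv[[svtype]]
    if (n == 0) next
    lens <- sv_length_draw(svtype, n)
    fams <- if (svtype == "MEI") {
      ifelse(lens > 5000, ifelse(lens > 7000, "ERV", "LINE"), "SINE")
    } else rep("none", n)
    cats <- sample(names(config$placement_weights), n, replace = TRUE,
                   prob = config$placement_weights)
    for (i in seq_len(n)) {
      ti <- ti + 1L
      need <- if (svtype == "MEI") 1L else lens[i]
      placed <- NULL
      cat_i <- cats[i]
      for (try in 1:25) {
        f <- feats[[cat_i]]
        f <- f[f$end - f$start + 1L >= need, , drop = FALSE]
        if (nrow(f) == 0) { cat_i <- "intergenic"; next }
        row <- f[sample(nrow(f), 1), ]
        start <- row$start + sample.int(row$end - row$start + 2L - need, 1) - 1L
        placed <- list(chrom = row$chrom, start = start,
                       end = if (svtype == "MEI") start else start + need - 1L,
                       category = cat_i)
        break
      }
      if (is.null(placed)) stop("could not place SV of length ", need)
      out[[ti]] <- data.frame(
        truth_id = sprintf("T_%05d", ti), chrom = placed$chrom,
        start = placed$start, end = placed$end, svtype = svtype,
        mei_family = fams[i], length = lens[i],
        placed_category = placed$category, stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(chrom_rank(loci$chrom), loci$start), , drop = FALSE]
  loci$truth_id <- sprintf("T_%05d", seq_len(nrow(loci)))
  rownames(loci) <- NULL
  loci
}

#' Simulate per-caller, per-founder callsets
#'
#' Each caller observes each carrier founder's true loci of its types with
#' its per-type sensitivity; observed breakpoints are the true ones plus
#' truncated Gaussian jitter; quality scores fall below the QUAL filter
#' with the configured failure fraction (MEI calls fail the PASS filter
#' instead); false positives are appended at Poisson rate per Mb.
#'
#' @param truth output of [simulate_truth()].
#' @param config a [sim_config()].
#' @return an `sv_records` data frame of all calls.
#' @export
simulate_callsets <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  loci <- truth$loci
  geno <- truth$founder_geno
  genome_mb <- config$n_chrom * config$chrom_length / 1e6
  jit <- function(n, sd, mx) pmin(pmax(round(rnorm(n, 0, sd)), -mx), mx)
  recs <- list()
  for (prof in config$callers) {
    for (smp in colnames(geno)) {
      carrier <- which(geno[, smp] > 0 & loci$svtype %in% prof$types)
      if (length(carrier) > 0) {
        det <- carrier[runif(length(carrier)) <
                         prof$sensitivity[loci$svtype[carrier]]]
      } else det <- integer(0)
      if (length(det) > 0) {
        l <- loci[det, ]
        span <- l$svtype != "MEI"
        mx_s <- ifelse(span, pmin(prof$jitter_max, (l$length - 1) %/% 2),
                       prof$jitter_max)
        s_obs <- pmax(1L, l$start + jit(nrow(l), prof$jitter_sd, mx_s))
        e_obs <- ifelse(span, l$end + jit(nrow(l), prof$jitter_sd, mx_s),
                        s_obs)
        e_obs <- pmax(e_obs, s_obs)
        fail <- runif(nrow(l)) < prof$qual_fail_frac
        recs[[length(recs) + 1L]] <- sv_records(
          chrom = l$chrom, start = s_obs, end = e_obs, svtype = l$svtype,
          mei_family = l$mei_family,
          length = ifelse(span, e_obs - s_obs + 1L, l$length),
          qual = ifelse(fail, runif(nrow(l), 20, 200),
                        runif(nrow(l), 201, 999)),
          filter = ifelse(l$svtype == "MEI" & fail, "lowqual", "PASS"),
          caller = prof$name, sample = smp)
      }
      # false positives
      n_fp <- rpois(1, prof$fp_per_mb * genome_mb)
      if (n_fp > 0) {
        fp_type <- sample(prof$types, n_fp, replace = TRUE)
        fp_len <- vapply(fp_type, function(tt) sv_length_draw(tt, 1), 1)
        fp_chrom <- paste0("chr", sample.int(config$n_chrom, n_fp,
                                             replace = TRUE))
        fp_start <- sapply(fp_len, function(ln)
          sample.int(config$chrom_length - ln, 1))
        fp_fam <- ifelse(fp_type == "MEI",
                         sample(names(MEI_FAMILY_PROBS), n_fp, replace = TRUE,
                                prob = MEI_FAMILY_PROBS), "none")
        fail <- runif(n_fp) < prof$qual_fail_frac
        recs[[length(recs) + 1L]] <- sv_records(
          chrom = fp_chrom, start = fp_start,
          end = ifelse(fp_type == "MEI", fp_start, fp_start + fp_len - 1),
          svtype = fp_type, mei_family = fp_fam,
          length = fp_len,
          qual = ifelse(fail, runif(n_fp, 20, 200), runif(n_fp, 201, 999)),
          filter = ifelse(fp_type == "MEI" & fail, "lowqual", "PASS"),
          caller = prof$name, sample = smp)
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("sv_records", "data.frame")
  out
}

#' Simulate the F2 intercross
#'
#' F1 individuals are formed from breed-A x breed-B parent pairs, F2 from
#' F1 x F1 pairs; gametes carry Poisson crossovers under the Haldane map
#' (no interference) at the configured cM/Mb rate, so Mendelian
#' transmission is exact.
#'
#' @param truth output of [simulate_truth()].
#' @param config a [sim_config()].
#' @return list with `geno` (loci x F2 dosage matrix), `samples`
#'   (sex/batch metadata) and `pedigree`.
#' @export
simulate_f2 <- function(truth, config = truth$config) {
  set.seed(config$seed + 2L)
  loci <- truth$loci
  if (config$n_parents_a < 1 || config$n_parents_b < 1) {
    stop("at least one parent per breed required")
  }
  pos_by_chrom <- split(seq_len(nrow(loci)), loci$chrom)
  morgans <- config$chrom_length / 1e6 * config$recomb_cm_per_mb / 100

  gamete <- function(h1, h2) {
    out <- integer(nrow(loci))
    for (chrom in names(pos_by_chrom)) {
      idx <- pos_by_chrom[[chrom]]
      k <- rpois(1, morgans)
      xo <- if (k > 0) sort(runif(k, 1, config$chrom_length)) else numeric(0)
      phase <- (findInterval(loci$start[idx], xo) +
                  sample.int(2L, 1L)) %% 2L
      out[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
    }
    out
  }

  a_ids <- truth$founder_samples$sample[truth$founder_samples$breed == "A"]
  b_ids <- truth$founder_samples$sample[truth$founder_samples$breed == "B"]
  a_par <- a_ids[seq_len(config$n_parents_a)]
  b_par <- b_ids[seq_len(config$n_parents_b)]

  f1_h1 <- matrix(0L, nrow(loci), config$n_f1)
  f1_h2 <- matrix(0L, nrow(loci), config$n_f1)
  f1_ped <- data.frame(id = paste0("F1_", seq_len(config$n_f1)),
                       parent_a = sample(a_par, config$n_f1, replace = TRUE),
                       parent_b = sample(b_par, config$n_f1, replace = TRUE))
  for (i in seq_len(config$n_f1)) {
    pa <- f1_ped$parent_a[i]; pb <- f1_ped$parent_b[i]
    f1_h1[, i] <- gamete(truth$hap1[, pa], truth$hap2[, pa])
    f1_h2[, i] <- gamete(truth$hap1[, pb], truth$hap2[, pb])
  }

  n_f2 <- config$n_f2
  ids <- sprintf("F2_%04d", seq_len(n_f2))
  geno <- matrix(0L, nrow(loci), n_f2,
                 dimnames = list(loci$truth_id, ids))
  sire <- sample.int(config$n_f1, n_f2, replace = TRUE)
  dam_off <- sample.int(config$n_f1 - 1L, n_f2, replace = TRUE)
  dam <- (sire + dam_off - 1L) %% config$n_f1 + 1L  # distinct from sire
  for (j in seq_len(n_f2)) {
    geno[, j] <- gamete(f1_h1[, sire[j]], f1_h2[, sire[j]]) +
      gamete(f1_h1[, dam[j]], f1_h2[, dam[j]])
  }
  samples <- sample_info(ids, breed = "F2", generation = "F2",
                         sex = sample(c("M", "F"), n_f2, replace = TRUE),
                         batch = paste0("B", sample.int(config$n_batches,
                                                        n_f2, replace = TRUE)))
  list(geno = geno, samples = samples,
       pedigree = data.frame(id = ids, sire = f1_ped$id[sire],
                             dam = f1_ped$id[dam]),
       f1_pedigree = f1_ped)
}

#' Simulate positional genotype evidence
#'
#' Turns a true genotype matrix into the per-sample evidence a positional
#' genotyper would produce: each (locus, sample) genotype is dropped with
#' probability `genotype_dropout` and miscalled with probability
#' `genotype_error`; a confidence score accompanies each call.
#'
#' @param truth output of [simulate_truth()].
#' @param geno true dosage matrix (loci x samples), rownames = truth ids.
#' @param config a [sim_config()].
#' @param seed_offset offset added to the config seed (use different
#'   offsets for founder and offspring evidence).
#' @return data frame with `chrom`, `pos`, `svtype`, `sample`, `dosage`,
#'   `conf`.
#' @export
simulate_genotype_evidence <- function(truth, geno, config = truth$config,
                                       seed_offset = 3L) {
  set.seed(config$seed + seed_offset)
  loci <- truth$loci[match(rownames(geno), truth$loci$truth_id), ]
  n_l <- nrow(geno); n_s <- ncol(geno)
  dosage <- as.vector(geno)
  err <- runif(length(dosage)) < config$genotype_error
  dosage[err] <- (dosage[err] + sample.int(2L, sum(err), replace = TRUE)) %% 3L
  keep <- runif(length(dosage)) >= config$genotype_dropout
  ev <- data.frame(
    chrom = rep(loci$chrom, times = n_s),
    pos = rep(loci$start, times = n_s),
    svtype = rep(loci$svtype, times = n_s),
    sample = rep(colnames(geno), each = n_l),
    dosage = dosage,
    conf = runif(length(dosage), 0.5, 1),
    stringsAsFactors = FALSE)
  ev[keep, , drop = FALSE]
}

#' Simulate a partial reference SV database
#'
#' A configurable fraction of the true loci, with small proportional
#' coordinate jitter, standing in for a public SV database so that novelty
#' labelling has known ground truth.
#'
#' @param truth output of [simulate_truth()].
#' @param config a [sim_config()].
#' @return data frame with `chrom`, `start`, `end`, `svtype` and the
#'   source `truth_id`.
#' @export
simulate_reference_db <- function(truth, config = truth$config) {
  set.seed(config$seed + 6L)
  loci <- truth$loci
  keep <- sort(sample.int(nrow(loci), round(config$db_known_fraction *
                                              nrow(loci))))
  db <- loci[keep, c("chrom", "start", "end", "svtype", "truth_id")]
  span <- db$svtype != "MEI"
  shift <- round(ifelse(span,
                        (db$end - db$start + 1) * runif(nrow(db), -0.03, 0.03),
                        runif(nrow(db), -200, 200)))
  db$start <- pmax(1L, db$start + shift)
  db$end <- ifelse(span, db$end + shift, db$start)
  rownames(db) <- NULL
  db
}

#' Simulate phenotypes with planted causal SVs
#'
#' `y = mu + sex + batch + sum_j beta_j dosage_j + g + e` with
#' `g ~ N(0, sigma2_g K)` and `e ~ N(0, sigma2_e I)`.  Effect sizes are
#' set so each causal SV explains its configured fraction of phenotypic
#' variance; the polygenic and residual components fill the rest.
#'
#' @param f2 output of [simulate_f2()].
#' @param truth output of [simulate_truth()].
#' @param K kinship matrix over the F2 samples (e.g. [kinship()] on the
#'   true genotypes).
#' @param config a [sim_config()].
#' @return list with `phenotypes` (data frame: sample, sex, batch, one
#'   column per trait) and `truth` (per-trait causal ids, betas and
#'   variance components).
#' @export
simulate_phenotypes <- function(f2, truth, K, config = truth$config) {
  set.seed(config$seed + 5L)
  n <- ncol(f2$geno)
  ph <- data.frame(sample = colnames(f2$geno), sex = f2$samples$sex,
                   batch = f2$samples$batch, stringsAsFactors = FALSE)
  ev <- eigen(K, symmetric = TRUE)   # K need not be PD (IBS); clamp
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n)
  info <- list()
  for (tr in names(config$traits)) {
    spec <- config$traits[[tr]]
    cid <- truth$loci$truth_id[!is.na(truth$loci$trait) &
                                 truth$loci$trait == tr]
    if (!all(cid %in% rownames(f2$geno))) {
      stop("causal locus absent from genotype matrix for trait ", tr)
    }
    base <- config$trait_base_var
    causal_total <- spec$causal_var * length(cid)
    if (config$h2_polygenic + causal_total > 1) {
      stop("variance budget exceeded for trait ", tr)
    }
    sigma2_e <- base * (1 - config$h2_polygenic - causal_total)
    beta <- numeric(length(cid))
    g_term <- numeric(n)
    for (k in seq_along(cid)) {
      gdos <- f2$geno[cid[k], ]
      v <- var(gdos)
      beta[k] <- if (v > 0) sqrt(base * spec$causal_var / v) else 0
      g_term <- g_term + beta[k] * (gdos - mean(gdos))
    }
    u <- sqrt(base * config$h2_polygenic) * as.vector(A %*% rnorm(n))
    e <- rnorm(n, 0, sqrt(sigma2_e))
    batch_eff <- rnorm(config$n_batches, 0, config$batch_sd)
    names(batch_eff) <- paste0("B", seq_len(config$n_batches))
    y <- 100 + config$sex_effect * (ph$sex == "M") +
      batch_eff[ph$batch] + g_term + u + e
    ph[[tr]] <- as.numeric(y)
    info[[tr]] <- list(causal_ids = cid, beta = beta,
                       sigma2_g = base * config$h2_polygenic,
                       sigma2_e = sigma2_e, batch_effects = batch_eff)
  }
  list(phenotypes = ph, truth = info)
}

#' Simulate a complete two-breed study
#'
#' Runs every generator stage in order under the single config seed and
#' bundles the results: truth, callsets, founder and offspring genotype
#' evidence, F2 genotypes, reference database and phenotypes.
#'
#' @param config a [sim_config()].
#' @return a list of class `sv_study`.
#' @export
simulate_study <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  callsets <- simulate_callsets(truth, config)
  founder_evidence <- simulate_genotype_evidence(truth, truth$founder_geno,
                                                 config, seed_offset = 3L)
  f2 <- simulate_f2(truth, config)
  f2_evidence <- simulate_genotype_evidence(truth, f2$geno, config,
                                            seed_offset = 4L)
  reference_db <- simulate_reference_db(truth, config)
  K_true <- kinship(f2$geno, method = "IBS")
  phen <- simulate_phenotypes(f2, truth, K_true, config)
  structure(list(config = config, truth = truth, callsets = callsets,
                 founder_evidence = founder_evidence, f2 = f2,
                 f2_evidence = f2_evidence, reference_db = reference_db,
                 K_true = K_true, phenotypes = phen$phenotypes,
                 phenotype_truth = phen$truth),
            class = "sv_study")
}
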