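# Ground-truth generator: determinism, counts, divergence, caller noise,
# Mendelian transmission, recombination, phenotype construction.

test_that("the same seed reproduces the whole study byte for byte", {
  cfg <- sim_config(seed = 5, n_chrom = 1, chrom_length = 5e6,
                    n_sv = c(DEL = 40, DUP = 10, INV = 10, MEI = 10),
                    n_f2 = 30)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth$loci, s2$truth$loci)
  expect_identical(s1$truth$founder_geno, s2$truth$founder_geno)
  expect_identical(as.data.frame(s1$callsets), as.data.frame(s2$callsets))
  expect_identical(s1$f2$geno, s2$f2$geno)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("requested per-type locus counts are produced exactly", {
  cfg <- sim_config(seed = 6, n_chrom = 1, chrom_length = 1e7,
                    n_sv = c(DEL = 200, DUP = 0, INV = 0, MEI = 50),
                    traits = list())
  truth <- simulate_truth(cfg)
  expect_equal(as.integer(table(truth$loci$svtype)[c("DEL", "MEI")]),
               c(200L, 50L))
  expect_true(all(truth$loci$end[truth$loci$svtype == "MEI"] ==
                    truth$loci$start[truth$loci$svtype == "MEI"]))
})

test_that("zero divergence gives identical breed frequencies; positive
           divergence separates them", {
  cfg0 <- sim_config(seed = 7, n_chrom = 1, chrom_length = 5e6,
                     n_sv = c(DEL = 300, DUP = 0, INV = 0, MEI = 0),
                     divergence_f = 0, traits = list())
  t0 <- simulate_truth(cfg0)
  expect_equal(mean(abs(t0$loci$p_a - t0$loci$p_b)), 0)
  cfg2 <- sim_config(seed = 7, n_chrom = 1, chrom_length = 5e6,
                     n_sv = c(DEL = 300, DUP = 0, INV = 0, MEI = 0),
                     divergence_f = 0.2, traits = list())
  t2 <- simulate_truth(cfg2)
  expect_gt(mean(abs(t2$loci$p_a - t2$loci$p_b)), 0.1)
})

test_that("the noiseless limit recovers the true loci exactly", {
  cfg <- sim_config(seed = 8, n_chrom = 1, chrom_length = 1e7,
                    n_sv = c(DEL = 80, DUP = 20, INV = 20, MEI = 20),
                    traits = list())
  cfg$callers <- lapply(default_caller_profiles(), function(p) {
    p$sensitivity[] <- 1
    p$jitter_sd <- 0; p$jitter_max <- 0
    p$fp_per_mb <- 0; p$qual_fail_frac <- 0
    p
  })
  truth <- simulate_truth(cfg)
  # restrict to loci that cannot merge with a neighbour, so one true locus
  # maps to exactly one cluster (random placement can put two same-type
  # loci within the 1000-bp linkage rule)
  sep <- vapply(seq_len(nrow(truth$loci)), function(i) {
    l <- truth$loci[i, ]
    other <- truth$loci[-i, ]
    same <- other[other$svtype == l$svtype, , drop = FALSE]
    nrow(same) == 0 || all(abs(same$start - l$start) > 1100 |
                             abs(same$end - l$end) > 1100)
  }, logical(1))
  truth$loci <- truth$loci[sep, ]
  truth$hap1 <- truth$hap1[sep, ]; truth$hap2 <- truth$hap2[sep, ]
  truth$founder_geno <- truth$founder_geno[sep, ]
  cs <- simulate_callsets(truth, cfg)
  merged <- merge_callsets(cs)
  # only loci carried by at least one founder can be observed
  carried <- truth$loci[rowSums(truth$founder_geno) > 0, ]
  expect_equal(nrow(merged), nrow(carried))
  expect_equal(merged$start, carried$start)
  expect_equal(merged$end, ifelse(carried$svtype == "MEI", carried$start,
                                  carried$end))
  expect_equal(merged$svtype, carried$svtype)
})

test_that("per-locus detection by at least one caller follows the union
           probability", {
  cfg <- sim_config(seed = 9, n_chrom = 2, chrom_length = 1e7,
                    n_sv = c(DEL = 400, DUP = 0, INV = 0, MEI = 0),
                    traits = list())
  cfg$callers <- lapply(default_caller_profiles()[1:4], function(p) {
    p$sensitivity[] <- 0.7
    p$fp_per_mb <- 0
    p
  })
  truth <- simulate_truth(cfg)
  cs <- simulate_callsets(truth, cfg)
  carriers <- which(truth$founder_geno > 0, arr.ind = TRUE)
  key_all <- paste(truth$loci$truth_id[carriers[, 1]],
                   colnames(truth$founder_geno)[carriers[, 2]])
  tid <- match_loci_to_truth(cs, truth$loci)
  key_seen <- unique(paste(tid, cs$sample))
  p_hat <- mean(key_all %in% key_seen)
  p_want <- 1 - 0.3^4
  expect_lt(abs(p_hat - p_want),
            4 * sqrt(p_want * (1 - p_want) / length(key_all)) + 0.005)
})

test_that("false-positive counts are Poisson-consistent with the rate", {
  cfg <- sim_config(seed = 10, n_chrom = 1, chrom_length = 1e7,
                    n_sv = c(DEL = 50, DUP = 0, INV = 0, MEI = 0),
                    traits = list())
  cfg$callers <- list(list(name = "fponly", types = "DEL",
                           sensitivity = c(DEL = 0), jitter_sd = 0,
                           jitter_max = 0, fp_per_mb = 2,
                           qual_fail_frac = 0))
  truth <- simulate_truth(cfg)
  cs <- simulate_callsets(truth, cfg)
  # 30 founders x 10 Mb x 2/Mb: Poisson(20) per sample
  n_per_sample <- table(factor(cs$sample,
                               levels = truth$founder_samples$sample))
  lambda <- 20
  expect_lt(abs(mean(n_per_sample) - lambda),
            4 * sqrt(lambda / length(n_per_sample)))
  expect_lt(var(n_per_sample) / mean(n_per_sample), 2.5)
})

test_that("a locus fixed in all founders stays fixed in the F2", {
  cfg <- sim_config(seed = 11, n_chrom = 1, chrom_length = 2e6,
                    n_sv = c(DEL = 20, DUP = 0, INV = 0, MEI = 0),
                    n_f2 = 100, traits = list())
  truth <- simulate_truth(cfg)
  truth$hap1[1, ] <- 0L; truth$hap2[1, ] <- 0L
  truth$hap1[2, ] <- 1L; truth$hap2[2, ] <- 1L
  f2 <- simulate_f2(truth, cfg)
  expect_true(all(f2$geno[1, ] == 0))
  expect_true(all(f2$geno[2, ] == 2))
})

test_that("a fixed breed difference segregates 1:2:1 in the F2", {
  cfg <- sim_config(seed = 12, n_chrom = 1, chrom_length = 2e6,
                    n_sv = c(DEL = 10, DUP = 0, INV = 0, MEI = 0),
                    n_f2 = 2000, traits = list())
  truth <- simulate_truth(cfg)
  a <- truth$founder_samples$breed == "A"
  truth$hap1[, a] <- 1L; truth$hap2[, a] <- 1L
  truth$hap1[, !a] <- 0L; truth$hap2[, !a] <- 0L
  f2 <- simulate_f2(truth, cfg)
  expect_true(all(f2$geno[, 1] %in% 0:2))
  counts <- table(factor(f2$geno[1, ], levels = 0:2))
  expect_gt(chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 0.01)
})

test_that("the recombinant fraction follows the Haldane map", {
  cfg <- sim_config(seed = 13, n_chrom = 1, chrom_length = 6e7,
                    n_sv = c(DEL = 2, DUP = 0, INV = 0, MEI = 0),
                    n_f2 = 2000, recomb_cm_per_mb = 1, traits = list())
  truth <- simulate_truth(cfg)
  # place the two loci exactly 1 Mb apart; fix opposite breed alleles
  truth$loci$start <- c(10e6, 11e6)
  truth$loci$end <- truth$loci$start + 200
  a <- truth$founder_samples$breed == "A"
  truth$hap1[, a] <- 1L; truth$hap2[, a] <- 1L
  truth$hap1[, !a] <- 0L; truth$hap2[, !a] <- 0L
  f2 <- simulate_f2(truth, cfg)
  # for an F2 with codominant fixed-difference loci, cor(d1, d2) = 1 - 2r
  r_hat <- (1 - cor(f2$geno[1, ], f2$geno[2, ])) / 2
  d_morgan <- 0.01
  r_want <- (1 - exp(-2 * d_morgan)) / 2           # ~ 0.0099
  expect_lt(abs(r_hat - r_want), 0.012)
  # 55 Mb apart: 0.55 Morgan under the same map
  truth$loci$start <- c(1e6, 56e6)
  f2b <- simulate_f2(truth, cfg)
  r_far <- (1 - cor(f2b$geno[1, ], f2b$geno[2, ])) / 2
  expect_lt(abs(r_far - (1 - exp(-2 * 0.55)) / 2), 0.05)
})

test_that("phenotypes decompose as configured", {
  cfg <- sim_config(seed = 14, n_chrom = 2, chrom_length = 1e7,
                    n_sv = c(DEL = 100, DUP = 0, INV = 0, MEI = 0),
                    n_f2 = 400,
                    traits = list(tr = list(n_causal = 1, causal_var = 0.15)))
  truth <- simulate_truth(cfg)
  f2 <- simulate_f2(truth, cfg)
  K <- kinship(f2$geno)
  out <- t(vapply(1:20, function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + 100 + i   # phenotype noise varies per replicate
    ph <- simulate_phenotypes(f2, truth, K, cfg_i)
    tinfo <- ph$truth$tr
    g <- f2$geno[tinfo$causal_ids, ]
    c(causal = var(tinfo$beta * g), share = var(tinfo$beta * g) /
        var(ph$phenotypes$tr))
  }, numeric(2)))
  # the causal component carries exactly its configured variance
  expect_equal(unname(out[, "causal"]), rep(0.15, 20), tolerance = 1e-10)
  # its share of total variance: the polygenic term's *shared* component
  # (an IBS kinship has a large common baseline) shifts rather than
  # spreads the sample, so the realised share sits a little above the
  # nominal 0.15/1.0
  expect_lt(abs(mean(out[, "share"]) - 0.15), 0.05)
  # all components zero: constant phenotype
  cfg0 <- cfg
  cfg0$trait_base_var <- 0
  cfg0$sex_effect <- 0
  cfg0$batch_sd <- 0
  ph0 <- simulate_phenotypes(f2, truth, K, cfg0)
  expect_equal(var(ph0$phenotypes$tr), 0)
})

test_that("a missing causal locus is an explicit error", {
  cfg <- sim_config(seed = 15, n_chrom = 1, chrom_length = 5e6,
                    n_sv = c(DEL = 50, DUP = 0, INV = 0, MEI = 0),
                    n_f2 = 50)
  truth <- simulate_truth(cfg)
  f2 <- simulate_f2(truth, cfg)
  f2$geno <- f2$geno[!rownames(f2$geno) %in%
                       truth$loci$truth_id[truth$loci$causal], ]
  K <- diag(ncol(f2$geno))
  expect_error(simulate_phenotypes(f2, truth, K, cfg), "causal locus absent")
})
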