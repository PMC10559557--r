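#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-breed resource population.
#
# Simulates the complete study with known ground truth: a 9 x 10 Mb genome
# with a gene model, 1,100 true SV loci (DEL/DUP/INV/MEI) with
# Balding-Nichols breed divergence, 15 + 15 founders, noisy callsets from
# five callers, a 513-individual F2 intercross, genotype evidence with 3%
# dropout, a partial reference SV database, and two phenotypes each driven
# by one planted causal deletion (15% of variance) plus polygenic
# background.  Writes the standard input files a real study would start
# from, and caches the study object for the later stages.

library(svforge)

seed <- 1
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
study <- simulate_study(cfg)

# standard-format exports: per-caller VCFs (one per caller), gene model,
# sample sheet, phenotypes, truth table
dir.create("scratch/callsets", showWarnings = FALSE)
for (cl in unique(study$callsets$caller)) {
  write_sv_vcf(study$callsets[study$callsets$caller == cl, ],
               file.path("scratch/callsets", paste0(cl, ".vcf")))
}
write_gene_model_gff3(study$truth$gene_model, "results/genes.gff3")
write.table(study$truth$founder_samples, "results/founders.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$phenotypes, "results/phenotypes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$truth$loci, "results/truth_loci.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(study, "scratch/study.rds")

cat("Simulated", nrow(study$truth$loci), "true loci;",
    nrow(study$callsets), "raw calls from",
    length(unique(study$callsets$caller)), "callers;",
    ncol(study$f2$geno), "F2 offspring.\n")
cat("Causal loci:\n")
print(study$truth$loci[study$truth$loci$causal,
                       c("truth_id", "chrom", "start", "length", "trait")])
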