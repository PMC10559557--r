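#!/usr/bin/env Rscript
# Stage 2: union-merge the five callsets, filter the merged map, and label
# novelty against the reference SV database.
#
# Merging uses the 1000-bp breakpoint-distance rule (both breakpoints) for
# DEL/DUP/MEI and the stratified >75% reciprocal-overlap rule for INV,
# first within each founder across callers, then across founders.  QC
# keeps DEL/DUP/INV with QUAL > 200 and length 50 bp..1 Mb, and MEI loci
# flagged PASS.

library(svforge)

study <- readRDS("scratch/study.rds")

merged <- merge_callsets(study$callsets)
qc <- filter_loci(merged)
loci <- compare_to_database(qc$kept, study$reference_db)

write_sv_vcf(loci, "results/merged_map.vcf")
report <- data.frame(
  stage = c("raw calls", "merged loci", "after QC", "novel"),
  n = c(nrow(study$callsets), nrow(merged), nrow(qc$kept),
        sum(!loci$known)))
write.table(report, "results/merge_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
removed <- as.data.frame(table(qc$removed$reason))
names(removed) <- c("reason", "n")
write.table(removed, "results/qc_removals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(loci, "scratch/merged_loci.rds")

cat(nrow(study$callsets), "calls ->", nrow(merged), "merged loci ->",
    nrow(qc$kept), "after QC;",
    sprintf("%.2f%% novel vs the reference set.\n",
            100 * mean(!loci$known)))
cat("Per-type counts after QC:\n")
print(table(qc$kept$svtype))
cat("Removal reasons:\n")
print(removed)
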