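# svforge

Population-scale structural-variant (SV) analysis for a two-breed resource
population, built as a tested R package plus a numbered analysis workflow.

Mapping studies in livestock often sequence two diverged founder breeds at
high coverage, call SVs (deletions, duplications, inversions, mobile-element
insertions) with several complementary callers, and then ask which variants
separate the breeds and which drive quantitative traits in a segregating F2
cross. svforge implements that whole chain:

1. **Union merge** of multi-caller callsets: single-linkage clustering with
   a 1,000-bp rule on *both* breakpoints for DEL/DUP/MEI, and a strict
   \>75% reciprocal-overlap merge for inversions, stratified at 100 kb so
   large inversions cannot swallow small ones. Every call lands in exactly
   one locus; single-caller calls are kept.
2. **QC**: DEL/DUP/INV kept iff QUAL > 200 and 50 bp ≤ length ≤ 1 Mb; MEI
   kept iff `PASS`; novelty labels against a reference SV set at ≥75%
   reciprocal overlap.
3. **Annotation**: one positional category per locus
   (coverage > exon > UTR > intron > upstream > downstream > intergenic,
   strand-aware 1-kb flanks) and an explicit impact-class table.
4. **Breed stratification**: per-locus Weir–Cockerham F<sub>ST</sub>
   (θ = a/(a+b+c)) between the breeds, with inclusive top-5% selection;
   genomic-relationship PCA and an allele-sharing neighbour-joining tree.
5. **Founder screen**: a locus is a candidate iff one genotype class is
   specific to one breed (>80% of the 6 purebred breed-A founders, i.e.
   ≥5) while the other breed carries the complementary classes (>50% of
   15, i.e. ≥8); candidates are genotyped in the F2 by position.
6. **Mixed-model GWAS** (EMMAX-style): REML variance components on the
   null model via the spectral decomposition of an IBS kinship matrix,
   then per-marker generalized least squares with sex + batch fixed
   effects and PC covariates, Bonferroni-corrected at 0.05/n.

A first-class **synthetic-data module** generates every input with known
ground truth — diverged founder breeds under a Balding–Nichols frequency
model, noisy per-caller callsets, a 513-offspring F2 intercross with
Haldane recombination, and phenotypes with planted causal SVs — so every
stage is validated against truth, brute-force oracles, or closed forms.
See `vignettes/sv-pipeline-methods.Rmd` for the methods and design
decisions.

## Worked example

The `analysis/` scripts run the whole study in order:

```sh
Rscript analysis/01_simulate.R     # synthetic study -> results/, scratch/
Rscript analysis/02_merge_qc.R     # merge + QC + novelty
Rscript analysis/03_popgen.R       # founder genotyping, annotation, FST, PCA, NJ
Rscript analysis/04_screen_gwas.R  # screen, F2 genotyping, mixed-model GWAS
```

On the default study (seed 1: 1,100 true loci, 15+15 founders, 513 F2),
stage 2 prints

```
55518 calls -> 2300 merged loci -> 1963 after QC; 75.65% novel vs the reference set.
```

— 55,518 raw calls from five callers collapse to 2,300 population loci
(true loci plus caller false positives, which die later at the MAF
filter), 1,963 survive QC. Stage 3 reports the founder population
genetics:

```
1376 loci with defined theta; 69 in the top 5% (threshold 0.5498).
PC1 separates the breeds: A in [-0.50, -0.43], B in [0.41, 0.54].
```

and stage 4 closes the loop on the planted truth:

```
1963 QC'd loci -> 349 screen candidates; F2 genotyping success 97.05%; 340 loci tested per trait.
body_length:    h2=0.33; 1 significant loci (Bonferroni p < 1.47e-04); top hit SV_01125 at chr5:4230585 (p = 6.66e-12)
carcass_length: h2=0.37; 1 significant loci (Bonferroni p < 1.47e-04); top hit SV_00774 at chr3:9076529 (p = 4.53e-12)
Planted causal SV is the top association: body_length TRUE; carcass_length TRUE
```

Both planted causal deletions (each 15% of trait variance) are recovered
as the top — and only Bonferroni-significant — association of their
trait, within a few bp of their true positions. Output tables (merged
map VCF, F<sub>ST</sub>, annotation, PCA coordinates, Newick tree,
per-trait GWAS tables sorted by position) land under `results/`.

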