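---
title: "Methods: population-scale SV merging, breed stratification, and mixed-model association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scale SV merging, breed stratification, and mixed-model association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

svforge implements a population-scale structural-variant (SV) analysis for
a two-breed resource population: a high-coverage founder cohort of two
diverged breeds is used to build a multi-caller SV map, the map is
quality-filtered and characterised (positional annotation, breed
F~ST~), breed-differential loci are screened in the founders, those
candidates are genotyped by position in a large F2 cohort, and each
candidate is tested for association with quantitative traits under a
mixed linear model. Every stage is exercised end-to-end on a synthetic
study with known ground truth, so the pipeline's operating
characteristics (locus recovery, genotyping success, estimator
calibration, power on planted causal SVs) are measured rather than
assumed.

## The union merge

SV callers disagree on breakpoints, and no single caller sees every
event. The pipeline therefore merges callsets by *union*: every call ends
up in exactly one population locus, and calls seen by only one caller are
retained rather than discarded. Merging is two-stage — within each sample
across callers, then across samples — and each stage is a single-linkage
transitive clustering:

* **DEL / DUP / MEI** — two calls link iff they share type, orientation
  (and element family for MEIs) and *both* breakpoint offsets satisfy
  $|\Delta s| \le d$ and $|\Delta e| \le d$ with $d = 1000$ bp. The
  both-breakpoints reading is the strictest interpretation of a
  breakpoint-distance rule; a start-only variant is available via
  `merge_config(link_mode = "start")`.
* **INV** — inversion breakpoints are reported in reverse order by some
  callers, so distance clustering is unreliable. Inversions instead link
  iff their reciprocal overlap — $\min(o/\ell_1,\, o/\ell_2)$ on 1-based
  inclusive intervals — strictly exceeds 0.75, computed separately within
  two length strata (≤ 100 kb and > 100 kb; the boundary falls in the
  lower stratum) so a large inversion cannot absorb the small ones it
  covers.

Representative breakpoints are the lower medians of the member
breakpoints, which makes the output invariant to the order in which
calls arrive; the test suite verifies order-invariance, idempotence
(merging the merged map changes nothing), conservation (member counts
sum to the input count) and exact agreement with a brute-force
all-pairs transitive closure on hundreds of random instances.

Single-linkage clustering *chains*: two same-type loci less than
$d$ apart fuse into one locus whose representative position may sit
between them. This is an inherent property of the published rule, not a
defect, and the simulator reproduces it (see "What the generator does
and does not emulate" below).

Novelty against a reference SV set uses the same reciprocal-overlap
statistic at ≥ 0.75 for span types and insertion-point distance ≤ $d$
for MEIs.

## Locus and genotype QC

Quality thresholds are *strict* inequalities throughout, with boundary
cases pinned by tests: DEL/DUP/INV loci are kept iff QUAL > 200 (locus
QUAL is the maximum over member calls — a union merge keeps the best
evidence) and 50 bp ≤ length ≤ 1 Mb; MEI loci are kept iff their filter
token is `PASS`. The genotype matrix is filtered in a fixed order:
samples with call rate ≤ 90% first, then loci with call rate ≤ 90%
(computed over the surviving samples), then loci with minor-allele
frequency ≤ 5% (computed over non-missing dosages). Computing MAF after
the call-rate stages, on observed dosages only, matches the behaviour of
the standard genotype-QC toolkits; the order is exposed in `qc_config()`
and its monotonicity (relaxing a threshold never shrinks the kept set)
is a tested property.

## Positional annotation and impact classes

Each locus gets exactly one positional category under the precedence
*coverage > exon > UTR5/UTR3 > intron > upstream > downstream >
intergenic*. DEL/DUP are annotated on their full span, inversions on
their two breakpoints only (the inverted interior is neither gained nor
lost), MEIs on the insertion point; "coverage" marks a span that
contains at least one entire gene, and the 1-kb upstream/downstream
flanks are strand-aware. The impact classes (HIGH / MODERATE / LOW /
MODIFIER) come from an explicit rule table — exon or coverage is HIGH,
UTRs are MODERATE for copy-changing types and LOW otherwise, everything
else is MODIFIER. A production annotator's impact rules are versioned,
codon-aware and far richer; this table is deliberately simple and
documented, and no claim is made that its HIGH/MODERATE proportions
reproduce any specific annotator's output. What *is* tested is the
category machinery itself: precedence totality, strand handling, and
recovery of the simulator's known placement distribution at n = 5,000.

## Weir–Cockerham F~ST~ and stratified loci

Between-breed differentiation is the per-locus Weir & Cockerham (1984)
estimator for two populations: variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$
(within individuals), with $\theta = a/(a+b+c)$. Missing genotypes are
excluded per locus per group; negative estimates are retained; a locus
is undefined when monomorphic ($a+b+c = 0$) or when a group has fewer
than two genotypes. The implementation is vectorised and cross-checked
against an independent scalar evaluation of the component formulas to
1e-10 on 10,000 random loci, and against the analytic fixation case
($\theta = 1$ at opposite fixation).

"Top 5%" selection takes every locus with $\theta$ at or above the
$\lceil qn \rceil$-th largest defined value — ties at the threshold all
enter, so the selection is a floor, not an exact count.

Population structure uses a genomic-relationship PCA (dosages centred
by $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$, mean-imputed for
missing values, monomorphic loci skipped) and a neighbour-joining tree
on allele-sharing distances $1 - \overline{(1 - |d_i - d_j|/2)}$.
F~ST~ and the founder screen never impute: frequency estimators are
computed on observed genotypes only.

## The founder screen

A locus is a breed-differential candidate iff some genotype class $g$
and some assignment of ($g$ → breed X, the other two classes jointly →
breed Y) satisfies both conditions: the count of $g$ among X's founders
strictly exceeds $f_X n_X$ and the count of the complement classes
among Y's founders strictly exceeds $f_Y n_Y$, with defaults $f_A =
0.8$ over the 6 purebred breed-A founders and $f_B = 0.5$ over the 15
breed-B founders — so the minimal passing counts are 5 of 6 and 8
of 15. Both breed directions are tested. The thresholds use *nominal*
breed sizes; a missing founder genotype therefore counts toward neither
the numerator nor a reduced denominator, which makes the screen
conservative under genotyping dropout. The screen's symmetry under
breed relabelling and its monotonicity in both thresholds are tested
properties. The complement condition is applied to the two remaining
classes *jointly*; requiring a single specific class on the second
breed would be stricter, and the joint reading is the one consistent
with the minimal-count arithmetic above.

Candidates are genotyped in offspring by position: evidence is keyed by
(chromosome, position within the merge distance, type), the nearest
evidence position wins, duplicate evidence resolves by confidence, and
the genotyping success rate is reported as non-missing cells over total
cells.

## The mixed model

Association uses the two-step approximation popularised by EMMAX: fit
$y = X\beta + u + e$, $u \sim N(0, \sigma^2_g K)$,
$e \sim N(0, \sigma^2_e I)$ once on the null model, then test each
marker by generalized least squares with the covariance fixed.

* **Kinship** is pairwise identity-by-state allele sharing (the EMMAX
  default), mean-imputed for missing dosages, with a 1e-6 ridge on the
  diagonal; a VanRaden GRM is available.
* **REML** maximises the restricted likelihood over
  $\delta = \sigma^2_e/\sigma^2_g$ using the spectral decomposition of
  $K$: a fixed grid on $\log_{10}\delta \in [-5, 5]$ (step 0.1)
  followed by local refinement with Brent's method, which is
  deterministic and cannot miss a mode between grid points wider than
  the step. Eigenvalues are clamped at zero since an IBS matrix need
  not be positive definite.
* **Per-marker tests** rotate $y$, $X$ and the dosage vector into the
  eigenbasis, weight by $1/\sqrt{S_i + \delta}$, residualise on the
  fixed effects and form a Wald t-test on the marker coefficient, with
  the residual scale re-estimated per marker. Missing dosages are
  mean-imputed per marker (the matrix is already filtered to > 90%
  call rate), and markers monomorphic after imputation return `NA`
  with a reason.
* **Significance** is Bonferroni at $\alpha / n$ with $n$ the number of
  markers actually tested for that trait.

Correctness anchors: with identity kinship the whole machinery reduces
*exactly* (to 1e-9) to ordinary least squares; on small problems it
matches a dense matrix-inversion GLS oracle; on 5,000 null markers at
n = 500 the p-values are uniform (Kolmogorov–Smirnov) and
genomic-control lambda sits in [0.9, 1.1]. Default fixed effects are
sex and slaughter batch plus the first 3 PCs of the candidate genotype
matrix; the PC count is a free choice (`n_pcs`) since reasonable
analyses use anywhere from 0 to 10.

One caveat worth stating explicitly: the tested marker participates in
the kinship matrix ("proximal contamination"). With tens of thousands
of markers spread over many chromosomes this deflates each test
negligibly; on a drastically compressed genome it does not, which
constrains how small the simulated genome may be (below).

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: 15 + 15 founders
of two breeds (4 + 15 of them parenting the cross, the first 6 of
breed A tagged purebred for the screen), 513 F2 offspring, four SV
types in a realistic mix (DEL-heavy, DUPs mostly > 5 kb, MEIs 80%
SINE), five caller profiles (four span-SV callers with complementary
sensitivities, breakpoint jitter truncated at 400 bp — below half the
merge distance, so calls of one locus always cluster — false positives
at 0.02–0.08 per Mb, ~10% quality failures, plus one MEI caller), 3%
genotyping dropout with 0.5% miscalls, and a reference database
covering 46% of true loci. Breed allele frequencies follow a
Balding–Nichols model with divergence F = 0.2, which yields a wide
F~ST~ spectrum for the stratification machinery.

Three generator choices deserve their rationale:

* **Genome shape.** The genome is 9 chromosomes × 10 Mb at 25 cM/Mb.
  Physical size is compressed ~25-fold for tractability, but two
  architectural properties of a livestock genome are preserved because
  the pipeline's behaviour depends on them: total genetic map length
  (~22.5 Morgans, so F2 linkage disequilibrium decays over a realistic
  number of independently segregating blocks) and chromosome *count*
  (so no single chromosome dominates the kinship matrix — with few long
  chromosomes, proximal contamination of the mixed model becomes an
  artifact that a real 18-autosome genome does not exhibit). Gene
  density is ~9 genes/Mb in non-overlapping slots with 3–8 exons and
  terminal UTRs.
* **Causal loci.** Planted causal SVs are deletions fixed for opposite
  alleles in the two breeds ($p_A = 1$, $p_B = 0$) — the
  breed-differential causal model the screening strategy is designed to
  find — each explaining 15% of phenotypic variance by construction,
  on top of a 30%-heritable polygenic background plus sex and batch
  effects. Causal loci are planted only at *isolated* positions (no
  same-type neighbour within 2.5 kb): single-linkage chaining would
  otherwise fuse a causal locus with a neighbour and make its identity
  unrecoverable by any position-based evaluation. The chaining
  behaviour itself is retained for non-causal loci and covered by the
  merge tests.
* **Recombination** uses Poisson crossovers under the Haldane map (no
  interference), verified against closed-form recombinant fractions.

The generator does *not* emulate read-level data (no FASTQ/BAM, no
depth model — callsets and genotype evidence are drawn directly from
truth), linkage disequilibrium beyond pedigree recombination, crossover
interference, or caller-specific error structure beyond the
sensitivity/jitter/FP/quality parameters. Passing the end-to-end tests
therefore demonstrates that the pipeline's logic is correct under a
faithful abstraction of multi-caller noise, not that any particular
real caller's error profile is handled.

All randomness flows from the single config seed, with fixed small
offsets per stage so each stage is independently reproducible; the same
seed reproduces the whole study byte for byte.

## Numerical and degenerate-case choices

* VCF is written by a deterministic in-package formatter (sorted by
  natural chromosome order, then position, then type) so identical
  inputs give byte-identical files; write→read→write is byte-stable.
  Non-numeric chromosome names fall back to lexicographic order with a
  warning.
* Lengths are recomputed from breakpoints (`END − POS + 1`, inclusive);
  a stated SVLEN that disagrees is counted and reported, and the
  breakpoints win. MEIs are point events (`END == POS`) whose length is
  the inserted element's.
* The lower median breaks representative-breakpoint ties
  deterministically; locus filter-status is `PASS` if any member
  passes, else the lexicographically first member token.
* An empty reference database labels everything novel with a warning;
  an emptied genotype matrix is an error, not a silent empty result;
  top-quantile selection with fewer than $1/q$ defined loci returns
  everything with a warning.
* REML reports a boundary flag when the optimum lands at the grid edge;
  with identity-like kinship the variance split is unidentifiable but
  the total (and hence every association statistic) is not.

Known limitations: short inversions with breakpoint jitter comparable
to their length can fragment under the strict reciprocal-overlap merge
(several merged loci for one true inversion) — these fragments genotype
identically and are redundant rather than wrong; the screen loses a
candidate when genotyping noise pushes the purebred count below 5 of 6
(~1.7% of loci at the default 3% dropout + 0.5% error), which is the
designed behaviour of a fixed-count screen under noise; and the
impact-class table is a documented simplification, not a reimplemented
annotator.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on purpose-built small instances (tens to
thousands of records). The end-to-end recovery tests keep the full
30-founder and 513-F2 cohorts — power depends on them — over a reduced
6 × 3.3 Mb genome with 270 true loci; the acceptance script runs the
full default study (9 × 10 Mb, 1,100 true loci, ~55,000 raw calls) once
plus replicate sets for heritability recovery (25 × n = 500), null
calibration (3,000 markers × n = 400) and causal recovery (10 pipeline
replicates). These sizes are the package's choice of simulation scale;
all of them, including the full pipeline, run in minutes on one core.
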