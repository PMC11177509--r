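---
title: "Methods: PMN alterations, 19q microdeletion discovery, and the single-cell MYC model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMN alterations, 19q microdeletion discovery, and the single-cell MYC model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific setting

Relative MYC overexpression is a core driver event in IDH-mutant
astrocytoma, yet a sizeable fraction of these tumours carries no visible
oncogenic alteration in the proximal MYC network (PMN) — the 14-gene module
of MYC, its paralogs (MYCN, MYCL), the E-box activators MLXIP/MLXIPL, the
inhibitors FBXW7/MGA/MNT/MXD1/MXD3/MXD4/MXI1, and the dimerization partners
MAX/MLX. `astromyc` implements, as a reusable and fully tested pipeline,
the integrative analysis used to (1) quantify PMN somatic alterations in a
bulk cohort, (2) show their count exceeds chance by a stratified Monte-Carlo
permutation test, (3) screen PMN-wild-type tumours for genes whose
alterations track elevated MYC expression, (4) reduce the recurrent 19q
loss events of those tumours to a minimal common region (MCR), (5) classify
tumours into PMN-hit / MCR-loss / WT sub-classes with their clinical and
instability correlates, and (6) validate the MCR–MYC association in
single-cell data through a per-region Poisson interaction model.

The package operates entirely on generic file formats (SEG segments,
MAF-lite variants, genes-by-samples TSV, per-cell copy-number TSV) and
ships a synthetic-data generator that plants the cohort structure the
analysis assumes, so every stage is exercised without any external
download.

## Copy-number model

Input segments carry log2 copy-ratio segment means on 1-based, fully
closed intervals (the SEG convention); all interval arithmetic in the
package keeps that convention, converting only on BED export (0-based,
half-open). A segment, or a gene-level summary, is called a somatic
copy-number alteration (SCNA) when its value exceeds +0.3 (gain) or falls
below −0.3 (loss), with *strict* inequalities: a gene summarized at exactly
0.3 is neutral. Threshold statements for this rule sometimes appear with
the sign dropped on the loss side; the ±0.3 reading is the only one that
captures both shallow/deep deletions and gains, and it is the one
implemented.

Gene-level summarization is the overlap-length-weighted mean of the
overlapping segment means, i.e. the average log-ratio over the gene's
covered bases. It is deterministic, continuous in the inputs, and the
standard choice for SNP-array segmentations. Because any-overlap ("most
extreme segment wins") summarization is also common in practice, an
`"extreme"` option (largest magnitude overlapping segment mean) is
provided; tests and defaults use the weighted mean. Genes with no overlapping segment are neutral with value 0.
Per sample and chromosome, input segments must be non-overlapping — the
caller validates this rather than resolving conflicts silently.

A sample is **PMN-hit** when any PMN gene has a non-neutral call or a
non-silent somatic variant. "Non-silent" is a configurable include-list
(missense, nonsense, nonstop, frameshift, in-frame indel, splice site,
translation start); silent/intron/UTR classes never count, matching
oncoprint semantics.

## The stratified permutation test

To ask whether the observed number of SCNA events in a gene set exceeds
chance, the observed statistic counts non-neutral (sample, gene) cells over
the samples carrying at least one SCNA in the target set. Each of B
iterations (default 10,000) then draws, without replacement, the same
number of samples from the whole cohort and the same number of genes from
the whole annotation universe, and counts SCNA events in the random block.
The empirical p-value is the add-one estimator (1 + #{null ≥ observed}) /
(B + 1): it is never exactly zero, and ties count against the alternative
(conservative). Three genuinely open design points were resolved as follows and are
exposed as arguments: gene sampling is without replacement; the gene
universe is the full annotation (an expressed-genes-only universe can be
passed by subsetting the calls); and sample resampling draws from the full
cohort — no within-stratum resampling is imposed, since the stratification
here is the conditioning of the observed statistic, not a resampling
constraint.

One property of this design is worth knowing: because the observed count
conditions on samples that have at least one target-set event while the
null does not, the test is slightly anti-conservative when target-set
alterations are rare. The calibration tests therefore check uniformity of
the p-value in a dense-alteration regime, where the conditioning is
negligible; in sparse regimes the test should be read as the field's
customary procedure, not as an exactly calibrated test.

## The PMN-WT regulator screen

Within PMN-wild-type samples, a gene is a candidate MYC regulator when it
passes two independent filters:

* **(a) correlation**: |Pearson r| > 0.2 between the gene's expression and
  MYC expression, with p < 0.05 from the t transform on n − 2 degrees of
  freedom. The magnitude condition is deliberately two-sided: inverse
  regulators are the expected discovery, but the filter itself does not
  presume a direction.
* **(b) alteration**: among genes altered (non-neutral call or non-silent
  variant) in 10%–90% of the samples (inclusive), a one-tailed Wilcoxon
  rank-sum test must show *higher* MYC expression in the altered samples at
  p < 0.05 — the direction lives here.

Commonly mutated astrocytoma genes (IDH1/2, TP53, ATRX, CDKN2A/B) and the
PMN genes themselves are excluded from both filters. No multiple-testing
correction is applied — the screen is a discovery filter, not an
inferential endpoint. The Wilcoxon policy
is exact enumeration when the smaller group has ≤ 10 observations and there
are no ties, otherwise the normal approximation with tie and continuity
corrections; tests verify the exact branch against exhaustive enumeration.
Candidates are ordered by Wilcoxon p, then |r| descending, then symbol.
Because altered-count denominators are a known source of reporting
ambiguity in this kind of screen, the output always carries both the
per-gene altered count and the sample denominator explicitly.

## Minimal common region

Per sample, loss segments (mean < −0.3) are merged (overlapping or abutting
intervals coalesced); the MCR is the set of maximal intervals covered by a
merged loss footprint of *every* sample in the screened set — a base-wise
intersection, computed with GenomicRanges and verified against a per-base
support-counting oracle. Multiple disjoint intervals are reported when
support permits; one interval is the expected case. Containment reporting
uses ≥ 1 bp overlap on closed intervals, so a gene starting one base past
an interval end is excluded. Whole-arm loss status (used to check that
total 19q loss is a different object than the focal MCR) flags an arm when
≥ 90% of its length is covered by loss segments; the fraction is a
configurable reconstruction; the literature does not pin down a single
definition of total-arm loss.

## Genomic-instability metrics

Exact definitions of these metrics vary across studies, so the package
implements standard reconstructions with every constant exposed: wGII is the per-chromosome fraction of length covered by
|mean| > 0.3 segments, averaged over chromosomes; CAER is the fraction of
arms with ≥ 50% of their length altered in a single direction; copy-number
amplitude is the maximum |segment mean|; the chromothripsis flag fires when
the position-ordered segment states of some chromosome change ≥ 10 times.
SNV and indel burdens are record counts. Group comparisons use rank tests
(Wilcoxon for two groups, Kruskal–Wallis for three) and Fisher's exact test
for the chromothripsis flag, with the direction of effect reported
alongside each p-value.

## Subclassification and bulk statistics

Tumours partition into **PMN_HIT** (any PMN alteration), **MCR_LOSS** (no
PMN alteration, but a loss segment overlapping the MCR by ≥ 1 bp), and
**WT** — exhaustive, disjoint, with PMN-hit taking precedence. Molecular
grade is the histologic grade upgraded to 4 upon CDKN2A/B homozygous
deletion. The MYC model is ordinary least squares of log expression on the
PMN-hit indicator plus *categorical* grade (grade 2 reference): adjusting
for grade carries no linearity claim, so grade enters as a factor; with a single grade present the model collapses to a
two-group comparison whose coefficient is exactly the group mean
difference. Grade trends in binary labels use the Cochran–Armitage score
test with scores (2, 3, 4) and a two-sided normal p. Survival contrasts use
the standard k-group log-rank test; the subclass-by-grade association uses
Fisher's exact test with a flagged Monte-Carlo fallback when the network
algorithm is infeasible. No multiplicity correction anywhere — each test
answers its own question.

## The single-cell Poisson interaction model

For cancer cells and each genomic region overlapping the MCR, per-cell MYC
counts are modelled as

$$\mathrm{MYC}_i \sim \mathrm{Poisson}\!\left(
  e^{\beta_0 + \beta_1\,\mathrm{CN}_i\,I(\text{with loss})
             + \beta_2\,\mathrm{CN}_i\,I(\text{without loss})}\right)$$

where CN is the region's copy-number estimate. Fitting is by iteratively
reweighted least squares with step-halving (which makes the log-likelihood
non-decreasing by construction), to a relative tolerance of 1e-8 within 100
iterations, and 95% Wald intervals come from the observed-information
covariance. The model deliberately contains no exposure/offset term, so the
coefficients read directly on raw counts; an offset can be emulated by
pre-scaling counts upstream if a library-size adjustment is wanted. Degenerate designs are flagged rather than
silently dropped — a status group whose CN column is identically zero
yields an inestimable slope (NA) and, with both slopes gone, the exact
closed form β0 = log(mean count).

The cell-level dichotomization into "with/without MCR loss" is the
least standardized step of this kind of analysis. The package classifies a
cell as carrying the loss when its *average* estimate over MCR-overlapping
regions falls below −0.05 (CopyKat-like log-ratio scale); the threshold is
an explicit argument and `cell_status_sensitivity()` sweeps it, reporting
how the classified fraction moves. Averaging over regions is what gives
the default threshold its accuracy: per-region estimates are noisy
(SD ≈ 0.05) but the across-region mean of 9 windows concentrates near the
cell's true state.

## The synthetic world

`sim_config()` fixes one stated world; its defaults are chosen once, from
the cohort the analyses target or from what a practitioner would call
realistic, and the tests never move them:

* **Cohort**: n = 236, molecular grades drawn with probabilities
  119/104/13 over 236; CDKN2A/B homozygous deletion planted exactly in the
  grade-4 samples.
* **PMN events**: each PMN gene × sample gains with probability 0.04 and
  loses with 0.03 (focal events padded 50–300 kb beyond the gene), plus a
  2% per-sample non-silent FBXW7 mutation rate — together giving roughly
  two-thirds of samples at least one PMN alteration, the hit fraction
  reported for real IDH-mutant astrocytoma cohorts. Planted event means are drawn Uniform(0.35, 1.2) /
  Uniform(−1.2, −0.35) so every planted event clears the 0.3 threshold
  with margin; near-threshold behaviour is exercised separately by unit
  tests at the exact boundary.
* **MCR deletion**: a quarter of PMN-wild-type samples carry a focal loss
  covering chr19:55005440–56958964 (the exemplar coordinates). Each side
  of the deletion extends beyond the target boundary with probability 0.5
  by Uniform(50 kb, 1 Mb) and is otherwise flush with it. The flush
  breakpoints model a recurrent deletion with shared boundaries and make
  the intersection of a handful of samples exactly equal the planted
  region; the extended sides still cover flanking genes in a fraction of
  carriers, which is what produces realistic above-threshold screen
  candidates *outside* the MCR — real screens of this design likewise
  recover more correlated genes than the MCR itself contains.
* **Expression**: per-gene baselines N(5, 1); planted events shift the
  covered genes' log expression by ±1.5 (a strong cis-dosage effect); MYC
  follows baseline + 0.25·(grade − 2) + 1.0·I(PMN-hit) + 0.6·I(MCR-loss) +
  N(0, 0.4) — effects ordered PMN > MCR > 0.
* **Background**: ~1 random focal event per sample kept clear of the PMN
  genes and the MCR neighbourhood (so planted truth stays exact); neutral
  segment means N(0, 0.05); ~8 background SNVs and ~2 indels per sample,
  doubled in PMN-hit samples so instability contrasts have signal;
  exponential PFI with hazard ratios 2 / 1.5 for PMN-hit / MCR-loss.
* **Single cells**: 2000 cells, 45% non-cancer ("Macrophages",
  "Oligodendrocyte", "Endothelial cell", 7:2:1) with neutral CN and
  status-independent Poisson(e^{β0}) counts; cancer cells carry the loss
  with probability 0.5; per-region estimates are i.i.d. N(−0.2·I(loss),
  0.05); counts are Poisson with the interaction mean evaluated at the
  cell's across-region average CN (with one region, exactly that region's
  estimate — the configuration the parameter-recovery experiments use, so
  the fitted covariate is the generative one and no errors-in-variables
  attenuation clouds the check); generative coefficients β0 = 1, β1 = −2,
  β2 = 0.

What a green test establishes: that the implementation recovers planted
structure exactly or within stated statistical tolerance under this world.
What it does not establish: robustness to tumour purity and ploidy shifts,
segmentation artefacts, library-size variation in single cells (the
generator is purely Poisson, no overdispersion), batch effects, or any
claim about the real TCGA/GEO cohorts — those require the original data.

## Numerical choices and degenerate inputs

Strict inequalities at every threshold (±0.3, |r| > 0.2, p < 0.05);
add-one permutation p-values; exact Wilcoxon only without ties and with a
small group; zero-variance genes flagged and excluded from correlation
rather than propagating NaN; empty loss lists, empty MCRs, unknown gene
symbols, cell-id mismatches, singular designs and sub-minimum group sizes
all raise early, named errors. Screen ties sort by (Wilcoxon p, |r|
descending, symbol) so output order is total and reproducible. All
randomness flows through explicit seeds; identical configurations produce
byte-identical synthetic data.

## Known limitations

No purity/ploidy correction or allele-specific copy number; no
GISTIC-style significance for the MCR itself; the permutation test's
conditioning subtlety described above; the chromothripsis flag is a
segment-oscillation heuristic, not ShatterSeek; the single-cell model
consumes CopyKat-like estimates and cell-type labels — it never infers
them; and the identity of the real screened genes and MCR genes in the
TCGA cohort cannot be reproduced without the original cohort data.
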