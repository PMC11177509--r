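# astromyc

Integrative analysis of proximal MYC network (PMN) alterations and 19q
microdeletion discovery in IDH-mutant astrocytoma, packaged as a tested,
reusable R pipeline.

## The problem

MYC overexpression drives malignancy in IDH-mutant astrocytoma, but many
tumours carry no visible alteration in the PMN — the 14-gene module of MYC,
its paralogs MYCN/MYCL, the E-box activators MLXIP/MLXIPL, the inhibitors
FBXW7/MGA/MNT/MXD1/MXD3/MXD4/MXI1, and the dimerizers MAX/MLX. This
package implements the full analysis chain used to characterize PMN
alterations in a bulk cohort and to discover, in the PMN-wild-type
remainder, a recurrent focal 19q deletion whose minimal common region (MCR)
tracks elevated MYC expression:

1. **Gene-level SCNA calling** from SEG-format segments: a gene is gained
   (lost) when its overlap-weighted mean log2 copy-ratio exceeds +0.3
   (falls below −0.3), strict inequalities.
2. **PMN-hit annotation**: any non-neutral PMN call or non-silent PMN
   mutation.
3. **Stratified Monte-Carlo permutation test** for SCNA-count enrichment:
   observed events in the altered-sample × target-gene block versus B
   random sample/gene blocks; p = (1 + #{null ≥ obs}) / (B + 1).
4. **Two-filter regulator screen** in PMN-WT samples: (a) |Pearson r| > 0.2
   with MYC at p < 0.05; (b) gene altered in 10–90% of samples with
   one-tailed Wilcoxon evidence of higher MYC in altered samples.
5. **MCR discovery**: base-wise intersection of every screened sample's
   merged loss footprint (1-based closed intervals), plus gene containment
   and arm-level loss status.
6. **Instability metrics** (SNV/indel burden, wGII, CAER, copy-number
   amplitude, chromothripsis flag) and group comparisons.
7. **Three-way subclassification** (PMN_HIT / MCR_LOSS / WT) with the MYC
   linear model adjusting for grade, Cochran–Armitage grade trend, Fisher
   exact subclass-by-grade, and k-group log-rank on progression-free
   interval.
8. **Single-cell validation**: per-region Poisson interaction model
   `E[MYC] = exp(b0 + b1·CN·I(with loss) + b2·CN·I(without loss))`
   fitted by IRLS with Wald 95% CIs, on cancer cells classified by their
   average MCR copy-number estimate.

A synthetic-data generator (`sim_config()`, `simulate_cohort()`,
`simulate_cells()`) plants this exact structure — grade mix 119/104/13,
roughly two-thirds PMN-hit, a focal chr19:55005440–56958964 deletion in a
quarter of PMN-WT samples, MYC effects ordered PMN > MCR > 0, Poisson
single-cell counts — so the whole pipeline runs and is tested without any
external data. See `vignettes/astromyc-methods.Rmd` for the model details
and every default's rationale.

## Worked example

```r
library(astromyc)

cfg <- sim_config(n_samples = 60, seed = 42)
sim <- simulate_cohort(cfg)

calls <- call_gene_scna(sim$segments, sim$annotation, threshold = 0.3)
hits  <- pmn_hit_status(calls, sim$variants)
sum(hits$pmn_hit)                      # 39 of 60 samples are PMN-hit

stratified_permutation_test(calls, pmn_genes(), B = 10000, seed = 42)
#> Stratified permutation test: 52 SCNA events in 14 genes across 38 samples
#> null mean 7.19 over 10000 iterations; p = 9.999e-05

mcr <- find_mcr(loss_segments(sim$segments),
                sim$truth$sample_id[sim$truth$mcr_loss],
                annotation = sim$annotation)
mcr
#> MCR over 7 samples: 1 interval(s)
#>   chr19:55005440-56958964
#> genes contained: G0388, G0389, G0390, G0391, G0392, G0393, G0394

sub <- assign_subclass(hits, sim$segments, mcr)
table(sub$subclass)
#>  PMN_HIT MCR_LOSS       WT
#>       39        7       14

myc_linear_model(sim$expression, hits, sim$clinical)
#> MYC ~ PMN-hit + grade (n = 60 )
#> PMN-hit coefficient: 0.7954 (SE 0.138 ), p = 3.57e-07

sc     <- simulate_cells(cfg, tile_regions("chr19", 55005440, 56958964, 9))
cancer <- select_cancer_cells(sc$cells)
status <- classify_cell_mcr_status(cancer, mcr$intervals)
fit_poisson_interaction(cancer, status, 5)
#> Poisson interaction fit, chr19:55873673-56090731 (n = 1080 cells)
#>   beta0 = 1.0320  beta1 = -1.7728 [-2.0759, -1.4697]  beta2 = -0.5604 [-1.5710, 0.4501]
#>   converged: TRUE  loglik: -2169.89
```

Reading the numbers: the permutation p (the smallest attainable at
B = 10,000, because every null draw fell below the 52 observed events) says
the planted PMN SCNA load cannot be a sampling artefact; the recovered MCR
is exactly the planted interval and contains the 7 synthetic genes tiled
into it; the linear model recovers MYC elevation in PMN-hit tumours
independent of grade; and in single cells the fitted β1 < 0 with a CI
excluding 0 reproduces the signature of interest — in cells carrying the
MCR loss, lower copy-number estimates go with *higher* MYC counts — while
β2 (cells without loss) is compatible with 0. The generative truth here
was β0 = 1, β1 = −2, β2 = 0.

## Command-line interface

A dispatcher script is installed at
`system.file("cli", "astromyc", package = "astromyc")`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "astromyc", package = "astromyc"))')
Rscript $CLI simulate   --outdir sim --n-samples 60 --seed 42
Rscript $CLI call-scna  --seg sim/segments.seg --genes sim/genes.tsv --threshold 0.3 --out calls.tsv
Rscript $CLI pmn-hit    --seg sim/segments.seg --genes sim/genes.tsv --maf sim/variants.maf.tsv --out hits.tsv
Rscript $CLI perm-test  --calls calls.tsv --gene-set pmn.txt --iterations 10000 --seed 1 --out perm.json
Rscript $CLI mcr        --seg sim/segments.seg --samples mcr_samples.txt --genes sim/genes.tsv --out-json mcr.json
Rscript $CLI screen     --expr sim/expression.tsv --calls calls.tsv --variants sim/variants.maf.tsv --pmn-wt-samples wt.txt --out screen.tsv
Rscript $CLI instability --seg sim/segments.seg --maf sim/variants.maf.tsv --out metrics.tsv
Rscript $CLI classify   --seg sim/segments.seg --genes sim/genes.tsv --maf sim/variants.maf.tsv \
                        --expr sim/expression.tsv --clinical sim/clinical.tsv --mcr-json mcr.json --out-prefix cls
Rscript $CLI sc-assoc   --cn-matrix sim/cell_cn.tsv --cell-meta sim/cell_meta.tsv --mcr-json mcr.json --out sc.json
```

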