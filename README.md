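# proteopipe

Proteogenomic tumor/normal cohort analysis as one tested, reusable R
pipeline. The package is aimed at computational biologists who need the
bespoke machinery of large isobaric-label (TMT) tumor studies without
re-deriving it: reporter-ion quantification and normalization,
purity-aware differential expression, permutation empirical-FDR cis/trans
association, allele-specific copy-number inference with genome-instability
calling, consensus subtype discovery with a transfer classifier,
cross-omic correlation/alignment QC, and kinase–substrate phosphosite
ranking. A synthetic-cohort generator with recorded ground truth makes
every stage verifiable end to end without any external or controlled-access
data.

## The core models

**Quantification.** PSM reporter intensities become log2 ratios to a
pooled reference channel, are IQR-trimmed and median-summarized per entry,
then MAD-normalized per sample:

    R^C_ij = R_ij − M_i,      R^N_ij = (R^C_ij / MAD_i) · MAD_0 + M_0,
    A_ij   = R^N_ij + log2(REF_i),

where `REF_i` is the weighted top-3 peptide-ion MS1 reference intensity.
After normalization every sample's median and MAD equal `M_0` and `MAD_0`
exactly.

**Purity deconvolution.** Observed abundance is a fixed-purity mixture
`X_ij ~ N(π_i μY_j + (1−π_i) μZ_j, π_i²σY² + (1−π_i)²σZ²)`; tumor-vs-NAT
differences of the pure component `μY` are tested against a 200-permutation
empirical-FDR null at 10% with a 2-fold-equivalent effect requirement.

**Copy number.** For a segment with total/minor copies (C, K) at purity p,
`E[lr] = log2((pC + 2(1−p))/2)` (centered by ploidy) and
`E[baf] = (pK + (1−p))/(pC + 2(1−p))`; purity/ploidy are found by grid
search over a bin-weighted Gaussian likelihood with a parsimony tie-break,
arm events use length-weighted mean (C − 2) with ±0.5 thresholds, and PGA
(length fraction not in state (2,1)) ≥ 0.85 marks genome instability.

**Association.** Traits are rank-inverse-normal transformed and regressed
on genomic features plus covariates; significance cut-offs are the
smallest |t| with permutation empirical FDR < 10% (trans) or an evidence
score threshold at eFDR < 5% after directional biology filters (cis).
Pathways are scored by rank-sum tests on `T = −sign(β)·log p` with
`±log10(adjusted p)` scores.

## Worked example

```r
library(proteopipe)

cfg    <- cohort_config(n_tumor = 30, n_nat = 30, n_genes = 200, seed = 42)
cohort <- generate_cohort(cfg)

## TMT quantification: PSM table -> normalized gene abundance
quant <- tmt_quantify(cohort$psm, cohort$design, level = "gene")
#> abundance matrix: 199 genes x 60 samples
#> M0 = 0.0031, MAD0 = 0.2289

## differential expression, bulk and purity-deconvolved
tumor <- cohort$abundance$protein[, cohort$clinical$tissue == "tumor"]
nat   <- cohort$abundance$protein[, cohort$clinical$tissue == "nat"]
wilcoxon_diff(tumor, nat, fc_threshold = 2, fdr_threshold = 0.05)
#> bulk Wilcoxon calls: 15 of 200 genes
pur <- cohort$truth$purity
pd  <- purity_diff(tumor, nat, pur[colnames(tumor)], pur[colnames(nat)],
                   n_perm = 200, seed = 7)
#> purity-deconvolved calls: 19 genes (all 19 are planted effect genes)

## copy number: binned LR/BAF -> purity, states, arm events, PGA
tracks <- generate_segments(cfg, cohort$truth, samples = "T004")
fit <- fit_purity_ploidy(joint_segment(gc_correct(tracks$T004)))
#> T004: purity 0.67 (truth 0.67), ploidy 2.00, PGA 0.333
arm_events(fit$states, synthetic_arms())
#>     arm score call loh_prop   loh
#>   chr1p    -1 loss        1  TRUE
#>   chr1q     1 gain        0 FALSE
```

The numbers mean: one gene dropped out of a whole plex (199 of 200
quantified); normalization centered samples at M0 ≈ 0 on the log2-ratio
scale; the purity-deconvolved test recovers planted pure-tumor effects
that stromal dilution hides from the bulk test; and the copy-number stack
recovers the planted purity to the grid step and calls the planted arm
loss (with LOH) and gain exactly.

A command-line front end for the main stages is installed at
`system.file("cli", "proteopipe.R", package = "proteopipe")`.

## Documentation

`vignettes/proteopipe-methods.Rmd` describes the models, parameter
defaults, numerical choices, the synthetic cohort's stated world, and
known limitations.
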