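---
title: "proteopipe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proteopipe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

proteopipe re-implements, as one tested pipeline, the computational core of
a proteogenomic tumor/normal cohort analysis: isobaric-label (TMT)
quantification, purity-aware differential expression, permutation-FDR
cis/trans association, allele-specific copy-number inference, consensus
subtype discovery with a transfer classifier, cross-omic QC, and
kinase–substrate ranking. Every stage is driven by a synthetic-cohort
generator with recorded ground truth, so each method has a
parameter-recovery test rather than a fixture file. This vignette explains
the models, the tunable parameters, and the numerical choices made where
the procedures left room for interpretation.

## TMT quantification

A PSM (peptide-spectrum match) table is filtered by sequential quality
rules: no isobaric label; missing reference-channel quantification;
precursor-ion purity below 50%; summed reporter intensity below the 5th
percentile of the plex's PSM file (2.5th for phosphopeptide-enriched data);
non-phosphopeptides in phospho mode; contaminants; and, among redundant
PSMs of one peptide ion in a run, all but the highest summed-intensity PSM.
Two choices are ours: quartiles use linear interpolation between order
statistics (R's default, type 7), and the intensity-percentile floor is
attached to the filtered table and reused on re-filtering so the filter is
idempotent — recomputing the percentile on survivors would shave another
percentile with every application.

Reporter intensities become log2 ratios to the pooled reference channel.
Per entry (gene, protein, peptide or site) and sample, ratios outside
Q1 − 1.5·IQR and Q3 + 1.5·IQR are discarded and the median of the
survivors is the entry's ratio. Normalization removes per-sample location
and scale: with `M_i` the sample median, `M_0` the global median of the
`M_i`, `MAD_i` the median absolute deviation of the centered ratios, and
`MAD_0` their global median,

    R^N_ij = (R_ij − M_i) / MAD_i × MAD_0 + M_0.

After normalization every column has median `M_0` and MAD `MAD_0` exactly;
this is an algebraic identity the tests check to 1e-9. Ratios return to
the absolute scale through a per-entry reference intensity: the weighted
sum of the MS1 intensities of the entry's top-three peptide ions per plex
(weights: reference reporter share of the summed reporter intensity),
averaged over plexes with missing plexes imputed by the global minimum.
The final abundance is `A_ij = R^N_ij + log2(REF_i)`.

## Purity-aware differential expression

Bulk comparison uses a two-sided Wilcoxon rank-sum test per feature, BH
adjustment, and calls significance at fold change ≥ 2 and FDR < 0.05. The
deconvolved analysis models the observed abundance of feature j in sample
i as a purity-weighted mixture of a pure-tissue and a stroma/immune
component,

    X_ij ~ Normal(π_i μY_j + (1 − π_i) μZ_j,
                  π_i² σY_j² + (1 − π_i)² σZ_j²),

with purity π fixed per sample (supplied externally, as in the source
procedure). Features are z-scored across the joint tumor + NAT cohort
before fitting. The estimator is ours to choose: we alternate weighted
least squares for (μY, μZ) with Fisher-scoring updates of the log
variances, vectorized across features because all features share the
purity design. Twenty-five iterations leave the mean estimates within
about 1e-5 of full convergence; the same iteration cap is used for
observed and permuted fits so the permutation null stays exchangeable.
Significance of Δ_j = μY_tumor − μY_nat comes from 200 label-shuffling
permutations and a Storey-style empirical FDR with π0 = 1: at threshold t,
eFDR(t) is the mean permuted exceedance count over the observed count,
monotonized to be non-increasing in t; the smallest t with eFDR < 10% is
used, and calls additionally require the z-scale equivalent of a 2-fold
change (log2 2 divided by the feature's pre-z-scoring sd).

Degenerate designs are handled explicitly: purity identically 1 collapses
the mixture (μY is the sample mean; μZ is flagged unidentifiable), and any
other constant-purity design is an error.

## Cis/trans association with empirical FDR

Each molecular trait is rank-inverse-normal transformed and regressed on a
genomic feature plus covariates (age, gender, embedding, ischemic time,
purity in the synthetic cohort). The trans procedure permutes the sample
labels of the outcomes — jointly across traits, preserving trait–trait
correlation — 100 times, and selects the smallest |t| cut-off whose
averaged empirical FDR is below 10%. The eFDR curve is monotonized
(running minimum from large thresholds down), which both matches the
"smallest T" reading and guarantees the relax-the-threshold monotonicity
property the tests assert.

The cis analysis fits, per gene, three regressions (mRNA, protein,
phospho on CNV log-ratio + CNV BAF + methylation + covariates, with a
mutation term where the mutation rate exceeds 5%). The cited tool's
Bayesian configuration posterior is out of scope; its procedure is kept
with a substituted evidence score, −log10 p per (variation, trait).
Directional biology filters are applied before significance: CNV (lr)
effects must be positive on all traits, methylation negative on all
traits, CNV (baf) and mutation consistent in sign. Thresholds on the
evidence score are calibrated per (variation, trait) by the same
permutation eFDR at 5%, and each gene/variation is labeled with one of the
eight trait-configuration patterns. Explained variance is reported as
ΔR² = R²(full) − R²(without the variation), clipped at zero.

Pathway scoring uses T_j = −sign(β_j)·log(p_j), a two-sided rank-sum test
of in-set versus out-of-set T values, BH across sets, and the signed score
±log10(adjusted p). The clinical module fits one joint regression per gene
on all clinical covariates and tabulates genes below adjusted p 0.10 per
covariate.

## Copy number

Binned log coverage-ratio (LR) tracks are GC-corrected by LOESS (span 0.5,
degree 2) fitted on mappable bins with GC in \[0.3, 0.7\] and applied to
all bins; because LOESS is quadratic in the fitting set, fitting uses an
evenly GC-spaced subsample of at most 5,000 bins and the curve is
interpolated from a 201-point grid — the trend estimate is unchanged at
test tolerances. LR and mirrored BAF (folded to \[0.5, 1\]; phasing is
unobserved) are segmented independently by permutation-tested binary
segmentation (significance alpha = 0.01, variance from a 2.5%-trimmed
sample), the breakpoints pooled, and adjacent segments merged shortest
first while their LR means differ by < 0.1 and BAF means by < 0.05 (both
exposed as parameters; the source describes the pruning only
qualitatively).

Purity p and ploidy τ are inferred by grid search (p: 0.05–1.00 step 0.01;
τ: 1.0–6.0 step 0.05). For a segment in state (C, K),

    E[lr]  = log2(p·C + 2(1−p)) − log2(p·τ + 2(1−p)),
    E[baf] = (p·K + (1−p)) / (p·C + 2(1−p)),

and each candidate assigns every segment the (C, K) maximizing a
bin-weighted Gaussian likelihood. Two numerical points matter. First, the
model compares the *mirrored* BAF mean against the folded-normal
expectation of Normal(E\[baf\], sd) folded at 0.5 — the folding bias
(+sd·√(2/π) for balanced states) otherwise lets spurious low-purity
solutions absorb it. Second, the likelihood is exactly degenerate under
solution families such as C′ = 2C at p′ = p/(2−p), or C′ = C − 2,
K′ = K − 1 whenever every K ≥ 1; near-tied solutions (within a window that
scales with total bin weight, absorbing grid-discretization wobble) are
therefore ranked by parsimony — ploidy closest to 2, then highest purity —
so a whole-genome-duplication call requires at least one segment that no
low-ploidy solution can explain (e.g. an odd copy number plus a K = 0
anchor). Large homozygous deletions (> 10 Mb at C = 0) are rejected
outright, and an all-neutral genome is flagged purity-unidentifiable
rather than assigned an arbitrary grid point.

Arm events use the length-weighted mean of (C − 2): gain above +0.5, loss
below −0.5; the LOH proportion is the length fraction with K = 0
(including copy-neutral LOH) and LOH is called above 0.5, optionally only
on loss arms. The proportion of genome altered (PGA) is the length
fraction differing from (2, 1); samples at or above 0.85 are classified
genome-unstable.

## Subtypes, immune groups, transfer classification

Consensus clustering subsamples 80% of samples without replacement,
clusters each subset (PAM with deterministic build/swap, or
complete-linkage hierarchical clustering on Euclidean distances), and
forms the consensus matrix of co-clustering frequencies among co-sampled
pairs; final labels cut a complete-linkage tree of 1 − consensus (the
extraction method is not specified by the source; complete linkage is our
fixed choice). The methylation CIMP classifier clusters samples on a
marker-probe panel (Euclidean, complete, no scaling) into two groups and
labels the higher-mean-beta cluster CIMP+ — in synthetic data the panel's
beta height is its defining property; the source labeled clusters via
late-stage enrichment, which a null cohort cannot supply.

Per-group differential signals use the no-intercept indicator regression
X_ij = Σ_k β_kj 1(i ∈ group k) + ε: β is exactly the group mean of the
z-scored feature, tested with the pooled residual variance and BH-adjusted
per group. Signature activity is the combined z-score, Σ z / √(set size).
One-vs-rest markers require BH FDR < 10% and log fold change strictly
greater than 1.

The transfer classifier scores an external sample k against each training
group i twice: Z_ik, the Spearman correlation of the group's weight vector
with the sample's panel expression, and Q_ik, the average of the
per-training-sample Spearman correlations S_sk over the group. "Normalized
to the unit interval by subtracting the lowest value and dividing by the
maximum" is ambiguous; we subtract the minimum and divide the shifted
values by their own maximum so the range is exactly \[0, 1\], applying it
to the whole Z matrix and, for S, within each training group before
averaging (the quoted order). The final score is X = (Z + Q)/2 and
assignment is argmax with ties broken by group order. Weight vectors are
accepted as input; `train_transfer_model()` provides a fallback centroid
trainer that is not part of the source procedure.

## Cross-omic QC and phospho

Gene-wise and sample-wise Spearman correlations between mRNA and protein
use complete-case genes; sample-wise correlations are split into
high/middle/low tertiles and modeled on covariates with and without
purity adjustment. The alignment check takes the 500 genes most correlated
across the two data types under the nominal pairing, rank-transforms each
gene, and scores every sample pair by the Spearman correlation of rank
profiles; a sample is flagged when its self-score sits less than 2 sd
above its cross-pair distribution. One caveat the tests encode: under a
*globally* mismatched pairing, top-gene selection itself inflates all
self-scores (selection bias), so the check is a swap detector, not a test
of global independence.

Kinase–substrate ranking matches annotation (gene, site) pairs to the
site-level matrix exactly, drops and counts the rest, computes per
tumor/NAT pair the log2 fold change, ranks events with fold change > 1.5
within each tumor, and summarizes events that rank first in a majority of
tumors. Grade strata are compared per site by a two-sided Mann–Whitney
test (p < 0.05). The module-correlation test compares within-module
pairwise correlations between data types with a one-sided two-sample
t-test.

## The synthetic cohort

`generate_cohort()` emits a full cohort — PSM table with plex design,
protein/mRNA/phospho matrices, methylation betas, gene-level CNV tracks,
cell scores, clinical covariates — plus the ground truth that produced it.
Its stated world: TMT 10-plex with one pooled reference channel per plex
(pooling all samples; the source pooled ~90% but does not list the
membership); tumors mixed from pure-tumor and pure-stroma profiles with
purity Uniform(0.4, 0.9); lognormal MS1 intensities and multiplicative
reporter noise (log2 sd 0.1); per-plex feature dropout (2%) mirroring TMT
missingness; planted PSM quality failures at 2–3%; whole-arm integer copy
states on a six-arm, 600 Mb genome driving LR/BAF and cis dosage; planted
arm-level trans effects (−0.8 per carrier on a remote gene set), cis
methylation coupling, four immune archetypes at separation 3 in cell-score
space, and 2-fold kinase–substrate fold changes. Where the sources state
no value we fixed one a practitioner would call realistic and did not
revisit it. The generator does not emulate batch effects, retention-time
structure, isotopic impurity, subclonal copy number, or correlated
clinical confounding — a green test establishes correctness of the
computations under the stated model, not robustness to everything real
data does.

## Known limitations

The segmentation is binary rather than fully circular; the cis evidence
score is a per-trait −log10 p, not the cited tool's joint posterior; PAM
subsampling makes consensus matrices exchangeable but not identical to the
cited package's internals; and the purity-mixture fitter assumes Gaussian
components on the z-scale. All empirical claims above are computed by the
test suite (`tests/testthat/`, in particular `test-acceptance.R`) — the
vignette states nothing the tests do not measure.
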