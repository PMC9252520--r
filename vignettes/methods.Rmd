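---
title: "Individual disease signatures and drug-reversal scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual disease signatures and drug-reversal scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revsig)
```

`revsig` predicts drugs for an individual tumor by building a
patient-specific disease signature and ranking a perturbation library by how
strongly each drug's induced expression changes reverse it. This vignette
explains the model behind each stage, the tunable parameters and their
defaults, the numerical choices, and what the synthetic test bed does and
does not establish.

## Why an *individual* signature

A differential-expression contrast needs replicates, but a single patient
has none. The package's premise is that the cohort samples most similar to
the patient's transcriptome can stand in as biological replicates: the
patient is assigned to a cohort subtype, and the N subtype samples with the
highest Spearman correlation to the patient (the *subgroup*) are contrasted
against matched normals. N defaults to 5, a middle ground between the power
of more replicates and the dilution of patient specificity as less-similar
samples enter; 3 and 10 are the other sizes we consider reasonable, and N is
a plain argument everywhere.

## Consensus NMF subtyping

The cohort is clustered on its 1,500 most variant genes (log2 scale;
variance ties break lexicographically by symbol so the panel is
deterministic). Counts are transformed as log2(CPM + 1); the pseudocount
keeps zero counts finite and is standard practice.

Non-negative matrix factorization with multiplicative updates minimizes the
Frobenius reconstruction error; samples are assigned to their argmax
metagene. Because NMF is initialization-sensitive, we run it 30 times per
candidate rank k from random starts and record how often each sample pair
co-clusters — the consensus matrix, whose entries we assert to lie in [0, 1]
with unit diagonal and symmetry. Average-linkage hierarchical clustering of
1 − consensus gives the final labels. The rank is chosen by the cophenetic
correlation of that dissimilarity (how tree-like, i.e. how stable, the
consensus is), with the average silhouette width breaking ties; both metrics
are reported for every k so the choice is inspectable. Defaults: k from 2
to 6, 30 runs, at most 500 iterations, relative objective tolerance 1e-5.
All runs draw from one user-supplied seed, so results are bit-reproducible.

A constant dissimilarity (perfectly stable consensus at k) makes the
cophenetic correlation 0/0; we define it as 1 there, since perfect stability
is the limit the statistic rewards.

## Subgroup, controls, and purification

Similarity to a subtype is the *median* Spearman rho over its samples —
median, not mean, so a few outlying samples cannot capture the patient.
Spearman makes the assignment invariant to any monotone transform of the
patient's values, which matters when patient and cohort come from different
processing. Controls are the N normal-pool samples with the highest median
Spearman correlation to the subgroup on the same gene panel: a
correlation-based stand-in for learned-feature matching, chosen because it
is deterministic and dependency-free. Batch offsets between sources can be
removed beforehand with `center_batches()`, a per-gene batch mean-centering
on the log2 scale (equivalent to regressing out a single batch covariate).

Bulk tumors mix cancer and non-cancer cells. Stromal and immune content is
scored per sample by ssGSEA: genes are ranked by descending expression and a
running sum adds weight `pos^alpha` (alpha = 0.25; alpha = 0 is the
unweighted KS walk) at in-set genes and subtracts 1/(n−t) elsewhere; the
score integrates the running sum over all positions (integrated enrichment
score rather than maximum deviation — the integrated form is less sensitive
to a single extreme run). The score depends only on within-sample ranks. A
subgroup whose mean stromal+immune score exceeds the cohort's 75th
percentile (q configurable) is flagged high-infiltration.

Flagged subgroups are purified by per-sample deconvolution: on the linear
scale, tumor ≈ Σ w_j · normal_j + cancer, fitted by non-negative least
squares with a non-negative intercept; alpha = Σ w_j is the contamination
fraction, capped at 0.99 by rescaling the weights (an exact
inequality-constrained fit changes alpha-hat by less than the method's own
error at this scale). The purified profile is
log2(1 + max(0, (x − Σ w_j n_j)/(1 − alpha))); the clipping guarantees
non-negative linear expression. This is a deliberate simplification of
Bayesian deconvolution models: it captures the convex-combination structure
but attributes *any* tumor component expressible as a non-negative
combination of the normals to contamination, so alpha is an upper-leaning
estimate when cancer and normal profiles are strongly collinear. Our
recovery tests therefore use cancer profiles drawn independently of the
normals; with correlated profiles, absolute alpha accuracy degrades even
though purified profiles still improve correlation with the true cancer
component. Recovery is evaluated on the linear scale — the scale the
mixture model is defined and fitted on; on the log scale, which amplifies
the low-expression genes the subtraction estimates worst, the improvement
is present but not uniform across mixtures. We also tried
inverse-magnitude-weighted NNLS and a log-scale nonlinear refinement of
the fit; both *worsened* alpha recovery on the same mixtures and were
rejected, so the plain linear-scale NNLS stands.

## The signature and its thresholds

Differential expression is a per-gene Welch t-test on log2(CPM + 1) with
Benjamini–Hochberg correction; log2FC is the difference of group means on
the log scale. One built-in method keeps the dependency surface small; the
DE step is isolated behind `differential_expression()` so count-model
alternatives can be swapped in. Defaults for the signature: FDR < 0.05,
|log2FC| ≥ 1, and at most 100 genes per direction kept by descending
|log2FC|. The cap matters: the KS statistics below lose resolution when a
set covers a large fraction of the ranked universe, and 100 + 100 genes is
in the range where rank-based connectivity scoring behaves well. All three
thresholds are arguments; relaxing them can only grow the signature
(monotonicity is tested).

## KS connectivity, RGES, sRGES

For a gene set with sorted ranks V(1) < … < V(t) in an n-gene ranking, the
two one-sided Kolmogorov–Smirnov statistics are

- a = max_j ( j/t − V(j)/n ) — enrichment toward the top,
- b = max_j ( V(j)/n − (j−1)/t ) — enrichment toward the bottom,

and the signed enrichment score is a if a > b, −b if b > a, and +a on an
exact tie (ties are a measure-zero curiosity on real data but the rule must
be fixed; resolving toward a keeps the worked 1-gene-in-2 example at +0.5).
Signature genes absent from a record's universe are dropped before positions
are computed; a set with fewer than `min_overlap = 5` genes present is
rejected for that record — below that, the statistic is noise.

RGES combines the up- and down-set scores: es_up − es_down when their signs
oppose (drug moves the two halves coherently), 0 when they agree (both
halves dragged the same way — neither mimicry nor reversal). Positive RGES
means the treatment mimics the disease pattern, negative means it reverses
it.

Perturbation assays respond more strongly at high dose and long duration, so
raw RGES is not comparable across conditions. Treatments are binned into
dose (< 10 µM vs ≥ 10 µM) × time (< 24 h vs ≥ 24 h) classes with the
10 µM / 24 h standard condition as reference. Each non-reference class gets
an additive offset: the mean, over drugs observed in both that class and
the reference, of (mean reference RGES − mean class RGES) — a paired
estimator that self-calibrates on whatever library is supplied and degrades
to zero offsets when no pairs exist. A drug's sRGES is the unweighted mean
of its standardized RGES values across treatments; we deliberately do not
weight by cell-line similarity (weight ≡ 1), keeping the summary a plain
linear combination. A single reference-condition treatment therefore has
sRGES equal to its RGES exactly.

## In-silico validation

Predictions are checked against dose-response AUCs on the cell line most
correlated with the patient (Spearman on the 1,500 most variant genes of
the cell-line panel; ties to the smallest identifier): (a) Pearson
correlation between sRGES and AUC over shared drugs — positive r means
predicted reversers really are the sensitive drugs; (b) Welch t-test of
sRGES between effective and ineffective drugs, where effective means
AUC ≤ mean − 0.5·SD on that line (sample SD; the boundary is inclusive, and
a zero-SD line labels every drug effective); (c) a permutation null: 100
random same-size subgroups drawn from the patient's subtype, the whole
signature-and-scoring pipeline re-run for each, and the observed correlation
compared to the null sample by a one-sample t-test (the null is the sample,
the observed r the hypothesized mean). Drawing from the subtype rather than
the whole cohort is the stricter null — it breaks only the *within-subtype*
patient-subgroup link; a flag widens it to the cohort. Correlations of
constant vectors are defined as 0 with a warning rather than an error, so
one degenerate replicate cannot abort a null run. Responder discrimination
uses the Mann–Whitney identity for the ROC AUC with lower scores ranked
more responder-like; it equals the trapezoidal ROC integral exactly, which
the tests verify exhaustively on small instances.

## The synthetic test bed

`scenario_config()` fixes the study conditions: 2,000 genes, 3 subtypes of
30 samples, 30 normals, between-subtype log2 shift 2, within-sample log2
noise SD 0.5, a planted 100-up/100-down signature at log2FC 2 (4-fold), 20
drugs with 5 reversers on a {1, 10} µM × {6, 24} h grid, AUCs linearly
linked to planted reversal strength (slope 0.5, noise SD 0.05), and 40
labelled patients. Each tumor expresses the signature with a continuous
*activity* drawn from U(0.2, 1) (the held-out patient has activity 1):
disease-signature strength varies across a real cohort, and this
heterogeneity is exactly what the permutation-null validation probes — a
subgroup picked for similarity to the patient carries the signature more
strongly than a random subtype subgroup, so the observed correlation can
exceed the null. A cohort-wide uniform signature would make the null
statistically indistinguishable from the observed value, and a *binary*
carrier status would itself form a discrete expression cluster that
consensus NMF picks up, again collapsing the within-subtype null; the
continuous gradient avoids both degeneracies. Tests whose conditions call
for a uniformly planted signature (subtype recovery, signature recovery)
pin the activity range to {1}. Gene baselines are normal on the log2 scale with mean 7
(≈ 128 counts) and SD 1.5 — a realistic depth for a 2,000-gene panel at
which Poisson noise does not drown a 4-fold change in a 5-vs-5 contrast.
Counts are Poisson around the linear-scale mean, so log-scale noise acts on
the mean and planted effects read directly as log2FC; we accept the
under-dispersion relative to negative-binomial RNA-seq as the price of a
dependency-light generator. Reverser rankings shift a standard-normal gene
score by 3 × strength, with strength halved at low dose and halved again at
short duration — the decay the reward model is meant to undo — and each
reverser carries a potency in (0.6, 1] so reversal strengths differ across
drugs. Response labels threshold a noisy per-patient score (noise SD 1.3,
set so the mean ROC AUC across seeds sits mid-band near 0.78; individual
seeds at 40 patients scatter around it).

What passing these tests shows: every stage recovers what was planted under
its stated conditions, end to end, from counts to validated drug ranks.
What it does not show: robustness to negative-binomial dispersion, batch
structure, partially overlapping gene universes, non-additive contamination,
or drugs with heterogeneous effects across cell lines — none of which the
generator emulates. Subtype recovery is tested at noise SD 1 (its stated,
harder condition); signature recovery is tested on a homogeneous cohort,
because in a subtyped cohort the subgroup's own subtype-marker genes are
genuinely differential against normals and compete with the planted
signature for the capped 100 slots — a structural property of capped
signatures, not a defect of the DE step.

## Numerical and degenerate-input choices

- Variance and correlation ties break deterministically (gene symbol or
  sample id order), so every selection is reproducible without a seed.
- Zero-variance genes in the t-test get p = 1 when means are equal
  (0/0 → no evidence) rather than NaN.
- All-zero gene rows are dropped from DE with a message stating the count.
- Duplicate gene rows collapse by sum for counts (counts are additive) and
  mean for log2 values (log values are not).
- `purify_profiles` on a tumor identical to a normal hits the 0.99 alpha
  cap and still returns a finite profile; purified linear values are
  clipped at 0.
- Randomness everywhere flows from one integer seed; the RNG state of the
  caller is saved and restored, so library calls do not perturb user code.

## Problem sizes

The test suite and the acceptance script run the full subtyping condition
(90 samples × 1,500 genes × 30 NMF restarts × k ∈ 2..6) twice and the
end-to-end scenario with a 100-replicate permutation null once; smaller
integration tests use a 600-gene, 2-subtype scenario. These sizes were
chosen to exercise every code path at the stated study conditions while
keeping a full run in the minutes range on one core.
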