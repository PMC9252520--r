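# revsig

Personalized drug repurposing by reversal of individual disease signatures.

Bulk tumor transcriptomes vary so much between patients that a cohort-level
disease signature can misrepresent any single case. `revsig` builds a
signature for *one* patient by borrowing strength from the reference-cohort
samples most similar to them, then searches a drug-perturbation library for
compounds whose induced expression changes run *opposite* to that signature
— the connectivity-map idea that a drug reversing a disease expression
pattern is a therapeutic candidate. It is aimed at computational biologists
prototyping expression-based drug repurposing for individual tumors, and
ships a synthetic-data generator so the whole workflow runs and is tested
without any external downloads.

## The method

1. **Subtyping.** The cohort's 1,500 most variant genes (log2 scale) feed
   consensus non-negative matrix factorization: repeated multiplicative-update
   NMF runs cluster samples by dominant metagene, co-clustering frequencies
   form a consensus matrix per candidate rank k, and k is chosen by
   cophenetic correlation (silhouette width breaks ties).
2. **Subgroup replicates.** The patient is assigned to the subtype with
   maximal median Spearman rho, and the top-N most-correlated subtype
   samples (N = 3, 5 or 10; default 5) become their biological replicates.
   Matched normal controls are chosen from a normal pool by median Spearman
   correlation to the subgroup.
3. **Purity deconvolution (optional).** Subgroups flagged high-infiltration
   by ssGSEA stromal/immune scores are purified: each bulk profile is
   modelled on the linear scale as a non-negative mix of normal profiles
   plus a cancer residual (constrained NNLS), and the cancer component is
   extracted.
4. **Signature.** Welch t-tests on log2 CPM between subgroup and controls,
   BH-adjusted, give up/down gene sets (FDR < 0.05, |log2FC| >= 1, up to
   100 genes per side).
5. **Reversal scoring.** For each library treatment (drug, cell line, dose,
   time) two one-sided Kolmogorov–Smirnov statistics per gene set —
   a = max_j(j/t − V(j)/n), b = max_j(V(j)/n − (j−1)/t) — give signed
   enrichment scores; RGES = es_up − es_down when the signs oppose, else 0.
   A reward model standardizes RGES across dose/time classes to the 10 µM /
   24 h reference, and the per-drug mean is the summary score **sRGES** —
   the lower, the stronger the predicted reversal.
6. **In-silico validation.** Against a matched cell line's dose-response
   AUCs: Pearson correlation of sRGES with AUC, a Welch t-test of sRGES
   between effective (AUC ≤ mean − 0.5·SD) and ineffective drugs, a
   100-replicate permutation null over random subgroups, and responder ROC
   AUC via the Mann–Whitney identity.

## Worked example

```r
library(revsig)

cfg  <- scenario_config(seed = 7)            # synthetic study conditions
sim  <- simulate_cohort(cfg)                 # cohort + normals + patient
pert <- simulate_perturbation_library(cfg, sim$truth$sig_up, sim$truth$sig_down)
sr   <- simulate_sensitivity_and_response(cfg, pert$strength)

rec <- recommend_drugs(sim$patient, sim$cohort, sim$normals, pert$library,
                       seed = 7)
rec
#> drug recommendation for PT1
#>   subtype: 1 of 3 (median Spearman rho 0.902)
#>   subgroup: T026, T001, T029, T016, T009
#>   signature: 100 up / 100 down genes
#>   top reversal candidates (lowest sRGES):
#>    drug      srges n_treatments
#>  drug05 -0.8417875            4
#>  drug03 -0.7962875            4
#>  drug04 -0.7602875            4
#>  drug02 -0.7447875            4
#>  drug01 -0.5589125            4

validate_correlation(rec$srges, sr$sensitivity, "CL-1")[c("r", "p")]
#> $r
#> [1] 0.9418019
#> $p
#> [1] 5.883194e-10
```

The five drugs built as reversers (`drug01`–`drug05`) take the five lowest
sRGES ranks, and sRGES correlates strongly with the simulated dose-response
AUCs (low sRGES — strong predicted reversal — goes with low AUC, i.e. high
measured sensitivity).

A thin command-line wrapper over the same functions is installed at
`inst/cli/revsig.R`, e.g.
`Rscript inst/cli/revsig.R signature --case sub.tsv --control ctrl.tsv --out sig.json`.

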