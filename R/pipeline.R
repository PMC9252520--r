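#' End-to-end personalized drug recommendation
#'
#' Runs the whole workflow for one patient: log2 transformation, variant-gene
#' selection, consensus NMF subtyping of the cohort, patient-to-subtype
#' assignment by median Spearman similarity, subgroup and matched-control
#' selection, optional infiltration scoring and tumor-purity deconvolution,
#' differential expression, signature construction, and sRGES scoring of the
#' perturbation library.
#'
#' @param patient one-column `expr_matrix` (counts or log2).
#' @param cohort `expr_matrix` - the reference tumor cohort.
#' @param normals `expr_matrix` - the pool of normal samples.
#' @param lib a `perturbation_library`.
#' @param gene_sets optional `gene_sets` collection with stromal/immune sets
#'   for infiltration scoring; when supplied and `purify = "auto"`, subgroup
#'   profiles are purified if flagged high-infiltration.
#' @param n_genes variant-gene panel size (default 1500).
#' @param k_range,n_runs consensus subtyping parameters
#'   (see [consensus_subtype()]).
#' @param N subgroup size (default 5).
#' @param purify `"auto"` (purify when flagged), `"never"` or `"always"`.
#' @param q infiltration quantile for the high-infiltration flag.
#' @param fdr_max,lfc_min,cap signature thresholds
#'   (see [build_signature()]).
#' @param min_overlap KS overlap requirement (see [score_library()]).
#' @param seed integer seed governing all randomness.
#' @param subtype optional precomputed `subtype_result` for the cohort; when
#'   supplied, subtyping is skipped (useful when scoring many patients
#'   against one cohort).
#' @return object of class `drug_recommendation`: list with elements
#'   `subtype` (`subtype_result`), `similarity`, `subgroup`
#'   (`subgroup_result` with a `controls` field), `infiltration`,
#'   `purification` (NULL unless run), `signature`, `srges`
#'   (`srges_table`) and `params`.
#' @export
recommend_drugs <- function(patient, cohort, normals, lib,
                            gene_sets = NULL, n_genes = 1500L,
                            k_range = 2:6, n_runs = 30L, N = 5L,
                            purify = c("auto", "never", "always"),
                            q = 0.75, fdr_max = 0.05, lfc_min = 1,
                            cap = 100L, min_overlap = 5L, seed = 1L,
                            subtype = NULL) {
  purify <- match.arg(purify)
  al <- align_genes(cohort, normals)
  cohort <- al$a; normals <- al$b
  pat_al <- align_genes(patient, cohort)
  patient <- pat_al$a
  cohort_log <- log2_cpm(cohort)
  normals_log <- log2_cpm(normals)
  patient_log <- log2_cpm(patient)

  genes <- select_variant_genes(cohort_log, min(n_genes, nrow(cohort_log)))
  if (is.null(subtype))
    subtype <- consensus_subtype(cohort_log, genes, k_range = k_range,
                                 n_runs = n_runs, seed = seed)
  sim <- subtype_similarity(patient_log, cohort_log, subtype, genes)
  sub <- select_subgroup(sim, subtype, N = N)
  sub$controls <- select_controls(cohort_log[, sub$subgroup, drop = FALSE],
                                  normals_log, N = N, genes = genes)

  infiltration <- NULL
  purification <- NULL
  do_purify <- purify == "always"
  if (!is.null(gene_sets) && purify != "never") {
    tme <- tme_scores(cohort_log, gene_sets)
    infiltration <- infiltration_flag(tme, sub$subgroup,
                                      set_names = names(gene_sets)[1:2],
                                      q = q)
    if (purify == "auto") do_purify <- infiltration$flag
  }

  case_log <- cohort_log[, sub$subgroup, drop = FALSE]
  ctrl_log <- normals_log[, sub$controls, drop = FALSE]
  if (do_purify) {
    purification <- purify_profiles(case_log, ctrl_log)
    case_log <- purification$purified
  }
  de <- differential_expression(case_log, ctrl_log)
  sig <- build_signature(de, fdr_max = fdr_max, lfc_min = lfc_min, cap = cap,
                         patient_id = sim$patient_id, purified = do_purify)
  scores <- srges(sig, lib, min_overlap = min_overlap)

  structure(list(subtype = subtype, similarity = sim, subgroup = sub,
                 infiltration = infiltration, purification = purification,
                 de = de, signature = sig, srges = scores,
                 params = list(n_genes = n_genes, N = N, q = q,
                               fdr_max = fdr_max, lfc_min = lfc_min,
                               cap = cap, min_overlap = min_overlap,
                               purify = purify, seed = seed)),
            class = "drug_recommendation")
}

#' @export
print.drug_recommendation <- function(x, ...) {
  cat(sprintf("drug recommendation for %s\n", x$similarity$patient_id))
  cat(sprintf("  subtype: %d of %d (median Spearman rho %.3f)\n",
              x$similarity$subtype, x$subtype$k,
              max(x$similarity$per_subtype)))
  cat(sprintf("  subgroup: %s\n", paste(x$subgroup$subgroup, collapse = ", ")))
  if (!is.null(x$infiltration))
    cat(sprintf("  infiltration: mean %.3f vs threshold %.3f (%s)\n",
                x$infiltration$mean_score, x$infiltration$threshold,
                if (x$infiltration$flag) "high - purified" else "not high"))
  cat(sprintf("  signature: %d up / %d down genes\n",
              length(x$signature$up), length(x$signature$down)))
  cat("  top reversal candidates (lowest sRGES):\n")
  print(utils::head(x$srges, 5), row.names = FALSE)
  invisible(x)
}

#' @export
summary.drug_recommendation <- function(object, ...) {
  s <- object$srges
  cat(sprintf("%d drugs scored over %d treatments (%d skipped)\n",
              nrow(s), nrow(attr(s, "rges")),
              attr(attr(s, "rges"), "n_skipped")))
  cat(sprintf("sRGES range: [%.3f, %.3f]; %d drug(s) below -0.1\n",
              min(s$srges), max(s$srges), sum(s$srges < -0.1)))
  invisible(object)
}
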