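#' Match a patient to the most similar cell line
#'
#' Computes Spearman rank correlation between the patient and each cell
#' line over the `n_genes` most variant genes of the cell-line panel
#' (variance taken across the panel itself), and returns the best match;
#' ties go to the lexicographically smallest cell line id.
#'
#' @param patient named numeric vector or one-column `expr_matrix`.
#' @param cell_lines `expr_matrix` (log2) of the cell-line panel.
#' @param n_genes size of the variant-gene panel (default 1500, capped at
#'   the number of shared genes).
#' @return list with `cell_line` (id) and `rho`.
#' @export
match_cell_line <- function(patient, cell_lines, n_genes = 1500L) {
  stopifnot(inherits(cell_lines, "expr_matrix"))
  if (ncol(cell_lines) == 0L) stop("empty cell-line matrix", call. = FALSE)
  if (inherits(patient, "expr_matrix"))
    patient <- stats::setNames(as.vector(patient[, 1L]), rownames(patient))
  panel <- select_variant_genes(cell_lines,
                                min(n_genes, nrow(cell_lines)))
  shared <- intersect(panel, names(patient))
  if (length(shared) < 2L)
    stop("fewer than 2 genes shared with the cell-line panel", call. = FALSE)
  rho <- suppressWarnings(
    stats::cor(patient[shared],
               unclass(cell_lines[shared, , drop = FALSE]),
               method = "spearman"))[1L, ]
  rho[!is.finite(rho)] <- 0
  ord <- order(-rho, colnames(cell_lines), method = "radix")
  list(cell_line = colnames(cell_lines)[ord[1L]], rho = unname(rho[ord[1L]]))
}

#' Label drugs effective/ineffective on one cell line
#'
#' Over the cell line's measured AUCs, a drug is effective when its AUC is
#' at least half a standard deviation below the mean:
#' `AUC <= mean - 0.5 * SD` (sample SD; the boundary is inclusive). With
#' all AUCs equal the SD is 0, the threshold equals the mean and every drug
#' is labelled effective.
#'
#' @param sens drug-sensitivity data.frame (drug, cell_line, auc).
#' @param cell_line cell line id; needs >= 3 measured drugs.
#' @return data.frame of class `efficacy_labels` with columns drug, auc,
#'   effective; attributes `mean`, `sd`, `threshold`.
#' @export
classify_drug_efficacy <- function(sens, cell_line) {
  d <- sens[sens$cell_line == cell_line, , drop = FALSE]
  if (nrow(d) < 3L)
    stop(sprintf("only %d drug(s) measured on %s; need >= 3",
                 nrow(d), cell_line), call. = FALSE)
  mu <- mean(d$auc); sd <- stats::sd(d$auc)
  thr <- mu - 0.5 * sd
  out <- data.frame(drug = d$drug, auc = d$auc,
                    effective = d$auc <= thr, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, mean = mu, sd = sd, threshold = thr,
            class = c("efficacy_labels", class(out)))
}

# Pearson r with the package's degenerate-input convention: a constant
# vector has no linear association, so r = 0 (with a warning)
safe_pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector in correlation; returning r = 0", call. = FALSE)
    return(list(r = 0, p = 1))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlate drug predictions with measured sensitivity
#'
#' Over the drugs shared between the sRGES table and the cell line's
#' sensitivity measurements: (a) Pearson correlation between sRGES and AUC
#' (a good prediction gives a positive r - strong reversers, i.e. low
#' sRGES, should have low AUC); (b) Welch t-test of sRGES between
#' effective and ineffective drugs as labelled by
#' [classify_drug_efficacy()]. When only one label class is present the
#' t-test is reported as not applicable (NA).
#'
#' @param srges_tab a `srges_table`.
#' @param sens drug-sensitivity data.frame (drug, cell_line, auc).
#' @param cell_line the matched cell line id.
#' @return list with `r`, `p`, `t_stat`, `t_p`, `n_drugs`, `labels`
#'   (the `efficacy_labels` used), `drugs`.
#' @export
validate_correlation <- function(srges_tab, sens, cell_line) {
  d <- sens[sens$cell_line == cell_line, , drop = FALSE]
  common <- intersect(srges_tab$drug, d$drug)
  if (length(common) < 3L)
    stop(sprintf("only %d drug(s) shared with the sensitivity table; need >= 3",
                 length(common)), call. = FALSE)
  s <- srges_tab$srges[match(common, srges_tab$drug)]
  a <- d$auc[match(common, d$drug)]
  ct <- safe_pearson(s, a)
  labels <- classify_drug_efficacy(d[d$drug %in% common, , drop = FALSE],
                                   cell_line)
  eff <- labels$effective[match(common, labels$drug)]
  if (length(unique(eff)) == 2L && sum(eff) >= 2L && sum(!eff) >= 2L) {
    tt <- stats::t.test(s[eff], s[!eff])
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
  } else {
    t_stat <- NA_real_; t_p <- NA_real_
  }
  list(r = ct$r, p = ct$p, t_stat = t_stat, t_p = t_p,
       n_drugs = length(common), labels = labels, drugs = common)
}

#' Permutation null for the prediction-sensitivity correlation
#'
#' Breaks the patient-subgroup relationship: each replicate draws a
#' uniformly random subgroup of the same size from the assigned subtype
#' (optionally the whole cohort), recomputes the drug sRGES scores through
#' the supplied pipeline, and records the Pearson correlation with the
#' cell line's AUCs. The observed correlation is then compared against the
#' null sample with a one-sample t-test (null sample vs the observed value
#' as the hypothesized mean).
#'
#' @param observed_r the observed correlation ([validate_correlation()]).
#' @param subtype_samples sample ids of the patient's subtype (or cohort).
#' @param pipeline function(subgroup_ids) -> `srges_table` (or any
#'   data.frame with drug and srges columns).
#' @param sens drug-sensitivity data.frame.
#' @param cell_line matched cell line id.
#' @param N subgroup size to draw.
#' @param n_perm number of replicates (default 100, >= 2).
#' @param seed integer seed for the subgroup draws.
#' @return object of class `permutation_null`: list with `null_r`
#'   (length-n_perm vector), `observed_r`, `p` (one-sample t-test), `t_stat`.
#' @export
permutation_null <- function(observed_r, subtype_samples, pipeline, sens,
                             cell_line, N, n_perm = 100L, seed = 1L) {
  if (n_perm < 2L) stop("n_perm must be >= 2", call. = FALSE)
  if (N >= length(subtype_samples))
    stop("subtype must have more than N samples", call. = FALSE)
  d <- sens[sens$cell_line == cell_line, , drop = FALSE]
  null_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sub <- sample(subtype_samples, N)
    # a replicate whose subgroup supports no signature (or too few shared
    # drugs) is dropped rather than aborting the whole null
    st <- tryCatch(pipeline(sub), error = function(e) NULL)
    if (is.null(st)) return(NA_real_)
    common <- intersect(st$drug, d$drug)
    if (length(common) < 3L) return(NA_real_)
    suppressWarnings(
      safe_pearson(st$srges[match(common, st$drug)],
                   d$auc[match(common, d$drug)])$r)
  }, numeric(1)))
  if (anyNA(null_r))
    warning(sum(is.na(null_r)), " null replicate(s) dropped", call. = FALSE)
  null_r <- null_r[!is.na(null_r)]
  if (stats::sd(null_r) == 0) {
    warning("degenerate null (constant correlations); p undefined, set to 1",
            call. = FALSE)
    return(structure(list(null_r = null_r, observed_r = observed_r,
                          p = 1, t_stat = NA_real_),
                     class = "permutation_null"))
  }
  tt <- stats::t.test(null_r, mu = observed_r)
  structure(list(null_r = null_r, observed_r = observed_r,
                 p = tt$p.value, t_stat = unname(tt$statistic)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation null (%d replicates): mean r = %.3f, observed r = %.3f, one-sample t-test p = %.3g\n",
              length(x$null_r), mean(x$null_r), x$observed_r, x$p))
  invisible(x)
}

#' Discriminate responders by score: t-test and ROC AUC
#'
#' Welch t-test of the score between responders and non-responders, and the
#' ROC AUC computed via the Mann-Whitney identity with *lower* scores
#' ranked as more responder-like (as for reversal scores, where lower means
#' stronger predicted efficacy): AUC = P(score_responder < score_other),
#' ties counted 1/2.
#'
#' @param scores named numeric vector, one score per patient.
#' @param labels named vector over the same patients with values
#'   `"responder"` / `"non-responder"` (or a logical, TRUE = responder).
#' @return list with `auc`, `t_stat`, `p`, `n_responder`, `n_other`.
#' @export
responder_auc <- function(scores, labels) {
  if (!is.null(names(labels)) && !is.null(names(scores)))
    labels <- labels[names(scores)]
  resp <- if (is.logical(labels)) labels else labels == "responder"
  if (anyNA(resp)) stop("labels must cover every scored patient", call. = FALSE)
  x <- scores[resp]; y <- scores[!resp]
  if (length(x) == 0L || length(y) == 0L)
    stop("both responder and non-responder classes must be non-empty",
         call. = FALSE)
  # Mann-Whitney: rank-sum of the responder scores in the pooled ranking
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  auc <- 1 - U / (length(x) * length(y))   # lower score = more responder-like
  if (length(x) >= 2L && length(y) >= 2L &&
      (stats::sd(x) > 0 || stats::sd(y) > 0)) {
    tt <- stats::t.test(x, y)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    t_stat <- NA_real_; p <- NA_real_
  }
  list(auc = auc, t_stat = t_stat, p = p,
       n_responder = length(x), n_other = length(y))
}
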