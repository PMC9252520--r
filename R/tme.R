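#' Single-sample gene set enrichment score (ssGSEA)
#'
#' Per sample, genes are ranked by descending expression (position 1 = most
#' expressed). A running sum walks down the ranking, adding
#' `pos^alpha_weight / sum(in-set pos^alpha_weight)` at in-set genes and
#' subtracting `1/(n - t)` at out-of-set genes; the score is the integral
#' (sum) of the running sum over all positions. The score depends only on
#' within-sample ranks, so it is invariant to monotone transforms of the
#' expression values.
#'
#' @param expr `expr_matrix` (log2).
#' @param gene_set character vector of gene symbols; must overlap `expr`'s
#'   genes but not cover all of them.
#' @param alpha_weight rank-weight exponent (default 0.25; 0 gives the
#'   unweighted Kolmogorov-Smirnov running sum).
#' @return named numeric vector, one score per sample.
#' @export
ssgsea_score <- function(expr, gene_set, alpha_weight = 0.25) {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- rownames(expr)
  n <- length(genes)
  inset <- genes %in% gene_set
  t <- sum(inset)
  if (t == 0L) stop("gene set shares no genes with the matrix", call. = FALSE)
  if (t == n) stop("gene set covers every gene; out-of-set ECDF undefined",
                   call. = FALSE)
  vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-unclass(expr)[, j], genes, method = "radix")
    hit <- inset[ord]
    pos <- seq_len(n)
    w <- ifelse(hit, pos^alpha_weight, 0)
    w <- w / sum(w)
    dec <- ifelse(hit, 0, 1 / (n - t))
    sum(cumsum(w - dec))
  }, numeric(1)) -> scores
  stats::setNames(scores, colnames(expr))
}

#' Score a collection of gene sets per sample
#'
#' Applies [ssgsea_score()] to each set of a collection, producing the
#' infiltration score matrix (gene set x sample) used to quantify stromal
#' and immune cell content.
#'
#' @param expr `expr_matrix` (log2).
#' @param gene_sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param alpha_weight rank-weight exponent passed to [ssgsea_score()].
#' @return matrix of class `tme_scores`, rows = gene sets, columns = samples.
#' @export
tme_scores <- function(expr, gene_sets, alpha_weight = 0.25) {
  m <- t(vapply(gene_sets, function(gs) ssgsea_score(expr, gs, alpha_weight),
                numeric(ncol(expr))))
  structure(m, class = c("tme_scores", class(m)))
}

#' Flag a subgroup as high-infiltration
#'
#' The subgroup statistic is the mean over subgroup samples of the summed
#' stromal + immune scores; the subgroup is flagged when that mean exceeds
#' the q-quantile of the same per-sample statistic across the whole cohort
#' (default q = 0.75).
#'
#' @param tme a `tme_scores` matrix for the cohort.
#' @param subgroup character vector of subgroup sample ids.
#' @param set_names names of the rows summed into the infiltration
#'   statistic (default the first two rows).
#' @param q cohort quantile defining "high" (default 0.75).
#' @return list with `mean_score`, `threshold`, `flag`.
#' @export
infiltration_flag <- function(tme, subgroup, set_names = rownames(tme)[1:2],
                              q = 0.75) {
  if (length(subgroup) == 0L) stop("empty subgroup", call. = FALSE)
  if (!all(set_names %in% rownames(tme)))
    stop("unknown gene set name(s): ",
         paste(setdiff(set_names, rownames(tme)), collapse = ", "),
         call. = FALSE)
  if (!all(subgroup %in% colnames(tme)))
    stop("subgroup sample(s) absent from score matrix", call. = FALSE)
  per_sample <- colSums(tme[set_names, , drop = FALSE])
  mean_score <- mean(per_sample[subgroup])
  threshold <- stats::quantile(per_sample, q, names = FALSE)
  list(mean_score = mean_score, threshold = threshold,
       flag = mean_score > threshold)
}

#' Purify tumor profiles by normal-profile deconvolution
#'
#' Models each bulk tumor profile, on the linear scale (2^x - 1), as a
#' non-negative combination of the normal profiles plus a non-negative
#' cancer residual: `x_s ~ sum_j w_j n_j + c_s`, fitted by non-negative
#' least squares per tumor sample. The contamination fraction is
#' `alpha_s = sum_j w_j`, capped at 0.99; the purified cancer profile is
#' `log2(1 + max(0, (x_s - sum_j w_j n_j) / (1 - alpha_s)))`. This is a
#' convex-combination deconvolution in the spirit of ISOpure's first stage,
#' without its Bayesian regularization.
#'
#' @param subgroup `expr_matrix` (log2) of tumor samples.
#' @param normals `expr_matrix` (log2) of normal samples, gene-aligned with
#'   `subgroup`.
#' @return object of class `purification`: list with `alphas` (named vector
#'   in \[0, 0.99\]) and `purified` (`expr_matrix`, log2).
#' @export
purify_profiles <- function(subgroup, normals) {
  stopifnot(inherits(subgroup, "expr_matrix"), inherits(normals, "expr_matrix"))
  if (!identical(rownames(subgroup), rownames(normals)))
    stop("subgroup and normals must be gene-aligned; see align_genes()",
         call. = FALSE)
  if (ncol(normals) < 1L) stop("need at least one normal sample", call. = FALSE)
  N <- 2^unclass(normals) - 1          # linear scale
  A <- cbind(N, intercept = 1)
  m <- ncol(N)
  alphas <- numeric(ncol(subgroup))
  purified <- matrix(0, nrow(subgroup), ncol(subgroup),
                     dimnames = dimnames(subgroup))
  for (s in seq_len(ncol(subgroup))) {
    x <- 2^unclass(subgroup)[, s] - 1
    fit <- pracma::lsqnonneg(A, x)
    w <- fit$x[seq_len(m)]
    alpha <- sum(w)
    if (alpha > 0.99) {                 # cap: rescale the normal weights
      w <- w * 0.99 / alpha
      alpha <- 0.99
    }
    normal_part <- as.vector(N %*% w)
    cancer <- pmax(0, (x - normal_part) / (1 - alpha))
    alphas[s] <- alpha
    purified[, s] <- log2(1 + cancer)
  }
  names(alphas) <- colnames(subgroup)
  structure(list(alphas = alphas,
                 purified = expression_matrix(purified, "log2")),
            class = "purification")
}

#' @export
print.purification <- function(x, ...) {
  cat(sprintf("purification of %d tumor profile(s)\n", length(x$alphas)))
  cat("estimated normal-contamination fractions:\n")
  print(round(x$alphas, 3))
  invisible(x)
}
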