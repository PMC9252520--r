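# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Most variant genes across samples
#'
#' Returns the `n` genes with the largest sample variance on the log2 scale,
#' in descending variance order. Ties are broken by gene symbol
#' (lexicographic), so the selection is deterministic.
#'
#' @param expr `expr_matrix` with units log2.
#' @param n number of genes to keep (default 1500).
#' @return character vector of `n` gene symbols.
#' @export
select_variant_genes <- function(expr, n = 1500) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr_units(expr) != "log2")
    stop("variant-gene selection expects log2 values; see log2_cpm()",
         call. = FALSE)
  if (n > nrow(expr))
    stop(sprintf("requested %d genes but matrix has only %d", n, nrow(expr)),
         call. = FALSE)
  v <- apply(unclass(expr), 1L, stats::var)
  ord <- order(-v, rownames(expr), method = "radix")
  rownames(expr)[ord[seq_len(n)]]
}

# one multiplicative-update Frobenius NMF run; returns per-sample hard
# assignment to the argmax metagene
nmf_assign <- function(V, k, max_iter = 500L, tol = 1e-5) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  eps <- .Machine$double.eps
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L) {
      obj <- sum((V - W %*% H)^2)
      if (is.finite(obj_old) && abs(obj_old - obj) <= tol * obj_old) break
      obj_old <- obj
    }
  }
  apply(H, 2L, which.max)
}

#' Consensus NMF subtyping of a cohort
#'
#' Repeated non-negative matrix factorizations (multiplicative updates,
#' Frobenius objective, random initialization) cluster samples by their
#' dominant metagene; co-clustering frequencies across runs form a consensus
#' matrix per candidate rank k. Final labels come from average-linkage
#' hierarchical clustering of the consensus dissimilarity (1 - consensus).
#' The rank is chosen to maximize the cophenetic correlation of that
#' dissimilarity, with average silhouette width breaking ties.
#'
#' @param expr `expr_matrix` (log2) - the cohort.
#' @param genes gene panel to cluster on (typically from
#'   [select_variant_genes()]).
#' @param k_range candidate numbers of subtypes (all >= 2).
#' @param n_runs NMF restarts per k (>= 2; default 30).
#' @param seed integer seed; all randomness in the procedure flows from it.
#' @param max_iter,tol NMF stopping rule: at most `max_iter` multiplicative
#'   updates, stop early when the relative decrease of the Frobenius
#'   objective over 10 iterations falls below `tol`.
#' @return object of class `subtype_result`: list with `labels` (named
#'   integer vector, subtype id per sample), `k`, `metrics` (data.frame of
#'   cophenetic correlation and mean silhouette width per k), `consensus`
#'   (sample x sample co-clustering frequencies for the chosen k) and
#'   `consensus_all` (one consensus matrix per candidate k).
#' @export
consensus_subtype <- function(expr, genes, k_range = 2:6, n_runs = 30L,
                              seed = 1L, max_iter = 500L, tol = 1e-5) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (min(k_range) < 2L) stop("k_range minimum must be >= 2", call. = FALSE)
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes))
    stop("genes absent from matrix: ", missing_genes[1L], " ...", call. = FALSE)
  V <- unclass(expr[genes, , drop = FALSE])
  V <- V - apply(V, 1L, min)          # per-gene min-subtraction -> non-negative
  m <- ncol(V)
  samples <- colnames(V)

  consensus_all <- list()
  metrics <- data.frame(k = integer(), cophenetic = numeric(),
                        silhouette = numeric())
  labels_all <- list()
  with_seed(seed, {
    for (k in k_range) {
      co <- matrix(0, m, m)
      for (r in seq_len(n_runs)) {
        a <- nmf_assign(V, k, max_iter = max_iter, tol = tol)
        co <- co + outer(a, a, "==")
      }
      co <- co / n_runs
      dimnames(co) <- list(samples, samples)
      d <- stats::as.dist(1 - co)
      hc <- stats::hclust(d, method = "average")
      lab <- stats::cutree(hc, k = k)
      coph <- suppressWarnings(stats::cor(stats::cophenetic(hc), d))
      if (!is.finite(coph)) coph <- 1  # zero-spread dissimilarity: perfectly stable
      sil <- if (length(unique(lab)) > 1L)
        mean(cluster::silhouette(lab, d)[, "sil_width"]) else NA_real_
      consensus_all[[as.character(k)]] <- co
      labels_all[[as.character(k)]] <- lab
      metrics <- rbind(metrics,
                       data.frame(k = k, cophenetic = coph, silhouette = sil))
    }
  })
  ord <- order(-metrics$cophenetic,
               -ifelse(is.na(metrics$silhouette), -Inf, metrics$silhouette),
               metrics$k)
  best_k <- metrics$k[ord[1L]]
  structure(list(labels = labels_all[[as.character(best_k)]],
                 k = best_k,
                 metrics = metrics,
                 consensus = consensus_all[[as.character(best_k)]],
                 consensus_all = consensus_all,
                 genes = genes, seed = seed),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("consensus NMF subtyping: %d samples, chosen k = %d\n",
              length(x$labels), x$k))
  print(x$metrics, row.names = FALSE)
  cat("subtype sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.subtype_result <- function(x, ...) {
  ord <- order(x$labels)
  graphics::image(x$consensus[ord, ord], axes = FALSE, useRaster = TRUE,
        main = sprintf("consensus matrix (k = %d)", x$k), ...)
  invisible(x)
}

#' Patient-to-subtype similarity by median Spearman correlation
#'
#' Spearman rank correlation of the patient against every cohort sample on
#' the supplied gene panel; the similarity to a subtype is the median rho
#' over that subtype's samples, and the patient is assigned to the subtype
#' with maximal similarity (ties to the smallest subtype id). Because only
#' ranks matter, the result is invariant to any monotone transform of the
#' patient's expression values.
#'
#' @param patient named numeric vector (gene -> expression) or one-column
#'   `expr_matrix`.
#' @param cohort `expr_matrix`.
#' @param result a `subtype_result` for the cohort.
#' @param genes gene panel for the correlation.
#' @param patient_id identifier recorded in the output.
#' @return object of class `subtype_similarity`: list with `per_sample`
#'   (rho per cohort sample), `per_subtype` (median rho per subtype),
#'   `subtype` (assigned id) and `patient_id`.
#' @export
subtype_similarity <- function(patient, cohort, result, genes,
                               patient_id = "patient") {
  if (inherits(patient, "expr_matrix")) {
    if (ncol(patient) == 1L) patient_id <- colnames(patient)
    patient <- stats::setNames(as.vector(patient[, 1L]), rownames(patient))
  }
  genes <- intersect(genes, intersect(names(patient), rownames(cohort)))
  if (length(genes) < 2L)
    stop("fewer than 2 genes shared between patient and cohort", call. = FALSE)
  rho <- suppressWarnings(
    stats::cor(patient[genes], unclass(cohort[genes, , drop = FALSE]),
               method = "spearman"))[1L, ]
  rho[!is.finite(rho)] <- 0
  labs <- result$labels[names(rho)]
  per_subtype <- tapply(rho, labs, stats::median)
  ids <- sort(as.integer(names(per_subtype)))
  per_subtype <- per_subtype[as.character(ids)]
  assigned <- ids[which(per_subtype == max(per_subtype))[1L]]
  structure(list(per_sample = rho, per_subtype = per_subtype,
                 subtype = assigned, patient_id = patient_id),
            class = "subtype_similarity")
}

#' Select the patient's subgroup (biological replicates)
#'
#' The N samples of the assigned subtype with the largest Spearman rho to
#' the patient, ties broken by sample id. Increasing N only ever adds
#' samples. Typical subgroup sizes are 3, 5 or 10; the default is 5.
#'
#' @param sim a `subtype_similarity` object.
#' @param result the `subtype_result` the similarity was computed against.
#' @param N subgroup size.
#' @return object of class `subgroup_result`: list with `patient_id`,
#'   `subtype`, `subgroup` (sample ids), `similarity` (rho of the
#'   subgroup samples) and `N`.
#' @export
select_subgroup <- function(sim, result, N = 5L) {
  stopifnot(inherits(sim, "subtype_similarity"))
  members <- names(result$labels)[result$labels == sim$subtype]
  if (N > length(members))
    stop(sprintf("N = %d exceeds subtype size %d", N, length(members)),
         call. = FALSE)
  rho <- sim$per_sample[members]
  ord <- order(-rho, members, method = "radix")
  chosen <- members[ord[seq_len(N)]]
  structure(list(patient_id = sim$patient_id, subtype = sim$subtype,
                 subgroup = chosen, similarity = rho[chosen], N = N),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf("subgroup for %s (subtype %d, N = %d):\n",
              x$patient_id, x$subtype, x$N))
  print(round(x$similarity, 3))
  if (!is.null(x$controls)) cat("controls:", paste(x$controls, collapse = ", "), "\n")
  invisible(x)
}

#' Select matched normal controls for a subgroup
#'
#' Ranks every sample of the normal pool by its median Spearman rho to the
#' subgroup members (on the given gene panel) and returns the top N, ties
#' broken by sample id. This is a correlation-based proxy for learned-feature
#' matching of controls to tumors.
#'
#' @param subgroup_expr `expr_matrix` of the subgroup samples.
#' @param normals `expr_matrix` - the pool of normal samples.
#' @param N number of controls (usually `= |subgroup|`).
#' @param genes gene panel for the correlation.
#' @return character vector of N control sample ids.
#' @export
select_controls <- function(subgroup_expr, normals, N, genes) {
  if (N > ncol(normals))
    stop(sprintf("N = %d exceeds normal pool size %d", N, ncol(normals)),
         call. = FALSE)
  genes <- intersect(genes, intersect(rownames(subgroup_expr), rownames(normals)))
  if (length(genes) < 2L)
    stop("fewer than 2 shared genes for control matching", call. = FALSE)
  rho <- suppressWarnings(
    stats::cor(unclass(normals[genes, , drop = FALSE]),
               unclass(subgroup_expr[genes, , drop = FALSE]),
               method = "spearman"))
  rho[!is.finite(rho)] <- 0
  med <- apply(rho, 1L, stats::median)
  ord <- order(-med, colnames(normals), method = "radix")
  colnames(normals)[ord[seq_len(N)]]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples;
#' 1 means identical partitions, 0 is the expected value under independence.
#'
#' @param a,b cluster label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
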