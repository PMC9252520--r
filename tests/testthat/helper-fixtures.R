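# shared builders and independent oracles for the test suite

make_expr <- function(values, units = "counts",
                      genes = sprintf("g%d", seq_len(nrow(values))),
                      samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, units)
}

# named ranking with the given set positions occupied by the set genes
make_ranking <- function(n, set_positions, set_genes = NULL) {
  genes <- sprintf("G%02d", seq_len(n))
  if (!is.null(set_genes)) genes[set_positions] <- set_genes
  stats::setNames(seq_len(n), genes)
}

# brute-force KS oracle: loop straight over the two max definitions
ks_brute <- function(set_positions, n) {
  V <- sort(set_positions)
  t <- length(V)
  a <- -Inf; b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - V[j] / n)
    b <- max(b, V[j] / n - (j - 1) / t)
  }
  list(a = a, b = b)
}

# brute-force ssGSEA running-sum oracle (explicit position loop)
ssgsea_brute <- function(expr_col, genes, set, alpha) {
  ord <- order(-expr_col, genes, method = "radix")
  ranked <- genes[ord]
  n <- length(ranked); t <- sum(ranked %in% set)
  win <- sum((which(ranked %in% set))^alpha)
  rs <- 0; total <- 0
  for (pos in seq_len(n)) {
    if (ranked[pos] %in% set) rs <- rs + pos^alpha / win
    else rs <- rs - 1 / (n - t)
    total <- total + rs
  }
  total
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# one-column expr_matrix from a named vector
patient_col <- function(v, units = "log2", id = "PT1") {
  expression_matrix(matrix(v, dimnames = list(names(v), id)), units)
}

# a tiny, fast scenario for integration-style tests
small_scenario <- function(seed = 1L, ...) {
  scenario_config(seed = seed, n_genes = 600L, k = 2L,
                  samples_per_subtype = 10L, n_normals = 10L,
                  block_size = 50L, sig_size = 50L, sig_activity_range = c(1, 1),
                  n_drugs = 8L, n_reversers = 3L, n_patients = 30L, ...)
}
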