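#' Construct an expression matrix
#'
#' The central container of the package: a numeric gene x sample matrix with
#' gene symbols as row names, sample identifiers as column names, and a units
#' tag declaring whether values are raw counts or log2-scale expression.
#'
#' @param values numeric matrix, rows = genes, columns = samples; row and
#'   column names must be present and unique.
#' @param units `"counts"` or `"log2"`.
#' @return an object of class `expr_matrix` (a matrix with a `units`
#'   attribute).
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' x <- expression_matrix(m, "counts")
#' expr_units(x)
#' @export
expression_matrix <- function(values, units = c("counts", "log2")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (units == "counts" && any(values < 0))
    stop("counts must be non-negative", call. = FALSE)
  structure(values, units = units, class = c("expr_matrix", class(values)))
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
expr_units <- function(x) attr(x, "units")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), expr_units(x)))
  nr <- min(5L, nrow(x)); nc <- min(5L, ncol(x))
  print(unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE])
  if (nrow(x) > nr || ncol(x) > nc) cat("...\n")
  invisible(x)
}

# subsetting keeps class/units when the result is still a named matrix
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, units = expr_units(x),
                     class = c("expr_matrix", class(out)))
  out
}

#' Read an expression matrix from TSV/CSV
#'
#' First column holds gene symbols, the header row holds sample identifiers.
#' Duplicate gene rows are collapsed: summed for counts (counts are additive),
#' averaged for log2 values.
#'
#' @param path file path; field separator inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param units `"counts"` or `"log2"` - the units the file stores.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, units = c("counts", "log2")) {
  units <- match.arg(units)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2L || nrow(df) == 0L)
    stop("empty expression matrix in ", path, call. = FALSE)
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   df[[j + 1L]][bad[1L]], genes[bad[1L]], samples[j]),
           call. = FALSE)
    vals[, j] <- v
  }
  if (anyDuplicated(genes)) {
    f <- factor(genes, levels = unique(genes))
    agg <- if (units == "counts") rowsum(vals, f) else
      rowsum(vals, f) / as.vector(table(f))
    vals <- agg
    genes <- levels(f)
  }
  dimnames(vals) <- list(genes, samples)
  expression_matrix(vals, units)
}

#' Write an expression matrix to TSV/CSV
#'
#' Inverse of [read_expression_matrix()]; values are written at full
#' precision so a read round-trips exactly.
#'
#' @param x an `expr_matrix`.
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(x),
                   format(unclass(x), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Order of sets and of genes within a set is preserved.
#'
#' @param path GMT file path.
#' @return named list of character vectors (class `gene_sets`), with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                   i, length(f)), call. = FALSE)
    nm <- f[1L]
    if (nm %in% names(sets))
      stop("duplicate gene set name: ", nm, call. = FALSE)
    genes <- unique(f[-(1:2)])
    sets[[nm]] <- genes
    desc[nm] <- f[2L]
  }
  structure(sets, descriptions = desc, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene set collection: %d set(s)\n", length(x)))
  for (nm in utils::head(names(x), 10))
    cat(sprintf("  %s: %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors (or a `gene_sets` object).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug-sensitivity table
#'
#' CSV with columns `drug`, `cell_line`, `auc` (dose-response area under the
#' curve; lower = more sensitive). Repeated (drug, cell line) measurements
#' are aggregated by their median AUC.
#'
#' @param path CSV file path.
#' @return data.frame with columns drug, cell_line, auc; one row per
#'   (drug, cell line) pair.
#' @export
read_drug_sensitivity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "cell_line", "auc")
  if (!all(need %in% colnames(df)))
    stop("drug-sensitivity file needs columns drug, cell_line, auc",
         call. = FALSE)
  drug_sensitivity(df)
}

#' @rdname read_drug_sensitivity
#' @param df data.frame with columns drug, cell_line, auc (repeats allowed).
#' @export
drug_sensitivity <- function(df) {
  if (any(!is.finite(df$auc)))
    stop("AUC values must be finite", call. = FALSE)
  if (any(df$auc < 0))
    stop("negative AUC for drug ", df$drug[which(df$auc < 0)[1L]],
         call. = FALSE)
  agg <- stats::aggregate(auc ~ drug + cell_line, data = df, FUN = stats::median)
  agg <- agg[order(agg$drug, agg$cell_line), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Restrict two expression matrices to their shared genes
#'
#' Both outputs contain exactly the intersection of gene symbols, in the
#' same order (order of appearance in `a`). Matching is case-sensitive on
#' plain symbols; no identifier translation is attempted.
#'
#' @param a,b `expr_matrix` objects.
#' @return list with elements `a` and `b`, gene-aligned.
#' @export
align_genes <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  common <- intersect(rownames(a), rownames(b))
  if (length(common) == 0L)
    stop("no genes shared between the two matrices", call. = FALSE)
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}

#' Mean-center per-gene batch effects on the log2 scale
#'
#' Removes additive per-gene batch offsets: within each batch every gene is
#' shifted so its batch mean equals its grand mean across all samples.
#' With a single batch covariate and no other design terms this equals
#' classical linear batch-effect removal. Apply only to log2-scale values.
#'
#' @param x `expr_matrix` with units log2.
#' @param batch factor/character of length `ncol(x)` giving each sample's batch.
#' @return batch-centered `expr_matrix`.
#' @export
center_batches <- function(x, batch) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_units(x) != "log2")
    stop("batch centering is defined on log2 values", call. = FALSE)
  batch <- as.factor(batch)
  if (length(batch) != ncol(x))
    stop("`batch` must have one entry per sample", call. = FALSE)
  grand <- rowMeans(x)
  out <- unclass(x)
  for (b in levels(batch)) {
    idx <- which(batch == b)
    out[, idx] <- out[, idx, drop = FALSE] -
      (rowMeans(out[, idx, drop = FALSE]) - grand)
  }
  expression_matrix(out, "log2")
}

#' Convert counts to log2 CPM
#'
#' counts -> counts-per-million -> log2(CPM + 1). Log2 input passes through
#' unchanged.
#'
#' @param x `expr_matrix`.
#' @return `expr_matrix` with units log2.
#' @export
log2_cpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_units(x) == "log2") return(x)
  libsize <- colSums(x)
  if (any(libsize == 0))
    stop("sample with zero total counts: ",
         colnames(x)[which(libsize == 0)[1L]], call. = FALSE)
  cpm <- sweep(unclass(x), 2L, libsize, "/") * 1e6
  expression_matrix(log2(cpm + 1), "log2")
}
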