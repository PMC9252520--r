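#' Differential expression between subgroup and controls
#'
#' Counts are converted to log2(CPM + 1); log2 input is used as is. Per gene,
#' a Welch (unequal-variance) t-test compares case against control samples;
#' p-values are Benjamini-Hochberg adjusted. The log2 fold change is the
#' difference of group means on the log scale. Gene rows that are all-zero
#' across both groups are dropped (a message reports how many).
#'
#' @param case,control `expr_matrix` objects with identical units and
#'   gene-aligned rows; each needs >= 2 samples.
#' @return data.frame of class `de_table` with columns gene, log2fc,
#'   mean_expr, p, fdr, ordered by p.
#' @export
differential_expression <- function(case, control) {
  stopifnot(inherits(case, "expr_matrix"), inherits(control, "expr_matrix"))
  if (!identical(rownames(case), rownames(control)))
    stop("case and control must be gene-aligned; see align_genes()",
         call. = FALSE)
  if (ncol(case) < 2L || ncol(control) < 2L)
    stop("need >= 2 samples per group for the t-test", call. = FALSE)
  if (expr_units(case) != expr_units(control))
    stop("case and control units differ", call. = FALSE)

  zero <- rowSums(unclass(case)) == 0 & rowSums(unclass(control)) == 0
  if (any(zero)) {
    message(sum(zero), " all-zero gene row(s) dropped")
    case <- case[!zero, , drop = FALSE]
    control <- control[!zero, , drop = FALSE]
  }
  x <- unclass(log2_cpm(case)); y <- unclass(log2_cpm(control))
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1L, stats::var); vy <- apply(y, 1L, stats::var)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1                # zero-variance genes with equal means
  out <- data.frame(gene = rownames(x),
                    log2fc = mx - my,
                    mean_expr = (mx * nx + my * ny) / (nx + ny),
                    p = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_table", class(out))
  out
}

#' Build the individual disease signature from a DE table
#'
#' Splits significant genes into an up-regulated set (FDR < `fdr_max`,
#' log2FC >= `lfc_min`) and a down-regulated set (FDR < `fdr_max`,
#' log2FC <= -`lfc_min`), each truncated to at most `cap` genes by
#' descending |log2FC|. Both sides must be non-empty for a valid signature.
#'
#' @param de a `de_table`.
#' @param fdr_max FDR cutoff (default 0.05).
#' @param lfc_min minimum |log2FC| (default 1).
#' @param cap maximum genes per direction (default 100; bounds the gene-set
#'   size fed to the KS statistics).
#' @param patient_id,purified provenance recorded in the signature.
#' @return object of class `disease_signature`: list with `up` and `down`
#'   (ordered gene vectors), `log2fc` (named vector over both sets) and
#'   `provenance`.
#' @export
build_signature <- function(de, fdr_max = 0.05, lfc_min = 1, cap = 100L,
                            patient_id = NA_character_, purified = FALSE) {
  stopifnot(inherits(de, "de_table"))
  sig <- de[de$fdr < fdr_max & abs(de$log2fc) >= lfc_min, , drop = FALSE]
  take <- function(d) {
    d <- d[order(-abs(d$log2fc), d$gene), , drop = FALSE]
    utils::head(d, cap)
  }
  up <- take(sig[sig$log2fc > 0, , drop = FALSE])
  down <- take(sig[sig$log2fc < 0, , drop = FALSE])
  if (nrow(up) == 0L || nrow(down) == 0L)
    stop("empty ", if (nrow(up) == 0L) "up" else "down",
         "-regulated set; relax fdr_max/lfc_min or check the input groups",
         call. = FALSE)
  lfc <- stats::setNames(c(up$log2fc, down$log2fc), c(up$gene, down$gene))
  structure(list(up = up$gene, down = down$gene, log2fc = lfc,
                 provenance = list(patient_id = patient_id,
                                   fdr_max = fdr_max, lfc_min = lfc_min,
                                   cap = cap, purified = purified)),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat(sprintf("disease signature: %d up / %d down genes (patient %s%s)\n",
              length(x$up), length(x$down), x$provenance$patient_id,
              if (isTRUE(x$provenance$purified)) ", purified" else ""))
  cat("top up:  ", paste(utils::head(x$up, 5), collapse = ", "), "\n")
  cat("top down:", paste(utils::head(x$down, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Write a disease signature as a two-line GMT file
#'
#' Sets are named `<name>_up` and `<name>_down`.
#'
#' @param sig a `disease_signature`.
#' @param path output path.
#' @param name base set name (default the patient id).
#' @export
write_signature_gmt <- function(sig, path,
                                name = sig$provenance$patient_id) {
  if (is.na(name)) name <- "signature"
  sets <- stats::setNames(list(sig$up, sig$down),
                          paste0(name, c("_up", "_down")))
  write_gmt(sets, path)
}
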