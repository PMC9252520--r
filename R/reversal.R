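#' Construct a perturbation library
#'
#' A perturbation library holds one record per drug treatment (drug, cell
#' line, dose in uM, duration in hours), each carrying a complete ranking of
#' a shared gene universe: rank 1 is the gene most up-regulated by the
#' treatment, rank n the most down-regulated.
#'
#' @param records list of records; each a list with fields `drug`,
#'   `cell_line`, `dose_um`, `time_h` and `ranking` (named integer vector,
#'   a bijection gene -> 1..n over the universe).
#' @param universe character vector of gene symbols shared by all records.
#' @return object of class `perturbation_library`.
#' @export
perturbation_library <- function(records, universe) {
  n <- length(universe)
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (r$dose_um <= 0 || r$time_h <= 0)
      stop("record ", i, ": dose and time must be positive", call. = FALSE)
    rk <- r$ranking
    if (length(rk) != n || !setequal(names(rk), universe) ||
        !setequal(rk, seq_len(n)))
      stop("record ", i, " (", r$drug,
           "): ranking is not a complete permutation of the gene universe",
           call. = FALSE)
  }
  structure(list(records = records, universe = universe),
            class = "perturbation_library")
}

#' @export
print.perturbation_library <- function(x, ...) {
  drugs <- unique(vapply(x$records, `[[`, character(1), "drug"))
  cat(sprintf("perturbation library: %d record(s), %d drug(s), %d-gene universe\n",
              length(x$records), length(drugs), length(x$universe)))
  invisible(x)
}

#' Read/write a perturbation library in long TSV form
#'
#' Long format, one row per (treatment, gene): columns
#' `drug, cell_line, dose_um, time_h, gene, rank`.
#'
#' @param path file path.
#' @return a `perturbation_library`.
#' @export
read_perturbation_library <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("drug", "cell_line", "dose_um", "time_h", "gene", "rank")
  if (!all(need %in% colnames(df)))
    stop("perturbation TSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- interaction(df$drug, df$cell_line, df$dose_um, df$time_h, drop = TRUE)
  universe <- sort(unique(df$gene))
  records <- lapply(split(df, key), function(d) {
    list(drug = d$drug[1L], cell_line = d$cell_line[1L],
         dose_um = d$dose_um[1L], time_h = d$time_h[1L],
         ranking = stats::setNames(as.integer(d$rank), d$gene))
  })
  names(records) <- NULL
  perturbation_library(records, universe)
}

#' @rdname read_perturbation_library
#' @param lib a `perturbation_library`.
#' @export
write_perturbation_library <- function(lib, path) {
  rows <- lapply(lib$records, function(r)
    data.frame(drug = r$drug, cell_line = r$cell_line, dose_um = r$dose_um,
               time_h = r$time_h, gene = names(r$ranking),
               rank = unname(r$ranking), stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two-sided Kolmogorov-Smirnov enrichment of a gene set in a ranking
#'
#' With V(1) < ... < V(t) the sorted ranks of the set's genes in an n-gene
#' ranking, the two one-sided KS statistics are
#' `a = max_j( j/t - V(j)/n )` (enrichment toward the top) and
#' `b = max_j( V(j)/n - (j-1)/t )` (enrichment toward the bottom).
#' The signed enrichment score is `a` if `a > b`, `-b` if `b > a`, and `+a`
#' on an exact tie.
#'
#' @param gene_set character vector of gene symbols.
#' @param ranking named integer vector (gene -> rank, bijective onto 1..n),
#'   or a perturbation record holding one.
#' @param min_overlap minimum genes of the set present in the ranking
#'   (default 5); smaller overlaps return NULL and a message, as such a
#'   score would be dominated by noise.
#' @return object of class `ks_result` (fields `a`, `b`, `es`, `t`, `n`),
#'   or NULL when the overlap is insufficient.
#' @export
ks_enrichment <- function(gene_set, ranking, min_overlap = 5L) {
  if (is.list(ranking) && !is.null(ranking$ranking)) ranking <- ranking$ranking
  n <- length(ranking)
  V <- sort(unname(ranking[intersect(gene_set, names(ranking))]))
  t <- length(V)
  if (t < min_overlap) {
    message(sprintf("gene set overlap %d < min_overlap %d; set rejected",
                    t, min_overlap))
    return(NULL)
  }
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  es <- if (a >= b) a else -b
  structure(list(a = a, b = b, es = es, t = t, n = n), class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS enrichment: a = %.4f, b = %.4f, es = %+.4f (t = %d, n = %d)\n",
              x$a, x$b, x$es, x$t, x$n))
  invisible(x)
}

#' Connectivity (RGES) of a disease signature with one treatment
#'
#' Scores the up- and down-regulated signature sets separately with
#' [ks_enrichment()] and combines them: when the two enrichment scores have
#' opposite signs, `rges = es_up - es_down`; when they share a sign the
#' treatment neither mimics nor reverses the signature coherently and
#' `rges = 0`. Positive RGES means the drug mimics the disease pattern;
#' negative RGES means it reverses it.
#'
#' @param sig a `disease_signature`.
#' @param record one perturbation record (see [perturbation_library()]).
#' @param min_overlap per-set overlap requirement passed to
#'   [ks_enrichment()]; a record failing it on either set is skipped
#'   (returns NULL with a message).
#' @return object of class `rges_record` (drug, cell_line, dose_um, time_h,
#'   es_up, es_down, rges), or NULL.
#' @export
rges_score <- function(sig, record, min_overlap = 5L) {
  ks_up <- ks_enrichment(sig$up, record$ranking, min_overlap)
  ks_down <- ks_enrichment(sig$down, record$ranking, min_overlap)
  if (is.null(ks_up) || is.null(ks_down)) {
    message(sprintf("record %s (%s, %g uM, %g h) skipped: signature overlap below %d",
                    record$drug, record$cell_line, record$dose_um,
                    record$time_h, min_overlap))
    return(NULL)
  }
  rges <- if (sign(ks_up$es) != sign(ks_down$es)) ks_up$es - ks_down$es else 0
  structure(list(drug = record$drug, cell_line = record$cell_line,
                 dose_um = record$dose_um, time_h = record$time_h,
                 es_up = ks_up$es, es_down = ks_down$es, rges = rges),
            class = "rges_record")
}

#' Score every treatment of a library against a signature
#'
#' @param sig a `disease_signature`.
#' @param lib a `perturbation_library`.
#' @param min_overlap per-set overlap requirement (default 5).
#' @return data.frame of class `rges_table` with one row per scored record
#'   (columns drug, cell_line, dose_um, time_h, es_up, es_down, rges);
#'   attribute `n_skipped` counts records rejected for insufficient overlap.
#' @export
score_library <- function(sig, lib, min_overlap = 5L) {
  stopifnot(inherits(lib, "perturbation_library"))
  scored <- lapply(lib$records, rges_score, sig = sig,
                   min_overlap = min_overlap)
  keep <- !vapply(scored, is.null, logical(1))
  if (!any(keep))
    stop("no record met the signature overlap requirement", call. = FALSE)
  out <- do.call(rbind, lapply(scored[keep], function(r)
    data.frame(r[c("drug", "cell_line", "dose_um", "time_h",
                   "es_up", "es_down", "rges")], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!keep)
  class(out) <- c("rges_table", class(out))
  out
}

# treatment class of each row: dose low (<10 uM) / high (>=10), time short
# (<24 h) / long (>=24); reference class is (high, long) = (10 uM, 24 h)
treatment_class <- function(dose_um, time_h) {
  paste(ifelse(dose_um >= 10, "high", "low"),
        ifelse(time_h >= 24, "long", "short"), sep = ".")
}

#' Fit the reward model standardizing RGES across treatment conditions
#'
#' Treatments are binned into dose (low < 10 uM / high >= 10 uM) x time
#' (short < 24 h / long >= 24 h) classes; (high, long) - the standard
#' 10 uM / 24 h condition - is the reference with offset 0. For every other
#' class, the additive offset is the mean, over drugs measured in both the
#' reference and that class, of (drug's mean reference RGES - drug's mean
#' class RGES); a class with no paired drugs gets offset 0. Adding the
#' offset to a non-reference RGES standardizes it to the reference
#' condition.
#'
#' @param rges a `rges_table` from [score_library()].
#' @return object of class `reward_model`: data.frame with columns
#'   dose_class, time_class, offset.
#' @export
fit_reward_model <- function(rges) {
  cls <- treatment_class(rges$dose_um, rges$time_h)
  grid <- expand.grid(dose_class = c("high", "low"),
                      time_class = c("long", "short"),
                      stringsAsFactors = FALSE)
  grid$offset <- 0
  drug_cls_mean <- stats::aggregate(rges$rges,
                                    list(drug = rges$drug, cls = cls), mean)
  ref <- drug_cls_mean[drug_cls_mean$cls == "high.long", , drop = FALSE]
  for (i in seq_len(nrow(grid))) {
    key <- paste(grid$dose_class[i], grid$time_class[i], sep = ".")
    if (key == "high.long") next
    tgt <- drug_cls_mean[drug_cls_mean$cls == key, , drop = FALSE]
    paired <- merge(ref, tgt, by = "drug", suffixes = c(".ref", ".tgt"))
    if (nrow(paired) > 0L)
      grid$offset[i] <- mean(paired$x.ref - paired$x.tgt)
  }
  structure(grid, class = c("reward_model", class(grid)))
}

#' Summarize standardized RGES into one sRGES per drug
#'
#' Each record's RGES is standardized by adding its treatment class's
#' reward-model offset; a drug's sRGES is the unweighted mean of its
#' standardized values across all its treatments. Lower sRGES means
#' stronger reversal of the disease signature.
#'
#' @param rges a `rges_table`.
#' @param model a `reward_model` (default: fitted from `rges` itself).
#' @return data.frame of class `srges_table` with columns drug, srges,
#'   n_treatments, sorted ascending by srges (strongest reversers first).
#' @export
summarize_srges <- function(rges, model = fit_reward_model(rges)) {
  if (nrow(rges) == 0L) stop("no scored treatments", call. = FALSE)
  cls <- treatment_class(rges$dose_um, rges$time_h)
  key <- paste(model$dose_class, model$time_class, sep = ".")
  std <- rges$rges + model$offset[match(cls, key)]
  agg <- stats::aggregate(std, list(drug = rges$drug),
                          function(v) c(mean(v), length(v)))
  out <- data.frame(drug = agg$drug, srges = agg$x[, 1L],
                    n_treatments = as.integer(agg$x[, 2L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$srges, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("srges_table", class(out))
  out
}

#' Score and rank a drug library for signature reversal
#'
#' Convenience wrapper: [score_library()], [fit_reward_model()],
#' [summarize_srges()] in one call.
#'
#' @inheritParams score_library
#' @return a `srges_table`; the per-treatment `rges_table` and the fitted
#'   `reward_model` are attached as attributes `rges` and `reward_model`.
#' @export
srges <- function(sig, lib, min_overlap = 5L) {
  rges <- score_library(sig, lib, min_overlap)
  model <- fit_reward_model(rges)
  out <- summarize_srges(rges, model)
  attr(out, "rges") <- rges
  attr(out, "reward_model") <- model
  out
}
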