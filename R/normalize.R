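#' Log-transform a TPM matrix
#'
#' Elementwise \eqn{L = \log_2(\mathrm{TPM} + 1)}, the scale on which all
#' mixture fitting and summaries operate. Maps TPM 0 to 0 and TPM 1 to 1, so
#' the conventional TPM >= 1 cutoff is the same number on both scales.
#'
#' @param m Non-negative numeric matrix (or vector) of TPM values.
#' @return Matrix of the same shape and labels in log2(TPM+1) units.
#' @export
log_transform <- function(m) {
  if (any(!is.finite(m)) || any(m < 0))
    tpmeta_stop("tpmeta_bad_value", "TPM values must be finite and >= 0")
  out <- log2(m + 1)
  attr(out, "gene_symbols") <- attr(m, "gene_symbols")
  out
}

#' Merge studies into one global log-expression matrix
#'
#' Restricts every study to the genes common to all studies (sorted by gene
#' id), log-transforms, and concatenates the run columns in study order. The
#' number of genes each study loses to the intersection is reported via
#' `message()` so the restriction can be audited.
#'
#' @param s A `study_set` of TPM matrices.
#' @return A `global_log_matrix`: list with `values` (genes x runs,
#'   log2(TPM+1)), `run_study` (named character, run id -> study id),
#'   `gene_symbols`, and `normalized` (FALSE until [quantile_normalize()]).
#' @export
merge_studies <- function(s) {
  if (!inherits(s, "study_set") || s$n_studies < 2L)
    tpmeta_stop("tpmeta_bad_args", "need a study_set with at least 2 studies")
  gene_sets <- lapply(s$studies, rownames)
  common <- Reduce(intersect, gene_sets)
  if (length(common) == 0L)
    tpmeta_stop("tpmeta_empty", "no genes are shared by all studies")
  common <- sort(common)
  for (sid in names(s$studies)) {
    lost <- nrow(s$studies[[sid]]) - length(common)
    if (lost > 0L)
      message(sprintf("merge_studies: study '%s' loses %d gene(s) outside the intersection",
                      sid, lost))
  }
  blocks <- lapply(s$studies, function(m) log_transform(m[common, , drop = FALSE]))
  values <- do.call(cbind, unname(blocks))
  run_study <- setNames(
    rep(names(s$studies), vapply(s$studies, ncol, integer(1))),
    colnames(values))
  sym <- attr(s$studies[[1]], "gene_symbols")
  structure(list(values = values,
                 run_study = run_study,
                 gene_symbols = if (!is.null(sym)) sym[common] else setNames(common, common),
                 normalized = FALSE),
            class = "global_log_matrix")
}

#' @export
print.global_log_matrix <- function(x, ...) {
  cat(sprintf("<global_log_matrix> %d genes x %d runs (%d studies), %s\n",
              nrow(x$values), ncol(x$values), length(unique(x$run_study)),
              if (x$normalized) "quantile-normalized" else "raw log2(TPM+1)"))
  invisible(x)
}

#' Quantile-normalize the global matrix across all runs
#'
#' Classic rank-based quantile normalization, applied jointly to all run
#' columns to remove residual cross-study batch effects: the reference
#' distribution is the per-rank mean of the column-sorted values and each
#' entry is replaced by the reference value at its within-column rank, ties
#' receiving the mean of the reference values over the tied rank range.
#' After normalization every column holds the same multiset of values.
#' Delegates the computation to `limma::normalizeQuantiles()`.
#'
#' @param g A `global_log_matrix` with `normalized = FALSE`.
#' @return The same object with normalized values and `normalized = TRUE`.
#' @export
quantile_normalize <- function(g) {
  if (!inherits(g, "global_log_matrix"))
    tpmeta_stop("tpmeta_bad_args", "g must be a global_log_matrix")
  if (isTRUE(g$normalized))
    tpmeta_stop("tpmeta_double_normalize",
                "matrix is already quantile-normalized")
  if (nrow(g$values) < 2L || ncol(g$values) < 2L)
    tpmeta_stop("tpmeta_bad_args", "need at least 2 genes and 2 runs")
  norm <- limma::normalizeQuantiles(g$values, ties = TRUE)
  dimnames(norm) <- dimnames(g$values)
  g$values <- norm
  g$normalized <- TRUE
  g
}

#' Dump a global log matrix to TSV
#'
#' Writes the matrix with a leading `# normalized=true|false` comment line so
#' the normalization state travels with the file.
#'
#' @param g A `global_log_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_global_matrix <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalized=%s", tolower(as.character(g$normalized))), con)
  out <- data.frame(gene_id = rownames(g$values),
                    gene_symbol = unname(g$gene_symbols[rownames(g$values)]),
                    g$values, check.names = FALSE, stringsAsFactors = FALSE)
  writeLines(paste(colnames(out), collapse = "\t"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
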