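#' Per-gene within-study means
#'
#' Averages each gene's log2(TPM+1) values over the runs of each study,
#' reducing the global matrix to one column per study — the unit of
#' replication for the cross-study statistics.
#'
#' @param g A `global_log_matrix`.
#' @return Genes-by-studies numeric matrix of within-study means.
#' @export
within_study_means <- function(g) {
  if (!inherits(g, "global_log_matrix"))
    tpmeta_stop("tpmeta_bad_args", "g must be a global_log_matrix")
  study_ids <- unique(g$run_study)
  out <- vapply(study_ids, function(sid) {
    rowMeans(g$values[, g$run_study == sid, drop = FALSE])
  }, numeric(nrow(g$values)))
  dimnames(out) <- list(rownames(g$values), study_ids)
  out
}

#' Cross-study mean and confidence interval per gene
#'
#' Treats each study's within-study mean as one independent observation
#' (n = number of studies) and reports, per gene, the overall mean and the
#' two-sided t confidence interval
#' \eqn{\bar{x} \pm t_{(1+c)/2,\,n-1}\, s/\sqrt{n}} on the study means.
#'
#' @param study_means Genes-by-studies matrix from [within_study_means()].
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @return Data.frame with `gene_id`, `cross_mean`, `ci_low`, `ci_high`,
#'   `n_studies`.
#' @export
cross_study_summary <- function(study_means, confidence = 0.95) {
  if (is.null(dim(study_means)) || ncol(study_means) < 2L)
    tpmeta_stop("tpmeta_too_few",
                "confidence interval needs at least 2 studies")
  if (!(confidence > 0 && confidence < 1))
    tpmeta_stop("tpmeta_bad_args", "confidence must be in (0, 1)")
  n <- ncol(study_means)
  m <- rowMeans(study_means)
  sdev <- apply(study_means, 1L, sd)
  half <- qt((1 + confidence) / 2, df = n - 1) * sdev / sqrt(n)
  data.frame(gene_id = rownames(study_means),
             cross_mean = unname(m),
             ci_low = unname(m - half),
             ci_high = unname(m + half),
             n_studies = n,
             stringsAsFactors = FALSE)
}

#' Flag genes as expressed at a threshold
#'
#' A gene is expressed when its cross-study mean log2(TPM+1) is at or above
#' the threshold (inclusive, matching the conventional "TPM >= 1" rule, which
#' is tau = 1 on the log scale).
#'
#' @param summary Data.frame with a `cross_mean` column.
#' @param tau Threshold in log2(TPM+1) units (default 1).
#' @return `summary` with a logical `expressed` column.
#' @export
classify_expressed <- function(summary, tau = 1) {
  if (any(!is.finite(summary$cross_mean)))
    tpmeta_stop("tpmeta_bad_value", "cross_mean must be finite")
  summary$expressed <- summary$cross_mean >= tau
  summary
}

#' Restrict summaries to the gene-of-interest panel
#'
#' Keeps only panel genes (joined on `gene_id`) and annotates each with its
#' category and report class. Panel genes absent from the expression data are
#' returned in the `missing` attribute rather than silently dropped.
#'
#' @param summaries Per-gene summary data.frame (must contain `gene_id`).
#' @param panel Panel data.frame from [read_goi_panel()] or
#'   [simulate_goi_panel()].
#' @return The panel-restricted summaries with `gene_symbol`, `category` and
#'   `class` columns; attribute `missing` lists absent panel gene ids.
#' @export
filter_goi <- function(summaries, panel) {
  if (is.null(panel) || nrow(panel) == 0L)
    tpmeta_stop("tpmeta_empty", "GOI panel is empty")
  idx <- match(panel$gene_id, summaries$gene_id)
  present <- !is.na(idx)
  out <- summaries[idx[present], , drop = FALSE]
  out$gene_symbol <- panel$gene_symbol[present]
  out$category <- panel$category[present]
  out$class <- panel$class[present]
  rownames(out) <- NULL
  first <- c("gene_id", "gene_symbol", "category", "class")
  out <- out[, c(first, setdiff(names(out), first))]
  attr(out, "missing") <- panel$gene_id[!present]
  out
}

#' Pairwise Pearson correlation between studies over the panel genes
#'
#' Summarizes each study by its vector of within-study mean log-expression
#' over the panel genes and computes the Pearson correlation for every study
#' pair — the concordance check performed on quantile-normalized values in
#' the meta-analysis.
#'
#' @param g A `global_log_matrix` (typically quantile-normalized).
#' @param panel GOI panel data.frame; at least 3 panel genes must be present.
#' @param use_runs If `TRUE`, correlate per-run profiles study-pair-wise
#'   (pooling runs) instead of per-study mean vectors. Default `FALSE`.
#' @return Symmetric studies-by-studies correlation matrix with unit
#'   diagonal.
#' @export
pairwise_study_correlation <- function(g, panel, use_runs = FALSE) {
  if (!inherits(g, "global_log_matrix"))
    tpmeta_stop("tpmeta_bad_args", "g must be a global_log_matrix")
  study_ids <- unique(g$run_study)
  if (length(study_ids) < 2L)
    tpmeta_stop("tpmeta_bad_args", "need at least 2 studies")
  genes <- intersect(panel$gene_id, rownames(g$values))
  if (length(genes) < 3L)
    tpmeta_stop("tpmeta_too_few",
                "need at least 3 panel genes present in the matrix")
  means <- within_study_means(
    structure(list(values = g$values[genes, , drop = FALSE],
                   run_study = g$run_study,
                   gene_symbols = g$gene_symbols[genes],
                   normalized = g$normalized),
              class = "global_log_matrix"))
  zero_var <- study_ids[apply(means, 2L, sd) == 0]
  if (length(zero_var))
    tpmeta_stop("tpmeta_degenerate",
                sprintf("study '%s' has zero variance over the panel genes",
                        zero_var[1]))
  if (!use_runs) {
    r <- cor(means)
  } else {
    r <- diag(1, length(study_ids))
    dimnames(r) <- list(study_ids, study_ids)
    for (i in seq_along(study_ids)) for (j in seq_along(study_ids)) {
      if (i < j) {
        vi <- rowMeans(g$values[genes, g$run_study == study_ids[i], drop = FALSE])
        vj <- rowMeans(g$values[genes, g$run_study == study_ids[j], drop = FALSE])
        r[i, j] <- r[j, i] <- cor(vi, vj)
      }
    }
  }
  diag(r) <- 1
  r
}

#' Group expressed genes by report class and rank by mean expression
#'
#' Splits the expressed genes into the three report classes (transporter,
#' pore, receptor) and orders each table by decreasing cross-study mean, the
#' layout of the rank-ordered expression reports. Ties are broken by gene id
#' ascending so output files are deterministic.
#'
#' @param summaries Classified, panel-annotated summaries (needs `expressed`,
#'   `class`, `cross_mean`, `gene_id`).
#' @return Named list of three data.frames: `transporter`, `pore`,
#'   `receptor` (possibly empty).
#' @export
group_and_rank <- function(summaries) {
  need <- c("expressed", "class", "cross_mean", "gene_id")
  if (!all(need %in% names(summaries)))
    tpmeta_stop("tpmeta_bad_args",
                paste("summaries must contain:", paste(need, collapse = ", ")))
  expressed <- summaries[summaries$expressed, , drop = FALSE]
  out <- lapply(c(transporter = "transporter", pore = "pore",
                  receptor = "receptor"), function(cl) {
    tab <- expressed[expressed$class == cl, , drop = FALSE]
    tab <- tab[order(-tab$cross_mean, tab$gene_id), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
  out
}

#' Full per-gene meta-analysis summary table
#'
#' Convenience wrapper chaining [within_study_means()],
#' [cross_study_summary()], [classify_expressed()] and [filter_goi()]: one
#' row per panel gene with its within-study means, cross-study mean, CI and
#' expressed flag.
#'
#' @param g A quantile-normalized `global_log_matrix`.
#' @param panel GOI panel data.frame.
#' @param tau Expression threshold, log2(TPM+1) units.
#' @param confidence Confidence level for the cross-study CI.
#' @return Panel-annotated summary data.frame (see [filter_goi()]); the
#'   within-study means are included as one column per study.
#' @export
gene_summary_table <- function(g, panel, tau = 1, confidence = 0.95) {
  sm <- within_study_means(g)
  summaries <- cross_study_summary(sm, confidence)
  summaries <- classify_expressed(summaries, tau)
  out <- filter_goi(summaries, panel)
  sm_panel <- sm[out$gene_id, , drop = FALSE]
  colnames(sm_panel) <- paste0("mean_", colnames(sm_panel))
  res <- cbind(out[, c("gene_id", "gene_symbol", "category", "class")],
               as.data.frame(sm_panel, optional = TRUE),
               out[, c("cross_mean", "ci_low", "ci_high", "n_studies",
                       "expressed")])
  rownames(res) <- NULL
  attr(res, "missing") <- attr(out, "missing")
  res
}
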