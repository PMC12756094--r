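#' Read a gene-level TPM expression table
#'
#' Expects a tab-separated file with header
#' `gene_id<TAB>gene_symbol<TAB><run_id>...` and a numeric, non-negative body
#' — the shape of RSEM gene-level output summarized to TPM. Labels are kept
#' in file order.
#'
#' @param path Path to the TSV file.
#' @return A genes-by-runs numeric matrix with `gene_id` rownames, `run_id`
#'   colnames and a `gene_symbols` attribute (named by gene id).
#' @export
read_expression_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2),
                          data.table = FALSE)
  if (ncol(dt) < 3L || !identical(names(dt)[1:2], c("gene_id", "gene_symbol")))
    tpmeta_stop("tpmeta_bad_header",
                sprintf("'%s': header must start 'gene_id\\tgene_symbol' followed by run columns", path))
  dup <- which(duplicated(dt$gene_id))
  if (length(dup))
    tpmeta_stop("tpmeta_duplicate_gene",
                sprintf("'%s': duplicate gene_id '%s' at data row %d",
                        path, dt$gene_id[dup[1]], dup[1]))
  vals <- as.matrix(dt[, -(1:2), drop = FALSE])
  if (!is.numeric(vals))
    tpmeta_stop("tpmeta_bad_value",
                sprintf("'%s': non-numeric expression values", path))
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad))
    tpmeta_stop("tpmeta_bad_value",
                sprintf("'%s': negative or non-finite TPM for gene '%s', run '%s'",
                        path, dt$gene_id[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  if (anyDuplicated(colnames(vals)))
    tpmeta_stop("tpmeta_duplicate_run", sprintf("'%s': duplicate run ids", path))
  rownames(vals) <- dt$gene_id
  attr(vals, "gene_symbols") <- setNames(dt$gene_symbol, dt$gene_id)
  vals
}

#' Write an expression matrix in the format read_expression_table() reads
#' @param m Genes-by-runs TPM matrix (with optional `gene_symbols` attribute).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(m, path) {
  sym <- attr(m, "gene_symbols")
  if (is.null(sym)) sym <- setNames(rownames(m), rownames(m))
  out <- data.frame(gene_id = rownames(m),
                    gene_symbol = unname(sym[rownames(m)]),
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a run-metadata table
#'
#' Tab-separated with header `study_id  run_id  treated  library_layout`;
#' `treated` is logical (TRUE/FALSE or 0/1), `library_layout` is `PE` or `SE`.
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with one row per run.
#' @export
read_run_metadata <- function(path) {
  md <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("study_id", "run_id", "treated", "library_layout")
  if (!all(need %in% names(md)))
    tpmeta_stop("tpmeta_bad_header",
                sprintf("'%s': metadata must have columns %s",
                        path, paste(need, collapse = ", ")))
  md <- md[, need]
  md$treated <- as.logical(md$treated)
  if (anyNA(md$treated))
    tpmeta_stop("tpmeta_bad_value", sprintf("'%s': non-logical 'treated' values", path))
  if (!all(md$library_layout %in% c("PE", "SE")))
    tpmeta_stop("tpmeta_bad_value",
                sprintf("'%s': library_layout must be PE or SE", path))
  if (anyDuplicated(md[, c("study_id", "run_id")]))
    tpmeta_stop("tpmeta_duplicate_run",
                sprintf("'%s': duplicated (study_id, run_id)", path))
  md
}

#' Retain only untreated control runs
#'
#' Filters the run metadata to the untreated control samples, the selection
#' rule of the meta-analysis. Studies left without any usable run are dropped
#' with a warning so a single all-treated study does not abort the pipeline.
#'
#' @param metadata Data.frame as returned by [read_run_metadata()].
#' @return The rows with `treated == FALSE`, original order preserved.
#' @export
select_control_runs <- function(metadata) {
  if (is.null(metadata) || nrow(metadata) == 0L)
    tpmeta_stop("tpmeta_empty", "metadata is empty")
  keep <- metadata[!metadata$treated, , drop = FALSE]
  lost <- setdiff(unique(metadata$study_id), unique(keep$study_id))
  for (s in lost)
    warning(sprintf("study '%s' has no untreated control runs and is dropped", s),
            call. = FALSE)
  keep
}

#' Assemble the study set from expression tables and selected runs
#'
#' Restricts each study's expression matrix to its selected control runs (in
#' metadata order) and assembles the ordered series-to-runs hierarchy the
#' downstream stages operate on. Studies present in `tables` but absent from
#' `selected` are ignored.
#'
#' @param tables Named list mapping `study_id` to a genes-by-runs TPM matrix.
#' @param selected Metadata rows of the runs to keep (e.g. the output of
#'   [select_control_runs()]).
#' @return A `study_set`: list with `studies` (named list of matrices) and
#'   `n_studies`.
#' @export
assemble_study_set <- function(tables, selected) {
  if (nrow(selected) == 0L)
    tpmeta_stop("tpmeta_empty", "no runs selected")
  study_ids <- unique(selected$study_id)
  missing_tab <- setdiff(study_ids, names(tables))
  if (length(missing_tab))
    tpmeta_stop("tpmeta_missing_study",
                paste("no expression table for study:",
                      paste(missing_tab, collapse = ", ")))
  studies <- lapply(study_ids, function(sid) {
    runs <- selected$run_id[selected$study_id == sid]
    m <- tables[[sid]]
    absent <- setdiff(runs, colnames(m))
    if (length(absent))
      tpmeta_stop("tpmeta_missing_run",
                  sprintf("study '%s': run '%s' not found in its expression table",
                          sid, absent[1]))
    m2 <- m[, runs, drop = FALSE]
    attr(m2, "gene_symbols") <- attr(m, "gene_symbols")
    m2
  })
  names(studies) <- study_ids
  new_study_set(studies)
}

new_study_set <- function(studies) {
  stopifnot(is.list(studies), !is.null(names(studies)),
            !anyDuplicated(names(studies)))
  all_runs <- unlist(lapply(studies, colnames), use.names = FALSE)
  if (anyDuplicated(all_runs))
    tpmeta_stop("tpmeta_duplicate_run", "run ids must be unique across studies")
  structure(list(studies = studies, n_studies = length(studies)),
            class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf("<study_set> %d studies, %d runs total\n", x$n_studies,
              sum(vapply(x$studies, ncol, integer(1)))))
  for (sid in names(x$studies))
    cat(sprintf("  %s: %d genes x %d runs\n", sid,
                nrow(x$studies[[sid]]), ncol(x$studies[[sid]])))
  invisible(x)
}

#' Read and validate a gene-of-interest panel
#'
#' Comma-separated with header `gene_id,gene_symbol,category,class`.
#' Categories must be among ion_channel, aquaporin, atpase, slc, receptor;
#' the report class is recomputed from the category (atpase/slc ->
#' transporter, ion_channel/aquaporin -> pore, receptor -> receptor) and any
#' mismatch with the stored class is rejected.
#'
#' @param path Path to the panel CSV.
#' @return A validated panel data.frame.
#' @export
read_goi_panel <- function(path) {
  panel <- data.table::fread(path, sep = ",", header = TRUE,
                             colClasses = "character", data.table = FALSE)
  need <- c("gene_id", "gene_symbol", "category", "class")
  if (!identical(names(panel), need))
    tpmeta_stop("tpmeta_bad_header",
                sprintf("'%s': panel header must be %s", path,
                        paste(need, collapse = ",")))
  if (nrow(panel) == 0L) return(panel)
  unknown <- setdiff(unique(panel$category), names(goi_class_map()))
  if (length(unknown))
    tpmeta_stop("tpmeta_bad_category",
                sprintf("'%s': unknown category '%s'", path, unknown[1]))
  dup <- which(duplicated(panel$gene_id))
  if (length(dup))
    tpmeta_stop("tpmeta_duplicate_gene",
                sprintf("'%s': duplicate gene_id '%s'", path, panel$gene_id[dup[1]]))
  expected <- unname(goi_class_map()[panel$category])
  bad <- which(panel$class != expected)
  if (length(bad))
    tpmeta_stop("tpmeta_bad_class",
                sprintf("'%s': gene '%s' has class '%s' but category '%s' implies '%s'",
                        path, panel$gene_id[bad[1]], panel$class[bad[1]],
                        panel$category[bad[1]], expected[bad[1]]))
  panel
}

#' Write a gene-of-interest panel CSV
#' @param panel Panel data.frame (`gene_id`, `gene_symbol`, `category`, `class`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_goi_panel <- function(panel, path) {
  data.table::fwrite(panel[, c("gene_id", "gene_symbol", "category", "class")],
                     path, sep = ",")
  invisible(path)
}
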