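# Shared builders and independent oracles for the test suite.

# genes-by-runs TPM matrix with labels and symbols
make_expr <- function(values,
                      gene_ids = sprintf("g%02d", seq_len(NROW(values))),
                      run_ids = sprintf("r%02d",
                                        seq_len(length(values) / length(gene_ids))),
                      symbols = toupper(gene_ids)) {
  m <- matrix(values, nrow = length(gene_ids), ncol = length(run_ids),
              dimnames = list(gene_ids, run_ids))
  attr(m, "gene_symbols") <- stats::setNames(symbols, gene_ids)
  m
}

# global_log_matrix straight from a numeric matrix (one study per column
# unless run_study says otherwise)
make_global <- function(values, run_study = NULL, normalized = FALSE) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("r%02d", seq_len(ncol(values)))
  if (is.null(run_study))
    run_study <- stats::setNames(sprintf("s%02d", seq_len(ncol(values))),
                                 colnames(values))
  structure(list(values = values, run_study = run_study,
                 gene_symbols = stats::setNames(toupper(rownames(values)),
                                                rownames(values)),
                 normalized = normalized),
            class = "global_log_matrix")
}

# hand-rolled gmm3_fit for boundary tests
make_fit <- function(weights, means, sds, converged = TRUE) {
  structure(list(weights = weights, means = means, sds = sds,
                 log_likelihood = 0, ll_trace = numeric(0), n_iter = 1L,
                 converged = converged, boundary_log = NA_real_,
                 boundary_tpm = NA_real_, n = 0L),
            class = "gmm3_fit")
}

# independent bisection oracle for the weighted-density intersection
bisect_boundary <- function(w2, w3, m2, m3, s2, s3, tol = 1e-12) {
  f <- function(x) w2 * stats::dnorm(x, m2, s2) - w3 * stats::dnorm(x, m3, s3)
  lo <- m2 + (m3 - m2) * 1e-9
  hi <- m3 - (m3 - m2) * 1e-9
  if (sign(f(lo)) * sign(f(hi)) > 0) return(NA_real_)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# study_set from ready-made matrices (wraps the internal constructor)
make_study_set <- function(...) {
  studies <- list(...)
  if (is.null(names(studies)) || any(!nzchar(names(studies))))
    names(studies) <- sprintf("s%d", seq_along(studies))
  tpmeta:::new_study_set(studies)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "tpmeta", mustWork = TRUE)
}
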