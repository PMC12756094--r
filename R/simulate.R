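#' Configuration for the multi-study expression simulator
#'
#' Collects and validates the parameters of the synthetic-data generator. The
#' defaults describe the reference simulation scenario used throughout the
#' package: eight studies with the usable run counts of the real hCMEC/D3
#' meta-analysis (8, 3, 2, 2, 4, 3, 3, 5 — thirty runs in total), 20,000
#' genes, and a three-component log2(TPM+1) mixture whose background and
#' expressed components intersect exactly at log2(TPM+1) = 1, i.e. TPM = 1.
#'
#' @param n_studies Number of studies (series).
#' @param runs_per_study Integer vector of runs per study; recycled to
#'   `n_studies` if scalar.
#' @param n_genes Number of genes shared by all studies.
#' @param mixture_weights Proportions \eqn{(\pi_1,\pi_2,\pi_3)} of the null,
#'   background and expressed components; must be non-negative and sum to 1.
#' @param mixture_means Component means in log2(TPM+1) units, strictly
#'   increasing.
#' @param mixture_sds Component standard deviations (log2 units), positive.
#' @param batch_shift_sd SD of the per-study additive shift in log space.
#' @param replicate_noise_sd SD of the per-run, per-gene noise in log space.
#' @param seed Integer seed governing every random draw of the simulation.
#' @param rescale_tpm If `TRUE`, each run column is rescaled so its TPM values
#'   sum to 1,000,000 (the defining property of real TPM). The default is
#'   `FALSE` so that the configured mixture is exactly the log2(TPM+1)
#'   distribution of the emitted values and the analytic boundary recorded in
#'   the simulation truth applies to the observed data; rescaling multiplies
#'   all TPMs by 1e6 divided by the raw column sum, which shifts the
#'   log-space mixture by roughly that factor's log2 (see the methods
#'   vignette).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_studies = 8L,
                       runs_per_study = c(8L, 3L, 2L, 2L, 4L, 3L, 3L, 5L),
                       n_genes = 20000L,
                       mixture_weights = c(0.4, 0.3, 0.3),
                       mixture_means = c(0.02, 0.5, 1.5),
                       mixture_sds = c(0.02, 0.3, 0.3),
                       batch_shift_sd = 0.05,
                       replicate_noise_sd = 0.1,
                       seed = 1L,
                       rescale_tpm = FALSE) {
  n_studies <- as.integer(n_studies)
  if (length(runs_per_study) == 1L)
    runs_per_study <- rep(as.integer(runs_per_study), n_studies)
  runs_per_study <- as.integer(runs_per_study)
  if (is.na(n_studies) || n_studies < 1L)
    tpmeta_stop("tpmeta_bad_config", "n_studies must be >= 1")
  if (length(runs_per_study) != n_studies || any(runs_per_study < 1L))
    tpmeta_stop("tpmeta_bad_config",
                "runs_per_study must give a count >= 1 for each study")
  if (as.integer(n_genes) < 1L)
    tpmeta_stop("tpmeta_bad_config", "n_genes must be >= 1")
  if (length(mixture_weights) != 3L || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-8)
    tpmeta_stop("tpmeta_bad_config",
                "mixture_weights must be 3 non-negative proportions summing to 1")
  if (length(mixture_means) != 3L || is.unsorted(mixture_means, strictly = TRUE))
    tpmeta_stop("tpmeta_bad_config",
                "mixture_means must be 3 strictly increasing values")
  if (length(mixture_sds) != 3L || any(mixture_sds <= 0))
    tpmeta_stop("tpmeta_bad_config", "mixture_sds must be 3 positive values")
  if (batch_shift_sd < 0 || replicate_noise_sd < 0)
    tpmeta_stop("tpmeta_bad_config", "noise SDs must be non-negative")
  structure(list(
    n_studies = n_studies,
    runs_per_study = runs_per_study,
    n_genes = as.integer(n_genes),
    mixture_weights = as.numeric(mixture_weights),
    mixture_means = as.numeric(mixture_means),
    mixture_sds = as.numeric(mixture_sds),
    batch_shift_sd = as.numeric(batch_shift_sd),
    replicate_noise_sd = as.numeric(replicate_noise_sd),
    seed = as.integer(seed),
    rescale_tpm = isTRUE(rescale_tpm)
  ), class = "sim_config")
}

#' Build a synthetic gene-of-interest panel
#'
#' Draws `sum(category_sizes)` genes from a gene universe and assigns each a
#' functional category and the report class derived from it: ATPase pumps and
#' inorganic-solute SLC carriers are transporters, ion channels and aquaporins
#' are pores, and GPCR/RTK receptors form the receptor class.
#'
#' @param category_sizes Named integer vector or list mapping a category
#'   (`ion_channel`, `aquaporin`, `atpase`, `slc`, `receptor`) to the number
#'   of panel genes of that category.
#' @param gene_universe Character vector of available gene ids (assigned to
#'   categories in order).
#' @param gene_symbols Optional character vector of symbols parallel to
#'   `gene_universe`; defaults to the ids.
#' @return A `data.frame` with columns `gene_id`, `gene_symbol`, `category`,
#'   `class`, one row per panel gene.
#' @examples
#' simulate_goi_panel(c(ion_channel = 2, receptor = 1), c("g1", "g2", "g3"))
#' @export
simulate_goi_panel <- function(category_sizes, gene_universe,
                               gene_symbols = gene_universe) {
  sizes <- unlist(category_sizes)
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    tpmeta_stop("tpmeta_bad_args", "category_sizes must be named")
  unknown <- setdiff(names(sizes), names(goi_class_map()))
  if (length(unknown))
    tpmeta_stop("tpmeta_bad_category",
                paste("unknown categories:", paste(unknown, collapse = ", ")))
  if (anyDuplicated(gene_universe))
    tpmeta_stop("tpmeta_duplicate_gene", "gene_universe contains duplicate ids")
  total <- sum(sizes)
  if (total > length(gene_universe))
    tpmeta_stop("tpmeta_bad_args",
                "sum of category sizes exceeds the gene universe")
  category <- rep(names(sizes), times = sizes)
  panel <- data.frame(
    gene_id = gene_universe[seq_len(total)],
    gene_symbol = gene_symbols[seq_len(total)],
    category = category,
    class = unname(goi_class_map()[category]),
    stringsAsFactors = FALSE
  )
  if (total == 0L) panel$class <- character(0)
  panel
}

goi_class_map <- function() {
  c(ion_channel = "pore", aquaporin = "pore",
    atpase = "transporter", slc = "transporter",
    receptor = "receptor")
}

#' Simulate a multi-study TPM expression data set with known truth
#'
#' Generates one TPM expression matrix per study under the generative model
#' the downstream analysis assumes. For each gene a mixture component (null /
#' background / expressed) is drawn once and shared by all studies, and a
#' clean log2(TPM+1) expression value is drawn from that component's Gaussian.
#' Each study adds a common batch shift and each run adds per-gene noise, both
#' in log space; log values are floored at 0 and back-transformed via
#' TPM = 2^L - 1. With `rescale_tpm = TRUE` every run column is then rescaled
#' to sum to 1,000,000.
#'
#' The same config (including seed) reproduces the output bit for bit.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#' \describe{
#'   \item{study_set}{A `study_set`: named list of genes-by-runs TPM matrices
#'     (study ids `study01`, ...; run ids `study01_r1`, ...).}
#'   \item{truth}{Ground-truth record: per-gene `component` labels,
#'     `clean_log` draws (pre-floor), per-study `batch_shift`, the analytic
#'     background/expressed `boundary_log` and its TPM-scale equivalent
#'     `boundary_tpm` (NA when the configured components do not intersect
#'     between their means).}
#'   \item{metadata}{Run metadata data.frame (`study_id`, `run_id`, `treated`,
#'     `library_layout`) with all runs untreated controls.}
#' }
#' @export
simulate_study_set <- function(config) {
  if (!inherits(config, "sim_config"))
    tpmeta_stop("tpmeta_bad_config", "config must be built with sim_config()")
  set.seed(config$seed)

  ng <- config$n_genes
  gene_ids <- sprintf("G%06d", seq_len(ng))
  gene_symbols <- setNames(sprintf("SYN%06d", seq_len(ng)), gene_ids)

  component <- sample.int(3L, ng, replace = TRUE, prob = config$mixture_weights)
  clean_log <- rnorm(ng,
                     mean = config$mixture_means[component],
                     sd = config$mixture_sds[component])
  batch_shift <- rnorm(config$n_studies, 0, config$batch_shift_sd)

  studies <- vector("list", config$n_studies)
  study_ids <- sprintf("study%02d", seq_len(config$n_studies))
  names(studies) <- study_ids
  for (s in seq_len(config$n_studies)) {
    nr <- config$runs_per_study[s]
    noise <- matrix(rnorm(ng * nr, 0, config$replicate_noise_sd), ng, nr)
    logval <- pmax(clean_log + batch_shift[s] + noise, 0)
    tpm <- 2^logval - 1
    if (config$rescale_tpm) {
      tpm <- sweep(tpm, 2L, colSums(tpm), "/") * 1e6
    }
    rownames(tpm) <- gene_ids
    colnames(tpm) <- sprintf("%s_r%d", study_ids[s], seq_len(nr))
    attr(tpm, "gene_symbols") <- gene_symbols
    studies[[s]] <- tpm
  }

  boundary_log <- tryCatch(
    analytic_boundary(config$mixture_weights, config$mixture_means,
                      config$mixture_sds),
    tpmeta_error = function(e) NA_real_
  )

  metadata <- data.frame(
    study_id = rep(study_ids, times = config$runs_per_study),
    run_id = unlist(lapply(studies, colnames), use.names = FALSE),
    treated = FALSE,
    library_layout = "PE",
    stringsAsFactors = FALSE
  )

  list(
    study_set = new_study_set(studies),
    truth = list(
      component = component,
      clean_log = setNames(clean_log, gene_ids),
      batch_shift = setNames(batch_shift, study_ids),
      boundary_log = boundary_log,
      boundary_tpm = if (is.na(boundary_log)) NA_real_ else 2^boundary_log - 1
    ),
    metadata = metadata
  )
}

#' Write a simulated data set to disk in the pipeline's input formats
#'
#' Emits one expression TSV per study, the run-metadata TSV, and the
#' simulation truth as JSON, in the exact formats [read_expression_table()]
#' and [read_run_metadata()] consume.
#'
#' @param sim Output of [simulate_study_set()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulated_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (sid in names(sim$study_set$studies)) {
    p <- file.path(dir, paste0(sid, "_expression.tsv"))
    write_expression_table(sim$study_set$studies[[sid]], p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "run_metadata.tsv")
  data.table::fwrite(sim$metadata, mp, sep = "\t")
  tp <- file.path(dir, "sim_truth.json")
  jsonlite::write_json(
    list(component = sim$truth$component,
         clean_log = unname(sim$truth$clean_log),
         gene_id = names(sim$truth$clean_log),
         batch_shift = as.list(sim$truth$batch_shift),
         boundary_log = sim$truth$boundary_log,
         boundary_tpm = sim$truth$boundary_tpm),
    tp, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, mp, tp))
}
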