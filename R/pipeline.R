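#' Read and validate a pipeline configuration file
#'
#' YAML with either an `input` block (paths to per-study expression TSVs, the
#' run-metadata TSV and the panel CSV) or a `simulation` block (the
#' [sim_config()] fields), never both. Analysis settings and their defaults:
#' `tau` (1.0), `confidence` (0.95), EM `tol` (1e-8), `max_iter` (500),
#' `variance_floor` (1e-4), `seed` (1). Simulation runs also accept
#' `panel_sizes` (category -> count) for the panel drawn from the simulated
#' gene universe; the default is the real panel composition (436 ion
#' channels, 14 aquaporins, 90 ATPases, 81 SLCs, 51 receptors).
#'
#' @param path Path to the YAML config.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A config given directly as a named list instead of a file.
#' @export
validate_pipeline_config <- function(cfg) {
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulation)
  if (has_input == has_sim)
    tpmeta_stop("tpmeta_bad_config",
                "config must contain exactly one of 'input' or 'simulation'")
  defaults <- list(tau = 1.0, confidence = 0.95, tol = 1e-8, max_iter = 500L,
                   variance_floor = 1e-4, seed = 1L,
                   panel_sizes = list(ion_channel = 436L, aquaporin = 14L,
                                      atpase = 90L, slc = 81L, receptor = 51L))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (cfg$tau < 0)
    tpmeta_stop("tpmeta_bad_config", "tau must be >= 0")
  if (!(cfg$confidence > 0 && cfg$confidence < 1))
    tpmeta_stop("tpmeta_bad_config", "confidence must be in (0, 1)")
  if (has_input) {
    need <- c("expression_tables", "metadata", "panel")
    miss <- setdiff(need, names(cfg$input))
    if (length(miss))
      tpmeta_stop("tpmeta_bad_config",
                  paste("input block missing:", paste(miss, collapse = ", ")))
  } else {
    sim_args <- cfg$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cfg$simulation <- do.call(sim_config, sim_args)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full cross-study meta-analysis pipeline
#'
#' Executes ingest (or simulation), per-study mixture threshold validation on
#' the raw log values, merge + quantile normalization, panel filtering,
#' cross-study summaries, pairwise study correlations, and the rank-ordered
#' class reports, writing every artifact plus a JSON run manifest to
#' `out_dir`. Identical config and seed reproduce byte-identical outputs; on
#' a stage error all partial outputs are removed.
#'
#' Outputs: `threshold_report.json`, `gene_summary.tsv`, `correlations.tsv`,
#' `missing_goi.txt`, `report_{transporter,pore,receptor}.tsv`,
#' `global_matrix.tsv` (when `dump_global: true`), `manifest.json`, and for
#' simulation runs the simulated inputs under `simulated/`.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]) or the
#'   path to one.
#' @param out_dir Output directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the in-memory results (`study_set`,
#'   `threshold_report`, `global`, `summary`, `correlations`, `reports`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    tpmeta_stop("tpmeta_bad_args",
                sprintf("output directory '%s' is not empty", out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(p) written <<- c(written, p)
  stage <- "setup"
  res <- tryCatch({
    # --- ingest or simulate -------------------------------------------------
    if (!is.null(config$simulation)) {
      stage <- "simulate"
      sim <- simulate_study_set(config$simulation)
      simdir <- file.path(out_dir, "simulated")
      note(write_simulated_set(sim, simdir))
      studies <- sim$study_set
      panel <- simulate_goi_panel(
        unlist(config$panel_sizes),
        rownames(studies$studies[[1]]),
        unname(attr(studies$studies[[1]], "gene_symbols")))
      metadata <- sim$metadata
    } else {
      stage <- "ingest"
      tables <- lapply(config$input$expression_tables, read_expression_table)
      if (is.null(names(tables)) || any(!nzchar(names(tables))))
        tpmeta_stop("tpmeta_bad_config",
                    "input$expression_tables must be named by study_id")
      metadata <- read_run_metadata(config$input$metadata)
      panel <- read_goi_panel(config$input$panel)
      selected <- select_control_runs(metadata)
      studies <- assemble_study_set(tables, selected)
    }

    # --- per-study mixture threshold on raw log values ----------------------
    stage <- "fit-threshold"
    threshold_report <- validate_threshold(
      studies, tau = config$tau,
      tol = config$tol, max_iter = config$max_iter,
      variance_floor = config$variance_floor, seed = config$seed)
    note(write_threshold_report(threshold_report,
                                file.path(out_dir, "threshold_report.json")))

    # --- merge + quantile normalize -----------------------------------------
    stage <- "normalize"
    global <- quantile_normalize(merge_studies(studies))
    if (isTRUE(config$dump_global))
      note(write_global_matrix(global, file.path(out_dir, "global_matrix.tsv")))

    # --- summaries ----------------------------------------------------------
    stage <- "summarize"
    summary <- gene_summary_table(global, panel, tau = config$tau,
                                  confidence = config$confidence)
    p <- file.path(out_dir, "gene_summary.tsv")
    data.table::fwrite(summary, p, sep = "\t")
    note(p)
    p <- file.path(out_dir, "missing_goi.txt")
    writeLines(attr(summary, "missing"), p)
    note(p)

    stage <- "correlate"
    correlations <- pairwise_study_correlation(global, panel)
    p <- file.path(out_dir, "correlations.tsv")
    data.table::fwrite(
      data.frame(study_id = rownames(correlations), correlations,
                 check.names = FALSE), p, sep = "\t")
    note(p)

    stage <- "report"
    reports <- group_and_rank(summary)
    for (cl in names(reports)) {
      p <- file.path(out_dir, sprintf("report_%s.tsv", cl))
      data.table::fwrite(reports[[cl]], p, sep = "\t")
      note(p)
    }

    # --- manifest -----------------------------------------------------------
    stage <- "manifest"
    manifest <- list(
      package_version = as.character(packageVersion("tpmeta")),
      seed = config$seed,
      tau = config$tau,
      confidence = config$confidence,
      config = unclass_config(config),
      stages = list(
        n_studies = studies$n_studies,
        n_runs = sum(vapply(studies$studies, ncol, integer(1))),
        n_genes_global = nrow(global$values),
        n_panel_genes = nrow(panel),
        n_panel_present = nrow(summary),
        n_expressed = sum(summary$expressed)
      )
    )
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    note(p)
    list(study_set = studies, threshold_report = threshold_report,
         global = global, summary = summary, correlations = correlations,
         reports = reports, manifest = manifest)
  }, error = function(e) {
    unlink(unlist(written), recursive = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulation)) cfg$simulation <- unclass(cfg$simulation)
  cfg
}
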