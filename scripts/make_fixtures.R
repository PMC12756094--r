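#!/usr/bin/env Rscript
# Regenerates the plain-text fixtures shipped under inst/extdata/.
#
# goi_panel_synthetic.csv  — gene-of-interest panel with the real category
#   sizes (436 ion channels, 14 aquaporins, 90 ATPases, 81 inorganic-solute
#   SLCs, 51 GPCR/RTK receptors = 672 genes) but synthetic gene ids/symbols;
#   ids live in the simulator's G%06d universe so the fixture joins directly
#   against simulated matrices.
# run_metadata_synthetic.tsv — run metadata for the eight studies; study ids,
#   per-study usable control counts (8,3,2,2,4,3,3,5 = 30) and PE layout are
#   the published study attributes, while run accessions and the treated rows
#   are synthetic placeholders.

library(tpmeta)

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sizes <- c(ion_channel = 436L, aquaporin = 14L, atpase = 90L, slc = 81L,
           receptor = 51L)
prefix <- c(ion_channel = "ICH", aquaporin = "AQP", atpase = "ATP",
            slc = "SLC", receptor = "RCP")
universe <- sprintf("G%06d", seq_len(sum(sizes)))
symbols <- unlist(lapply(names(sizes), function(cat)
  sprintf("%s%03d", prefix[[cat]], seq_len(sizes[[cat]]))))
panel <- simulate_goi_panel(sizes, universe, symbols)
write_goi_panel(panel, file.path(out, "goi_panel_synthetic.csv"))

study_ids <- c("PRJNA307652", "PRJNA575504", "PRJNA578611", "PRJNA777606",
               "PRJNA847413", "PRJEB48614", "PRJNA667281", "PRJNA896725")
n_control <- c(8L, 3L, 2L, 2L, 4L, 3L, 3L, 5L)
n_treated <- c(2L, 1L, 2L, 1L, 0L, 1L, 2L, 1L)   # synthetic
md <- do.call(rbind, lapply(seq_along(study_ids), function(i) {
  rbind(
    data.frame(study_id = study_ids[i],
               run_id = sprintf("%s_C%d", study_ids[i], seq_len(n_control[i])),
               treated = FALSE, library_layout = "PE"),
    if (n_treated[i] > 0)
      data.frame(study_id = study_ids[i],
                 run_id = sprintf("%s_T%d", study_ids[i], seq_len(n_treated[i])),
                 treated = TRUE, library_layout = "PE")
  )
}))
data.table::fwrite(md, file.path(out, "run_metadata_synthetic.tsv"), sep = "\t")

cat("panel rows:", nrow(panel), " metadata rows:", nrow(md),
    " controls:", sum(!md$treated), "\n")
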