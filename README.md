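# tpmeta

Cross-study meta-analysis of RNA-seq TPM expression with mixture-based
expression thresholding.

## What it does

Public archives hold several independent RNA-seq studies of the hCMEC/D3
human brain endothelial cell line — the standard in vitro model of the
blood–brain barrier. `tpmeta` merges such per-study gene-level TPM tables
into a single cross-study expression profile for a curated 672-gene panel of
ion channels, aquaporins, ATPase pumps, inorganic-solute SLC carriers and
GPCR/RTK receptors, answering: which of these genes are reliably expressed,
at what level, and how consistently across studies?

The statistical core:

- **Expression threshold validation.** For each study, the pooled
  log2(TPM+1) distribution is fitted with a three-component Gaussian
  mixture (null, background, expressed) by EM written in the package. The
  decision boundary is the solution of

  π₂·N(x; μ₂, σ₂) = π₃·N(x; μ₃, σ₃),  x ∈ (μ₂, μ₃)

  — the point where background and expressed densities cross, obtained in
  closed form (quadratic in x after taking logs) with a bisection fallback.
  A boundary near log2(TPM+1) = 1 supports the conventional TPM ≥ 1 cutoff.
- **Cross-study summaries.** Studies are merged on the common gene set,
  quantile-normalized jointly (via `limma`), and summarized per gene:
  within-study means, cross-study mean with a t-based 95% CI (each study is
  one observation), an inclusive expressed flag at τ = 1, pairwise Pearson
  correlations between studies, and rank-ordered report tables per class
  (transporter / pore / receptor).
- **A seeded synthetic-data generator** reproducing the multi-study mixture
  structure (shared gene programs, per-study batch shifts, per-run noise)
  with recorded ground truth, so the entire pipeline is testable offline.

See `vignettes/cross-study-tpm-meta-analysis.Rmd` for the methods account.

## Worked example

```r
library(tpmeta)

# Reference scenario: 8 studies, 30 runs, 20,000 genes, true boundary TPM = 1
sim <- simulate_study_set(sim_config(seed = 42))
report <- validate_threshold(sim$study_set, tau = 1, seed = 42)
report$summary[, c("study_id", "boundary_log", "boundary_tpm", "deviation")]
#>  study_id boundary_log boundary_tpm   deviation
#>   study01    0.9245225    0.8980559 -0.07547755
#>   study02    0.9564555    0.9405364 -0.04354453
#>   study03    0.8968837    0.8620395 -0.10311631
#>   study04    0.9414782    0.9204950 -0.05852179
#>   study05    0.7927496    0.7323731 -0.20725036
#>   study06    0.9435069    0.9231975 -0.05649306
#>   study07    0.9433968    0.9230508 -0.05660315
#>   study08    0.9654102    0.9526187 -0.03458976
mean(report$summary$boundary_tpm)
#> [1] 0.8940458
```

Every study's fitted boundary lands close to the generating intersection at
TPM = 1 (log 1.0): the data-driven boundary supports the conventional
cutoff. Deviations reflect per-study batch shifts (SD 0.05 log2 units),
replicate noise, and the flooring of log values at zero.

Full pipeline from a config file (simulation or real input tables):

```sh
Rscript inst/cli/tpmeta.R run --config config.yaml --out results/
```

writes `threshold_report.json`, `gene_summary.tsv`, `correlations.tsv`,
`missing_goi.txt`, per-class `report_*.tsv` and a `manifest.json`; identical
config + seed reproduces all outputs byte for byte.

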