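#' Pool a study's log-expression values
#'
#' Flattens all gene-by-run log2(TPM+1) values of one study into a single
#' vector — the empirical distribution to which the three-component mixture
#' is fitted. The fit deliberately uses raw (pre-quantile-normalization)
#' values: the threshold check concerns each study's own distribution.
#'
#' @param study Genes-by-runs TPM matrix for one study.
#' @return Numeric vector of length `n_genes * n_runs`, log2(TPM+1) units.
#' @export
pool_study_values <- function(study) {
  if (is.null(dim(study)) || nrow(study) == 0L || ncol(study) == 0L)
    tpmeta_stop("tpmeta_empty", "study matrix is empty")
  as.vector(log_transform(study))
}

#' Fit a three-component univariate Gaussian mixture by EM
#'
#' Models a study's log2(TPM+1) distribution as a mixture of a null (or
#' quasi-null) component near zero, a low-abundance background component, and
#' an expressed component. Standard EM: responsibilities in the E-step
#' (computed with log-sum-exp for stability), weight/mean/variance updates in
#' the M-step. Initialization is deterministic from the data's 5th/50th/95th
#' percentiles with equal weights and sd(data)/3 spreads; optional random
#' restarts (seeded) keep the best log-likelihood. Variances are clamped at
#' `variance_floor` so no component can collapse onto repeated values.
#' Components are relabeled in ascending mean order on return.
#'
#' Exact zeros (undetected genes) form a point mass that no Gaussian can
#' represent; left in, it rewards degenerate solutions that spend two
#' components near zero and distort the background/expressed boundary. They
#' are therefore excluded from the fit by default (`include_zeros = FALSE`),
#' which leaves the null component modeling the near-zero smear of barely
#' detected genes; the switch restores the all-values behaviour.
#'
#' @param values Numeric vector of pooled log2(TPM+1) values (>= 30 finite
#'   values, >= 3 distinct).
#' @param tol Convergence tolerance on the absolute change in log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param variance_floor Lower bound on component variances (log2 units
#'   squared).
#' @param seed Integer seed used only when `restarts > 0` or `subsample` is
#'   set.
#' @param restarts Number of additional randomly initialized EM runs.
#' @param subsample Optional cap on the number of values used (random
#'   subsample without replacement); `NULL` uses all values.
#' @param include_zeros Include exact-zero log values in the fit (default
#'   `FALSE`; see Details).
#' @return A `gmm3_fit`: list with `weights`, `means`, `sds`,
#'   `log_likelihood`, `ll_trace`, `n_iter`, `converged`, `n`, and (once
#'   [decision_boundary()] has run) `boundary_log`/`boundary_tpm`.
#' @export
fit_gmm3 <- function(values, tol = 1e-8, max_iter = 500L,
                     variance_floor = 1e-4, seed = NULL, restarts = 0L,
                     subsample = NULL, include_zeros = FALSE) {
  x <- values[is.finite(values)]
  if (!include_zeros) x <- x[x != 0]
  if (length(x) < 30L)
    tpmeta_stop("tpmeta_too_few", "need at least 30 finite values to fit")
  if (length(unique(x)) < 3L)
    tpmeta_stop("tpmeta_degenerate", "need at least 3 distinct values to fit")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(subsample) && length(x) > subsample)
    x <- x[sample.int(length(x), subsample)]

  mu0 <- unname(quantile(x, c(0.05, 0.5, 0.95), names = FALSE))
  if (anyDuplicated(mu0))
    mu0 <- mu0 + c(-1, 0, 1) * max(diff(range(x)) * 1e-3, 1e-6)
  s0 <- rep(max(sd(x) / 3, sqrt(variance_floor)), 3L)

  best <- em_gmm3(x, mu0, s0, rep(1 / 3, 3), tol, max_iter, variance_floor)
  if (restarts > 0L) {
    for (r in seq_len(restarts)) {
      probs <- sort(stats::runif(3, 0.02, 0.98))
      mu_r <- unname(quantile(x, probs, names = FALSE))
      if (anyDuplicated(mu_r))
        mu_r <- mu_r + c(-1, 0, 1) * max(diff(range(x)) * 1e-3, 1e-6)
      cand <- em_gmm3(x, mu_r, s0, rep(1 / 3, 3), tol, max_iter, variance_floor)
      if (cand$log_likelihood > best$log_likelihood) best <- cand
    }
  }
  best$n <- length(x)
  structure(best, class = "gmm3_fit")
}

em_gmm3 <- function(x, mu, s, w, tol, max_iter, variance_floor) {
  n <- length(x)
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    ld <- vapply(1:3, function(k) log(w[k]) + dnorm(x, mu[k], s[k], log = TRUE),
                 numeric(n))
    mx <- pmax(ld[, 1], ld[, 2], ld[, 3])
    lse <- mx + log(exp(ld[, 1] - mx) + exp(ld[, 2] - mx) + exp(ld[, 3] - mx))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(ld - lse)                      # n x 3 responsibilities
    nk <- pmax(colSums(resp), 1e-12)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- vapply(1:3, function(k) sum(resp[, k] * (x - mu[k])^2) / nk[k],
                numeric(1))
    s <- sqrt(pmax(v, variance_floor))
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], sds = s[ord],
       log_likelihood = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, n_iter = iter, converged = converged,
       boundary_log = NA_real_, boundary_tpm = NA_real_)
}

#' @export
print.gmm3_fit <- function(x, ...) {
  cat("<gmm3_fit> 3-component Gaussian mixture on log2(TPM+1)\n")
  cat(sprintf("  weights: %s\n", paste(signif(x$weights, 4), collapse = ", ")))
  cat(sprintf("  means:   %s\n", paste(signif(x$means, 4), collapse = ", ")))
  cat(sprintf("  sds:     %s\n", paste(signif(x$sds, 4), collapse = ", ")))
  cat(sprintf("  logLik %.2f after %d iterations (%s)\n", x$log_likelihood,
              x$n_iter, if (x$converged) "converged" else "NOT converged"))
  if (!is.na(x$boundary_log))
    cat(sprintf("  boundary: log2(TPM+1) = %.4f (TPM = %.4f)\n",
                x$boundary_log, x$boundary_tpm))
  invisible(x)
}

#' Compute the background/expressed decision boundary of a fitted mixture
#'
#' Locates the intersection of the weighted densities of the second
#' (background) and third (expressed) components inside the open interval
#' between their means, via the closed-form quadratic root (bisection
#' fallback), and records it in both log2(TPM+1) and TPM units
#' (`boundary_tpm = 2^boundary_log - 1`). When the two densities do not cross
#' between the means the boundary fields stay `NA`.
#'
#' @param fit A `gmm3_fit` from [fit_gmm3()].
#' @return The fit with `boundary_log` and `boundary_tpm` filled in.
#' @export
decision_boundary <- function(fit) {
  if (!inherits(fit, "gmm3_fit"))
    tpmeta_stop("tpmeta_bad_args", "fit must come from fit_gmm3()")
  if (!isTRUE(fit$converged))
    warning("computing decision boundary on a non-converged fit", call. = FALSE)
  if (fit$means[2] >= fit$means[3])
    tpmeta_stop("tpmeta_degenerate",
                "background and expressed component means are not separated")
  b <- tryCatch(
    analytic_boundary(fit$weights, fit$means, fit$sds),
    tpmeta_no_boundary = function(e) NA_real_
  )
  fit$boundary_log <- b
  fit$boundary_tpm <- if (is.na(b)) NA_real_ else 2^b - 1
  fit
}

#' Fit per-study mixtures and compare boundaries to the conventional cutoff
#'
#' For every study, pools its log2(TPM+1) values, fits the three-component
#' mixture, computes the background/expressed boundary, and reports the
#' signed deviation `boundary_log - tau` from the conventional threshold
#' (default tau = 1, i.e. TPM = 1). A study whose fit or boundary fails is
#' flagged in the report without aborting the others.
#'
#' @param studies A `study_set` of TPM matrices.
#' @param tau Threshold in log2(TPM+1) units (default 1).
#' @param deviation_tol Absolute deviation beyond which a study is flagged.
#' @param ... Passed to [fit_gmm3()].
#' @return A `threshold_report`: list with `summary` (one data.frame row per
#'   study: boundary, deviation, convergence, flag), `fits` (named list of
#'   `gmm3_fit` or `NULL` on failure), `tau`.
#' @export
validate_threshold <- function(studies, tau = 1, deviation_tol = 0.25, ...) {
  if (!inherits(studies, "study_set") || studies$n_studies < 1L)
    tpmeta_stop("tpmeta_bad_args", "need a study_set with at least 1 study")
  rows <- list()
  fits <- list()
  for (sid in names(studies$studies)) {
    fit <- tryCatch({
      f <- fit_gmm3(pool_study_values(studies$studies[[sid]]), ...)
      decision_boundary(f)
    }, tpmeta_error = function(e) e)
    if (inherits(fit, "error")) {
      fits[sid] <- list(NULL)
      rows[[sid]] <- data.frame(
        study_id = sid, converged = NA, boundary_log = NA_real_,
        boundary_tpm = NA_real_, deviation = NA_real_, flagged = TRUE,
        note = conditionMessage(fit), stringsAsFactors = FALSE)
    } else {
      fits[[sid]] <- fit
      dev <- fit$boundary_log - tau
      rows[[sid]] <- data.frame(
        study_id = sid, converged = fit$converged,
        boundary_log = fit$boundary_log, boundary_tpm = fit$boundary_tpm,
        deviation = dev,
        flagged = is.na(dev) || abs(dev) > deviation_tol || !fit$converged,
        note = "", stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 fits = fits, tau = tau),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> tau = %g (TPM = %g)\n", x$tau, 2^x$tau - 1))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Serialize a threshold report to JSON
#' @param report A `threshold_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_threshold_report <- function(report, path) {
  per_study <- lapply(names(report$fits), function(sid) {
    f <- report$fits[[sid]]
    if (is.null(f))
      return(list(error = report$summary$note[report$summary$study_id == sid]))
    list(weights = f$weights, means = f$means, sds = f$sds,
         log_likelihood = f$log_likelihood, n_iter = f$n_iter,
         converged = f$converged, boundary_log = f$boundary_log,
         boundary_tpm = f$boundary_tpm)
  })
  names(per_study) <- names(report$fits)
  jsonlite::write_json(list(tau = report$tau, studies = per_study),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
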