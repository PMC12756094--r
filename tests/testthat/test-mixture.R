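test_that("pooling flattens a study's log values without loss", {
  m <- make_expr(c(0, 1, 3, 7, 15, 31), gene_ids = c("gA", "gB", "gC"))
  v <- pool_study_values(m)
  expect_length(v, 6L)
  expect_equal(sort(v), 0:5)  # log2(TPM+1) of 0,1,3,7,15,31

  one <- make_expr(1, gene_ids = "gA", run_ids = "r1")
  expect_equal(pool_study_values(one), 1.0)

  expect_error(pool_study_values(make_expr(numeric(0), gene_ids = character(0),
                                           run_ids = "r1")),
               class = "tpmeta_empty")
})

gmm_sample <- function(n, w, mu, s, seed) {
  set.seed(seed)
  k <- sample.int(3L, n, replace = TRUE, prob = w)
  rnorm(n, mu[k], s[k])
}

test_that("EM recovers well-separated mixture parameters", {
  x <- gmm_sample(30000, c(0.3, 0.3, 0.4), c(0, 1.5, 5), c(0.05, 0.5, 1), 42)
  fit <- fit_gmm3(x)
  expect_true(fit$converged)
  expect_equal(fit$means, c(0, 1.5, 5), tolerance = 0.1)
  expect_equal(fit$weights, c(0.3, 0.3, 0.4), tolerance = 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$sds >= 1e-4))
  # log-likelihood is non-decreasing at every EM step
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
  # relabeling: means ascending by contract
  expect_false(is.unsorted(fit$means))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- gmm_sample(10000, c(0.25, 0.35, 0.4), c(-1, 1.5, 4), c(0.3, 0.4, 0.8), 7)
  fit <- fit_gmm3(x)
  mc <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(fit$means, sort(unname(mc$parameters$mean)), tolerance = 0.05)
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 1)
})

test_that("EM rejects degenerate inputs", {
  expect_error(fit_gmm3(rnorm(10)), class = "tpmeta_too_few")
  expect_error(fit_gmm3(rep(c(1, 2), 50)), class = "tpmeta_degenerate")
  # 30+ values but fewer than 30 after dropping non-finite entries
  expect_error(fit_gmm3(c(rnorm(20), rep(NA, 20))), class = "tpmeta_too_few")
})

test_that("exact zeros are excluded by default but kept on request", {
  x <- c(rep(0, 5000), gmm_sample(10000, c(0.2, 0.4, 0.4), c(0.1, 0.8, 2),
                                  c(0.05, 0.2, 0.3), 3))
  fit <- fit_gmm3(x)
  expect_equal(fit$n, 10000L)
  fit0 <- fit_gmm3(x, include_zeros = TRUE)
  expect_equal(fit0$n, 15000L)
})

test_that("the decision boundary sits at the symmetric midpoint", {
  fit <- make_fit(c(0.4, 0.3, 0.3), c(0.0, 0.5, 1.5), c(0.05, 0.3, 0.3))
  fit <- decision_boundary(fit)
  expect_equal(fit$boundary_log, 1.0, tolerance = 1e-12)
  expect_equal(fit$boundary_tpm, 1.0, tolerance = 1e-12)
})

test_that("the decision boundary matches bisection on an asymmetric fit", {
  fit <- make_fit(c(0.2, 0.6, 0.2), c(0.0, 0.4, 3.0), c(0.05, 0.2, 0.8))
  fit <- decision_boundary(fit)
  expect_equal(fit$boundary_log, bisect_boundary(0.6, 0.2, 0.4, 3.0, 0.2, 0.8),
               tolerance = 1e-8)
})

test_that("boundary-free and unordered fits are handled explicitly", {
  flat <- make_fit(c(0.1, 1e-6, 1 - 0.1 - 1e-6), c(-2, 0, 0.1), c(1, 1, 1))
  flat <- decision_boundary(flat)
  expect_true(is.na(flat$boundary_log))
  expect_true(is.na(flat$boundary_tpm))

  same <- make_fit(c(1, 1, 1) / 3, c(0, 1, 1), c(0.1, 0.1, 0.1))
  expect_error(decision_boundary(same), class = "tpmeta_degenerate")

  expect_warning(
    decision_boundary(make_fit(c(1, 1, 1) / 3, c(0, 1, 2), c(0.1, 0.1, 0.1),
                               converged = FALSE)),
    "non-converged")
})

test_that("decision boundary equals bisection over random converged fits", {
  set.seed(202)
  n_ok <- 0L
  while (n_ok < 100L) {
    w <- runif(3); w <- w / sum(w)
    mu <- sort(runif(3, -1, 4))
    if (mu[3] - mu[2] < 0.2) next
    s <- runif(3, 0.05, 0.8)
    oracle <- bisect_boundary(w[2], w[3], mu[2], mu[3], s[2], s[3])
    if (is.na(oracle)) next
    fit <- decision_boundary(make_fit(w, mu, s))
    expect_equal(fit$boundary_log, oracle, tolerance = 1e-8)
    expect_equal(fit$boundary_tpm, 2^oracle - 1, tolerance = 1e-8)
    n_ok <- n_ok + 1L
  }
})

test_that("threshold validation isolates per-study failures", {
  good <- make_expr(2^gmm_sample(600, c(0.3, 0.3, 0.4), c(0.05, 0.6, 2),
                                 c(0.05, 0.2, 0.4), 8) - 1,
                    gene_ids = sprintf("g%03d", 1:300),
                    run_ids = c("r1", "r2"))
  good[good < 0] <- 0
  bad <- make_expr(rep(1, 300), gene_ids = sprintf("g%03d", 1:300),
                   run_ids = "r3")  # constant: degenerate fit input
  rep <- validate_threshold(make_study_set(good = good, bad = bad), tau = 1)
  expect_s3_class(rep, "threshold_report")
  expect_equal(nrow(rep$summary), 2L)
  expect_true(rep$summary$flagged[rep$summary$study_id == "bad"])
  expect_null(rep$fits$bad)
  gd <- rep$summary[rep$summary$study_id == "good", ]
  expect_false(is.na(gd$boundary_log))
  expect_equal(gd$deviation, gd$boundary_log - 1)

  single <- validate_threshold(make_study_set(good = good))
  expect_equal(nrow(single$summary), 1L)
})

test_that("threshold reports serialize to JSON and back", {
  m <- make_expr(2^gmm_sample(400, c(0.3, 0.3, 0.4), c(0.05, 0.6, 2),
                              c(0.05, 0.2, 0.4), 9) - 1,
                 gene_ids = sprintf("g%03d", 1:200), run_ids = c("r1", "r2"))
  m[m < 0] <- 0
  rep <- validate_threshold(make_study_set(s1 = m))
  p <- withr::local_tempfile(fileext = ".json")
  write_threshold_report(rep, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$tau, 1)
  expect_equal(parsed$studies$s1$boundary_log, rep$fits$s1$boundary_log,
               tolerance = 1e-12)
  expect_length(parsed$studies$s1$means, 3L)
})
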