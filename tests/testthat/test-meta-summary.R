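test_that("within-study means average runs per study", {
  vals <- matrix(c(1, 5, 3, 7, 2, 6), 2, 3,
                 dimnames = list(c("gA", "gB"), c("r1", "r2", "r3")))
  g <- make_global(vals, run_study = c(r1 = "s1", r2 = "s1", r3 = "s2"))
  sm <- within_study_means(g)
  expect_equal(sm, matrix(c(2, 6, 2, 6), 2, 2,
                          dimnames = list(c("gA", "gB"), c("s1", "s2"))))
  # single-run study mean is the run itself; run order is irrelevant
  g2 <- make_global(vals[, c(2, 1, 3)],
                    run_study = c(r2 = "s1", r1 = "s1", r3 = "s2"))
  expect_equal(within_study_means(g2), sm)
})

test_that("cross-study summary matches the t-interval computed by t.test", {
  x <- as.numeric(1:8)
  sm <- matrix(x, 1, 8, dimnames = list("gA", sprintf("s%d", 1:8)))
  cs <- cross_study_summary(sm, confidence = 0.95)
  tt <- t.test(x, conf.level = 0.95)
  expect_equal(cs$cross_mean, 4.5)
  expect_equal(cs$ci_low, tt$conf.int[1], tolerance = 1e-12)
  expect_equal(cs$ci_high, tt$conf.int[2], tolerance = 1e-12)
  expect_equal(cs$n_studies, 8L)

  # equal study means give a zero-width interval
  cs0 <- cross_study_summary(matrix(2, 1, 8, dimnames = list("gA", NULL)))
  expect_equal(c(cs0$ci_low, cs0$cross_mean, cs0$ci_high), c(2, 2, 2))

  expect_error(cross_study_summary(matrix(1, 1, 1)), class = "tpmeta_too_few")
})

test_that("cross-study summary brackets the mean for random inputs", {
  set.seed(14)
  sm <- matrix(rnorm(200 * 5), 200, 5,
               dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:5)))
  cs <- cross_study_summary(sm, 0.9)
  expect_true(all(cs$ci_low <= cs$cross_mean & cs$cross_mean <= cs$ci_high))
  for (i in c(1, 57, 200)) {
    tt <- t.test(sm[i, ], conf.level = 0.9)
    expect_equal(c(cs$ci_low[i], cs$ci_high[i]), as.numeric(tt$conf.int),
                 tolerance = 1e-12)
  }
})

test_that("mean CI half-width shrinks as studies are added", {
  set.seed(21)
  sm <- matrix(rnorm(2000 * 8), 2000, 8)
  rownames(sm) <- sprintf("g%04d", 1:2000)
  widths <- vapply(2:8, function(n) {
    cs <- cross_study_summary(sm[, 1:n, drop = FALSE])
    mean(cs$ci_high - cs$ci_low)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("expressed classification is the inclusive threshold rule", {
  s <- data.frame(gene_id = c("a", "b", "c"),
                  cross_mean = c(1.0, 0.999, 0))
  cl <- classify_expressed(s, tau = 1)
  expect_equal(cl$expressed, c(TRUE, FALSE, FALSE))
  # exhaustive brute-force agreement on random values and thresholds
  set.seed(4)
  for (i in 1:10) {
    tau <- runif(1, 0, 3)
    s <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    cross_mean = runif(100, 0, 3))
    got <- classify_expressed(s, tau)$expressed
    brute <- vapply(s$cross_mean, function(v) v >= tau, logical(1))
    expect_identical(got, brute)
  }
  expect_error(classify_expressed(data.frame(cross_mean = NA_real_)),
               class = "tpmeta_bad_value")
})

test_that("panel filtering annotates present genes and reports missing ones", {
  summaries <- data.frame(gene_id = c("g1", "g2", "g3"),
                          cross_mean = c(2, 1, 0.5))
  panel <- simulate_goi_panel(c(slc = 2, receptor = 2),
                              c("g2", "g9", "g1", "g8"))
  out <- filter_goi(summaries, panel)
  expect_equal(out$gene_id, c("g2", "g1"))
  expect_equal(out$category, c("slc", "receptor"))
  expect_equal(out$class, c("transporter", "receptor"))
  expect_equal(attr(out, "missing"), c("g9", "g8"))
  expect_error(filter_goi(summaries, panel[0, ]), class = "tpmeta_empty")
})

test_that("study correlations match the direct Pearson formula", {
  set.seed(77)
  vals <- matrix(rnorm(30), 10, 3,
                 dimnames = list(sprintf("g%02d", 1:10), c("r1", "r2", "r3")))
  g <- make_global(vals, run_study = c(r1 = "s1", r2 = "s2", r3 = "s3"))
  panel <- simulate_goi_panel(c(slc = 10), sprintf("g%02d", 1:10))
  r <- pairwise_study_correlation(g, panel)
  direct <- function(a, b) {
    num <- sum((a - mean(a)) * (b - mean(b)))
    num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) 1 else direct(vals[, i], vals[, j])
    expect_equal(r[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(r, t(r), tolerance = 1e-12)
  expect_true(all(r >= -1 & r <= 1))
})

test_that("correlation handles perfect agreement, anti-correlation and degeneracy", {
  vals <- cbind(r1 = c(1, 2, 3), r2 = c(1, 2, 3), r3 = c(6, 4, 2))
  rownames(vals) <- c("gA", "gB", "gC")
  g <- make_global(vals, run_study = c(r1 = "s1", r2 = "s2", r3 = "s3"))
  panel <- simulate_goi_panel(c(atpase = 3), c("gA", "gB", "gC"))
  r <- pairwise_study_correlation(g, panel)
  expect_equal(r["s1", "s2"], 1)
  expect_equal(r["s1", "s3"], -1)

  fv <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
               dimnames = list(c("gA", "gB", "gC"), c("r1", "r2")))
  flat <- make_global(fv, run_study = c(r1 = "s1", r2 = "s2"))
  expect_error(pairwise_study_correlation(flat, panel), "s2",
               class = "tpmeta_degenerate")

  tiny <- simulate_goi_panel(c(slc = 2), c("gA", "gB"))
  expect_error(pairwise_study_correlation(g, tiny), class = "tpmeta_too_few")
})

test_that("report tables keep expressed genes sorted within class", {
  s <- data.frame(
    gene_id = c("g4", "g1", "g2", "g3", "g5"),
    gene_symbol = c("S4", "S1", "S2", "S3", "S5"),
    category = c("slc", "atpase", "ion_channel", "receptor", "slc"),
    class = c("transporter", "transporter", "pore", "receptor", "transporter"),
    cross_mean = c(3, 1.5, 0.9, 1.5, 1.5),
    expressed = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  rep <- group_and_rank(s)
  expect_named(rep, c("transporter", "pore", "receptor"))
  expect_equal(rep$transporter$gene_id, c("g4", "g1", "g5"))  # tie g1/g5 by id
  expect_equal(rep$transporter$cross_mean, c(3, 1.5, 1.5))
  expect_equal(nrow(rep$pore), 0L)
  expect_equal(rep$receptor$gene_id, "g3")

  none <- s
  none$expressed <- FALSE
  expect_true(all(vapply(group_and_rank(none), nrow, integer(1)) == 0L))
})

test_that("the combined summary table carries per-study means and flags", {
  set.seed(8)
  vals <- matrix(runif(40, 0, 4), 10, 4,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 c("r1", "r2", "r3", "r4")))
  g <- make_global(vals, run_study = c(r1 = "s1", r2 = "s1",
                                       r3 = "s2", r4 = "s2"))
  panel <- simulate_goi_panel(c(ion_channel = 5), sprintf("g%02d", 1:5))
  tab <- gene_summary_table(g, panel, tau = 1)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$mean_s1, unname(rowMeans(vals[1:5, 1:2])))
  expect_equal(tab$expressed, tab$cross_mean >= 1)
  expect_equal(tab$n_studies, rep(2L, 5))
  expect_true(all(tab$ci_low <= tab$cross_mean & tab$cross_mean <= tab$ci_high))
})
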