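annotation_fixture <- function() {
  data.frame(
    gene_id = sprintf("g%d", 1:6),
    is_single_copy = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    is_dev_regulated = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    has_kinetoplastid_homolog = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
}

test_that("training-set filtering applies the three exclusion rules", {
  tpm <- setNames(c(10, 20, 30, 40, 50, 60), sprintf("g%d", 1:6))
  ann <- annotation_fixture()
  kept <- filter_training_set(tpm, ann)
  expect_identical(names(kept), c("g1", "g5"))
  counts <- attr(kept, "filter_counts")
  expect_equal(unname(counts["dev_regulated"]), 2)
  expect_equal(unname(counts["no_kinetoplastid_homolog"]), 1)
  expect_equal(unname(counts["multicopy"]), 1)
  expect_equal(attr(kept, "n_retained"), 2)
})

test_that("filtering is idempotent and rejects unannotated or empty outcomes", {
  tpm <- setNames(c(10, 20, 30, 40, 50, 60), sprintf("g%d", 1:6))
  ann <- annotation_fixture()
  once <- filter_training_set(tpm, ann)
  twice <- filter_training_set(once, ann)
  expect_identical(names(twice), names(once))
  expect_equal(as.numeric(twice), as.numeric(once))
  expect_equal(sum(attr(twice, "filter_counts")), 0)

  expect_error(filter_training_set(setNames(1, "gX"), ann), "gX")
  none <- ann
  none$is_single_copy <- FALSE
  expect_error(filter_training_set(tpm, none), "no genes survive")
})

test_that("the expression model recovers exact log-linear data", {
  scores <- setNames(seq(0.1, 0.9, length.out = 20), sprintf("g%d", 1:20))
  tpm <- setNames(10^(1 + 3 * scores), names(scores))
  # noiseless input: lm warns about a perfect fit, which is the point here
  fit <- suppressWarnings(fit_expression_model(scores, tpm))
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$spearman_rho, 1)
  expect_equal(predict(fit, 0.5), 10^(1 + 1.5), tolerance = 1e-9)
  # anti-monotone data
  anti <- suppressWarnings(
    fit_expression_model(scores, setNames(rev(unname(tpm)), names(tpm))))
  expect_equal(anti$spearman_rho, -1)
})

test_that("zero-TPM genes are dropped from the log fit but kept for Spearman", {
  scores <- setNames(seq(0.2, 0.8, length.out = 10), sprintf("g%d", 1:10))
  tpm <- setNames(10^(0.5 + 2 * scores), names(scores))
  tpm[1] <- 0
  fit <- suppressWarnings(fit_expression_model(scores, tpm))  # perfect fit
  expect_equal(fit$n, 9)
  expect_equal(fit$n_dropped_zero, 1)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
})

test_that("the expression model recovers the slope of noisy synthetic data", {
  # informative design: a bimodal hidden matrix plus strongly biased per-gene
  # composition spreads true scores widely, so the slope is well identified
  tw <- codon_weights(setNames(rep(c(0.02, 1), c(30, 31)), sense_codons()))
  ds <- simulate_dataset(n_genes = 1000, true_weights = tw,
                         noise = lognormal_tpm(intercept = 0.5, slope = 4,
                                               sigma = 0.3),
                         composition = "dirichlet", dirichlet_alpha = 0.1,
                         seed = 99)
  fit <- fit_expression_model(ds$true_scores, ds$abundances)
  expect_lt(abs(fit$slope - 4), 0.2)
  expect_lt(abs(fit$intercept - 0.5), 0.15)
})

test_that("TPM converts linearly to molecules per cell", {
  expect_identical(tpm_to_molecules(20), 1)
  expect_identical(tpm_to_molecules(0), 0)
  expect_identical(tpm_to_molecules(50), 2.5)
  expect_equal(tpm_to_molecules(c(20, 40)), c(1, 2))
  expect_equal(tpm_to_molecules(20, mrnas_per_cell = 1e5), 2)
  expect_error(tpm_to_molecules(-1), "non-negative")
})

test_that("copy-number adjustment is a plain positive scaling", {
  expect_equal(adjust_copy_number(3.5, 8), 28)
  expect_equal(adjust_copy_number(3.5, 1), 3.5)
  expect_equal(adjust_copy_number(0, 8), 0)
  expect_error(adjust_copy_number(1, 0), "positive")
})

test_that("group comparison matches the closed-form pooled-variance t statistic", {
  a <- c(1.1, 2.3, 3.2, 4.8)
  b <- c(2.0, 2.2, 5.1)
  res <- compare_groups(a, b)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$df, na + nb - 2)
  expect_equal(res$p, 2 * pt(-abs(t_manual), na + nb - 2), tolerance = 1e-10)
  expect_equal(res$mean_a, mean(a))
  expect_equal(res$sd_b, sd(b))
})

test_that("group comparison degenerate and extreme cases behave", {
  idn <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idn$t, 0)
  expect_equal(idn$p, 1)
  shifted <- compare_groups(c(1, 2, 3), c(11, 12, 13))
  # exact pooled-variance t: t = -10 / sqrt(1 * 2/3) on 4 df
  expect_equal(shifted$p, 2 * pt(-10 / sqrt(2 / 3), 4), tolerance = 1e-10)
  expect_lt(shifted$p, 1e-3)
  expect_error(compare_groups(c(2, 2), c(2, 2)), "pooled variance")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("simulated ribosomal-protein-like groups separate decisively", {
  # groups drawn at the published cytosolic/mitochondrial means and SDs
  set.seed(1234)
  cyto <- rnorm(75, 0.439, 0.034)
  mito <- rnorm(41, 0.378, 0.033)
  res <- compare_groups(cyto, mito)
  expect_lt(res$p, 1e-5)
  expect_gt(res$mean_a, res$mean_b)
})

test_that("score-vs-external correlation works over id intersections", {
  scores <- setNames(c(0.2, 0.4, 0.5, 0.7, 0.9), sprintf("g%d", 1:5))
  half_life <- setNames(c(12, 18, 15, 40, 60), sprintf("g%d", 1:5))
  rho <- correlate_scores(scores, half_life)
  # manual average-rank Spearman on the 5 hand-built pairs
  expect_equal(as.numeric(rho), cor(rank(scores), rank(half_life)),
               tolerance = 1e-12)
  expect_equal(attr(rho, "n"), 5)
  expect_equal(as.numeric(correlate_scores(scores, scores)), 1)
  disjoint <- setNames(1:3, c("x1", "x2", "x3"))
  expect_error(correlate_scores(scores, disjoint), "shared")
})

test_that("transforms drop non-finite values with a count", {
  scores <- setNames(c(0.2, 0.4, 0.5, 0.7, 0.9), sprintf("g%d", 1:5))
  ext <- setNames(c(0, 10, 100, 1000, 10000), names(scores))
  r <- correlate_scores(scores, ext, method = "pearson", transform = "log10")
  expect_equal(attr(r, "n"), 4)
  expect_equal(attr(r, "n_dropped"), 1)
  expect_equal(as.numeric(r),
               cor(c(0.4, 0.5, 0.7, 0.9), log10(c(10, 100, 1000, 10000))),
               tolerance = 1e-12)
})
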