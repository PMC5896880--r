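# Small shared dataset for learner tests.
learner_fixture <- function(n = 40, seed = 13) {
  ds <- simulate_dataset(n_genes = n, noise = lognormal_tpm(sigma = 0.4),
                         seed = seed)
  list(orfs = ds$orfs, tpm = ds$abundances, true = ds$true_weights)
}

test_that("the Spearman objective handles concordance, discordance and ties", {
  w <- toy_weights()
  # hand-built score/abundance pairs exercised through cor() directly mirror
  # the objective's contract
  expect_equal(cor(c(0.1, 0.2, 0.3), c(1, 2, 3), method = "spearman"), 1)
  expect_equal(cor(c(0.1, 0.2, 0.3), c(3, 2, 1), method = "spearman"), -1)
  # average-rank ties: scores (1,2,3,4) vs TPM (1,2,2,4); hand-computed
  # Pearson of ranks (1,2,3,4) and (1,2.5,2.5,4) = 4.5/sqrt(5*4.5)
  expect_equal(cor(c(1, 2, 3, 4), c(1, 2, 2, 4), method = "spearman"),
               4.5 / sqrt(5 * 4.5), tolerance = 1e-12)

  fx <- learner_fixture()
  expect_error(spearman_objective(w, fx$orfs[1:2], fx$tpm), "at least 3")
  const <- setNames(rep(5, length(fx$orfs)), fx$orfs$ids)
  expect_error(spearman_objective(w, fx$orfs, const), "constant")
  expect_error(spearman_objective(w, fx$orfs,
                                  fx$tpm[-match(fx$orfs$ids[1], names(fx$tpm))]),
               fx$orfs$ids[1])
})

test_that("random starting matrices satisfy the global max-1 constraint", {
  set.seed(1)
  for (i in 1:20) {
    w <- random_weight_matrix()
    expect_equal(max(as.numeric(w)), 1)
    expect_gt(min(as.numeric(w)), 0)
  }
  set.seed(99); w1 <- random_weight_matrix()
  set.seed(99); w2 <- random_weight_matrix()
  expect_identical(as.numeric(w1), as.numeric(w2))
})

test_that("proposals perturb exactly k codons and stay inside (floor, 1]", {
  set.seed(5)
  w <- random_weight_matrix()
  for (i in 1:20) {
    p <- propose_weights(w, sigma = 0.1, k = 1)
    expect_equal(sum(as.numeric(p) != as.numeric(w)), 1)
    expect_true(all(as.numeric(p) > 0 & as.numeric(p) <= 1))
  }
  p3 <- propose_weights(w, sigma = 0.3, k = 3)
  expect_lte(sum(as.numeric(p3) != as.numeric(w)), 3)
  # vanishing step size leaves the matrix essentially unchanged
  tiny <- propose_weights(w, sigma = 1e-12, k = 1)
  expect_equal(as.numeric(tiny), as.numeric(w), tolerance = 1e-9)
  # large kicks are reflected, not clamped, so values do not pile up at bounds
  set.seed(6)
  big <- replicate(200, {
    p <- propose_weights(w, sigma = 5, k = 1)
    as.numeric(p)[which(as.numeric(p) != as.numeric(w))]
  })
  expect_true(all(big > 0 & big <= 1))
  expect_lt(mean(big %in% c(1e-4, 1)), 0.05)
})

test_that("chains are greedy: traces never decrease and zero generations is the identity", {
  fx <- learner_fixture()
  cfg <- learner_config(n_chains = 1, n_generations = 300, seed = 4,
                        record_trace_every = 7)
  ch <- run_chain(fx$orfs, fx$tpm, cfg, chain_seed = 42)
  expect_true(all(diff(ch$trace$best_rho) >= 0))
  expect_equal(ch$best_rho, ch$trace$best_rho[nrow(ch$trace)])
  expect_equal(max(ch$trace$generation), 300)

  cfg0 <- learner_config(n_chains = 1, n_generations = 0, seed = 4)
  ch0 <- run_chain(fx$orfs, fx$tpm, cfg0, chain_seed = 42)
  set.seed(42)
  init <- random_weight_matrix(cfg0$weight_floor)
  expect_identical(as.numeric(ch0$best_weights), as.numeric(init))
})

test_that("incremental chain rescoring matches a full rescore through the public objective", {
  fx <- learner_fixture()
  cfg <- learner_config(n_chains = 1, n_generations = 250, seed = 8)
  ch <- run_chain(fx$orfs, fx$tpm, cfg, chain_seed = 17)
  # dual route: the chain's incrementally tracked rho vs stats::cor on a
  # fresh full scoring of the final matrix
  expect_equal(spearman_objective(ch$best_weights, fx$orfs, fx$tpm),
               ch$best_rho, tolerance = 1e-12)
})

test_that("the objective is invariant under global weight rescaling", {
  fx <- learner_fixture()
  set.seed(3)
  w <- random_weight_matrix()
  base <- spearman_objective(w, fx$orfs, fx$tpm)
  for (k in c(0.2, 0.9)) {
    wk <- codon_weights(setNames(as.numeric(w) * k, names(w)))
    expect_equal(spearman_objective(wk, fx$orfs, fx$tpm), base, tolerance = 1e-12)
  }
})

test_that("learning aggregates chains by per-codon median and renormalizes", {
  fx <- learner_fixture()
  cfg1 <- learner_config(n_chains = 1, n_generations = 150, seed = 21)
  fit1 <- learn_gecai(fx$orfs, fx$tpm, cfg1)
  ch <- run_chain(fx$orfs, fx$tpm, cfg1, chain_seed = cfg1$seed + 1)
  expect_equal(as.numeric(fit1$median_weights),
               as.numeric(ch$best_weights) / max(as.numeric(ch$best_weights)),
               tolerance = 1e-12)
  expect_true(attr(fit1$median_weights, "normalized"))

  cfg <- learner_config(n_chains = 4, n_generations = 150, seed = 21)
  fit <- learn_gecai(fx$orfs, fx$tpm, cfg)
  W <- vapply(fit$chains, function(c) as.numeric(c$best_weights), numeric(61))
  expect_equal(unname(fit$quartiles[, "median"]), unname(apply(W, 1, median)),
               tolerance = 1e-12)
  # median lies within the per-codon range across chains
  expect_true(all(fit$quartiles[, "median"] >= apply(W, 1, min) - 1e-12))
  expect_true(all(fit$quartiles[, "median"] <= apply(W, 1, max) + 1e-12))
  # renormalizing the median matrix does not change its objective
  expect_equal(fit$objective_median,
               spearman_objective(codon_weights(
                 setNames(fit$quartiles[, "median"], sense_codons())),
                 fx$orfs, fx$tpm),
               tolerance = 1e-12)
})

test_that("an identical seed reproduces an identical fit", {
  fx <- learner_fixture()
  cfg <- learner_config(n_chains = 3, n_generations = 100, seed = 77)
  f1 <- learn_gecai(fx$orfs, fx$tpm, cfg)
  f2 <- learn_gecai(fx$orfs, fx$tpm, cfg)
  expect_identical(as.numeric(f1$median_weights), as.numeric(f2$median_weights))
  expect_identical(f1$objective_median, f2$objective_median)
  expect_identical(lapply(f1$chains, `[[`, "trace"),
                   lapply(f2$chains, `[[`, "trace"))
})

test_that("greedy learning never loses ground against its starting matrices", {
  fx <- learner_fixture()
  cfg <- learner_config(n_chains = 3, n_generations = 200, seed = 5)
  fit <- learn_gecai(fx$orfs, fx$tpm, cfg)
  for (ch in fit$chains) {
    expect_gte(ch$best_rho, ch$trace$best_rho[1])
  }
  expect_gte(fit$best_chain_rho, max(vapply(fit$chains, function(c)
    c$trace$best_rho[1], 0)))
})

test_that("chains plateau: the final fifth of a long run adds under 1% of improvement", {
  ds <- simulate_dataset(n_genes = 500, noise = rank_noise(0.7), seed = 31)
  cfg <- learner_config(n_chains = 3, n_generations = 5000, seed = 31)
  fit <- learn_gecai(ds$orfs, ds$abundances, cfg)
  late_frac <- vapply(fit$chains, function(ch) {
    tr <- ch$trace
    total <- tr$best_rho[nrow(tr)] - tr$best_rho[1]
    late <- tr$best_rho[nrow(tr)] -
      tr$best_rho[max(which(tr$generation <= 0.8 * max(tr$generation)))]
    late / total
  }, 0)
  expect_lt(median(late_frac), 0.01)
})

test_that("fit outputs are written completely", {
  fx <- learner_fixture(n = 20)
  cfg <- learner_config(n_chains = 2, n_generations = 50, seed = 2)
  fit <- learn_gecai(fx$orfs, fx$tpm, cfg)
  dir <- withr::local_tempdir()
  write_gecai_fit(fit, dir)
  expect_true(all(file.exists(file.path(dir,
    c("median_weights.tsv", "quartiles.tsv", "traces.tsv", "fit.json")))))
  w <- read_weight_table(file.path(dir, "median_weights.tsv"))
  expect_identical(as.numeric(w), as.numeric(fit$median_weights))
})
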