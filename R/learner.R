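#' Learner configuration
#'
#' Configuration for the multi-chain stochastic hill-climber of
#' [learn_gecai()]. Defaults mirror the full-scale learning setup (1000
#' chains of 5000 generations); scale `n_chains`/`n_generations` down for
#' exploratory runs.
#'
#' @param n_chains Number of independent chains (>= 1).
#' @param n_generations Generations per chain (>= 0; 0 returns the initial
#'   random matrix).
#' @param proposal_sigma Standard deviation of the Gaussian perturbation
#'   applied to a proposed codon weight. The default 0.1 lets a chain
#'   traverse the (0, 1] interval within a few thousand single-codon moves.
#' @param codons_per_proposal Number of distinct codons perturbed per
#'   generation.
#' @param seed Integer master seed; chain `i` runs with seed `seed + i`.
#' @param record_trace_every Record the best objective every this many
#'   generations (plus generation 0 and the final generation).
#' @param weight_floor Smallest admissible weight. A weight of exactly 0
#'   annihilates any geometric mean containing that codon and makes the log
#'   undefined, so weights live in (floor, 1].
#' @return An object of class `learner_config`.
#' @export
learner_config <- function(n_chains = 1000, n_generations = 5000,
                           proposal_sigma = 0.1, codons_per_proposal = 1,
                           seed = 1, record_trace_every = 10,
                           weight_floor = 1e-4) {
  stopifnot(n_chains >= 1, n_generations >= 0, proposal_sigma > 0,
            codons_per_proposal >= 1, codons_per_proposal <= 61,
            record_trace_every >= 1, weight_floor > 0, weight_floor < 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_generations = as.integer(n_generations),
                 proposal_sigma = proposal_sigma,
                 codons_per_proposal = as.integer(codons_per_proposal),
                 seed = as.integer(seed),
                 record_trace_every = as.integer(record_trace_every),
                 weight_floor = weight_floor),
            class = "learner_config")
}

#' @export
print.learner_config <- function(x, ...) {
  cat(sprintf(paste0("Learner config: %d chains x %d generations, ",
                     "sigma %.3g, %d codon(s)/proposal, seed %d\n"),
              x$n_chains, x$n_generations, x$proposal_sigma,
              x$codons_per_proposal, x$seed))
  invisible(x)
}

## Align an ORF set with an abundance vector; precompute the quantities the
## chain loop needs: counts/length matrix and the (fixed) abundance ranks.
.learner_data <- function(orfs, abundances) {
  orfs <- codonize_orfs(orfs)
  missing <- setdiff(orfs$ids, names(abundances))
  if (length(missing))
    stop("ORF id(s) missing from abundances: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  if (length(orfs) < 3) stop("need at least 3 paired genes")
  tpm <- as.numeric(abundances[orfs$ids])
  if (max(tpm) == min(tpm)) stop("abundance vector is constant; Spearman undefined")
  list(Mnorm = orfs$counts / orfs$length_codons, rank_tpm = rank(tpm))
}

#' Spearman objective of a weight matrix
#'
#' The learning objective: Spearman's rank correlation (average ranks on
#' ties) between geCAI scores of the ORFs and their measured abundances.
#' Because the geometric mean is degree-1 homogeneous, the objective is
#' invariant to a global rescaling of the weights.
#'
#' @param weights A [codon_weights] object.
#' @param orfs An `orf_set`; every id must appear in `abundances`.
#' @param abundances Named numeric vector of TPM.
#' @return Spearman's rho in \[-1, 1\].
#' @export
spearman_objective <- function(weights, orfs, abundances) {
  orfs <- codonize_orfs(orfs)
  missing <- setdiff(orfs$ids, names(abundances))
  if (length(missing))
    stop("ORF id(s) missing from abundances: ", paste(missing, collapse = ", "))
  if (length(orfs) < 3) stop("need at least 3 paired genes")
  tpm <- as.numeric(abundances[orfs$ids])
  if (max(tpm) == min(tpm)) stop("abundance vector is constant; Spearman undefined")
  stats::cor(gecai_scores(orfs, weights), tpm, method = "spearman")
}

#' Draw a random starting weight matrix
#'
#' Each codon gets a weight drawn uniformly from (floor, 1], then one codon
#' chosen uniformly is set to exactly 1 -- the single global constraint that
#' at least one of the 61 codons carries the maximum value.
#'
#' Uses R's global RNG; call `set.seed()` for reproducibility.
#'
#' @param weight_floor Lower bound keeping weights positive.
#' @return A normalized [codon_weights] object.
#' @export
random_weight_matrix <- function(weight_floor = 1e-4) {
  w <- stats::runif(61, min = weight_floor, max = 1)
  w[sample.int(61, 1)] <- 1
  codon_weights(setNames(w, .SENSE_CODONS))
}

## Reflect values into (floor, 1]; reflection (rather than clamping) avoids
## probability mass accumulating at the boundaries.
.reflect <- function(x, floor) {
  span <- 1 - floor
  z <- (x - floor) %% (2 * span)
  z <- ifelse(z > span, 2 * span - z, z)
  floor + z
}

#' Propose a perturbed weight matrix
#'
#' Copies the matrix and adds Gaussian noise of sd `sigma` to `k` distinct
#' uniformly chosen codons, reflecting the result back into
#' (`weight_floor`, 1]. All untouched weights are unchanged.
#'
#' Uses R's global RNG.
#'
#' @param weights A [codon_weights] object.
#' @param sigma Perturbation standard deviation.
#' @param k Number of codons to perturb.
#' @param weight_floor Lower reflection boundary.
#' @return A `codon_weights` object.
#' @export
propose_weights <- function(weights, sigma = 0.1, k = 1, weight_floor = 1e-4) {
  w <- as.numeric(weights)
  names(w) <- names(weights)
  j <- sample.int(61, k)
  w[j] <- .reflect(w[j] + stats::rnorm(k, 0, sigma), weight_floor)
  codon_weights(w)
}

#' Run one hill-climbing chain
#'
#' Starts from a random weight matrix and runs `n_generations` of greedy
#' stochastic search: each generation perturbs the current best matrix
#' ([propose_weights()]) and the proposal replaces it if and only if its
#' Spearman objective is strictly greater. Rescoring is incremental (a
#' proposal touching k codons updates all gene scores in O(n_genes * k)),
#' and matches full rescoring to floating-point accuracy.
#'
#' @param orfs An `orf_set`.
#' @param abundances Named numeric vector of TPM covering all ORF ids.
#' @param config A [learner_config()].
#' @param chain_seed Integer seed for this chain's RNG stream.
#' @return An object of class `chain_result`: list with `best_weights`
#'   (a [codon_weights]), `best_rho`, `trace` (data frame of `generation`,
#'   `best_rho`; non-decreasing by construction) and `chain_seed`.
#' @export
run_chain <- function(orfs, abundances, config = learner_config(),
                      chain_seed = config$seed) {
  dat <- .learner_data(orfs, abundances)
  .run_chain_fast(dat$Mnorm, dat$rank_tpm, config, chain_seed)
}

## Core loop on precomputed matrices; shared by run_chain() and learn_gecai().
.run_chain_fast <- function(Mnorm, rank_tpm, config, chain_seed) {
  set.seed(chain_seed)
  floor <- config$weight_floor
  sigma <- config$proposal_sigma
  k <- config$codons_per_proposal
  w <- as.numeric(random_weight_matrix(floor))
  lw <- log(w)
  ls <- as.vector(Mnorm %*% lw)
  best <- stats::cor(rank(ls), rank_tpm)
  gens <- config$n_generations
  trace_at <- unique(c(0L, seq_len(gens)[seq_len(gens) %% config$record_trace_every == 0],
                       gens))
  trace_rho <- numeric(length(trace_at))
  trace_rho[1] <- best
  ti <- 2L
  for (g in seq_len(gens)) {
    j <- sample.int(61, k)
    nw <- .reflect(w[j] + stats::rnorm(k, 0, sigma), floor)
    dl <- log(nw) - lw[j]
    cand <- if (k == 1) ls + Mnorm[, j] * dl
            else ls + as.vector(Mnorm[, j, drop = FALSE] %*% dl)
    rho <- stats::cor(rank(cand), rank_tpm)
    if (rho > best) {          # strictly greater: ties reject
      best <- rho
      w[j] <- nw
      lw[j] <- log(nw)
      ls <- cand
    }
    if (ti <= length(trace_at) && g == trace_at[ti]) {
      trace_rho[ti] <- best
      ti <- ti + 1L
    }
  }
  structure(list(best_weights = codon_weights(setNames(w, .SENSE_CODONS)),
                 best_rho = best,
                 trace = data.frame(generation = trace_at, best_rho = trace_rho),
                 chain_seed = chain_seed),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("Chain (seed %d): best rho %.4f after %d generations\n",
              x$chain_seed, x$best_rho, max(x$trace$generation)))
  invisible(x)
}

#' Learn a geCAI weight matrix
#'
#' Runs `n_chains` independent hill-climbing chains ([run_chain()]), each
#' from a different random starting matrix with seed `config$seed + i`, and
#' aggregates them: the learned weight of each codon is the median of its
#' per-chain best values, renormalized so the maximum weight is 1
#' (renormalization cannot change the objective, which is scale-invariant).
#' Per-codon quartiles across chains quantify learning stability.
#'
#' Chain seeds are fixed by the configuration, so results are independent
#' of execution order.
#'
#' @param orfs An `orf_set` (or named character vector of sequences).
#' @param abundances Named numeric vector of TPM covering all ORF ids.
#' @param config A [learner_config()].
#' @return An object of class `gecai_fit`: list with `config`, `chains`
#'   (list of `chain_result`), `median_weights` (normalized
#'   [codon_weights]), `quartiles` (61 x 3 matrix: Q1, median, Q3),
#'   `objective_median` (Spearman objective of the median matrix),
#'   `best_chain` and `best_chain_rho`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(n_genes = 100, seed = 7,
#'                        noise = lognormal_tpm(sigma = 0.2))
#' fit <- learn_gecai(ds$orfs, ds$abundances,
#'                    learner_config(n_chains = 2, n_generations = 200, seed = 7))
#' fit$objective_median
#' }
#' @export
learn_gecai <- function(orfs, abundances, config = learner_config()) {
  orfs <- codonize_orfs(orfs)
  dat <- .learner_data(orfs, abundances)
  chains <- lapply(seq_len(config$n_chains), function(i)
    .run_chain_fast(dat$Mnorm, dat$rank_tpm, config, config$seed + i))
  W <- vapply(chains, function(ch) as.numeric(ch$best_weights), numeric(61))
  qs <- t(apply(W, 1, stats::quantile, probs = c(0.25, 0.5, 0.75)))
  dimnames(qs) <- list(.SENSE_CODONS, c("Q1", "median", "Q3"))
  med <- normalize_weights(setNames(qs[, "median"], .SENSE_CODONS))
  rhos <- vapply(chains, `[[`, 0, "best_rho")
  fit <- structure(list(config = config, chains = chains,
                        median_weights = med, quartiles = qs,
                        objective_median = spearman_objective(med, orfs, abundances),
                        best_chain = which.max(rhos),
                        best_chain_rho = max(rhos)),
                   class = "gecai_fit")
  fit
}

#' @export
print.gecai_fit <- function(x, ...) {
  cat(sprintf("geCAI fit: %d chains x %d generations\n",
              x$config$n_chains, x$config$n_generations))
  cat(sprintf("  objective of median matrix: rho = %.4f\n", x$objective_median))
  cat(sprintf("  best single chain: #%d, rho = %.4f\n",
              x$best_chain, x$best_chain_rho))
  invisible(x)
}

#' Write the outputs of a geCAI fit
#'
#' Writes `median_weights.tsv`, `quartiles.tsv`, the per-chain traces
#' (`traces.tsv`, long format) and a JSON manifest of the run.
#'
#' @param fit A `gecai_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gecai_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_weight_table(fit$median_weights, file.path(dir, "median_weights.tsv"))
  qtab <- data.frame(codon = rownames(fit$quartiles), fit$quartiles,
                     check.names = FALSE)
  utils::write.table(qtab, file.path(dir, "quartiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  traces <- do.call(rbind, lapply(seq_along(fit$chains), function(i)
    cbind(chain = i, fit$chains[[i]]$trace)))
  utils::write.table(traces, file.path(dir, "traces.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(fit$config),
                   objective_median = fit$objective_median,
                   best_chain = fit$best_chain,
                   best_chain_rho = fit$best_chain_rho,
                   package_version = as.character(utils::packageVersion("gecai")))
  jsonlite::write_json(manifest, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
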