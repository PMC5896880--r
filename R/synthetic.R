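#' Noise models for synthetic abundances
#'
#' `rank_noise(target_rho)` degrades the rank agreement between true scores
#' and abundances to a chosen Spearman correlation using a Gaussian copula:
#' the copula correlation is `r = 2 sin(pi * rho_S / 6)` (the inverse of
#' `rho_S = (6 / pi) asin(r / 2)`), and abundances are a monotone log-normal
#' transform of the noisy normal scores. `lognormal_tpm(...)` generates
#' `TPM = 10^(intercept + slope * score + Normal(0, sigma))`, the log-linear
#' relationship used when regressing abundance on score.
#'
#' @param target_rho Spearman correlation the generated data should realize
#'   (attained to about +/-0.03 for 300 genes or more).
#' @param intercept,slope,sigma Log10-scale regression parameters and noise
#'   sd of the log-normal model.
#' @return A `noise_model` object.
#' @export
rank_noise <- function(target_rho = 0.55) {
  if (!is.numeric(target_rho) || target_rho <= 0 || target_rho > 1)
    stop("`target_rho` must lie in (0, 1]")
  structure(list(model = "rank_noise", target_rho = target_rho),
            class = "noise_model")
}

#' @rdname rank_noise
#' @export
lognormal_tpm <- function(intercept = 0.5, slope = 4, sigma = 0.3) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  structure(list(model = "lognormal_tpm", intercept = intercept,
                 slope = slope, sigma = sigma),
            class = "noise_model")
}

#' Generate a synthetic ORF/abundance dataset with a known weight matrix
#'
#' Builds `n_genes` coding sequences (a leading ATG, sampled sense codons,
#' a random stop codon) and abundances tied to the geCAI scores under a
#' hidden "true" weight matrix, for parameter-recovery testing of
#' [learn_gecai()]. Gene lengths follow a log-normal (default mean 400
#' codons, sd 0.4 in log space, floored at 30 codons), roughly matching
#' trypanosome ORF lengths. Per-gene codon composition is Dirichlet by
#' default, with `dirichlet_alpha = 0.4` calibrated so that, under the
#' bundled published weight matrix, the simulated inter-gene score
#' dispersion (sd about 0.06, central range about 0.2-0.5) matches the
#' spread observed across a real procyclic transcriptome;
#' `composition = "uniform"` gives every gene the same expected
#' composition (and a much narrower score spread than real data).
#'
#' The generator is a pure function of its arguments: a fixed seed yields a
#' byte-identical dataset.
#'
#' @param n_genes Number of genes (>= 3).
#' @param true_weights Hidden [codon_weights]; default: a fresh
#'   [random_weight_matrix()].
#' @param noise A `noise_model` from [rank_noise()] or [lognormal_tpm()].
#' @param length_mean,length_sdlog Log-normal codon-length parameters.
#' @param composition `"dirichlet"` (default) or `"uniform"`.
#' @param dirichlet_alpha Symmetric Dirichlet concentration per codon.
#' @param seed Integer seed for all randomness in the generator.
#' @return An object of class `synthetic_dataset`: list with `orfs`
#'   (an `orf_set`), `abundances` (named TPM vector), `true_weights`,
#'   `true_scores` and `realized_rho` (Spearman between true scores and
#'   abundances actually attained).
#' @examples
#' ds <- simulate_dataset(n_genes = 50, seed = 1)
#' ds$realized_rho
#' @export
simulate_dataset <- function(n_genes, true_weights = NULL,
                             noise = rank_noise(0.55),
                             length_mean = 400, length_sdlog = 0.4,
                             composition = c("dirichlet", "uniform"),
                             dirichlet_alpha = 0.4, seed = 1) {
  composition <- match.arg(composition)
  if (n_genes < 3) stop("`n_genes` must be >= 3")
  if (!inherits(noise, "noise_model")) stop("`noise` must be a noise_model")
  set.seed(seed)
  if (is.null(true_weights)) true_weights <- random_weight_matrix()
  true_weights <- codon_weights(true_weights)
  lens <- pmax(30L, as.integer(round(stats::rlnorm(n_genes, log(length_mean),
                                                   length_sdlog))))
  ids <- sprintf("g%04d", seq_len(n_genes))
  seqs <- vapply(seq_len(n_genes), function(i) {
    p <- if (composition == "dirichlet") {
      g <- stats::rgamma(61, dirichlet_alpha)
      g / sum(g)
    } else rep(1 / 61, 61)
    body <- .SENSE_CODONS[sample.int(61, lens[i] - 1L, replace = TRUE, prob = p)]
    paste0("ATG", paste(body, collapse = ""), sample(stop_codons(), 1))
  }, "")
  orfs <- codonize_orfs(setNames(seqs, ids))
  true_scores <- gecai_scores(orfs, true_weights)
  tpm <- switch(noise$model,
    lognormal_tpm = 10^(noise$intercept + noise$slope * true_scores +
                          stats::rnorm(n_genes, 0, noise$sigma)),
    rank_noise = {
      r <- 2 * sin(pi * noise$target_rho / 6)
      z1 <- stats::qnorm((rank(true_scores) - 0.5) / n_genes)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_genes)
      stats::qlnorm(stats::pnorm(z2), meanlog = log(100), sdlog = 1)
    })
  tpm <- setNames(as.numeric(tpm), ids)
  structure(list(orfs = orfs, abundances = tpm,
                 true_weights = true_weights,
                 true_scores = true_scores,
                 realized_rho = stats::cor(true_scores, tpm, method = "spearman"),
                 spec = list(n_genes = n_genes, noise = unclass(noise),
                             length_mean = length_mean,
                             length_sdlog = length_sdlog,
                             composition = composition,
                             dirichlet_alpha = dirichlet_alpha, seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d genes, %s noise, realized rho %.3f\n",
              length(x$orfs), x$spec$noise$model, x$realized_rho))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `orfs.fa`, `tpm.tsv`, `true_weights.tsv` and `manifest.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_orf_fasta(dataset$orfs, file.path(dir, "orfs.fa"))
  write_abundance_table(dataset$abundances, file.path(dir, "tpm.tsv"))
  write_weight_table(dataset$true_weights, file.path(dir, "true_weights.tsv"))
  manifest <- c(dataset$spec,
                list(realized_rho = dataset$realized_rho,
                     package_version = as.character(utils::packageVersion("gecai"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

.translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  unname(gc[codons])
}

#' Translate a coding sequence
#'
#' @param sequence DNA string (multiple of 3; terminal stop allowed).
#' @return Amino-acid string (stop stripped).
#' @export
translate_orf <- function(sequence) {
  rec <- codonize_orf("x", sequence)
  n <- nchar(rec$sequence)
  codons <- substring(rec$sequence, seq(1, n, 3), seq(3, n, 3))
  codons <- codons[!codons %in% stop_codons()]
  paste(.translate_codons(codons), collapse = "")
}

#' Achievable geCAI score range of a protein
#'
#' The extreme scores reachable by synonymous recoding: geometric means of
#' the per-position minimum and maximum family weights.
#'
#' @param x Amino-acid string, or a DNA ORF (auto-detected and translated).
#' @param weights A [codon_weights] object.
#' @return Numeric vector `c(min, max)`.
#' @export
achievable_score_range <- function(x, weights) {
  aa <- .as_protein(x)
  weights <- codon_weights(weights)
  fam <- split(as.numeric(weights), codon_amino_acids())
  lo <- vapply(aa, function(a) min(fam[[a]]), 0)
  hi <- vapply(aa, function(a) max(fam[[a]]), 0)
  c(min = exp(mean(log(lo))), max = exp(mean(log(hi))))
}

## Accept a protein string or a DNA ORF; return the amino-acid vector.
.as_protein <- function(x) {
  stopifnot(is.character(x), length(x) == 1, nzchar(x))
  s <- toupper(x)
  if (grepl("^[ACGTU]+$", s) && nchar(s) %% 3 == 0 && nchar(s) >= 6) {
    s <- translate_orf(s)
  }
  aa <- strsplit(sub("\\*$", "", s), "")[[1]]
  valid <- aa %in% unique(codon_amino_acids())
  if (!all(valid))
    stop("unknown amino acid(s): ", paste(unique(aa[!valid]), collapse = ", "))
  aa
}

#' Synonymously recode an ORF to a target geCAI score
#'
#' Designs a coding sequence for a protein (or for the translation of an
#' input ORF) whose geCAI score lies within `tolerance` of `target_score`,
#' mimicking the construction of reporter panels recoded across a range of
#' scores. The search starts from the per-position codon whose log-weight
#' is closest to the target log-score and then greedily re-picks codons in
#' random sweeps, at each position choosing the family codon that brings
#' the running mean log-weight closest to the target.
#'
#' Uses R's global RNG for sweep order and tie-breaking; call `set.seed()`
#' for reproducible designs.
#'
#' @param x Protein string or DNA ORF.
#' @param weights A [codon_weights] object.
#' @param target_score Desired geCAI score; must lie within
#'   [achievable_score_range()] of the protein.
#' @param tolerance Admissible absolute deviation of the realized score.
#' @param id Identifier for the returned record.
#' @param max_sweeps Upper bound on refinement sweeps.
#' @return An `orf_record` of the recoded sequence (terminal TAA appended),
#'   with attribute `score` giving its realized geCAI score.
#' @examples
#' w <- gecai_weights_pcf()
#' rec <- recode_orf("MKTAYIAK", w, target_score = 0.5, tolerance = 0.01)
#' attr(rec, "score")
#' @export
recode_orf <- function(x, weights, target_score, tolerance = 0.005,
                       id = "recoded", max_sweeps = 200) {
  aa <- .as_protein(x)
  weights <- codon_weights(weights)
  rng <- achievable_score_range(paste(aa, collapse = ""), weights)
  if (target_score < rng[["min"]] - tolerance ||
      target_score > rng[["max"]] + tolerance)
    stop(sprintf("target score %.4f is unreachable; achievable interval is [%.4f, %.4f]",
                 target_score, rng[["min"]], rng[["max"]]))
  fam_codons <- split(names(codon_amino_acids()), codon_amino_acids())
  fam_logw <- lapply(fam_codons, function(cs) log(as.numeric(weights[cs])))
  n <- length(aa)
  tlog <- log(target_score)
  ## start: per-position codon with log-weight closest to the target
  pick <- integer(n)
  for (i in seq_len(n)) pick[i] <- which.min(abs(fam_logw[[aa[i]]] - tlog))
  cur <- vapply(seq_len(n), function(i) fam_logw[[aa[i]]][pick[i]], 0)
  m <- mean(cur)
  log_tol <- abs(log(max(target_score - tolerance, 1e-12)) - tlog)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in sample.int(n)) {
      lws <- fam_logw[[aa[i]]]
      cand_m <- m + (lws - cur[i]) / n
      j <- which.min(abs(cand_m - tlog))
      if (j != pick[i] && abs(cand_m[j] - tlog) < abs(m - tlog) - 1e-15) {
        m <- cand_m[j]
        pick[i] <- j
        cur[i] <- lws[j]
        changed <- TRUE
      }
    }
    if (abs(m - tlog) <= log_tol * 0.5 || !changed) break
  }
  seq <- paste0(paste(vapply(seq_len(n), function(i)
    fam_codons[[aa[i]]][pick[i]], ""), collapse = ""), "TAA")
  rec <- codonize_orf(id, seq)
  score <- gecai_score(rec, weights)
  if (abs(score - target_score) > tolerance)
    stop(sprintf(paste0("recoding converged to score %.4f, outside the ",
                        "+/-%.4g tolerance of target %.4f"),
                 score, tolerance, target_score))
  attr(rec, "score") <- score
  rec
}
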