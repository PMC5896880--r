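#' Filter a training set by annotation flags
#'
#' Retains the genes suitable for weight learning: single-copy genes that
#' are not developmentally regulated (no more-than-twofold abundance change
#' between life-cycle stages) and that have a homolog in at least one other
#' kinetoplastid species. The three exclusions respectively remove genes
#' whose TPM is unreliable (multicopy read allocation), genes whose levels
#' are set by stage-specific trans-acting factors, and potentially spurious
#' ORFs.
#'
#' @param abundances Named numeric vector of TPM.
#' @param annotations Data frame with columns `gene_id`, `is_single_copy`,
#'   `is_dev_regulated`, `has_kinetoplastid_homolog` (logical flags); must
#'   cover every abundance id.
#' @return The filtered abundance vector, with attribute `filter_counts`:
#'   named counts of genes removed under each rule (a gene failing several
#'   rules is counted under each) and `n_retained`.
#' @export
filter_training_set <- function(abundances, annotations) {
  req <- c("gene_id", "is_single_copy", "is_dev_regulated",
           "has_kinetoplastid_homolog")
  if (!all(req %in% names(annotations)))
    stop("`annotations` must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(annotations$gene_id))
    stop("duplicate gene id(s) in annotations")
  ids <- names(abundances)
  missing <- setdiff(ids, annotations$gene_id)
  if (length(missing))
    stop("unannotated gene id(s): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  ann <- annotations[match(ids, annotations$gene_id), ]
  keep <- ann$is_single_copy & !ann$is_dev_regulated &
    ann$has_kinetoplastid_homolog
  counts <- c(dev_regulated = sum(ann$is_dev_regulated),
              no_kinetoplastid_homolog = sum(!ann$has_kinetoplastid_homolog),
              multicopy = sum(!ann$is_single_copy))
  if (!any(keep)) stop("no genes survive the training-set filter")
  out <- abundances[keep]
  attr(out, "filter_counts") <- counts
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_replicates") <- attr(abundances, "n_replicates")
  out
}

#' Fit the log-linear expression model
#'
#' Ordinary least squares of `log10(TPM)` on geCAI score, the model behind
#' score-based predictions of absolute expression. Genes with TPM = 0 are
#' dropped from the log-scale fit (their count is reported) but retained in
#' the Spearman correlation, which is computed on raw ranks.
#'
#' @param scores Named numeric vector of ORF scores.
#' @param abundances Named numeric vector of TPM.
#' @return An object of class `expression_fit`: list with `intercept`,
#'   `slope`, `r_squared` (Pearson r^2 on the log scale), `spearman_rho`,
#'   `n` (genes in the OLS fit) and `n_dropped_zero`.
#' @export
fit_expression_model <- function(scores, abundances) {
  shared <- intersect(names(scores), names(abundances))
  if (length(shared) < 3) stop("need at least 3 paired genes")
  s <- as.numeric(scores[shared])
  tpm <- as.numeric(abundances[shared])
  rho <- stats::cor(s, tpm, method = "spearman")
  pos <- tpm > 0
  if (sum(pos) < 3) stop("need at least 3 genes with positive TPM for the log fit")
  fit <- stats::lm(log10(tpm[pos]) ~ s[pos])
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 spearman_rho = rho,
                 n = sum(pos),
                 n_dropped_zero = sum(!pos)),
            class = "expression_fit")
}

#' @export
print.expression_fit <- function(x, ...) {
  cat(sprintf("log10(TPM) = %.3f + %.3f * score  (n = %d, %d zero-TPM dropped)\n",
              x$intercept, x$slope, x$n, x$n_dropped_zero))
  cat(sprintf("  Pearson r^2 (log scale) = %.3f, Spearman rho = %.3f\n",
              x$r_squared, x$spearman_rho))
  invisible(x)
}

#' Predict TPM from scores under a fitted expression model
#'
#' @param object An `expression_fit`.
#' @param scores Numeric vector of ORF scores.
#' @param ... Unused.
#' @return Predicted TPM values.
#' @export
predict.expression_fit <- function(object, scores, ...) {
  10^(object$intercept + object$slope * as.numeric(scores))
}

#' Convert TPM to mRNA molecules per cell
#'
#' Under the standing assumption that a mid-log procyclic cell contains
#' about 50,000 mRNA molecules, 20 TPM corresponds to one molecule per
#' cell: `molecules = tpm * mrnas_per_cell / 1e6`.
#'
#' @param tpm Non-negative TPM value(s).
#' @param mrnas_per_cell Total mRNA molecules per cell (default 50000).
#' @return Molecules per cell.
#' @examples
#' tpm_to_molecules(20)   # 1 molecule/cell
#' tpm_to_molecules(50)   # 2.5 molecules/cell
#' @export
tpm_to_molecules <- function(tpm, mrnas_per_cell = 50000) {
  if (any(tpm < 0)) stop("TPM must be non-negative")
  if (mrnas_per_cell <= 0) stop("`mrnas_per_cell` must be positive")
  tpm * mrnas_per_cell / 1e6
}

#' Adjust a measured TPM for effective gene copy number
#'
#' Transgene abundances measured in pooled libraries are depressed by the
#' lower effective copy number of each transgene relative to endogenous
#' genes (e.g. 8-fold for one haploid transgene copy in an equal mix of
#' four diploid lines); multiplying by the effective copy factor puts them
#' on the endogenous per-diploid-gene-pair scale.
#'
#' @param tpm Measured TPM value(s).
#' @param effective_copy_factor Positive multiplier (e.g. 8).
#' @return Adjusted TPM.
#' @export
adjust_copy_number <- function(tpm, effective_copy_factor) {
  if (effective_copy_factor <= 0) stop("`effective_copy_factor` must be positive")
  tpm * effective_copy_factor
}

#' Compare the scores of two gene groups
#'
#' Unpaired two-sample t test with pooled (equal) variance, two-sided --
#' e.g. cytosolic versus mitochondrial ribosomal-protein mRNA scores.
#'
#' @param scores_a,scores_b Numeric vectors, each of length >= 2.
#' @return List with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`, `df`, `p`.
#' @export
compare_groups <- function(scores_a, scores_b) {
  if (length(scores_a) < 2 || length(scores_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(c(scores_a - mean(scores_a), scores_b - mean(scores_b))) == 0)
    stop("zero pooled variance; t statistic undefined")
  ht <- stats::t.test(scores_a, scores_b, var.equal = TRUE)
  list(mean_a = mean(scores_a), sd_a = stats::sd(scores_a),
       mean_b = mean(scores_b), sd_b = stats::sd(scores_b),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Correlate ORF scores with an external per-gene quantity
#'
#' Generic correlation over the id intersection -- e.g. scores against
#' measured half-lives or ribosome densities. Values that are not finite
#' after the transform (e.g. log of zero) are dropped and counted.
#'
#' @param scores Named numeric vector of ORF scores.
#' @param external_values Named numeric vector (gene id -> value).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param transform Transform applied to `external_values` before
#'   correlating: `"none"`, `"log10"` or `"log2"`.
#' @return Correlation coefficient with attributes `n` (pairs used) and
#'   `n_dropped`.
#' @export
correlate_scores <- function(scores, external_values,
                             method = c("spearman", "pearson"),
                             transform = c("none", "log10", "log2")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  shared <- intersect(names(scores), names(external_values))
  if (length(shared) < 3)
    stop("fewer than 3 shared gene ids between scores and external values")
  x <- as.numeric(scores[shared])
  y <- as.numeric(external_values[shared])
  y <- switch(transform, none = y, log10 = log10(y), log2 = log2(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("fewer than 3 finite pairs after transform")
  structure(stats::cor(x[ok], y[ok], method = method),
            n = sum(ok), n_dropped = sum(!ok))
}
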