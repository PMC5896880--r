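## Shared geometric-mean kernel. All three metrics (geCAI, CAI, tAI) score an
## ORF as exp(sum(counts * log w) / L); log space avoids underflow on long
## ORFs (a 3000-codon ORF of weight-0.02 codons underflows a naive product).
.geo_mean_scores <- function(counts, length_codons, weights) {
  lw <- log(as.numeric(weights))
  as.vector(counts %*% lw) / length_codons
}

#' geCAI score of a single ORF
#'
#' The geCAI score of an ORF is the geometric mean of the weights of its
#' codons, computed in log space. Scores lie in (0, 1] and do not depend on
#' codon order or ORF length, only on codon proportions.
#'
#' @param orf An `orf_record` (see [codonize_orf()]).
#' @param weights A [codon_weights] object covering all 61 sense codons.
#' @return A single numeric score in (0, 1].
#' @examples
#' gecai_score(codonize_orf("g", "ATGAACGGATAA"), gecai_weights_pcf())
#' @export
gecai_score <- function(orf, weights) {
  if (!inherits(orf, "orf_record")) stop("`orf` must be an orf_record")
  weights <- codon_weights(weights)
  if (orf$length_codons < 1) stop("'", orf$id, "' has no scorable codons")
  exp(.geo_mean_scores(matrix(orf$codon_counts, 1), orf$length_codons, weights))
}

#' geCAI scores for a set of ORFs
#'
#' Element-wise [gecai_score()] over an ORF set; the result is a named
#' vector independent of input order.
#'
#' @param orfs An `orf_set` (or named character vector of sequences).
#' @param weights A [codon_weights] object.
#' @return Named numeric vector of scores in (0, 1].
#' @export
gecai_scores <- function(orfs, weights) {
  orfs <- codonize_orfs(orfs)
  weights <- codon_weights(weights)
  if (any(orfs$length_codons < 1))
    stop("ORF(s) with no scorable codons: ",
         paste(orfs$ids[orfs$length_codons < 1], collapse = ", "))
  setNames(exp(.geo_mean_scores(orfs$counts, orfs$length_codons, weights)),
           orfs$ids)
}

#' Relative-adaptiveness CAI weights from a reference set
#'
#' Classical codon adaptation index weights: within each synonymous family,
#' `w(codon) = (count + pseudocount) / (max family count + pseudocount)`,
#' so the most frequent codon of every family gets weight 1 (the per-family
#' "local" constraint that geCAI replaces with a single global one).
#'
#' @param reference An `orf_set` of reference ORFs, conventionally the most
#'   highly expressed genes (see [select_reference_set()]).
#' @param pseudocount Added to counts to keep unobserved codons scorable;
#'   with `pseudocount = 0` any family absent from the reference is an error.
#' @return A [codon_weights] object.
#' @export
cai_weights <- function(reference, pseudocount = 0.5) {
  reference <- codonize_orfs(reference)
  if (length(reference) == 0) stop("reference set is empty")
  if (pseudocount < 0) stop("`pseudocount` must be >= 0")
  counts <- colSums(reference$counts)
  aa <- codon_amino_acids()
  w <- setNames(numeric(length(counts)), names(counts))
  for (fam in split(names(aa), aa)) {
    fam_counts <- counts[fam]
    if (max(fam_counts) == 0 && pseudocount == 0)
      stop("amino-acid family {", paste(fam, collapse = ", "),
           "} is absent from the reference set and pseudocount is 0")
    w[fam] <- (fam_counts + pseudocount) / (max(fam_counts) + pseudocount)
  }
  if (any(w == 0))
    stop("codon(s) with zero relative adaptiveness (",
         paste(names(w)[w == 0], collapse = ", "),
         "); use a positive pseudocount")
  codon_weights(w)
}

#' CAI score of one ORF / of a set
#'
#' Geometric mean of CAI relative-adaptiveness weights over the ORF's
#' codons -- the same kernel as [gecai_score()] with CAI weights.
#'
#' @param orf,orfs ORF record / ORF set.
#' @param cai_matrix Weights from [cai_weights()].
#' @return Numeric score(s) in (0, 1].
#' @export
cai_score <- function(orf, cai_matrix) gecai_score(orf, cai_matrix)

#' @rdname cai_score
#' @export
cai_scores <- function(orfs, cai_matrix) gecai_scores(orfs, cai_matrix)

#' Select a highly expressed CAI reference set
#'
#' Convenience selector: the top `q` fraction of genes by TPM.
#'
#' @param orfs An `orf_set`.
#' @param abundances Named numeric vector of TPM (must cover all ORF ids).
#' @param q Fraction of genes to keep (default 0.05).
#' @return The subset `orf_set`.
#' @export
select_reference_set <- function(orfs, abundances, q = 0.05) {
  orfs <- codonize_orfs(orfs)
  if (q <= 0 || q > 1) stop("`q` must be in (0, 1]")
  missing <- setdiff(orfs$ids, names(abundances))
  if (length(missing))
    stop("ORF id(s) missing from abundances: ", paste(missing, collapse = ", "))
  tpm <- abundances[orfs$ids]
  keep <- order(tpm, decreasing = TRUE)[seq_len(max(1L, ceiling(q * length(orfs))))]
  orfs[keep]
}

## Wobble-pairing classes, keyed "anticodon position 34 : codon position 3".
## Watson-Crick pairs have no penalty; the wobble constants are the standard
## published selective-constraint estimates (A at 34 is read as inosine;
## C:A is the lysidine pairing).
.TAI_DEFAULT_S <- c("A:T" = 0, "G:C" = 0, "T:A" = 0, "C:G" = 0,
                    "G:T" = 0.41, "A:C" = 0.28, "A:A" = 0.9999,
                    "T:G" = 0.68, "C:A" = 0.89)

.revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(ch)
    paste(rev(ch), collapse = ""), "")
}

#' tRNA adaptation index weights
#'
#' Computes per-codon tAI weights from a caller-supplied table of
#' codon-anticodon pairings and tRNA gene copy numbers. The absolute
#' adaptiveness of a codon is `W = sum over recognizing anticodons of
#' (1 - s) * copy_number`, where `s` is the wobble penalty of the pairing
#' class (anticodon position 34 against codon position 3). Relative weights
#' are `W / max(W)`; codons with no decoder are imputed the geometric mean
#' of the nonzero relative weights.
#'
#' No organism table is bundled: tRNA gene complements (e.g. the 66 genes of
#' *T. brucei*) must be supplied by the caller.
#'
#' @param trna Data frame with columns `codon`, `anticodon`, `copy_number`.
#'   Positions 2-3 of each anticodon must be the reverse complement of
#'   positions 1-2 of its codon.
#' @param s Named numeric vector of wobble penalties in \[0, 1\] keyed by
#'   `"<anticodon base 34>:<codon base 3>"`; defaults to the standard
#'   published constants (Watson-Crick pairs 0).
#' @return A [codon_weights] object.
#' @export
tai_weights <- function(trna, s = NULL) {
  if (!all(c("codon", "anticodon", "copy_number") %in% names(trna)))
    stop("`trna` must have columns codon, anticodon, copy_number")
  pen <- .TAI_DEFAULT_S
  if (!is.null(s)) pen[names(s)] <- s
  if (any(pen < 0 | pen > 1)) stop("wobble penalties must lie in [0, 1]")
  codon <- toupper(chartr("U", "T", trna$codon))
  anti <- toupper(chartr("U", "T", trna$anticodon))
  copy <- trna$copy_number
  if (any(copy < 0) || any(copy != round(copy)))
    stop("copy numbers must be non-negative integers")
  if (all(copy == 0)) stop("all tRNA copy numbers are zero")
  bad <- which(!codon %in% .SENSE_CODONS)
  if (length(bad)) stop("not a sense codon: ", paste(codon[bad], collapse = ", "))
  ok <- substr(anti, 2, 3) == .revcomp(substr(codon, 1, 2))
  if (!all(ok))
    stop("anticodon does not decode codon (positions 1-2): ",
         paste(sprintf("%s~%s", codon[!ok], anti[!ok]), collapse = ", "))
  cls <- paste0(substr(anti, 1, 1), ":", substr(codon, 3, 3))
  unknown <- setdiff(cls, names(pen))
  if (length(unknown))
    stop("no wobble penalty defined for pairing class(es): ",
         paste(unique(unknown), collapse = ", "))
  W <- setNames(numeric(61), .SENSE_CODONS)
  contrib <- (1 - pen[cls]) * copy
  for (i in seq_along(codon)) W[codon[i]] <- W[codon[i]] + contrib[i]
  if (max(W) == 0) stop("every codon has zero adaptiveness")
  w <- W / max(W)
  nz <- w > 0
  w[!nz] <- exp(mean(log(w[nz])))
  codon_weights(w)
}

#' tAI score of one ORF / of a set
#'
#' Geometric mean of tAI weights over the ORF's codons.
#'
#' @param orf,orfs ORF record / ORF set.
#' @param tai_matrix Weights from [tai_weights()].
#' @return Numeric score(s) in (0, 1].
#' @export
tai_score <- function(orf, tai_matrix) gecai_score(orf, tai_matrix)

#' @rdname tai_score
#' @export
tai_scores <- function(orfs, tai_matrix) gecai_scores(orfs, tai_matrix)

#' Write a score table
#'
#' Writes `gene_id<TAB>score<TAB>metric` at full float precision.
#'
#' @param scores Named numeric vector of scores.
#' @param metric Metric label (`"geCAI"`, `"CAI"`, `"tAI"`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, metric, path) {
  tab <- data.frame(gene_id = names(scores),
                    score = sprintf("%.17g", as.numeric(scores)),
                    metric = metric)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
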