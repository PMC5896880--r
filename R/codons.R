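#' The three stop codons
#'
#' TAA, TAG and TGA terminate translation and never carry a geCAI weight;
#' only the 61 sense codons are scored.
#'
#' @return Character vector of length 3.
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

#' The 61 sense codons
#'
#' All DNA triplets over A/C/G/T except the three stop codons, in
#' alphabetical order. This fixed ordering is the canonical codon index used
#' throughout the package (weight vectors, count matrices).
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() .SENSE_CODONS

.ALL_CODONS <- sort(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"))[, 3:1], 1,
                          paste, collapse = ""))
.SENSE_CODONS <- setdiff(.ALL_CODONS, c("TAA", "TAG", "TGA"))

#' Amino acid encoded by each sense codon
#'
#' @return Named character vector (one-letter amino-acid codes) over the 61
#'   sense codons, in [sense_codons()] order.
#' @export
codon_amino_acids <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc[.SENSE_CODONS]
}

#' Construct a codon weight matrix
#'
#' A codon weight matrix maps each of the 61 sense codons to a weight in
#' (0, 1]. It is the object learned by [learn_gecai()] and the parameter of
#' [gecai_scores()]. The matrix is "normalized" when its maximum weight is
#' exactly 1 (the single global constraint of geCAI, as opposed to CAI's
#' per-family constraint).
#'
#' @param weights Named numeric vector; names must be exactly the 61 sense
#'   codons (any order), values in (0, 1].
#' @return An object of class `codon_weights`: a named numeric vector in
#'   [sense_codons()] order with attribute `normalized`.
#' @examples
#' w <- codon_weights(setNames(rep(1, 61), sense_codons()))
#' attr(w, "normalized")
#' @export
codon_weights <- function(weights) {
  if (is.null(names(weights)) || !is.numeric(weights))
    stop("`weights` must be a named numeric vector")
  nm <- toupper(chartr("U", "T", names(weights)))
  missing <- setdiff(.SENSE_CODONS, nm)
  extra <- setdiff(nm, .SENSE_CODONS)
  if (length(missing) || length(extra))
    stop("weight table must cover exactly the 61 sense codons; missing: ",
         if (length(missing)) paste(missing, collapse = ", ") else "none",
         "; unexpected: ",
         if (length(extra)) paste(extra, collapse = ", ") else "none")
  if (anyDuplicated(nm))
    stop("duplicated codons in weight table: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  w <- as.numeric(weights)
  names(w) <- nm
  w <- w[.SENSE_CODONS]
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1))
    stop("codon weights must lie in (0, 1]; offending codons: ",
         paste(names(w)[!is.finite(w) | w <= 0 | w > 1], collapse = ", "))
  structure(w, class = "codon_weights",
            normalized = isTRUE(all.equal(max(w), 1, tolerance = 1e-12)))
}

#' @export
print.codon_weights <- function(x, ...) {
  cat("Codon weight matrix (61 sense codons)\n")
  cat(sprintf("  max %.4g (normalized: %s), min %.4g, median %.4g\n",
              max(x), attr(x, "normalized"), min(x), stats::median(x)))
  top <- sort(unclass(x), decreasing = TRUE)[1:6]
  cat("  top codons:", paste(sprintf("%s=%.3g", names(top), top),
                             collapse = " "), "\n")
  invisible(x)
}

#' Renormalize a weight matrix so its maximum weight is 1
#'
#' Rescaling all weights by a common factor multiplies every geometric-mean
#' ORF score by the same factor, so rank order -- and any Spearman objective
#' -- is unchanged.
#'
#' @param weights A [codon_weights] object (or named numeric convertible to one).
#' @return A normalized `codon_weights` object.
#' @export
normalize_weights <- function(weights) {
  w <- codon_weights(weights)
  codon_weights(setNames(as.numeric(w) / max(w), names(w)))
}

#' Read a codon weight table
#'
#' Reads a tab-separated table with columns `codon` and `weight` (61 rows,
#' one per sense codon) into a [codon_weights] object.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `codon_weights` object.
#' @seealso [write_weight_table()], [gecai_weights_pcf()]
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("weight table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("codon", "weight") %in% names(tab)))
    stop("weight table must have columns `codon` and `weight`: ", path)
  codon_weights(setNames(tab$weight, tab$codon))
}

#' Write a codon weight table
#'
#' Writes a `codon<TAB>weight` table at full float precision so that
#' `read_weight_table(write_weight_table(w, path))` round-trips losslessly.
#'
#' @param weights A [codon_weights] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path) {
  w <- codon_weights(weights)
  tab <- data.frame(codon = names(w), weight = sprintf("%.17g", as.numeric(w)),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled geCAI weights for procyclic-form Trypanosoma brucei
#'
#' The published per-codon geCAI weights for logarithmically growing
#' procyclic-form *T. brucei*, printed to two decimals. Seven codons carry
#' the maximum weight 1.00: six from amino-acid families with synonymous
#' choice (GGA, ATT, AAG, AAC, ACG, TAC) plus ATG, methionine's only codon.
#'
#' @return A [codon_weights] object.
#' @examples
#' w <- gecai_weights_pcf()
#' w[["TGT"]]
#' @export
gecai_weights_pcf <- function() {
  read_weight_table(system.file("extdata", "gecai_weights_pcf.tsv",
                                package = "gecai", mustWork = TRUE))
}
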