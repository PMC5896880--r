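#' Read ORF sequences from a FASTA file
#'
#' Loads a (wrapped or unwrapped) multi-record FASTA of coding DNA
#' sequences. Sequences are uppercased and RNA `U` is mapped to `T`; record
#' ids are the first whitespace-delimited token of each header and must be
#' unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of DNA sequences.
#' @export
read_orf_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA file has a record with an empty header: ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("U", "T", toupper(as.character(x)))
  names(seqs) <- ids
  seqs
}

#' Validate and codonize a single coding sequence
#'
#' Splits a coding DNA sequence into triplets, strips a single terminal stop
#' codon if present, rejects internal stops, and tallies counts over the 61
#' sense codons. Stop codons are never counted: they carry no weight under
#' any metric in this package.
#'
#' @param id Sequence identifier.
#' @param sequence DNA string; length must be a multiple of 3.
#' @param ambiguous How to treat codons containing non-ACGT characters:
#'   `"error"` (default) aborts, `"skip_codon"` drops the codon from the
#'   counts and tallies it in `n_skipped`.
#' @return An object of class `orf_record`: a list with elements `id`,
#'   `sequence`, `codon_counts` (named integer vector over
#'   [sense_codons()]), `length_codons` and `n_skipped`.
#' @examples
#' rec <- codonize_orf("g1", "ATGGGATAA")
#' rec$codon_counts[c("ATG", "GGA")]
#' @export
codonize_orf <- function(id, sequence, ambiguous = c("error", "skip_codon")) {
  ambiguous <- match.arg(ambiguous)
  if (!nzchar(sequence)) stop("empty sequence for '", id, "'")
  s <- chartr("U", "T", toupper(sequence))
  n <- nchar(s)
  if (n %% 3 != 0)
    stop("sequence length of '", id, "' (", n, " nt) is not a multiple of 3")
  codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
  if (codons[length(codons)] %in% stop_codons())
    codons <- codons[-length(codons)]
  internal <- which(codons %in% stop_codons())
  if (length(internal))
    stop("internal stop codon ", codons[internal[1]], " at codon position ",
         internal[1], " in '", id, "'")
  clean <- grepl("^[ACGT]{3}$", codons)
  if (!all(clean)) {
    if (ambiguous == "error")
      stop("non-ACGT base in codon ", which(!clean)[1], " ('",
           codons[which(!clean)[1]], "') of '", id,
           "'; use ambiguous = \"skip_codon\" to drop such codons")
    codons <- codons[clean]
  }
  if (length(codons) == 0)
    stop("'", id, "' has no scorable codons after stop stripping/skipping")
  counts <- table(factor(codons, levels = .SENSE_CODONS))
  counts <- setNames(as.integer(counts), .SENSE_CODONS)
  structure(list(id = id, sequence = s, codon_counts = counts,
                 length_codons = length(codons),
                 n_skipped = sum(!clean)),
            class = "orf_record")
}

#' @export
print.orf_record <- function(x, ...) {
  cat(sprintf("ORF record '%s': %d scored codons (%d skipped)\n",
              x$id, x$length_codons, x$n_skipped))
  invisible(x)
}

#' Codonize a set of ORFs
#'
#' Validates and codonizes a collection of named coding sequences into an
#' `orf_set`, the container scored by [gecai_scores()] and consumed by
#' [learn_gecai()]. Counts are stored as a genes-by-61 matrix for fast
#' rescoring.
#'
#' @param sequences Named character vector of DNA sequences (e.g. from
#'   [read_orf_fasta()]), or a list of `orf_record` objects.
#' @param ambiguous Passed to [codonize_orf()].
#' @return An object of class `orf_set`: list with `ids`, `counts` (integer
#'   matrix, rows = genes, columns = [sense_codons()]), `length_codons`,
#'   `n_skipped` and `sequences`.
#' @export
codonize_orfs <- function(sequences, ambiguous = c("error", "skip_codon")) {
  ambiguous <- match.arg(ambiguous)
  if (inherits(sequences, "orf_set")) return(sequences)
  if (is.list(sequences) && all(vapply(sequences, inherits, TRUE, "orf_record"))) {
    recs <- sequences
  } else {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("`sequences` must be a named character vector")
    if (anyDuplicated(names(sequences)))
      stop("duplicate sequence id(s): ",
           paste(unique(names(sequences)[duplicated(names(sequences))]),
                 collapse = ", "))
    recs <- lapply(names(sequences), function(id)
      codonize_orf(id, sequences[[id]], ambiguous))
  }
  ids <- vapply(recs, `[[`, "", "id")
  counts <- do.call(rbind, lapply(recs, `[[`, "codon_counts"))
  rownames(counts) <- ids
  seqs <- vapply(recs, `[[`, "", "sequence")
  structure(list(ids = ids, counts = counts,
                 length_codons = setNames(vapply(recs, `[[`, 0L, "length_codons"), ids),
                 n_skipped = setNames(vapply(recs, `[[`, 0L, "n_skipped"), ids),
                 sequences = setNames(seqs, ids)),
            class = "orf_set")
}

#' @export
length.orf_set <- function(x) length(x$ids)

#' @export
print.orf_set <- function(x, ...) {
  cat(sprintf("ORF set: %d sequences, %d-%d scored codons (median %d)\n",
              length(x$ids), min(x$length_codons), max(x$length_codons),
              as.integer(stats::median(x$length_codons))))
  invisible(x)
}

#' @export
`[.orf_set` <- function(x, i) {
  idx <- if (is.character(i)) match(i, x$ids) else i
  structure(list(ids = x$ids[idx],
                 counts = x$counts[idx, , drop = FALSE],
                 length_codons = x$length_codons[idx],
                 n_skipped = x$n_skipped[idx],
                 sequences = x$sequences[idx]),
            class = "orf_set")
}

#' Write an ORF set to FASTA
#'
#' @param orfs An `orf_set`.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path, width = 60) {
  orfs <- codonize_orfs(orfs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(orfs$ids)) {
    s <- orfs$sequences[[i]]
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(width, nchar(s) + width - 1, width), nchar(s)))
    writeLines(c(paste0(">", orfs$ids[[i]]), chunks), con)
  }
  invisible(path)
}

#' Read a transcript abundance table
#'
#' Reads a tab-separated table whose first column is the gene id and whose
#' remaining (or selected) columns are per-replicate TPM values. The
#' per-gene abundance is the arithmetic mean of the replicate TPMs.
#'
#' @param path Path to the TSV file (header row required).
#' @param replicate_columns Optional character vector naming the replicate
#'   columns to average; default: every column except the first.
#' @return Named numeric vector of mean TPM with attribute `n_replicates`.
#' @export
read_abundance_table <- function(path, replicate_columns = NULL) {
  if (!file.exists(path)) stop("abundance table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2) stop("abundance table needs a gene-id column and at least ",
                          "one numeric column: ", path)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in abundance table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  reps <- if (is.null(replicate_columns)) names(tab)[-1] else replicate_columns
  missing <- setdiff(reps, names(tab))
  if (length(missing))
    stop("replicate column(s) not found: ", paste(missing, collapse = ", "))
  vals <- matrix(NA_real_, nrow(tab), length(reps),
                 dimnames = list(NULL, reps))
  for (cn in reps) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    bad <- which(is.na(v) & !(tab[[cn]] %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric TPM value '", tab[[cn]][bad[1]], "' at row ", bad[1],
           ", column '", cn, "'")
    if (anyNA(v))
      stop("missing TPM value at row ", which(is.na(v))[1], ", column '", cn, "'")
    if (any(v < 0))
      stop("negative TPM value at row ", which(v < 0)[1], ", column '", cn, "'")
    vals[, cn] <- v
  }
  structure(setNames(rowMeans(vals), ids), n_replicates = length(reps))
}

#' Write an abundance table
#'
#' @param abundances Named numeric vector of TPM values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(abundances, path) {
  tab <- data.frame(gene_id = names(abundances),
                    tpm = sprintf("%.17g", as.numeric(abundances)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
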