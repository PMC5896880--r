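# Shared fixture builders; everything is generated in code, no stored data.

pcf_weights <- function() gecai_weights_pcf()

egfp_sequence <- function() {
  path <- system.file("extdata", "egfp_orf.fasta", package = "gecai")
  unname(read_orf_fasta(path)[1])
}

# A weight matrix with distinct, easily traceable values.
toy_weights <- function() {
  w <- seq(0.05, 1, length.out = 61)
  codon_weights(setNames(w, sense_codons()))
}

# Random ORF sequences (valid: leading ATG, sense body, terminal stop).
random_orf_seqs <- function(n, len_codons = 50, seed = 1) {
  set.seed(seed)
  setNames(vapply(seq_len(n), function(i) {
    body <- sample(sense_codons(), len_codons - 1, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), sample(stop_codons(), 1))
  }, ""), sprintf("orf%03d", seq_len(n)))
}

write_temp_fasta <- function(seqs, width = 60) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  con <- file(path, "w")
  for (id in names(seqs)) {
    s <- seqs[[id]]
    writeLines(c(paste0(">", id),
                 substring(s, seq(1, nchar(s), width),
                           pmin(seq(width, nchar(s) + width - 1, width), nchar(s)))),
               con)
  }
  close(con)
  path
}

write_temp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force geometric mean: explicit product-then-root, the independent
# oracle for the log-space scorer.
brute_force_score <- function(sequence, weights) {
  s <- toupper(chartr("U", "T", sequence))
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  if (codons[length(codons)] %in% stop_codons()) codons <- codons[-length(codons)]
  prod(as.numeric(weights[codons]))^(1 / length(codons))
}
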