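Package: gecai
Title: Gene Expression Codon Adaptation Index for Trypanosomatid mRNA Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns per-codon weights that predict steady-state mRNA abundance
    from coding-sequence composition. The gene expression codon adaptation
    index (geCAI) scores an open reading frame as the geometric mean of its
    codon weights; the weights themselves are learned by running many
    independent stochastic hill-climbing chains that maximise the Spearman
    rank correlation between ORF scores and measured transcript abundances
    (TPM), then aggregating chains by the per-codon median. Also provides the
    classical codon adaptation index (CAI) and tRNA adaptation index (tAI) as
    baselines, a synthetic-data generator with a known hidden weight matrix
    for parameter-recovery testing, synonymous ORF recoding to a target score,
    and evaluation utilities (training-set filtering, expression regression,
    TPM-to-molecules conversion, group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
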