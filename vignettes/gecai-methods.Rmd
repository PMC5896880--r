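---
title: "geCAI: model, learning procedure, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{geCAI: model, learning procedure, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gecai)
```

## The model

The gene expression codon adaptation index assigns each of the 61 sense
codons a weight $w_c \in (0, 1]$ and scores an open reading frame of $L$
codons (terminal stop stripped, internal stops forbidden) by the
geometric mean

$$ S = \exp\!\Big(\frac{1}{L}\sum_c n_c \ln w_c\Big), $$

where $n_c$ counts codon $c$ in the ORF. The score is permutation
invariant, length neutral (an ORF concatenated with itself scores the
same), and degree-1 homogeneous in the weights: rescaling every weight by
$k$ rescales every score by exactly $k$, so score *ranks* — and any rank
correlation with abundances — are invariant to the overall scale of the
matrix. That homogeneity is why the matrix needs only one global
constraint (some codon has weight 1) rather than CAI's per-family
constraint, and why renormalizing a learned matrix is always safe.

The working assumption is that codon choice drives steady-state mRNA
levels for constitutively expressed genes, so weights can be *learned*
by making ORF scores maximally rank-concordant with measured abundances.
Spearman's $\rho$ (average ranks on ties) is the objective precisely to
avoid distributional assumptions about either the hidden per-gene
translational efficiencies or the measured TPM values.

## The learning procedure

Each chain starts from a random matrix: 61 weights uniform on
$(\varepsilon, 1]$ with one uniformly chosen codon set to exactly 1. Each
generation perturbs `codons_per_proposal` uniformly chosen codons with
Gaussian noise of sd `proposal_sigma`, reflecting values back into
$(\varepsilon, 1]$, and accepts the proposal **iff** its objective is
strictly greater (ties reject), so the best-$\rho$ trace is non-decreasing
by construction. Many independent chains are aggregated by the per-codon
median, then renormalized to maximum 1; per-codon quartiles across chains
quantify how well each weight is pinned down. Both the median-matrix
objective and the best single chain are reported, since either could
legitimately be quoted as "the" learned correlation.

Rescoring is incremental: with per-ORF codon proportions precomputed, a
proposal touching $k$ codons updates all gene log-scores in
$O(n_{\text{genes}} \cdot k)$, and the tests verify this matches a full
rescore through the public objective to $10^{-12}$.

### Tunable parameters

| parameter | default | notes |
|---|---|---|
| `n_chains` | 1000 | full-scale default; 10–20 suffice to see stable medians on small synthetic sets |
| `n_generations` | 5000 | chains plateau well before this on realistic sizes |
| `proposal_sigma` | 0.1 | weight units; see below |
| `codons_per_proposal` | 1 | smallest-move search; larger values coarsen the search |
| `weight_floor` ($\varepsilon$) | $10^{-4}$ | a zero weight annihilates any score containing that codon and makes $\ln$ undefined; the published table's minimum is 0.02, so a small positive floor loses nothing |
| `record_trace_every` | 10 | bounds trace memory |
| `seed` | 1 | chain $i$ uses `seed + i`, so results are independent of execution order |

`proposal_sigma = 0.1` was chosen by measurement: with single-codon
moves, sd 0.05 cannot traverse the unit interval in a few thousand
generations and chains stall measurably short of attainable optima
(median final $\rho \approx 0.91$ on noiseless 200-gene data where
$\rho = 1$ is reachable), whereas sd 0.1 reliably exceeds 0.95 under the
same budget. Reflection at the boundaries was preferred to clamping so
proposal mass does not accumulate at $\varepsilon$ or 1.

## The synthetic-data generator

`simulate_dataset()` exists so that learning and scoring are testable
against a known truth with no external data. It emulates:

* **ORF lengths** — log-normal, mean 400 codons, sd 0.4 in log space,
  floored at 30 codons: roughly the shape of trypanosomatid ORF lengths.
* **Codon composition** — per-gene Dirichlet frequencies over the 61
  sense codons, `dirichlet_alpha = 0.4`. This concentration was
  calibrated against an observable: scoring simulated genes with the
  *bundled published weight table* should reproduce the inter-gene score
  dispersion seen across a real procyclic transcriptome (scores spanning
  roughly 0.2–0.6, sd $\approx$ 0.06). Near-uniform composition
  (large $\alpha$, or `composition = "uniform"`) compresses scores into a
  $\pm 0.05$ band, which real transcriptomes clearly do not show.
* **Abundance noise** — two models. `lognormal_tpm(a, b, sigma)` draws
  $\mathrm{TPM} = 10^{a + bS + N(0,\sigma)}$, the same log-linear form the
  evaluation module fits. `rank_noise(target_rho)` uses a Gaussian copula
  on the score ranks with copula correlation $r = 2\sin(\pi\rho_S/6)$
  (the inverse of $\rho_S = \frac{6}{\pi}\arcsin(r/2)$), then maps the
  noisy normal scores monotonically onto a log-normal TPM scale; the
  realized Spearman concentrates at `target_rho` ($\pm 0.03$ for
  $n \ge 300$).

It deliberately does **not** emulate UTRs, trans-splicing signals,
GC-skew or neighbour-dependent codon correlations, gene families, or any
coupling between composition and abundance beyond the score itself.
Consequently, passing recovery tests shows the learner does what it
claims *given the model's own assumptions*; it does not show that real
abundances are driven by codon choice to any particular degree — that
evidence has to come from real transcriptomes and recoded reporters.

`recode_orf()` complements the generator: it designs a synonymous coding
sequence hitting a target score (within ±0.005 by default), starting
from the per-position codon closest in log-weight to the target and
refining with randomized greedy sweeps. The achievable interval is the
geometric mean of per-position family minima/maxima, and unreachable
targets report it.

## Numerical and policy choices

* All scoring is in log space; a naive product underflows on long,
  low-weight ORFs.
* A single terminal stop is silently stripped; internal stops and
  non-triplet lengths are hard errors; ambiguous bases are errors unless
  `ambiguous = "skip_codon"` is requested, in which case skipped codons
  are counted per record.
* The initiator ATG is scored like any other codon (it carries weight
  1.00 in the bundled table, so its contribution is neutral there).
* Spearman ties use average ranks throughout.
* Genes with TPM = 0 are dropped (and counted) from log-scale regression
  but retained for rank correlations.
* CAI needs a reference set the data do not uniquely determine;
  `select_reference_set()` defaults to the top 5% of genes by TPM, and
  `cai_weights()` uses pseudocount 0.5 so every codon keeps a positive
  weight. tAI wobble penalties default to the standard published
  constants but both the pairing table and the penalties are
  caller-supplied.
* Weight tables are written at full float precision (`%.17g`) so
  write→read round-trips are lossless; the bundled table stores the
  printed two-decimal values.

## Finite-sample behaviour and limitations

Maximizing a rank correlation over 61 free weights **overfits** on small
training sets: the training objective of the learned matrix
systematically exceeds the rank correlation realized by the *true*
scores. At the scale used by the test suite and acceptance script
(500 genes, rank-noise target 0.55, 20 chains × 2000 generations —
sizes chosen so a full run completes in seconds), the learned objective
exceeds the realized correlation by roughly 0.06–0.10, and the
recovered-versus-true weight Spearman correlation is about 0.72–0.83
across seeds. The gap behaves like the usual
$O(\sqrt{n_{\text{params}}/n_{\text{genes}}})$ optimism and shrinks to a
few hundredths at full transcriptome scale (thousands of genes), where
the per-codon median over many more chains also stabilizes individual
weights. Rarely used codons are the least identifiable: their weights
move few gene scores, so their chain-to-chain quartile ranges stay wide.

Other known limitations: the learner is a greedy maximizer, so a single
chain can stall at a rank-order plateau (no downhill moves, no
temperature) — the multi-chain median is the remedy, not any
per-chain guarantee; the objective ignores abundance *magnitudes*, so
the learned matrix predicts ranks, and absolute predictions require the
separate log-linear calibration fit; and weights learned from one
transcriptome inherit that study's measurement idiosyncrasies, so
cross-study scores should be compared by rank, not value.

```{r example, eval = FALSE}
## a complete small-scale run
ds  <- simulate_dataset(n_genes = 300, noise = rank_noise(0.55), seed = 42)
fit <- learn_gecai(ds$orfs, ds$abundances,
                   learner_config(n_chains = 10, n_generations = 1500, seed = 42))
fit$objective_median                         # training-objective rho
ds$realized_rho                              # what the data actually contain
cor(as.numeric(fit$median_weights),
    as.numeric(ds$true_weights), method = "spearman")
```
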