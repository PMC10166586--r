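---
title: "Decomposing and visualizing tandem repeat alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing and visualizing tandem repeat alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifcomp)
```

## The problem

Variable number tandem repeats (VNTRs) harbor variation beyond copy-number
change: point substitutions and small indels turn some copies into variant
motifs, rare alleles carry private motifs, and groups of motifs can expand
together. Associating such patterns with phenotypes or populations requires
seeing the *composition* of each allele — which motif sits at which
position — not just its length. `motifcomp` provides that view: it parses
each allele into motif copies, encodes the motifs as symbols, aligns the
encoded alleles, and draws the result as one color band per allele.

The package deliberately does **not** discover TR loci or motifs: the
repeat boundaries and candidate motifs are user input (tools like Tandem
Repeats Finder produce them), because motif choice is partly a modelling
decision — `CTTACCGATT` versus `CTTAC` + `CGATT` is a matter of parsimony,
and users should be able to compare both views.

## The decomposition model

Let `Σ = {A,C,G,T}`, let `M` be the motif set and `d(x, y)` the global
(Needleman–Wunsch) alignment score with match +5 and mismatch/indel −4
(linear gaps). An allele `x` is parsed into consecutive substrings
`x(1), x(2), …` maximizing `Σᵢ max_{m∈M} d(x(i), m)`. The optimum is found
by dynamic programming over states "prefix `x[1..i]`, position `j` of
motif `m`", with three transitions inside a motif (diagonal
match/mismatch, insertion, deletion) and a boundary transition: the
completed end state of any motif feeds position 0 of every motif, so the
parse chains motifs freely. The DP is initialized with score 0 before the
first base, start and end of the parse are anchored (no free end gaps),
and a segment may have any positive length — pure-indel alignments are
allowed but penalized. Backtracking recovers the boundaries segment by
segment; where several parses tie, we prefer an exact copy over an inexact
one, then the motif earliest in the user's order, then the longer segment,
making output deterministic. Segments equal to no input motif are reported
with `origin = "novel"` and their substring becomes a new motif; novel
motifs are *not* fed back into `M` (single-pass parsing), so results do not
depend on allele order.

Scores are configurable via `scoring_params()`; the invariants
(`match > 0 > indel`, `mismatch < match`) keep the optimum well defined
(empty segments can never improve a parse). `N` is accepted in alleles and
mismatches everything, so unresolved bases never create spurious exact
copies.

Correctness is checked against `brute_force_decompose()`, an exhaustive
oracle that enumerates all `2^(n−1)` partitions of the allele and scores
each part with an independent plain NW implementation; the two agree on
hundreds of random instances (up to 15 bp, up to 3 motifs) and the DP also
recovers `k` exact copies of any pure repeat up to motif length 20 × 30
copies.

## Encoding

Each distinct observed motif (counted once per segment) is mapped to one
character of a fixed 90-character alphabet — digits `1..9,0`, upper-case,
lower-case, then 28 punctuation characters, excluding the gap `-`, the
private symbol `?`, whitespace and quoting hazards. Symbols are assigned in
descending count order (ties lexicographic), so symbol `1` is always the
most frequent motif. Motifs below the frequency threshold collapse into the
shared private symbol. `threshold = "auto"` chooses the smallest t ≥ 1 with
at most 90 motifs reaching t — the maximal number of distinct symbols that
fits the cap — and therefore never fails; an explicit threshold that would
need more than 90 symbols raises an error suggesting a higher value or
`auto`. Symbols are dataset-relative: the same motif may get different
symbols in different datasets.

## Alignment and rearrangement

Encoded alleles are aligned as symbol strings, not nucleotides, so one
alignment column is one motif copy regardless of motif length. The
substitution score between two symbols is derived from motif similarity,
`round(s_max − (s_max − s_min) · ed(m_a, m_b) / max(|m_a|, |m_b|))` with
defaults `s_min = 0`, `s_max = 10`; the private symbol scores `s_min`
against everything but itself. Gaps are affine (`gap_open = −12`,
`gap_extend = −2`); the constructor enforces `gap_open < s_min − 1` so a
gap always costs more than the worst mismatch — substituting two similar
motifs is always preferred to gapping them apart.

The MSA is progressive: normalized pairwise distances
`1 − 2·S(a,b)/(S(a,a)+S(b,b))` feed an average-linkage guide tree
(`stats::hclust`), and profiles are merged by profile–profile alignment
(Gotoh three-state DP on expected column scores from symbol frequencies)
with "once a gap, always a gap". This internal aligner keeps the package
free of binary dependencies and hermetically testable; for two sequences it
reduces exactly to optimal pairwise alignment, which the tests verify
against an independent plain-loop DP. Progressive alignment is a heuristic
for three or more rows — no optimality is claimed there, only row
conservation, equal widths and absence of all-gap columns.

Row rearrangement defaults to hierarchical clustering on the *aligned*
rows — distance = fraction of columns that differ, a gap versus a symbol
counting as a difference — with average linkage. Leaf order is read off the
dendrogram deterministically: at each node the smaller subtree comes first,
ties broken by the lexicographically (byte-order) smallest id; no
optimal-leaf-ordering pass is applied, trading a little aesthetics for
reproducibility. Alternatives: ascending motif count, ascending allele
length (requires the nucleotide lengths, which the pipeline passes
automatically), lexicographic, or a manual permutation.

## Rendering

Alleles are horizontal bands, motif position increasing left to right; each
non-gap column is a colored cell, gaps are empty space. Colors are assigned
by symbol rank as evenly spaced HSV hues (s = 0.62, v = 0.92), so they are
deterministic and pairwise distinct up to the 90-symbol cap; the private
symbol is grey. Group labels (e.g. population codes) appear as a color
patch beside the sample name, using the Okabe–Ito palette. The default
output is hand-written SVG, which makes figures machine-checkable — tests
count `<g class="allele">` bands and distinct cell fills; PNG and PDF are
drawn with the same layout on base graphics devices. The motif table
(symbol, motif sequence, count, color hex) is written alongside as TSV.

## The simulator, and what the tests do and do not show

`simulate_tr_alleles()` generates alleles as concatenations of motif
copies: per allele a uniform copy number from `copy_range`, per copy a
uniform choice among the motifs, then i.i.d. per-base substitution (to a
uniformly chosen different base) with rate `sub_rate` and, independently,
length-1 indels with rate `indel_rate` (deletion, or insertion of a uniform
base, with equal probability). A truth table records the generating motif
of every copy. Default rates used in the validation suite — 2% substitution
and 0.5% indel, 4–14 copies of 6–9 bp motifs, 100–200 alleles — are typical
of the desk-scale regime where repeat copies are recognizably related but
not identical.

This model is intentionally simple: it has no slippage-driven duplication
phylogeny, no positional mutation bias, and mutations are independent
across copies. Passing tests therefore demonstrate correctness of the
algorithms (optimal parsing, exact encoding, conservative alignment,
deterministic output), not robustness to every pattern in real repeat
loci. At the simulated rates, decomposition recovers the true copy number
for ≥95% of alleles (100% with no mutation); occasional disagreements
arise when an indel near a copy boundary makes a merged or split parse
genuinely score better — a property of the objective, not a bug.

## Numerical and design choices

* All scores are integers; the DP runs in doubles with exact integer
  arithmetic, so equality tests in backtracking use a 1e-9 tolerance purely
  defensively.
* Inner DP loops are vectorised per row; the in-row (deletion) dependency
  is resolved with a cumulative-maximum transform, keeping the whole
  pipeline in plain R at ~seconds for 100 alleles.
* The brute-force oracle refuses inputs over 20 bp (2^19 partitions).
* `hclust` merge order determines profile-merge order in the MSA; input
  order breaks remaining ties, so a fixed input yields byte-identical
  output across runs (verified end to end).
* Degenerate inputs: empty allele sets, empty strings, duplicate ids or
  motifs, non-ACGTN characters, inconsistent manual orders and malformed
  mapping files all fail fast with informative errors naming the offender.

## Known limitations

* Novel motifs are emitted per segment and never re-enter the motif set;
  loci whose true units are absent from the input motifs will be described
  as many related novel motifs rather than one unit.
* The progressive MSA can be suboptimal for ≥3 sequences, and complex
  nested or fused repeats may align imperfectly — consistent with using an
  off-the-shelf alignment strategy at the symbol level.
* Symbols, and hence colors, are dataset-relative; figures from different
  datasets are not directly comparable motif-for-motif without consulting
  the motif tables.
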