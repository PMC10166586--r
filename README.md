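# motifcomp

Motif composition of tandem repeat (TR) alleles.

Tandem repeats — and in particular VNTRs with long repeat units — vary not
only in copy number but in the internal composition of their motifs:
substitutions and indels create imperfect copies, rare private motifs, and
higher-order patterns that length-based genotypers cannot see. `motifcomp`
takes a collection of TR alleles (the repeat region only) plus one or more
motifs and produces a motif-centric, alignment-style view of the locus:

1. **Decompose** — each allele `x` is optimally parsed into consecutive
   segments `x(1), x(2), …`, each globally aligned to its best motif, so that

   `D(x, M) = Σᵢ max_{m ∈ M} d(x(i), m)`

   is maximal, where `d` is a global-alignment score (match +5,
   mismatch/indel −4 by default) and `M` the motif set. The dynamic program
   runs over states `D[i, m, j]` (prefix `x[1..i]`, character `j` of motif
   `m`), with the end state of any motif feeding the start of any other, so
   motifs chain freely. Segments matching no input motif are emitted as
   *novel* motifs.
2. **Encode** — every distinct observed motif becomes a single-character
   symbol (at most 90); motifs rarer than a frequency threshold (or an
   `"auto"` rule that maximizes the symbol count) collapse into a shared
   *private* symbol `?`.
3. **Align & rearrange** — the encoded alleles are multiply aligned with a
   motif-similarity scoring matrix
   (`score(a,b) = round(s_max − (s_max − s_min)·ed(m_a, m_b)/max(|m_a|, |m_b|))`)
   and affine gap penalties, then reordered (hierarchical clustering by
   default) so similar alleles sit together.
4. **Render** — a color-coded figure, one band per allele and one colored
   cell per motif copy (grey for private motifs), with sample names,
   optional group annotation, and a motif/frequency table.

A synthetic allele simulator and brute-force oracles are included for
validation.

## Worked example

```r
library(motifcomp)
alleles <- c(s1 = "ACCTTGACCTTGACCTTTG",
             s2 = "ACCTTGACCTTG",
             s3 = "ACCTTGACCTTTGACCTTTG")
res <- tr_composition(alleles, "ACCTTG")
res
#> Motif composition of 3 tandem repeat alleles
#>   motifs: 1 input, 1 novel, 0 private; alignment width 3; order: clustering
summary(res)
#> 3 alleles, 12-20 bp, 2-3 motif copies
#> 2 motif symbols (+0 private motifs), alignment width 3
#>  symbol   motif count
#>       1  ACCTTG     5
#>       2 ACCTTTG     3
res$alignment$rows[res$order$order]
#>    s3    s1    s2
#> "122" "112" "11-"
```

The parser found five exact `ACCTTG` copies and three copies of a novel
motif `ACCTTTG` (one extra `T`, global-alignment score 26 vs 30 for an
exact copy); symbol `1` is the most frequent motif, symbol `2` the novel
one; after alignment and clustering, the two three-copy alleles are
adjacent and the two-copy allele is gapped at its missing third copy.
`plot(res)` draws the composition; `write_composition_svg()` /
`render_composition()` write SVG/PNG/PDF plus the motif color table.

File-based runs go through `run_pipeline(run_config(...))`, which writes
six artifacts (segment TSV, mapping TSV, aligned symbol FASTA, row order,
figure, motif table) and is byte-deterministic; `inst/scripts/motifcomp`
wraps it for the shell:

```sh
Rscript inst/scripts/motifcomp run --fasta alleles.fa --motif ACCTTG --out-dir out/
```

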