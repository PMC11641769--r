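# S1Domains

Comparative analysis of tandem **RNA-binding S1 domain** repeats in
protein sequences, built around the question the domain raises for the
theory of symbiogenesis: chloroplast and mitochondrial proteins carry S1
domains, and if those organelles descend from engulfed Cyanobacteria and
Alphaproteobacteria, the organellar domains should look like — and nest
phylogenetically within — one specific domain position of their bacterial
relatives.

The package is aimed at molecular-evolution researchers who want to run
that analysis end to end, offline, and with a simulator that supplies
ground truth for every stage:

1. **Profile scanning** — build a position-specific log-odds profile from
   a seed alignment of S1 domains and detect all non-overlapping repeats
   in a protein by iterated best-hit search (glocal alignment, affine
   gaps, greedy masking). For residue *a* in a profile column,

   *s(a) = ln[(c_a + λ·b_a) / ((n_eff + λ)·b_a)]*

   with column counts *c*, background *b* and pseudocount mass *λ*; a hit
   is accepted when its raw score divided by the profile length reaches
   the cutoff.
2. **Census** — the distribution of S1 domain counts per domain of life
   with per-cell protein-size extremes, and the Spearman rank correlation
   between protein length and repeat count.
3. **Per-position identity matrices** — slice k-domain proteins into
   their N→C domain positions, compute mean pairwise percent identity
   (Needleman–Wunsch global alignment, BLOSUM62, gap open 10 / extend
   0.5; identity = identical columns / both-residue columns) between
   every position pair of two taxon groups, and call each row's best
   corresponding position.
4. **Trees** — convert identities to distances (Kimura protein
   correction, *d = −ln(1 − p − 0.2p²)*, or p-distance) and build
   neighbor-joining trees (Saitou–Nei with the Studier–Keppler Q
   criterion) with deterministic Newick output.
5. **Simulation** — a bead-on-a-string generator: an ancestral domain,
   per-group divergence, paralogous position lineages, orthologous
   copies, random linkers, and an optional "organellar" group seeded from
   one position of a "bacterial" group, with full ground truth (domain
   coordinates, source map, lineage tree).

## Worked example

Simulate the endosymbiosis scenario (a 3-domain bacterial source group,
an organellar group descending from its **third** domain position, an
unrelated bacterial outgroup; divergence 0.3 substitutions/site), then
run the full pipeline — scan, slice, compare, and build the tree:

```r
library(S1Domains)

truth <- generateFamily(endosymbiosisSpec(seed = 42))
res   <- recoverTransfer(truth)   # profile scan -> identity matrix -> NJ tree

res$idMatrix
#> IdentityMatrix: Organelle (rows) vs SourceBac (cols)
#>      pos1 pos2 pos3
#> pos1 56.8 60.4 77.6
#> pos2 55.5 61.2 79.7
#> pos3 52.9 60.0 79.3

res$correspondence
#>   position_a position_b identity tied
#> 1          1          3   0.7765
#> 2          2          3   0.7970
#> 3          3          3   0.7930

res$cladeRecovered
#> [1] TRUE
```

Every organellar domain position is most similar to source position 3
(77–80% identity versus 53–61% elsewhere) — the generator's transfer
really did come from position 3 — and the NJ tree places all organellar
domains inside the clade of the source group's third domains
(`res$cladeRecovered`). This is exactly the reasoning used on real
chloroplast/mitochondrial EF-Ts and ribosomal protein S1 records, where
the first organellar domain corresponds to the third bacterial S1 domain.

A file-based interface with the same stages (`simulate`, `scan`,
`census`, `idmatrix`, `correspond`, `tree`, `fetch`) is available through
`s1Pipeline()` and the wrapper script `inst/scripts/s1pipeline.R`.

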