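---
title: "Methods: S1 domain repeat detection, correspondence and phylogeny"
author: "S1Domains authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: S1 domain repeat detection, correspondence and phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

The S1 domain is an OB-fold β-barrel of roughly 70–90 residues that binds
RNA and occurs in one to fifteen tandem copies per protein, joined by
flexible linkers — a bead-on-a-string architecture. Archaeal proteins
carry a single copy; bacterial ribosomal protein S1 (RpS1) carries a
phylum-characteristic number of copies (e.g. three in Cyanobacteria, six
in Alphaproteobacteria); and a handful of organellar eukaryotic proteins
(chloroplast RpS1, chloroplast and mitochondrial elongation factor Ts)
carry two or three. Under symbiogenesis, the organellar domains should
descend from — and therefore resemble most closely — a *specific domain
position* of their bacterial sister group. The package turns that
argument into a measurable pipeline: detect repeats, slice proteins into
N→C domain positions, compute position-by-position identity matrices
between taxon groups, call the best-corresponding position, and check
that organellar domains nest within the source clade of a
neighbor-joining tree.

# Profile scanning

`buildProfile()` turns a seed alignment of S1 domains into a
position-specific log-odds profile. Column scores are
$\ln\big[(c_a + \lambda b_a)/((n_\mathrm{eff}+\lambda) b_a)\big]$ with
residue counts $c_a$, background $b$ (uniform 1/20 by default),
pseudocount mass $\lambda = 1$, and $n_\mathrm{eff}$ the number of
sequences contributing a residue to the column. Two normalizations are
deliberate:

* **Duplicate seed sequences are collapsed before counting.** This is the
  simplest form of redundancy weighting; it also makes the profile a pure
  function of the *set* of seed sequences, so trivially redundant seeds
  cannot sharpen a column.
* **Columns with more than 50% gaps are dropped**; they describe linker
  overhang, not the domain.
* **X scores zero everywhere** — an unknown residue neither helps nor
  hurts, matching its treatment in the pairwise module (and B/Z/U/O in
  input records are mapped to X with a warning rather than rejected,
  since public records contain them).

`scanSequence()` finds repeats by iterated best-hit search: a *glocal*
alignment (the profile consumed in full, the sequence contributing a
local window) with affine gaps, implemented in C++ (a gap of length $g$
costs $\mathrm{open} + g\cdot\mathrm{extend}$; defaults 11 and 1,
conventional protein-profile values). The best hit is accepted when its
raw score divided by the profile length reaches the cutoff; its residues
are then masked (no later hit may cross them) and the search repeats.
Greedy masking is deterministic and adequate for well-separated tandem
repeats; it would be the wrong tool for overlapping or circularly
permuted repeats, which are out of scope.

**The cutoff (default 1.0 mean nats per column)** is the one genuinely
calibrated constant. It was chosen against two requirements measured on
the simulator at its default settings: random 200–300-residue sequences
must yield zero hits, and true domains must survive out to at least 0.5
substitutions/site of divergence from the seed family. Measured best-hit
normalized scores of random sequences peak near −0.86, while true
domains at high divergence still score above 1.5 — the default sits in
the middle of a wide margin. Scores are in natural-log units, so 1.0
means the window is on average e-fold better explained by the profile
than by background, per column.

The glocal formulation means a domain truncated at a protein terminus
scores poorly (its missing columns are charged as deletions). The
simulator never truncates domains, and PROSITE-style matches are
similarly full-length, so we accept this bias and document it.

# Pairwise identity

All percentages rest on global Needleman–Wunsch alignment with affine
gaps (BLOSUM62, open 10, extend 0.5 — Clustal-like defaults), provided
by Biostrings behind the package's interface. Identity is
**identical columns / columns where both sequences carry a residue**;
gap columns are excluded from the denominator. The source analyses do
not define their identity measure, and on closely related sequences this
convention tracks Clustal-style percent identity most closely; the
alignment-length denominator is available as an option
(`denominator = "columns"`). Group identity is the mean over all
unordered pairs, and cross-group identity the mean over all A×B pairs —
*not* the identity of consensus sequences, matching the "average
percentage of identity" framing of the analyses this package
re-implements. A joint progressive MSA is deliberately not used: all-pairs
global alignment removes an unreproducible heuristic at the cost of a
small systematic difference absorbed by the ±3-percentage-point
tolerance used for reproduction checks.

# Correspondence calling

`identityMatrix()` fills cell $(i,j)$ with the cross-group mean identity
between position $i$ of group A and position $j$ of group B (diagonal
cells of a self-comparison hold the within-position mean).
`bestCorrespondence()` takes each row's argmax; ties are broken toward
the smaller column index and flagged, so downstream code can refuse to
over-interpret a tie. Proteins whose detected domain count differs from
the group's required k are excluded with a warning rather than
re-aligned: domain counts are phylum-characteristic, so a deviating
count more likely signals a scanner miss or an unusual protein than a
genuine variant architecture.

# Distances and trees

Identity converts to distance either as the raw proportion of differing
sites ($d = 1-I$) or with Kimura's empirical protein correction
($d = -\ln(1 - p - 0.2p^2)$, $p = 1-I$), the default, chosen because
MEGA-style workflows apply it by default; the correction diverges below
~14.6% identity, where the function stops with an instruction to use the
p-distance instead. Tree scale-bar units are substitutions per site.

`neighborJoining()` is an in-package implementation of Saitou–Nei
agglomeration with the Studier–Keppler criterion
$Q(i,j) = (N-2)d(i,j) - r_i - r_j$: deterministic tie-breaking
(lexicographically smallest label pair, a node labelled by its smallest
contained leaf), standard branch-length formulas, and negative branch
estimates clamped to zero with the deficit moved to the sister branch so
the joined pair's path length is preserved. Newick serialization orders
children by smallest contained leaf label and prints lengths to six
significant digits, so identical inputs always produce byte-identical
trees. The implementation is cross-checked in the test suite against
topology enumeration with least-squares branch fitting (all unrooted
topologies for n ≤ 6) and against the independent ape implementation;
the clade test used for the organellar question is an unrooted
bipartition check (does some edge separate exactly the organellar
domains plus the source position's domains from everything else?).

No bootstrap is computed by default; the analyses being reproduced
report none.

# The simulator and what it does (not) show

`generateFamily()` draws one root domain per family, then per-group
ancestors at `root_divergence` (default 0.6 substitutions/site) from the
root — all groups are homologous, as real S1 domains are across the
domains of life, but only distantly. Within a group, each of the k
domain positions is an independently diverged copy of the group ancestor
(`divergence`, the paralogous duplication depth), and each protein's
copy diverges from its position lineage by `divergence × ortholog_scale`
(default 1/3: speciation is shallower than the ancient duplications that
separated positions; with equal depths, position lineages would not be
recoverable even in principle). A transfer redirects every position of
the target group to descend from one source position at
`extra_divergence` (default 0.1) — the generative form of organellar
inheritance. Sites are substituted with probability $1-e^{-d}$, the
replacement drawn from the background excluding the current residue;
30% of sites are frozen by default, mimicking the conserved fold and
binding site versus variable loops. Domains have a fixed length of 80
residues (inside the 70–150 OB-fold range) and no indels, so true
coordinates stay exact; linkers and terminal tails are uniform random
10–25 residues.

The default study conditions for the recovery benchmark are: k = 3
source group, transfer from position 3, divergence 0.3, five proteins
per group, plus an independent bacterial outgroup, 100 seeded
replicates. What a pass shows: the pipeline recovers planted signal of
realistic strength through every stage (scan → slice → compare → tree).
What it does not show: robustness to indels inside domains, to
rate heterogeneity across lineages, to horizontal transfer networks, or
to database-scale noise — the generator is deliberately a clean null
model, not a realistic evolutionary simulator.

`generateCensusFixture()` builds mixed three-kingdom families for the
census module; the first and last protein of each row are pinned to the
row's min/max length so the census extremes are exact, and middle
protein lengths cluster near the minimal architecture (a Beta(1.2, 4)
profile over the row's range), which couples protein length to domain
count the way real multidomain families do — the basis of the positive
length/repeat-count rank correlation.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere files are written.
* Empty alignments, ragged alignments, overlapping domain intervals,
  unknown taxonomy values and duplicate ids are hard errors; zero-domain
  proteins are excluded from the census with a logged count.
* A constant length or domain count makes the Spearman correlation
  undefined; the package returns 0 with a warning rather than NA, so
  pipelines keep running on degenerate fixtures.
* `percentIdentity()` returns 0 for an alignment with no both-residue
  columns.
* Identity matrices store the contributing pair count per cell, so a
  cell's sensitivity to one pair (1/count) is always inspectable.

# Problem sizes

The shipped tests and the acceptance script run, per replicate, a family
of 15 proteins (~300 residues each), profile scans over all of them, a
3×3 identity matrix from 25 domain pairs per cell, and a 30-leaf NJ
tree; 100 replicates complete in well under a minute. Brute-force
oracles run at deliberately tiny sizes (alignments to length 7,
profiles to ~14 columns with at most 2 gap residues, topologies to
n = 6), where exhaustive enumeration is exact and fast.

# Known limitations

* Detection requires a seed family related to the scanned proteins; with
  the bundled synthetic seed the scanner will not (and should not) find
  real S1 domains. Users analysing real data must supply a real S1 seed
  alignment or bootstrap one from an annotated record.
* Greedy masking cannot represent overlapping repeat architectures.
* All-pairs identity differs slightly from MSA-derived identity; treat
  reported percentages as comparable within a few points, not exactly.
* The NJ implementation targets the small trees of this analysis
  (tens of leaves); it is O(n³) and not meant for thousands of taxa.
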