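---
title: "Annotation-free synteny anchors from k-mer rareness statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-free synteny anchors from k-mer rareness statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most genome-wide synteny tools take annotated genes as their input, which
restricts the anchors of a synteny map to protein-coding loci and ties the
result to annotation quality. `syntenyanchors` instead detects anchors
directly on genomic DNA: intervals that are *sufficiently unique* within
their own genome, so that a strong cross-genome hit pins an unambiguous
1-1 orthologous correspondence. The package covers the whole workflow:

1. **per-genome precomputation** — candidate windows from k-mer statistics
   and a within-genome uniqueness score for each candidate;
2. **pairwise matching** — cross-genome comparison of the candidate sets
   under score thresholds derived from the uniqueness scores;
3. **multi-genome consolidation** — an anchor graph whose connected
   components are clusters, plus transitivity and reciprocal-best audits.

A synthetic-genome simulator with exact truth maps makes every stage
testable without external data.

## Uniqueness, distances, and the anchor-match guarantee

A genome is a set of fragments over `{A,C,G,T,N}`; its substring universe
contains every fragment substring and every reverse complement, and never
crosses a fragment boundary. Sequences are compared by local alignment bit
score $s$, converted to a distance by

$$d(w, w') = \alpha\,\ell - s(w, w'),$$

where $\ell$ is the candidate length and $\alpha$ the per-position
self-information of a match (2 bits under uniform nucleotide composition —
exact for the simulator's background, approximate for real genomes).

A candidate $w$ is $d_0$-unique if every substring of the genome with $w$'s
own locus excised is farther than $d_0$. Excision — splitting the host
fragment at the locus boundaries — is what prevents $w$'s own substrings
from masking genuine near-copies. The bit-score form of the uniqueness
level is $s_0(w)$, the best surviving self-hit score.

The theoretical backbone is a triangle-inequality argument: if $w$ and $y$
are $d_0^G$- and $d_0^H$-unique in their genomes and
$d(w,y) \le \min(d_0^G, d_0^H)/2$, the pair is a *guaranteed* anchor match —
each side is closer to the other than to anything else in the partner
genome. In bit scores the guarantee reads
$s(w,y) > \max(s_0^G, s_0^H)/2 + \alpha\ell/2$. In practice this is
conservative, so accepted matches use the relaxed margin rule below; the
guarantee is recorded as a per-match flag (`lemma_guaranteed`) and never
used to reject. The acceptance suite verifies the guarantee's soundness by
brute force on toy genomes: no flagged pair is ever beaten by another
substring.

## Stage 1: candidates from k-mer counts

The per-position occurrence count $h_k(i)$ counts how often the k-mer at
position $i$ occurs in the genome, on both strands, optionally within
Hamming distance $m$ (GenMap-style mappability is its inverse, $1/h_k$).
Window rareness aggregates counts over candidate windows:

$$f_{\ell,k}(i) = \sum_{j=0}^{\ell-k} h_k(i+j).$$

Defaults follow the published method: windows of $\ell = 500$ nt every
250 nt, profiles $(k=13, m=0)$, $(k=15, m=0)$, $(k=21, m=2)$ applied in
that order, each keeping the windows within the 15th nearest-rank
percentile of finite $f$ (ties at the cutoff kept, for determinism).
Windows of later profiles merge into the existing set: an overlap of at
least 30% of an existing interval extends it to the union, smaller
overlaps are discarded, novel windows are appended. `k ≈ log4(n)`
(`suggest_k()`) keeps a random k-mer at roughly one expected genomic copy.

Positions whose k-mer contains `N` are *poison*: they carry `NA`, make any
covering window ineligible, and thus keep assembly gaps from producing
artifactual "unique" sequence. Soft-masking is deliberately ignored
(sequences are uppercased): the rareness filter itself is the masking
mechanism, and honouring external masks would bias the candidate set.

Counting is exact Hamming-ball enumeration over a flat hash table of both
strands' k-mers — no seeding heuristics — which is exactly testable against
a naive quadratic scan and fast enough for the multi-hundred-kb genomes the
test conditions use ($m \le 2$, $k \le 31$).

## Stage 1 continued: within-genome uniqueness

Each candidate is aligned against its genome with the candidate's locus
excised. The aligner is a seed-and-extend engine on the blastn bit scale:
exact word seeds (word size 11), banded affine-gap extension with x-drop
termination, match +2 / mismatch −3 / gap open 5 / gap extend 2, gapped
Karlin–Altschul parameters $\lambda = 0.625$, $K = 0.41$, E-value cutoff
0.001. On seeded instances the engine reproduces the exact Smith–Waterman
optimum (verified against an independent full-matrix scorer). Alignment
fragments are chained per (target fragment, strand) by dynamic programming:
chains are strictly collinear on both axes, zero-gap adjacency allowed,
scores summed without inter-fragment gap costs.

Surviving hits (those not substantially overlapping the origin — more than
25% of a hit's target length; the exact fraction is configurable because
"substantial" is a judgement call) fill a per-nucleotide maximum-score
track. The uniqueness score $s_0$ is the track maximum, floored at 40 bits
— roughly the smallest significant bit score, so the absence of self-hits
is never over-read as infinite uniqueness. The best surviving chain score
is kept alongside as a diagnostic; the track maximum is authoritative
because it is the conservative choice for the downstream thresholds.

## Stage 2: pairwise anchor matches

Candidates of two genomes are aligned against each other (candidates only,
not whole genomes — this is what makes pairwise comparison cheap), chained
per candidate pair, and accepted as anchor matches when the chain score
clears

* `max(s0_x + sqrt(s0_x), s0_y + sqrt(s0_y))` — the standard rule; the
  square-root margin absorbs score variance;
* `2 * max(s0_x, s0_y)` — whenever either candidate has more than one raw
  hit partner (ambiguity triggers conservatism).

A candidate whose accepted partners lie more than 10 kb apart (or on
different fragments) in the partner genome indicates a rearrangement or
insertion inside the candidate; such candidates are omitted entirely
(splitting them is possible in principle but not implemented, matching the
method's published behaviour). Partners in close proximity are all kept if
their alignments cover essentially disjoint parts of the shared candidate
(overlap below 20% of the shorter subinterval — the quantification is ours,
the criterion is configurable); otherwise only the best-scoring match
survives. The result is a near-perfect 1-1 table.

Matching is computed once per pair with the lexicographically smaller
genome id as the query side and mirrored on demand, which makes
`find_anchor_matches(G, H)` and `(H, G)` *exactly* symmetric instead of
approximately so under aligner asymmetries.

## Stage 3: clusters and audits

Anchor candidates become vertices, matches edges; connected components of
this anchor graph are multi-genome clusters with deterministic ids (the
lexicographically smallest member). Two audits quantify internal
consistency:

* **transitivity** — within a component, every pair of members from
  distinct genomes not joined by an edge is an implied-missing match; each
  is optionally re-aligned to see whether any significant similarity exists
  at all. Implied pairs are enumerated over all non-adjacent
  cross-genome pairs of a component, not just length-2 paths, matching the
  cluster-level accounting of the method.
* **reciprocal best** — for each match (w, y), w is searched against the
  whole partner genome (and y against w's); a best hit more than 10 kb from
  the matched locus (or on another fragment — the conservative reading)
  flags the match, recording the overlap between the offending subsequence
  and the originally matched subinterval as a fraction of their combined
  length.

## The simulator and what passing tests mean

`simulate_genome()` draws an i.i.d. uniform background (making
$\alpha = 2$ exact) with optional planted repeat families (fixed copy
number, unit length, intra-family divergence). `evolve_genome()` applies
point substitutions, single-nucleotide indels, and logged rearrangement
events (inversion, translocation, duplication, deletion), and returns an
exact interval-level orthology map; duplication copies are flagged and
excluded from the unique-orthology truth subset. Replaying the logs
reproduces the derived genome byte-for-byte, which is the consistency
guarantee the evaluation rests on. Indels are single-nucleotide by design:
larger events belong in the event log, keeping truth coordinates exactly
computable.

The simulator emulates neutral divergence on an unstructured background.
It does not model GC heterogeneity, transposon landscapes, tandem repeats,
segmental duplication mosaics or assembly artifacts, so passing tests
demonstrate the machinery's correctness under its stated model — not
performance on real genomes, where candidate density and threshold
behaviour will differ.

Evaluation counts a match as true when its source-side subinterval
overlaps a truth block by at least half, partner fragment and orientation
agree, and the observed partner subinterval sits within a slack (50 nt by
default) of the truth-mapped image at both ends. Recall is restricted to
blocks at least one window long in repeat-free regions, since shorter or
repeat-masked blocks are outside the method's design envelope.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; BED output is identical to
  internal coordinates, 1-based forms (MCScanX-style exports) are display
  conversions at the boundary.
* The percentile is nearest-rank and inclusive, per profile and per
  genome, chosen for exact reproducibility over interpolation schemes.
* The merge-rule denominator is the existing interval's length; merged
  candidates may grow without bound and are not re-split (downstream
  omission handles ambiguity).
* Chain ties break toward fewer fragments, then the smaller first query
  start; component ids and profile application order are fixed, so every
  stage is deterministic for a fixed configuration.
* The engine's band half-width (64) and x-drop (100 raw) comfortably
  contain the optimum for the divergence range the method targets
  (nucleotide-alignable genomes); both are configurable in
  `score_model()`.
* The configuration hash covers every parameter that affects scores or
  thresholds; mixing tracks with different hashes is an error, not a
  warning, because `s0` values are only comparable under one scoring
  model.
* Test and acceptance problem sizes (two 200 kb genomes at 5%
  substitution divergence with one 20 kb inversion and one 20 kb
  translocation; a 100 kb genome with an 8 × 2 kb repeat family; 40 kb
  clonal triples) are the package's chosen desk-scale rendition of the
  study conditions.

## Known limitations

* No FM-index-scale performance engineering: the k-mer counter and aligner
  are exact desk-scale implementations, not replacements for GenMap/blastn
  on gigabase genomes.
* Candidate boundaries come from the window grid and merging; no local
  boundary re-optimization is attempted, so boundary wobble of tens of
  nucleotides is expected and the matching thresholds are designed to
  tolerate it.
* Mismatch counting supports m ≤ 2; protein-level comparison, masking
  heuristics and synteny-block chaining (an MCScanX-class task, for which
  the package only exports input files) are out of scope.
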