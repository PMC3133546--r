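---
title: "refscaf: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{refscaf: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refscaf)
```

## Scope and model

`refscaf` maps a draft bacterial assembly onto one or more closed reference
replicons and plans the finishing PCR round. Its contract is *mapping*, not
assembly: contig sequences are never altered (no trimming, merging or
consensus) except for the single cut applied to a contig that spans the
origin of a circular replicon. The underlying assumptions are the usual ones
for reference-guided finishing: the reference is structurally close to the
target (no large rearrangements between consecutive contigs), divergence is
mostly substitutions at the few-percent level, and every replicon of a
multipartite genome is represented by its own reference sequence.

All internal coordinates are 0-based half-open; the on-disk formats (crunch
comparison files, EMBL feature tables, PTT) are 1-based inclusive, and the
conversion happens exactly once, in the writers' constructors
(`as_crunch()`, `tab_feature()`).

## Alignment

The aligner is deliberately an exact-match machine. A replicon is indexed by
all its A/C/G/T-only k-mers (`k = 15`); k-mers occurring more than 50 times
are dropped (repeat guard). For both strands of a contig, shared k-mers are
merged along diagonals and extended to maximal exact matches (anchors);
anchors are chained by sparse dynamic programming — chainable when query and
subject both advance, neither gap exceeds `max_gap = 1000` bp, and the
diagonal shifts by at most `max_diag_drift = 200` bp — and disjoint chains
are extracted greedily by descending summed anchor length. Each chain is
reported as one hit whose `identity` is matched bases over the longer span:
an exact-match proxy, not a gapped-alignment identity. That proxy is
sufficient for coverage profiling and placement and avoids genome-scale DP;
it slightly *under*states identity when indels inflate a span, which only
makes the hit filters (`min_hit_len = 100`, `min_identity = 0.80`)
conservative. Non-ACGT letters never match anything, including themselves.

Defaults were chosen to tolerate strain-level divergence (a 1 %
substitution rate leaves an exact 15-mer roughly every `1/0.01 = 100` bp,
comfortably seeding every 100 bp-scale region) while rejecting spurious
repeat matches. None of these values is inherited from earlier tools; all
are overridable from the CLI.

## Profiling and replicon assignment

Per contig, coverage on each replicon is the union length of its hit query
intervals divided by contig length. Status rules, in order: shorter than
`min_contig_length = 1000` bp → `excluded_short` (too little landing room
for primers); no hits → `excluded_no_hit`; best coverage below
`min_coverage = 0.20` → `excluded_low_coverage`; otherwise `mapped`. A
mapped contig is assigned to the replicon with the most aligned bp — robust
to fragmented hit sets, unlike best-single-hit — with a lexicographic
tie-break for reproducibility. Because assignment picks one replicon per
contig by construction, the multipartite guarantee (no contig placed twice)
is structural, and the tests assert it end to end.

## Scaffolding

Orientation is the matched-bp majority over the contig's hits (ties → `+`).
The placement anchor is the contig's *projected left edge*: the best hit's
subject start minus its query offset, orientation-aware. Projecting the
edge, rather than using hit midpoints, makes the inter-contig gap estimate
`next_left_edge − prev_right_edge` equal to the true unsequenced distance
whenever placement is correct — the property that lets the primer stage
target realistic product sizes (and which the acceptance suite checks
exactly on mutation-free fixtures). Negative estimates (overlapping
projections) are floored at `min_spacer = 100` N so contigs stay visually
distinct and the primer designer still has a gap to span; overlapping
placements are *not* trimmed, per the no-assembly contract.

A contig spanning the origin of a circular replicon has strong hits in both
the first and last `min(origin_window, L/4)` bp of the reference with
disjoint query intervals. The 30 kb default window generously bounds draft
contig lengths; the `L/4` cap keeps the criterion meaningful on small
(test-scale) replicons. The contig is cut at the boundary between the
end-matching and start-matching query intervals; the start-matching part is
pinned to the molecule head, the end-matching part to the tail (whether the
original tool re-sorted or pinned is unknowable from its description;
pinning is deterministic and keeps the wrap-around explicit). If the two
intervals overlap, the cut is ambiguous: the contig is placed whole, with a
warning.

## Primer design

Candidates are all 18–25-mers of the last/first 500 bp of the flanking
placements (the right primer read from the reverse strand). Filters:
screening Tm 57–63 °C using `Tm = 64.9 + 41(nGC − 16.4)/len` — the
GC-count approximation, chosen because it is deterministic and
parameter-free; it is *not* nearest-neighbour thermodynamics, and Tm values
should be read as ranking scores, not annealing predictions — GC 30–70 %,
homopolymer runs ≤ 4, and 3'-end complementarity ≤ 3, where the score is
the longest 3'-terminal suffix whose reverse complement occurs in the
primer itself (self) or its partner (pair). The suffix criterion is
monotone, so the threshold test reduces to one 4-mer lookup.

Uniqueness is exact occurrence counting of the full primer plus its reverse
complement over *all* input contigs, overlaps included — strictly stronger
than an alignment-based scan and trivially auditable (the acceptance suite
recounts every emitted primer with a naive sliding window). Per gap the
emitted pair minimises |ΔTm| then product size, with |ΔTm| ≤ 5 °C and
product ≤ 4 kb hard; uniqueness and pair complementarity are verified
lazily in objective order, so the emitted pair is the best valid one and the
procedure is fully deterministic. Gaps with no valid pair are reported
`unpaired`, which is an outcome, not an error.

A gap is counted *putatively closed* when its flanks are adjacent under a
supplied relation and a pair was designed. Tests supply the synthetic truth
adjacency; pipeline summaries, which have no truth, use consecutive
placements with a projected gap ≤ the maximum product size.

## Protein scan

Reference proteins wholly inside regions that no *placed* contig covers
(minimum region length 1 kb) are aligned against all six frame translations
of every excluded contig. Using only placed contigs' hits to define the
regions matters: an excluded contig that still resembles the reference would
otherwise mask exactly the regions this stage is meant to probe. Alignment
is full Smith–Waterman (BLOSUM62, gap open 11, extend 1, a gap of length
*L* costing `11 + L`), affordable because the excluded set is small; hits
need score ≥ 50. Stop codons render as `*` and score −4 against everything
(including `*`/`*`, diverging from NCBI's +1 — a stop aligning to a stop is
not evidence of homology here). PTT rows whose span is not a multiple of 3
(pseudogenes) are skipped with a warning rather than failing the run.

## The synthetic world

The generator states the conditions the package is tested under: i.i.d.
bases at chosen GC; contigs are ordered reference fragments separated by
geometric gaps (mean 500 bp, minimum 1 — variable, occasionally large, like
real coverage gaps), each fragment independently inverted (default
probability 0.2) and point-mutated (default 1 %, substitutions only);
minimum fragment 1500 bp so every genuine contig clears the profiling
length filter; contaminants (1.5–3 kb) are rejection-sampled to share no
15-mer with the reference on either strand, making "excluded" unambiguous
ground truth; optionally one fragment is built across the origin. Defaults
were set once, from what a finishing project against a same-species
reference typically looks like, and are not tuned against test outcomes.

What a green test therefore establishes: correct behaviour under
substitution-level divergence, arbitrary inversion patterns, unplaceable
contamination, and origin wrap-around. What it does not: performance under
indels, rearrangements between reference and draft, shared repeat families,
or assembly errors inside contigs — the generator simulates none of these,
and the aligner's exact-match identity would degrade gracefully but
untestedly under heavy indels.

## Numerical and degenerate-input choices

* Ties are broken deterministically everywhere (lexicographic contig ids,
  `+` strand on orientation ties, stable hit sort by score/position), so
  identical inputs give byte-identical outputs.
* Tm is rounded to 0.01 °C before range checks; identity is kept as an
  exact ratio.
* Empty cases are legal, not errors: no hits → excluded contig; no gaps →
  no primers; no assigned contigs → the replicon directory is skipped and
  the summary says so.
* `estimate_gap` may be negative (overlapping projections); only the N
  spacer is floored.
* The crunch `score` is the integer chain score (matched bases) — ACT only
  needs a monotone score — and `percent_id` prints with one decimal.

## Known limitations

* Identity is an exact-match proxy; heavily indel-divergent references will
  depress it and can push genuine contigs under `min_identity`.
* The Tm model is a screening approximation; validate primers with a
  thermodynamic tool before ordering if conditions are demanding.
* No E-value statistics anywhere; thresholds are score-based.
* The protein scan is all-vs-all Smith–Waterman and will slow down if the
  excluded set is large (thousands of contigs with many unaligned-region
  proteins).
* One finishing round only: the iterative re-assembly loop (new contigs →
  re-run) is the user's outer loop, not the package's.
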