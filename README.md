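# refscaf

Reference-guided scaffolding and gap-closure primer design for bacterial
draft genomes.

## The problem

A draft bacterial assembly is a bag of contigs; finishing it means working
out where each contig sits, in what orientation, and then closing the
sequencing gaps — classically by PCR across each gap followed by Sanger
sequencing, iterated until the molecule is closed. When a closed genome of a
related strain exists, the contigs can be mapped onto it and most of that
work planned in one pass. Two things make naive mapping insufficient:

* **Multipartite genomes.** Many bacteria carry several replicons
  (chromosome plus megaplasmids/plasmids). A contig must end up on *at most
  one* replicon, or the downstream PCR plan is nonsense.
* **Primer uniqueness.** A gap-closure primer that anneals twice in the
  draft produces ambiguous reactions; every primer must occur exactly once
  (counting both strands) across *all* input contigs.

`refscaf` implements the whole pipeline natively in R, for people finishing
(or structurally comparing) bacterial drafts against reference replicons:

1. **align** — seed-and-chain local alignment of every contig against every
   reference replicon: exact k-mer seeds (k = 15) are extended to maximal
   exact matches (anchors), anchors are chained by sparse dynamic
   programming (gap ≤ 1 kb, diagonal drift ≤ 200 bp), and each chain becomes
   one hit with identity = matched / max(query span, subject span).
2. **profile** — per-contig coverage per replicon from the union of hit
   intervals; contigs become `mapped` or `excluded_*` (short / no hit / low
   coverage), and each mapped contig is assigned to the single replicon with
   the greatest aligned bp (ties broken lexicographically).
3. **scaffold** — assigned contigs are oriented (matched-bp majority),
   anchored at their projected left edge on the reference, ordered, and
   concatenated into one pseudocontig per replicon with runs of N standing
   in for the gaps (N count = projected gap, floored at 100). Contigs
   spanning the origin of a circular replicon are split; the part matching
   the reference start is pinned to the molecule head, the other to the
   tail.
4. **primers** — for every gap, candidate 18–25-mers from the 500 bp flanks
   are filtered on Tm (57–63 °C, `Tm = 64.9 + 41·(nGC − 16.4)/len`), GC
   (30–70 %), homopolymers (≤ 4) and 3'-end complementarity (≤ 3), then
   verified unique over all input contigs; the emitted pair minimises
   |ΔTm|, then product size (≤ 4 kb).
5. **protein scan** (optional, needs NCBI PTT tables) — reference proteins
   lying wholly inside regions no placed contig covers are aligned
   (Smith–Waterman, BLOSUM62, gap open 11 / extend 1) against all six frame
   translations of the excluded contigs, flagging genes that survive in the
   draft with lower homology or a different arrangement.
6. **outputs** — per replicon, the Artemis Comparison Tool file set:
   `Reference.fsa`, `PseudoContig.fsa`, `PseudoContig.crunch`,
   `ReferenceHits.tab`, `PseudoContig.tab`, plus `PCRProducts.tab`,
   `PrimerPairs.tsv` and `ReferenceProteinHits.tab` when enabled, and a
   top-level `UnMappedContigs.txt` and run summary.

A bundled synthetic-genome module generates multi-replicon references and
fragmented draft-contig sets (inversions, point mutations, contaminants,
origin-spanning fragments) with recorded ground truth, so the whole pipeline
is testable without downloading anything.

## Worked example

```r
library(refscaf)

genome <- generate_genome(c(30000, 15000), seed = 1)     # chromosome + plasmid
frag   <- fragment_genome(genome, 10, n_contaminants = 2, seed = 2)
res    <- finish_genome(frag$contigs, genome)
print(res$summary, row.names = FALSE)
```

```
 replicon_id mapped_contigs gaps primer_pairs putatively_closed
 replicon_01              7    6            6                 6
 replicon_02              3    2            2                 2
```

Every genuine contig was assigned to its replicon (7 + 3 = 10), each
replicon's pseudocontig has one gap fewer than its contigs, every gap
received a verified primer pair, and all pairs bridge contigs that are truly
adjacent on the reference. The two contaminants were excluded:

```r
table(res$profiles$status)
```

```
excluded_no_hit          mapped
              2              10
```

The designed primers (first replicon, first three gaps):

```
              gap_id   status                  left_seq
 replicon_01_gap_001 designed       CTAGACCCTCACCCGACGG
 replicon_01_gap_002 designed GGCCGGACTTAGCGTTAATAAAGAG
 replicon_01_gap_003 designed   GTAGTGGGCGAGCGAAAATTAGG
                 right_seq tm_left tm_right product_size
       GAGCCCGGTGCTGGACTTC   57.56    57.56          990
 TAACCATGAACCAGTCACGATGCAG   57.68    57.68         1004
   AGGAACGGAGTTTCCTTCAGCCT   57.06    57.06          791
```

`tm_left`/`tm_right` are the screening melting temperatures in °C;
`product_size` is the expected amplicon length in bp including the N-gap.

## Command line

```sh
Rscript inst/scripts/refscaf \
  --contigs draft_contigs.fasta \
  --reference chromosome.fasta --reference plasmid.fasta \
  --ptt chromosome.ptt --ptt plasmid.ptt --protein-scan \
  --outdir finished/
```

Load `Reference.fsa` vs `PseudoContig.fsa` with `PseudoContig.crunch` into
ACT, then add the `.tab` entries. Feature colours: mapped contig 4 (blue),
origin-split part 9, reference hit 10 (orange), PCR product 2 (red),
protein hit 3 (green).

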