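---
title: "Tracing lincRNA origins by synteny-constrained homology search"
author: "lincorigins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing lincRNA origins by synteny-constrained homology search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Long intergenic non-coding RNAs (lincRNAs) are transcripts longer than
200 nt that lie between protein-coding genes.  Three origination routes
are commonly proposed: de novo emergence from intergenic sequence (often
via transposable-element insertions), duplication from other long
non-coding RNAs, and pseudogenization of protein-coding genes.  The third
route is the hardest to see: lincRNA sequence drifts quickly, and TE
content inside lincRNA exons can mask a protein-coding ancestry.

`lincorigins` implements a comparative-genomics procedure to weigh these
routes for a set of human lincRNAs.  For each lincRNA it searches multiple
vertebrate genomes for a *putative ortholog* — a region of significant
sequence similarity that also preserves the lincRNA's synteny context —
and then asks what that region is in the other species: intergenic
sequence, part of a protein-coding gene (exon or intron), or another
non-coding gene.  LincRNAs whose orthologs are exonic protein-coding
sequence are candidates for a pseudogenization origin, which the package
further types as *unitary* (the human copy was lost in place: no human
paralog, and the lincRNA overlaps or sits next to an annotated human
pseudogene) or *duplicated* (a significantly similar human paralog
exists).

## The procedure

1. **Filter.**  lincRNAs overlapping any human protein-coding gene span
   (1 bp or more, strand-blind) are removed, so later alignments cannot be
   driven by coding sequence.
2. **Neighbour context.**  For each lincRNA, the human protein-coding
   genes whose span midpoints lie within a window (default ±750 kb) of the
   lincRNA boundaries are collected, upstream and downstream separately.
3. **Syntenic windows.**  For every (upstream, downstream) anchor pair
   whose orthologs land on the same chromosome of the target species
   within twice the window of each other, the interval spanning the two
   orthologs, extended by one window on each side, is searched.
4. **Alignment.**  The lincRNA cDNA is aligned to the windows with the
   package's seed-and-extend local aligner (exact 7-mer seeds on both
   strands, ungapped X-drop extension, banded affine-gap extension) and
   hits are kept at E-value < 1e-10 under Karlin–Altschul statistics
   \(E = K m n e^{-\lambda S}\).
5. **Synteny test.**  A hit is a candidate only if at least one anchor
   pair *flanks* it — one anchor ortholog entirely on each side, each
   within the window.
6. **Cross-species selection.**  Candidates are grouped across species by
   their anchor pair; groups seen in only one species are dropped; per
   species the candidate from the group with the most supporting species
   wins, ties broken by lowest E-value, then by (chrom, start).
7. **Classification and coverage.**  Each selected ortholog is classified
   protein-coding > non-coding > intergenic by 1-bp overlap precedence,
   and its exon/intron/intergenic coverage ternary and TE coverage are
   computed in integer bp.
8. **Origin typing.**  For lincRNAs whose exonic orthologs carry zero TE
   coverage, the package collects the *aligned proteins* (coding genes
   overlapped by the orthologs), finds their human orthologs, and retains
   those whose spliced sequence aligns to the lincRNA at E < 1e-10
   (*putative paralogs*).  No paralog plus an overlapping/juxtaposed human
   pseudogene calls a unitary candidate; any paralog calls a duplicated
   candidate.
9. **Statistics.**  A dinucleotide-preserving shuffle null checks that the
   homology calls are not compositional artifacts, and a bootstrap tests
   whether lincRNA–paralog pairs are enriched for annotated ceRNA–mRNA
   pairs.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `word_size` | 7 | exact-match seed length; short for sensitivity to diverged non-coding sequence |
| `reward` / `penalty` | +1 / −1 | match/mismatch scores; λ = ln 3 under uniform base frequencies |
| `gap_open` / `gap_extend` | 2 / 1 | affine gap costs (a gap of length g costs 2 + g) |
| `evalue_cutoff` | 1e-10 | homology significance threshold; every downstream decision depends only on this threshold |
| `window_bp` | 750,000 | synteny window on each side of the lincRNA / hit |
| `min_species_support` | 2 | a candidate locus must recur in at least this many species |
| `min_te_bp` | 10 | TE-derived requires strictly more than this many TE bp |
| `juxtaposition_bp` | 10,000 | distance defining "juxtaposed to a pseudogene" |
| `B` | 10,000 | ceRNA bootstrap replicates |
| `n_shuffles` | 5,000 | dinucleotide shuffles per lincRNA for the homology null |

## Numerical choices and caveats

* **Karlin–Altschul parameters.**  λ is the positive root of
  \(\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1\), found by bracketed root
  finding to 1e-9; K is estimated by simulation (default 1e5 random
  pairs of length 100), fitting \(P(M < S) \approx \exp(-Kmn e^{-\lambda S})\)
  over the upper score range.  The K simulation uses its own fixed-seed
  random stream so E-values never depend on the caller's RNG state.  No
  finite-size edge correction is applied (windows are far longer than
  queries), and gapped alignments reuse the ungapped λ and K.  Both
  simplifications shift E-values by a bounded constant factor; the
  pipeline's decisions depend on a threshold ten orders of magnitude below
  the noise floor, not on matching any particular aligner's E-values
  digit for digit.
* **Gap costs** have no single canonical value for ±1 scoring in
  short-word searches; open 2 / extend 1 approximates common defaults
  and is configurable.
* **Banded extension.**  Gapped extension uses a band of 31 diagonals
  around each anchor.  With ±1 scoring and affine costs, an optimal local
  alignment that drifts 15+ diagonals away from its seed would need to buy
  15+ gaps, so the band recovers the full Smith–Waterman optimum in
  practice; the aligner test suite checks exactly this against a complete
  DP oracle.
* **Overlap is strand-blind everywhere** (filtering, classification,
  pseudogene relation): annotation strand is ignored because an antisense
  overlap is still an overlap for every question the pipeline asks.
* **Genes, not transcripts.**  Isoforms are collapsed to the exon union
  per gene and the gene span is the range of that union.  The coding
  overlap filter uses gene spans, not exons.
* **Pseudogene-biotype annotations** in target species trigger neither the
  protein-coding nor the non-coding class, keeping the three ortholog
  classes mutually exclusive; pseudogene annotations are consumed only on
  the human side by the origin-typing stage.
* **Anchor-group selection.**  "Present across the most species" is
  interpreted through the flanking anchor pair: the pair of human
  neighbour genes is the only species-independent key for "the same
  locus".  Anchor order/orientation relative to human is not required to
  be preserved.
* **Paralog alignment** is nucleotide spliced-vs-spliced (lincRNA cDNA
  against the gene's exon-union sequence), matching the transcript-level
  framing of the ceRNA question.
* **Bootstrap.**  Replicates sample pairs uniformly *with replacement*
  from all constructible (lincRNA, coding gene) pairs of the loaded
  annotation.  The p-value uses the strict indicator \(I(N_k > N_{obv})\)
  and can therefore be exactly 0; an add-one estimator
  \((1 + \#exceed)/(1 + B)\) is available behind a flag.
* **Shuffle null.**  The dinucleotide shuffle is the Eulerian-walk
  construction (random reserved last-edges, rejected until they form an
  arborescence into the final base), which is uniform over all
  arrangements with identical dinucleotide counts.  Sequences containing
  `N` are split at `N` runs and each N-free segment shuffled in place.
* **Degenerate inputs.**  `N` scores as a mismatch and never seeds;
  IUPAC codes other than `N` are rejected at parse time.  Empty alignment
  inputs yield empty hit lists; a lincRNA with no neighbour genes can
  never gain candidates.

## The synthetic data generator

Real genome-scale inputs are deliberately out of scope, so the package
ships a generator that emulates them end to end.  One human chromosome
carries a backbone of multi-exon protein-coding genes with one lincRNA in
each intergenic slot; each target species carries the orthologous backbone
in the same order (per-site substitution at the species divergence), so
every lincRNA has conserved flanking anchors by construction.  Per
scenario, the lincRNA sequence is planted in the target species as an
intergenic copy, inside a new exon, inside an intron (with a TE fragment
covering a configured fraction of the homolog, annotated exactly as
planted), under a lncRNA annotation, or not at all; the two
pseudogenization scenarios plant exonic coding copies in all species and
add, for the unitary case, a human pseudogene annotation over the lincRNA
with *no* human ortholog edge, and for the duplicated case, a diverged
human paralog gene wired into the orthology map.  The ceRNA table contains
a configured fraction of the planted (lincRNA, paralog) pairs plus random
decoys.

Default conditions: 3 target species at 5% divergence, 5 lincRNAs per
scenario, ~2.5 kb genes with 6 kb gaps on a chromosome of roughly 0.8 Mb,
and a synteny window of 50 kb matched to that gene spacing (the genome and
window scale down together; the biology of the test — anchors a few gene
lengths away, windows spanning several genes — is preserved).  Slot
spacing is kept above the 10 kb juxtaposition window so planted
pseudogene relations are unambiguous.  The shuffle-null checks use 200
shuffles per lincRNA rather than the 5,000 production default; exceedance
of an E < 1e-10 threshold by chance is far below either number.

What the generator does **not** emulate: insertions/deletions along the
backbone (substitution-only by default; `mutate_sequence()` offers small
indels behind a flag), rate heterogeneity, rearrangements and anchor-order
inversions, fragmented assemblies, imperfect repeat annotation (the
emitted repeat BED is exact by construction), and multi-isoform gene
models.  Passing tests on this generator therefore demonstrate the
correctness of the decision logic and the calibration of the statistics,
not robustness to assembly noise or annotation error in real genomes.

## Known limitations

* Gapped E-values inherit ungapped λ, K (documented above).
* A single anchor-pair key treats tandem duplications of the same flanks
  as one locus group.
* The coding-overlap filter uses gene spans; an exon-only variant would
  retain more lincRNAs in gene-dense regions.
* The CLI is a thin wrapper; orchestration of many-genome runs (caching,
  scheduling) is out of scope.
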