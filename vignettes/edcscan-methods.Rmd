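---
title: "Methods: discovering and comparing epidermal differentiation complex genes"
author: "edcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and comparing epidermal differentiation complex genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The epidermal differentiation complex (EDC) is a cluster of genes
encoding cornified-envelope precursors and related epidermal proteins.
Its core region is flanked by orthologs of *S100A9* and *S100A11*, and
the genes between the flanks fall into recognisable structural classes:

* **SEDC** genes (single-coding-exon EDC genes, e.g. loricrin,
  involucrin, LCEs, SPRRs): one 5' non-coding exon plus one coding
  exon.
* **S100A** genes: one non-coding and two coding exons, encoding a
  folded S100 domain.
* **SFTP** genes (S100 fused-type proteins, e.g. filaggrin, hornerin,
  trichohyalin): the S100A exon structure fused to a very long,
  low-complexity, quasi-repetitive carboxy-terminal exon.
* **PGLYRP** genes: more than three coding exons, structurally unlike
  the rest.

Annotating these genes is hard for exactly the reason they are
interesting: most of the encoded proteins are intrinsically disordered
and compositionally extreme, so default homology searches mask them as
low-complexity noise, and their tails cannot be aligned columnwise at
all. `edcscan` packages the complete analysis chain for such loci:
translated homology search with no low-complexity filtering,
splice-aware gene-model construction, pseudogene flagging, composition
clustering, S100-domain phylogenetics, orthology calling and gene-order
rearrangement reconstruction -- together with a locus simulator that
provides complete ground truth, so that every stage is testable without
downloading genome assemblies.

## Translated search (find-genes)

`seededSearch()` is a classic seed-and-extend translated search. The
genomic region is translated in all six frames (stop codons become
`*`, any codon containing `N` becomes `X`); word seeds of length 3 with
a BLOSUM62 word score of at least 11 are confirmed by the two-hit rule
(two word hits on one diagonal within 40 residues), extended ungapped
with an X-drop of 16, and extensions reaching a trigger score of 40
open a gapped extension window. Within a window the gapped extension is
exhaustive (full affine dynamic programming, gap open 11 / extend 1),
so with a guaranteed seed (`neighborhood_threshold = -Inf`) the
reported score provably equals the optimal local alignment score
against that frame's translation; the test suite asserts this against
an independent dynamic-programming oracle.

Two deliberate choices:

* **No low-complexity filter, anywhere.** Masking would remove the very
  genes the package targets. The cost is a dense seed field in
  low-complexity regions; the two-hit + ungapped-trigger stages keep
  that tractable without ever excluding a region from consideration.
* **Raw scores instead of E-values.** On a single locus there is no
  database-size semantics for Karlin--Altschul statistics. The
  reporting threshold `min_score` plays the role of the E-value cutoff;
  the pipeline default of 90 sits roughly three-fold above the maximal
  score expected for a ~300-residue query against ~0.4 Mresidues of
  random translated sequence, and well below the score of any planted
  gene at 60--80% protein identity (about 300 for the shortest).

Low-complexity coding sequence has a peculiarity worth naming: its
reverse complement often translates into a similarly biased peptide, so
a genuine gene throws weak "echo" alignments on the opposite strand and
over its own post-disruption remnants. Model merging therefore (i)
collapses same-strand overlapping models to the best-scoring one,
(ii) discards a model heavily overlapped by a >=1.5-fold stronger
opposite-strand model, and (iii) discards models scoring below 0.3 of a
neighbour within 1 kb. The score ratios make these rules inert for
genuine neighbouring genes, which score comparably.

## Gene models

`buildGeneModel()` extends a hit to a structured model:

* The start codon is the in-frame `ATG` closest to the position that
  the query alignment projects for the query's first residue, reachable
  upstream without crossing a stop; the stop codon is the first
  in-frame stop downstream. Models lacking either within
  `max_orf_extension` are flagged `incomplete`, never silently
  truncated.
* For queries annotated with two coding exons (`class=SFTP junction=93`
  metadata on the query FASTA), the two exons are located separately
  and joined across a canonical `GT..AG` intron sought at the position
  homologous to the query's exon junction. Junctions are assumed to lie
  at codon boundaries (phase 0), which is how the simulator plants
  them; real phase-1/2 junctions would need the obvious generalisation.
* A 5' non-coding exon is modelled as the stretch from the nearest
  upstream acceptor `AG` to the start codon. This is a deliberate
  stand-in: locating true first exons needs transcript evidence, so
  models without an acceptor in `upstream_scan_window` are flagged
  `missing_utr_exon` rather than guessed.

`classifyGeneType()` is a pure function of coding-exon count and
protein length: 1 coding exon is SEDC, 2 are S100A or (when the segment
after the S100 domain reaches `sftp_min_cterm_len = 300` residues)
SFTP, four or more are PGLYRP-like, exactly three stays `unknown`. The
300-residue default separates the S100A proteins (~100 aa) from even
the shortest fused-type tails by a wide margin while tolerating the
extensive natural length variation of SFTPs.

`detectPseudogene()` compares the model's genomic context with an
intact reference protein of the same family. A single reading frame
covering at least 90% of the reference with an internal stop codon
flags `premature_stop`; failure of any single frame, with two frames
jointly covering the reference with limited overlap, flags
`frameshift` (the signature of an indel of length not divisible by 3).
The 90% threshold avoids flagging natural C-terminal length variation,
which is extensive in SFTPs. Two numerical details matter for
low-complexity proteins: the context of a 2-coding-exon model has the
intron spliced out (an intron shifts the downstream frame and would
mimic an indel), and the frame-overlap tolerance is 35% of the
reference because frame-shifted low-complexity sequence keeps aligning
weakly around the breakpoint.

`iterativeDiscovery()` runs rounds of search, feeding newly discovered
intact proteins back as queries, and stops at a fixed point (no new
non-overlapping model) or `max_rounds`. Within a round, models are
built in global score order so the strongest evidence defines each gene
before weaker cross-family hits can. The output is deduplicated by
genomic footprint and sorted by coordinate; ties break by score, then
leftmost start, then query id, making the procedure deterministic.

## Composition clustering (compose / cluster)

Amino-acid composition is computed as percentages (`aaComposition`),
not counts, so a 100-residue LCE and a multi-thousand-residue SFTP tail
are comparable. Hierarchical clustering uses Euclidean distance with
average linkage by default; the literature behind this approach
specifies only "a clustermap", so the choice is explicit, configurable,
and recorded in outputs -- at the separations that matter (>= 15
percentage points on diagnostic residues) the qualitative groupings do
not depend on it. Input rows are sorted by protein id before
clustering, which makes the result invariant to input order.
`assignCompositionGroup()` labels a vector by its nearest centroid
among four canonical profiles (G/S-rich loricrin-like, Q/E-rich
involucrin-like, G/S/C/P-rich LCE-like, P/C/Q-rich SPRR-like); ties
resolve to the lexicographically smallest label and are reported.

Tandem repeats in SFTP tails are detected by shifted self-comparison:
the segment is compared with itself at every offset p, and offsets
whose identity reaches `min_identity` over at least `min_copies` copies
are reported, the smallest being the fundamental period. The method tag
travels with every report because the underlying literature names no
algorithm for this step.

## S100-domain phylogenetics (phylo)

Only the folded S100 domain aligns columnwise, so trees are built from
it alone; the domain span comes from the gene model's exon junction (or
`s100DomainEnd()` against a reference domain). The module is
self-contained by design: a progressive aligner (k-mer-distance guide
tree, sum-of-pairs profile alignment, affine gaps) feeds p- or
Poisson-corrected distances into neighbor joining, with column-resample
bootstrapping (default 100 replicates, the conventional count) and
outgroup rooting on the S100A11 flank's pendant-edge midpoint. This
replaces model-selected maximum-likelihood inference deliberately: the
downstream contract is group membership (which genes form a supported
clade), not branch-length estimation, and for that purpose
distance/NJ with bootstrap is accurate, fast and dependency-free. NJ
tie-breaking is by smallest index pair; negative branch lengths are
clamped to zero with the originals kept in an attribute.
`phyloGroups()` returns every clade whose subtending edge reaches the
support threshold (default 0.9), plus all singletons.

## Orthology and rearrangements (ortho / compare-loci)

Orthology calls combine three evidence streams -- reciprocal best hits,
shared local synteny (window of 3 genes per side, orientation-aware),
and supported phylogenetic groups -- under the rule that no single
criterion suffices. Concretely: one-to-one requires an RBH plus either
synteny >= 2 shared neighbours or an exclusive supported pair clade; a
gene whose minimal supported cross-locus clade has more than two
members is called a co-ortholog group over that clade, never
one-to-one; with no tree available, calls rest on RBH + synteny alone
and the evidence column says so. Score ties in the RBH computation
disqualify the gene (no call, ambiguity logged) -- near-tie paralogs
are exactly the situation where silent tie-breaking would fabricate
orthologs. Within the pipeline, discovered genes receive provisional
symbols from their best query's family so that synteny can see shared
neighbourhoods; the same renaming is applied consistently to RBH pairs
and phylogenetic group labels.

`detectLocusRearrangement()` decomposes the shared gene content of two
loci into maximal common-order segments (allowing whole-segment
reversal), then reports splits (with breakpoint genes stated in
reference-locus coordinates so the same ancestral event gets the same
key in every descendant), per-segment orientation relative to the
segment carrying the 5' flank, and which segment retains which flank.
`placeEventsOnTree()` assigns each event to the stem edge of the
smallest clade containing all species that exhibit it -- Dollo
parsimony, appropriate for rare structural events assumed to arise once
and not revert.

## The simulator and what it does (and does not) emulate

`buildLocus()` generates, for every species of a scenario tree, a
chromosome carrying the two S100A flanking marker genes and the
scenario's gene families in order, separated by i.i.d. uniform
intergenic DNA. Proteins are sampled from class-specific composition
profiles (SFTP tails as tandem-copied repeat units with 10% per-copy
mutation), evolved along the tree by i.i.d. substitutions with
per-family rates calibrated so the most distant leaves reach the
roster's stated divergence, and back-translated with uniform synonymous
codon choice. Introns are canonical `GT..AG` at phase-0 junctions.
Disruption events plant a `TAA` or a 1-nt deletion at ~45% of the last
coding exon; duplication events plant tandem copies with 4% extra
divergence; split events insert three non-EDC spacer genes at the
breakpoint, and inversion events reverse the 3'-flank segment. Every
build self-checks that translating the emitted truth CDS reproduces the
recorded translation and that all planted splice sites are canonical.
The same seed yields byte-identical output.

The bundled scenarios pin the study conditions used throughout the
validation suite:

* `fig1_locus`: ~190 kb, two species, 20 SEDC + 4 SFTP families at
  per-family divergences evenly spaced over 0.20--0.40 (60--80%
  protein identity to the query set), intergenic spacing 4--7 kb, five
  genes disrupted in the target species (three premature stops, two
  frameshifts).
* `fig2_rearrangement`: four species; locus split after one family on
  the stem of one two-species clade, plus an inversion of the second
  segment on a nested edge.
* `fig5_sftp_expansion`: two species; one SFTP family expands to three
  tandem copies in the second lineage.

What the simulator does **not** emulate: insertions/deletions during
protein evolution (so alignments of simulated homologs are gapless),
repeat structure or GC skew in intergenic DNA, transposable elements,
phase-1/2 introns, assembly gaps and sequencing error. Passing the
suite therefore demonstrates that the algorithms are implemented
correctly and behave as designed under realistic compositions, lengths
and divergences -- not that real assemblies, with their indels,
segmental duplications and gaps, will yield the same accuracy.

## Problem sizes and numerical choices

The validation suite runs discovery on the ~190 kb `fig1_locus`
(24 query proteins, up to 4 iterative rounds), 100 random search-oracle
pairs up to 200 residues, 200 random additive matrices up to 8 taxa
with exhaustive 6-taxon topology checks, 20 bootstrap simulations of
100 replicates each on 200-column six-taxon domains, and the full
pipeline twice on `fig5_sftp_expansion` with 50 bootstrap replicates --
sizes chosen to exercise every code path at desk scale. Floating-point
comparisons against oracles use exact equality for integer-valued
scores and 1e-8 tolerances for branch lengths; merge heights match the
brute-force linkage oracle to machine precision.

## Known limitations

* Iterative search stops at a fixed point; as with any homology-driven
  annotation, gene families with no detectable similarity to any query
  remain invisible, and reports flag the stopping rule.
* Five-prime non-coding exons are heuristic placeholders (see above).
* The builder assumes phase-0 coding-exon junctions for 2-exon genes.
* PGLYRP-class genes are classified when their exon structure is given,
  but the builder does not assemble >2-coding-exon models from hits.
* The outgroup itself cannot receive a pair-clade orthology call
  (rooting on its pendant edge separates it from everything), so its
  calls rest on RBH + synteny.
* Composition clustering is descriptive; no significance testing of
  composition differences is attempted.
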