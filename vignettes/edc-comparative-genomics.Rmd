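---
title: "Mapping gene gain and loss in the Epidermal Differentiation Complex"
author: "edcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gene gain and loss in the Epidermal Differentiation Complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcscan)
library(ape)
```

## The problem

The Epidermal Differentiation Complex (EDC) is the cluster of skin-barrier
genes between *S100A9* and *S100A11*. Most of its members are "simple" EDC
(SEDC) genes: two exons, with the entire protein-coding sequence in the
second exon and a short noncoding first exon driven by a TATA-box promoter.
The encoded proteins (loricrin, involucrin, the SPRR and LCE families,
CRCT1, and relatives) are low-complexity and highly repetitive, which is
exactly why standard annotation pipelines miss or mangle them — many were
deposited as lncRNAs or with wrong exon borders. Comparative work on this
locus therefore relies on translated homology search plus explicit
gene-structure modelling, and on parsimony reconstruction of family gains
and losses across species. `edcscan` packages that workflow: locus
extraction, iterative tBLASTn-style discovery, single-coding-exon gene
modelling, pseudogene detection, orthology and family assignment, SPRR
subtype profiling, junction-read verification, and Dollo/Fitch
reconstruction on a dated species tree — plus a synthetic-locus generator
that makes every stage testable without downloading assemblies.

## The locus model

A `Locus` is the oriented interval between the two anchor genes, anchors
included. All internal coordinates are 0-based half-open; GFF3 output is
converted to 1-based inclusive at the boundary. If the anchor requested as
"left" sits genomically to the right of the other, the sequence is
reverse-complemented so downstream stages always see the same frame. Runs of
`N` of at least `gapMinLength` (default 10 nt, so single ambiguous bases are
not flagged) form the gap track; a gene whose expected interval overlaps a
gap is reported `unknown` rather than `absent`, because real discontinuity
cannot be excluded in a draft assembly.

## Discovery: seeded translated search

Queries are protein sequences; the locus is translated in six frames
(codons containing `N` become `X`). Two-hit exact-word seeding (word length
4, both hits on one diagonal within a 40-residue window) nominates candidate
windows, and each window is then aligned by a full affine-gap
Smith–Waterman, so a reported hit score *is* the optimal local-alignment
score of its region — the suite checks this against
`Biostrings::pairwiseAlignment` as an independent oracle. Scoring is
BLOSUM62 with gap open 11 / extend 1, mirroring NCBI tBLASTn defaults; the
stop-codon row of the matrix is overridden to −4 against every residue so
that discovery alignments can cross pseudogene stops while still paying for
them. There is no E-value machinery: at locus scale a raw score threshold
(default 40) is self-contained and reproducible. The search iterates:
proteins derived from newly called genes are added as queries until no new
non-overlapping hit appears, emulating the iterative search by which
cetacean-specific paralogs are found from their own relatives.

## Gene models and coding integrity

`callOrf` extends a hit to the nearest in-frame ATG at or upstream of the
hit start (never across an in-frame stop) and to the nearest downstream
stop. When several ATGs are candidates, the one maximizing the alignment
score against the query wins; remaining ties go to the longest CDS. CDS
calls below 150 nt are rejected.

`findUpstreamExon` then looks for the canonical SEDC anatomy upstream of
the CDS: the acceptor `AG` closest to the start codon within 300 nt, a donor
`GT` giving an intron of 50–20,000 nt (closest to the acceptor on ties),
and a `TATAWA` box upstream of the putative exon 1. The transcription start
is placed 25 nt after the TATA box — a fixed promoter-anatomy convention
shared with the simulator, since no universal TSS rule exists for these
genes. Only canonical GT/AG introns are modelled. When no consistent
structure exists, the model falls back to single-exon with the TATA box
searched directly upstream of the CDS; absence of structure is a reported
outcome, not an error.

Coding integrity is classified by a frameshift-aware dynamic program over
(reference residue × candidate nucleotide): codon-match moves, codon-level
indels (linear penalty 13 per residue), and single-nucleotide
insertion/deletion moves that shift the reading frame at a penalty of 15.
Premature stops score −4 and are recorded as lesions. States:

* `intact` — at least 90 % of the reference aligned, no lesion;
* `disrupted_frameshift` / `disrupted_stop` — lesions present, with codon
  coordinates (a frameshift takes precedence because stops downstream of a
  frameshift are secondary consequences);
* `truncated` — lesion-free but covering less than 90 % of the reference
  (the spec's 60 % bound marks clear truncation; the band between 60 and
  90 % is also reported `truncated`, the conservative reading);
* `absent` — best score below 40;
* `unknown` — the expected interval overlaps an assembly gap.

On candidates whose divergence is substitution-only, the DP score equals a
brute-force enumeration of every single-nucleotide edit scored with a
linear-gap local aligner — the suite asserts this equality.

Frameshift placement inside repetitive or degenerate context can be
ambiguous: several placements score identically, exactly the ambiguity that
indel normalization addresses in variant calling. Each frameshift lesion is
therefore reported as the interval of co-optimal placements (bounded by a
leftmost- and a rightmost-preferring pass of the DP); the interval collapses
to a point when the placement is unique.

## Orthology, families, subtypes

Orthology follows the classic recipe: reciprocal best hits of the encoded
proteins (ties yield `ambiguous`, never a forced call) corroborated by gene
locus synteny — the fraction of the two nearest flanking genes per side
whose own orthologs flank the partner on the corresponding side. The
`ortholog` verdict requires RBH plus synteny support ≥ 0.5. Families are
single-linkage clusters at ≥ 50 % alignment identity over the shorter
sequence, with deterministic ids derived from sorted member names. Subtype
labels come from the nearest labelled reference protein; SPRR-specific
sequence evidence (two copies of the degenerate motif `QQCKQXCXP` for the
cetacean-specific SPRRc subtype, at least two cysteine duplets for SPRR5,
proline and glutamine fractions) breaks ties and is reported alongside.
`X` residues in a protein (from `N` codons) match only `X` in a motif
pattern, never a concrete letter, so ambiguous sequence cannot inflate
motif counts. Proteins matching no reference stay `unplaced`.

## Transcript evidence

Reads are aligned to the oriented locus either contiguously or as two
blocks split at any internal read position (each block ≥ 8 nt, gap within
the intron bounds), minimizing mismatches (≤ 2 by default); contiguous
placements are preferred on ties, then canonical GT..AG gaps. A two-exon
model is confirmed when at least one junction read reproduces the model's
intron interval *exactly*; genes with aligned reads but no matching
junction read are reported as "expression evidence, structure unconfirmed".

## Gain/loss reconstruction

Characters are gene families; tip states are `P`, `A`, `D`
(present-but-disrupted) or `?` (assembly gap). Dollo parsimony places the
single gain at the MRCA of all carriers and the provably minimal set of
losses — a branch is a loss exactly when its subtree contains no carrier
but at least one observed absence, and its parent's subtree still contains
a carrier. Unknown tips never force events. Disrupted genes count as
present for origin dating (a pseudogene is evidence of prior presence) and
additionally emit a `loss_in_progress` tag on their terminal branch; the
`disruptedAs` switch can instead map them to absent. Equally parsimonious
placements are resolved toward internal (stem) branches, and all co-optimal
maps are enumerable with a flag. Fitch parsimony is provided as the
unordered-state comparator. Divergence times are user-supplied tree
metadata (branch lengths); they are rendered on the annotated cladogram but
never estimated.

```{r dollo-example}
tr <- read.tree(text = "((dolphin,vaquita),(right_whale,(minke,blue)));")
pa <- matrix(c("P", "A", "P", "A", "A"), nrow = 1,
             dimnames = list("PRR9", tr$tip.label))
eventTable(dolloReconstruct(tr, pa))
```

## What the simulator emulates — and what it does not

The generator builds each gene as
`[TATAWA] [25 nt] [exon 1] [GT intron AG] [5'-UTR] [ATG CDS stop]`,
with family reference proteins drawn from composition profiles mirroring
the EDC protein classes (G/S-rich loricrin-like, Q-rich involucrin-like
with over 40 % glutamine, P-rich SPRR5-like with cysteine duplets,
SPRRc-like with two implanted `QQCKQXCXP` motifs), uniform synonymous
back-translation, 10 % per-site protein divergence between species, and
single implanted lesions (an in-frame stop or a one-nucleotide indel) in a
configurable fraction of copies. Family histories are simulated on the tree
with per-branch loss (0.1) and duplication (0.05) probabilities, and reads
are sampled from spliced transcripts with a configurable junction fraction.

Four idealisations matter for interpreting green tests. First, 5'-UTRs and
intron interiors are drawn from `{A,C,T}` and `TATAWA` is scrubbed from
non-promoter gene regions, so the closest-signal search rules recover the
implanted coordinates *exactly*; real loci contain decoy `AG`/`ATG`/`GT`
signals, and on real data the structure search can pick a nearby signal
instead (the coordinates, not the gene call, would shift). Second,
between-species divergence is substitution-only; real orthologs also
accumulate in-frame indels, which the integrity aligner absorbs through
its codon-gap moves but which the exact-coordinate round trip does not
exercise. Third, frameshift lesions are implanted in locally conserved
context (the ±4 codons around the lesion match the family reference);
next to a substituted residue a lesion's coordinate is genuinely
unidentifiable because score-equivalent placements exist. Fourth, uniformly
placed reads never cross the exon junction with less than `minAnchor`
overlap — such reads carry no usable junction evidence and their "true"
intron would be unrecoverable by any aligner. Passing tests therefore
demonstrate correctness of the machinery under the canonical gene anatomy,
not annotation accuracy on arbitrary genomes.

## Numerical choices and degenerate inputs

* Coordinates: 0-based half-open internally; GFF3 1-based inclusive on
  output; BED 0-based half-open.
* Sequences shorter than 3 nt translate to empty frames; candidates shorter
  than one codon classify as `absent`.
* Tie-breaks are deterministic everywhere: closest acceptor to the CDS,
  longest CDS among equal-scoring ORFs, contiguous-then-canonical for read
  placements, internal-branch preference for loss placements, lexicographic
  family ids.
* All randomness flows through R's RNG; a fixed seed makes simulation
  output byte-identical.
* Problem sizes in the shipped validation: five species with about 30
  genes per synthetic locus for the sequence round trip, 100
  presence/absence characters for event recovery, 200 random query/locus
  pairs for the aligner oracle, and 10,000 random strings for the motif
  oracle — compact enough to re-run routinely while still exercising every
  stage.

## Design decisions on open points

* Partial anchor annotations at scaffold edges are rejected: the locus
  contract requires both anchors complete and co-located, and the error
  says which anchor failed.
* GenBank-style predictions with wrong exon borders are corrected by the
  ortholog-alignment-maximizing rule built into `callOrf`; this is an
  explicit stand-in for manual curation.
* Family members whose placement evidence conflicts (e.g. candidate SPRR5
  copies outside the locus) are labelled `unplaced` rather than forced
  into a family.
* Only `X` is honoured as an ambiguity letter in motif patterns.
* The command-line wrapper (`inst/scripts/edcscan`) is a thin veneer over
  `simulateStudy()` and `runPipeline()`; the R functions are the primary
  interface.

## Known limitations

No E-value statistics (scores are raw); no multi-intron or non-canonical
splice models; SFTP (three-exon) genes are tracked only as
presence/absence; no likelihood-based gene-content models; orthology is
pairwise RBH + synteny, not tree reconciliation; the spliced aligner is for
locus-scale verification, not transcriptome-scale mapping.
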