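---
title: "Annotating germline TRB loci in salmonid genomes"
author: "trbloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating germline TRB loci in salmonid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trbloci)
library(GenomicRanges)
library(Biostrings)
```

# The problem

The T cell receptor beta (TRB) locus of salmonids has an unusual germline
architecture: the basic unit is a pair of complete V–D–J–C loci duplicated
head-to-head on one chromosome, in opposite transcriptional orientation
with the V genes in the middle and the C genes at the outer ends, plus
further copies or decayed remnants produced by the salmonid-specific whole
genome duplication. Annotating such loci means finding, for every gene
segment, the *recombination signal sequences* (RS: a heptamer and a
nonamer separated by a nominally 12- or 23-base spacer, subject to the
12/23 rule), the splice signals that delimit coding exons, and the
conserved residues that decide whether a gene can make a working protein.

`trbloci` implements that pipeline end to end:

1. **Motif evidence** — RS and splice-site scanners (`scanRS`,
   `scanSplice`, `pairRS1223`).
2. **Gene calling** — C, J, D and V segment callers combining similarity
   to reference libraries with motif evidence (`callCGenes` etc.,
   `annotateGenome`).
3. **Functionality** — F / ORF / P classification with machine-readable
   reasons (`classifyFunctionality`, `numberVDomain`).
4. **Subgroups and names** — clustering at the >75% nucleotide identity
   threshold and positional nomenclature (`clusterSubgroups`,
   `assignNames`).
5. **Phylogenetics** — neighbor-joining trees with bootstrap supports
   (`njTree`, `bootstrapSupports`).
6. **Expression** — read assignment to TRBC1/TRBC2 transcripts under a
   2-mismatch cap, RPKM and the TRBC1/TRBC2 ratio
   (`quantifyExpression`).
7. **Synthetic ground truth** — a seeded generator of TRB-style genomes
   with exact planted coordinates and labelled mutant genes
   (`generateLocusGenome`), which is what makes every stage testable.

# The evidence model

## Recombination signals

The scanners use the canonical V(D)J consensus, heptamer `CACAGTG` and
nonamer `ACAAAAACC`. The heptamer's first three bases (`CAC`) are the
recombinationally critical core and are required exact by default; beyond
that, the default gate is 2 heptamer and 3 nonamer mismatches with a
spacer tolerance of ±1 base. Scoring is the plain mismatch count — no
position weight matrix — so results are deterministic and checkable
against a brute-force oracle (the test suite does exactly that on random
kilobase sequences).

A scan hit licenses a coding end on the heptamer's `CAC` side. Per gene
type, the spacer classes are the universal TRB assignment: V 3'RS = 23,
J 5'RS = 12, D 5'RS = 12, D 3'RS = 23. `pairRS1223` forms candidate
D-gene units from (12, 23) hit pairs flanking an 8–25 base D region;
pairs must imply the same gene strand, and competing pairs are resolved
by lowest combined mismatch count, then smallest gap, then position.

Three RS levels drive classification: *intact* (found at the scan gate),
*defective* (found only at the relaxed gate, 3 heptamer / 4 nonamer
mismatches → ORF), and *missing* (not found even relaxed with the
heptamer starting within ±8 bases of the coding end → pseudogene). These
thresholds are explicit `trbConfig()` defaults: germline curation
practice distinguishes "degenerate but present" from "absent", but no
universal numeric boundary exists, so the package declares one and keeps
it configurable.

J genes deserve a note: they are called from motif evidence alone
(no similarity reference), so their discovery gate is stricter (1
heptamer / 2 nonamer mismatches) and a call additionally requires an
open J-REGION ending at a donor-like hexamer (best match to `GTAAGT`,
minimum score 4/6). Without these gates, random intergenic sequence
produces spurious J calls at a measurable rate; with them, a degenerate
donor (e.g. `GTAACT`) is still called and flagged, but a J gene whose RS
itself has decayed would need a relaxed re-scan — a deliberate
sensitivity/precision trade-off.

## Splice signals and gene models

Donors are `GT` positions scored by similarity to the conserved hexamer
`GTAAGT` (the 3' signal of salmonid TRBJ genes); acceptors are `AG`
preceded by a pyrimidine-rich tract (≥5 pyrimidines in the 8 preceding
bases — an operational definition, configurable, since only "splice
signals were used" is a biological given).

Multi-exon genes (the 4-exon C gene, and the atypical 4-exon V gene in
which the V-EXON is split by two introns) are placed by a *spliced walk*:
the spliced reference coding sequence is anchored by its best ungapped
placement, extended until the local mismatch density jumps (≥12
mismatches in a 20-base window — far above what 10% within-subgroup
divergence can produce), and each junction is resolved by enumerating
donor/acceptor candidates under the constraint that exon lengths must sum
to the reference length, scoring by downstream agreement. Because the
generator models divergence as substitutions only, recovered boundaries
on synthetic data are exact, and the tests assert exactness; on real data
boundary accuracy degrades with indel content (a documented limitation).

C-gene calls must have 4 exons with splice frames 1, 1 and 0 at the
EX1/EX2, EX2/EX3 and EX3/EX4 junctions; violations carry the
`incomplete_exon_structure` flag. The translated C domain is checked at
the conserved positions 23 (1st-CYS), 41 (CONSERVED-TRP), 89
(hydrophobic; allowed set `AVLIMFWCY`) and 104 (2nd-CYS).

## Functionality

A gene is **F** when its coding region is an open reading frame with no
splice, RS or conserved-residue defect; **ORF** when the frame is intact
but a splice site or RS is defective or an anchor residue changed; **P**
on a stop codon, frameshift, or missing RS. Reasons are machine-readable
(`stop_codon`, `frameshift`, `missing_rs`, `defective_rs`,
`defective_splice`, `anchor_change`, `contains_N`). Two operational
choices:

* "incorrect folding" is operationalised strictly as an anchor change at
  V positions 23/41/104 (via alignment-based numbering transfer,
  `numberVDomain`, against a numbered reference profile; identity below
  30% refuses to number) — no structure prediction;
* genes whose coding span contains `N` cannot be certified functional and
  are reported as ORF with reason `contains_N` (assembly gaps must not
  inflate F counts).

Frameshifts are detected both arithmetically (coding length not a
multiple of 3) and by alignment (a placement requiring a
non-multiple-of-3 indel against the reference), which catches the
1-base-deletion case even when an end-anchor hides the length change.

## Subgroups and names

Subgroups are single-linkage connected components over pairwise global
nucleotide identity **strictly greater than 75%** (sequences at exactly
75% are not linked). Identity is computed over the V region (the spliced
V-EXON minus the 11-base L-PART2), since subgroup definitions concern the
variable region; alignment scoring is match +1 / mismatch −1, gap open 4
/ extend 1. Single linkage is the natural reading of "sequences where
each subgroup shares more than 75% identity" (a connectivity criterion);
complete linkage is available via `linkage = "complete"`. Clusters
inherit the label of their best-identity reference exemplar when that
identity exceeds the threshold, otherwise they are novel and take the
next free number.

Names are positional: `TRB{locus}{type}{subgroup}-{rank}`, with ranks
counted 5'→3' along the locus *transcriptional* orientation within
(locus, type, subgroup) — so `TRB2V13-4` is the fourth subgroup-13 V gene
of locus 2, and reversing a contig changes no name (tested). C genes rank
across loci within their C subgroup (`TRB1C1-1`, `TRB2C1-2`). J genes are
numbered positionally per locus. Locus numbers follow a user-suppliable
contig order, then C-gene position within the contig, because locus
numbering encodes chromosome identity and history and cannot be derived
from sequence alone. Orphan inverted V genes (a remnant locus) take the
next locus number but are reported with locus label `remnant`.

## Locus assembly and duplication patterns

Each C gene seeds a locus; the nearest upstream same-strand D (within a
12 kb window, not crossing another C) joins it, J genes between the D and
C join, and every V gene attaches to the nearest same-strand downstream
D. Patterns are classified in priority order: an extra V-less D-J-C
cluster beside a complete locus → `tandem_DJC_duplication`; two complete
opposite-orientation loci with all their V genes between the two C genes
→ `head_to_head_pair`; orphan V genes beside a single complete locus →
`remnant`; otherwise `single`.

## Phylogenetics

`computeDistances` supports p-distance (default for nucleotides),
Poisson-corrected distance (default for proteins) and Kimura
2-parameter, under pairwise or complete deletion; saturated entries are
clamped to a configurable ceiling and flagged. A rate-matrix
("JTT-style") model is deliberately not offered: the study protocol
names an amino-acid matrix while feeding nucleotide alignments, which
cannot be reproduced literally, so topology-level agreement is the
comparison standard here. `njTree` is a from-scratch Saitou–Nei
implementation with a documented deterministic tie-break (lowest original
taxon pair joins first) and zero-clamped negative branch lengths (raw
values kept as an attribute); the test suite cross-checks it against
`ape` on additive matrices, where NJ recovery is exact. Bootstrap
supports resample alignment columns with replacement and are mapped onto
the full-data tree (not a majority-rule consensus), as percentages of
replicates containing each bipartition; everything is seeded and
bit-reproducible.

## Expression

Reads are assigned to TRBC references by exact enumeration of ungapped
placements: a read within the 2-mismatch cap must contain an exact
anchor chunk (pigeonhole over `maxMismatches + 1` chunks), so candidates
come from exact chunk matches and are verified by vectorised byte
comparison; reads with no anchored placement get a full ungapped scan
and, if still over the cap, a gapped alignment rescue in which indel
columns count toward the mismatch total. Ties between references are
discarded as `ambiguous_tie` (so both best-hit conventions remain
auditable), over-cap reads as `too_many_mismatches`, hopeless reads as
`unmapped`; counts plus discards always equal reads processed.

RPKM uses **total input reads** (the library depth, matching how
published tables report it), not mapped reads:
`rpkm = count × 1e9 / (inputReads × refLength)`. The TRBC1/TRBC2 ratio
is reported rounded half away from zero to one decimal (the precision of
published expression tables) with the raw value retained.

# The synthetic-data generator

`generateLocusGenome` builds the study conditions, not a tunable toy:

* **Architecture** — by default 20 V genes per locus over three
  subgroups, one D, ten J, one C, V-gene spacing ~3.5 kb (the observed
  density of real salmonid TRB loci), giving a ~200 kb head-to-head
  contig; patterns `head_to_head`, `single`, `remnant`, `tandem_djc` and
  `trout` (head-to-head chromosome plus a single+remnant chromosome)
  mirror the reported architectures.
* **Gene models** — V: 49-base L-PART1 (frame-1 donor), 11-base L-PART2,
  106-codon V region with CYS23/TRP41/CYS104, 23-spacer RS abutting the
  coding end; J: 12-spacer RS, 49-base J region with FGXG, `GTAAGT`
  donor; D: 12-base G-rich region readable in all frames between 12- and
  23-spacer RS; C: exon lengths 391/45/104/27 (splice frames 1, 1, 0)
  with conserved 23/41/89/104.
* **Divergence** — i.i.d. substitutions only (within-subgroup 0.10,
  between-subgroup 0.35 per site, straddling the 75% threshold;
  same-chromosome C copies 0.005, C1-vs-C2 0.12 ≈ 70% amino-acid
  identity), with anchors, start codon and stops protected, so truth
  coordinates are exact.
* **Mutant panel** — eight labelled operators (`none`, `stop`,
  `frameshift`, `ablate_rs`, `degrade_rs`, `break_donor`,
  `break_acceptor`, `anchor_change`) plant F/ORF/P variants by
  construction; `ablate_rs` re-randomises until no relaxed-threshold RS
  survives near the coding end, so the planted label is guaranteed.
* **Reads** — allocated across transcripts proportionally to target RPKM
  ratio × length with deterministic largest-remainder rounding, uniform
  start/strand, i.i.d. substitution errors.

What passing on this generator does **not** show: robustness to indels
and repeats (intergenic sequence is i.i.d. uniform; coding divergence is
substitution-only except the explicit frameshift operator), to assembly
gaps beyond `N` flagging, or to genes with no reference similarity at
all (discovery is similarity-seeded for V and C). Those are real-data
phenomena outside the desk-scale validation envelope.

# A worked example

```{r example, eval = FALSE}
cfg <- synthConfig(seed = 1, pattern = "trout")
ts  <- generateLocusGenome(cfg)
res <- annotateGenome(genomeSeq(ts), refLibrary(ts))
res$annotation
locusArchitectureReport(res$structures)
tab <- subgroupCountTable(res$annotation)
tab$counts

sim <- simulateReads(truthTranscripts(ts), nReads = 50000, ratio = 3,
                     seed = 1)
quantifyExpression(sim$reads, truthTranscripts(ts))
```

# Numerical choices and problem sizes

* The validation suite runs the full pipeline at desk scale: a ~200 kb
  head-to-head genome for exact-recovery checks; 20 seeds × 8 operators
  for the functionality confusion matrix; 20 seeds × 9 genes for
  subgroup recovery; 50 random additive trees (n ≤ 10) for NJ; 100
  random kilobase sequences against the brute-force RS oracle; 50 000
  reads per target ratio (1, 2.5, 7) at 1% error for expression
  recovery. These sizes were chosen as the smallest at which every
  property is a sharp pass/fail statement rather than a trend.
* Alignment engines: `Biostrings::pairwiseAlignment` throughout (local
  for similarity extension with blastn-like scoring 2/−3/5/2; global for
  identity and numbering); `PDict`/`matchPDict` for exact k-mer and
  anchor matching.
* Ties everywhere break deterministically (position, then score, or as
  documented per function); all stochastic steps take explicit seeds.
* Degenerate inputs: empty FASTA records, out-of-bounds intervals,
  non-symmetric distance matrices, zero-depth RPKM and sub-3-taxon trees
  are errors with informative messages; empty scan windows and regions
  return empty results.

# Known limitations

* Exon boundaries are exact only under substitution-style divergence;
  indel-rich pseudogenes will be called with approximate coordinates and
  usually classified P via the alignment-based frameshift check.
* The numbering transfer is a profile-alignment approximation of the
  full IMGT unique-numbering algorithm; insertions relative to the
  profile are not renumbered into CDR-specific insertion codes.
* J genes with decayed RS motifs are below the discovery gate (see
  above).
* Locus numbering across genomes is configuration, not inference; no
  synteny or orthology is computed.
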