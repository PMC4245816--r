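---
title: "Rule-based discovery of two-exon epidermal differentiation genes"
author: "sedcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based discovery of two-exon epidermal differentiation genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedcscan)
```

## The model

The epidermal differentiation complex (EDC) is a chromosomal gene cluster,
flanked by S100A genes, whose products are cross-linked by transglutaminases
into the cornified envelope of keratinocytes. Its "simple" members — SEDC
genes — share a stereotyped architecture:

* a TATA-box core promoter,
* a short noncoding exon 1 ending in a splice donor whose genomic context is
  `G-GTAAG` (the exon-terminal G followed by the intron-initial GTAAG),
* a single intron ending in a polypyrimidine tract and the acceptor `AG`,
* a second exon that begins with a 20–25 nt 5'UTR and contains the entire
  coding region.

`sedcscan` turns that architecture into an explicit scanning procedure.
Candidate coding exons are open reading frames (ATG start, standard code,
60–2000 codons, first in-frame stop) preceded by an accepted splice acceptor
at a 5'UTR distance of 20–25 nt inclusive. An acceptor is an `AG` whose
upstream window of 12 nt has a pyrimidine (C+T) fraction of at least 0.7 and
no `N`. For each surviving candidate, the noncoding exon 1 is sought as the
nearest upstream `GGTAAG` donor that has a TATA-box match (`TATAWAW`,
IUPAC) at 60–90 nt; the distance is counted as the number of nucleotides
strictly between the last TATA base and the exon-terminal G. Candidates
whose ORFs overlap on one strand are reduced to the longest ORF (ties:
leftmost, then shortest UTR). Finally, candidates are kept when their
protein either falls into one of the compositional classes below *or*
carries one of the conserved SEDC motifs — the two filters are independent
and combined by OR, matching how epidermal proteins are recognized either by
biased composition or by conserved termini.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `acceptor_distance_range` | 20–25 | nt | 5'UTR length between acceptor AG and ATG |
| `polypyrimidine_window` | 12 | nt | window scored 5' of the AG |
| `polypyrimidine_min_fraction` | 0.7 | fraction | minimum C+T in the window |
| `donor_motif` | `GGTAAG` | — | exact donor context |
| `tata_pattern` | `TATAWAW` | — | TATA consensus (IUPAC) |
| `tata_distance_range` | 60–90 | nt | TATA-to-donor spacer |
| `min_orf_codons` / `max_orf_codons` | 60 / 2000 | codons | ORF length bounds |
| `gs_min` | 0.5 | fraction | combined G+S for `GS_rich` |
| `single_residue_min` | 0.15 | fraction | C/P/Q single-residue classes |
| `similarity_threshold` | 40 | score | expansion acceptance (BLOSUM62 units) |

The acceptor and TATA distance windows are the architecture's defining
distances. The polypyrimidine tract is operationalized as a 12 nt window
with ≥ 70% pyrimidines: the tract itself is only qualitatively defined, so
both knobs are exposed in `pipeline_config()`. The 60-codon ORF minimum is
inferred from the smallest known SEDC proteins (about 70 residues) with some
margin; it is deliberately permissive because the composition/motif filter
does the final triage. The composition thresholds are anchored on reported
extremes — loricrin homologs reach ~70% combined glycine+serine, the
cysteine-rich EDCRP proteins 35–40% cysteine, proline-rich EDPE about 20%
proline — and are set at half those values so that moderately biased family
members still classify. An `intermediate` size class (171–300 residues) is
added so the size classification is total; the field's convention only names
the 70–170 "typical" range and the >300 "long" loricrin/involucrin-like
range.

## Numerical and algorithmic choices

*Coordinates.* All internal coordinates are 0-based half-open on the
forward strand; minus-strand features are stored as forward intervals with a
strand flag, and scanning the minus strand is implemented as scanning the
reverse complement followed by coordinate mirroring, which makes strand
symmetry exact by construction. GFF3 output converts to 1-based inclusive.

*N handling.* `N` is legal in input, but any signal window containing `N`
fails its test. This is the conservative choice for assembly gaps; nothing
is predicted across a gap.

*Exon-1 search.* Only the nearest accepted donor is reported, and among
in-range TATA matches the one nearest the donor. When several donors exist,
a donor without a TATA box does not block a farther donor that has one. The
reported exon-1 span runs from the end of the TATA match to the donor G: the
true transcription start cannot be resolved without 5'RACE data, so the span
is a window, not a TSS call.

*Overlap resolution.* Longest ORF, then leftmost, then shortest UTR. Real
screens resolved overlapping candidates manually; an automated pipeline
needs a deterministic rule, and preferring the longest ORF keeps the full
coding region when internal Met codons create nested candidates.

*Isoelectric point.* Henderson–Hasselbalch net charge over the termini and
D/E/C/Y/H/K/R side chains with an EMBOSS-style pKa table, solved by
bisection on pH 0–14 to 1e-4. The net charge is strictly decreasing in pH,
so the root is unique; tests verify |Z(pI)| ≤ 1e-3 and agreement with a
fine-grid scan. pKa tables differ between tools by a few tenths of a pH
unit, which is why the table is selectable.

*Local alignment.* The iterative screening's BLAST searches are replaced by
exact Smith–Waterman with BLOSUM62 and affine gaps (open 11, extend 1,
a gap of length L costing 11 + L). SEDC proteins are short and of low
sequence complexity, which makes heuristic seeding unreliable, while the
candidate pools here are small enough for exact dynamic programming. The
expansion threshold is a raw score (default 40), not an E-value; no E-value
calibration is attempted, and outputs record the threshold used. Expansion
is round-based — round k accepts every pool protein scoring at or above
threshold against anything accepted before round k — and equals the
connected-component closure of the seeds in the threshold graph, so the
result is independent of processing order. Reciprocal-best-hit calls drop
ties entirely (conservative partial matching).

*Repeats.* `repeat_score()` uses a self-match period profile: for each
candidate period the longest run of positions matching their period-shifted
partner defines a repeated block, required to span at least two full copies;
ties go to the smallest period. This is an approximation sufficient for
flagging repetitive proteins, not a tandem-repeat dynamic program — the
biological claim it supports is qualitative.

*Neighbor-composition statistic.* The claim that neighboring EDC genes
encode compositionally similar proteins is tested as: observed mean
Euclidean distance between the 20-dimensional composition-fraction vectors
of adjacent genes (locus order, genes between the anchors), against the
permutation distribution of random gene orderings, with an add-one p-value
`(1 + #{perm ≤ obs}) / (n + 1)` so the p-value is never zero. The statistic
is invariant to locus reversal and coordinate shifts.

## What the synthetic locus emulates — and what it does not

`generate_locus()` is the package's test bed: every embedded gene follows
the SEDC architecture exactly (all distances drawn uniformly from the rule
windows; intron length 100–300 nt; exon 1 length 25–45 nt; protein length
70–170 residues), proteins are sampled from class-specific residue
distributions (GS_rich: G 0.35/S 0.35; C_rich: C 0.35; P_rich: P 0.25;
Q_rich: Q 0.30 — values chosen to bracket the reported compositional
extremes of the families) and carry the conserved N- and C-terminal motifs.
Composition classes persist between consecutive genes with probability 0.75,
emulating the blocks of similar neighbors left by local gene duplication.
Decoys each violate exactly one rule (missing acceptor, missing ORF, 30 nt
UTR, 30-codon ORF, purine "tract"), so each prediction rule is exercised
individually.

Within a gene cassette, accidental copies of the planted signals (a second
TATA nearer the donor, a donor motif inside the intron, AG/ATG inside the
UTR, an out-of-frame ATG in the first codons, read-through ORFs entering a
cassette) are removed during construction, so that the planted coordinates
are the unique rule-conformant ones and recovery can be scored against exact
coordinates. The random spacers between cassettes are left untouched:
chance acceptor/ORF coincidences there are possible and are why precision is
benchmarked at ≥ 0.95 rather than 1.0. One seeded generator drives all
sampling, so a seed reproduces the locus byte-for-byte.

What the generator does *not* emulate: isochore/GC structure, repetitive
elements, pseudogenes, multi-intron neighbors (S100-fused type proteins,
PGLYRPs), sequencing error, or realistic intergenic composition. Passing
recovery benchmarks on this locus therefore shows that the scanner
implements its stated rules exactly and is robust to rule-violating decoys —
not that those rules are sufficient for real genomic annotation, where the
original screens needed RACE evidence, RT-PCR verification and manual
curation.

## Problem sizes

The standard benchmark locus carries 50 genes and 200 decoys (about 210 kb);
scanning and scoring it takes a few seconds. Oracle-equivalence checks run
the brute-force enumerations on one hundred 10 kb random contigs for the
acceptor stage, a 25-contig subset for the (much slower) six-frame ORF
oracle, 50 random pairs for the alignment DP oracle, and a 20-gene locus for
the exon-1 oracle. These sizes were chosen to keep the whole suite fast
while leaving each check statistically meaningful.

## Known limitations

* Exact donor matching (`GGTAAG`, mismatch budget 0) will miss genes with
  noncanonical donor contexts; the motif is configurable but the default is
  strict, as in the original screen.
* The 20–25 nt UTR window is enforced as hard bounds; "typical" distances
  in real genes admit exceptions, which a relaxed configuration can widen.
* Composition classes use fixed thresholds; borderline proteins near a
  threshold flip classes under small sampling differences (the OR with the
  motif filter absorbs most of this in the pipeline).
* The score-threshold expansion has no significance calibration; it is a
  stand-in for E-value-based search that behaves well only on small pools.
* `read_gff3_models()` reconstructs models from the package's own GFF3
  dialect (signal features as Sequence Ontology terms); arbitrary GFF3 from
  other tools is not supported.
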