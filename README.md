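# sedcscan

Rule-based discovery and characterization of **two-exon epidermal
differentiation genes** (SEDC genes) in genomic DNA.

The epidermal differentiation complex (EDC) is a gene cluster, flanked by
S100A genes, encoding the structural proteins that transglutaminases
cross-link into the cornified envelope of keratinocytes. Most of its
members share a minimal two-exon architecture — TATA-box promoter, short
noncoding exon 1, one intron, and a second exon carrying the entire coding
region — and encode short, low-complexity proteins enriched in small sets
of residues (glycine+serine, cysteine, proline, or glutamine). `sedcscan`
is for comparative genomicists who want to screen assembled genomic
sequence for this architecture and characterize the encoded proteins, and
for anyone who needs a fully controlled benchmark of such a screen.

## The method

A candidate gene is called when, and only when, the sequence satisfies the
architecture's signals:

```
TATA box ──60–90 nt── G | GTAAG ... intron ... (C/T)₁₂ AG ──20–25 nt── ATG ... ORF ... stop
(TATAWAW)           exon-1 donor              polypyrimidine acceptor     coding exon 2
```

* **acceptor**: `AG` preceded by a 12 nt window with ≥ 70% pyrimidines;
* **coding exon**: ATG at 20–25 nt from the acceptor opening an ORF of
  60–2000 codons (standard genetic code, first in-frame stop);
* **exon 1**: nearest upstream `GGTAAG` donor with a `TATAWAW` match at
  60–90 nt;
* **protein filter**: composition class (G+S ≥ 0.5, or C/P/Q ≥ 0.15) *or*
  a conserved SEDC motif (`MSYxxxxQQCKQPCQPPP` N-terminal,
  `MCSRxxxxxCH` internal, `QQxKQPSQWPxQxxK` C-terminal; `x` = any
  residue), combined by OR.

Downstream analyses: per-protein composition profiles, isoelectric points
(Henderson–Hasselbalch + bisection), glutamine/lysine cross-linking residue
counts, size classes, motif scans and sequence-logo matrices, internal
repeat scores, iterative Smith–Waterman similarity expansion with
reciprocal-best-hit orthology, and EDC locus maps with a permutation test
for the compositional similarity of neighboring genes. A seeded synthetic
locus generator with ground truth makes every stage testable end to end.

## Worked example

```r
library(sedcscan)

loc <- generate_locus(n_genes = 50, n_decoys = 200, seed = 11)
models <- predict_sedc_genes(loc$sequence, pipeline_config(),
                             contig = loc$contig)
rep <- recovery_report(models, loc$truth)
str(rep[c("sensitivity", "precision", "acceptor_exact", "donor_exact")])
#> List of 4
#>  $ sensitivity   : num 1
#>  $ precision     : num 1
#>  $ acceptor_exact: num 1
#>  $ donor_exact   : num 1
```

All 50 embedded genes are recovered (sensitivity 1.0), nothing else is
called on this seed (precision 1.0), and for every matched gene the
acceptor, donor and TATA coordinates are recovered exactly — the 200
rule-violating decoys are all rejected.

```r
prof <- profile_proteins(setNames(models$protein, models$id))
table(prof$size_class)
#> typical_70_170
#>             50
range(prof$pi)
#> [1]  4.88 10.63
```

The numbered scripts under `analysis/` run the same study as a narrative
pipeline — simulate (`01`), scan and score (`02`), protein features
(`03`), motifs and repeats (`04`), similarity expansion and orthology
(`05`), locus map and synteny (`06`) — writing their tables under
`results/`. Step 6, for instance, reports that neighboring genes encode
compositionally similar proteins (observed mean adjacent-pair distance
0.140 vs 0.289 under permutation, p = 0.001 with 999 permutations) and
that a simulated 10-gene inversion leaves 40/50 ortholog pairs fully
rank-concordant.

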