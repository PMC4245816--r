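## Synthetic EDC loci with ground truth.
##
## Each embedded gene follows the SEDC architecture exactly: TATA box ->
## short noncoding exon 1 ending in the exon-terminal G of a GGTAAG donor ->
## intron -> 12 nt all-pyrimidine tract + AG acceptor -> 20-25 nt 5'UTR ->
## ATG + compositionally biased CDS + stop. Decoys each violate exactly one
## rule. Within a gene cassette, accidental occurrences of the planted
## signals (a second TATA nearer the donor, a donor motif inside the intron,
## AG or ATG inside the UTR, an out-of-frame ATG in the first codons) are
## removed so that the planted coordinates are the unique rule-conformant
## ones; the random spacers between cassettes are left untouched, so chance
## coincidences there remain possible.

.DECOY_TYPES <- c("orf_no_acceptor", "acceptor_no_orf", "bad_utr_distance",
                  "short_orf", "low_pyrimidine")

## class-specific residue distributions over AA20
.class_distribution <- function(class) {
  p <- setNames(rep(1, length(AA20)), AA20)
  bump <- function(p, res, mass) {
    p[res] <- 0
    p <- p / sum(p) * (1 - sum(mass))
    p[res] <- mass
    p
  }
  p <- p / sum(p)
  switch(class,
         GS_rich = bump(p, c("G", "S"), c(0.35, 0.35)),
         C_rich = bump(p, "C", 0.35),
         P_rich = bump(p, "P", 0.25),
         Q_rich = bump(p, "Q", 0.30),
         stop("unknown composition class: ", class))
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

#' Generate a synthetic SEDC-like protein
#'
#' Residues are sampled from a class-specific distribution (e.g. GS_rich:
#' G 0.35, S 0.35, remainder uniform over the other residues); the first
#' residue is forced to M. Requested conserved motifs overwrite the termini,
#' with wildcard positions filled from the class distribution.
#'
#' @param length protein length in residues.
#' @param class one of `"GS_rich"`, `"C_rich"`, `"P_rich"`, `"Q_rich"`.
#' @param include_n_motif,include_c_motif plant the conserved N-/C-terminal
#'   motifs.
#' @param rng a seeded generator from `.sedc_rng()` (internal) — or an
#'   integer seed.
#' @return the protein as a character string.
#' @export
generate_protein <- function(length, class = "GS_rich",
                             include_n_motif = TRUE,
                             include_c_motif = TRUE,
                             rng = 1L) {
  if (!inherits(rng, "sedc_rng")) rng <- .sedc_rng(rng)
  motifs <- sedc_motifs()
  need <- 1L +
    (if (include_n_motif) nchar(motifs$n_terminal$consensus) else 0L) +
    (if (include_c_motif) nchar(motifs$c_terminal$consensus) else 0L)
  if (length < need) {
    stop("protein length ", length, " too short for the requested motifs (",
         need, " residues needed)")
  }
  dist <- .class_distribution(class)
  chars <- .rng_sample(rng, AA20, size = length, replace = TRUE, prob = dist)
  chars[1L] <- "M"
  fill_motif <- function(chars, consensus, at) {
    cons <- strsplit(consensus, "")[[1L]]
    for (k in seq_along(cons)) {
      chars[at + k - 1L] <- if (cons[k] == "x") {
        .rng_sample(rng, AA20, size = 1L, prob = dist)
      } else cons[k]
    }
    chars
  }
  if (include_n_motif) {
    chars <- fill_motif(chars, motifs$n_terminal$consensus, 1L)
  }
  if (include_c_motif) {
    cc <- motifs$c_terminal$consensus
    chars <- fill_motif(chars, cc, length - nchar(cc) + 1L)
  }
  paste(chars, collapse = "")
}

## reverse-translate sampling uniformly among synonymous codons;
## no stop codon can arise by construction
.protein_to_cds <- function(protein, rng, codons = .codon_table()) {
  chars <- strsplit(protein, "")[[1L]]
  vapply(chars, function(a) {
    opts <- codons[[a]]
    if (length(opts) == 1L) opts else .rng_sample(rng, opts, size = 1L)
  }, character(1), USE.NAMES = FALSE)
}

## reverse-translate so that the CDS contains no ATG after position 0: the
## body must be Met-free, codon choice avoids junction ATGs via a one-codon
## lookahead (next residue C/W forces TG at its codon start, so the current
## codon must not end in A; next residue G/D/E/V/A can force a G start, so
## the current codon must not end in AT). Every residue has a codon ending
## in C or G, so the constraints are always satisfiable.
.cds_no_internal_atg <- function(protein, rng, codons = .codon_table()) {
  chars <- strsplit(protein, "")[[1L]]
  if (any(chars[-1L] == "M")) stop("protein body must be Met-free")
  n <- length(chars)
  out <- character(n)
  for (i in seq_len(n)) {
    opts <- codons[[chars[i]]]
    if (i > 1L) opts <- setdiff(opts, "ATG")
    if (i < n) {
      nxt <- chars[i + 1L]
      if (nxt %in% c("C", "W")) {
        opts <- opts[substr(opts, 3L, 3L) != "A"]
      }
      if (nxt %in% c("G", "D", "E", "V", "A")) {
        opts <- opts[substr(opts, 2L, 3L) != "AT"]
      }
    }
    out[i] <- if (length(opts) == 1L) opts else
      .rng_sample(rng, opts, size = 1L)
  }
  stopifnot(!grepl("ATG", substr(paste(out, collapse = ""), 2L, 3L * n)))
  out
}

## 12 nt G-free block with stop codons in all three reading frames
## ("TTAATTAATTAA": TAA at offsets 1, 5, 9); terminates any read-through ORF
## entering a cassette from upstream without creating AG or ATG
.STOP_BLOCK <- "TTAATTAATTAA"

.rand_dna <- function(rng, n, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0L) return(character(0))
  .rng_sample(rng, alphabet, size = n, replace = TRUE)
}

## destroy every regex match starting strictly inside (from, to] of a char
## vector by setting the match's last base to `base`
.scrub_matches <- function(chars, regex, from, to, base = "C") {
  repeat {
    s <- paste(chars, collapse = "")
    pos <- .match_positions(s, regex)
    pos <- pos[pos > from & pos < to]
    if (length(pos) == 0L) return(chars)
    # length of the match: all patterns used here are fixed-width
    width <- nchar(gsub("\\[[^]]*\\]", "N", regex))
    chars[pos[1L] + width] <- base
  }
}

## generate a CDS for `protein` whose codons 2-3 contain no out-of-frame ATG
## (such an ATG at CDS offset 4 or 5 could seed a spurious overlapping ORF
## reachable from the acceptor distance window)
.cds_without_early_offframe_atg <- function(protein, rng,
                                            codons = .codon_table()) {
  for (try in 1:50) {
    cds <- .protein_to_cds(protein, rng, codons)
    head9 <- paste(cds[1:3], collapse = "")
    bad <- any(vapply(c(5L, 6L), function(i) substr(head9, i, i + 2L) == "ATG",
                      logical(1)))
    if (!bad) return(cds)
    # resample only codons 2-3 by rebuilding; cheap because proteins are short
  }
  stop("could not avoid an early out-of-frame ATG for protein starting ",
       substr(protein, 1, 3))
}

## Build one gene cassette in transcription orientation.
## Returns the cassette as a char vector plus 0-based cassette-relative
## coordinates of every signal.
.build_gene_cassette <- function(spec, rng, cfg) {
  tata <- c("T", "A", "T", "A",
            .rng_sample(rng, c("A", "T"), 1L), "A",
            .rng_sample(rng, c("A", "T"), 1L))
  tata_len <- length(tata)
  d <- spec$tata_donor_distance
  e <- spec$exon1_length
  gap <- d - e + 1L
  stopifnot(gap >= 0L)
  exon1 <- .rand_dna(rng, e)
  exon1[e] <- "G"                     # exon-terminal G of the donor
  intron_fill <- .rand_dna(rng, spec$intron_length - 19L)
  ppt <- .rng_sample(rng, c("C", "T"), size = cfg$polypyrimidine_window,
                     replace = TRUE)
  # G-free UTR (no internal AG or ATG) opening with the all-frame stop block
  # so no upstream ORF can read through into the CDS
  utr <- c(strsplit(.STOP_BLOCK, "")[[1L]],
           .rand_dna(rng, spec$utr_length - nchar(.STOP_BLOCK),
                     alphabet = c("A", "C", "T")))
  cds <- .cds_without_early_offframe_atg(spec$protein, rng)
  stop_codon <- strsplit(.rng_sample(rng, c("TAA", "TAG", "TGA"), 1L), "")[[1L]]

  chars <- c(tata, .rand_dna(rng, gap), exon1,
             strsplit("GTAAG", "")[[1L]], intron_fill, ppt, c("A", "G"),
             utr, strsplit(paste(cds, collapse = ""), "")[[1L]], stop_codon)

  tata_start <- 0L
  tata_end <- tata_len
  donor_pos <- tata_end + gap + e - 1L
  exon1_start <- tata_end + gap
  intron_start <- donor_pos + 1L
  intron_end <- intron_start + spec$intron_length
  acceptor_start <- intron_end - 2L
  ag_end <- intron_end
  orf_start <- ag_end + spec$utr_length
  orf_end <- orf_start + 3L * nchar(spec$protein) + 3L

  # remove accidental TATA matches nearer the donor than the planted one,
  # and accidental donor motifs inside the intron
  chars <- .scrub_matches(chars, .iupac_regex(cfg$tata_pattern),
                          from = tata_start, to = donor_pos - 6L, base = "C")
  chars <- .scrub_matches(chars, .iupac_regex(cfg$donor_motif),
                          from = donor_pos, to = acceptor_start - 5L,
                          base = "C")
  list(chars = chars,
       coords = list(tata_start = tata_start, tata_end = tata_end,
                     donor_pos = donor_pos,
                     exon1_start = exon1_start, exon1_end = donor_pos + 1L,
                     intron_start = intron_start, intron_end = intron_end,
                     acceptor_start = acceptor_start, acceptor_end = ag_end,
                     exon2_start = ag_end, exon2_end = orf_end,
                     orf_start = orf_start, orf_end = orf_end,
                     utr_length = spec$utr_length,
                     tata_donor_distance = d))
}

## Decoy cassettes: each violates exactly one prediction rule. A 30 nt G-free
## pad (ending in the all-frame stop block) shields the upstream side so no
## accidental acceptor context forms at the 20-25 nt distance and no ORF
## reads through from the spacer; G-free UTR stand-ins exclude internal
## AG/ATG; the decoy CDS itself carries no ATG after its start codon, so no
## internal or suffix ORF of the decoy can be picked up.
.build_decoy_cassette <- function(type, rng, cfg) {
  codons <- .codon_table()
  protein <- generate_protein(.rng_int(rng, 70L, 120L),
                              class = .rng_sample(rng, c("GS_rich", "C_rich",
                                                         "P_rich", "Q_rich"), 1L),
                              rng = rng)
  # Met-free body so the CDS can be built without internal ATGs
  protein <- paste0("M", gsub("M", "L", substr(protein, 2L, nchar(protein))))
  cds <- paste(.cds_no_internal_atg(protein, rng, codons), collapse = "")
  stopc <- .rng_sample(rng, c("TAA", "TAG", "TGA"), 1L)
  pad <- paste0(
    paste(.rand_dna(rng, 30L - nchar(.STOP_BLOCK),
                    alphabet = c("A", "C", "T")), collapse = ""),
    .STOP_BLOCK)
  ppt <- paste(.rng_sample(rng, c("C", "T"), size = cfg$polypyrimidine_window,
                           replace = TRUE), collapse = "")
  utr_n <- .rng_int(rng, cfg$acceptor_distance_range[1],
                    cfg$acceptor_distance_range[2])
  utr <- paste(.rand_dna(rng, utr_n, alphabet = c("A", "C", "T")),
               collapse = "")
  seq <- switch(
    type,
    orf_no_acceptor = paste0(pad, cds, stopc),
    acceptor_no_orf = paste0(pad, ppt, "AG",
                             paste(.rand_dna(rng, 28L,
                                             alphabet = c("A", "C", "T")),
                                   collapse = "")),
    bad_utr_distance = paste0(pad, ppt, "AG",
                              paste(.rand_dna(rng, 30L,
                                              alphabet = c("A", "C", "T")),
                                    collapse = ""),
                              cds, stopc),
    short_orf = paste0(pad, ppt, "AG", utr,
                       paste(.cds_no_internal_atg(substr(protein, 1L, 30L),
                                                  rng, codons), collapse = ""),
                       stopc),
    low_pyrimidine = paste0(pad, strrep("A", cfg$polypyrimidine_window),
                            "AG", utr, cds, stopc),
    stop("unknown decoy type: ", type)
  )
  list(seq = seq, type = type)
}

#' Generate a synthetic EDC locus with ground truth
#'
#' Plants `n_genes` rule-conformant two-exon genes and `n_decoys`
#' single-rule-violating decoys, in shuffled order on random strands,
#' separated by spacers of uniform-random DNA. Two anchor spans flank the
#' locus (stand-ins for the S100A9/S100A11 boundary genes). All sampling is
#' driven by one seeded generator, so a seed reproduces the locus
#' byte-for-byte.
#'
#' @param n_genes number of embedded genes.
#' @param n_decoys number of decoys, split round-robin over the decoy types
#'   (`orf_no_acceptor`, `acceptor_no_orf`, `bad_utr_distance`, `short_orf`,
#'   `low_pyrimidine`).
#' @param seed integer seed.
#' @param cfg a [pipeline_config()]; the planted architecture follows its
#'   distance rules.
#' @param contig scaffold identifier.
#' @param spacer_length spacer between cassettes, nt (>= 500 recommended).
#' @param class_persistence probability that a gene inherits the composition
#'   class of the previous gene along the locus, emulating the blocks of
#'   compositionally similar neighbors left by local gene duplication
#'   (0 = independent classes).
#' @return an object of class `synthetic_locus`: list with `sequence`
#'   (character scaffold), `contig`, `truth` (gene-model data frame plus
#'   `composition_class` and `tata_donor_distance` columns), `decoys`
#'   (data frame `type`, `start`, `end`, `strand`), `anchors` (two-row
#'   anchor data frame) and `seed`.
#' @export
generate_locus <- function(n_genes = 50L, n_decoys = 200L, seed = 11L,
                           cfg = pipeline_config(), contig = "synthetic_edc",
                           spacer_length = 500L, class_persistence = 0.75) {
  stopifnot(n_genes >= 0L, n_decoys >= 0L, spacer_length >= 100L,
            class_persistence >= 0, class_persistence <= 1)
  rng <- .sedc_rng(seed)
  classes <- c("GS_rich", "C_rich", "P_rich", "Q_rich")
  # composition classes form blocks along the locus (duplication footprint)
  gene_classes <- character(n_genes)
  for (i in seq_len(n_genes)) {
    gene_classes[i] <- if (i > 1L &&
                           .rng_eval(rng, function() runif(1)) < class_persistence) {
      gene_classes[i - 1L]
    } else {
      .rng_sample(rng, classes, 1L)
    }
  }

  items <- c(rep("gene", n_genes),
             rep(.DECOY_TYPES, length.out = n_decoys))
  if (length(items) > 1L) items <- .rng_sample(rng, items)

  pieces <- character(0)
  offset <- 0L
  push <- function(piece) {
    pieces[[length(pieces) + 1L]] <<- piece
    offset <<- offset + nchar(piece)
  }
  push(paste(.rand_dna(rng, spacer_length), collapse = ""))

  truth_rows <- list()
  decoy_rows <- list()
  gi <- 0L
  for (it in items) {
    if (it == "gene") {
      gi <- gi + 1L
      spec <- list(
        composition_class = gene_classes[gi],
        protein_length = .rng_int(rng, 70L, 170L),
        include_n_motif = TRUE, include_c_motif = TRUE,
        utr_length = .rng_int(rng, cfg$acceptor_distance_range[1],
                              cfg$acceptor_distance_range[2]),
        tata_donor_distance = .rng_int(rng, cfg$tata_distance_range[1],
                                       cfg$tata_distance_range[2]),
        intron_length = .rng_int(rng, 100L, 300L),
        exon1_length = .rng_int(rng, 25L, 45L)
      )
      spec$protein <- generate_protein(spec$protein_length,
                                       spec$composition_class,
                                       spec$include_n_motif,
                                       spec$include_c_motif, rng)
      cas <- .build_gene_cassette(spec, rng, cfg)
      strand <- .rng_sample(rng, c("+", "-"), 1L)
      cass_seq <- paste(cas$chars, collapse = "")
      C <- nchar(cass_seq)
      co <- cas$coords
      iv <- function(s, e) {
        if (strand == "+") c(s, e) else c(C - e, C - s)
      }
      pt <- function(p) if (strand == "+") p else C - 1L - p
      if (strand == "-") cass_seq <- .revcomp_chr(cass_seq)
      tata <- iv(co$tata_start, co$tata_end)
      exon1 <- iv(co$exon1_start, co$exon1_end)
      exon2 <- iv(co$exon2_start, co$exon2_end)
      intron <- iv(co$intron_start, co$intron_end)
      acc <- iv(co$acceptor_start, co$acceptor_end)
      orf <- iv(co$orf_start, co$orf_end)
      row <- gene_model_row(
        id = sprintf("%s.true%d", contig, gi),
        contig = contig, strand = strand, status = "two_exon",
        tata_start = offset + tata[1], tata_end = offset + tata[2],
        donor_pos = offset + pt(co$donor_pos),
        exon1_start = offset + exon1[1], exon1_end = offset + exon1[2],
        exon2_start = offset + exon2[1], exon2_end = offset + exon2[2],
        intron_start = offset + intron[1], intron_end = offset + intron[2],
        acceptor_start = offset + acc[1], acceptor_end = offset + acc[2],
        pyr_fraction = 1.0, utr_length = co$utr_length,
        orf_start = offset + orf[1], orf_end = offset + orf[2],
        protein = spec$protein
      )
      row$composition_class <- spec$composition_class
      row$tata_donor_distance <- co$tata_donor_distance
      truth_rows[[length(truth_rows) + 1L]] <- row
      push(cass_seq)
    } else {
      dec <- .build_decoy_cassette(it, rng, cfg)
      strand <- .rng_sample(rng, c("+", "-"), 1L)
      seq <- if (strand == "+") dec$seq else .revcomp_chr(dec$seq)
      decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
        type = it, start = offset, end = offset + nchar(seq),
        strand = strand, stringsAsFactors = FALSE)
      push(seq)
    }
    push(paste(.rand_dna(rng, spacer_length), collapse = ""))
  }
  scaffold <- paste(pieces, collapse = "")
  L <- nchar(scaffold)
  truth <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows) else {
    tr <- empty_gene_models()
    tr$composition_class <- character(0)
    tr$tata_donor_distance <- integer(0)
    tr
  }
  rownames(truth) <- NULL
  decoys <- if (length(decoy_rows) > 0L) do.call(rbind, decoy_rows) else
    data.frame(type = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  anchors <- data.frame(
    name = c("S100A9", "S100A11"),
    contig = contig,
    start = c(0L, L - 100L),
    end = c(100L, L),
    stringsAsFactors = FALSE
  )
  structure(list(sequence = scaffold, contig = contig, truth = truth,
                 decoys = decoys, anchors = anchors, seed = as.integer(seed)),
            class = "synthetic_locus")
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf(
    "synthetic EDC locus '%s': %d nt, %d genes, %d decoys (seed %d)\n",
    x$contig, nchar(x$sequence), nrow(x$truth), nrow(x$decoys), x$seed))
  invisible(x)
}

#' Write a synthetic locus to disk
#'
#' Emits the scaffold FASTA, the ground-truth GFF3, the true protein FASTA
#' and a decoy TSV into `dir`.
#'
#' @param locus a [generate_locus()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_synthetic_locus <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(setNames(locus$sequence, locus$contig),
              file.path(dir, "scaffold.fa"))
  write_gff3(locus$truth, file.path(dir, "truth.gff3"))
  if (nrow(locus$truth) > 0L) {
    write_fasta(setNames(locus$truth$protein, locus$truth$id),
                file.path(dir, "true_proteins.fa"))
  }
  write.table(locus$decoys, file.path(dir, "decoys.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score predictions against ground truth
#'
#' A prediction matches a truth gene iff contig, strand and CDS coordinates
#' are identical. Reports gene-level sensitivity and precision plus, over
#' the matched genes, the exact-recovery rates of the acceptor, donor and
#' TATA positions.
#'
#' @param predicted,truth gene-model data frames, or paths to GFF3 files
#'   written by [write_gff3()].
#' @return a list: `n_truth`, `n_predicted`, `n_matched`, `sensitivity`,
#'   `precision`, `acceptor_exact`, `donor_exact`, `tata_exact` (rates over
#'   matched genes; `NaN` when nothing matched).
#' @export
recovery_report <- function(predicted, truth) {
  as_models <- function(x) {
    if (is.character(x) && length(x) == 1L) read_gff3_models(x) else x
  }
  pred <- as_models(predicted)
  tru <- as_models(truth)
  key <- function(df) {
    sprintf("%s:%s:%d-%d", df$contig, df$strand, df$orf_start, df$orf_end)
  }
  pk <- key(pred)
  tk <- key(tru)
  m <- match(tk, pk)
  matched <- which(!is.na(m))
  exact_rate <- function(cols) {
    if (length(matched) == 0L) return(NaN)
    ok <- vapply(matched, function(i) {
      j <- m[i]
      all(vapply(cols, function(cl) {
        isTRUE(tru[[cl]][i] == pred[[cl]][j])
      }, logical(1)))
    }, logical(1))
    mean(ok)
  }
  list(
    n_truth = nrow(tru),
    n_predicted = nrow(pred),
    n_matched = length(matched),
    sensitivity = if (nrow(tru) > 0L) length(matched) / nrow(tru) else NaN,
    precision = if (nrow(pred) > 0L) length(matched) / nrow(pred) else NaN,
    acceptor_exact = exact_rate(c("acceptor_start", "acceptor_end")),
    donor_exact = exact_rate("donor_pos"),
    tata_exact = exact_rate(c("tata_start", "tata_end"))
  )
}
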