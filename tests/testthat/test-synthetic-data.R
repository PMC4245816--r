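cfg <- pipeline_config()

test_that("generated proteins carry the requested class bias and motifs", {
  # GS_rich draws G and S at 0.35 each: P(gs_fraction < 0.5) is below 1%
  # at length 500 (binomial tail), so a handful of seeded draws all pass
  for (seed in 1:5) {
    p <- generate_protein(500, "GS_rich", include_n_motif = FALSE,
                          include_c_motif = FALSE, rng = seed)
    expect_gte(composition_profile(p)$gs_fraction, 0.5)
  }
  p <- generate_protein(120, "C_rich", rng = 2)
  hits <- scan_motif(p, sedc_motifs()$n_terminal)
  expect_equal(hits$start, 0L)
  expect_equal(hits$mismatches, 0L)
  hits <- scan_motif(p, sedc_motifs()$c_terminal)
  expect_equal(nrow(hits), 1L)

  expect_identical(generate_protein(100, "Q_rich", rng = 9),
                   generate_protein(100, "Q_rich", rng = 9))
  expect_error(generate_protein(20, "Q_rich", rng = 1), "too short")
})

test_that("locus generation is deterministic under a fixed seed", {
  a <- generate_locus(n_genes = 4, n_decoys = 10, seed = 99)
  b <- generate_locus(n_genes = 4, n_decoys = 10, seed = 99)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$truth, b$truth)
  expect_identical(a$decoys, b$decoys)
  c_ <- generate_locus(n_genes = 4, n_decoys = 10, seed = 100)
  expect_false(identical(a$sequence, c_$sequence))
})

test_that("truth coordinates re-extract their signals from the scaffold", {
  loc <- generate_locus(n_genes = 10, n_decoys = 0, seed = 71)
  s <- loc$sequence
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # transcription-frame extraction of a forward interval
  ext <- function(start, end, strand) {
    if (strand == "+") substr(s, start + 1, end)
    else substr(rc, L - end + 1, L - start)
  }
  for (i in seq_len(nrow(loc$truth))) {
    tr <- loc$truth[i, ]
    expect_match(ext(tr$tata_start, tr$tata_end, tr$strand), "^TATA[AT]A[AT]$")
    # donor_pos is the forward coordinate of the exon-terminal G; the motif
    # occupies [donor_pos, donor_pos+6) on + and [donor_pos-5, donor_pos+1) on -
    donor_iv <- if (tr$strand == "+") c(tr$donor_pos, tr$donor_pos + 6L) else
      c(tr$donor_pos - 5L, tr$donor_pos + 1L)
    expect_equal(ext(donor_iv[1], donor_iv[2], tr$strand), "GGTAAG")
    expect_equal(ext(tr$acceptor_start, tr$acceptor_end, tr$strand), "AG")
    # polypyrimidine window immediately 5' of the AG
    win <- if (tr$strand == "+") {
      substr(s, tr$acceptor_start - 11, tr$acceptor_start)
    } else {
      substr(rc, (L - tr$acceptor_end) - 11, L - tr$acceptor_end)
    }
    expect_match(win, "^[CT]{12}$")
    orf <- ext(tr$orf_start, tr$orf_end, tr$strand)
    expect_equal(substr(orf, 1, 3), "ATG")
    expect_equal(translate_cds(substr(orf, 1, nchar(orf) - 3)), tr$protein)
    # UTR length and TATA-donor distance match the recorded architecture
    expect_true(tr$utr_length >= 20 && tr$utr_length <= 25)
    expect_true(tr$tata_donor_distance >= 60 && tr$tata_donor_distance <= 90)
  }
})

test_that("each decoy class is rejected by the rule it violates", {
  small <- pipeline_config()
  for (type in sedcscan:::.DECOY_TYPES) {
    rng <- sedcscan:::.sedc_rng(123)
    dec <- sedcscan:::.build_decoy_cassette(type, rng, small)
    # pad with flanking random sequence as in a real scaffold
    set.seed(5)
    s <- paste0(random_dna(300), dec$seq, random_dna(300))
    models <- predict_sedc_genes(s, small, filter = FALSE)
    # no predicted CDS may coincide with the decoy's planted reading frame
    planted_start <- 300 + regexpr("ATG", dec$seq, fixed = TRUE) - 1
    if (type %in% c("orf_no_acceptor", "bad_utr_distance", "short_orf",
                    "low_pyrimidine")) {
      expect_false(any(models$orf_start == planted_start),
                   label = paste("decoy type", type))
    } else {
      # acceptor_no_orf: the acceptor exists but yields no candidate
      acc <- scan_splice_acceptors(s, small, strands = "+")
      expect_gte(nrow(acc), 1L)
      expect_equal(nrow(scan_coding_exons(s, acc, small)), 0L)
    }
  }
})

test_that("a decoy-only locus yields no accepted gene models", {
  loc <- generate_locus(n_genes = 0, n_decoys = 20, seed = 72)
  models <- predict_sedc_genes(loc$sequence, cfg, contig = loc$contig)
  expect_equal(nrow(models), 0L)
})

test_that("recovery reports score matches and signal exactness", {
  loc <- generate_locus(n_genes = 10, n_decoys = 0, seed = 73)
  rep0 <- recovery_report(loc$truth, loc$truth)
  expect_equal(rep0$sensitivity, 1.0)
  expect_equal(rep0$precision, 1.0)
  expect_equal(rep0$acceptor_exact, 1.0)

  half <- loc$truth[1:5, ]
  rep1 <- recovery_report(half, loc$truth)
  expect_equal(rep1$sensitivity, 0.5)
  expect_equal(rep1$precision, 1.0)

  shifted <- loc$truth
  shifted$tata_start <- shifted$tata_start + 1L
  rep2 <- recovery_report(shifted, loc$truth)
  expect_equal(rep2$sensitivity, 1.0)
  expect_equal(rep2$tata_exact, 0.0)
  expect_equal(rep2$donor_exact, 1.0)
})

test_that("written locus files are consistent with the in-memory object", {
  loc <- generate_locus(n_genes = 3, n_decoys = 2, seed = 74)
  dir <- withr::local_tempdir()
  write_synthetic_locus(loc, dir)
  fa <- read_genome_fasta(file.path(dir, "scaffold.fa"))
  expect_equal(as.character(fa[[1]]), loc$sequence)
  back <- read_gff3_models(file.path(dir, "truth.gff3"))
  expect_equal(back$orf_start, sort(loc$truth$orf_start))
  prots <- read_protein_fasta(file.path(dir, "true_proteins.fa"))
  expect_setequal(as.character(prots), loc$truth$protein)
})

test_that("end-to-end recovery on a mid-sized locus is exact", {
  loc <- generate_locus(n_genes = 12, n_decoys = 30, seed = 75)
  models <- predict_sedc_genes(loc$sequence, cfg, contig = loc$contig)
  rep <- recovery_report(models, loc$truth)
  expect_equal(rep$sensitivity, 1.0)
  expect_gte(rep$precision, 0.9)
  expect_equal(rep$acceptor_exact, 1.0)
  expect_equal(rep$donor_exact, 1.0)
  expect_equal(rep$tata_exact, 1.0)
})
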