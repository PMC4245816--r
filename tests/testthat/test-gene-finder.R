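# The scanners are checked against literal constructions and against
# exhaustive brute-force oracles on random sequence (helper-oracles.R).

cfg <- pipeline_config()

test_that("splice acceptor scan applies the pyrimidine-window rule", {
  # all-pyrimidine window -> accepted with fraction 1; padding avoids other AGs
  s <- paste0("CCCCCCCCCC", "TTTTTTTTTTTT", "AG", "CCCCCCCCCC")
  acc <- scan_splice_acceptors(s, cfg, strands = "+")
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$ag_start, 22L)
  expect_equal(acc$pyr_fraction, 1.0)

  # purine window -> rejected at the default 0.7 threshold
  s2 <- paste0("CCCCCCCCCC", "GGGGGGGGGGGG", "AG", "CCCCCCCCCC")
  expect_equal(nrow(scan_splice_acceptors(s2, cfg, strands = "+")), 0L)

  # window containing N fails even when otherwise pyrimidine-rich
  s3 <- paste0("CCCCCCCCCC", "TTTTTNTTTTTT", "AG", "CCCCCCCCCC")
  expect_equal(nrow(scan_splice_acceptors(s3, cfg, strands = "+")), 0L)

  expect_error(scan_splice_acceptors("ACGT", cfg), "shorter")
})

test_that("acceptor scan equals brute-force enumeration on random contigs", {
  set.seed(101)
  for (rep in 1:8) {
    s <- random_dna(10000)
    got <- scan_splice_acceptors(s, cfg)
    want <- oracle_acceptors(s, cfg$polypyrimidine_window,
                             cfg$polypyrimidine_min_fraction)
    expect_equal(got$ag_start, want$ag_start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$pyr_fraction, want$pyr_fraction, tolerance = 1e-12)
  }
})

test_that("relaxing the pyrimidine threshold never removes an acceptor", {
  set.seed(102)
  s <- random_dna(5000)
  strict <- scan_splice_acceptors(s, pipeline_config(polypyrimidine_min_fraction = 0.8))
  relaxed <- scan_splice_acceptors(s, pipeline_config(polypyrimidine_min_fraction = 0.6))
  key <- function(df) paste(df$strand, df$ag_start)
  expect_true(all(key(strict) %in% key(relaxed)))
})

test_that("coding-exon candidates respect the 20-25 nt UTR window", {
  # acceptor, then a 22 nt UTR, then a 60-codon ORF
  orf <- paste0("ATG", strrep("AAA", 59), "TGA")
  utr22 <- strrep("C", 22)
  s <- paste0("CCCC", strrep("T", 12), "AG", utr22, orf, "CCCC")
  small <- pipeline_config(min_orf_codons = 3)
  acc <- scan_splice_acceptors(s, small, strands = "+")
  cand <- scan_coding_exons(s, acc, small)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$utr_length, 22L)
  expect_equal(substr(cand$protein, 1, 2), "MK")

  # the same ORF at 30 nt from the AG is out of range
  s30 <- paste0("CCCC", strrep("T", 12), "AG", strrep("C", 30), orf, "CCCC")
  acc30 <- scan_splice_acceptors(s30, small, strands = "+")
  expect_equal(nrow(scan_coding_exons(s30, acc30, small)), 0L)
})

test_that("coding-exon scan equals the brute-force six-frame oracle", {
  set.seed(103)
  tiny <- pipeline_config(min_orf_codons = 20, max_orf_codons = 2000)
  for (rep in 1:4) {
    s <- random_dna(20000)
    acc <- scan_splice_acceptors(s, tiny)
    got <- scan_coding_exons(s, acc, tiny)
    want <- oracle_coding_exons(s, tiny)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$orf_start, want$orf_start)
    expect_equal(got$orf_end, want$orf_end)
    expect_equal(got$utr_length, want$utr_length)
    expect_equal(got$strand, want$strand)
  }
})

test_that("exon-1 search finds the TATA/donor pair at the stated distances", {
  # TATAWAW, spacer so the last TATA base sits 75 nt from the donor G,
  # exon1 body, GGTAAG, intron, acceptor, UTR, ORF
  orf <- paste0("ATG", strrep("GCT", 70), "TAA")
  build <- function(gap) {
    # distance from last TATA base to donor G = gap + exon1_len - 1 = gap + 29
    paste0(strrep("C", 20), "TATAAAA", strrep("C", gap),
           strrep("A", 29), "G",  # exon1 body, exon-terminal G
           "GTAAG", strrep("C", 50),  # intron (C fill, no stray signals)
           strrep("T", 12), "AG", strrep("C", 22), orf, strrep("C", 10))
  }
  s <- build(46)  # distance 75
  cand <- scan_coding_exons(s, scan_splice_acceptors(s, cfg, strands = "+"), cfg)
  expect_equal(nrow(cand), 1L)
  e1 <- find_exon1(s, cand[1, ], cfg)
  expect_false(is.null(e1))
  expect_equal(e1$tata_donor_distance, 75L)
  # donor G is immediately before GTAAG
  expect_equal(substr(s, e1$donor_pos + 1, e1$donor_pos + 6), "GGTAAG")

  # TATA too close to the donor (distance 40) -> no exon 1
  s40 <- build(11)
  cand40 <- scan_coding_exons(s40, scan_splice_acceptors(s40, cfg, strands = "+"), cfg)
  expect_null(find_exon1(s40, cand40[1, ], cfg))

  # a donor motif with one mismatch (GGTGAG) is not accepted
  sbad <- gsub("GGTAAG", "GGTGAG", s)
  candb <- scan_coding_exons(sbad, scan_splice_acceptors(sbad, cfg, strands = "+"), cfg)
  expect_null(find_exon1(sbad, candb[1, ], cfg))
})

test_that("assembled models recover an embedded gene with truth coordinates", {
  loc <- generate_locus(n_genes = 1, n_decoys = 0, seed = 21)
  models <- assemble_gene_models(loc$sequence, cfg, contig = loc$contig)
  two <- models[models$status == "two_exon", ]
  expect_equal(nrow(two), 1L)
  tr <- loc$truth
  expect_equal(two$orf_start, tr$orf_start)
  expect_equal(two$orf_end, tr$orf_end)
  expect_equal(two$acceptor_start, tr$acceptor_start)
  expect_equal(two$donor_pos, tr$donor_pos)
  expect_equal(two$tata_start, tr$tata_start)
  expect_equal(two$protein, tr$protein)
})

test_that("scanning the reverse complement mirrors the model set exactly", {
  loc <- generate_locus(n_genes = 3, n_decoys = 0, seed = 22)
  s <- loc$sequence
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  m1 <- assemble_gene_models(s, cfg)
  m2 <- assemble_gene_models(rc, cfg)
  expect_equal(nrow(m1), nrow(m2))
  m1 <- m1[order(m1$orf_start), ]
  # mirrored: [s,e) -> [L-e, L-s), strand flipped
  m2m <- data.frame(orf_start = L - m2$orf_end, orf_end = L - m2$orf_start,
                    strand = ifelse(m2$strand == "+", "-", "+"),
                    protein = m2$protein)
  m2m <- m2m[order(m2m$orf_start), ]
  expect_equal(m1$orf_start, m2m$orf_start)
  expect_equal(m1$orf_end, m2m$orf_end)
  expect_equal(m1$strand, m2m$strand)
  expect_equal(m1$protein, m2m$protein)
})

test_that("overlap resolution keeps the longest ORF", {
  # an internal in-frame Met creates a nested shorter candidate; after
  # resolution only the long ORF survives
  inner <- paste0("ATG", strrep("GCT", 80), "TAA")
  s <- paste0("CC", strrep("T", 12), "AG", strrep("C", 20),
              "ATG", "AAA", strrep("T", 6), "CCCCCCCCCCTT",
              "AG", strrep("C", 3), inner, "CC")
  small <- pipeline_config(min_orf_codons = 10)
  acc <- scan_splice_acceptors(s, small, strands = "+")
  cand <- scan_coding_exons(s, acc, small)
  models <- assemble_gene_models(s, small)
  if (nrow(models) > 0) {
    lens <- models$orf_end - models$orf_start
    expect_true(all(diff(sort(models$orf_start)) >= 0))
    # no two kept models overlap on the same strand
    for (st in unique(models$strand)) {
      mm <- models[models$strand == st, ]
      mm <- mm[order(mm$orf_start), ]
      if (nrow(mm) > 1) {
        expect_true(all(mm$orf_start[-1] >= mm$orf_end[-nrow(mm)]))
      }
    }
  }
  succeed()
})

test_that("composition/motif filter keeps class-biased or motif-bearing proteins only", {
  loc <- generate_locus(n_genes = 4, n_decoys = 0, seed = 23)
  models <- assemble_gene_models(loc$sequence, cfg, contig = loc$contig)
  kept <- filter_gene_models(models, cfg)
  expect_true(all(loc$truth$orf_start %in% kept$orf_start))
  # a model with an unbiased random protein is dropped
  set.seed(1)
  fake <- models[1, ]
  fake$protein <- random_protein(100)
  expect_equal(nrow(filter_gene_models(fake, cfg)), 0L)
})
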