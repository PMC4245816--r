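make_models <- function(starts, ends, ids = NULL, strand = "+",
                        contig = "chr") {
  n <- length(starts)
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  df <- sedcscan:::empty_gene_models()
  for (i in seq_len(n)) {
    df <- rbind(df, sedcscan:::gene_model_row(
      id = ids[i], contig = contig, strand = strand,
      status = "coding_exon_only",
      tata_start = NA, tata_end = NA, donor_pos = NA,
      exon1_start = NA, exon1_end = NA,
      exon2_start = starts[i], exon2_end = ends[i],
      intron_start = NA, intron_end = NA,
      acceptor_start = starts[i] - 22L, acceptor_end = starts[i] - 20L,
      pyr_fraction = 1, utr_length = 20L,
      orf_start = starts[i], orf_end = ends[i], protein = "M"))
  }
  df
}

anchors <- data.frame(name = c("S100A9", "S100A11"), contig = "chr",
                      start = c(0L, 1000L), end = c(50L, 1050L))

test_that("locus maps order genes by midpoint and flag inside status", {
  m <- make_models(c(480, 80, 880), c(520, 120, 920),
                   ids = c("mid", "left", "right"))
  map <- build_locus_map(m, anchors)
  expect_equal(map$genes$id, c("left", "mid", "right"))
  expect_true(all(map$genes$inside))

  # gene inside an anchor span is not inside the locus
  m2 <- make_models(c(10), c(30))
  map2 <- build_locus_map(m2, anchors)
  expect_false(map2$genes$inside)

  # input order does not matter
  m3 <- m[c(3, 1, 2), ]
  expect_equal(build_locus_map(m3, anchors)$genes, map$genes)
})

test_that("anchor validation rejects overlaps and contig mismatches", {
  bad <- data.frame(name = c("a", "b"), contig = "chr",
                    start = c(0L, 30L), end = c(50L, 80L))
  expect_error(build_locus_map(make_models(100, 200), bad), "overlap")
  bad2 <- data.frame(name = c("a", "b"), contig = c("chr", "chr2"),
                     start = c(0L, 500L), end = c(50L, 550L))
  expect_error(build_locus_map(make_models(100, 200), bad2),
               "different contigs")
})

test_that("blocked composition classes give a small neighbor distance and p-value", {
  # 5 C-rich then 5 GS-rich genes, identical within blocks
  c_rich <- paste0(strrep("C", 40), strrep("A", 60))
  gs_rich <- paste0(strrep("G", 35), strrep("S", 35), strrep("A", 30))
  prots <- setNames(c(rep(c_rich, 5), rep(gs_rich, 5)), paste0("g", 1:10))
  m <- make_models(seq(100, 960, length.out = 10) - 10,
                   seq(100, 960, length.out = 10) + 10,
                   ids = paste0("g", 1:10))
  map <- build_locus_map(m, anchors)
  prof <- profile_proteins(prots)
  res <- neighbor_composition_statistic(map, prof, n_permutations = 999,
                                        seed = 1)
  expect_lt(res$observed, res$perm_mean)
  expect_lte(res$p_value, 0.05)
})

test_that("identical compositions give observed 0 and p-value 1", {
  p <- paste0(strrep("C", 40), strrep("A", 60))
  prots <- setNames(rep(p, 5), paste0("g", 1:5))
  m <- make_models(seq(100, 900, length.out = 5) - 10,
                   seq(100, 900, length.out = 5) + 10,
                   ids = paste0("g", 1:5))
  map <- build_locus_map(m, anchors)
  prof <- profile_proteins(prots)
  res <- neighbor_composition_statistic(map, prof, n_permutations = 199,
                                        seed = 3)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
})

test_that("the neighbor statistic is reproducible and reversal-invariant", {
  set.seed(61)
  prots <- setNames(vapply(1:6, function(i) random_protein(80), ""),
                    paste0("g", 1:6))
  m <- make_models(seq(100, 900, length.out = 6) - 10,
                   seq(100, 900, length.out = 6) + 10,
                   ids = paste0("g", 1:6))
  map <- build_locus_map(m, anchors)
  prof <- profile_proteins(prots)
  r1 <- neighbor_composition_statistic(map, prof, 499, seed = 7)
  r2 <- neighbor_composition_statistic(map, prof, 499, seed = 7)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 500)
  expect_lte(r1$p_value, 1)

  # reversed gene order: same observed statistic (adjacency is symmetric)
  mrev <- make_models(rev(seq(100, 900, length.out = 6) - 10),
                      rev(seq(100, 900, length.out = 6) + 10),
                      ids = paste0("g", 1:6))
  # reversing coordinates reverses locus order
  maprev <- build_locus_map(mrev, anchors)
  r3 <- neighbor_composition_statistic(maprev, prof, 499, seed = 7)
  expect_equal(r3$observed, r1$observed)
})

test_that("fewer than 3 inside genes is an error", {
  p <- paste0(strrep("C", 40), strrep("A", 60))
  m <- make_models(c(100, 200), c(120, 220), ids = c("g1", "g2"))
  map <- build_locus_map(m, anchors)
  prof <- profile_proteins(setNames(rep(p, 2), c("g1", "g2")))
  expect_error(neighbor_composition_statistic(map, prof), "at least 3")
})

test_that("synteny comparison ranks pairs and counts concordance", {
  ma <- build_locus_map(make_models(c(100, 300, 500, 700),
                                    c(120, 320, 520, 720),
                                    ids = paste0("a", 1:4)), anchors)
  mb <- build_locus_map(make_models(c(100, 300, 500, 700),
                                    c(120, 320, 520, 720),
                                    ids = paste0("b", 1:4)), anchors)
  pairs <- data.frame(id_a = paste0("a", 1:4), id_b = paste0("b", 1:4))
  tab <- compare_loci(ma, mb, pairs)
  expect_true(all(tab$concordant))
  expect_equal(tab$concordant_with, rep(3L, 4))

  # swap two genes in locus b: brute-force pair-order count
  pairs2 <- data.frame(id_a = paste0("a", 1:4),
                       id_b = paste0("b", c(2, 1, 3, 4)))
  tab2 <- compare_loci(ma, mb, pairs2)
  ra <- tab2$rank_a; rb <- tab2$rank_b
  want <- vapply(1:4, function(i) {
    sum(vapply(setdiff(1:4, i), function(j) {
      sign(ra[i] - ra[j]) == sign(rb[i] - rb[j])
    }, logical(1)))
  }, integer(1))
  expect_equal(tab2$concordant_with, want)
  expect_equal(sum(!tab2$concordant), 2L)

  expect_equal(nrow(compare_loci(ma, mb, pairs[0, ])), 0L)
  expect_error(compare_loci(ma, mb, data.frame(id_a = "aX", id_b = "b1")),
               "absent")
})
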