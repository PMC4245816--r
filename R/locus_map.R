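## EDC locus view between S100A anchor genes and the neighbor-composition
## permutation statistic.

#' Build an EDC locus map between anchor genes
#'
#' Orders predicted genes along the contig by midpoint coordinate and flags
#' which lie strictly between the two anchor gene spans (in the EDC these
#' are typically S100A9 and S100A11). Midpoint ordering avoids ambiguity for
#' nested models.
#'
#' @param models a gene-model data frame (needs `id`, `contig`, `strand`,
#'   `orf_start`, `orf_end`, and exon columns when present).
#' @param anchors a data frame with columns `name`, `contig`, `start`, `end`
#'   (0-based half-open) and exactly two rows.
#' @return an object of class `edc_locus_map`: list with `contig`, `anchors`
#'   and `genes` (data frame `id`, `strand`, `midpoint`, `inside` sorted by
#'   midpoint).
#' @export
build_locus_map <- function(models, anchors) {
  stopifnot(is.data.frame(anchors), nrow(anchors) == 2L,
            all(c("name", "contig", "start", "end") %in% names(anchors)))
  if (length(unique(anchors$contig)) != 1L) {
    stop("anchors lie on different contigs")
  }
  anchors <- anchors[order(anchors$start), , drop = FALSE]
  if (anchors$end[1] > anchors$start[2]) stop("anchors overlap")
  if (nrow(models) > 0L && any(models$contig != anchors$contig[1])) {
    stop("gene models and anchors lie on different contigs")
  }
  span_s <- ifelse(is.na(models$exon1_start),
                   models$exon2_start,
                   pmin(models$exon1_start, models$exon2_start))
  span_e <- ifelse(is.na(models$exon1_end),
                   models$exon2_end,
                   pmax(models$exon1_end, models$exon2_end))
  mid <- (span_s + span_e) / 2
  genes <- data.frame(id = models$id, strand = models$strand,
                      midpoint = mid,
                      inside = mid > anchors$end[1] & mid < anchors$start[2],
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$midpoint), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(contig = anchors$contig[1], anchors = anchors,
                 genes = genes),
            class = "edc_locus_map")
}

#' @export
print.edc_locus_map <- function(x, ...) {
  cat(sprintf("EDC locus map on %s: %d genes (%d inside anchors %s..%s)\n",
              x$contig, nrow(x$genes), sum(x$genes$inside),
              x$anchors$name[1], x$anchors$name[2]))
  invisible(x)
}

#' Neighbor-composition similarity statistic for an EDC locus
#'
#' SEDC proteins encoded by neighboring genes typically have similar
#' amino-acid compositions — the footprint of local gene duplication. This
#' operationalizes that claim: the observed statistic is the mean Euclidean
#' distance between the 20-dimensional composition-fraction vectors of
#' adjacent genes in locus order (genes inside the anchors only), and the
#' p-value is the add-one permutation probability that a random gene
#' ordering achieves a mean adjacent distance at most as small.
#'
#' @param map an [build_locus_map()] result.
#' @param profiles a profile data frame from [profile_proteins()] whose `id`
#'   column covers the inside genes.
#' @param n_permutations number of random orderings (>= 100).
#' @param seed integer seed for the permutation draw.
#' @return a list with `observed` (mean adjacent distance), `p_value`
#'   (`(1 + #{perm <= observed}) / (n_permutations + 1)`), `n_genes` and
#'   `perm_mean`.
#' @export
neighbor_composition_statistic <- function(map, profiles,
                                           n_permutations = 999L,
                                           seed = 1L) {
  stopifnot(inherits(map, "edc_locus_map"), n_permutations >= 100L)
  ids <- map$genes$id[map$genes$inside]
  if (length(ids) < 3L) stop("need at least 3 genes inside the anchors")
  frac_cols <- paste0("frac_", AA20)
  rows <- match(ids, profiles$id)
  if (anyNA(rows)) {
    stop("profiles missing for: ",
         paste(ids[is.na(rows)], collapse = ","))
  }
  mat <- as.matrix(profiles[rows, frac_cols])
  adj_mean <- function(ord) {
    d <- mat[ord[-length(ord)], , drop = FALSE] -
      mat[ord[-1L], , drop = FALSE]
    mean(sqrt(rowSums(d * d)))
  }
  n <- length(ids)
  observed <- adj_mean(seq_len(n))
  rng <- .sedc_rng(seed)
  perm <- vapply(seq_len(n_permutations), function(i) {
    adj_mean(.rng_sample(rng, n))
  }, numeric(1))
  list(observed = observed,
       p_value = (1 + sum(perm <= observed)) / (n_permutations + 1),
       n_genes = n,
       perm_mean = mean(perm))
}

#' Compare two locus maps through their ortholog pairs
#'
#' Ranks each ortholog pair within its locus (inside-anchor genes in
#' coordinate order) and counts, for every pair, how many other pairs sit in
#' the same relative order in both loci — the pairwise concordance that
#' underlies a synteny call. A pair is flagged `concordant` when it agrees
#' with every other pair.
#'
#' @param map_a,map_b [build_locus_map()] results.
#' @param ortholog_pairs a data frame with columns `id_a`, `id_b` (gene ids
#'   present in `map_a` / `map_b`).
#' @return a data frame: `id_a`, `id_b`, `rank_a`, `rank_b`,
#'   `concordant_with` (count of agreeing pairs), `concordant` (flag).
#' @export
compare_loci <- function(map_a, map_b, ortholog_pairs) {
  stopifnot(inherits(map_a, "edc_locus_map"), inherits(map_b, "edc_locus_map"))
  if (nrow(ortholog_pairs) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      rank_a = integer(0), rank_b = integer(0),
                      concordant_with = integer(0), concordant = logical(0)))
  }
  rank_in <- function(map, ids) {
    ord <- map$genes$id
    r <- match(ids, ord)
    if (anyNA(r)) {
      stop("ortholog pair references gene(s) absent from the locus map: ",
           paste(ids[is.na(r)], collapse = ","))
    }
    r
  }
  ra <- rank_in(map_a, ortholog_pairs$id_a)
  rb <- rank_in(map_b, ortholog_pairs$id_b)
  n <- length(ra)
  conc <- integer(n)
  for (i in seq_len(n)) {
    agree <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      if (sign(ra[i] - ra[j]) == sign(rb[i] - rb[j])) agree <- agree + 1L
    }
    conc[i] <- agree
  }
  data.frame(id_a = ortholog_pairs$id_a, id_b = ortholog_pairs$id_b,
             rank_a = ra, rank_b = rb,
             concordant_with = conc,
             concordant = conc == n - 1L,
             stringsAsFactors = FALSE)
}
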