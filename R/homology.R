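## Similarity-driven candidate expansion and reciprocal-best-hit orthology.
## BLAST-style heuristics are replaced by exact Smith-Waterman local
## alignment (BLOSUM62, affine gaps): SEDC proteins are low-complexity, the
## candidate pools are small, and exact scores make the iteration and the
## reciprocal-best criterion deterministic.

#' Optimal local alignment between two proteins
#'
#' Smith-Waterman local alignment with affine gap penalties via
#' [Biostrings::pairwiseAlignment()]. A gap of length L costs
#' `gap_open + L * gap_extend`. Scores are truncated at 0 (the empty local
#' alignment).
#'
#' @param a,b protein sequences (character).
#' @param matrix substitution matrix name or matrix (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return a one-row data frame: `query`, `subject`, `score`, `identity`
#'   (fraction of identical aligned columns; `NA` for an empty alignment).
#' @export
local_align <- function(a, b, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (is.character(matrix) && length(matrix) == 1L) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sc <- max(0, Biostrings::score(al))
  width <- Biostrings::nchar(al)
  ident <- if (sc > 0 && width > 0) Biostrings::nmatch(al) / width else NA_real_
  data.frame(query = if (!is.null(names(a))) names(a) else "a",
             subject = if (!is.null(names(b))) names(b) else "b",
             score = sc, identity = ident, stringsAsFactors = FALSE)
}

## score matrix for all pairs of two named protein vectors
.score_matrix <- function(set_a, set_b, matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1) {
  if (is.character(matrix) && length(matrix) == 1L) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  out <- matrix(0, nrow = length(set_a), ncol = length(set_b),
                dimnames = list(names(set_a), names(set_b)))
  for (i in seq_along(set_a)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(rep(toupper(set_a[[i]]), length(set_b))),
      Biostrings::AAStringSet(toupper(unname(set_b))),
      type = "local", substitutionMatrix = matrix,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
    out[i, ] <- pmax(0, al)
  }
  out
}

#' Iterative similarity-driven expansion of a seed set
#'
#' Mirrors the iterative screening in which newly identified SEDC proteins
#' are used as queries for the next search round: round k accepts every pool
#' protein scoring at or above `threshold` against any protein accepted in an
#' earlier round. The iteration stops at a fixed point or after
#' `max_iterations` rounds. The result equals the connected-component
#' closure of the seeds in the threshold similarity graph and is independent
#' of within-round processing order.
#'
#' @param seeds,pool named character vectors of protein sequences; names are
#'   the ids. Pool members whose id is in `seeds` are ignored.
#' @param threshold minimum local-alignment score for acceptance (> 0).
#' @param max_iterations round cap.
#' @param matrix,gap_open,gap_extend passed to the aligner.
#' @return a list with `accepted` (ids: seeds plus accepted pool members),
#'   `rounds` (rounds actually used; 0 for an empty seed set) and `edges`
#'   (data frame of accepting query/subject/score triples).
#' @export
iterative_expand <- function(seeds, pool, threshold = 40,
                             max_iterations = 20L, matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1) {
  stopifnot(threshold > 0)
  if (length(seeds) == 0L) {
    return(list(accepted = character(0), rounds = 0L,
                edges = data.frame(query = character(0),
                                   subject = character(0),
                                   score = numeric(0))))
  }
  stopifnot(!is.null(names(seeds)), !is.null(names(pool)) || length(pool) == 0L)
  pool <- pool[setdiff(names(pool), names(seeds))]
  accepted <- names(seeds)
  frontier <- seeds
  remaining <- pool
  edges <- list()
  rounds <- 0L
  while (rounds < max_iterations) {
    if (length(remaining) == 0L) break
    rounds <- rounds + 1L
    sm <- .score_matrix(frontier, remaining, matrix, gap_open, gap_extend)
    hit <- apply(sm >= threshold, 2L, any)
    if (!any(hit)) break
    for (j in which(hit)) {
      i <- which.max(sm[, j])
      edges[[length(edges) + 1L]] <- data.frame(
        query = rownames(sm)[i], subject = colnames(sm)[j],
        score = sm[i, j], stringsAsFactors = FALSE)
    }
    new_ids <- names(remaining)[hit]
    accepted <- c(accepted, new_ids)
    frontier <- remaining[new_ids]
    remaining <- remaining[!hit]
  }
  list(accepted = accepted, rounds = rounds,
       edges = if (length(edges) > 0L) do.call(rbind, edges) else
         data.frame(query = character(0), subject = character(0),
                    score = numeric(0)))
}

#' Reciprocal-best-hit ortholog pairs between two protein sets
#'
#' A pair (a, b) is reported iff b is a's unique highest-scoring partner in
#' set B and a is b's unique highest-scoring partner in set A. Ties produce
#' no pair (conservative), so the result is a partial matching.
#'
#' @param set_a,set_b named character vectors of protein sequences.
#' @param matrix,gap_open,gap_extend passed to the aligner.
#' @return a data frame of pairs: `id_a`, `id_b`, `score`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, matrix = "BLOSUM62",
                                 gap_open = 11, gap_extend = 1) {
  stopifnot(length(set_a) > 0L, length(set_b) > 0L,
            !is.null(names(set_a)), !is.null(names(set_b)))
  sm <- .score_matrix(set_a, set_b, matrix, gap_open, gap_extend)
  pairs <- list()
  for (i in seq_len(nrow(sm))) {
    best <- max(sm[i, ])
    js <- which(sm[i, ] == best)
    if (length(js) != 1L || best <= 0) next
    j <- js
    back <- max(sm[, j])
    is_ <- which(sm[, j] == back)
    if (length(is_) != 1L || is_ != i) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      id_a = rownames(sm)[i], id_b = colnames(sm)[j], score = sm[i, j],
      stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, pairs)
}
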