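## Conserved SEDC sequence motifs (wildcard consensus matching with
## anchoring), sequence-logo frequency matrices, and internal-repeat scoring.

#' Define a consensus motif
#'
#' A consensus is residue text in which a lowercase `x` matches any residue;
#' uppercase positions must match exactly up to the mismatch budget
#' (wildcards never count as mismatches). Anchoring restricts where the
#' motif may sit: `n_terminal` motifs only at position 0, `c_terminal`
#' motifs only flush with the protein end, `internal` motifs anywhere.
#'
#' @param name motif name.
#' @param consensus consensus text, lowercase `x` = wildcard.
#' @param anchor one of `"n_terminal"`, `"c_terminal"`, `"internal"`.
#' @param max_mismatches allowed non-wildcard mismatches.
#' @return an object of class `motif_definition`.
#' @export
motif_definition <- function(name, consensus,
                             anchor = c("internal", "n_terminal", "c_terminal"),
                             max_mismatches = 0L) {
  anchor <- match.arg(anchor)
  if (nzchar(consensus)) {
    n_fixed <- sum(strsplit(consensus, "")[[1L]] != "x")
    if (max_mismatches >= max(n_fixed, 1L)) {
      stop("max_mismatches must be smaller than the number of non-wildcard positions")
    }
  }
  structure(list(name = name, consensus = consensus, anchor = anchor,
                 max_mismatches = as.integer(max_mismatches)),
            class = "motif_definition")
}

#' The shipped SEDC motif catalogue
#'
#' Three conserved motifs of epidermal differentiation proteins: the
#' N-terminal transglutamination/disulfide motif `MSYxxxxQQCKQPCQPPP`, the
#' internal `MCSRxxxxxCH` motif of genes located between S100A9 and the
#' loricrin homologs, and the C-terminal `QQxKQPSQWPxQxxK` motif that ends at
#' the stop codon. A fourth entry, the beta-keratin core box, is a named
#' placeholder with an empty consensus to be supplied from configuration.
#'
#' @param max_mismatches mismatch budget applied to all returned motifs
#'   (default 0; discovery scans typically use 2).
#' @return a named list of [motif_definition()] objects.
#' @export
sedc_motifs <- function(max_mismatches = 0L) {
  list(
    n_terminal = motif_definition("sedc_n_terminal", "MSYxxxxQQCKQPCQPPP",
                                  "n_terminal", max_mismatches),
    internal = motif_definition("sedc_internal_mcsr", "MCSRxxxxxCH",
                                "internal", max_mismatches),
    c_terminal = motif_definition("sedc_c_terminal", "QQxKQPSQWPxQxxK",
                                  "c_terminal", max_mismatches),
    beta_keratin_core_box = motif_definition("beta_keratin_core_box", "",
                                             "internal", 0L)
  )
}

#' Scan a protein for a consensus motif
#'
#' @param protein residue text (matching is case-insensitive on the subject).
#' @param motif a [motif_definition()].
#' @param protein_id identifier carried into the hits.
#' @return a data frame of hits: `protein_id`, `motif`, `start` (0-based
#'   offset), `mismatches`. N-terminal hits have `start == 0`; c-terminal
#'   hits end flush with the protein.
#' @export
scan_motif <- function(protein, motif, protein_id = "protein") {
  stopifnot(inherits(motif, "motif_definition"))
  p <- toupper(as.character(protein))
  empty <- data.frame(protein_id = character(0), motif = character(0),
                      start = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(motif$consensus)) return(empty)
  cons <- strsplit(motif$consensus, "")[[1L]]
  L <- length(cons)
  n <- nchar(p)
  if (n < L) {
    stop("protein shorter than the motif consensus (", L, " residues)")
  }
  fixed <- cons != "x"
  starts <- switch(motif$anchor,
                   n_terminal = 0L,
                   c_terminal = n - L,
                   internal = 0L:(n - L))
  chars <- strsplit(p, "")[[1L]]
  hits <- lapply(starts, function(s0) {
    window <- chars[(s0 + 1L):(s0 + L)]
    mm <- sum(window[fixed] != toupper(cons[fixed]))
    if (mm <= motif$max_mismatches) {
      data.frame(protein_id = protein_id, motif = motif$name,
                 start = s0, mismatches = mm, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, hits)
  if (is.null(res)) empty else res
}

#' Position frequency matrix and information content of an aligned block
#'
#' Column-wise residue frequencies of a gapless-or-gapped alignment block
#' (gap characters `-` are excluded from the column counts), with per-column
#' information content `log2(20) - H(column)` as used for sequence logos.
#'
#' @param aligned_blocks character vector of two or more equal-length
#'   aligned residue texts.
#' @return a list with `freq` (20 x L matrix, columns sum to 1 where any
#'   residue is present) and `information` (length-L numeric, bits).
#' @export
position_frequency_matrix <- function(aligned_blocks) {
  seqs <- toupper(as.character(aligned_blocks))
  stopifnot(length(seqs) >= 2L)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("aligned blocks have unequal lengths")
  L <- lens[1L]
  mat <- do.call(rbind, strsplit(seqs, ""))
  freq <- matrix(0, nrow = length(AA20), ncol = L,
                 dimnames = list(AA20, NULL))
  info <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) next
    counts <- table(factor(col, levels = AA20))
    f <- as.numeric(counts) / length(col)
    freq[, j] <- f
    nz <- f[f > 0]
    info[j] <- log2(length(AA20)) + sum(nz * log2(nz))
  }
  list(freq = freq, information = info)
}

#' Score internal repetitiveness of a protein
#'
#' Self-match period profile: for each candidate period p, positions i with
#' residue(i) == residue(i+p) are marked, and the longest contiguous run of
#' matches with at least p matches (i.e. at least two full copies) defines a
#' repeated block covering run+p residues. The best period maximizes the
#' covered fraction of the protein; ties go to the smallest period. This is
#' an approximation sufficient for flagging repetitive SEDC proteins, not a
#' full tandem-repeat dynamic program.
#'
#' @param protein residue text.
#' @param min_period,max_period candidate period range in residues;
#'   `max_period` defaults to half the protein length.
#' @param protein_id identifier carried into the report.
#' @return a data frame: `protein_id`, `best_period`, `copy_number`,
#'   `repeat_fraction` (fraction of the protein covered by the best block;
#'   0 when no period achieves two full copies).
#' @export
repeat_score <- function(protein, min_period = 2L,
                         max_period = nchar(protein) %/% 2L,
                         protein_id = "protein") {
  p <- toupper(as.character(protein))
  n <- nchar(p)
  if (n < 2L * min_period) stop("protein too short for min_period ", min_period)
  max_period <- min(max_period, n %/% 2L)
  chars <- strsplit(p, "")[[1L]]
  best <- list(period = min_period, frac = 0, copies = 0L)
  for (per in seq(min_period, max_period)) {
    m <- chars[seq_len(n - per)] == chars[seq_len(n - per) + per]
    runs <- rle(m)
    lens <- runs$lengths[runs$values]
    if (length(lens) == 0L) next
    run <- max(lens)
    if (run < per) next  # need at least two full copies
    frac <- (run + per) / n
    if (frac > best$frac + 1e-12) {
      best <- list(period = per, frac = frac,
                   copies = (run + per) %/% per)
    }
  }
  data.frame(protein_id = protein_id,
             best_period = as.integer(best$period),
             copy_number = as.integer(best$copies),
             repeat_fraction = best$frac,
             stringsAsFactors = FALSE)
}
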