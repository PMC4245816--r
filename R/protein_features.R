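## Per-protein analyses: amino-acid composition, compositional and size
## classes, isoelectric point, transglutamination substrate residues.

#' The 20 standard amino acids, alphabetical one-letter codes
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Translate a coding sequence
#'
#' Standard genetic code. The CDS must start with ATG and have triplet
#' length; a trailing stop codon is removed, an internal stop is an error.
#'
#' @param cds DNA text (character or `DNAString`).
#' @return the protein as a character string.
#' @export
#' @examples
#' translate_cds("ATGAAATGA")  # "MK"
translate_cds <- function(cds) {
  s <- toupper(as.character(cds))
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  if (substr(s, 1L, 3L) != "ATG") stop("CDS does not start with ATG")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           no.init.codon = TRUE))
  body <- sub("\\*$", "", aa)
  star <- regexpr("*", body, fixed = TRUE)
  if (star > 0L) stop("internal stop codon at codon ", star)
  body
}

#' Amino-acid composition profile of a protein
#'
#' Exact residue counting over the 20 standard amino acids, plus the derived
#' quantities used throughout the EDC analyses: combined glycine+serine
#' fraction (the loricrin signature), glutamine and lysine counts (the
#' transglutamination cross-linking substrates), isoelectric point and size
#' class.
#'
#' @param protein residue text over the 20 standard amino acids.
#' @param id identifier carried into the profile.
#' @return an object of class `composition_profile`: a list with `id`,
#'   `length`, `counts` (named integer, all 20 residues), `fractions`,
#'   `gs_fraction`, `q_count`, `k_count`, `pi`, `size_class`.
#' @export
composition_profile <- function(protein, id = "protein") {
  p <- toupper(as.character(protein))
  if (nchar(p) == 0L) stop("empty protein")
  chars <- strsplit(p, "")[[1L]]
  bad <- setdiff(unique(chars), AA20)
  if (length(bad) > 0L) {
    stop("illegal residue(s) in '", id, "': ", paste(bad, collapse = ","))
  }
  counts <- table(factor(chars, levels = AA20))
  counts <- setNames(as.integer(counts), AA20)
  n <- length(chars)
  fractions <- counts / n
  structure(list(
    id = id,
    length = n,
    counts = counts,
    fractions = fractions,
    gs_fraction = unname(fractions["G"] + fractions["S"]),
    q_count = unname(counts["Q"]),
    k_count = unname(counts["K"]),
    pi = isoelectric_point(p),
    size_class = size_class(p)
  ), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  top <- sort(x$fractions, decreasing = TRUE)[1:3]
  cat(sprintf(
    "composition_profile '%s': %d aa, pI %.2f, G+S %.2f, Q %d, K %d, %s\n",
    x$id, x$length, x$pi, x$gs_fraction, x$q_count, x$k_count, x$size_class))
  cat("  top residues:",
      paste(sprintf("%s=%.2f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' Compositional class labels of a protein
#'
#' SEDC proteins are enriched for small subsets of residues: glycine+serine
#' (loricrin homologs, around 70% combined), cysteine (EDCRP, 35--40%),
#' proline (EDPE, about 20%) or glutamine (EDQrep/involucrin-like). A profile
#' is `GS_rich` when the combined G+S fraction reaches `gs_min`, and
#' `C_rich`/`P_rich`/`Q_rich` when the single-residue fraction reaches
#' `single_residue_min`. Labels are not mutually exclusive; a profile
#' matching none is `unclassified`.
#'
#' @param profile a [composition_profile()].
#' @param gs_min combined G+S fraction threshold (default 0.5).
#' @param single_residue_min single-residue threshold (default 0.15).
#' @return a character vector of labels.
#' @export
classify_composition <- function(profile, gs_min = 0.5,
                                 single_residue_min = 0.15) {
  stopifnot(inherits(profile, "composition_profile"))
  f <- profile$fractions
  labels <- character(0)
  if (profile$gs_fraction >= gs_min) labels <- c(labels, "GS_rich")
  if (f["C"] >= single_residue_min) labels <- c(labels, "C_rich")
  if (f["P"] >= single_residue_min) labels <- c(labels, "P_rich")
  if (f["Q"] >= single_residue_min) labels <- c(labels, "Q_rich")
  if (length(labels) == 0L) labels <- "unclassified"
  labels
}

## EMBOSS-style pKa values (iep defaults): side chains + termini
.pka_emboss <- list(
  nterm = 8.6, cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

#' Net charge of a protein at a given pH
#'
#' Henderson--Hasselbalch sum over the free termini and the ionizable side
#' chains (D, E, C, Y negative; H, K, R positive).
#'
#' @param protein residue text.
#' @param ph pH value(s).
#' @param pka_set named list of pKa values (`nterm`, `cterm`, and side
#'   chains); defaults to the EMBOSS-style table.
#' @return numeric net charge, vectorized over `ph`.
#' @export
net_charge <- function(protein, ph, pka_set = .pka_emboss) {
  p <- toupper(as.character(protein))
  chars <- strsplit(p, "")[[1L]]
  nres <- table(factor(chars, levels = AA20))
  pos_groups <- c(nterm = 1,
                  H = unname(nres["H"]), K = unname(nres["K"]),
                  R = unname(nres["R"]))
  neg_groups <- c(cterm = 1,
                  D = unname(nres["D"]), E = unname(nres["E"]),
                  C = unname(nres["C"]), Y = unname(nres["Y"]))
  vapply(ph, function(x) {
    pos <- sum(vapply(names(pos_groups), function(g) {
      pka <- if (g == "nterm") pka_set$nterm else pka_set[[g]]
      pos_groups[[g]] / (1 + 10^(x - pka))
    }, numeric(1)))
    neg <- sum(vapply(names(neg_groups), function(g) {
      pka <- if (g == "cterm") pka_set$cterm else pka_set[[g]]
      neg_groups[[g]] / (1 + 10^(pka - x))
    }, numeric(1)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in [0, 14] at which [net_charge()] is zero, by bisection to a
#' pH tolerance of 1e-4. The net charge is strictly decreasing in pH, so the
#' root is unique.
#'
#' @inheritParams net_charge
#' @return the pI in pH units.
#' @export
#' @examples
#' isoelectric_point("DDDD") < isoelectric_point("KKKK")
isoelectric_point <- function(protein, pka_set = .pka_emboss) {
  if (nchar(protein) == 0L) stop("empty protein")
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(protein, mid, pka_set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Count transglutamination substrate residues
#'
#' Glutamine and lysine are the acyl donor and acceptor of the
#' transglutaminase cross-links that build the cornified envelope; several
#' sauropsid SEDC proteins lack lysine entirely.
#'
#' @param protein residue text.
#' @return a named integer vector `c(q_count = , k_count = )`.
#' @export
count_crosslink_residues <- function(protein) {
  p <- toupper(as.character(protein))
  chars <- strsplit(p, "")[[1L]]
  c(q_count = sum(chars == "Q"), k_count = sum(chars == "K"))
}

#' Size class of a protein
#'
#' Most SEDC proteins fall between 70 and 170 residues (roughly 8--20 kDa);
#' loricrins and involucrin-like proteins exceed 300 residues.
#'
#' @param protein residue text (or an integer length).
#' @return one of `"short"` (<70), `"typical_70_170"` (70--170 inclusive),
#'   `"intermediate"` (171--300), `"long_gt300"` (>300).
#' @export
size_class <- function(protein) {
  n <- if (is.numeric(protein)) as.integer(protein) else nchar(protein)
  if (n < 70L) "short"
  else if (n <= 170L) "typical_70_170"
  else if (n <= 300L) "intermediate"
  else "long_gt300"
}

#' Profile a set of proteins into a feature table
#'
#' @param proteins named character vector or `AAStringSet`.
#' @param gs_min,single_residue_min thresholds passed to
#'   [classify_composition()].
#' @return a data frame with one row per protein: `id`, `length`, the 20
#'   residue fractions as `frac_*` columns, `gs_fraction`, `q_count`,
#'   `k_count`, `pi`, `size_class` and the comma-joined `class_labels`.
#' @export
profile_proteins <- function(proteins, gs_min = 0.5,
                             single_residue_min = 0.15) {
  ids <- names(proteins)
  seqs <- as.character(proteins)
  if (is.null(ids)) ids <- sprintf("protein%d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    prof <- composition_profile(seqs[i], id = ids[i])
    fr <- as.list(prof$fractions)
    names(fr) <- paste0("frac_", AA20)
    cbind(
      data.frame(id = prof$id, length = prof$length,
                 stringsAsFactors = FALSE),
      as.data.frame(fr),
      data.frame(
        gs_fraction = prof$gs_fraction,
        q_count = prof$q_count, k_count = prof$k_count,
        pi = prof$pi, size_class = prof$size_class,
        class_labels = paste(
          classify_composition(prof, gs_min, single_residue_min),
          collapse = ","),
        stringsAsFactors = FALSE
      )
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
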