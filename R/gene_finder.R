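## Candidate discovery for the two-exon SEDC gene architecture.
## All coordinates are 0-based half-open on the forward strand; scanning the
## minus strand means scanning the reverse complement and mirroring results.

#' @keywords internal
gene_model_row <- function(id, contig, strand, status,
                           tata_start, tata_end, donor_pos,
                           exon1_start, exon1_end,
                           exon2_start, exon2_end,
                           intron_start, intron_end,
                           acceptor_start, acceptor_end,
                           pyr_fraction, utr_length,
                           orf_start, orf_end, protein) {
  data.frame(
    id = id, contig = contig, strand = strand, status = status,
    tata_start = as.integer(tata_start), tata_end = as.integer(tata_end),
    donor_pos = as.integer(donor_pos),
    exon1_start = as.integer(exon1_start), exon1_end = as.integer(exon1_end),
    exon2_start = as.integer(exon2_start), exon2_end = as.integer(exon2_end),
    intron_start = as.integer(intron_start), intron_end = as.integer(intron_end),
    acceptor_start = as.integer(acceptor_start),
    acceptor_end = as.integer(acceptor_end),
    pyr_fraction = as.numeric(pyr_fraction),
    utr_length = as.integer(utr_length),
    orf_start = as.integer(orf_start), orf_end = as.integer(orf_end),
    protein = protein,
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
empty_gene_models <- function() {
  gene_model_row(character(0), character(0), character(0), character(0),
                 integer(0), integer(0), integer(0), integer(0), integer(0),
                 integer(0), integer(0), integer(0), integer(0), integer(0),
                 integer(0), numeric(0), integer(0), integer(0), integer(0),
                 character(0))
}

.as_seq_chr <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "DNAStringSet")) {
    if (methods::is(seq, "DNAStringSet")) {
      stopifnot(length(seq) == 1L)
      seq <- seq[[1L]]
    }
    return(as.character(seq))
  }
  toupper(as.character(seq))
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## IUPAC consensus -> regular expression over {A,C,G,T,N}
.iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pattern), "")[[1L]]
  bad <- setdiff(chars, names(map))
  if (length(bad) > 0L) stop("unknown IUPAC code(s): ", paste(bad, collapse = ","))
  paste0(map[chars], collapse = "")
}

## all 0-based start positions of a regex (literal motifs included),
## overlapping matches allowed
.match_positions <- function(s, regex) {
  hits <- gregexpr(sprintf("(?=%s)", regex), s, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Scan one strand of a contig for splice acceptor sites
#'
#' A splice acceptor is an AG dinucleotide whose immediately 5' window of
#' `polypyrimidine_window` nt has a pyrimidine (C+T) fraction of at least
#' `polypyrimidine_min_fraction` and contains no N. Both strands are scanned;
#' minus-strand sites are reported as forward-strand coordinates with a
#' strand flag.
#'
#' @param seq a contig: character string, `DNAString`, or length-1
#'   `DNAStringSet`.
#' @param cfg a [pipeline_config()].
#' @param contig contig identifier carried into the output.
#' @param strands strands to scan, subset of `c("+", "-")`.
#' @return a data frame with columns `contig`, `strand`, `ag_start`,
#'   `ag_end` (0-based half-open span of the AG in transcription-strand
#'   reading direction, mirrored to forward coordinates for minus-strand
#'   sites) and `pyr_fraction`, sorted by position.
#' @export
scan_splice_acceptors <- function(seq, cfg = pipeline_config(),
                                  contig = "contig", strands = c("+", "-")) {
  s <- .as_seq_chr(seq)
  w <- cfg$polypyrimidine_window
  if (nchar(s) < w + 2L) {
    stop("sequence shorter than polypyrimidine window + AG (",
         w + 2L, " nt)")
  }
  one <- function(fwd, strand) {
    pos <- .match_positions(fwd, "AG")
    pos <- pos[pos >= w]
    if (length(pos) == 0L) {
      return(data.frame(contig = character(0), strand = character(0),
                        ag_start = integer(0), ag_end = integer(0),
                        pyr_fraction = numeric(0)))
    }
    win <- substring(fwd, pos - w + 1L, pos)  # window immediately 5' of AG
    has_n <- grepl("N", win, fixed = TRUE)
    pyr <- (nchar(win) - nchar(gsub("[CT]", "", win))) / w
    keep <- !has_n & pyr >= cfg$polypyrimidine_min_fraction
    pos <- pos[keep]; pyr <- pyr[keep]
    L <- nchar(fwd)
    if (strand == "+") {
      data.frame(contig = rep(contig, length(pos)), strand = rep("+", length(pos)),
                 ag_start = pos, ag_end = pos + 2L, pyr_fraction = pyr,
                 stringsAsFactors = FALSE)
    } else {
      # mirror [pos, pos+2) from the reverse-complement frame
      data.frame(contig = rep(contig, length(pos)), strand = rep("-", length(pos)),
                 ag_start = L - (pos + 2L), ag_end = L - pos,
                 pyr_fraction = pyr, stringsAsFactors = FALSE)
    }
  }
  out <- list()
  if ("+" %in% strands) out[["+"]] <- one(s, "+")
  if ("-" %in% strands) out[["-"]] <- one(.revcomp_chr(s), "-")
  res <- do.call(rbind, out)
  res <- res[order(res$ag_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## first in-frame stop codon at or after 0-based position `from` in `s`;
## returns 0-based start of the stop codon or NA
.first_inframe_stop <- function(s, from) {
  n <- nchar(s)
  i <- from
  while (i + 3L <= n) {
    codon <- substr(s, i + 1L, i + 3L)
    if (codon %in% c("TAA", "TAG", "TGA")) return(i)
    i <- i + 3L
  }
  NA_integer_
}

#' Scan for coding-exon candidates downstream of splice acceptors
#'
#' For each accepted splice acceptor, every ATG whose distance from the
#' acceptor AG (the 5'UTR length) lies within `acceptor_distance_range` and
#' that opens an open reading frame of `min_orf_codons`--`max_orf_codons`
#' codons (terminated by an in-frame stop, no internal stop) yields one
#' candidate. Translation uses the standard genetic code; the stop codon is
#' excluded from the protein but included in the ORF span.
#'
#' @inheritParams scan_splice_acceptors
#' @param acceptors acceptor data frame from [scan_splice_acceptors()] on the
#'   same contig.
#' @return a data frame with acceptor columns plus `utr_length`,
#'   `orf_start`, `orf_end` (forward 0-based half-open, stop included) and
#'   `protein`.
#' @export
scan_coding_exons <- function(seq, acceptors, cfg = pipeline_config(),
                              contig = "contig") {
  s <- .as_seq_chr(seq)
  L <- nchar(s)
  rc <- .revcomp_chr(s)
  rng <- cfg$acceptor_distance_range
  out <- list()
  for (i in seq_len(nrow(acceptors))) {
    a <- acceptors[i, ]
    # work in the transcription-strand frame
    if (a$strand == "+") {
      fwd <- s
      ag_end_t <- a$ag_end
    } else {
      fwd <- rc
      ag_end_t <- L - a$ag_start
    }
    for (utr in seq(rng[1], rng[2])) {
      atg <- ag_end_t + utr
      if (atg + 3L > nchar(fwd)) next
      if (substr(fwd, atg + 1L, atg + 3L) != "ATG") next
      stop_at <- .first_inframe_stop(fwd, atg)
      if (is.na(stop_at)) next
      n_codons <- (stop_at - atg) %/% 3L
      if (n_codons < cfg$min_orf_codons || n_codons > cfg$max_orf_codons) next
      cds <- substr(fwd, atg + 1L, stop_at)
      protein <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds), no.init.codon = TRUE))
      orf_t <- c(atg, stop_at + 3L)
      orf_f <- if (a$strand == "+") orf_t else c(L - orf_t[2], L - orf_t[1])
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, strand = a$strand,
        ag_start = a$ag_start, ag_end = a$ag_end,
        pyr_fraction = a$pyr_fraction,
        utr_length = utr,
        orf_start = orf_f[1], orf_end = orf_f[2],
        protein = protein, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(0), strand = character(0),
                      ag_start = integer(0), ag_end = integer(0),
                      pyr_fraction = numeric(0), utr_length = integer(0),
                      orf_start = integer(0), orf_end = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$orf_start, res$strand, res$utr_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Search upstream of a coding-exon candidate for the noncoding exon 1
#'
#' Looks 5' of the splice acceptor (on the transcription strand) for the
#' nearest splice-donor motif (exon-terminal G + intronic GTAAG, matched
#' exactly by default) that is preceded by a TATA-box match at a spacer
#' distance within `tata_distance_range`. The spacer distance is the number
#' of nt strictly between the last base of the TATA match and the
#' exon-terminal G. Among several TATA matches in range the one nearest the
#' donor is reported. Donors whose implied intron could not contain the
#' GTAAG, polypyrimidine tract and AG are skipped.
#'
#' @inheritParams scan_splice_acceptors
#' @param candidate one row of the data frame from [scan_coding_exons()].
#' @param max_upstream maximum search distance upstream of the acceptor, nt.
#' @return a one-row data frame with `tata_start`, `tata_end`, `donor_pos`,
#'   `tata_donor_distance`, `exon1_start`, `exon1_end`, `intron_start`,
#'   `intron_end` (forward 0-based half-open), or `NULL` when no donor with a
#'   TATA box in range exists within `max_upstream`.
#' @export
find_exon1 <- function(seq, candidate, cfg = pipeline_config(),
                       max_upstream = cfg$max_upstream) {
  stopifnot(max_upstream > 0)
  s <- .as_seq_chr(seq)
  L <- nchar(s)
  if (is.null(candidate$ag_start)) {  # accept assembled gene-model rows too
    candidate$ag_start <- candidate$acceptor_start
    candidate$ag_end <- candidate$acceptor_end
  }
  if (candidate$orf_end > L || candidate$orf_start < 0) {
    stop("candidate does not lie on the given contig")
  }
  fwd <- if (candidate$strand == "+") s else .revcomp_chr(s)
  ag_start_t <- if (candidate$strand == "+") candidate$ag_start else
    L - candidate$ag_end
  ag_end_t <- ag_start_t + 2L
  donor_re <- .iupac_regex(cfg$donor_motif)
  tata_re <- .iupac_regex(cfg$tata_pattern)
  tata_len <- nchar(cfg$tata_pattern)
  # minimal intron: GTAAG + polypyrimidine window + AG
  min_intron <- 5L + cfg$polypyrimidine_window + 2L
  lo <- max(0L, ag_start_t - max_upstream)
  region <- substr(fwd, lo + 1L, ag_start_t)
  donors <- lo + .match_positions(region, donor_re)
  donors <- donors[(ag_end_t - (donors + 1L)) >= min_intron]
  if (length(donors) == 0L) return(NULL)
  tatas <- lo + .match_positions(region, tata_re)
  rng <- cfg$tata_distance_range
  for (donor in rev(donors)) {  # nearest (largest position) first
    # spacer between last TATA base and the exon-terminal G
    d <- donor - (tatas + tata_len)
    ok <- which(d >= rng[1] & d <= rng[2])
    if (length(ok) == 0L) next
    t0 <- tatas[ok[which.max(tatas[ok])]]
    mirror <- function(iv) if (candidate$strand == "+") iv else
      c(L - iv[2], L - iv[1])
    tata_f <- mirror(c(t0, t0 + tata_len))
    exon1_f <- mirror(c(t0 + tata_len, donor + 1L))
    intron_f <- mirror(c(donor + 1L, ag_end_t))
    donor_f <- if (candidate$strand == "+") donor else L - 1L - donor
    return(data.frame(
      tata_start = tata_f[1], tata_end = tata_f[2],
      donor_pos = donor_f,
      tata_donor_distance = donor - (t0 + tata_len),
      exon1_start = exon1_f[1], exon1_end = exon1_f[2],
      intron_start = intron_f[1], intron_end = intron_f[2],
      stringsAsFactors = FALSE
    ))
  }
  NULL
}

#' Assemble two-exon gene models for a contig
#'
#' Runs the acceptor, coding-exon and exon-1 stages on both strands and
#' resolves overlapping candidates. Candidates on the same strand whose ORF
#' spans overlap are reduced to the one with the longest ORF (ties broken by
#' leftmost ORF start, then shortest 5'UTR). Each surviving candidate becomes
#' one gene model; models with a recovered exon 1 have status `two_exon`,
#' the rest `coding_exon_only`. No compositional or motif filtering is
#' applied here — see [filter_gene_models()].
#'
#' @inheritParams scan_splice_acceptors
#' @return a gene-model data frame sorted by coordinate, with ids
#'   `<contig>.g1`, `<contig>.g2`, ...
#' @export
assemble_gene_models <- function(seq, cfg = pipeline_config(),
                                 contig = "contig") {
  s <- .as_seq_chr(seq)
  acc <- scan_splice_acceptors(s, cfg, contig = contig)
  cand <- scan_coding_exons(s, acc, cfg, contig = contig)
  if (nrow(cand) == 0L) return(empty_gene_models())
  # overlap resolution per strand: longest ORF, then leftmost, then shortest UTR
  keep <- logical(nrow(cand))
  for (strand in unique(cand$strand)) {
    idx <- which(cand$strand == strand)
    sub <- cand[idx, ]
    len <- sub$orf_end - sub$orf_start
    ord <- order(-len, sub$orf_start, sub$utr_length)
    chosen <- integer(0)
    for (j in ord) {
      overlaps <- FALSE
      for (k in chosen) {
        if (sub$orf_start[j] < sub$orf_end[k] &&
            sub$orf_start[k] < sub$orf_end[j]) {
          overlaps <- TRUE
          break
        }
      }
      if (!overlaps) chosen <- c(chosen, j)
    }
    keep[idx[chosen]] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$orf_start, cand$strand), , drop = FALSE]
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cc <- cand[i, ]
    e1 <- find_exon1(s, cc, cfg)
    # exon 2 spans acceptor end (transcription sense) through ORF end
    if (cc$strand == "+") {
      exon2 <- c(cc$ag_end, cc$orf_end)
    } else {
      exon2 <- c(cc$orf_start, cc$ag_start)
    }
    rows[[i]] <- gene_model_row(
      id = sprintf("%s.g%d", contig, i),
      contig = contig, strand = cc$strand,
      status = if (!is.null(e1)) "two_exon" else "coding_exon_only",
      tata_start = if (!is.null(e1)) e1$tata_start else NA,
      tata_end = if (!is.null(e1)) e1$tata_end else NA,
      donor_pos = if (!is.null(e1)) e1$donor_pos else NA,
      exon1_start = if (!is.null(e1)) e1$exon1_start else NA,
      exon1_end = if (!is.null(e1)) e1$exon1_end else NA,
      exon2_start = exon2[1], exon2_end = exon2[2],
      intron_start = if (!is.null(e1)) e1$intron_start else NA,
      intron_end = if (!is.null(e1)) e1$intron_end else NA,
      acceptor_start = cc$ag_start, acceptor_end = cc$ag_end,
      pyr_fraction = cc$pyr_fraction, utr_length = cc$utr_length,
      orf_start = cc$orf_start, orf_end = cc$orf_end,
      protein = cc$protein
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Filter gene models by protein composition and conserved motifs
#'
#' A candidate survives if its protein resembles an epidermal differentiation
#' protein either compositionally (any of the GS_rich / C_rich / P_rich /
#' Q_rich classes, see [classify_composition()]) or by carrying one of the
#' conserved SEDC motifs (see [sedc_motifs()]) within the discovery mismatch
#' budget. The two filters are independent and combined by OR.
#'
#' @param models a gene-model data frame.
#' @param cfg a [pipeline_config()].
#' @param motifs a list of motif definitions; defaults to the shipped SEDC
#'   catalogue.
#' @return the surviving rows of `models`.
#' @export
filter_gene_models <- function(models, cfg = pipeline_config(),
                               motifs = sedc_motifs()) {
  if (nrow(models) == 0L) return(models)
  keep <- vapply(models$protein, function(p) {
    prof <- composition_profile(p)
    labels <- classify_composition(prof, gs_min = cfg$gs_min,
                                   single_residue_min = cfg$single_residue_min)
    if (!identical(labels, "unclassified")) return(TRUE)
    for (m in motifs) {
      if (!nzchar(m$consensus)) next
      if (nchar(p) < nchar(m$consensus)) next
      m$max_mismatches <- cfg$motif_max_mismatches
      if (nrow(scan_motif(p, m)) > 0L) return(TRUE)
    }
    FALSE
  }, logical(1))
  res <- models[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict SEDC genes on a contig
#'
#' Convenience wrapper: [assemble_gene_models()] followed by
#' [filter_gene_models()].
#'
#' @inheritParams scan_splice_acceptors
#' @param filter apply the composition/motif filter (default `TRUE`).
#' @return a gene-model data frame.
#' @export
predict_sedc_genes <- function(seq, cfg = pipeline_config(),
                               contig = "contig", filter = TRUE) {
  models <- assemble_gene_models(seq, cfg, contig = contig)
  if (filter) models <- filter_gene_models(models, cfg)
  models
}
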