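#' Convert gene models to GRanges / GFF3
#'
#' Gene models are held internally as a data frame with 0-based half-open
#' forward-strand coordinates (see [assemble_gene_models()]). GFF3 output is
#' 1-based inclusive, one `gene`/`mRNA` pair per model with `exon` and `CDS`
#' children, plus the discovered signal features as Sequence Ontology terms:
#' `TATA_box`, `five_prime_cis_splice_site` (the exon-terminal G of the
#' donor), and `three_prime_cis_splice_site` (the acceptor AG).
#'
#' @param models a gene-model data frame.
#' @return a [GenomicRanges::GRanges] with `type`, `ID` and `Parent` columns.
#' @export
models_to_granges <- function(models) {
  stopifnot(is.data.frame(models))
  if (nrow(models) == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (any(is.na(models$orf_start) | is.na(models$orf_end))) {
    stop("gene model missing coding exon (orf_start/orf_end)")
  }
  rows <- list()
  add <- function(contig, s0, e0, strand, type, id, parent) {
    list(contig = contig, start = s0 + 1L, end = e0, strand = strand,
         type = type, ID = id, Parent = parent)
  }
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    gid <- m$id
    mid <- paste0(gid, ".t1")
    span_s <- min(m$exon1_start, m$exon2_start, na.rm = TRUE)
    span_e <- max(m$exon1_end, m$exon2_end, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- add(m$contig, span_s, span_e, m$strand,
                                     "gene", gid, NA_character_)
    rows[[length(rows) + 1L]] <- add(m$contig, span_s, span_e, m$strand,
                                     "mRNA", mid, gid)
    if (!is.na(m$exon1_start)) {
      rows[[length(rows) + 1L]] <- add(m$contig, m$exon1_start, m$exon1_end,
                                       m$strand, "exon",
                                       paste0(gid, ".exon1"), mid)
    }
    rows[[length(rows) + 1L]] <- add(m$contig, m$exon2_start, m$exon2_end,
                                     m$strand, "exon",
                                     paste0(gid, ".exon2"), mid)
    rows[[length(rows) + 1L]] <- add(m$contig, m$orf_start, m$orf_end,
                                     m$strand, "CDS",
                                     paste0(gid, ".cds"), mid)
    if (!is.na(m$tata_start)) {
      rows[[length(rows) + 1L]] <- add(m$contig, m$tata_start, m$tata_end,
                                       m$strand, "TATA_box",
                                       paste0(gid, ".tata"), gid)
    }
    if (!is.na(m$donor_pos)) {
      rows[[length(rows) + 1L]] <- add(m$contig, m$donor_pos, m$donor_pos + 1L,
                                       m$strand, "five_prime_cis_splice_site",
                                       paste0(gid, ".donor"), gid)
    }
    rows[[length(rows) + 1L]] <- add(m$contig, m$acceptor_start, m$acceptor_end,
                                     m$strand, "three_prime_cis_splice_site",
                                     paste0(gid, ".acceptor"), gid)
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr
}

#' Write gene models as GFF3
#'
#' @param models a gene-model data frame (may have zero rows, which yields a
#'   header-only file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  gr <- models_to_granges(models)
  if (length(gr) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  lines <- c("##gff-version 3", .granges_to_gff3_lines(gr))
  writeLines(lines, path)
  invisible(path)
}

.granges_to_gff3_lines <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  attr_col <- ifelse(
    nzchar(mc$Parent),
    sprintf("ID=%s;Parent=%s", mc$ID, mc$Parent),
    sprintf("ID=%s", mc$ID)
  )
  sprintf("%s\tsedcscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
          as.character(GenomicRanges::seqnames(gr)),
          mc$type,
          GenomicRanges::start(gr),
          GenomicRanges::end(gr),
          as.character(GenomicRanges::strand(gr)),
          ifelse(mc$type == "CDS", "0", "."),
          attr_col)
}

#' Read a sedcscan GFF3 back into a gene-model data frame
#'
#' Reconstructs the internal 0-based half-open coordinate columns from a GFF3
#' written by [write_gff3()] (or any GFF3 using the same feature types).
#' Parsing goes through [rtracklayer::import()].
#'
#' @param path a GFF3 file path.
#' @return a gene-model data frame; protein sequences are not stored in GFF3
#'   and come back as `NA`.
#' @export
read_gff3_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_gene_models())
  mc <- S4Vectors::mcols(gr)
  parent <- as.character(mc$Parent)
  parent[is.na(parent) | parent == "character(0)"] <- ""
  # gene id per row: genes are their own id, children strip the .t1 tag
  gid <- ifelse(mc$type == "gene", as.character(mc$ID),
                sub("\\.(t1|tata|donor|acceptor)$", "", parent))
  out <- lapply(split(seq_along(gr), gid), function(idx) {
    sub <- gr[idx]
    smc <- S4Vectors::mcols(sub)
    pick <- function(type) {
      j <- which(smc$type == type)
      if (length(j) == 0L) return(c(NA_integer_, NA_integer_))
      c(GenomicRanges::start(sub)[j[1]] - 1L, GenomicRanges::end(sub)[j[1]])
    }
    exons <- which(smc$type == "exon")
    exon_sp <- if (length(exons) > 0L) {
      es <- GenomicRanges::start(sub)[exons] - 1L
      ee <- GenomicRanges::end(sub)[exons]
      ord <- order(es)
      cbind(es[ord], ee[ord])
    } else matrix(integer(0), ncol = 2)
    cds <- pick("CDS")
    tata <- pick("TATA_box")
    donor <- pick("five_prime_cis_splice_site")
    acc <- pick("three_prime_cis_splice_site")
    strand <- as.character(GenomicRanges::strand(sub))[1]
    # with two exons, which is exon1 depends on strand
    two <- nrow(exon_sp) == 2L
    if (two) {
      e1 <- if (strand == "+") exon_sp[1, ] else exon_sp[2, ]
      e2 <- if (strand == "+") exon_sp[2, ] else exon_sp[1, ]
    } else {
      e1 <- c(NA_integer_, NA_integer_)
      e2 <- if (nrow(exon_sp) == 1L) exon_sp[1, ] else c(NA_integer_, NA_integer_)
    }
    gene_model_row(
      id = names(split(seq_along(gr), gid))[1], # overwritten below
      contig = as.character(GenomicRanges::seqnames(sub))[1],
      strand = strand,
      status = if (two) "two_exon" else "coding_exon_only",
      tata_start = tata[1], tata_end = tata[2],
      donor_pos = donor[1],
      exon1_start = e1[1], exon1_end = e1[2],
      exon2_start = e2[1], exon2_end = e2[2],
      intron_start = NA_integer_, intron_end = NA_integer_,
      acceptor_start = acc[1], acceptor_end = acc[2],
      pyr_fraction = NA_real_,
      utr_length = NA_integer_,
      orf_start = cds[1], orf_end = cds[2],
      protein = NA_character_
    )
  })
  res <- do.call(rbind, out)
  res$id <- names(out)
  # recompute intron span where both exons present
  has1 <- !is.na(res$exon1_start)
  res$intron_start[has1] <- pmin(res$exon1_end[has1], res$exon2_end[has1])
  res$intron_end[has1] <- pmax(res$exon1_start[has1], res$exon2_start[has1])
  res[order(res$contig, res$orf_start), , drop = FALSE]
}

#' Write a protein feature table as TSV
#'
#' One row per protein: length, the 20 residue fractions (4 decimals), G+S
#' fraction, glutamine/lysine counts, isoelectric point, size class and
#' composition class labels.
#'
#' @param profiles a composition-profile data frame from [profile_proteins()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(profiles, path) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0L)
  out <- profiles
  frac_cols <- paste0("frac_", AA20)
  for (cl in c(frac_cols, "gs_fraction")) {
    out[[cl]] <- sprintf("%.4f", out[[cl]])
  }
  out$pi <- sprintf("%.3f", out$pi)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a protein feature table
#'
#' @param path TSV path written by [write_feature_table()].
#' @return a data frame with numeric fraction columns.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  num_cols <- c(paste0("frac_", AA20), "gs_fraction", "pi")
  for (cl in intersect(num_cols, names(df))) df[[cl]] <- as.numeric(df[[cl]])
  df
}
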