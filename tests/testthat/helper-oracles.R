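# Independent brute-force oracles used to cross-check the scanners, the
# aligner and the pI solver. These deliberately use different algorithms and
# data flow than the package implementations.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(AAS, n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# --- acceptor oracle: positional loop over every dinucleotide ---------------
oracle_acceptors_one_strand <- function(s, w = 12, minfrac = 0.7) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (i in seq_len(n - 1)) {
    if (chars[i] != "A" || chars[i + 1] != "G") next
    if (i - w < 1) next
    win <- chars[(i - w):(i - 1)]
    if (any(win == "N")) next
    frac <- sum(win %in% c("C", "T")) / w
    if (frac >= minfrac) {
      # 0-based: AG spans [i-1, i+1)
      hits[[length(hits) + 1]] <- c(ag_start = i - 1, pyr = frac)
    }
  }
  hits
}

oracle_acceptors <- function(s, w = 12, minfrac = 0.7) {
  n <- nchar(s)
  fwd <- oracle_acceptors_one_strand(s, w, minfrac)
  rev <- oracle_acceptors_one_strand(revcomp(s), w, minfrac)
  out <- data.frame(strand = character(0), ag_start = integer(0),
                    pyr_fraction = numeric(0))
  for (h in fwd) {
    out <- rbind(out, data.frame(strand = "+", ag_start = h[["ag_start"]],
                                 pyr_fraction = h[["pyr"]]))
  }
  for (h in rev) {
    out <- rbind(out, data.frame(strand = "-",
                                 ag_start = n - (h[["ag_start"]] + 2),
                                 pyr_fraction = h[["pyr"]]))
  }
  out[order(out$ag_start, out$strand), , drop = FALSE]
}

# --- coding-exon oracle: six-frame ATG..stop enumeration intersected with
# --- the acceptor/distance rule ---------------------------------------------
oracle_coding_exons <- function(s, cfg) {
  n <- nchar(s)
  acc <- oracle_acceptors(s, cfg$polypyrimidine_window,
                          cfg$polypyrimidine_min_fraction)
  out <- list()
  for (strand in c("+", "-")) {
    fwd <- if (strand == "+") s else revcomp(s)
    chars <- strsplit(fwd, "")[[1]]
    # all ORFs: every ATG with its first in-frame stop
    atgs <- which(chars == "A" &
                    c(chars[-1], "") == "T" &
                    c(chars[-(1:2)], "", "") == "G")
    orfs <- list()
    for (a in atgs) {
      j <- a
      stop_at <- NA
      while (j + 2 <= n) {
        cod <- paste(chars[j:(j + 2)], collapse = "")
        if (j > a && cod %in% c("TAA", "TAG", "TGA")) { stop_at <- j; break }
        j <- j + 3
      }
      if (is.na(stop_at)) next
      ncod <- (stop_at - a) / 3
      if (ncod < cfg$min_orf_codons || ncod > cfg$max_orf_codons) next
      orfs[[length(orfs) + 1]] <- c(atg = a - 1, end = stop_at + 2) # 0-based
    }
    sacc <- acc[acc$strand == strand, , drop = FALSE]
    for (k in seq_len(nrow(sacc))) {
      ag_end_t <- if (strand == "+") sacc$ag_start[k] + 2 else
        n - sacc$ag_start[k]
      for (o in orfs) {
        utr <- o[["atg"]] - ag_end_t
        if (utr < cfg$acceptor_distance_range[1] ||
            utr > cfg$acceptor_distance_range[2]) next
        orf_t <- c(o[["atg"]], o[["end"]])
        orf_f <- if (strand == "+") orf_t else c(n - orf_t[2], n - orf_t[1])
        out[[length(out) + 1]] <- data.frame(
          strand = strand, ag_start = sacc$ag_start[k], utr_length = utr,
          orf_start = orf_f[1], orf_end = orf_f[2])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(strand = character(0), ag_start = integer(0),
                      utr_length = integer(0), orf_start = integer(0),
                      orf_end = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$orf_start, res$strand, res$utr_length,
                   res$ag_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- Smith-Waterman affine-gap DP oracle ------------------------------------
oracle_local_align_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1], 0) + mat[A[i - 1], B[j - 1]])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# --- pI grid-search oracle ---------------------------------------------------
oracle_pi_grid <- function(protein) {
  coarse <- seq(0, 14, by = 0.001)
  z <- net_charge(protein, coarse)
  i <- max(which(z > 0))
  fine <- seq(coarse[i] - 0.001, coarse[i] + 0.002, by = 1e-5)
  zf <- net_charge(protein, fine)
  fine[which.min(abs(zf))]
}

# --- exon-1 oracle: positional loop for nearest donor with an in-range TATA -
# Works in the transcription frame; returns transcription-frame 0-based
# donor position and TATA start, or NULL.
oracle_exon1 <- function(fwd, ag_start_t, cfg, max_upstream = 10000) {
  min_intron <- 5 + cfg$polypyrimidine_window + 2
  lo <- max(0, ag_start_t - max_upstream)
  rng <- cfg$tata_distance_range
  for (p in seq(ag_start_t - 1, lo, by = -1)) {
    if (p < 0) break
    if (substr(fwd, p + 1, p + 6) != "GGTAAG") next
    if ((ag_start_t + 2) - (p + 1) < min_intron) next
    best_q <- NULL
    for (q in seq(p - 1, lo, by = -1)) {
      if (q < 0) break
      if (!grepl("^TATA[AT]A[AT]", substr(fwd, q + 1, q + 7))) next
      d <- p - (q + 7)
      if (d >= rng[1] && d <= rng[2]) { best_q <- q; break }  # nearest TATA
      if (d > rng[2]) break  # further TATAs are even farther
    }
    if (!is.null(best_q)) return(list(donor = p, tata = best_q))
  }
  NULL
}
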