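#' Pipeline configuration
#'
#' Bundle of the tunable rule parameters used by the gene scan and the
#' downstream protein filters. The defaults encode the SEDC gene architecture:
#' the splice acceptor (polypyrimidine tract + AG) sits 20--25 nt upstream of
#' the ATG, and the noncoding exon 1 ends in a G-GTAAG splice donor preceded
#' by a TATA box at 60--90 nt.
#'
#' @param acceptor_distance_range integer pair, allowed 5'UTR length in nt
#'   between the acceptor AG and the start codon (inclusive).
#' @param tata_distance_range integer pair, allowed distance in nt between the
#'   last base of the TATA-box match and the exon-terminal G of the splice
#'   donor (exclusive of both; i.e. the spacer length), inclusive bounds.
#' @param donor_motif splice donor consensus on the genome: the exon-terminal
#'   G followed by the intron-initial GTAAG. Matched exactly.
#' @param polypyrimidine_window width in nt of the window immediately 5' of
#'   the acceptor AG scored for pyrimidine content.
#' @param polypyrimidine_min_fraction minimum C+T fraction in that window.
#' @param tata_pattern TATA-box consensus, IUPAC codes allowed.
#' @param min_orf_codons,max_orf_codons protein length bounds in codons
#'   (stop codon excluded).
#' @param max_upstream maximum distance in nt searched upstream of the
#'   acceptor for the exon-1 donor.
#' @param gs_min,single_residue_min composition-class thresholds: combined
#'   glycine+serine fraction for GS_rich; per-residue fraction for
#'   C_rich/P_rich/Q_rich.
#' @param similarity_threshold raw local-alignment score (BLOSUM62 units)
#'   at or above which a pool protein is accepted during iterative expansion.
#' @param max_iterations cap on expansion rounds.
#' @param motif_max_mismatches mismatch budget for discovery-mode motif scans.
#' @param random_seed integer seed recorded with the run.
#'
#' @return an object of class `pipeline_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$acceptor_distance_range
pipeline_config <- function(acceptor_distance_range = c(20L, 25L),
                            tata_distance_range = c(60L, 90L),
                            donor_motif = "GGTAAG",
                            polypyrimidine_window = 12L,
                            polypyrimidine_min_fraction = 0.7,
                            tata_pattern = "TATAWAW",
                            min_orf_codons = 60L,
                            max_orf_codons = 2000L,
                            max_upstream = 10000L,
                            gs_min = 0.5,
                            single_residue_min = 0.15,
                            similarity_threshold = 40,
                            max_iterations = 20L,
                            motif_max_mismatches = 2L,
                            random_seed = 1L) {
  stopifnot(
    length(acceptor_distance_range) == 2L,
    acceptor_distance_range[1] <= acceptor_distance_range[2],
    length(tata_distance_range) == 2L,
    tata_distance_range[1] <= tata_distance_range[2],
    polypyrimidine_min_fraction >= 0, polypyrimidine_min_fraction <= 1,
    min_orf_codons <= max_orf_codons,
    nchar(donor_motif) > 0, nchar(tata_pattern) > 0
  )
  cfg <- list(
    acceptor_distance_range = as.integer(acceptor_distance_range),
    tata_distance_range = as.integer(tata_distance_range),
    donor_motif = toupper(donor_motif),
    polypyrimidine_window = as.integer(polypyrimidine_window),
    polypyrimidine_min_fraction = polypyrimidine_min_fraction,
    tata_pattern = toupper(tata_pattern),
    min_orf_codons = as.integer(min_orf_codons),
    max_orf_codons = as.integer(max_orf_codons),
    max_upstream = as.integer(max_upstream),
    gs_min = gs_min,
    single_residue_min = single_residue_min,
    similarity_threshold = similarity_threshold,
    max_iterations = as.integer(max_iterations),
    motif_max_mismatches = as.integer(motif_max_mismatches),
    random_seed = as.integer(random_seed)
  )
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("SEDC pipeline configuration\n")
  for (k in names(x)) {
    cat(sprintf("  %-28s %s\n", k, paste(x[[k]], collapse = "-")))
  }
  invisible(x)
}

#' Read or write a pipeline configuration as YAML
#'
#' The configuration is stored as a flat key-value document so a run can be
#' reproduced from its logged config alone.
#'
#' @param path file path.
#' @param cfg a [pipeline_config()] object.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write config files")
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
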