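#!/usr/bin/env Rscript
# Step 4 — conserved motifs and internal repeats.
#
# Scans the predicted proteins for the three conserved SEDC motifs (the
# N-terminal MSYxxxxQQCKQPCQPPP, internal MCSRxxxxxCH and C-terminal
# QQxKQPSQWPxQxxK consensus), builds a sequence-logo frequency matrix from
# the N-terminal motif instances, and flags internally repetitive proteins.

suppressMessages(library(sedcscan))

prots <- read_protein_fasta("results/predicted_proteins.fa")
seqs <- setNames(as.character(prots), names(prots))
motifs <- sedc_motifs(max_mismatches = 2L)  # discovery budget

hits <- do.call(rbind, lapply(names(seqs), function(id) {
  do.call(rbind, lapply(motifs[c("n_terminal", "internal", "c_terminal")],
                        function(m) {
    if (nchar(seqs[[id]]) < nchar(m$consensus)) return(NULL)
    scan_motif(seqs[[id]], m, protein_id = id)
  }))
}))
write.table(hits, "results/motif_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("motif hits per consensus:\n")
print(table(hits$motif))

# sequence logo matrix of the N-terminal motif block
nterm_ids <- unique(hits$protein_id[hits$motif == "sedc_n_terminal"])
width <- nchar(motifs$n_terminal$consensus)
block <- substr(seqs[nterm_ids], 1, width)
pfm <- position_frequency_matrix(block)
write.table(round(pfm$freq, 4), "results/nterm_motif_pfm.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat(sprintf("\nN-terminal motif logo: %d sequences, mean information %.2f bits\n",
            length(block), mean(pfm$information)))

reps <- do.call(rbind, lapply(names(seqs), function(id) {
  repeat_score(seqs[[id]], protein_id = id)
}))
write.table(reps, "results/repeat_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("proteins with repeat_fraction >= 0.5: %d of %d\n",
            sum(reps$repeat_fraction >= 0.5), nrow(reps)))
cat("\nwrote results/{motif_hits.tsv,nterm_motif_pfm.tsv,repeat_scores.tsv}\n")
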