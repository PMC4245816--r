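#!/usr/bin/env Rscript
# Step 5 — iterative similarity expansion and reciprocal-best-hit orthology.
#
# Emulates the iterative screening: a "second species" protein set is derived
# from the predicted proteins by seeded point substitution (25% of sites),
# mirroring divergent but orthologous SEDC repertoires. Starting from three
# seed proteins, the candidate set is expanded by Smith-Waterman similarity
# (BLOSUM62, gap open 11 / extend 1, raw-score threshold 40) until a fixed
# point; orthologs are then called by reciprocal best hits and checked
# against the known derivation.

suppressMessages(library(sedcscan))

prots <- read_protein_fasta("results/predicted_proteins.fa")
species1 <- setNames(as.character(prots), names(prots))

set.seed(13)
aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
mutate <- function(p, rate = 0.25) {
  chars <- strsplit(p, "")[[1]]
  idx <- which(runif(length(chars)) < rate)
  chars[idx] <- sample(aas, length(idx), replace = TRUE)
  paste(chars, collapse = "")
}
species2 <- setNames(vapply(species1, mutate, ""),
                     sub("synthetic_edc", "sp2", names(species1)))

# iterative expansion within species 1 from three seeds
seeds <- species1[1:3]
pool <- species1[-(1:3)]
exp <- iterative_expand(seeds, pool, threshold = 40)
cat(sprintf("expansion: %d seeds -> %d accepted in %d rounds (threshold 40)\n",
            length(seeds), length(exp$accepted), exp$rounds))
write.table(exp$edges, "results/expansion_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# reciprocal best hits across the two species
rbh <- reciprocal_best_hits(species1, species2)
correct <- sum(sub("synthetic_edc", "sp2", rbh$id_a) == rbh$id_b)
cat(sprintf("reciprocal best hits: %d pairs, %d matching the known derivation\n",
            nrow(rbh), correct))
write.table(rbh, "results/ortholog_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote results/{expansion_edges.tsv,ortholog_pairs.tsv}\n")
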