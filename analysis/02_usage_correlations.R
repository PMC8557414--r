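#!/usr/bin/env Rscript
# Stage 2: codon usage versus amino-acid atom content.
#
# For each species of stage 1: Pearson's correlation, across the 61 sense
# codons, between a codon's relative frequency and the N / C / N+C atom
# count of the amino acid it encodes. Negative values mean the genome
# avoids codons for atom-rich amino acids (resource-driven codon usage).
# Also demonstrates the CDS route: counting codons from the synthetic
# FASTA recovers the first species' table.

library(codoncost)

in_dir <- "results/01_species"
files <- list.files(in_dir, pattern = "^species_.*\\.tsv$", full.names = TRUE)
stopifnot(length(files) > 0)
tables <- lapply(files, read_frequency_table)
names(tables) <- vapply(tables, `[[`, character(1), "species")

usage <- sapply(c("N", "C", "CN"), function(el) {
  vapply(tables, usage_atom_correlation, numeric(1), element = el)
})
out <- data.frame(species = rownames(usage), usage, row.names = NULL)
dir.create("results", showWarnings = FALSE)
write.table(out, "results/02_usage_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(out, digits = 3)

cds <- Biostrings::readDNAStringSet(file.path(in_dir, "synthetic_cds.fasta"))
counted <- count_codons_from_cds(cds)
recovered <- normalize_codon_counts(counted$counts, "sense61")
l1 <- sum(abs(recovered$freqs - tables[[1]]$freqs[names(recovered$freqs)]))
cat(sprintf("\nCDS round trip for %s: %d codons counted, L1 distance %.4f\n",
            names(tables)[1], sum(counted$counts), l1))
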