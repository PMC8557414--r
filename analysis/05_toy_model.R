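#!/usr/bin/env Rscript
# Stage 5: why second-order selection cannot fix the code.
#
# The two-codon closed-form model: codon A at 80%, B at 20%; A encodes the
# cheap amino acid L under the wild-type code. A code-altering swap would
# make 80% of *future* mutations cost-decreasing (second-order benefit),
# but immediately raises the cost of 80% of the *current* codons
# (first-order penalty) - so first-order selection wins at any usage bias.

library(codoncost)

wt <- toy_model(freq_A = 0.8, orientation = "wild_type")
swapped <- toy_model(freq_A = 0.8, orientation = "mutant")

cat(sprintf("wild type: %.0f%% of mutations are L-to-H, %.0f%% H-to-L\n",
            100 * toy_mutation_fractions(wt)[["L_to_H"]],
            100 * toy_mutation_fractions(wt)[["H_to_L"]]))
cat(sprintf("after the code swap: %.0f%% of future mutations are H-to-L\n",
            100 * toy_mutation_fractions(swapped)[["H_to_L"]]))
cat(sprintf("immediate cost of the swap: %+.2f per codon (costs L=1, H=2)\n",
            toy_code_swap_immediate_cost(wt)))

grid <- data.frame(freq_A = seq(0.5, 0.95, by = 0.05))
grid$immediate_cost <- vapply(grid$freq_A, function(fA) {
  toy_code_swap_immediate_cost(toy_model(freq_A = fA))
}, numeric(1))
grid$future_H_to_L <- vapply(grid$freq_A, function(fA) {
  toy_mutation_fractions(toy_model(freq_A = fA, orientation = "mutant"))[["H_to_L"]]
}, numeric(1))
write.table(grid, "results/05_toy_model.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/05_toy_model.tsv\n")
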