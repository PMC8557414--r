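# codoncost

Is the standard genetic code (SGC) optimized to keep proteomic **nitrogen
and carbon usage** low under random point mutation? `codoncost` implements
the statistic and null models needed to ask that question properly, for
molecular evolutionists working on genetic-code optimization and elemental
stoichiometry of proteomes.

The core quantity is the **net expected random mutation cost**

```
nERMC = Σᵢ Σⱼ w_ij [n(j) − n(i)]  /  Σᵢ Σⱼ w_ij
```

where `n(i)` is the N (or C, or N+C) atom count of the amino acid encoded
by sense codon `i`, and `w_ij` is `f_i` for a transversion, `κ·f_i` for a
transition, and 0 otherwise (`f_i` = relative codon frequency, `κ` =
transition/transversion rate ratio; mutation rates symmetric). Counting
*both* increases and decreases matters: with uniform codon usage nERMC is
identically zero for every code table and every κ, and its expectation over
random codes is zero — so any apparent optimization is a property of
present-day codon usage, not of the code. Two contrast variants
(positive-cost-only ERMC with stop codons as zero-atom states, and a signed
stop-inclusive hybrid) are included for comparison with earlier analyses,
along with two random-genetic-code null models (a stop-constrained codon-box
shuffle preserving SGC degeneracy, and the conventional amino-acid label
shuffle), empirical P-values over a species × κ × element grid, Bonferroni
control, codon-usage/atom-content correlations, a synthetic codon-usage
generator, and the closed-form two-codon model contrasting first- and
second-order selection.

## Worked example

```r
library(codoncost)

# a species that avoids codons for nitrogen-rich amino acids
ft <- synth_frequencies(s = 0.3, noise_sd = 0.2, seed = 7)
usage_atom_correlation(ft, element = "N")
#> [1] -0.7259181

# its nERMC under the SGC at kappa = 3: positive, i.e. an average mutation
# *raises* nitrogen usage
nermc(standard_code(), ft, cost_params(kappa = 3, element = "N"))
#> <cost_result> nermc_sense (N, kappa = 3): 0.1320608

# compare against 2,000 box-shuffled random codes
report <- run_grid(list(sp = ft), kappa = 3, elements = "N",
                   null_method = "box_shuffle", n_rgcs = 2000, seed = 1)
report$nominal_p
#> [1] 0.9965
```

A nominal P of 0.9965 means 99.65% of random codes had a *smaller* mutation
cost than the SGC for this species: far from optimized, the SGC looks
anti-optimized — the expected signature when codon usage already avoids
nitrogen-rich amino acids. The two-codon toy model shows why selection can
never fix this at the code level:

```r
toy_mutation_fractions(toy_model(freq_A = 0.8))
#>  L_to_H  H_to_L
#>     0.8     0.2
toy_code_swap_immediate_cost(toy_model(freq_A = 0.8))
#> [1] 0.6
```

80% of mutations raise the cost under the wild-type code, and the code swap
that would reverse this is immediately deleterious (+0.6 per codon):
first-order selection on the present proteome beats second-order selection
on future mutations.

See `vignettes/resource-conservation.Rmd` for the model, assumptions,
parameter choices and limitations.

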