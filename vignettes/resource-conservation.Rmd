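---
title: "Testing genetic-code optimization for nitrogen and carbon conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing genetic-code optimization for nitrogen and carbon conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codoncost)
```

## The question

Amino acids differ in how many nitrogen and carbon atoms they contain
(arginine carries four N, glycine one), so the structure of a genetic code
determines how point mutations move a proteome's elemental budget. A natural
hypothesis is that the standard genetic code (SGC) was selected so that
random mutations tend not to *increase* proteomic N/C usage — optimization
for resource conservation. `codoncost` implements the statistic and the null
models needed to test that hypothesis, together with the closed-form
two-codon model that explains why such optimization is theoretically
implausible: it would require second-order selection (on the cost of future
mutations) to beat the much stronger first-order selection (on the
present-day proteome), and the two always point in opposite directions when
codon usage is biased.

## The statistic

For a code table and a set of relative codon frequencies $f_i$, the net
expected random mutation cost is

$$\mathrm{nERMC} \;=\; \frac{\sum_i \sum_j w_{ij}\,[n(j) - n(i)]}
                           {\sum_i \sum_j w_{ij}},$$

where $n(i)$ is the N (or C, or N+C) atom count of the amino acid encoded by
codon $i$, and $w_{ij}$ is the relative frequency of the $i \to j$ mutation
channel: $f_i$ when $i$ and $j$ differ by one transversion, $\kappa f_i$
when they differ by one transition, and $0$ otherwise. Mutation rates are
assumed symmetric ($\mu_{ij} = \mu_{ji}$), so the single transition/
transversion ratio $\kappa$ fully describes the mutation process. The sums
run over ordered pairs of the code's *sense* codons: mutations into or out
of stop codons change protein length, an effect incommensurate with a
one-residue atom change, so they are excluded.

Two contrast variants are provided for comparison with the older literature
(`cost_params(variant = ...)`):

* `ermc_positive_stop0` — counts only cost *increases*
  ($\max(n(j)-n(i), 0)$) and includes stop codons as zero-atom states; a
  reconstruction of the original ERMC from its published description
  (the original normalization is not fully specified there).
* `nermc_stop0` — signed costs, but stop codons kept as zero-atom states.

Two analytic identities anchor the test suite:

* **Uniform usage ⇒ zero.** If all 64 codons are equally frequent,
  $w_{ij} = w_{ji}$ up to $\kappa$-symmetry and every $[n(j)-n(i)]$ term is
  cancelled by its reverse, so nERMC $= 0$ for *any* code table and any
  $\kappa$ (asserted to $10^{-12}$ over 100 random codes and the 9-point
  $\kappa$ grid). The same cancellation makes nERMC identically zero
  whenever realized $i\to j$ mutation counts equal $j\to i$ counts.
* **Null expectation zero.** Under unequal frequencies the statistic varies
  across code tables but averages to zero over label-shuffled random codes
  (checked at 100,000 draws within 3 Monte-Carlo SE).

Together they mean any apparent "optimization" of a code must come from the
coupling between the code and *present-day codon usage* — which is exactly
what the protocol measures.

## Atom counts

The packaged table (`atom_table()`) stores C and N counts of the free amino
acids' molecular formulas (e.g. arginine C6H14N4O2). Residue-in-peptide
counts would be identical for C and N, since peptide-bond formation removes
only water; the formulas ship with the counts so the chemistry can be
audited, and a test re-parses them. The combined "CN" element defaults to
the plain atom sum $n_N + n_C$; how the two elements should be weighted in
a combined test is not established, so the weights are exposed
(`cn_weights`) and default to 1:1.

## Null models

* **Box shuffle** (`box_shuffle_rgc()`): the 16 codon boxes (quartets
  sharing their first two positions) are placed on a uniformly random
  permutation of box positions, carrying their third-position assignments.
  A placement is accepted only if the relocated single-stop box's stop
  codon differs from one of the relocated two-stop box's stops by exactly
  one transition — mirroring the TGA/TAA adjacency of the SGC, so every
  random code keeps a contiguous stop neighbourhood and exactly the SGC's
  per-amino-acid codon counts. Rejection sampling is used because it is
  provably uniform over constraint-satisfying permutations; enumeration of
  the $16 \times 15$ ordered placements of the two stop boxes gives an
  acceptance rate of $32/240 = 2/15$, cheap enough at any scale. The
  constraint's wording is compressed in the source literature; our literal
  reading (whole-codon, one-transition comparison) is isolated in the
  predicate `stop_adjacency_ok()` so an alternative reading can be swapped
  in without touching the sampler.
* **Label shuffle** (`label_shuffle_rgc()`): the conventional null — stops
  fixed at TAA/TAG/TGA, the 20 amino-acid labels permuted over the SGC's
  synonymous blocks. Per-amino-acid codon counts then range 1–6; a
  200,000-draw test checks each amino acid reaches the 6-codon leucine
  block with frequency $1/20$ within 3 binomial SE.

Frequencies attach to *genomic codons*, not amino acids: when a box-shuffled
code turns an SGC stop position into a sense codon, that codon carries its
table frequency (0 when a 61-codon table was supplied — coding sequences
contribute one terminal stop each, which frequency tables typically omit,
so imputing 0 without renormalization is the conservative choice). This
coupling between code and usage is precisely what the test exploits.

## The significance protocol

`run_grid()` evaluates, for each species × $\kappa$ × element cell, the SGC
against `n_rgcs` random codes, reporting the nominal P — the fraction of
random codes with *strictly smaller* cost (ties break against
significance; an `(n+1)`-style estimator is available for users worried
about zero P). One RGC sample is drawn per species and reused across
$\kappa$ and element cells: the cells then share Monte-Carlo noise, which
reduces variance for within-species contrasts and keeps runs deterministic;
`reuse_rgcs = FALSE` forces independent samples per cell. Multiple-testing
control is Bonferroni within each element over the species × $\kappa$
family (the most conservative standard choice, matching the way the grid
multiplies tests).

`correlation_usage_vs_significance()` relates, across species, the
usage–atom correlation to the significance of optimization at $\kappa = 3$
(a typical genome-wide transition/transversion ratio). The "significance"
axis is the nominal P itself by default — the quantity the grid's heat maps
encode, under which stronger avoidance of atom-rich codons (more negative
usage correlation) drives P up and the relation is negative; `one_minus_p`
and `neg_log10` transforms are provided since only the direction of the
relation, not its scale, is meaningful.

## Synthetic species

The generator (`synth_frequencies()`) draws
$f_i \propto \exp(-s\,n(i) + \epsilon_i)$ over the sense codons, with
$\epsilon_i \sim N(0, \sigma^2)$. This is a modelling choice, not an
empirical claim: the exponential form is the simplest monotone family whose
single parameter $s$ maps to "resource-driven selection strength" and whose
realized usage–atom correlations span the range seen across real genomes
(roughly $-0.8$ to $+0.2$ for the default panel, $s \in \{-0.1, 0, 0.05,
0.1, 0.2, 0.3, 0.5\}$ with $\sigma = 0.2$). What the synthetic data do *not*
emulate: amino-acid-level usage structure beyond atom content, GC-content
constraints, among-gene expression weighting, and phylogenetic correlation
between species — so green tests demonstrate the machinery and the
mechanism's direction, not any claim about a particular real genome.
`synth_cds()` wraps a table into in-frame start–body–stop gene records
(body length $1 + \mathrm{Pois}(\bar L - 1)$) for exercising the counting
path; at $10^6$ codons the round trip recovers the table within $L_1 <
0.02$.

## Numerical and degenerate-input choices

* All accumulation is in double precision; the uniform-usage zero is
  asserted at $10^{-12}$, never as exact equality.
* A zero denominator (no single-point channel with positive frequency in
  the summed set, e.g. all mass on a stop codon) is an explicit error, as
  is a Pearson correlation over a zero-variance input — never silently 0.
* Codons are canonical uppercase DNA internally; RNA (`U`) and lowercase
  are normalized at the boundary only.
* Seeds: every sampler takes an integer seed, restores the caller's RNG
  state, and derives per-species sub-seeds below $2^{31}$; reruns are
  byte-identical.
* The vectorized cost engine is one shared $\kappa$-linear decomposition
  used by the scalar API, the grid and the null sampler; it is checked to
  $10^{-12}$ against a brute-force 64×64 pair-loop oracle on random
  (code, frequency, $\kappa$, element, variant) tuples, and the
  label-shuffle fast path (numerator linear in the atom-count vector) is
  checked against the per-code route.

## Problem sizes

The reference protocol compares the SGC against $10^6$ random codes per
species. The packaged examples, tests and analysis scripts run at
$10^3$–$10^5$ codes — the nominal P's Monte-Carlo SE at $n$ codes is
$\sqrt{p(1-p)/n}$ ($\le 0.016$ at $n = 1000$), ample for the directional
and calibration properties they assert, and the grid scales linearly in
`n_rgcs` for users who want reference-scale runs.

## Known limitations

* Only the standard nuclear code family is modelled (no mitochondrial
  tables); elements beyond C and N (S, O, H) are out of scope.
* The two null models are the two specified here; other RGC-generation
  schemes from the literature give known-different answers and are not
  implemented.
* `ermc_positive_stop0` is a reconstruction of the original ERMC from its
  published description, not a line-for-line reimplementation.
* The multi-species empirical codon-frequency tables used in published
  analyses of this question are not publicly deposited; the pipeline
  accepts user-supplied tables of the same shape (61- or 64-codon, counts
  or frequencies) but ships only synthetic panels.
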