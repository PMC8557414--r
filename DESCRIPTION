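Package: codoncost
Title: Mutation-Cost Statistics for Testing Genetic Code Optimization for
    Nitrogen and Carbon Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether a genetic code is optimized for elemental
    resource (nitrogen/carbon) conservation. Implements the net expected
    random mutation cost (nERMC) of point mutations under a code table and a
    set of codon frequencies, together with two contrast variants (a
    positive-cost-only ERMC and a signed variant that treats stop codons as
    zero-atom states), two random-genetic-code null models (a stop-constrained
    codon-box shuffle and a conventional amino-acid label shuffle), empirical
    significance testing over a grid of transition/transversion rate ratios,
    codon-usage versus atom-content correlations, a synthetic codon-usage
    generator, and a closed-form two-codon toy model contrasting first- and
    second-order selection for resource conservation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
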