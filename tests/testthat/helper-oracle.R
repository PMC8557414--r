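# Independent oracles and small generators used across the suite.
# The cost oracle loops explicitly over all 64 x 64 codon pairs with
# if-branches and its own mutation classification; it shares nothing with
# the vectorized implementation except the packaged chemistry data.

oracle_mutation_class <- function(i, j) {
  ci <- strsplit(i, "")[[1]]
  cj <- strsplit(j, "")[[1]]
  ndiff <- 0L
  kind <- "tv"
  for (p in 1:3) {
    if (ci[p] != cj[p]) {
      ndiff <- ndiff + 1L
      pair <- sort(c(ci[p], cj[p]))
      if (identical(pair, c("A", "G")) || identical(pair, c("C", "T"))) {
        kind <- "ts"
      } else {
        kind <- "tv"
      }
    }
  }
  if (ndiff != 1L) return("none")
  kind
}

oracle_atoms <- function(aa, element) {
  tab <- atom_table()
  if (element == "N") return(tab[aa, "n_N"])
  if (element == "C") return(tab[aa, "n_C"])
  tab[aa, "n_N"] + tab[aa, "n_C"]
}

# freqs: full named vector over the 64 codons (0 where unobserved).
oracle_cost <- function(code, freqs, kappa, element, variant) {
  codons <- names(code)
  num <- 0; den <- 0
  for (i in codons) {
    for (j in codons) {
      cls <- oracle_mutation_class(i, j)
      if (cls == "none") next
      aa_i <- code[[i]]; aa_j <- code[[j]]
      if (variant == "nermc_sense") {
        if (aa_i == "*" || aa_j == "*") next
        d <- oracle_atoms(aa_j, element) - oracle_atoms(aa_i, element)
      } else {
        ni <- if (aa_i == "*") 0 else oracle_atoms(aa_i, element)
        nj <- if (aa_j == "*") 0 else oracle_atoms(aa_j, element)
        d <- nj - ni
        if (variant == "ermc_positive_stop0") d <- max(d, 0)
      }
      w <- if (cls == "ts") kappa * freqs[[i]] else freqs[[i]]
      num <- num + w * d
      den <- den + w
    }
  }
  num / den
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

all_codons <- function() names(standard_code())

# A random genetic code: the SGC's 64 assignments scattered over random
# codon positions (keeps 3 stops, 61 sense, every amino acid present).
random_scrambled_code <- function() {
  sgc <- standard_code()
  genetic_code(stats::setNames(sample(as.character(sgc)), names(sgc)),
               name = "scrambled")
}

random_freq_table <- function(codon_set = "sense61") {
  codons <- if (codon_set == "sense61") sense_codons(standard_code())
            else all_codons()
  codon_freq_table(stats::setNames(stats::rgamma(length(codons), 1), codons),
                   codon_set = codon_set, source = "synthetic")
}

uniform_table <- function(codon_set = "sense61") {
  codons <- if (codon_set == "sense61") sense_codons(standard_code())
            else all_codons()
  codon_freq_table(stats::setNames(rep(1, length(codons)), codons),
                   codon_set = codon_set, source = "synthetic")
}

full_freq_vector <- function(ft) {
  f <- stats::setNames(numeric(64), all_codons())
  f[names(ft$freqs)] <- ft$freqs
  f
}
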