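#' Synthetic codon usage under resource-driven selection
#'
#' Generates a per-species relative-frequency vector over the sense codons
#' of `code` with \eqn{f_i \propto \exp(-s\,n(i) + \epsilon_i)}, where
#' \eqn{n(i)} is the atom count of the encoded amino acid for `element` and
#' \eqn{\epsilon_i} is i.i.d. Gaussian noise. Positive `s` emulates
#' selection against atom-rich amino acids (codon usage anti-correlated
#' with atom content, the pattern seen for nitrogen in real genomes);
#' negative `s` yields a positive usage–atom correlation; `s = 0` with
#' noise gives an uncorrelated table. The exponential-preference form is
#' the simplest monotone family spanning the observed correlation range,
#' with `s` mapping interpretably to selection strength.
#'
#' @param s selection strength (real; sign sets the expected sign of
#'   `-`[usage_atom_correlation()]).
#' @param element `"N"` or `"C"`: which atom count selection acts on.
#' @param noise_sd standard deviation of the log-scale noise (>= 0).
#' @param seed integer seed (caller's RNG preserved); `NULL` uses the
#'   current stream.
#' @param code a `genetic_code`.
#' @param species label.
#' @return a `codon_freq_table` over the code's sense codons, source
#'   `"synthetic"`.
#' @examples
#' ft <- synth_frequencies(s = 0.3, noise_sd = 0.2, seed = 7)
#' usage_atom_correlation(ft, element = "N")  # negative
#' @export
synth_frequencies <- function(s = 0.3, element = c("N", "C"), noise_sd = 0.2,
                              seed = NULL, code = standard_code(),
                              species = sprintf("synthetic_s%g", s)) {
  element <- match.arg(element)
  stopifnot(is.numeric(noise_sd), noise_sd >= 0)
  sense <- sense_codons(code)
  n <- .atom_vector(code, element, stop_as_zero = TRUE)[sense]
  eps <- .with_seed(seed, stats::rnorm(length(sense), 0, noise_sd))
  w <- exp(-s * n + eps)
  codon_freq_table(stats::setNames(w, sense), species = species,
                   codon_set = "sense61", source = "synthetic")
}

#' Generate in-frame coding sequences from a frequency table
#'
#' Each record is `ATG` + codons drawn i.i.d. from `freqs` + one stop codon
#' drawn uniformly from the code's stops; body lengths are
#' `1 + Poisson(mean_length_codons - 1)`, i.e. mean exactly
#' `mean_length_codons` with a minimum of one codon. Records round-trip
#' through [count_codons_from_cds()].
#'
#' @param freqs a `codon_freq_table` over sense codons.
#' @param n_genes number of records.
#' @param mean_length_codons mean body length in codons.
#' @param seed integer seed (caller's RNG preserved).
#' @param code a `genetic_code` supplying the stop codons.
#' @return a [Biostrings::DNAStringSet] named `gene_1 ... gene_n`.
#' @export
synth_cds <- function(freqs, n_genes = 100L, mean_length_codons = 300L,
                      seed = NULL, code = standard_code()) {
  stopifnot(n_genes >= 1L, mean_length_codons >= 1)
  sense <- names(freqs$freqs)
  stops <- stop_codons(code)
  seqs <- .with_seed(seed, {
    lens <- 1L + stats::rpois(n_genes, mean_length_codons - 1)
    vapply(lens, function(L) {
      body <- sample(sense, L, replace = TRUE, prob = freqs$freqs)
      paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
    }, character(1))
  })
  names(seqs) <- paste0("gene_", seq_len(n_genes))
  Biostrings::DNAStringSet(seqs)
}

#' Write a bundle of synthetic species fixtures
#'
#' Writes one frequency TSV per selection strength in `s_values`, plus one
#' synthetic CDS FASTA for the first species, plus a YAML manifest
#' recording every seed and parameter.
#'
#' @param dir output directory (created; must not already exist).
#' @param s_values selection strengths, one species each. The default panel
#'   spans the roughly negative-to-weakly-positive usage–atom correlation
#'   range observed across real genomes.
#' @param element,noise_sd passed to [synth_frequencies()].
#' @param n_genes,mean_length_codons passed to [synth_cds()].
#' @param seed master seed; per-species seeds are derived from it.
#' @return invisibly, the list of `codon_freq_table`s written.
#' @export
write_fixture_bundle <- function(dir,
                                 s_values = c(-0.1, 0, 0.05, 0.1, 0.2, 0.3, 0.5),
                                 element = "N", noise_sd = 0.2,
                                 n_genes = 50L, mean_length_codons = 200L,
                                 seed = 1L) {
  if (dir.exists(dir)) stop("output directory already exists: ", dir)
  dir.create(dir, recursive = TRUE)
  tables <- list()
  for (i in seq_along(s_values)) {
    sp_seed <- .sub_seed(seed, i)
    ft <- synth_frequencies(s = s_values[i], element = element,
                            noise_sd = noise_sd, seed = sp_seed,
                            species = sprintf("species_%02d", i))
    write_frequency_table(ft, file.path(dir, paste0(ft$species, ".tsv")))
    tables[[ft$species]] <- ft
  }
  cds <- synth_cds(tables[[1]], n_genes = n_genes,
                   mean_length_codons = mean_length_codons,
                   seed = .sub_seed(seed, 0L))
  Biostrings::writeXStringSet(cds, file.path(dir, "synthetic_cds.fasta"))
  yaml::write_yaml(list(seed = seed, s_values = s_values, element = element,
                        noise_sd = noise_sd, n_genes = n_genes,
                        mean_length_codons = mean_length_codons,
                        species = names(tables),
                        package_version = as.character(utils::packageVersion("codoncost"))),
                   file.path(dir, "manifest.yaml"))
  invisible(tables)
}

#' Two-codon toy model of first- versus second-order selection
#'
#' A hypothetical organism has two codons, A (frequency `freq_A`) and B,
#' and two amino acids, L (low resource cost) and H (high cost). Under the
#' `"wild_type"` code A encodes L and B encodes H; a code-table-altering
#' swap (`"mutant"`) makes A encode H and B encode L. With equal per-codon
#' mutation probability every mutation flips A and B, so the closed forms
#' below follow directly.
#'
#' @param freq_A frequency of codon A, in (0, 1).
#' @param orientation `"wild_type"` or `"mutant"`.
#' @param cost_L,cost_H resource costs of the two amino acids
#'   (`cost_H > cost_L`).
#' @return an object of class `toy_model`.
#' @export
toy_model <- function(freq_A = 0.8, orientation = c("wild_type", "mutant"),
                      cost_L = 1, cost_H = 2) {
  orientation <- match.arg(orientation)
  stopifnot(freq_A > 0, freq_A < 1, cost_H > cost_L, cost_L >= 0)
  structure(list(freq_A = freq_A, freq_B = 1 - freq_A,
                 orientation = orientation,
                 cost_L = cost_L, cost_H = cost_H),
            class = "toy_model")
}

#' @rdname toy_model
#' @details `toy_mutation_fractions()`: the fraction of mutations that
#' raise the cost (L-to-H) equals the current frequency of the codon
#' encoding L — `freq_A` under the wild-type code, `freq_B` after the
#' swap — and the H-to-L fraction is its complement. With `freq_A = 0.8`,
#' 80% of wild-type mutations are L-to-H, while after the swap 80% are
#' H-to-L: the swap reverses the expected direction of future mutation
#' costs (second-order benefit).
#' @param model a `toy_model`.
#' @return `toy_mutation_fractions()`: named numeric
#'   `c(L_to_H = , H_to_L = )` summing to 1.
#' @examples
#' toy_mutation_fractions(toy_model(0.8))             # 0.8, 0.2
#' toy_mutation_fractions(toy_model(0.8, "mutant"))   # 0.2, 0.8
#' @export
toy_mutation_fractions <- function(model) {
  stopifnot(inherits(model, "toy_model"))
  f_L <- switch(model$orientation, wild_type = model$freq_A,
                mutant = model$freq_B)
  c(L_to_H = f_L, H_to_L = 1 - f_L)
}

#' @rdname toy_model
#' @details `toy_code_swap_immediate_cost()`: the immediate change in
#' expected per-codon resource consumption caused by adopting the mutant
#' code, `(freq_A - freq_B) * (cost_H - cost_L)`. Positive whenever
#' `freq_A > 0.5`: the swap that improves future mutations (second-order
#' selection) is immediately deleterious (first-order selection), and by a
#' larger margin the stronger the codon bias.
#' @return `toy_code_swap_immediate_cost()`: a real; positive iff
#'   `freq_A > 0.5`.
#' @export
toy_code_swap_immediate_cost <- function(model) {
  stopifnot(inherits(model, "toy_model"))
  if (model$orientation != "wild_type") {
    stop("the immediate swap cost is defined from the wild-type orientation")
  }
  (model$freq_A - model$freq_B) * (model$cost_H - model$cost_L)
}
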