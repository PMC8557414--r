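test_that("mutation weights follow the transition/transversion rule", {
  expect_equal(mutation_weight(0.02, "transversion", 3), 0.02)
  expect_equal(mutation_weight(0.02, "transition", 3), 0.06)
  expect_equal(mutation_weight(0.02, "not_single_point", 3), 0)
  expect_error(mutation_weight(-0.1, "transition", 3), "non-negative")
})

test_that("uniform codon frequencies give zero cost for any code and kappa", {
  set.seed(21)
  # uniform over all 64 genomic codons: uniform over any code's sense set
  u64 <- uniform_table("all64")
  codes <- c(list(standard_code()),
             replicate(50, random_scrambled_code(), simplify = FALSE))
  for (code in codes) {
    for (k in kappa_grid()) {
      expect_lt(abs(nermc(code, u64, cost_params(kappa = k))$value), 1e-12)
      expect_lt(abs(nermc_stop0(code, u64, cost_params(kappa = k))$value), 1e-12)
    }
  }
  # the SGC's own sense set: a sense-only uniform table suffices
  expect_lt(abs(nermc(standard_code(), uniform_table("sense61"),
                      cost_params(kappa = 3))$value), 1e-12)
})

test_that("vectorized costs equal the brute-force pair-loop oracle", {
  set.seed(31)
  variants <- c("nermc_sense", "ermc_positive_stop0", "nermc_stop0")
  elements <- c("N", "C", "CN")
  for (rep in 1:100) {
    code <- switch(1 + rep %% 3,
                   random_scrambled_code(),
                   box_shuffle_rgc(),
                   label_shuffle_rgc())
    ft <- random_freq_table(sample(c("sense61", "all64"), 1))
    kappa <- sample(kappa_grid(), 1)
    element <- sample(elements, 1)
    variant <- sample(variants, 1)
    got <- mutation_cost(code, ft,
                         cost_params(kappa, element, variant))$value
    want <- oracle_cost(code, full_freq_vector(ft), kappa, element, variant)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("frozen oracle values for the fixed synthetic table reproduce", {
  # computed with an independent pair-loop implementation (Biopython codon
  # table, formula-derived atom counts) on the seed-7 table
  sgc <- standard_code()
  ft <- synth_frequencies(s = 0.3, noise_sd = 0.2, seed = 7)
  expect_equal(nermc(sgc, ft, cost_params(3, "N"))$value,
               0.132060772582986, tolerance = 1e-12)
  expect_equal(nermc(sgc, ft, cost_params(0.5, "C"))$value,
               0.0142044282472085, tolerance = 1e-10)
  expect_equal(nermc_stop0(sgc, ft, cost_params(3, "N"))$value,
               0.0702300384533112, tolerance = 1e-10)
  expect_equal(ermc_positive(sgc, ft, cost_params(2, "C"))$value,
               0.690801968817191, tolerance = 1e-10)
  expect_equal(ermc_positive(sgc, uniform_table("all64"),
                             cost_params(1, "N"))$value,
               0.305555555555556, tolerance = 1e-12)
})

test_that("the numerator is antisymmetric and additive in the atom counts", {
  set.seed(41)
  sgc <- standard_code()
  ft <- random_freq_table()
  p <- cost_params(3, "N")
  # n -> -n (the c - n map at c = 0, via signed element weights)
  neg <- cost_params(3, "CN", cn_weights = c(N = -1, C = 0))
  expect_equal(mutation_cost(sgc, ft, neg)$value,
               -mutation_cost(sgc, ft, p)$value)
  # linearity: combined-element value = N value + C value (same denominator)
  expect_equal(mutation_cost(sgc, ft, cost_params(3, "CN"))$value,
               mutation_cost(sgc, ft, cost_params(3, "N"))$value +
                 mutation_cost(sgc, ft, cost_params(3, "C"))$value)
})

test_that("costs are invariant to rescaling the input counts", {
  counts <- stats::setNames(stats::rpois(61, 50) + 1,
                            sense_codons(standard_code()))
  a <- normalize_codon_counts(counts)
  b <- normalize_codon_counts(counts * 10)
  for (variant in c("nermc_sense", "ermc_positive_stop0", "nermc_stop0")) {
    expect_equal(mutation_cost(standard_code(), a, cost_params(2, "N", variant))$value,
                 mutation_cost(standard_code(), b, cost_params(2, "N", variant))$value)
  }
})

test_that("positive-only variant is nonnegative; value is continuous in kappa", {
  set.seed(51)
  for (rep in 1:10) {
    ft <- random_freq_table("all64")
    expect_gte(ermc_positive(standard_code(), ft, cost_params(sample(kappa_grid(), 1)))$value, 0)
  }
  ft <- synth_frequencies(s = 0.3, noise_sd = 0.2, seed = 7)
  v <- vapply(c(3 - 1e-6, 3, 3 + 1e-6), function(k) {
    nermc(standard_code(), ft, cost_params(k, "N"))$value
  }, numeric(1))
  expect_lt(max(abs(diff(v))), 1e-6)
})

test_that("a frequency table with no sense-pair weight raises the zero-denominator error", {
  f <- stats::setNames(numeric(64), all_codons())
  f["TAA"] <- 1   # all mass on a stop codon: no sense -> sense channel left
  ft <- codon_freq_table(f, codon_set = "all64", source = "synthetic")
  expect_error(nermc(standard_code(), ft, cost_params(1, "N")),
               "zero denominator")
})

test_that("the label-shuffle fast path equals the generic per-code route", {
  ft <- synth_frequencies(s = 0.2, noise_sd = 0.3, seed = 13)
  for (variant in c("nermc_sense", "nermc_stop0")) {
    p <- cost_params(3, "N", variant)
    fast <- cost_null_distribution(ft, p, 50, "label_shuffle", seed = 77)
    codes <- sample_rgcs(50, "label_shuffle", seed = 77)
    slow <- vapply(codes, function(cd) mutation_cost(cd, ft, p)$value, numeric(1))
    expect_equal(fast, slow, tolerance = 1e-12)
  }
  # the positive variant takes the generic route by construction
  p <- cost_params(3, "N", "ermc_positive_stop0")
  a <- cost_null_distribution(ft, p, 10, "label_shuffle", seed = 78)
  codes <- sample_rgcs(10, "label_shuffle", seed = 78)
  b <- vapply(codes, function(cd) mutation_cost(cd, ft, p)$value, numeric(1))
  expect_identical(a, b)
})
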