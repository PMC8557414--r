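test_that("codon counting follows the in-frame triplet rules", {
  res <- count_codons_from_cds(c(g1 = "ATGAAATAA"))
  expect_identical(unname(res$counts[c("ATG", "AAA")]), c(1L, 1L))
  expect_identical(sum(res$counts), 2L)
  expect_identical(res$diagnostics$n_terminal_stops, 1L)

  res <- count_codons_from_cds(c(g1 = "ATGNNNAAA"))
  expect_identical(unname(res$counts[c("ATG", "AAA")]), c(1L, 1L))
  expect_identical(res$diagnostics$n_ambiguous_triplets, 1L)

  expect_message(res <- count_codons_from_cds(c(bad = "ATGAA", ok = "ATGGGGTAA")),
                 "rejecting record 'bad'")
  expect_identical(res$diagnostics$rejected_ids, "bad")
  expect_identical(sum(res$counts), 2L)

  # internal stops go to diagnostics, not to the sense counts
  res <- count_codons_from_cds(c(g = "ATGTAAAAATAA"))
  expect_identical(res$diagnostics$n_internal_stops, 1L)
  expect_identical(sum(res$counts), 2L)

  expect_error(count_codons_from_cds(character(0)), "no sequence records")
  expect_error(suppressMessages(count_codons_from_cds("ATGAA")),
               "all records were rejected")

  # DNAStringSet input and RNA/case tolerance
  res2 <- count_codons_from_cds(Biostrings::DNAStringSet(c(g1 = "ATGAAATAA")))
  expect_identical(unname(res2$counts[c("ATG", "AAA")]), c(1L, 1L))
  res3 <- count_codons_from_cds(c(g1 = "augaaauaa"))
  expect_identical(unname(res3$counts[c("ATG", "AAA")]), c(1L, 1L))
})

test_that("count normalization is proportional and scale-invariant", {
  ft <- normalize_codon_counts(c(AAA = 3, AAG = 1))
  expect_equal(unname(ft$freqs[c("AAA", "AAG")]), c(0.75, 0.25))
  expect_equal(sum(ft$freqs), 1)
  ft10 <- normalize_codon_counts(c(AAA = 30, AAG = 10))
  expect_equal(ft$freqs, ft10$freqs)
  expect_error(normalize_codon_counts(c(AAA = 0)), "no positive counts")
})

test_that("frequency tables read, validate, and renormalize", {
  sense <- sense_codons(standard_code())
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)

  write.table(data.frame(codon = sense, frequency = rep(2, 61)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  ft <- read_frequency_table(path)
  expect_equal(unname(ft$freqs), rep(1 / 61, 61))
  expect_identical(ft$codon_set, "sense61")

  write.table(data.frame(codon = sense, frequency = rep(1, 61)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_frequency_table(path)$freqs, ft$freqs)

  write.table(data.frame(codon = sense[-1], frequency = rep(1, 60)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_frequency_table(path), "missing codon: TTT")

  write.table(data.frame(codon = c(sense, sense[1]), v = rep(1, 62)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_frequency_table(path), "duplicate codon: TTT")

  vals <- rep(1, 61); vals[5] <- -1
  write.table(data.frame(codon = sense, frequency = vals), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_frequency_table(path), "negative value")

  # comma-separated, no header, 64 rows
  writeLines(paste(all_codons(), 1, sep = ","), path)
  ft64 <- read_frequency_table(path)
  expect_identical(ft64$codon_set, "all64")
})

test_that("usage-atom correlation matches the textbook formula and its limits", {
  sgc <- standard_code()
  sense <- sense_codons(sgc)
  n <- vapply(sense, function(cd) atom_count(sgc, cd, "N"), numeric(1))

  up <- codon_freq_table(stats::setNames(n, sense), source = "synthetic")
  expect_equal(usage_atom_correlation(up, sgc, "N"), 1)
  down <- codon_freq_table(stats::setNames(max(n) - n + 0.5, sense),
                           source = "synthetic")
  expect_equal(usage_atom_correlation(down, sgc, "N"), -1)

  # frozen value for the fixed synthetic table, computed with an
  # independent sum-based Pearson implementation
  ft <- synth_frequencies(s = 0.3, noise_sd = 0.2, seed = 7)
  expect_equal(usage_atom_correlation(ft, sgc, "N"), -0.725918087091854,
               tolerance = 1e-12)
  expect_equal(usage_atom_correlation(ft, sgc, "N"),
               oracle_pearson(as.numeric(ft$freqs[sense]), n))

  # invariant to rescaling of the frequencies
  scaled <- ft$freqs * 7
  expect_equal(usage_atom_correlation(scaled, sgc, "N"),
               usage_atom_correlation(ft, sgc, "N"))

  expect_error(usage_atom_correlation(uniform_table(), sgc, "N"),
               "undefined correlation")
})

test_that("synthetic CDS round-trips to the generating frequencies", {
  ft <- synth_frequencies(s = 0.3, noise_sd = 0.2, seed = 7)
  cds <- synth_cds(ft, n_genes = 1000L, mean_length_codons = 1000L, seed = 3)
  counted <- count_codons_from_cds(cds)
  back <- normalize_codon_counts(counted$counts, "sense61")
  l1 <- sum(abs(back$freqs[names(ft$freqs)] - ft$freqs))
  expect_lt(l1, 0.02)
  expect_gt(sum(counted$counts), 9e5)
})
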