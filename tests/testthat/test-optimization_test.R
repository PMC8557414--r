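test_that("empirical P is the fraction of nulls strictly below the observation", {
  expect_equal(empirical_p(-1, c(0, 1, 2, 3)), 0)
  expect_equal(empirical_p(1.5, c(1, 2)), 0.5)
  expect_equal(empirical_p(1, c(1, 1, 1)), 0)        # ties do not count
  expect_equal(empirical_p(1, c(0, 2), "add_one"), 2 / 3)
  expect_error(empirical_p(1, numeric(0)), "empty null sample")
})

test_that("run_grid emits one reproducible row per grid cell", {
  tables <- lapply(c(0.1, 0.3, 0.5), function(s) {
    synth_frequencies(s = s, noise_sd = 0.2, seed = round(100 * s))
  })
  names(tables) <- paste0("sp", 1:3)
  report <- run_grid(tables, kappa = kappa_grid(), elements = "N",
                     null_method = "label_shuffle", n_rgcs = 200, seed = 11)
  expect_s3_class(report, "grid_report")
  expect_identical(nrow(report), 27L)
  expect_setequal(unique(report$species), names(tables))
  expect_true(all(report$nominal_p == report$n_smaller / report$n_rgcs))
  expect_true(all(report$n_smaller >= 0 & report$n_smaller <= report$n_rgcs))
  report2 <- run_grid(tables, kappa = kappa_grid(), elements = "N",
                      null_method = "label_shuffle", n_rgcs = 200, seed = 11)
  expect_identical(report, report2)
  # exact output column contract
  expect_identical(names(report)[1:10],
                   c("species", "element", "variant", "null_method", "kappa",
                     "sgc_value", "n_rgcs", "n_smaller", "nominal_p", "seed"))
})

test_that("uniform usage puts the SGC at zero cost in every cell", {
  report <- run_grid(list(u = uniform_table()), kappa = c(1, 3),
                     elements = "N", null_method = "box_shuffle",
                     n_rgcs = 100, seed = 3)
  expect_true(all(abs(report$sgc_value) < 1e-12))
})

test_that("strong avoidance of nitrogen-rich codons makes the SGC look unoptimized", {
  ft <- synth_frequencies(s = 0.5, noise_sd = 0.1, seed = 19)
  expect_lt(usage_atom_correlation(ft, element = "N"), -0.5)
  report <- run_grid(list(neg = ft), kappa = 3, elements = "N",
                     null_method = "box_shuffle", n_rgcs = 500, seed = 4)
  expect_gt(report$nominal_p, 0.5)
})

test_that("Bonferroni correction uses the per-element species x kappa family", {
  tables <- list(a = synth_frequencies(0.2, seed = 1),
                 b = synth_frequencies(0.4, seed = 2))
  report <- run_grid(tables, kappa = c(1, 2, 3), elements = c("N", "C"),
                     null_method = "label_shuffle", n_rgcs = 100, seed = 5)
  adj <- bonferroni_adjust(report, alpha = 0.05)
  expect_true(all(adj$n_tests == 6L))              # 2 species x 3 kappa
  expect_equal(adj$p_cutoff, rep(0.05 / 6, nrow(adj)))
  expect_identical(adj$significant, adj$nominal_p < 0.05 / 6)
  # all-large P: nothing significant
  adj$nominal_p <- pmax(adj$nominal_p, 0.5)
  adj2 <- bonferroni_adjust(adj, alpha = 0.05)
  expect_false(any(adj2$significant))
  # single cell: correction is a no-op
  one <- run_grid(tables[1], kappa = 3, elements = "N",
                  null_method = "label_shuffle", n_rgcs = 50, seed = 6)
  adj1 <- bonferroni_adjust(one, alpha = 0.05)
  expect_equal(adj1$p_cutoff, 0.05)
})

test_that("usage correlation and apparent optimization relate negatively", {
  s_values <- c(-0.1, 0, 0.1, 0.2, 0.35, 0.5)
  tables <- lapply(seq_along(s_values), function(i) {
    synth_frequencies(s = s_values[i], noise_sd = 0.15, seed = 300 + i,
                      species = paste0("sp", i))
  })
  names(tables) <- paste0("sp", seq_along(tables))
  usage <- vapply(tables, usage_atom_correlation, numeric(1), element = "N")
  expect_gt(diff(range(usage)), 0.4)   # the panel spans a real range
  report <- run_grid(tables, kappa = 3, elements = "N",
                     null_method = "label_shuffle", n_rgcs = 1000, seed = 8)
  r <- correlation_usage_vs_significance(report, usage, element = "N", kappa = 3)
  expect_lt(r, 0)
  # alternative axis conventions only flip the sign
  r2 <- correlation_usage_vs_significance(report, usage, element = "N",
                                          kappa = 3, transform = "one_minus_p")
  expect_equal(r2, -r)

  expect_error(correlation_usage_vs_significance(report, usage[1:2],
                                                 element = "N", kappa = 3),
               "at least 3 species")
  expect_error(correlation_usage_vs_significance(report, usage, element = "N",
                                                 kappa = 9.9),
               "no cells at kappa")
  flat <- stats::setNames(rep(0.3, length(usage)), names(usage))
  expect_error(correlation_usage_vs_significance(report, flat,
                                                 element = "N", kappa = 3),
               "zero variance")
})

test_that("replacing the SGC by a null draw makes the empirical P uniform", {
  ft <- synth_frequencies(s = 0.3, noise_sd = 0.2, seed = 7)
  p <- cost_params(3, "N")
  pvals <- vapply(1:200, function(rep) {
    vals <- cost_null_distribution(ft, p, 2001, "label_shuffle", seed = 5000 + rep)
    empirical_p(vals[1], vals[-1])
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("label-shuffle null costs average to zero under unequal frequencies", {
  ft <- synth_frequencies(s = 0.3, noise_sd = 0.2, seed = 7)
  vals <- cost_null_distribution(ft, cost_params(3, "N"), 20000,
                                 "label_shuffle", seed = 17)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("stronger resource-driven selection makes the SGC look less optimized", {
  # shared noise realization: only the selection strength varies
  s_values <- c(0.05, 0.2, 0.6)
  p_at_3 <- vapply(seq_along(s_values), function(i) {
    ft <- synth_frequencies(s = s_values[i], noise_sd = 0.1, seed = 400)
    report <- run_grid(stats::setNames(list(ft), "sp"), kappa = 3,
                       elements = "N", null_method = "label_shuffle",
                       n_rgcs = 2000, seed = 9)
    report$nominal_p
  }, numeric(1))
  expect_true(all(diff(p_at_3) >= 0))
})
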