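#' Empirical P-value against a sampled null
#'
#' The nominal P-value of the optimization test: the fraction of random
#' genetic codes whose cost statistic is *strictly smaller* than the SGC's
#' (ties do not count; small P means few random codes beat the code under
#' test, i.e. apparent optimization).
#'
#' @param sgc_value observed statistic.
#' @param rgc_values statistic under sampled random codes (nonempty).
#' @param method `"strict"` (fraction strictly smaller) or `"add_one"`
#'   (`(n_smaller + 1) / (n + 1)`, never exactly zero).
#' @return P in \[0, 1\].
#' @examples
#' empirical_p(1.5, c(1, 2))  # 0.5
#' empirical_p(1, c(1, 1, 1)) # 0: ties do not count
#' @export
empirical_p <- function(sgc_value, rgc_values, method = c("strict", "add_one")) {
  method <- match.arg(method)
  if (length(rgc_values) == 0L) stop("empty null sample")
  n_smaller <- sum(rgc_values < sgc_value)
  switch(method,
         strict = n_smaller / length(rgc_values),
         add_one = (n_smaller + 1) / (length(rgc_values) + 1))
}

#' Run the optimization test over a species x kappa x element grid
#'
#' For each species' codon-frequency table: sample `n_rgcs` random genetic
#' codes (one sample per species, reused across kappa and element cells so
#' the grid is cheap and cells within a species share Monte-Carlo noise;
#' set `reuse_rgcs = FALSE` for independent samples per cell), evaluate the
#' chosen cost variant for the SGC and for every random code at each grid
#' cell, and record the nominal P. Fully deterministic given `seed`.
#'
#' @param freq_tables list of `codon_freq_table` (names used as species
#'   labels when the tables carry none).
#' @param kappa numeric vector of transition/transversion ratios (> 0).
#' @param elements subset of `c("N", "C", "CN")`.
#' @param variant cost variant, as in [cost_params()].
#' @param null_method `"box_shuffle"` or `"label_shuffle"`.
#' @param n_rgcs random codes per null sample. The reference analysis scale
#'   is 1e6; desk-scale runs use 1e3–1e4, with Monte-Carlo standard error
#'   `sqrt(p(1-p)/n_rgcs)` on each nominal P.
#' @param seed master seed; per-species sub-seeds are derived from it.
#' @param reuse_rgcs share one RGC sample across a species' cells.
#' @param p_method tie handling, as in [empirical_p()].
#' @param strict_missense,cn_weights passed to [cost_params()].
#' @return a `grid_report`: data.frame with columns species, element,
#'   variant, null_method, kappa, sgc_value, n_rgcs, n_smaller, nominal_p,
#'   seed; one row per (species, element, kappa) cell.
#' @export
run_grid <- function(freq_tables, kappa = kappa_grid(),
                     elements = c("N", "C", "CN"),
                     variant = "nermc_sense",
                     null_method = c("box_shuffle", "label_shuffle"),
                     n_rgcs = 1000L, seed = 1L, reuse_rgcs = TRUE,
                     p_method = "strict",
                     strict_missense = FALSE, cn_weights = c(N = 1, C = 1)) {
  null_method <- match.arg(null_method)
  if (length(freq_tables) == 0L) stop("no frequency tables supplied")
  if (!length(kappa)) stop("kappa grid is empty")
  if (any(!is.finite(kappa)) || any(kappa <= 0)) {
    stop("kappa values must be positive")
  }
  elements <- match.arg(elements, several.ok = TRUE)
  if (is.null(names(freq_tables))) {
    names(freq_tables) <- vapply(freq_tables, function(x) x$species, character(1))
  }
  sgc <- standard_code()
  rows <- list()
  for (sp_i in seq_along(freq_tables)) {
    ft <- freq_tables[[sp_i]]
    sp <- names(freq_tables)[sp_i]
    sp_seed <- .sub_seed(seed, sp_i)
    if (reuse_rgcs) codes <- sample_rgcs(n_rgcs, null_method, sp_seed)
    for (el_i in seq_along(elements)) {
      el <- elements[el_i]
      sgc_comp <- .cost_components(sgc, ft, el, variant, strict_missense,
                                   cn_weights)
      if (reuse_rgcs) {
        rgc_comp <- lapply(codes, .cost_components, freqs = ft, element = el,
                           variant = variant,
                           strict_missense = strict_missense,
                           cn_weights = cn_weights)
      }
      for (k_i in seq_along(kappa)) {
        k <- kappa[k_i]
        if (!reuse_rgcs) {
          cell_codes <- sample_rgcs(n_rgcs, null_method,
                                    .sub_seed(sp_seed, 100L * el_i + k_i))
          rgc_comp <- lapply(cell_codes, .cost_components, freqs = ft,
                             element = el, variant = variant,
                             strict_missense = strict_missense,
                             cn_weights = cn_weights)
        }
        sgc_value <- .cost_value(sgc_comp, k)$value
        rgc_values <- vapply(rgc_comp, function(cc) .cost_value(cc, k)$value,
                             numeric(1))
        n_smaller <- sum(rgc_values < sgc_value)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, element = el, variant = variant,
          null_method = null_method, kappa = k, sgc_value = sgc_value,
          n_rgcs = n_rgcs, n_smaller = n_smaller,
          nominal_p = empirical_p(sgc_value, rgc_values, p_method),
          seed = seed, stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("grid_report", class(report))
  report
}

#' Bonferroni adjustment over the test grid
#'
#' Flags cells significant after correcting for the multiplicity of tests.
#' The correction family is the (species x kappa) cells *within each
#' element*: with 39 species and 9 kappa values that is 351 tests per
#' element, per-cell threshold `alpha / 351`.
#'
#' @param report a `grid_report` from [run_grid()].
#' @param alpha family-wise error rate.
#' @return the report with columns `n_tests`, `p_cutoff`, `significant`
#'   added.
#' @export
bonferroni_adjust <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "grid_report"))
  n_tests <- stats::ave(report$nominal_p, report$element,
                        FUN = length)
  report$n_tests <- as.integer(n_tests)
  report$p_cutoff <- alpha / report$n_tests
  report$significant <- report$nominal_p < report$p_cutoff
  report
}

#' Relation between codon-usage correlation and apparent optimization
#'
#' Pearson's correlation, across species, between each species'
#' usage–atom-content correlation (see [usage_atom_correlation()]) and its
#' significance level of optimization at a fixed kappa (default 3, a
#' typical genome-wide transition/transversion ratio). The significance
#' axis defaults to the nominal P itself, the quantity mapped in the test's
#' heat maps (stronger avoidance of atom-rich codons pushes the SGC's cost
#' up and its nominal P towards 1, so a negative relation is the
#' resource-driven-usage signature); `transform` switches to `1 - P`
#' ("higher = more apparently optimized") or `-log10(P)`.
#'
#' @param report a `grid_report` containing cells at `kappa`.
#' @param correlations named numeric vector: per-species usage–atom
#'   correlation for the element examined.
#' @param element which element's cells to use.
#' @param kappa fixed kappa (must be present in the report).
#' @param transform `"nominal_p"`, `"one_minus_p"`, or `"neg_log10"`.
#' @return Pearson correlation across species.
#' @export
correlation_usage_vs_significance <- function(report, correlations,
                                              element = "N", kappa = 3,
                                              transform = c("nominal_p",
                                                            "one_minus_p",
                                                            "neg_log10")) {
  transform <- match.arg(transform)
  stopifnot(inherits(report, "grid_report"))
  cells <- report[report$element == element & report$kappa == kappa, ]
  if (nrow(cells) == 0L) stop("no cells at kappa = ", kappa,
                              " for element ", element)
  sp <- intersect(cells$species, names(correlations))
  if (length(sp) < 3L) stop("need at least 3 species with both a grid cell ",
                            "and a usage correlation")
  p <- cells$nominal_p[match(sp, cells$species)]
  sig <- switch(transform,
                nominal_p = p,
                one_minus_p = 1 - p,
                neg_log10 = -log10(pmax(p, 1 / (cells$n_rgcs[1] + 1))))
  r <- correlations[sp]
  if (stats::sd(r) == 0 || stats::sd(sig) == 0) {
    stop("undefined correlation: zero variance across species")
  }
  stats::cor(r, sig)
}
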