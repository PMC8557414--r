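#' Run the end-to-end code-optimization protocol
#'
#' Ties the stages together: per-species usage–atom correlations, the
#' species x kappa x element grid of SGC-versus-RGC comparisons, Bonferroni
#' adjustment, and (when cells at `ef_kappa` exist) the across-species
#' correlation between codon-usage bias and apparent optimization. Writes
#' tab-separated artifacts plus a YAML manifest into a fresh run directory
#' (append-never: an existing directory is an error, so no run can
#' overwrite another's provenance).
#'
#' @param freq_tables list of `codon_freq_table`; `NULL` generates the
#'   default synthetic species panel (see [write_fixture_bundle()] for the
#'   panel's selection strengths).
#' @param out_dir run directory to create.
#' @param kappa,elements,variant,null_method,n_rgcs,seed,reuse_rgcs,strict_missense
#'   passed to [run_grid()].
#' @param alpha family-wise error rate for [bonferroni_adjust()].
#' @param ef_kappa kappa at which the usage-vs-significance correlation is
#'   evaluated (skipped if absent from `kappa`).
#' @return invisibly, a list with `report` (adjusted `grid_report`),
#'   `usage_correlations` (species x element matrix), and
#'   `usage_vs_significance` (named per-element vector, possibly empty).
#' @export
run_conservation_protocol <- function(freq_tables = NULL, out_dir,
                                      kappa = kappa_grid(),
                                      elements = c("N", "C", "CN"),
                                      variant = "nermc_sense",
                                      null_method = "box_shuffle",
                                      n_rgcs = 2000L, seed = 1L,
                                      reuse_rgcs = TRUE,
                                      strict_missense = FALSE,
                                      alpha = 0.05, ef_kappa = 3) {
  if (!length(kappa) || any(!is.finite(kappa)) || any(kappa <= 0)) {
    stop("kappa values must be positive")
  }
  if (dir.exists(out_dir)) stop("output directory already exists: ", out_dir)
  if (is.null(freq_tables)) {
    s_values <- c(-0.1, 0, 0.05, 0.1, 0.2, 0.3, 0.5)
    freq_tables <- lapply(seq_along(s_values), function(i) {
      synth_frequencies(s = s_values[i], noise_sd = 0.2,
                        seed = .sub_seed(seed, 1000L + i),
                        species = sprintf("species_%02d", i))
    })
    names(freq_tables) <- vapply(freq_tables, `[[`, character(1), "species")
  }
  dir.create(out_dir, recursive = TRUE)

  usage <- sapply(c("N", "C", "CN"), function(el) {
    vapply(freq_tables, usage_atom_correlation, numeric(1), element = el)
  })
  rownames(usage) <- names(freq_tables)

  report <- run_grid(freq_tables, kappa = kappa, elements = elements,
                     variant = variant, null_method = null_method,
                     n_rgcs = n_rgcs, seed = seed, reuse_rgcs = reuse_rgcs,
                     strict_missense = strict_missense)
  report <- bonferroni_adjust(report, alpha = alpha)

  ef <- numeric(0)
  if (any(abs(kappa - ef_kappa) < 1e-12) && length(freq_tables) >= 3L) {
    ef <- vapply(intersect(elements, colnames(usage)), function(el) {
      correlation_usage_vs_significance(report, usage[, el], element = el,
                                        kappa = ef_kappa)
    }, numeric(1))
  }

  utils::write.table(report, file.path(out_dir, "grid_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(species = rownames(usage), usage, row.names = NULL),
    file.path(out_dir, "usage_correlations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(ef)) {
    utils::write.table(
      data.frame(element = names(ef), correlation = unname(ef), kappa = ef_kappa),
      file.path(out_dir, "usage_vs_significance.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(
    list(seed = seed, n_rgcs = n_rgcs, kappa = kappa, elements = elements,
         variant = variant, null_method = null_method, alpha = alpha,
         ef_kappa = ef_kappa, species = names(freq_tables),
         package_version = as.character(utils::packageVersion("codoncost"))),
    file.path(out_dir, "manifest.yaml"))

  invisible(list(report = report, usage_correlations = usage,
                 usage_vs_significance = ef))
}
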