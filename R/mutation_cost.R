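#' Cost parameters for the mutation-cost statistics
#'
#' @param kappa transition/transversion mutation rate ratio (> 0). Mutation
#'   rates are assumed symmetric (the rate from codon i to j equals the rate
#'   from j to i), so a single kappa describes the mutation process.
#' @param element element whose proteomic usage is costed: `"N"`, `"C"`, or
#'   `"CN"` (combined; weighted atom sum, equal weights by default).
#' @param variant which statistic:
#'   * `"nermc_sense"` — the net expected random mutation cost: signed atom
#'     change, sums over ordered sense-codon pairs of the code only
#'     (mutations involving stop codons are excluded);
#'   * `"ermc_positive_stop0"` — positive-cost-only reconstruction of the
#'     original ERMC: sums over all 64x64 ordered pairs, numerator
#'     `max(n(j) - n(i), 0)`, stop codons treated as zero-atom states;
#'   * `"nermc_stop0"` — hybrid: signed change as in nERMC but over all
#'     64x64 pairs with stops as zero-atom states.
#' @param strict_missense exclude synonymous single-point pairs from the
#'   sums (sensitivity switch; the default keeps them, where they contribute
#'   weight to the denominator but zero to the numerator).
#' @param cn_weights length-2 `c(N = , C = )` weights for `element = "CN"`.
#' @return an object of class `cost_params`.
#' @export
cost_params <- function(kappa = 1, element = c("N", "C", "CN"),
                        variant = c("nermc_sense", "ermc_positive_stop0",
                                    "nermc_stop0"),
                        strict_missense = FALSE,
                        cn_weights = c(N = 1, C = 1)) {
  element <- match.arg(element)
  variant <- match.arg(variant)
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa), kappa > 0)
  structure(list(kappa = kappa, element = element, variant = variant,
                 strict_missense = isTRUE(strict_missense),
                 cn_weights = cn_weights),
            class = "cost_params")
}

#' Default grid of transition/transversion rate ratios
#' @return `c(1/5, 1/4, 1/3, 1/2, 1, 2, 3, 4, 5)`.
#' @export
kappa_grid <- function() c(1/5, 1/4, 1/3, 1/2, 1, 2, 3, 4, 5)

#' Weight of a single mutation channel
#'
#' The relative frequency of conversion from codon i to codon j: the
#' frequency of codon i for a transversion, kappa times that for a
#' transition, and 0 when i and j do not differ by a single point change.
#'
#' @param f_i relative frequency of the source codon (>= 0).
#' @param cls mutation class, as returned by [mutation_class()].
#' @param kappa transition/transversion rate ratio.
#' @return non-negative weight.
#' @export
mutation_weight <- function(f_i, cls = c("transversion", "transition",
                                         "not_single_point"), kappa = 1) {
  cls <- match.arg(cls)
  if (!is.numeric(f_i) || any(f_i < 0)) stop("frequency must be non-negative")
  switch(cls,
         transversion = f_i,
         transition = kappa * f_i,
         not_single_point = 0 * f_i)
}

# kappa-free decomposition of a cost statistic for one (code, freqs,
# element, variant) combination:
#   numerator(kappa)   = kappa * num_ts + num_tv
#   denominator(kappa) = kappa * den_ts + den_tv
# This single engine backs mutation_cost(), the grid runner, and the null
# sampler, so every caller shares one arithmetic path.
#' @noRd
.cost_components <- function(code, freqs, element, variant,
                             strict_missense = FALSE,
                             cn_weights = c(N = 1, C = 1)) {
  mats <- .mutation_class_matrices()
  f <- .freq64(freqs)              # sense61 tables: stops imputed 0
  sense <- code != STOP_SYMBOL
  n0 <- .atom_vector(code, element, stop_as_zero = TRUE, cn_weights)

  if (variant == "nermc_sense") {
    M <- outer(sense, sense)
  } else {
    M <- matrix(TRUE, 64L, 64L)
  }
  if (strict_missense) {
    M <- M & outer(as.character(code), as.character(code), "!=")
  }
  FTS <- f * mats$ts * M
  FTV <- f * mats$tv * M
  den_ts <- sum(FTS); den_tv <- sum(FTV)

  if (variant == "ermc_positive_stop0") {
    D <- outer(-n0, n0, "+")       # D[i, j] = n(j) - n(i)
    P <- pmax(D, 0)
    num_ts <- sum(FTS * P); num_tv <- sum(FTV * P)
  } else {
    num_ts <- sum((colSums(FTS) - rowSums(FTS)) * n0)
    num_tv <- sum((colSums(FTV) - rowSums(FTV)) * n0)
  }
  list(num_ts = num_ts, num_tv = num_tv, den_ts = den_ts, den_tv = den_tv)
}

#' @noRd
.cost_value <- function(comp, kappa) {
  den <- kappa * comp$den_ts + comp$den_tv
  if (!(den > 0)) {
    stop("zero denominator: no single-point pairs with positive frequency ",
         "in the summed codon set")
  }
  list(value = (kappa * comp$num_ts + comp$num_tv) / den,
       numerator = kappa * comp$num_ts + comp$num_tv,
       denominator = den)
}

#' Expected random mutation cost of a genetic code
#'
#' Computes, for a code table and a set of codon frequencies, the
#' frequency- and kappa-weighted mean change in the encoded amino acids'
#' atom count per single-point mutation:
#' \deqn{\mathrm{nERMC} = \frac{\sum_i \sum_j w_{ij}\,[n(j) - n(i)]}
#'                              {\sum_i \sum_j w_{ij}}}
#' with \eqn{w_{ij}} the weight of [mutation_weight()] and \eqn{n(i)} the
#' element atom count of the amino acid encoded by codon i. The sums run
#' over ordered pairs of the code's sense codons (`"nermc_sense"`; the
#' formula's 61x61, synonymous pairs included in the denominator) or over
#' all 64x64 pairs with stops as zero-atom states (the two contrast
#' variants; see [cost_params()]).
#'
#' Frequencies attach to genomic codons, not to amino acids: a sense-only
#' (61-codon) table evaluated on a code whose stop codons differ from the
#' SGC's imputes frequency 0 at the three SGC stop positions, without
#' renormalization.
#'
#' @param code a `genetic_code`.
#' @param freqs a `codon_freq_table`.
#' @param params a [cost_params()] object.
#' @return an object of class `cost_result`: list with `value`,
#'   `numerator`, `denominator` (> 0) and the echoed `params`.
#' @examples
#' f <- codon_freq_table(stats::setNames(rep(1, 61),
#'                       sense_codons(standard_code())))
#' nermc(standard_code(), f, cost_params(kappa = 3))$value  # 0: uniform usage
#' @export
mutation_cost <- function(code, freqs, params = cost_params()) {
  stopifnot(inherits(params, "cost_params"))
  comp <- .cost_components(code, freqs, params$element, params$variant,
                           params$strict_missense, params$cn_weights)
  v <- .cost_value(comp, params$kappa)
  structure(c(v, list(params = params)), class = "cost_result")
}

#' @rdname mutation_cost
#' @param ... passed to [cost_params()] (kappa, element, ...).
#' @export
nermc <- function(code, freqs, params = cost_params(variant = "nermc_sense", ...),
                  ...) {
  params$variant <- "nermc_sense"
  mutation_cost(code, freqs, params)
}

#' @rdname mutation_cost
#' @export
ermc_positive <- function(code, freqs,
                          params = cost_params(variant = "ermc_positive_stop0", ...),
                          ...) {
  params$variant <- "ermc_positive_stop0"
  mutation_cost(code, freqs, params)
}

#' @rdname mutation_cost
#' @export
nermc_stop0 <- function(code, freqs,
                        params = cost_params(variant = "nermc_stop0", ...),
                        ...) {
  params$variant <- "nermc_stop0"
  mutation_cost(code, freqs, params)
}

#' @export
print.cost_result <- function(x, ...) {
  cat("<cost_result> ", x$params$variant, " (", x$params$element,
      ", kappa = ", format(x$params$kappa), "): ", format(x$value), "\n",
      sep = "")
  invisible(x)
}

#' Null distribution of a cost statistic over random genetic codes
#'
#' Samples `n_codes` random codes under the chosen null model and evaluates
#' the statistic of `params` on each, under `freqs`. For the label-shuffle
#' null with a signed variant the code enters the statistic only through
#' the per-codon atom-count vector, which is linear in the numerator, so
#' those values are computed by one matrix product over the permuted label
#' vectors; the generic per-code route is used otherwise. Both routes draw
#' the same permutation stream, so results are seed-reproducible across
#' routes.
#'
#' @param freqs a `codon_freq_table`.
#' @param params a [cost_params()].
#' @param n_codes number of random codes.
#' @param method `"box_shuffle"` or `"label_shuffle"`.
#' @param seed integer seed (caller's RNG state preserved); `NULL` uses the
#'   current stream.
#' @return numeric vector of length `n_codes`.
#' @export
cost_null_distribution <- function(freqs, params, n_codes,
                                   method = c("box_shuffle", "label_shuffle"),
                                   seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(params, "cost_params"), n_codes >= 1L)
  if (method == "label_shuffle" && params$variant != "ermc_positive_stop0") {
    return(.label_shuffle_null_fast(freqs, params, n_codes, seed))
  }
  codes <- sample_rgcs(n_codes, method, seed)
  vapply(codes, function(cd) mutation_cost(cd, freqs, params)$value, numeric(1))
}

# Linear fast path: under the label shuffle the pair mask (sense set, and
# the synonymous-pair structure) is that of the SGC, so
# numerator = sum_k g(k) * n(k) with g fixed; only n varies with the label
# permutation.
#' @noRd
.label_shuffle_null_fast <- function(freqs, params, n_codes, seed = NULL) {
  sgc <- standard_code()
  mats <- .mutation_class_matrices()
  f <- .freq64(freqs)
  sense <- sgc != STOP_SYMBOL
  M <- if (params$variant == "nermc_sense") outer(sense, sense) else
    matrix(TRUE, 64L, 64L)
  if (params$strict_missense) {
    M <- M & outer(as.character(sgc), as.character(sgc), "!=")
  }
  FTS <- f * mats$ts * M
  FTV <- f * mats$tv * M
  g <- params$kappa * (colSums(FTS) - rowSums(FTS)) +
    (colSums(FTV) - rowSums(FTV))
  den <- params$kappa * sum(FTS) + sum(FTV)
  if (!(den > 0)) stop("zero denominator under the null's codon set")

  aas <- rownames(atom_table())
  a <- vapply(aas, .aa_atoms, numeric(1),
              element = params$element, cn_weights = params$cn_weights)
  blk <- match(as.character(sgc)[sense], aas)   # block label index per sense codon
  perms <- .with_seed(seed,
                      t(vapply(seq_len(n_codes), function(i) sample.int(20L),
                               integer(20L))))
  N <- matrix(a[perms[, blk, drop = FALSE]], nrow = n_codes)  # n_codes x 61
  as.numeric(N %*% g[sense]) / den
}
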