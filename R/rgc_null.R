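#' Random genetic code (RGC) null models
#'
#' Two null models for "a random genetic code":
#'
#' * **Box shuffle** ([box_shuffle_rgc()]): the 16 codon boxes (quartets of
#'   codons sharing their first two positions) of the SGC are placed on a
#'   uniformly random permutation of box positions, each box carrying its
#'   third-position assignments with it. Placements are rejected until the
#'   stop-codon constraint holds: the relocated single-stop box's stop codon
#'   must differ from one of the two stop codons of the relocated two-stop
#'   box by exactly one transition. Per-amino-acid codon counts are
#'   therefore identical to the SGC's, and every code has exactly 3 stops.
#' * **Label shuffle** ([label_shuffle_rgc()]): the conventional null —
#'   stops stay at TAA/TAG/TGA, the 20 synonymous codon sets of the SGC keep
#'   their membership, and the 20 amino-acid labels are permuted uniformly
#'   at random over those sets. Codons per amino acid then range 1..6.
#'
#' Both draw from the session RNG; use [sample_rgcs()] for a seeded,
#' reproducible stream that leaves the caller's RNG state untouched.
#'
#' @name rgc_null
NULL

# Box index (1..16 by first-two-base prefix) of each of the 64 codons.
#' @noRd
.box_prefixes <- function() {
  g <- expand.grid(b2 = .bases, b1 = .bases, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2)
}

# Apply a permutation of the 16 box positions to the SGC: the box at
# prefix q moves to prefix p = perm[q], keeping third-position assignments.
#' @noRd
.apply_box_permutation <- function(perm, name = "RGC_box") {
  prefixes <- .box_prefixes()
  src <- prefixes[perm]            # box placed at position k comes from src[k]
  sgc <- standard_code()
  out <- sgc
  for (k in seq_len(16L)) {
    out[paste0(prefixes[k], .bases)] <- sgc[paste0(src[k], .bases)]
  }
  attr(out, "name") <- name
  out
}

#' Stop-codon adjacency constraint for box-shuffled codes
#'
#' The predicate behind the box-shuffle rejection step, isolated so the
#' constraint's reading can be swapped: among the three stop codons of
#' `code`, one codon box holds a single stop and another holds two; the
#' constraint requires the single stop to differ from at least one of the
#' other two stops by exactly one transition (whole-codon comparison).
#'
#' @param code a `genetic_code` with exactly 3 stop codons.
#' @return `TRUE` or `FALSE`.
#' @export
stop_adjacency_ok <- function(code) {
  stops <- stop_codons(code)
  if (length(stops) != 3L) return(FALSE)
  box <- substr(stops, 1L, 2L)
  tab <- table(box)
  if (!setequal(as.integer(tab), c(1L, 2L))) return(FALSE)
  solo <- stops[box == names(tab)[tab == 1L]]
  pair <- stops[box != substr(solo, 1L, 2L)]
  any(vapply(pair, function(s) mutation_class(solo, s) == "transition",
             logical(1)))
}

#' @rdname rgc_null
#' @param max_tries rejection-sampling cap (the acceptance rate is 2/15, so
#'   the default is never approached in practice).
#' @return a `genetic_code`.
#' @export
box_shuffle_rgc <- function(max_tries = 10000L) {
  for (t in seq_len(max_tries)) {
    code <- .apply_box_permutation(sample.int(16L))
    if (stop_adjacency_ok(code)) return(code)
  }
  stop("internal error: box-shuffle rejection cap reached")
}

#' @rdname rgc_null
#' @export
label_shuffle_rgc <- function() {
  sgc <- standard_code()
  aas <- rownames(atom_table())
  perm <- stats::setNames(aas[sample.int(20L)], aas)
  out <- sgc
  sense <- sgc != STOP_SYMBOL
  out[sense] <- perm[sgc[sense]]
  attr(out, "name") <- "RGC_label"
  out
}

#' Sample random genetic codes reproducibly
#'
#' @param n number of codes.
#' @param method `"box_shuffle"` or `"label_shuffle"`.
#' @param seed integer seed; the caller's RNG state is preserved. `NULL`
#'   uses (and advances) the current stream.
#' @return list of `genetic_code` objects.
#' @export
sample_rgcs <- function(n, method = c("box_shuffle", "label_shuffle"),
                        seed = NULL) {
  method <- match.arg(method)
  gen <- switch(method, box_shuffle = box_shuffle_rgc,
                label_shuffle = label_shuffle_rgc)
  .with_seed(seed, replicate(n, gen(), simplify = FALSE))
}

#' Structural diagnostics for a genetic code
#'
#' Checks either that per-amino-acid codon counts equal the SGC's
#' (`"sgc_degeneracy"`, the box-shuffle guarantee) or that the SGC's
#' synonymous-block structure is intact with stops fixed
#' (`"block_structure"`, the label-shuffle guarantee).
#'
#' @param code a `genetic_code`.
#' @param expected `"sgc_degeneracy"` or `"block_structure"`.
#' @return list with `pass` (logical), `violations` (character), the stop
#'   count and per-amino-acid codon counts.
#' @export
validate_code <- function(code, expected = c("sgc_degeneracy", "block_structure")) {
  expected <- match.arg(expected)
  sgc <- standard_code()
  counts <- table(factor(code[code != STOP_SYMBOL], levels = rownames(atom_table())))
  violations <- character(0)
  n_stops <- length(stop_codons(code))
  if (n_stops != 3L) {
    violations <- c(violations, sprintf("stop count is %d, expected 3", n_stops))
  }
  if (any(counts == 0L)) {
    violations <- c(violations, paste0("amino acid(s) with no codon: ",
                                       paste(names(counts)[counts == 0L], collapse = ", ")))
  }
  if (expected == "sgc_degeneracy") {
    sgc_counts <- table(factor(sgc[sgc != STOP_SYMBOL], levels = rownames(atom_table())))
    if (!identical(sort(as.integer(counts)), sort(as.integer(sgc_counts)))) {
      violations <- c(violations, "per-amino-acid codon count multiset differs from the SGC")
    }
  } else {
    if (!setequal(stop_codons(code), stop_codons(sgc))) {
      violations <- c(violations, "stop codons moved from {TAA, TAG, TGA}")
    }
    # every SGC synonymous set must map to a single label
    split_sets <- split(names(sgc)[sgc != STOP_SYMBOL], sgc[sgc != STOP_SYMBOL])
    for (aa in names(split_sets)) {
      labels <- unique(code[split_sets[[aa]]])
      if (length(labels) != 1L) {
        violations <- c(violations,
                        paste0("synonymous set of ", aa, " split across labels"))
      }
    }
  }
  list(pass = length(violations) == 0L,
       violations = violations,
       n_stops = n_stops,
       codons_per_aa = counts)
}
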