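# Internal helpers shared across modules.

# Cache for lazily built constants (codon list, mutation-class matrices,
# packaged atom tables).
.cc_cache <- new.env(parent = emptyenv())

#' @noRd
.bases <- c("T", "C", "A", "G")

#' All 64 codons in fixed T/C/A/G order (first position slowest).
#' @noRd
.codons <- function() {
  if (is.null(.cc_cache$codons)) {
    g <- expand.grid(b3 = .bases, b2 = .bases, b1 = .bases,
                     stringsAsFactors = FALSE)
    .cc_cache$codons <- paste0(g$b1, g$b2, g$b3)
  }
  .cc_cache$codons
}

# Canonicalize codon strings: uppercase, RNA U -> T. Validation optional.
#' @noRd
.canon_codon <- function(x, validate = TRUE) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  if (validate) {
    bad <- nchar(x) != 3L | grepl("[^TCAG]", x)
    if (any(bad)) {
      stop("invalid codon(s): ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  x
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards (no global random state is disturbed).
# seed = NULL means: use the current stream.
#' @noRd
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit sub-seed from a master seed, kept inside 32-bit range.
#' @noRd
.sub_seed <- function(seed, index) {
  (as.integer(seed) + 7919L * as.integer(index)) %% 2147483587L
}
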