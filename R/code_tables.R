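#' Genetic code tables, amino-acid atom counts, and mutation classification
#'
#' A genetic code is represented as a named character vector of length 64
#' mapping each DNA codon (alphabet T/C/A/G) to a one-letter amino-acid
#' symbol, with `"*"` for stop. Constructors validate the mapping; the
#' standard genetic code (SGC) comes from [Biostrings::GENETIC_CODE].
#'
#' @name code_tables
NULL

STOP_SYMBOL <- "*"

#' Construct a genetic code object
#'
#' @param assignments named character vector: names are the 64 codons
#'   (T/C/A/G alphabet, case-insensitive, U tolerated), values are one-letter
#'   amino-acid symbols or `"*"` for stop.
#' @param name free-text label stored with the code.
#' @return an object of class `genetic_code` (named character vector of
#'   length 64 in canonical codon order).
#' @export
genetic_code <- function(assignments, name = "code") {
  if (is.null(names(assignments)) || length(assignments) != 64L) {
    stop("`assignments` must be a named vector with 64 codon entries")
  }
  codons <- .canon_codon(names(assignments))
  if (anyDuplicated(codons)) {
    stop("duplicated codon(s): ",
         paste(unique(codons[duplicated(codons)]), collapse = ", "))
  }
  vals <- toupper(as.character(assignments))
  ok <- vals %in% c(rownames(atom_table()), STOP_SYMBOL)
  if (!all(ok)) {
    stop("invalid amino-acid symbol(s): ", paste(unique(vals[!ok]), collapse = ", "))
  }
  out <- vals[match(.codons(), codons)]
  if (anyNA(out)) {
    stop("missing codon(s): ", paste(setdiff(.codons(), codons), collapse = ", "))
  }
  names(out) <- .codons()
  structure(out, class = "genetic_code", name = name)
}

#' The standard genetic code
#'
#' @return a `genetic_code` with 61 sense codons and stop set
#'   \{TAA, TAG, TGA\}.
#' @examples
#' code <- standard_code()
#' code[["TGG"]]           # "W"
#' sum(code != "*")        # 61 sense codons
#' @export
standard_code <- function() {
  if (is.null(.cc_cache$sgc)) {
    .cc_cache$sgc <- genetic_code(Biostrings::GENETIC_CODE, name = "SGC")
  }
  .cc_cache$sgc
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> ", attr(x, "name"), ": ",
      sum(x != STOP_SYMBOL), " sense codons, stops {",
      paste(stop_codons(x), collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Sense and stop codons of a code
#' @param code a `genetic_code`.
#' @return character vector of codons.
#' @export
sense_codons <- function(code) names(code)[code != STOP_SYMBOL]

#' @rdname sense_codons
#' @export
stop_codons <- function(code) names(code)[code == STOP_SYMBOL]

#' Packaged elemental composition tables
#'
#' `atom_table()` returns the per-amino-acid carbon and nitrogen atom counts
#' (columns `n_C`, `n_N`, plus the molecular formula of the free amino acid
#' they were derived from), rownames = one-letter symbols. Counts follow the
#' free amino acid's molecular formula; for C and N these equal the
#' residue-in-peptide counts, since peptide-bond formation removes only H2O.
#'
#' @return data.frame with rownames the 20 one-letter amino-acid symbols.
#' @export
atom_table <- function() {
  if (is.null(.cc_cache$atoms)) {
    path <- system.file("extdata", "amino_acid_atoms.tsv", package = "codoncost",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab$aa
    .cc_cache$atoms <- tab
  }
  .cc_cache$atoms
}

#' @rdname atom_table
#' @export
nucleotide_atom_table <- function() {
  if (is.null(.cc_cache$nt_atoms)) {
    path <- system.file("extdata", "nucleotide_atoms.tsv", package = "codoncost",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab$base
    .cc_cache$nt_atoms <- tab
  }
  .cc_cache$nt_atoms
}

#' Atom count of the amino acid encoded by a codon
#'
#' Returns the nitrogen count, carbon count, or their (optionally weighted)
#' sum for the amino acid a codon encodes under `code`. Stop codons have no
#' amino acid; they are an error unless `stop_as_zero = TRUE`, in which case
#' they count 0 atoms (the convention used by the stop-inclusive cost
#' variants).
#'
#' @param code a `genetic_code`.
#' @param codon length-3 codon string (case-insensitive, U tolerated).
#' @param element `"N"`, `"C"`, or `"CN"` (combined; see `cn_weights`).
#' @param stop_as_zero treat stop codons as zero-atom states instead of
#'   erroring.
#' @param cn_weights numeric length-2 `c(N = , C = )` weights for the
#'   combined element; default equal weight (plain atom sum).
#' @return a single non-negative number.
#' @examples
#' atom_count(standard_code(), "CGT", "N")  # arginine: 4
#' atom_count(standard_code(), "GGT", "C")  # glycine: 2
#' atom_count(standard_code(), "TAA", "N", stop_as_zero = TRUE)  # 0
#' @export
atom_count <- function(code, codon, element = c("N", "C", "CN"),
                       stop_as_zero = FALSE, cn_weights = c(N = 1, C = 1)) {
  element <- match.arg(element)
  codon <- .canon_codon(codon)
  stopifnot(length(codon) == 1L)
  aa <- code[[codon]]
  if (identical(aa, STOP_SYMBOL)) {
    if (!stop_as_zero) {
      stop("codon ", codon, " is a stop codon under this code; ",
           "set stop_as_zero = TRUE only for the stop-inclusive variants")
    }
    return(0)
  }
  .aa_atoms(aa, element, cn_weights)
}

#' @noRd
.aa_atoms <- function(aa, element, cn_weights = c(N = 1, C = 1)) {
  tab <- atom_table()
  switch(element,
    N  = tab[aa, "n_N"],
    C  = tab[aa, "n_C"],
    CN = cn_weights[["N"]] * tab[aa, "n_N"] + cn_weights[["C"]] * tab[aa, "n_C"]
  )
}

# Per-codon atom-count vector over all 64 codons; stops get 0 when
# stop_as_zero, NA otherwise (callers restricting to sense codons never see
# the NAs).
#' @noRd
.atom_vector <- function(code, element, stop_as_zero = FALSE,
                         cn_weights = c(N = 1, C = 1)) {
  n <- .aa_atoms(ifelse(code == STOP_SYMBOL, "A", code), element, cn_weights)
  n[code == STOP_SYMBOL] <- if (stop_as_zero) 0 else NA_real_
  names(n) <- names(code)
  n
}

#' Classify a single-nucleotide change between two codons
#'
#' @param i,j length-3 codons over T/C/A/G (case-insensitive, U tolerated).
#' @return `"transition"` (one position differs, purine–purine or
#'   pyrimidine–pyrimidine), `"transversion"` (one position differs,
#'   otherwise), or `"not_single_point"` (0 or >= 2 positions differ).
#' @examples
#' mutation_class("AAA", "AAG")  # transition
#' mutation_class("AAA", "AAT")  # transversion
#' @export
mutation_class <- function(i, j) {
  i <- .canon_codon(i); j <- .canon_codon(j)
  stopifnot(length(i) == 1L, length(j) == 1L)
  ci <- strsplit(i, "")[[1]]; cj <- strsplit(j, "")[[1]]
  d <- which(ci != cj)
  if (length(d) != 1L) return("not_single_point")
  purine <- c("A", "G")
  same_class <- (ci[d] %in% purine) == (cj[d] %in% purine)
  if (same_class) "transition" else "transversion"
}

# 64 x 64 logical matrices marking transition / transversion pairs, built
# once per session.
#' @noRd
.mutation_class_matrices <- function() {
  if (is.null(.cc_cache$ts_matrix)) {
    codons <- .codons()
    ch <- do.call(rbind, strsplit(codons, ""))
    purine <- ch %in% c("A", "G")
    dim(purine) <- dim(ch)
    ndiff <- matrix(0L, 64, 64)
    ts_at <- matrix(FALSE, 64, 64)
    for (p in 1:3) {
      diff_p <- outer(ch[, p], ch[, p], "!=")
      ndiff <- ndiff + diff_p
      same_class_p <- outer(purine[, p], purine[, p], "==")
      ts_at <- ts_at | (diff_p & same_class_p)
    }
    single <- ndiff == 1L
    ts <- single & ts_at
    tv <- single & !ts_at
    dimnames(ts) <- dimnames(tv) <- list(codons, codons)
    .cc_cache$ts_matrix <- ts
    .cc_cache$tv_matrix <- tv
  }
  list(ts = .cc_cache$ts_matrix, tv = .cc_cache$tv_matrix)
}

#' Nitrogen atoms in a Watson–Crick base pair
#'
#' Totals from the molecular formulas of the paired bases: a G:C pair
#' (guanine C5H5N5O + cytosine C4H5N3O) holds 8 nitrogen atoms, an A:T pair
#' (adenine C5H5N5 + thymine C5H6N2O2) 7 — the one-atom difference behind
#' nitrogen-driven selection on genomic GC content.
#'
#' @param pair `"GC"` or `"AT"`.
#' @return integer nitrogen atom count of the pair.
#' @examples
#' base_pair_nitrogen("GC")  # 8
#' base_pair_nitrogen("AT")  # 7
#' @export
base_pair_nitrogen <- function(pair = c("GC", "AT")) {
  pair <- match.arg(toupper(pair), c("GC", "AT"))
  nt <- nucleotide_atom_table()
  b <- strsplit(pair, "")[[1]]
  as.integer(nt[b[1], "n_N"] + nt[b[2], "n_N"])
}

#' Read / write a genetic code as two-column tabular text
#'
#' The on-disk format is a 64-row table with columns `codon` and `symbol`
#' (stop spelled `"*"`), tab- or comma-separated, header optional.
#'
#' @param path file path.
#' @param code a `genetic_code`.
#' @param name label for the code read in.
#' @return `read_genetic_code`: a `genetic_code`; `write_genetic_code`:
#'   the path, invisibly.
#' @export
read_genetic_code <- function(path, name = basename(path)) {
  tab <- .read_two_col(path, c("codon", "symbol"))
  assignments <- stats::setNames(tab[[2]], tab[[1]])
  genetic_code(assignments, name = name)
}

#' @rdname read_genetic_code
#' @export
write_genetic_code <- function(code, path) {
  utils::write.table(
    data.frame(codon = names(code), symbol = as.character(code)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared two-column reader (genetic codes, frequency tables): sniffs the
# separator and an optional header.
#' @noRd
.read_two_col <- function(path, default_names) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  header <- grepl("codon", first, ignore.case = TRUE)
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE, comment.char = "#",
                           strip.white = TRUE)
  if (ncol(tab) < 2L) stop("expected two columns in ", path)
  tab <- tab[, 1:2]
  names(tab) <- default_names
  tab
}
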