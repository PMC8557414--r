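#' Codon frequency tables
#'
#' A `codon_freq_table` stores one species' relative codon frequencies over
#' either the 61 sense codons of the SGC (`codon_set = "sense61"`) or all 64
#' codons (`"all64"`), together with provenance: where the frequencies came
#' from and how many codons were counted.
#'
#' @param freqs named non-negative numeric vector over the declared codon
#'   set; renormalized to sum to 1.
#' @param species label.
#' @param codon_set `"sense61"` or `"all64"`.
#' @param source one of `"counted_from_cds"`, `"file"`, `"synthetic"`.
#' @param n_codons_counted number of codons behind the frequencies (0 when
#'   not counted).
#' @return an object of class `codon_freq_table`.
#' @export
codon_freq_table <- function(freqs, species = "species",
                             codon_set = c("sense61", "all64"),
                             source = c("file", "counted_from_cds", "synthetic"),
                             n_codons_counted = 0L) {
  codon_set <- match.arg(codon_set)
  source <- match.arg(source)
  expected <- switch(codon_set,
                     sense61 = sense_codons(standard_code()),
                     all64 = .codons())
  if (is.null(names(freqs))) stop("`freqs` must be a named vector")
  names(freqs) <- .canon_codon(names(freqs))
  if (anyDuplicated(names(freqs))) {
    stop("duplicate codon: ",
         paste(unique(names(freqs)[duplicated(names(freqs))]), collapse = ", "))
  }
  missing <- setdiff(expected, names(freqs))
  if (length(missing)) {
    stop("missing codon: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(freqs), expected)
  if (length(extra)) {
    stop("unexpected codon for codon_set '", codon_set, "': ",
         paste(extra, collapse = ", "))
  }
  f <- as.numeric(freqs[expected])
  if (any(!is.finite(f)) || any(f < 0)) {
    bad <- expected[!is.finite(f) | f < 0]
    stop("negative or non-finite value at codon: ", paste(bad, collapse = ", "))
  }
  tot <- sum(f)
  if (tot <= 0) stop("all frequencies are zero")
  structure(
    list(species = species,
         freqs = stats::setNames(f / tot, expected),
         codon_set = codon_set,
         source = source,
         n_codons_counted = as.integer(n_codons_counted)),
    class = "codon_freq_table")
}

#' @export
print.codon_freq_table <- function(x, ...) {
  cat("<codon_freq_table> ", x$species, ": ", length(x$freqs), " codons (",
      x$codon_set, "), source = ", x$source,
      if (x$n_codons_counted > 0) paste0(", n = ", x$n_codons_counted) else "",
      "\n", sep = "")
  invisible(x)
}

#' Count codons in coding sequences
#'
#' Reads each record in frame from its first base in non-overlapping
#' triplets. Records whose length is not a multiple of 3 are rejected (and
#' reported); triplets with characters outside T/C/A/G (after U -> T) are
#' skipped and tallied; a terminal stop codon is excluded from the counts;
#' internal stop codons are tallied in the diagnostics and excluded from the
#' sense-codon counts.
#'
#' @param records a [Biostrings::DNAStringSet], or a (possibly named)
#'   character vector of nucleotide sequences.
#' @param code genetic code used to recognize stop codons.
#' @return list with `counts` (named integer vector over the 61 sense
#'   codons) and `diagnostics` (records seen/rejected, rejected ids,
#'   ambiguous-triplet and internal/terminal-stop tallies).
#' @export
count_codons_from_cds <- function(records, code = standard_code()) {
  if (inherits(records, "DNAStringSet")) records <- as.character(records)
  if (length(records) == 0L) stop("no sequence records supplied")
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("record_", seq_along(records))
  seqs <- chartr("u", "U", toupper(records))
  seqs <- chartr("U", "T", seqs)

  stops <- stop_codons(code)
  sense <- sense_codons(code)
  counts <- stats::setNames(integer(length(sense)), sense)
  n_ambiguous <- 0L; n_internal_stop <- 0L; n_terminal_stop <- 0L
  rejected <- character(0)

  for (k in seq_along(seqs)) {
    s <- seqs[[k]]
    len <- nchar(s)
    if (len %% 3L != 0L || len == 0L) {
      rejected <- c(rejected, ids[k])
      message("rejecting record '", ids[k], "': length ", len,
              " is not a multiple of 3")
      next
    }
    cods <- substring(s, seq(1L, len - 2L, by = 3L), seq(3L, len, by = 3L))
    ambiguous <- grepl("[^TCAG]", cods)
    n_ambiguous <- n_ambiguous + sum(ambiguous)
    cods <- cods[!ambiguous]
    if (length(cods) && cods[length(cods)] %in% stops) {
      n_terminal_stop <- n_terminal_stop + 1L
      cods <- cods[-length(cods)]
    }
    is_stop <- cods %in% stops
    n_internal_stop <- n_internal_stop + sum(is_stop)
    tab <- table(cods[!is_stop])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (length(rejected) == length(seqs)) stop("all records were rejected")
  list(counts = counts,
       diagnostics = list(
         n_records = length(seqs),
         n_rejected = length(rejected),
         rejected_ids = rejected,
         n_ambiguous_triplets = n_ambiguous,
         n_internal_stops = n_internal_stop,
         n_terminal_stops = n_terminal_stop))
}

#' Normalize codon counts into a frequency table
#'
#' @param counts named non-negative numeric vector of codon counts (codons
#'   outside `codon_set` are dropped; codons of the set missing from
#'   `counts` get 0).
#' @param codon_set `"sense61"` or `"all64"`.
#' @param species,source,n_codons_counted passed to [codon_freq_table()];
#'   `n_codons_counted` defaults to `sum(counts)` within the set.
#' @return a `codon_freq_table`.
#' @export
normalize_codon_counts <- function(counts, codon_set = c("sense61", "all64"),
                                   species = "species",
                                   source = "counted_from_cds",
                                   n_codons_counted = NULL) {
  codon_set <- match.arg(codon_set)
  if (is.null(names(counts))) stop("`counts` must be a named vector")
  names(counts) <- .canon_codon(names(counts))
  expected <- switch(codon_set,
                     sense61 = sense_codons(standard_code()),
                     all64 = .codons())
  full <- stats::setNames(numeric(length(expected)), expected)
  keep <- intersect(names(counts), expected)
  full[keep] <- full[keep] + as.numeric(counts[keep])
  if (sum(full) <= 0) stop("no positive counts within the requested codon set")
  if (is.null(n_codons_counted)) n_codons_counted <- sum(full)
  codon_freq_table(full, species = species, codon_set = codon_set,
                   source = source, n_codons_counted = n_codons_counted)
}

#' Read a codon frequency table from tabular text
#'
#' Accepts a two-column (codon, value) file, tab- or comma-separated,
#' header optional; values may be counts or frequencies and are
#' renormalized. The file must cover exactly the 61 SGC sense codons or all
#' 64 codons.
#'
#' @param path file path.
#' @param species label (defaults to the file name without extension).
#' @return a `codon_freq_table`.
#' @export
read_frequency_table <- function(path, species = NULL) {
  if (is.null(species)) species <- sub("\\.[^.]*$", "", basename(path))
  tab <- .read_two_col(path, c("codon", "value"))
  codons <- .canon_codon(tab$codon)
  if (anyDuplicated(codons)) {
    stop("duplicate codon: ",
         paste(unique(codons[duplicated(codons)]), collapse = ", "))
  }
  vals <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(vals)) stop("non-numeric value at codon: ",
                        paste(codons[is.na(vals)], collapse = ", "))
  if (any(vals < 0)) stop("negative value at codon: ",
                          paste(codons[vals < 0], collapse = ", "))
  codon_set <- if (length(codons) == 64L) "all64" else "sense61"
  codon_freq_table(stats::setNames(vals, codons), species = species,
                   codon_set = codon_set, source = "file")
}

#' Write a codon frequency table to tab-separated text
#' @param freqs a `codon_freq_table`.
#' @param path file path.
#' @export
write_frequency_table <- function(freqs, path) {
  utils::write.table(
    data.frame(codon = names(freqs$freqs), frequency = unname(freqs$freqs)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Frequencies over the sense codons of `code`, from a table on either codon
# set. For an all64 table the stop rows of *the SGC sense set's complement*
# are dropped and the remainder renormalized when renormalize = TRUE.
# For 64-codon cost variants (.freq64) a sense61 table gets frequency 0 at
# the three SGC stop codons, without renormalization.
#' @noRd
.freq64 <- function(freqs) {
  f <- stats::setNames(numeric(64L), .codons())
  f[names(freqs$freqs)] <- freqs$freqs
  f
}

#' Correlation between codon usage and encoded atom content
#'
#' Pearson's correlation, across the sense codons of `code`, between the
#' relative frequency of each codon and the nitrogen (or carbon, or
#' combined) atom count of the amino acid it encodes. Stop-codon rows of an
#' all-64 table are dropped and the remainder renormalized (the correlation
#' itself is scale-invariant).
#'
#' @param freqs a `codon_freq_table` (or named numeric vector covering the
#'   sense codons).
#' @param code a `genetic_code`.
#' @param element `"N"`, `"C"`, or `"CN"`.
#' @param cn_weights weights for the combined element, as in [atom_count()].
#' @return correlation in \[-1, 1\].
#' @export
usage_atom_correlation <- function(freqs, code = standard_code(),
                                   element = c("N", "C", "CN"),
                                   cn_weights = c(N = 1, C = 1)) {
  element <- match.arg(element)
  if (inherits(freqs, "codon_freq_table")) {
    fv <- freqs$freqs
  } else {
    fv <- freqs
    names(fv) <- .canon_codon(names(fv))
  }
  sense <- sense_codons(code)
  missing <- setdiff(sense, names(fv))
  if (length(missing)) {
    stop("frequency table does not cover sense codon(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  f <- as.numeric(fv[sense])
  n <- .atom_vector(code, element, stop_as_zero = TRUE, cn_weights)[sense]
  if (stats::sd(n) == 0) stop("atom counts have zero variance across sense codons")
  if (stats::sd(f) == 0) {
    stop("undefined correlation: codon frequencies have zero variance")
  }
  stats::cor(f, n)
}
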