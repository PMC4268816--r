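#' Construct a codon count table
#'
#' A `codon_counts` object is a named integer vector over the 61 sense
#' codons (DNA spelling, zeros included), with a `source_ids` attribute
#' listing the gene ids the counts were accumulated from. Counts supplied
#' in RNA spelling are accepted.
#'
#' @param counts named numeric vector of non-negative codon counts; codons
#'   not mentioned get zero. Stop codons are not allowed.
#' @param source_ids character vector of contributing gene ids.
#' @return An object of class `codon_counts`.
#' @examples
#' codon_counts(c(UUU = 99671, UUC = 106107))
#' @export
codon_counts <- function(counts, source_ids = character(0L)) {
  code <- genetic_code()
  if (is.null(names(counts)) && length(counts) > 0L) {
    stop("'counts' must be a named vector of codon counts", call. = FALSE)
  }
  nm <- toupper(rna_to_dna(names(counts)))
  bad <- setdiff(nm, code$sense_codons)
  if (length(bad)) {
    stop("not sense codons: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicated codon names in 'counts'", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative codon counts", call. = FALSE)
  out <- stats::setNames(numeric(61L), code$sense_codons)
  out[nm] <- as.numeric(counts)
  structure(out, source_ids = as.character(source_ids),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts:", format(sum(x), big.mark = ","), "codons",
      "from", length(attr(x, "source_ids")), "source id(s)\n")
  invisible(x)
}

#' Total number of codons in a count table
#'
#' @param counts a [codon_counts()] table.
#' @return The sum of all codon counts.
#' @export
total_codons <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  sum(unclass(counts))
}

#' Count the codons of a coding sequence
#'
#' Splits the sequence into non-overlapping triplets from position 1 and
#' tallies the sense codons. Codons containing `N` are skipped entirely
#' (they contribute to no index in this package) and a terminal stop codon
#' is not counted.
#'
#' @param seq a DNA string whose length is a multiple of 3, or a one-row
#'   subset of a [cds_set()].
#' @param id gene id recorded in `source_ids`.
#' @param code a [genetic_code()].
#' @return A [codon_counts()] table.
#' @examples
#' count_codons("ATGTGGTAA")
#' @export
count_codons <- function(seq, id = NA_character_, code = genetic_code()) {
  cod <- split_codons(normalize_nucleotides(seq))
  if (length(cod) > 0L && cod[length(cod)] %in% code$stop_codons) {
    cod <- cod[-length(cod)]
  }
  cod <- cod[!grepl("N", cod, fixed = TRUE)]
  if (any(cod %in% code$stop_codons)) {
    stop("internal stop codon in sequence", if (!is.na(id)) paste0(" '", id, "'"),
         "; run validate_and_filter() first", call. = FALSE)
  }
  tab <- table(factor(cod, levels = code$sense_codons))
  codon_counts(stats::setNames(as.numeric(tab), names(tab)),
               source_ids = if (is.na(id)) character(0L) else id)
}

#' Pool codon count tables elementwise
#'
#' @param ... [codon_counts()] tables, or a single list of them.
#' @return A [codon_counts()] table of elementwise sums, with the
#'   concatenated `source_ids`.
#' @export
pool_counts <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) &&
      !inherits(tabs[[1L]], "codon_counts")) {
    tabs <- tabs[[1L]]
  }
  if (!length(tabs)) stop("nothing to pool", call. = FALSE)
  stopifnot(all(vapply(tabs, inherits, logical(1L), "codon_counts")))
  total <- Reduce(`+`, lapply(tabs, unclass))
  ids <- unlist(lapply(tabs, attr, "source_ids"), use.names = FALSE)
  codon_counts(total, source_ids = ids)
}

#' Count codons for every gene of a CDS set
#'
#' @param set a validated [cds_set()].
#' @param code a [genetic_code()].
#' @return A named list of [codon_counts()] tables, one per gene.
#' @export
count_codons_set <- function(set, code = genetic_code()) {
  stopifnot(inherits(set, "cds_set"))
  out <- lapply(seq_len(nrow(set)), function(i) {
    count_codons(set$seq[i], id = set$id[i], code = code)
  })
  names(out) <- set$id
  out
}

#' Read a codon count table from TSV
#'
#' Reads a two-column tab-separated table with columns `codon` (DNA or RNA
#' spelling) and `count`, e.g. a published codon-usage table of another
#' species for side-by-side RSCU comparison.
#'
#' @param path path to a TSV file.
#' @param codon_col,count_col column names to use.
#' @return A [codon_counts()] table.
#' @export
read_codon_counts_tsv <- function(path, codon_col = "codon",
                                  count_col = "count") {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c(codon_col, count_col) %in% names(x))) {
    stop("expected columns '", codon_col, "' and '", count_col,
         "' in ", path, call. = FALSE)
  }
  codon_counts(stats::setNames(x[[count_col]], x[[codon_col]]),
               source_ids = path)
}
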