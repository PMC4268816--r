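#' Construct a CDS set
#'
#' A `cds_set` is the package's container for coding sequences: a
#' data.frame with columns `id`, `seq` (uppercase DNA) and `length_nt`,
#' carrying a free-text `provenance` attribute. Sequences are normalised to
#' uppercase DNA spelling; IUPAC ambiguity letters other than `N` are
#' replaced by `N`.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of nucleotide sequences (DNA or RNA
#'   spelling, any case).
#' @param provenance free-text label recording where the set came from.
#' @return An object of class `cds_set`.
#' @examples
#' cds_set(c("g1", "g2"), c("atgaaatga", "AUGUUUUAA"))
#' @export
cds_set <- function(id, seq, provenance = "in-memory") {
  id <- as.character(id)
  seq <- normalize_nucleotides(as.character(seq))
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = id, seq = seq, length_nt = nchar(seq),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("cds_set", "data.frame")
  out
}

# Uppercase, map RNA U to T, collapse ambiguity codes to N; reject anything
# outside the nucleotide alphabet.
normalize_nucleotides <- function(seq) {
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  seq <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  seq
}

#' @export
print.cds_set <- function(x, ...) {
  cat("CDS set: ", nrow(x), " records (provenance: ",
      attr(x, "provenance"), ")\n", sep = "")
  if (nrow(x) > 0L) {
    cat("  lengths", min(x$length_nt), "-", max(x$length_nt), "nt\n")
  }
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a
#' [cds_set()]. The record id is the first whitespace-delimited token of
#' the header; sequences are uppercased and RNA `U` is mapped to `T`.
#'
#' @param path path to a FASTA file.
#' @return A [cds_set()]; empty files yield an empty set.
#' @seealso [write_cds_fasta()]
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0L) {
    return(cds_set(character(0L), character(0L), provenance = path))
  }
  if (!startsWith(trimws(lines[meaningful[1L]]), ">")) {
    stop("malformed FASTA in '", path, "': sequence data before first header at line ",
         meaningful[1L], call. = FALSE)
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s) in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  cds_set(ids, as.character(x), provenance = path)
}

#' Write a CDS set to FASTA
#'
#' @param set a [cds_set()].
#' @param path output file path.
#' @param width line-wrap width in nucleotides.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(set, path, width = 60L) {
  stopifnot(inherits(set, "cds_set"))
  x <- Biostrings::BStringSet(stats::setNames(set$seq, set$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Validate and filter coding sequences
#'
#' Applies the CDS quality filter used throughout the package: a record is
#' retained only if it is strictly longer than `min_len_nt` nucleotides,
#' and after trimming any incomplete terminal codon (and a terminal stop
#' codon, if present) it contains no in-frame internal stop codon.
#' Rejections are data, not errors: each rejected record is logged with a
#' reason code.
#'
#' @param set a [cds_set()].
#' @param min_len_nt minimum length in nucleotides; the comparison is
#'   strict (`length > min_len_nt`), so a CDS of exactly `min_len_nt`
#'   nucleotides is rejected.
#' @return A list with elements `retained` (a [cds_set()] of trimmed,
#'   frame-validated sequences whose lengths are multiples of 3 and that
#'   end on a sense codon) and `rejected` (a data.frame with columns `id`,
#'   `length_nt`, `reason`; reasons are `"too_short"` and
#'   `"internal_stop"`).
#' @examples
#' set <- cds_set("g1", paste(rep("ATG", 120), collapse = ""))
#' validate_and_filter(set)$retained
#' @export
validate_and_filter <- function(set, min_len_nt = 300L) {
  stopifnot(inherits(set, "cds_set"))
  code <- genetic_code()
  keep_id <- character(0L)
  keep_seq <- character(0L)
  rej <- list()
  for (i in seq_len(nrow(set))) {
    id <- set$id[i]
    s <- set$seq[i]
    len <- nchar(s)
    if (len <= min_len_nt) {
      rej[[length(rej) + 1L]] <- data.frame(id = id, length_nt = len,
                                            reason = "too_short")
      next
    }
    s <- substr(s, 1L, len - len %% 3L)
    cod <- split_codons(s)
    if (cod[length(cod)] %in% code$stop_codons) {
      cod <- cod[-length(cod)]
    }
    if (any(cod %in% code$stop_codons)) {
      rej[[length(rej) + 1L]] <- data.frame(id = id, length_nt = len,
                                            reason = "internal_stop")
      next
    }
    keep_id <- c(keep_id, id)
    keep_seq <- c(keep_seq, paste(cod, collapse = ""))
  }
  rejected <- if (length(rej)) {
    do.call(rbind, rej)
  } else {
    data.frame(id = character(0L), length_nt = integer(0L),
               reason = character(0L))
  }
  list(
    retained = cds_set(keep_id, keep_seq,
                       provenance = attr(set, "provenance")),
    rejected = rejected
  )
}

#' Write the rejection log of [validate_and_filter()] as TSV
#'
#' @param rejected the `rejected` data.frame from [validate_and_filter()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rejection_log <- function(rejected, path) {
  utils::write.table(rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Translate a coding sequence
#'
#' @param seq a DNA string whose length is a multiple of 3 (e.g. a
#'   sequence retained by [validate_and_filter()]).
#' @param code a [genetic_code()].
#' @return The protein as a character string, one residue per sense codon.
#'   Codons containing `N` translate to `X`; a terminal stop codon is
#'   dropped; an internal stop codon is an error naming its codon position.
#' @examples
#' translate_cds("ATGTGG")
#' translate_cds("ATGNNNTGG")
#' @export
translate_cds <- function(seq, code = genetic_code()) {
  cod <- split_codons(normalize_nucleotides(seq))
  if (length(cod) == 0L) return("")
  if (cod[length(cod)] %in% code$stop_codons) {
    cod <- cod[-length(cod)]
  }
  aa <- unname(code$codon_to_aa[cod])
  aa[is.na(aa)] <- "X"  # codons containing N
  if (any(aa == "*", na.rm = TRUE)) {
    stop("internal stop codon at codon position ",
         which(aa == "*")[1L], call. = FALSE)
  }
  paste(aa, collapse = "")
}
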