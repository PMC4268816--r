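# Environment used to memoise the genetic-code object.
.cubkit <- new.env(parent = emptyenv())

# Standard code (NCBI translation table 1) as a 64-character amino-acid
# string over codons ordered T,C,A,G at each position, slowest first.
.AA64 <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

#' The standard genetic code with synonymous-family structure
#'
#' Builds the standard (nuclear) genetic code as used throughout the
#' package: the codon-to-amino-acid map, the synonymous codon families,
#' their degeneracy classes, and the codon subsets on which the various
#' indices operate. Codons are spelled in DNA (`T`) internally; use
#' [dna_to_rna()] to obtain the RNA spelling used in reports.
#'
#' @return An object of class `"genetic_code"`, a list with elements:
#' \describe{
#'   \item{codon_to_aa}{named character vector of length 64 mapping codons
#'     to one-letter amino acids, with `"*"` for the three stop codons.}
#'   \item{families}{named list mapping each amino acid to its ordered
#'     synonymous codons.}
#'   \item{degeneracy}{named integer vector giving each amino acid's family
#'     size (1, 2, 3, 4 or 6).}
#'   \item{sense_codons}{the 61 non-stop codons.}
#'   \item{analysis_codons}{the 59 codons with a synonymous alternative,
#'     i.e. excluding Met, Trp and stops; this is the codon set used for
#'     GC3s, CAI and correspondence analysis.}
#'   \item{stop_codons}{TAA, TAG, TGA.}
#'   \item{fourfold_families}{list of the eight four-codon boxes (third
#'     position fully degenerate) used by the parity-rule-2 analysis:
#'     Ala, Arg (CGN), Gly, Leu (CTN), Pro, Ser (TCN), Thr and Val.}
#' }
#' @examples
#' gc <- genetic_code()
#' gc$codon_to_aa[["ATG"]]
#' gc$families$L
#' @export
genetic_code <- function() {
  if (!is.null(.cubkit$code)) {
    return(.cubkit$code)
  }
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  aa <- strsplit(.AA64, "")[[1L]]
  names(aa) <- codons

  sense <- codons[aa != "*"]
  families <- split(sense, aa[sense])
  families <- families[order(names(families))]
  degeneracy <- vapply(families, length, integer(1L))

  # Four-codon boxes: groups of 4 synonymous codons sharing their first two
  # bases. Splits the six-fold families into their four-fold sub-boxes.
  boxes <- split(sense, list(substr(sense, 1L, 2L), aa[sense]), drop = TRUE)
  fourfold <- boxes[vapply(boxes, length, integer(1L)) == 4L]
  names(fourfold) <- vapply(fourfold, function(x) substr(x[1L], 1L, 2L), character(1L))

  code <- structure(
    list(
      codon_to_aa = aa,
      families = families,
      degeneracy = degeneracy,
      sense_codons = sense,
      analysis_codons = setdiff(sense, c("ATG", "TGG")),
      stop_codons = codons[aa == "*"],
      fourfold_families = fourfold
    ),
    class = "genetic_code"
  )
  .cubkit$code <- code
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stop codons,",
      length(x$families), "amino acids\n")
  invisible(x)
}

#' Convert codon spelling between DNA and RNA
#'
#' Reports in this package use RNA spelling (`U`) to match the codon-usage
#' literature, while sequences are handled in DNA spelling internally.
#'
#' @param x character vector of codons or sequences.
#' @return `x` with `T` and `U` interchanged (case preserved).
#' @examples
#' dna_to_rna("CTG")
#' rna_to_dna("UUC")
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# Split a DNA string into consecutive non-overlapping codons.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, " nt) is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return(character(0L))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
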