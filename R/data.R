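#' Published codon-usage counts for the Taenia saginata transcriptome
#'
#' Codon counts (and the relative synonymous codon usage computed from
#' them, as published) tabulated across the 11,399 predicted coding
#' sequences of a *Taenia saginata* cysticercus transcriptome survey.
#' The table covers the 61 sense codons except Trp (absent from the
#' published tabulation); codons are in RNA spelling.
#'
#' @return A data.frame with columns `amino_acid`, `codon`, `count`,
#'   `rscu_published`.
#' @seealso [taenia_expression_pools()]
#' @export
taenia_codon_usage <- function() {
  utils::read.delim(
    system.file("extdata", "tsaginata_codon_usage.tsv", package = "cubkit"),
    stringsAsFactors = FALSE
  )
}

#' Published high/low-expression codon pools for Taenia saginata
#'
#' Pooled codon counts and RSCU of the 5 percent of *Taenia saginata*
#' genes with the highest and lowest CAI values, as published, together
#' with the published significance marking (`starred`) of codons used
#' significantly more often in the high-expression pool.
#'
#' @return A data.frame with columns `amino_acid`, `codon`, `rscu_high`,
#'   `count_high`, `rscu_low`, `count_low`, `starred`.
#' @examples
#' pools <- taenia_expression_pools()
#' part <- expression_partition(
#'   codon_counts(setNames(pools$count_high, pools$codon)),
#'   codon_counts(setNames(pools$count_low, pools$codon))
#' )
#' determine_optimal_codons(part)
#' @export
taenia_expression_pools <- function() {
  utils::read.delim(
    system.file("extdata", "tsaginata_expression_pools.tsv",
                package = "cubkit"),
    stringsAsFactors = FALSE
  )
}
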