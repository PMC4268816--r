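#' Build an expression partition from pooled count tables
#'
#' Container for the high/low-expression comparison used by
#' [determine_optimal_codons()]. Usually produced by [partition_by_cai()],
#' but can be constructed directly from pooled codon counts (for example,
#' a published pair of high/low-expression codon-usage tables).
#'
#' @param pooled_high,pooled_low [codon_counts()] tables pooled over the
#'   high- and low-expression gene sets.
#' @param high_ids,low_ids optional member gene ids (must be disjoint).
#' @param fraction the extreme fraction used to form the sets, if known.
#' @return An object of class `expression_partition`.
#' @export
expression_partition <- function(pooled_high, pooled_low,
                                 high_ids = attr(pooled_high, "source_ids"),
                                 low_ids = attr(pooled_low, "source_ids"),
                                 fraction = NA_real_) {
  stopifnot(inherits(pooled_high, "codon_counts"),
            inherits(pooled_low, "codon_counts"))
  if (length(intersect(high_ids, low_ids))) {
    stop("high and low gene sets overlap", call. = FALSE)
  }
  structure(
    list(high_ids = high_ids, low_ids = low_ids, fraction = fraction,
         pooled_high = pooled_high, pooled_low = pooled_low),
    class = "expression_partition"
  )
}

#' @export
print.expression_partition <- function(x, ...) {
  cat("Expression partition:", length(x$high_ids), "high /",
      length(x$low_ids), "low genes",
      if (!is.na(x$fraction)) sprintf("(extreme fraction %.2f)", x$fraction),
      "\n")
  invisible(x)
}

#' Partition genes into CAI-defined expression extremes
#'
#' Sorts genes by CAI and takes the top and bottom `floor(fraction * N)`
#' (at least one gene each) as the putative high- and low-expression
#' sets, pooling their codon counts. CAI ties are broken lexicographically
#' by gene id so the partition is reproducible.
#'
#' @param set the validated [cds_set()] the indices were computed from.
#' @param indices data.frame from [codon_usage_indices()] with a non-`NA`
#'   `cai` column.
#' @param fraction extreme fraction on each side (default 0.05, i.e. the
#'   5 percent tails).
#' @param code a [genetic_code()].
#' @return An [expression_partition()].
#' @export
partition_by_cai <- function(set, indices, fraction = 0.05,
                             code = genetic_code()) {
  d <- indices[!is.na(indices$cai), ]
  if (nrow(d) < 2L) stop("need at least 2 genes with defined CAI",
                         call. = FALSE)
  k <- max(1L, floor(fraction * nrow(d)))
  ord <- order(-d$cai, d$id)
  high_ids <- d$id[ord][seq_len(k)]
  low_ids <- d$id[order(d$cai, d$id)][seq_len(k)]
  if (length(intersect(high_ids, low_ids))) {
    stop("high and low tails overlap; use a smaller 'fraction'",
         call. = FALSE)
  }
  pool_of <- function(ids) {
    sub <- set[match(ids, set$id), , drop = FALSE]
    pool_counts(count_codons_set(structure(sub, class = class(set)), code))
  }
  expression_partition(pool_of(high_ids), pool_of(low_ids),
                       high_ids = high_ids, low_ids = low_ids,
                       fraction = fraction)
}

#' Chi-square test for one codon between expression pools
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' of codon-versus-rest-of-family counts in the high and low pools: the
#' family-conditional test of whether the codon's synonymous share
#' differs between pools.
#'
#' @param codon the codon to test (DNA or RNA spelling).
#' @param pooled_high,pooled_low [codon_counts()] tables.
#' @param code a [genetic_code()].
#' @return A list with `chi2` and `p_value`; both `NA` when any margin of
#'   the 2x2 table is zero (the test is undefined).
#' @export
codon_chi_square <- function(codon, pooled_high, pooled_low,
                             code = genetic_code()) {
  codon <- toupper(rna_to_dna(codon))
  aa <- code$codon_to_aa[[codon]]
  if (is.na(aa) || aa == "*") stop("not a sense codon: ", codon, call. = FALSE)
  fam <- code$families[[aa]]
  hi <- unclass(pooled_high)[fam]
  lo <- unclass(pooled_low)[fam]
  tab <- matrix(c(hi[[codon]], sum(hi) - hi[[codon]],
                  lo[[codon]], sum(lo) - lo[[codon]]),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("high", "low"), c("codon", "rest")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = NA_real_, p_value = NA_real_))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), p_value = ht$p.value)
}

#' Determine optimal codons from an expression partition
#'
#' For each of the 59 analysis codons, compares its family-conditional
#' usage between the high- and low-expression pools with
#' [codon_chi_square()] and computes the pool RSCU values. A codon is
#' flagged optimal iff its usage is significantly different (p below
#' `alpha`) and its RSCU is higher in the high-expression pool. Met and
#' Trp, having no synonymous alternative, are never flagged.
#'
#' @param partition an [expression_partition()].
#' @param code a [genetic_code()].
#' @param alpha significance level on the raw p-value (default 0.01).
#' @param bonferroni if `TRUE`, apply a Bonferroni correction across the
#'   tested codons before thresholding (off by default: the conventional
#'   rule in the codon-usage literature is a raw p cutoff).
#' @return An object of class `optimal_codon_report`: a data.frame with
#'   one row per analysis codon and columns `codon` (RNA spelling),
#'   `amino_acid`, `rscu_high`, `count_high`, `rscu_low`, `count_low`,
#'   `chi2`, `p_value`, `optimal`.
#' @export
determine_optimal_codons <- function(partition, code = genetic_code(),
                                     alpha = 0.01, bonferroni = FALSE) {
  stopifnot(inherits(partition, "expression_partition"))
  hi <- partition$pooled_high
  lo <- partition$pooled_low
  if (total_codons(hi) == 0 || total_codons(lo) == 0) {
    stop("pooled count tables must be non-empty", call. = FALSE)
  }
  rscu_hi <- rscu(hi, code)
  rscu_lo <- rscu(lo, code)
  codons <- code$analysis_codons
  tests <- lapply(codons, codon_chi_square, pooled_high = hi,
                  pooled_low = lo, code = code)
  chi2 <- vapply(tests, `[[`, numeric(1L), "chi2")
  p <- vapply(tests, `[[`, numeric(1L), "p_value")
  p_crit <- if (bonferroni) alpha / sum(!is.na(p)) else alpha
  out <- data.frame(
    codon = dna_to_rna(codons),
    amino_acid = unname(code$codon_to_aa[codons]),
    rscu_high = unname(rscu_hi[codons]),
    count_high = unname(unclass(hi)[codons]),
    rscu_low = unname(rscu_lo[codons]),
    count_low = unname(unclass(lo)[codons]),
    chi2 = chi2,
    p_value = p,
    stringsAsFactors = FALSE
  )
  out$optimal <- !is.na(out$p_value) & out$p_value < p_crit &
    !is.na(out$rscu_high) & !is.na(out$rscu_low) &
    out$rscu_high > out$rscu_low
  class(out) <- c("optimal_codon_report", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "bonferroni") <- bonferroni
  out
}

#' @export
print.optimal_codon_report <- function(x, ...) {
  opt <- x$codon[x$optimal]
  cat(length(opt), "optimal codon(s) at alpha =", attr(x, "alpha"), "\n")
  if (length(opt)) cat("  ", paste(sort(opt), collapse = " "), "\n")
  invisible(x)
}

#' Write the optimal-codon report as TSV
#'
#' @param report an `optimal_codon_report` from
#'   [determine_optimal_codons()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_optimal_report <- function(report, path) {
  out <- as.data.frame(report)
  out$optimal <- as.integer(out$optimal)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
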