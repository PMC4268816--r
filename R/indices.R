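#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' every synonym of its amino acid were used equally: for codon i of an
#' amino acid with n synonymous codons and family counts g,
#' `RSCU_i = n * g_i / sum(g)`. Values above 1 mark codons used more often
#' than expected, below 1 less often; 1 means no bias. Methionine and
#' tryptophan, having a single codon, are 1 whenever observed.
#'
#' @param counts a [codon_counts()] table.
#' @param code a [genetic_code()].
#' @param as_rna if `TRUE`, name the result in RNA spelling.
#' @return A named numeric vector over the 61 sense codons; families with
#'   zero total usage yield `NA` (RSCU undefined).
#' @examples
#' rscu(codon_counts(c(UUU = 99671, UUC = 106107)))[c("TTT", "TTC")]
#' @export
rscu <- function(counts, code = genetic_code(), as_rna = FALSE) {
  stopifnot(inherits(counts, "codon_counts"))
  x <- unclass(counts)
  out <- stats::setNames(rep(NA_real_, length(x)), names(x))
  for (fam in code$families) {
    tot <- sum(x[fam])
    if (tot > 0) {
      out[fam] <- length(fam) * x[fam] / tot
    }
  }
  if (as_rna) names(out) <- dna_to_rna(names(out))
  out
}

#' Codon homozygosity of one synonymous family
#'
#' Wright's estimator of the "codon homozygosity" F of a synonymous
#' family, the quantity averaged per degeneracy class by the effective
#' number of codons: with family total n and usage proportions p,
#' `F = (n * sum(p^2) - 1) / (n - 1)`.
#'
#' @param family_counts numeric vector of codon counts within one
#'   synonymous family.
#' @return F in \[0, 1\], or `NA` when the family total is 0 or 1 (the
#'   estimator is undefined).
#' @examples
#' family_homozygosity(c(3, 1))   # 0.5
#' family_homozygosity(c(2, 2))   # 1/3
#' @export
family_homozygosity <- function(family_counts) {
  n <- sum(family_counts)
  if (n <= 1) return(NA_real_)
  p <- family_counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

# Degeneracy classes used by Wright's ENC: number of amino acids per class.
.ENC_CLASS_SIZES <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)

#' Observed effective number of codons (ENC)
#'
#' Wright's ENC summarises how far a gene departs from uniform synonymous
#' codon usage. Codon homozygosity F is estimated per synonymous family
#' (see [family_homozygosity()]) and averaged within each degeneracy class
#' (nine two-fold, one three-fold, five four-fold and three six-fold amino
#' acids); then `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. ENC ranges from 20,
#' when exactly one codon is used per amino acid, to 61, when all
#' synonyms are used equally; estimates above 61 are capped at 61.
#'
#' If the three-fold class (Ile) is unobserved its mean is imputed as the
#' average of the two-fold and four-fold class means; if any other class
#' mean is undefined or zero, ENC is reported as `NA`.
#'
#' @param counts a [codon_counts()] table for one gene (or pool).
#' @param code a [genetic_code()].
#' @return ENC in \[20, 61\], or `NA` when it cannot be estimated.
#' @export
enc_observed <- function(counts, code = genetic_code()) {
  stopifnot(inherits(counts, "codon_counts"))
  x <- unclass(counts)
  fhat <- vapply(code$families, function(fam) {
    if (length(fam) == 1L) NA_real_ else family_homozygosity(x[fam])
  }, numeric(1L))
  deg <- code$degeneracy
  fbar <- vapply(names(.ENC_CLASS_SIZES), function(k) {
    v <- fhat[deg == as.integer(k)]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  if (is.na(fbar[["3"]]) &&
      !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- mean(c(fbar[["2"]], fbar[["4"]]))
  }
  if (any(is.na(fbar)) || any(fbar == 0)) return(NA_real_)
  enc <- 2 + sum(.ENC_CLASS_SIZES / fbar)
  min(enc, 61)
}

#' Expected ENC under GC3s-driven mutation bias alone
#'
#' Wright's null curve for the ENC of a gene whose codon usage is shaped
#' only by the G+C content at synonymous third positions (s):
#' `ENC_exp = 2 + s + 29 / (s^2 + (1 - s)^2)`, capped at 61. The curve
#' equals 31 at s = 0, rises above 60 near s = 0.5, and falls to 32 at
#' s = 1. This is the standard form of the expression: the variant with
#' denominator `s^2 + (1 - s^2)` sometimes seen in print peaks near 31.5
#' and cannot reproduce the near-61 ENC values observed at intermediate
#' GC3s, so it is treated as a typographical corruption of `(1 - s)^2`.
#'
#' @param s GC3s fraction(s) in \[0, 1\].
#' @return Expected ENC, vectorised over `s`.
#' @examples
#' enc_expected(c(0, 0.5, 1))  # 31, 60.5, 32
#' @export
enc_expected <- function(s) {
  if (any(is.na(s)) || any(s < 0 | s > 1)) {
    stop("'s' must lie in [0, 1]", call. = FALSE)
  }
  pmin(2 + s + 29 / (s^2 + (1 - s)^2), 61)
}

#' Positional GC content of a coding sequence
#'
#' Computes the G+C fraction at each codon position over the sense codons
#' of a validated CDS: GC1, GC2, GC3, their first/second-position average
#' GC12 = (GC1 + GC2) / 2, the overall GC content, and GC3s, the G+C
#' fraction at third positions of the 59 synonymously variable codons only
#' (Met, Trp and stops excluded). Codons containing `N` are excluded from
#' numerator and denominator alike.
#'
#' GC3 and GC3s are deliberately distinct quantities: the neutrality plot
#' uses GC3 over all sense codons, while the ENC-GC3s curve and the
#' ordination correlations use GC3s.
#'
#' @param seq a validated DNA coding sequence (length a multiple of 3).
#' @param code a [genetic_code()].
#' @return A named numeric vector with elements `gc1`, `gc2`, `gc3`,
#'   `gc3s`, `gc12`, `gc_all`.
#' @export
gc_metrics <- function(seq, code = genetic_code()) {
  cod <- split_codons(normalize_nucleotides(seq))
  if (length(cod) > 0L && cod[length(cod)] %in% code$stop_codons) {
    cod <- cod[-length(cod)]
  }
  cod <- cod[!grepl("N", cod, fixed = TRUE)]
  cod <- cod[!(cod %in% code$stop_codons)]
  if (!length(cod)) {
    return(c(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
             gc3s = NA_real_, gc12 = NA_real_, gc_all = NA_real_))
  }
  pos_gc <- function(codons, k) {
    if (!length(codons)) return(NA_real_)
    mean(substr(codons, k, k) %in% c("G", "C"))
  }
  gc1 <- pos_gc(cod, 1L)
  gc2 <- pos_gc(cod, 2L)
  gc3 <- pos_gc(cod, 3L)
  gc3s <- pos_gc(cod[cod %in% code$analysis_codons], 3L)
  c(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc3s = gc3s,
    gc12 = (gc1 + gc2) / 2, gc_all = mean(c(gc1, gc2, gc3)))
}

#' Relative adaptiveness weights for the codon adaptation index
#'
#' From the pooled codon counts of a reference set of highly expressed
#' genes (classically, ribosomal-protein genes), computes each codon's
#' relative adaptiveness `w = RSCU / max RSCU within its synonymous
#' family`, so the most-used codon of every family has w = 1 exactly.
#' Codons unobserved in the reference receive a pseudocount before the
#' ratio is formed, keeping every w strictly positive so that the CAI
#' geometric mean stays finite.
#'
#' @param reference a [codon_counts()] table pooled over the reference
#'   genes.
#' @param code a [genetic_code()].
#' @param pseudocount count added to unobserved codons (default 0.5).
#' @return An object of class `cai_weights`: a named numeric vector over
#'   the 59 analysis codons (Met, Trp and stops excluded), with attribute
#'   `reference_ids`.
#' @export
cai_weights <- function(reference, code = genetic_code(), pseudocount = 0.5) {
  stopifnot(inherits(reference, "codon_counts"))
  if (total_codons(reference) == 0) {
    stop("reference count table is empty", call. = FALSE)
  }
  x <- unclass(reference)
  x[x == 0] <- pseudocount
  w <- stats::setNames(rep(NA_real_, length(code$analysis_codons)),
                       code$analysis_codons)
  for (fam in code$families) {
    if (length(fam) == 1L) next
    r <- length(fam) * x[fam] / sum(x[fam])
    w[fam] <- r / max(r)
  }
  structure(w, reference_ids = attr(reference, "source_ids"),
            class = "cai_weights")
}

#' @export
print.cai_weights <- function(x, ...) {
  cat("CAI relative-adaptiveness weights for", length(unclass(x)),
      "codons (", sum(unclass(x) == 1), "with w = 1 )\n")
  invisible(x)
}

#' Codon adaptation index (CAI)
#'
#' The geometric mean of relative adaptiveness weights over a gene's
#' codons, restricted to the 59 synonymously variable codons (Met, Trp and
#' stops carry no information about synonymous choice). CAI lies in
#' (0, 1\]; higher values indicate usage closer to the reference set of
#' highly expressed genes, and CAI is widely used as a proxy for
#' expression level.
#'
#' @param counts a [codon_counts()] table for one gene.
#' @param weights a [cai_weights()] table.
#' @return CAI in (0, 1\], or `NA` for a gene with no analysis codons.
#' @export
cai <- function(counts, weights) {
  stopifnot(inherits(counts, "codon_counts"), inherits(weights, "cai_weights"))
  w <- unclass(weights)
  n <- unclass(counts)[names(w)]
  tot <- sum(n)
  if (tot == 0) return(NA_real_)
  exp(sum(n * log(w)) / tot)
}

# Kyte-Doolittle hydropathy scale.
.KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over the residues
#' of a protein. Unknown residues (`X`) are excluded.
#'
#' @param protein a protein string in one-letter code.
#' @return Mean hydropathy, or `NA` if no scoreable residues remain.
#' @examples
#' gravy("MW")  # (1.9 - 0.9) / 2 = 0.5
#' @export
gravy <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  v <- .KYTE_DOOLITTLE[aa]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Aromaticity of a protein
#'
#' Fraction of residues that are aromatic (Phe, Tyr, Trp).
#'
#' @param protein a protein string in one-letter code.
#' @return Aromatic fraction in \[0, 1\], `NA` for an empty protein.
#' @examples
#' aromo("FYWA")  # 0.75
#' @export
aromo <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  if (!length(aa)) return(NA_real_)
  mean(aa %in% c("F", "Y", "W"))
}

#' Per-gene codon-usage indices for a CDS set
#'
#' Computes the full per-gene index table: sense-codon count, positional
#' GC metrics, observed ENC, CAI (when weights are supplied), GRAVY and
#' aromaticity.
#'
#' @param set a validated [cds_set()] (see [validate_and_filter()]).
#' @param code a [genetic_code()].
#' @param weights optional [cai_weights()]; without them the `cai` column
#'   is `NA`.
#' @return A data.frame with one row per gene and columns `id`,
#'   `length_codons`, `gc1`, `gc2`, `gc3`, `gc3s`, `gc12`, `gc_all`,
#'   `enc`, `cai`, `gravy`, `aromo`.
#' @export
codon_usage_indices <- function(set, code = genetic_code(), weights = NULL) {
  stopifnot(inherits(set, "cds_set"))
  counts <- count_codons_set(set, code)
  rows <- lapply(seq_len(nrow(set)), function(i) {
    cc <- counts[[i]]
    gm <- gc_metrics(set$seq[i], code)
    prot <- translate_cds(set$seq[i], code)
    prot_clean <- gsub("X", "", prot, fixed = TRUE)
    data.frame(
      id = set$id[i],
      length_codons = total_codons(cc),
      gc1 = gm[["gc1"]], gc2 = gm[["gc2"]], gc3 = gm[["gc3"]],
      gc3s = gm[["gc3s"]], gc12 = gm[["gc12"]], gc_all = gm[["gc_all"]],
      enc = enc_observed(cc, code),
      cai = if (is.null(weights)) NA_real_ else cai(cc, weights),
      gravy = gravy(prot),
      aromo = if (nchar(prot_clean)) aromo(prot_clean) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-gene RSCU matrix over the 59 analysis codons
#'
#' @param set a validated [cds_set()].
#' @param code a [genetic_code()].
#' @param as_rna if `TRUE`, use RNA spelling for column names.
#' @return A genes x 59 numeric matrix of RSCU values (`NA` where a
#'   gene does not use a family), rows named by gene id, columns in a
#'   fixed documented codon order (the genetic-code family order).
#' @export
rscu_matrix <- function(set, code = genetic_code(), as_rna = FALSE) {
  counts <- count_codons_set(set, code)
  m <- t(vapply(counts, function(cc) rscu(cc, code)[code$analysis_codons],
                numeric(length(code$analysis_codons))))
  rownames(m) <- set$id
  if (as_rna) colnames(m) <- dna_to_rna(colnames(m))
  m
}

#' Write per-gene indices (and RSCU) as TSV
#'
#' Writes the index table of [codon_usage_indices()], optionally joined
#' with the 59 RSCU columns of [rscu_matrix()] (RNA spelling), as a
#' tab-separated file.
#'
#' @param indices data.frame from [codon_usage_indices()].
#' @param path output file path.
#' @param rscu optional matrix from [rscu_matrix()] with matching rows.
#' @return `path`, invisibly.
#' @export
write_indices_tsv <- function(indices, path, rscu = NULL) {
  out <- indices
  if (!is.null(rscu)) {
    stopifnot(identical(rownames(rscu), indices$id))
    colnames(rscu) <- dna_to_rna(colnames(rscu))
    out <- cbind(out, as.data.frame(rscu, check.names = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Round half away from zero, matching how codon-usage tables are printed.
round_half_up <- function(x, digits = 2L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
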