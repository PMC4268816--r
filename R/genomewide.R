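#' Neutrality analysis (GC12 versus GC3)
#'
#' Regresses each gene's GC12 (mean of first- and second-position GC) on
#' its GC3 (third-position GC over all sense codons). Under pure
#' mutational pressure the three codon positions drift together and the
#' slope approaches 1; selective constraint on first/second positions
#' flattens the slope toward 0. A Spearman rank correlation and its
#' two-sided p-value are reported alongside the least-squares fit.
#'
#' @param indices data.frame from [codon_usage_indices()] (needs columns
#'   `gc3`, `gc12`); at least 3 genes.
#' @return An object of class `neutrality_result`: a list with `slope`,
#'   `intercept`, `rho`, `p_value`, `n`, and the per-gene `points`
#'   data.frame (`id`, `gc3`, `gc12`). With constant GC3 the slope is
#'   undefined and reported `NA`.
#' @export
neutrality_analysis <- function(indices) {
  d <- indices[stats::complete.cases(indices[, c("gc3", "gc12")]), ]
  if (nrow(d) < 3L) stop("need at least 3 genes with defined GC3 and GC12",
                         call. = FALSE)
  if (stats::sd(d$gc3) == 0) {
    slope <- NA_real_; intercept <- NA_real_
    rho <- NA_real_; p <- NA_real_
  } else {
    fit <- stats::lm(gc12 ~ gc3, data = d)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    ct <- suppressWarnings(
      stats::cor.test(d$gc3, d$gc12, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(slope = slope, intercept = intercept, rho = rho, p_value = p,
         n = nrow(d),
         points = data.frame(id = d$id, gc3 = d$gc3, gc12 = d$gc12)),
    class = "neutrality_result"
  )
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat("Neutrality plot (GC12 ~ GC3), n =", x$n, "genes\n")
  cat(sprintf("  slope = %.4f, intercept = %.4f\n", x$slope, x$intercept))
  cat(sprintf("  Spearman rho = %.4f, p = %.3g\n", x$rho, x$p_value))
  invisible(x)
}

#' ENC versus GC3s profile and deviation histogram
#'
#' For each gene with a defined observed ENC, computes the expected ENC
#' from its GC3s under Wright's mutation-only curve and the relative
#' deviation `(ENC_exp - ENC_obs) / ENC_exp`. Genes shaped only by
#' third-position composition fall near 0; genes under additional
#' selective codon bias have markedly positive deviations. The deviations
#' are binned into a left-closed histogram over \[-1, 1) with bin width
#' 0.05, making statements such as "the mode lies in 0-0.05" operational.
#'
#' @param indices data.frame from [codon_usage_indices()] (needs `enc`,
#'   `gc3s`).
#' @return An object of class `enc_profile`: list with `genes` (data.frame
#'   `id`, `gc3s`, `enc_obs`, `enc_exp`, `ratio`) and `histogram`
#'   (data.frame `lower`, `upper`, `count`).
#' @export
enc_gc3_profile <- function(indices) {
  d <- indices[stats::complete.cases(indices[, c("enc", "gc3s")]), ]
  enc_exp <- enc_expected(d$gc3s)
  ratio <- (enc_exp - d$enc) / enc_exp
  breaks <- seq(-1, 1, by = 0.05)
  idx <- findInterval(ratio, breaks, rightmost.closed = FALSE,
                      left.open = FALSE)
  idx[ratio < -1 | ratio >= 1] <- NA_integer_
  count <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(
    list(
      genes = data.frame(id = d$id, gc3s = d$gc3s, enc_obs = d$enc,
                         enc_exp = enc_exp, ratio = ratio),
      histogram = data.frame(lower = breaks[-length(breaks)],
                             upper = breaks[-1L], count = count)
    ),
    class = "enc_profile"
  )
}

#' @export
print.enc_profile <- function(x, ...) {
  h <- x$histogram
  mode_bin <- h[which.max(h$count), ]
  cat("ENC deviation profile, n =", nrow(x$genes), "genes\n")
  cat(sprintf("  modal (ENCexp-ENCobs)/ENCexp bin: [%.2f, %.2f), %d genes\n",
              mode_bin$lower, mode_bin$upper, mode_bin$count))
  invisible(x)
}

#' Parity rule 2 (PR2) bias analysis
#'
#' Within the eight four-codon boxes (Ala, Arg CGN, Gly, Leu CUN, Pro,
#' Ser UCN, Thr, Val) the third position is fully degenerate, so under
#' mutation pressure alone A should balance T and G should balance C
#' there. For each gene the third-position base counts A3, T3, G3, C3 are
#' tallied over those boxes and the PR2 coordinates `x = G3 / (G3 + C3)`
#' and `y = A3 / (A3 + T3)` computed; (0.5, 0.5) is the parity point.
#'
#' @param set a validated [cds_set()], or a list of [codon_counts()].
#' @param code a [genetic_code()].
#' @return An object of class `pr2_result`: list with `genes` (data.frame
#'   `id`, `a3`, `t3`, `g3`, `c3`, `x`, `y`), `mean_x`, `sd_x`, `mean_y`,
#'   `sd_y`, and `n_skipped` (genes excluded because a denominator was
#'   zero or no four-fold codons were present).
#' @export
pr2_bias <- function(set, code = genetic_code()) {
  counts <- if (inherits(set, "cds_set")) {
    count_codons_set(set, code)
  } else {
    set
  }
  stopifnot(all(vapply(counts, inherits, logical(1L), "codon_counts")))
  ff <- unlist(code$fourfold_families, use.names = FALSE)
  third <- substr(ff, 3L, 3L)
  rows <- lapply(seq_along(counts), function(i) {
    x <- unclass(counts[[i]])[ff]
    base_tot <- vapply(c("A", "T", "G", "C"),
                       function(b) sum(x[third == b]), numeric(1L))
    data.frame(id = names(counts)[i] %||% NA_character_,
               a3 = base_tot[["A"]], t3 = base_tot[["T"]],
               g3 = base_tot[["G"]], c3 = base_tot[["C"]])
  })
  d <- do.call(rbind, rows)
  d$x <- ifelse(d$g3 + d$c3 > 0, d$g3 / (d$g3 + d$c3), NA_real_)
  d$y <- ifelse(d$a3 + d$t3 > 0, d$a3 / (d$a3 + d$t3), NA_real_)
  ok <- stats::complete.cases(d[, c("x", "y")])
  structure(
    list(genes = d[ok, , drop = FALSE],
         mean_x = mean(d$x[ok]), sd_x = stats::sd(d$x[ok]),
         mean_y = mean(d$y[ok]), sd_y = stats::sd(d$y[ok]),
         n_skipped = sum(!ok)),
    class = "pr2_result"
  )
}

#' @export
print.pr2_result <- function(x, ...) {
  cat("PR2 bias over four-fold boxes, n =", nrow(x$genes), "genes",
      "(", x$n_skipped, "skipped )\n")
  cat(sprintf("  G3/(G3+C3): %.4f +/- %.4f\n", x$mean_x, x$sd_x))
  cat(sprintf("  A3/(A3+T3): %.4f +/- %.4f\n", x$mean_y, x$sd_y))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correspondence analysis of the per-gene RSCU matrix
#'
#' Standard correspondence analysis (chi-square standardised residuals of
#' the relative frequency matrix, decomposed by SVD) applied to the genes
#' x 59 RSCU matrix, embedding genes and codons in shared axes ordered by
#' the fraction of total inertia they explain. Missing RSCU entries
#' (unused families) are treated as zero usage; all-zero rows or columns
#' are dropped with a warning.
#'
#' CA axis signs are arbitrary. When per-gene GC content is supplied, the
#' first axis is oriented so that its correlation with GC is negative
#' (GC-rich genes plot on the left), giving a reproducible convention.
#'
#' @param x non-negative matrix (genes in rows, codons in columns),
#'   typically from [rscu_matrix()]; at least 2 rows.
#' @param gc optional numeric vector of per-gene GC content (aligned with
#'   rows of `x`) used to orient axis 1.
#' @param naxes number of leading axes to keep (fewer are returned for
#'   rank-deficient inputs, never an error).
#' @return An object of class `codon_ca`: list with `row_coords` (gene
#'   principal coordinates), `col_coords` (codon principal coordinates),
#'   `inertia_fraction` (per retained axis, over all positive-inertia
#'   axes), `singular_values`, `naxes`, and `axis1_flipped`.
#' @export
correspondence_analysis <- function(x, gc = NULL, naxes = 4L) {
  x <- as.matrix(x)
  x[is.na(x)] <- 0
  if (any(x < 0)) stop("input matrix must be non-negative", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 genes", call. = FALSE)
  keep_r <- rowSums(x) > 0
  keep_c <- colSums(x) > 0
  if (!all(keep_r)) {
    warning(sum(!keep_r), " all-zero row(s) dropped from CA")
  }
  if (!all(keep_c)) {
    warning(sum(!keep_c), " all-zero column(s) dropped from CA")
  }
  gc <- if (!is.null(gc)) gc[keep_r] else NULL
  x <- x[keep_r, keep_c, drop = FALSE]

  p <- x / sum(x)
  r <- rowSums(p)
  c_ <- colSums(p)
  s <- (p - outer(r, c_)) / sqrt(outer(r, c_))
  sv <- svd(s)
  pos <- which(sv$d > max(sv$d[1L], 1) * 1e-10)
  k <- min(naxes, length(pos))
  if (k == 0L) {
    # No variation at all: every gene shares the same codon profile.
    row_coords <- matrix(0, nrow(x), 1L, dimnames = list(rownames(x), "axis1"))
    col_coords <- matrix(0, ncol(x), 1L, dimnames = list(colnames(x), "axis1"))
    return(structure(list(row_coords = row_coords, col_coords = col_coords,
                          inertia_fraction = 0, singular_values = 0,
                          naxes = 1L, axis1_flipped = FALSE),
                     class = "codon_ca"))
  }
  d <- sv$d[pos]
  row_coords <- sweep(sv$u[, pos[seq_len(k)], drop = FALSE], 1L, sqrt(r), "/") %*%
    diag(d[seq_len(k)], k, k)
  col_coords <- sweep(sv$v[, pos[seq_len(k)], drop = FALSE], 1L, sqrt(c_), "/") %*%
    diag(d[seq_len(k)], k, k)
  dimnames(row_coords) <- list(rownames(x), paste0("axis", seq_len(k)))
  dimnames(col_coords) <- list(colnames(x), paste0("axis", seq_len(k)))

  flipped <- FALSE
  if (!is.null(gc) && stats::sd(row_coords[, 1L]) > 0 && stats::sd(gc) > 0) {
    if (stats::cor(row_coords[, 1L], gc) > 0) {
      row_coords[, 1L] <- -row_coords[, 1L]
      col_coords[, 1L] <- -col_coords[, 1L]
      flipped <- TRUE
    }
  }
  structure(
    list(row_coords = row_coords, col_coords = col_coords,
         inertia_fraction = d^2 / sum(d^2),
         singular_values = d, naxes = k, axis1_flipped = flipped),
    class = "codon_ca"
  )
}

#' @export
print.codon_ca <- function(x, ...) {
  cat("Correspondence analysis of RSCU:", nrow(x$row_coords), "genes,",
      nrow(x$col_coords), "codons\n")
  k <- min(4L, length(x$inertia_fraction))
  cat("  inertia fractions:",
      paste(sprintf("%.1f%%", 100 * x$inertia_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Classify genes for ordination colouring
#'
#' Assigns each gene one label with precedence ribosomal > hydrophobic >
#' aromatic > other: a gene in `ribosomal_ids` is `ribosomal`; otherwise
#' a gene with GRAVY strictly above `gravy_threshold` is `hydrophobic`;
#' otherwise a gene with aromaticity at or above `aromo_threshold` is
#' `aromatic`.
#'
#' The default GRAVY cutoff of 5 follows the convention of published
#' transcriptome-wide surveys, but note it exceeds the maximum attainable
#' Kyte-Doolittle mean (4.5 for poly-Ile), so with that default the
#' hydrophobic class is necessarily empty; set a lower threshold (e.g.
#' 0.5) to obtain a non-trivial class.
#'
#' @param indices data.frame from [codon_usage_indices()].
#' @param ribosomal_ids character vector of reference (ribosomal-protein)
#'   gene ids; unknown ids trigger a warning and are ignored.
#' @param gravy_threshold strict lower GRAVY cutoff for `hydrophobic`.
#' @param aromo_threshold inclusive lower aromaticity cutoff for
#'   `aromatic`.
#' @return A data.frame with columns `id`, `label` (factor with levels
#'   ribosomal, hydrophobic, aromatic, other), and the thresholds as
#'   attributes.
#' @export
classify_genes <- function(indices, ribosomal_ids = character(0L),
                           gravy_threshold = 5, aromo_threshold = 0.15) {
  unknown <- setdiff(ribosomal_ids, indices$id)
  if (length(unknown)) {
    warning("ignoring ", length(unknown),
            " ribosomal id(s) absent from the index table")
  }
  label <- rep("other", nrow(indices))
  label[!is.na(indices$aromo) & indices$aromo >= aromo_threshold] <- "aromatic"
  label[!is.na(indices$gravy) & indices$gravy > gravy_threshold] <- "hydrophobic"
  label[indices$id %in% ribosomal_ids] <- "ribosomal"
  out <- data.frame(
    id = indices$id,
    label = factor(label, levels = c("ribosomal", "hydrophobic",
                                     "aromatic", "other"))
  )
  attr(out, "gravy_threshold") <- gravy_threshold
  attr(out, "aromo_threshold") <- aromo_threshold
  out
}

# The index/ordination variable pairs examined genome-wide.
.BATTERY_PAIRS <- list(
  c("axis1", "gc_all"), c("axis1", "gc3s"), c("axis1", "enc"),
  c("cai", "enc"), c("cai", "gc3s"), c("cai", "gc_all"), c("cai", "axis1"),
  c("length_codons", "axis1"), c("length_codons", "enc"),
  c("length_codons", "cai"),
  c("gravy", "enc"), c("aromo", "enc")
)

#' Spearman correlation battery over codon-usage indices
#'
#' Computes the battery of rank correlations routinely examined in
#' codon-usage surveys: CA axis-1 position against GC, GC3s and ENC; CAI
#' against ENC, GC3s, GC and axis 1; gene length against axis 1, ENC and
#' CAI; and GRAVY and aromaticity against ENC. Missing values are deleted
#' pairwise; a pair with fewer than 5 complete observations is reported
#' with `NA`.
#'
#' @param indices data.frame from [codon_usage_indices()].
#' @param ca optional [correspondence_analysis()] result supplying the
#'   axis-1 gene coordinates (matched to `indices` by gene id).
#' @return A data.frame with columns `var1`, `var2`, `rho`, `p_value`,
#'   `n`.
#' @export
correlation_battery <- function(indices, ca = NULL) {
  if (nrow(indices) < 5L) stop("need at least 5 genes", call. = FALSE)
  d <- indices
  d$axis1 <- NA_real_
  if (!is.null(ca)) {
    m <- match(d$id, rownames(ca$row_coords))
    d$axis1 <- ca$row_coords[m, 1L]
  }
  rows <- lapply(.BATTERY_PAIRS, function(pr) {
    x <- d[[pr[1L]]]
    y <- d[[pr[2L]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 5L) {
      return(data.frame(var1 = pr[1L], var2 = pr[2L], rho = NA_real_,
                        p_value = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(var1 = pr[1L], var2 = pr[2L], rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok))
  })
  do.call(rbind, rows)
}
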