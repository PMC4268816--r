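#' Default preferred-codon set for the simulator
#'
#' One designated codon per synonymous family with at least two members:
#' the first C-ending codon of the family, or the first G-ending codon
#' when the family has no C-ending member (Gln, Lys, Glu). Mirrors the
#' empirical pattern in many invertebrate transcriptomes, where
#' translationally optimal codons end in G or C.
#'
#' @param code a [genetic_code()].
#' @return Named character vector (amino acid -> preferred codon, DNA
#'   spelling) over the 18 families with a synonymous choice.
#' @export
default_preferred_codons <- function(code = genetic_code()) {
  fams <- code$families[vapply(code$families, length, integer(1L)) > 1L]
  vapply(fams, function(fam) {
    third <- substr(fam, 3L, 3L)
    if (any(third == "C")) fam[third == "C"][1L] else fam[third == "G"][1L]
  }, character(1L))
}

#' Configuration for the synthetic CDS generator
#'
#' Defines the generative model for a set of coding sequences with
#' controllable mutation bias, selection and expression structure:
#' \itemize{
#'   \item Gene length (in interior codons) is uniform on `length_range`.
#'   \item Each gene draws a mutational GC3 target t from
#'     `Beta(gc3_shape[1], gc3_shape[2])`; within every synonymous family
#'     the third position favours G/C-ending codons with odds
#'     `t / (1 - t)` (G and C equiprobable, likewise A and T).
#'   \item Each gene draws an expression level e in \[0, 1\]; the gene's
#'     preferred codon in every family receives a multiplicative
#'     selection bonus `exp(s_sel * e)` before renormalisation.
#'   \item Amino acids are drawn i.i.d. from `aa_freq`; a start codon is
#'     prepended and a random stop codon appended.
#' }
#'
#' @param n_genes number of genes.
#' @param length_range integer 2-vector: min/max interior codons (the
#'   default keeps every simulated CDS above the 300 nt filter).
#' @param gc3_shape Beta shape parameters for the per-gene GC3 target;
#'   the default Beta(2.2, 1.9) has mean 0.54 with a wide spread, the
#'   regime of a slightly GC-rich transcriptome whose genes span nearly
#'   the whole GC3 range.
#' @param s_sel non-negative selection strength; 0 switches selection off.
#' @param expression either a numeric 2-vector of Beta shape parameters
#'   (default Beta(1.5, 5.3), right-skewed with mean 0.22), or the string
#'   `"bimodal"` for an equal mixture at 0.05 and 0.95.
#' @param preferred_codons named character vector amino acid -> codon
#'   (see [default_preferred_codons()]).
#' @param aa_freq optional named frequency vector over the 20 amino
#'   acids; defaults to uniform.
#' @param reference_fraction fraction of genes (the most highly
#'   expressed) emitted as the "ribosomal" reference id list for CAI.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500L,
                             length_range = c(110L, 400L),
                             gc3_shape = c(2.2, 1.9),
                             s_sel = 1.5,
                             expression = c(1.5, 5.3),
                             preferred_codons = default_preferred_codons(),
                             aa_freq = NULL,
                             reference_fraction = 0.05,
                             seed = 1L) {
  code <- genetic_code()
  if (n_genes < 1L) stop("'n_genes' must be positive", call. = FALSE)
  if (length(length_range) != 2L || any(length_range < 1L) ||
      length_range[1L] > length_range[2L]) {
    stop("'length_range' must be an increasing pair of positive codon counts",
         call. = FALSE)
  }
  if (any(gc3_shape <= 0)) stop("'gc3_shape' must be positive", call. = FALSE)
  if (s_sel < 0) stop("'s_sel' must be non-negative", call. = FALSE)
  if (is.null(aa_freq)) {
    aa_freq <- stats::setNames(rep(1 / 20, 20L), names(code$families))
  }
  aa_freq <- aa_freq / sum(aa_freq)
  if (!setequal(names(aa_freq), names(code$families))) {
    stop("'aa_freq' must cover exactly the 20 amino acids", call. = FALSE)
  }
  bad <- !preferred_codons %in% code$sense_codons
  if (length(preferred_codons) == 0L || any(bad)) {
    stop("'preferred_codons' must be sense codons, one per family",
         call. = FALSE)
  }
  if (!(identical(expression, "bimodal") ||
        (is.numeric(expression) && length(expression) == 2L &&
         all(expression > 0)))) {
    stop("'expression' must be Beta shape parameters or \"bimodal\"",
         call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes),
         length_range = as.integer(length_range),
         gc3_shape = gc3_shape, s_sel = s_sel, expression = expression,
         preferred_codons = preferred_codons, aa_freq = aa_freq,
         reference_fraction = reference_fraction, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Per-gene within-family codon sampling weights: mutational odds on the
# third base times the selection bonus on the preferred codon.
codon_weights_for_gene <- function(code, gc3_target, sel_bonus,
                                   preferred_codons) {
  lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    third <- substr(fam, 3L, 3L)
    w <- ifelse(third %in% c("G", "C"), gc3_target, 1 - gc3_target)
    pref <- preferred_codons[aa]
    if (!is.na(pref)) w[fam == pref] <- w[fam == pref] * sel_bonus
    stats::setNames(w / sum(w), fam)
  }) |> stats::setNames(names(code$families))
}

#' Simulate a CDS set with known mutation and selection structure
#'
#' Generates coding sequences under the model described in
#' [synthetic_config()] and returns them together with the ground truth
#' needed to score downstream recovery (per-gene GC3 targets and
#' expression levels, the preferred-codon set, the selection strength,
#' and the reference id list).
#'
#' @param config a [synthetic_config()].
#' @param code a [genetic_code()].
#' @return A list with elements `set` (a [cds_set()]), `truth` (list with
#'   `genes` data.frame of `id`, `length_codons`, `gc3_target`,
#'   `expression`, `is_reference`; plus `preferred_codons`, `s_sel`,
#'   `reference_ids`) and `config`.
#' @examples
#' sim <- simulate_cds_set(synthetic_config(n_genes = 5, seed = 42))
#' sim$set
#' @export
simulate_cds_set <- function(config, code = genetic_code()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  n <- config$n_genes
  ids <- sprintf("sim%05d", seq_len(n))
  len <- sample(seq(config$length_range[1L], config$length_range[2L]),
                n, replace = TRUE)
  gc3_target <- stats::rbeta(n, config$gc3_shape[1L], config$gc3_shape[2L])
  # keep mutational odds finite
  gc3_target <- pmin(pmax(gc3_target, 0.01), 0.99)
  expr <- if (identical(config$expression, "bimodal")) {
    sample(c(0.05, 0.95), n, replace = TRUE)
  } else {
    stats::rbeta(n, config$expression[1L], config$expression[2L])
  }

  aas <- names(config$aa_freq)
  seqs <- character(n)
  for (i in seq_len(n)) {
    w <- codon_weights_for_gene(code, gc3_target[i],
                                exp(config$s_sel * expr[i]),
                                config$preferred_codons)
    aa_seq <- sample(aas, len[i], replace = TRUE, prob = config$aa_freq)
    codons <- character(len[i])
    for (aa in unique(aa_seq)) {
      at <- which(aa_seq == aa)
      fam <- code$families[[aa]]
      codons[at] <- if (length(fam) == 1L) {
        fam
      } else {
        sample(fam, length(at), replace = TRUE, prob = w[[aa]])
      }
    }
    stop_codon <- sample(code$stop_codons, 1L)
    seqs[i] <- paste(c("ATG", codons, stop_codon), collapse = "")
  }

  n_ref <- max(1L, floor(config$reference_fraction * n))
  ref_ids <- ids[order(-expr, ids)][seq_len(n_ref)]

  truth <- list(
    genes = data.frame(id = ids, length_codons = len + 1L,
                       gc3_target = gc3_target, expression = expr,
                       is_reference = ids %in% ref_ids,
                       stringsAsFactors = FALSE),
    preferred_codons = config$preferred_codons,
    s_sel = config$s_sel,
    reference_ids = ref_ids
  )
  list(set = cds_set(ids, seqs, provenance = sprintf("simulated(seed=%d)",
                                                     config$seed)),
       truth = truth, config = config)
}

#' Write a simulation to disk
#'
#' Emits the simulated sequences as FASTA together with the ground-truth
#' table (TSV) and the reference-gene id list (one id per line), the
#' inputs consumed by [run_pipeline()].
#'
#' @param sim result of [simulate_cds_set()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "simulated_cds.fasta")
  truth <- file.path(dir, "ground_truth.tsv")
  refs <- file.path(dir, "reference_ids.txt")
  write_cds_fasta(sim$set, fasta)
  utils::write.table(sim$truth$genes, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$truth$reference_ids, refs)
  invisible(c(fasta = fasta, truth = truth, reference_ids = refs))
}
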