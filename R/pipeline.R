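#' Run the full codon-usage analysis pipeline
#'
#' Executes the complete analysis on a FASTA file of coding sequences:
#' filtering and validation, per-gene indices, CAI against a
#' reference-gene set, neutrality and ENC-GC3s diagnostics, PR2 bias,
#' correspondence analysis of RSCU, gene classification, the Spearman
#' correlation battery, and optimal-codon determination. All results are
#' written as TSV files into `output_dir`, together with a flat
#' key-value manifest recording the package version, thresholds, seed
#' and input checksums, so a run can be reproduced exactly.
#'
#' @param input_fasta path to a FASTA file of CDS records.
#' @param output_dir directory to create/write outputs into.
#' @param reference_ids reference (ribosomal-protein) gene ids for CAI:
#'   a character vector, or the path of a file with one id per line.
#'   With `NULL`, CAI weights are computed from the pooled usage of all
#'   retained genes (self-referential CAI; documented fallback).
#' @param min_len_nt length filter passed to [validate_and_filter()].
#' @param cai_fraction extreme fraction for [partition_by_cai()].
#' @param alpha significance level for [determine_optimal_codons()].
#' @param gravy_threshold,aromo_threshold cutoffs for [classify_genes()].
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed governs any simulation used upstream).
#' @param verbose print progress to stderr.
#' @return `output_dir`, invisibly. Fails with an error (and removes
#'   partial outputs) if no sequence survives the filter.
#' @export
run_pipeline <- function(input_fasta, output_dir, reference_ids = NULL,
                         min_len_nt = 300L, cai_fraction = 0.05,
                         alpha = 0.01, gravy_threshold = 5,
                         aromo_threshold = 0.15, seed = 1L,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[cubkit] ", ...)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0L)
  emit <- function(writer, object, file) {
    path <- file.path(output_dir, file)
    writer(object, path)
    written <<- c(written, path)
    path
  }
  fail <- function(...) {
    unlink(written)
    stop(..., call. = FALSE)
  }

  code <- genetic_code()
  say("reading ", input_fasta)
  set <- read_cds_fasta(input_fasta)
  flt <- validate_and_filter(set, min_len_nt = min_len_nt)
  emit(write_rejection_log, flt$rejected, "rejections.tsv")
  retained <- flt$retained
  say(nrow(retained), " of ", nrow(set), " CDS retained")
  if (nrow(retained) == 0L) {
    fail("no sequence passed the filter (min length ", min_len_nt,
         " nt); nothing to analyse")
  }

  if (is.character(reference_ids) && length(reference_ids) == 1L &&
      file.exists(reference_ids)) {
    reference_ids <- readLines(reference_ids)
  }
  ref_ids_used <- intersect(reference_ids %||% character(0L), retained$id)
  ref_counts <- if (length(ref_ids_used)) {
    sub <- retained[retained$id %in% ref_ids_used, , drop = FALSE]
    class(sub) <- class(retained)
    pool_counts(count_codons_set(sub, code))
  } else {
    say("no reference ids supplied/matched; using whole-set CAI weights")
    pool_counts(count_codons_set(retained, code))
  }
  weights <- cai_weights(ref_counts, code)

  say("computing per-gene indices")
  indices <- codon_usage_indices(retained, code, weights = weights)
  m <- rscu_matrix(retained, code)
  emit(function(o, p) write_indices_tsv(o, p, rscu = m), indices,
       "indices.tsv")

  say("genome-wide diagnostics")
  neut <- neutrality_analysis(indices)
  neut_df <- data.frame(slope = neut$slope, intercept = neut$intercept,
                        rho = neut$rho, p_value = neut$p_value, n = neut$n)
  emit(write_tsv_plain, neut_df, "neutrality.tsv")

  prof <- enc_gc3_profile(indices)
  emit(write_tsv_plain, prof$genes, "enc_profile.tsv")
  emit(write_tsv_plain, prof$histogram, "enc_ratio_histogram.tsv")

  pr2 <- pr2_bias(retained, code)
  emit(write_tsv_plain, pr2$genes, "pr2.tsv")

  ca <- correspondence_analysis(m, gc = indices$gc_all)
  emit(write_tsv_plain,
       data.frame(id = rownames(ca$row_coords), ca$row_coords),
       "ca_genes.tsv")
  emit(write_tsv_plain,
       data.frame(codon = dna_to_rna(rownames(ca$col_coords)),
                  ca$col_coords),
       "ca_codons.tsv")
  emit(write_tsv_plain,
       data.frame(axis = seq_along(ca$inertia_fraction),
                  inertia_fraction = ca$inertia_fraction),
       "ca_inertia.tsv")

  labels <- classify_genes(indices, ribosomal_ids = ref_ids_used,
                           gravy_threshold = gravy_threshold,
                           aromo_threshold = aromo_threshold)
  emit(write_tsv_plain, labels, "gene_classes.tsv")
  emit(write_tsv_plain, correlation_battery(indices, ca),
       "correlations.tsv")

  say("optimal codons")
  part <- partition_by_cai(retained, indices, fraction = cai_fraction,
                           code = code)
  report <- determine_optimal_codons(part, code, alpha = alpha)
  emit(write_optimal_report, report, "optimal_codons.tsv")

  manifest <- c(
    package = "cubkit",
    version = as.character(utils::packageVersion("cubkit")),
    input_fasta = input_fasta,
    input_md5 = unname(tools::md5sum(input_fasta)),
    n_input = nrow(set), n_retained = nrow(retained),
    n_reference = length(ref_ids_used),
    min_len_nt = min_len_nt, cai_fraction = cai_fraction, alpha = alpha,
    gravy_threshold = gravy_threshold, aromo_threshold = aromo_threshold,
    seed = seed
  )
  writeLines(paste0(names(manifest), "=", manifest),
             file.path(output_dir, "manifest.txt"))
  say("done: ", output_dir)
  invisible(output_dir)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
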