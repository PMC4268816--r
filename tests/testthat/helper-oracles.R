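# Independent oracles and fixture builders shared across the test files.
# Oracles deliberately avoid the package's own code paths: family structure
# comes from Biostrings::GENETIC_CODE, brute-force loops replace vectorised
# arithmetic, and MASS::corresp provides an external CA decomposition.

# Synonymous families derived from Biostrings' genetic-code table.
oracle_families <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  split(sense, gc_tab[sense])
}

# Brute-force RSCU: loop codon by codon.
oracle_rscu <- function(counts) {
  fams <- oracle_families()
  counts <- setNames(as.numeric(counts), names(counts))
  out <- setNames(rep(NA_real_, length(counts)), names(counts))
  for (fam in fams) {
    tot <- sum(counts[fam])
    for (cd in fam) {
      out[cd] <- if (tot > 0) length(fam) * counts[cd] / tot else NA_real_
    }
  }
  out
}

# Brute-force Wright ENC with families enumerated explicitly.
oracle_enc <- function(counts) {
  fams <- oracle_families()
  fams <- fams[!names(fams) %in% c("M", "W")]
  fhat <- sapply(fams, function(fam) {
    n <- sum(counts[fam])
    if (n <= 1) return(NA_real_)
    p <- counts[fam] / n
    (n * sum(p^2) - 1) / (n - 1)
  })
  deg <- sapply(fams, length)
  fbar <- c()
  for (k in c(2, 3, 4, 6)) {
    v <- fhat[deg == k]
    v <- v[!is.na(v)]
    fbar[as.character(k)] <- if (length(v)) mean(v) else NA_real_
  }
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  }
  if (any(is.na(fbar)) || any(fbar == 0)) return(NA_real_)
  enc <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
  unname(min(enc, 61))
}

# Geometric-mean CAI via explicit per-occurrence log weights.
oracle_cai <- function(counts, w) {
  logs <- numeric(0)
  for (cd in names(w)) {
    if (counts[cd] > 0) logs <- c(logs, rep(log(w[cd]), counts[cd]))
  }
  if (!length(logs)) return(NA_real_)
  exp(mean(logs))
}

# Random small codon-count table over the 61 sense codons.
random_counts <- function(max_count = 30L) {
  code <- cubkit::genetic_code()
  n <- sample(0:max_count, 61, replace = TRUE)
  cubkit::codon_counts(setNames(n, code$sense_codons))
}

# Random valid CDS (start codon + sense codons + stop).
random_cds <- function(n_codons = 60L) {
  code <- cubkit::genetic_code()
  body <- sample(code$sense_codons, n_codons, replace = TRUE)
  paste(c("ATG", body, sample(code$stop_codons, 1)), collapse = "")
}

# Write a cds_set-like list of sequences to a temporary FASTA file.
write_fasta_fixture <- function(ids, seqs, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- character(0)
  for (i in seq_along(ids)) {
    s <- seqs[i]
    if (!is.null(wrap)) {
      s <- gsub(sprintf("(.{%d})", wrap), "\\1\n", s)
      s <- strsplit(s, "\n")[[1]]
    }
    lines <- c(lines, paste0(">", ids[i]), s)
  }
  writeLines(lines, path)
  path
}

# Count tables for the published T. saginata high/low expression pools.
pools_fixture <- function() {
  pools <- cubkit::taenia_expression_pools()
  list(
    high = cubkit::codon_counts(setNames(pools$count_high, pools$codon)),
    low = cubkit::codon_counts(setNames(pools$count_low, pools$codon)),
    table = pools
  )
}
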