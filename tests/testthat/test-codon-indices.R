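test_that("codon counting skips stops and N codons", {
  cc <- count_codons("ATGTGGTAA")
  expect_equal(total_codons(cc), 2)
  expect_equal(unclass(cc)[["ATG"]], 1)
  expect_equal(unclass(cc)[["TGG"]], 1)

  cc <- count_codons("ATGANNTGG")
  expect_equal(total_codons(cc), 2)
  expect_equal(sum(unclass(cc)[c("ATG", "TGG")]), 2)

  expect_error(count_codons("ATGA"), "multiple of 3")
})

test_that("codon counting equals a sliding-window oracle", {
  withr::local_seed(21)
  s <- random_cds(100)
  cc <- count_codons(s)
  # independent splitter: regmatches on triplets
  trip <- regmatches(s, gregexpr("...", s))[[1]]
  trip <- trip[-length(trip)]  # terminal stop
  oracle <- table(trip)
  for (cd in names(oracle)) {
    expect_equal(unclass(cc)[[cd]], unname(oracle[[cd]]))
  }
  expect_equal(total_codons(cc), 101)  # 100 body + start ATG
})

test_that("pooling count tables is elementwise addition", {
  a <- count_codons(random_cds(40), id = "a")
  b <- count_codons(random_cds(50), id = "b")
  pooled <- pool_counts(a, b)
  expect_equal(unclass(pooled), unclass(a) + unclass(b),
               ignore_attr = TRUE)
  expect_setequal(attr(pooled, "source_ids"), c("a", "b"))
})

test_that("RSCU reproduces published two-fold and six-fold values", {
  # Phe counts from the transcriptome-wide usage table
  phe <- codon_counts(c(UUU = 99671, UUC = 106107))
  r <- rscu(phe, as_rna = TRUE)
  expect_equal(cubkit:::round_half_up(r[["UUU"]]), 0.97)
  expect_equal(cubkit:::round_half_up(r[["UUC"]]), 1.03)

  # Leu counts from the high-expression pool
  leu <- codon_counts(c(UUA = 540, UUG = 2598, CUU = 2570, CUC = 5332,
                        CUA = 1099, CUG = 4118))
  expect_equal(cubkit:::round_half_up(rscu(leu, as_rna = TRUE)[["UUA"]]), 0.20)
})

test_that("uniform usage gives RSCU 1 and family sums equal degeneracy", {
  code <- genetic_code()
  uniform <- codon_counts(setNames(rep(5, 61), code$sense_codons))
  r <- rscu(uniform)
  expect_true(all(abs(r - 1) < 1e-12))

  withr::local_seed(31)
  for (i in 1:20) {
    cc <- random_counts()
    r <- rscu(cc)
    for (fam in code$families) {
      if (sum(unclass(cc)[fam]) > 0) {
        expect_equal(sum(r[fam]), length(fam))
      } else {
        expect_true(all(is.na(r[fam])))
      }
    }
    # invariance under scaling all counts
    r2 <- rscu(codon_counts(unclass(cc) * 7))
    expect_equal(r2, r)
  }
})

test_that("family homozygosity matches hand arithmetic", {
  expect_equal(family_homozygosity(c(3, 1)), 0.5)
  expect_equal(family_homozygosity(c(5, 0)), 1)
  expect_equal(family_homozygosity(c(2, 2)), 1 / 3)
  expect_true(is.na(family_homozygosity(c(1, 0))))
  expect_true(is.na(family_homozygosity(c(0, 0))))
})

test_that("ENC attains its theoretical bounds", {
  code <- genetic_code()
  # one codon per amino acid, used many times
  one_per_aa <- vapply(code$families, `[[`, character(1), 1)
  cc <- codon_counts(setNames(rep(50, 20), one_per_aa))
  expect_equal(enc_observed(cc), 20)

  # equal usage of all 61 sense codons at n = 1000 each
  cc <- codon_counts(setNames(rep(1000, 61), code$sense_codons))
  expect_lt(abs(enc_observed(cc) - 61), 0.5)
})

test_that("ENC equals a brute-force family enumeration on random tables", {
  withr::local_seed(101)
  for (i in 1:200) {
    cc <- random_counts(max_count = if (i %% 2) 8L else 40L)
    mine <- enc_observed(cc)
    theirs <- oracle_enc(unclass(cc))
    if (is.na(mine)) {
      expect_true(is.na(theirs))
    } else {
      expect_equal(mine, theirs, tolerance = 1e-12)
    }
  }
})

test_that("expected-ENC curve has the standard closed-form values", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 32)
  expect_equal(enc_expected(0), 31)
  expect_error(enc_expected(1.2), "0, 1")
  # maximized near s = 0.5 and above 60 there
  s <- seq(0, 1, by = 0.01)
  expect_equal(s[which.max(enc_expected(s))], 0.5)
  expect_gt(max(enc_expected(s)), 60)
})

test_that("GC metrics match a per-position letter-counting oracle", {
  full_gc <- paste(rep("GCC", 10), collapse = "")
  gm <- gc_metrics(full_gc)
  expect_true(all(gm == 1))

  gm <- gc_metrics("ATGTAT")
  expect_equal(gm[["gc3"]], 0.5)   # ATG counts toward GC3...
  expect_equal(gm[["gc3s"]], 0)    # ...but not toward GC3s

  withr::local_seed(55)
  s <- random_cds(50)
  gm <- gc_metrics(s)
  cod <- regmatches(s, gregexpr("...", s))[[1]]
  cod <- cod[-length(cod)]
  pos_count <- function(k) mean(substr(cod, k, k) %in% c("G", "C"))
  expect_equal(gm[["gc1"]], pos_count(1))
  expect_equal(gm[["gc2"]], pos_count(2))
  expect_equal(gm[["gc3"]], pos_count(3))
  expect_equal(gm[["gc12"]], (gm[["gc1"]] + gm[["gc2"]]) / 2)
})

test_that("CAI weights give w = 1 to each family's top codon", {
  phe_ref <- codon_counts(c(UUU = 99671, UUC = 106107))
  w <- cai_weights(phe_ref)
  expect_equal(w[["TTC"]], 1)
  expect_equal(w[["TTT"]], 99671 / 106107, tolerance = 1e-12)

  # every family's maximum is exactly 1
  withr::local_seed(77)
  ref <- random_counts(max_count = 50L)
  w <- cai_weights(ref)
  code <- genetic_code()
  for (fam in code$families) {
    fam <- intersect(fam, names(unclass(w)))
    if (length(fam)) expect_equal(max(unclass(w)[fam]), 1)
  }

  # unobserved codon gets the pseudocount, keeping w in (0, 1)
  one_gone <- codon_counts(c(UUU = 0, UUC = 10))
  w <- cai_weights(one_gone)
  expect_gt(w[["TTT"]], 0)
  expect_lt(w[["TTT"]], 1)

  # uniform reference: no preference anywhere
  uniform <- codon_counts(setNames(rep(3, 61), code$sense_codons))
  expect_true(all(unclass(cai_weights(uniform)) == 1))

  expect_error(cai_weights(codon_counts(c(UUU = 0))), "empty")
})

test_that("CAI is the geometric mean of weights", {
  # equal occurrences of w = 1 and w = 0.25 codons
  ref <- codon_counts(c(UUC = 80, UUU = 20, UAC = 10, UAU = 10))
  w <- cai_weights(ref)
  expect_equal(w[["TTT"]], 0.25)
  gene <- codon_counts(c(UUC = 5, UUU = 5))
  expect_equal(cai(gene, w), sqrt(1 * 0.25))

  # only w = 1 codons
  gene <- codon_counts(c(UUC = 9))
  expect_equal(cai(gene, w), 1)

  # against the per-occurrence log oracle
  withr::local_seed(88)
  for (i in 1:10) {
    gene <- random_counts(max_count = 6L)
    expect_equal(cai(gene, w = cai_weights(ref)),
                 oracle_cai(unclass(gene), unclass(cai_weights(ref))))
  }
})

test_that("reference set scores at least as high as uniform usage on its own weights", {
  usage <- taenia_codon_usage()
  ref <- codon_counts(setNames(usage$count, usage$codon))
  w <- cai_weights(ref)
  code <- genetic_code()
  uniform <- codon_counts(setNames(rep(10, 61), code$sense_codons))
  expect_gte(cai(ref, w), cai(uniform, w))
})

test_that("GRAVY and aromaticity follow the published scales", {
  expect_equal(gravy("AAAA"), 1.8)
  expect_equal(gravy("MW"), 0.5)
  expect_true(is.na(gravy("XXX")))

  expect_equal(aromo("FYWA"), 0.75)
  expect_equal(aromo("AAAA"), 0)

  # lookup-and-average oracle on a random protein
  withr::local_seed(13)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  p <- paste(sample(names(kd), 20, replace = TRUE), collapse = "")
  expect_equal(gravy(p), mean(kd[strsplit(p, "")[[1]]]))
  expect_equal(aromo(p),
               sum(strsplit(p, "")[[1]] %in% c("F", "Y", "W")) / 20)
})

test_that("per-gene index table is complete and self-consistent", {
  sim <- simulate_cds_set(synthetic_config(n_genes = 25, seed = 3))
  ref <- sim$truth$reference_ids
  sub <- sim$set[sim$set$id %in% ref, ]
  class(sub) <- class(sim$set)
  w <- cai_weights(pool_counts(count_codons_set(sub)))
  idx <- codon_usage_indices(sim$set, weights = w)
  expect_equal(nrow(idx), 25)
  expect_true(all(idx$enc >= 20 & idx$enc <= 61, na.rm = TRUE))
  expect_true(all(idx$cai > 0 & idx$cai <= 1))
  expect_equal(idx$gc12, (idx$gc1 + idx$gc2) / 2)
  # simulated genes: ATG + body + stop, stop not counted
  expect_equal(idx$length_codons, sim$truth$genes$length_codons)
})
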