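# Minimal index table builder for analyses that only need a few columns.
fake_indices <- function(gc3, gc12, id = sprintf("g%03d", seq_along(gc3))) {
  data.frame(id = id, gc3 = gc3, gc12 = gc12)
}

test_that("neutrality analysis recovers trivial regimes", {
  x <- seq(0.2, 0.8, length.out = 10)
  res <- neutrality_analysis(fake_indices(x, x))
  expect_equal(res$slope, 1)
  expect_equal(res$rho, 1)

  res <- neutrality_analysis(fake_indices(x, rep(0.5, 10)))
  expect_equal(res$slope, 0)

  res <- neutrality_analysis(fake_indices(rep(0.5, 10), x))
  expect_true(is.na(res$slope))
})

test_that("neutrality slope is recovered from noisy simulated points", {
  withr::local_seed(42)
  gc3 <- runif(50, 0.2, 0.9)
  gc12 <- 0.25 + 0.3 * gc3 + rnorm(50, sd = 0.02)
  res <- neutrality_analysis(fake_indices(gc3, gc12))
  se <- summary(lm(gc12 ~ gc3))$coefficients[2, 2]
  expect_lt(abs(res$slope - 0.3), 2 * se)
})

test_that("ENC deviation ratios and histogram bins are as defined", {
  idx <- data.frame(id = c("a", "b"),
                    enc = c(enc_expected(0.5), 45),
                    gc3s = c(0.5, NA))
  prof <- enc_gc3_profile(idx)
  expect_equal(nrow(prof$genes), 1)
  expect_equal(prof$genes$ratio, 0)
  bin <- prof$histogram[prof$histogram$count > 0, ]
  expect_equal(bin$lower, 0)
  expect_equal(bin$upper, 0.05)

  # direct arithmetic: exp 60.5 at s = 0.5, obs 45.375 -> ratio 0.25
  idx <- data.frame(id = "c", enc = 45.375, gc3s = 0.5)
  prof <- enc_gc3_profile(idx)
  expect_equal(prof$genes$ratio, 0.25)
})

test_that("unselected simulated genes sit near the expected ENC curve", {
  sim <- simulate_cds_set(synthetic_config(n_genes = 150, s_sel = 0,
                                           seed = 19))
  idx <- codon_usage_indices(sim$set)
  prof <- enc_gc3_profile(idx)
  h <- prof$histogram
  mode_bin <- h$lower[which.max(h$count)]
  # modal bin adjacent to zero deviation
  expect_lte(abs(mode_bin), 0.05)
  expect_lt(abs(mean(prof$genes$ratio)), 0.05)
})

test_that("PR2 coordinates follow their definition", {
  # hand-built: four-fold third-position counts A=1, T=3, G=2, C=2
  cc <- codon_counts(c(GCA = 1, GCU = 3, GCG = 2, GCC = 2))
  res <- pr2_bias(list(g1 = cc))
  expect_equal(res$genes$x, 0.5)
  expect_equal(res$genes$y, 0.25)

  # parity in every family
  cc <- codon_counts(c(GCA = 2, GCU = 2, GCG = 2, GCC = 2,
                       GUA = 5, GUU = 5, GUG = 5, GUC = 5))
  res <- pr2_bias(list(g1 = cc))
  expect_equal(c(res$genes$x, res$genes$y), c(0.5, 0.5))

  # all C-ending four-fold codons: A3+T3 = 0, gene excluded with tally
  cc <- codon_counts(c(GCC = 4, ACC = 2))
  res <- pr2_bias(list(g1 = cc))
  expect_equal(nrow(res$genes), 0)
  expect_equal(res$n_skipped, 1)

  # two-fold families never contribute
  cc <- codon_counts(c(UUU = 50, UUC = 50, GCA = 1, GCU = 1, GCG = 1,
                       GCC = 1))
  res <- pr2_bias(list(g1 = cc))
  expect_equal(res$genes$a3 + res$genes$t3 + res$genes$g3 + res$genes$c3, 4)
})

test_that("PR2 means approach parity on mutation-balanced simulations", {
  sim <- simulate_cds_set(synthetic_config(n_genes = 200, s_sel = 0,
                                           gc3_shape = c(60, 60), seed = 23))
  res <- pr2_bias(sim$set)
  expect_true(res$mean_x >= 0 && res$mean_x <= 1)
  se_x <- res$sd_x / sqrt(nrow(res$genes))
  se_y <- res$sd_y / sqrt(nrow(res$genes))
  expect_lt(abs(res$mean_x - 0.5), 3 * se_x)
  expect_lt(abs(res$mean_y - 0.5), 3 * se_y)
})

test_that("correspondence analysis matches an independent decomposition", {
  withr::local_seed(7)
  m <- matrix(rexp(9) + 0.1, 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  ca <- correspondence_analysis(m, naxes = 2)

  or <- suppressWarnings(MASS::corresp(m, nf = 2))
  # MASS returns standard coordinates; convert to principal coordinates
  oracle_coords <- sweep(or$rscore, 2, or$cor, `*`)
  for (k in 1:2) {
    a <- ca$row_coords[, k]
    b <- oracle_coords[, k]
    expect_equal(abs(cor(a, b)), 1, tolerance = 1e-8)
    expect_equal(sort(abs(a)), sort(abs(b)), tolerance = 1e-8)
  }
  expect_equal(ca$singular_values[1:2], unname(or$cor), tolerance = 1e-8)
})

test_that("CA handles degenerate inputs without exceptions", {
  # identical rows: no inertia
  m <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  ca <- correspondence_analysis(m)
  expect_true(all(ca$inertia_fraction == 0))
  expect_true(all(ca$row_coords == 0))

  # rank-deficient tiny input: fewer axes, no error
  m <- matrix(c(1, 2, 2, 4, 1, 2), 3, 2, byrow = TRUE)
  expect_no_error(ca <- correspondence_analysis(m, naxes = 4))
  expect_lte(ca$naxes, 2)

  # zero row dropped with warning
  m <- rbind(a = c(1, 2, 3), b = c(0, 0, 0), c = c(3, 1, 1))
  expect_warning(ca <- correspondence_analysis(m), "all-zero")
  expect_equal(nrow(ca$row_coords), 2)
})

test_that("CA axis 1 separates GC-rich from AT-rich genes and is GC-oriented", {
  sim_hi <- simulate_cds_set(synthetic_config(n_genes = 40, s_sel = 0,
                                              gc3_shape = c(60, 8),
                                              seed = 1))
  sim_lo <- simulate_cds_set(synthetic_config(n_genes = 40, s_sel = 0,
                                              gc3_shape = c(8, 60),
                                              seed = 2))
  ids <- c(paste0("hi_", sim_hi$set$id), paste0("lo_", sim_lo$set$id))
  set <- cds_set(ids, c(sim_hi$set$seq, sim_lo$set$seq))
  idx <- codon_usage_indices(set)
  m <- rscu_matrix(set)
  ca <- correspondence_analysis(m, gc = idx$gc_all)
  ax1 <- ca$row_coords[, 1]
  hi <- ax1[startsWith(ids, "hi_")]
  lo <- ax1[startsWith(ids, "lo_")]
  # complete separation at strong bias
  expect_true(max(hi) < min(lo) || max(lo) < min(hi))
  # orientation: GC-rich genes on the negative side
  expect_lt(cor(ax1, idx$gc_all), 0)
  expect_lt(mean(hi), mean(lo))
})

test_that("CA gene coordinates are invariant under duplicating every gene", {
  withr::local_seed(12)
  sim <- simulate_cds_set(synthetic_config(n_genes = 15, seed = 5))
  m <- rscu_matrix(sim$set)
  m[is.na(m)] <- 0
  ca1 <- correspondence_analysis(m)
  m2 <- rbind(m, m)
  rownames(m2) <- make.unique(rownames(m2))
  ca2 <- correspondence_analysis(m2)
  for (k in seq_len(min(ca1$naxes, ca2$naxes))) {
    a <- ca1$row_coords[, k]
    b <- ca2$row_coords[seq_len(nrow(m)), k]
    expect_equal(abs(a), abs(b), tolerance = 1e-6)
  }
  expect_equal(ca1$inertia_fraction, ca2$inertia_fraction, tolerance = 1e-8)
})

test_that("inertia fractions are non-negative, non-increasing and sum to 1", {
  sim <- simulate_cds_set(synthetic_config(n_genes = 20, seed = 8))
  m <- rscu_matrix(sim$set)
  ca <- correspondence_analysis(m, naxes = 59)
  f <- ca$inertia_fraction
  expect_true(all(f >= 0))
  expect_true(all(diff(f) <= 1e-12))
  expect_equal(sum(f), 1)
})

test_that("gene classification applies thresholds with precedence", {
  idx <- data.frame(id = c("r1", "h1", "a1", "o1", "edge"),
                    gravy = c(6, 6, 0, 0, 5),
                    aromo = c(0.2, 0.05, 0.15, 0.1, 0.15))
  labels <- classify_genes(idx, ribosomal_ids = "r1")
  expect_identical(as.character(labels$label),
                   c("ribosomal", "hydrophobic", "aromatic", "other",
                     "aromatic"))  # gravy 5 is not > 5; aromo 0.15 inclusive
  expect_warning(classify_genes(idx, ribosomal_ids = "absent"), "absent")
})

test_that("correlation battery behaves on identity, monotone and null pairs", {
  withr::local_seed(3)
  n <- 40
  idx <- data.frame(
    id = sprintf("g%02d", 1:n),
    length_codons = sample(100:400, n), gc1 = runif(n), gc2 = runif(n),
    gc3 = runif(n), gc3s = runif(n), gc12 = runif(n), gc_all = runif(n),
    enc = runif(n, 20, 61), cai = runif(n), gravy = rnorm(n),
    aromo = runif(n, 0, 0.3)
  )
  # monotone transform: rho(cai, exp(cai)) = 1 via the enc slot
  idx$enc <- exp(idx$cai)
  bat <- correlation_battery(idx)
  row <- bat[bat$var1 == "cai" & bat$var2 == "enc", ]
  expect_equal(row$rho, 1)
  expect_equal(nrow(bat), 12)
  # no CA supplied: axis-1 rows reported as missing
  expect_true(all(is.na(bat$rho[bat$var1 == "axis1"])))

  # independent variables: small rho at n = 1000
  withr::local_seed(31)
  big <- idx[rep(1, 1000), ]
  big$id <- sprintf("g%04d", 1:1000)
  big$cai <- runif(1000)
  big$enc <- runif(1000, 20, 61)
  bat <- correlation_battery(big)
  expect_lt(abs(bat$rho[bat$var1 == "cai" & bat$var2 == "enc"]), 0.1)
})
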