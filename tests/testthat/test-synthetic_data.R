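test_that("forward model is seed-deterministic", {
  truth1 <- simulate_truth(n_genes = 100, n_imprinted = 6, n_x = 10, seed = 5)
  truth2 <- simulate_truth(n_genes = 100, n_imprinted = 6, n_x = 10, seed = 5)
  expect_identical(truth1, truth2)
  s1 <- simulate_reciprocal_cross(truth1, n_per_direction = 2, n_maternal = 2,
                                  library_size = 1e5, seed = 9)
  s2 <- simulate_reciprocal_cross(truth2, n_per_direction = 2, n_maternal = 2,
                                  library_size = 1e5, seed = 9)
  expect_identical(s1$allele_counts, s2$allele_counts)
  expect_identical(s1$counts, s2$counts)
})

test_that("truth invariants hold: non-imprinted autosomes biallelic, X maternal", {
  truth <- simulate_truth(n_genes = 300, n_imprinted = 10, n_x = 30, seed = 2)
  g <- truth$genes
  auto_ni <- !g$imprinted & g$chromosome != "chrX"
  expect_true(all(g$theta[auto_ni] == 0.5))
  xg <- g$chromosome == "chrX"
  expect_true(all(g$theta[xg & g$x_class == "maternal"] > 0.9))
  expect_true(sum(g$x_class == "paternal", na.rm = TRUE) == 1)
  expect_true(all(g$theta[which(g$x_class == "escaper")] == 0.5))
  # ground truth never leaks into pipeline inputs
  sim <- simulate_reciprocal_cross(truth, n_per_direction = 2, n_maternal = 2,
                                   library_size = 1e5, seed = 3)
  expect_false(any(c("theta", "rho", "imprinted") %in% names(sim$allele_counts)))
  expect_false(any(c("theta", "rho", "imprinted") %in% names(sim$sites)))
})

test_that("simulated maternal fraction converges to the closed-form mixture", {
  # c = 0.1, m = e, theta = 0.5: expected maternal fraction
  # (0.5 * 0.9 + 0.1) / 1 = 0.55
  n_genes <- 200
  truth <- simulate_truth(n_genes = n_genes, n_imprinted = 0, n_x = 0,
                          cis_sd_shape = 1e6, me_sdlog = 0, seed = 11)
  expect_equal(truth$genes$maternal_tpm, truth$genes$base_tpm, tolerance = 1e-9)
  sim <- simulate_reciprocal_cross(truth, n_per_direction = 1,
                                   library_size = 2e6, n_maternal = 2,
                                   contamination = 0.1, seed = 12)
  ac <- sim$allele_counts
  f <- ac$maternal / (ac$maternal + ac$paternal)
  se <- stats::sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.55), 3 * se + 1e-12)

  # no contamination, no signal: fraction 0.5 in both directions
  sim0 <- simulate_reciprocal_cross(truth, n_per_direction = 1,
                                    library_size = 2e6, n_maternal = 2,
                                    contamination = 0, seed = 13)
  f0 <- sim0$allele_counts$maternal /
    (sim0$allele_counts$maternal + sim0$allele_counts$paternal)
  expect_lt(abs(mean(f0) - 0.5), 3 * stats::sd(f0) / sqrt(length(f0)))
})

test_that("complete maternal imprinting yields bias 1 in expectation", {
  truth <- simulate_truth(n_genes = 600, n_imprinted = 0, n_x = 0,
                          cis_sd_shape = 1e6, seed = 21)
  truth$genes$theta[] <- 1
  sim <- simulate_reciprocal_cross(truth, n_per_direction = 2,
                                   library_size = 1e6, n_maternal = 2,
                                   contamination = 0, seed = 22)
  bias <- suppressMessages(
    ase_bias_table(sim$allele_counts, sim$meta, "dom_x_dom", cfg = pi_config())
  )
  expect_equal(mean(bias$P1, na.rm = TRUE), 1)
  expect_equal(mean(bias$P2, na.rm = TRUE), 0)
  expect_equal(mean(bias$raw_bias, na.rm = TRUE), 1)
})

test_that("invalid truth parameters are rejected", {
  truth <- simulate_truth(n_genes = 50, n_imprinted = 2, n_x = 5, seed = 1)
  truth$genes$theta[1] <- 1.2
  expect_error(simulate_reciprocal_cross(truth, seed = 1), "theta")
  truth$genes$theta[1] <- 0.5
  truth$genes$rho[2] <- -0.1
  expect_error(simulate_reciprocal_cross(truth, seed = 1), "rho")
})

test_that("layer matrices reflect the truth profile under the induction rule", {
  truth <- simulate_truth(n_genes = 1500, frac_induced = 0.2, seed = 31)
  g <- truth$genes
  prof <- as.matrix(g[, truth$layers])
  # truth-induced genes satisfy the 2x rule on expected values; others do not
  for (j in 1:3) {
    ind <- !is.na(g$induced_layer) & g$induced_layer == truth$layers[j]
    others <- rowSums(prof[, -j, drop = FALSE])
    expect_true(all(prof[ind, j] >= 2 * others[ind]))
  }
  flat <- is.na(g$induced_layer)
  hits <- sapply(1:3, function(j) prof[flat, j] >= 2 * rowSums(prof[flat, -j, drop = FALSE]))
  expect_lt(mean(rowSums(hits) > 0), 0.01)
})

test_that("bisulfite reads honour methylation state and conversion", {
  # conversion 1.0, methylation 0: every read C is converted on its strand
  bs <- simulate_bisulfite_set(region_length = 1200, n_cpgs = 10, n_snvs = 5,
                               meth_maternal = 0, meth_paternal = 0,
                               conversion = 1.0, seed = 3)
  reads <- simulate_bisulfite_reads(bs, n_reads = 50, seed = 4)
  plus <- reads$sequence[reads$strand == "+"]
  expect_false(any(grepl("C", plus)))
  minus <- reads$sequence[reads$strand == "-"]
  expect_false(any(grepl("G", minus)))

  # methylation 1: the CpG cytosine is retained in every covering plus read
  bs1 <- simulate_bisulfite_set(region_length = 1200, n_cpgs = 10, n_snvs = 5,
                                meth_maternal = 1, meth_paternal = 1,
                                conversion = 1.0, seed = 5)
  reads1 <- simulate_bisulfite_reads(bs1, n_reads = 200, seed = 6)
  for (i in which(reads1$strand == "+")) {
    s <- reads1$pos[i]
    covered <- bs1$cpg_positions[bs1$cpg_positions >= s &
                                   bs1$cpg_positions < s + bs1$read_length]
    if (!length(covered)) next
    bases <- substring(reads1$sequence[i], covered - s + 1, covered - s + 1)
    expect_true(all(bases == "C"))
  }

  # a 50% parental mix partitions within the binomial 99% interval
  bs2 <- simulate_bisulfite_set(region_length = 4000, n_cpgs = 30, n_snvs = 40,
                                conversion = 1.0, seed = 7)
  reads2 <- simulate_bisulfite_reads(bs2, n_reads = 1000, maternal_frac = 0.5,
                                     seed = 8)
  pr <- partition_reads(reads2, bs2$variants)
  assigned <- pr[pr$parent %in% c("maternal", "paternal"), ]
  frac <- mean(assigned$parent == "maternal")
  ci <- qbinom(c(0.005, 0.995), nrow(assigned), 0.5) / nrow(assigned)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])

  expect_error(simulate_bisulfite_set(conversion = 0.4), "conversion")
})
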