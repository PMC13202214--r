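test_that("M:E ratios and the high-M:E flag follow the threshold", {
  emb <- matrix(c(100, 100, 100, 100, 100, 100), 3, 2,
                dimnames = list(c("a", "b", "c"), c("e1", "e2")))
  mat <- matrix(c(100, 400, 0, 100, 400, 0), 3, 2,
                dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  me <- compute_me_ratios(emb, mat, "WSB")
  expect_equal(me$ratio[me$gene_id == "a"], 1)
  expect_false(me$high_me[me$gene_id == "a"])
  expect_equal(me$ratio[me$gene_id == "b"], 4)
  expect_true(me$high_me[me$gene_id == "b"])
  expect_equal(me$ratio[me$gene_id == "c"], 0)
  expect_false(me$high_me[me$gene_id == "c"])
  # maternal-only expression: infinite ratio, flagged
  emb0 <- emb; emb0["c", ] <- 0
  mat0 <- mat; mat0["c", ] <- 50
  me0 <- compute_me_ratios(emb0, mat0, "WSB")
  expect_true(is.infinite(me0$ratio[me0$gene_id == "c"]))
  expect_true(me0$high_me[me0$gene_id == "c"])
  expect_error(compute_me_ratios(emb, mat[, 1, drop = FALSE], "WSB"),
               ">= 2 maternal-tissue replicates")
})

test_that("balanced genes are autosomal, unvalidated, powered and near 1:1", {
  genes <- sprintf("g%d", 1:6)
  bias <- make_bias_frame(genes, bias = 0, p_bonf = 1)
  bias$P1 <- c(0.52, 0.70, 0.50, 0.52, 0.52, NA)
  bias$P2 <- c(0.50, 0.68, 0.50, 0.50, 0.50, NA)
  bias$powered <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  ann <- make_annotations(genes)
  ann$chromosome[4] <- "chrX"
  ann$validated_imprinted[3] <- "maternal"
  cfg <- pi_config(min_balanced_genes = 1)
  out <- suppressMessages(select_balanced_genes(bias, ann, cfg))
  expect_identical(out, "g1")  # g2 cis-imbalanced, g3 validated, g4 X, g5 unpowered, g6 NA
  cfg200 <- pi_config()
  expect_error(suppressMessages(select_balanced_genes(bias, ann, cfg200)),
               "balanced genes")
})

test_that("mixture inversion recovers contamination from allelic deviation", {
  # e = m = 100, observed maternal fraction 0.55 -> c = 0.1
  genes <- sprintf("g%d", 1:10)
  meta <- make_meta(n = 1)
  # contamination inflates the maternal-allele fraction in both directions
  ac <- make_allele_counts(genes, f_fwd = 0.55, f_rev = 0.55, total = 10000,
                           n = 1)
  me <- data.frame(gene_id = genes, maternal_genotype = "WSB",
                   m = 100, e = 100, ratio = 1, high_me = FALSE)
  me <- rbind(me, transform(me, maternal_genotype = "LEW"))
  est <- estimate_contamination(ac, meta, genes, me)
  expect_equal(est$c_median, rep(0.1, 2), tolerance = 1e-9)

  # no deviation -> c = 0
  ac0 <- make_allele_counts(genes, 0.5, 0.5, total = 10000, n = 1)
  est0 <- estimate_contamination(ac0, meta, genes, me)
  expect_equal(est0$c_median, rep(0, 2))
})

test_that("contamination contribution follows the exact mixture form", {
  expect_equal(contamination_contribution(0, 5), 0)
  expect_equal(contamination_contribution(0.5, 0), 0)
  expect_equal(contamination_contribution(0.069, 1), 0.069, tolerance = 1e-9)
  expect_equal(contamination_contribution(0.069, 3), 0.182, tolerance = 1e-3)
  expect_equal(contamination_contribution(0.069, Inf), 1)
  # product form is the first-order approximation
  expect_equal(contamination_contribution(0.01, 1, method = "product"), 0.01)
  expect_gt(contamination_contribution(0.3, 5, method = "product"),
            contamination_contribution(0.3, 5))
  # monotone in both arguments
  cs <- seq(0, 0.4, by = 0.05)
  expect_true(all(diff(contamination_contribution(cs, 2)) > 0))
  rs <- seq(0, 10, by = 0.5)
  expect_true(all(diff(contamination_contribution(0.07, rs)) > 0))
  expect_error(contamination_contribution(1.2, 1), "\\[0, 1\\)")
})

test_that("corrected scores subtract the predicted contribution and clip", {
  genes <- c("a", "b", "c")
  bias <- make_bias_frame(genes, bias = c(0.5, 0.9, -0.9), p_bonf = 1e-5)
  me <- data.frame(gene_id = genes, maternal_genotype = "WSB",
                   m = c(100, 100, 100), e = c(100, 100, 100),
                   ratio = c(1, 1, 1), high_me = FALSE)
  out <- corrected_bias(bias, me, 0)
  expect_equal(out$corrected_bias, bias$raw_bias)  # c = 0: unchanged
  out2 <- corrected_bias(bias, me, 0.069)
  expect_equal(out2$corrected_bias, bias$raw_bias - 0.069, tolerance = 1e-9)
  # infinite ratio: not correctable
  me$ratio[1] <- Inf; me$high_me[1] <- TRUE
  out3 <- corrected_bias(bias, me, 0.069)
  expect_true(is.na(out3$corrected_bias[1]))
  expect_true(out3$high_me[1])
})

test_that("round-trip: correction recentres biallelic genes and keeps imprinting", {
  truth <- simulate_truth(n_genes = 1200, n_imprinted = 20, n_x = 0, seed = 15)
  sim <- simulate_reciprocal_cross(truth, n_per_direction = 5,
                                   library_size = 4e6, n_maternal = 3,
                                   contamination = 0.08, seed = 16)
  ann <- build_annotations(truth, seed = 17)
  res <- suppressMessages(analyze_cross(sim, ann))
  b <- res$corrected
  g <- truth$genes
  ni <- match(g$gene_id[!g$imprinted], b$gene_id)
  cb <- b$corrected_bias[ni]
  se <- stats::sd(cb, na.rm = TRUE) / sqrt(sum(!is.na(cb)))
  expect_lt(abs(mean(cb, na.rm = TRUE)), 3 * se)
  # imprinted genes stay centred on the truth-derived value: the correction
  # removes the additive inflation D but not the multiplicative dilution of
  # the embryonic signal, so the expectation is (2 theta - 1) (1 - D)
  imp <- g[g$imprinted, ]
  r_true <- imp$maternal_tpm / imp$base_tpm
  D_true <- contamination_contribution(0.08, r_true)
  expected <- (2 * imp$theta - 1) * (1 - D_true)
  got <- b$corrected_bias[match(imp$gene_id, b$gene_id)]
  keep <- !is.na(got)
  expect_lt(mean(abs(got[keep] - expected[keep])), 0.05)
})

test_that("contamination estimator error shrinks with the balanced-gene count", {
  truth <- simulate_truth(n_genes = 3000, n_imprinted = 0, n_x = 0, seed = 18)
  sim <- simulate_reciprocal_cross(truth, n_per_direction = 2,
                                   library_size = 8e6, n_maternal = 3,
                                   contamination = 0.07, seed = 19)
  ann <- build_annotations(truth, seed = 20)
  lengths <- setNames(ann$annotated_length, ann$gene_id)
  emb_tpm <- compute_tpm_fpkm(sim$counts, lengths)$tpm
  mat_tpm <- compute_tpm_fpkm(sim$maternal_counts, lengths)$tpm
  mt <- sim$meta[sim$meta$tissue == "maternal_tissue", ]
  me <- do.call(rbind, lapply(unique(mt$dam_strain), function(gt) {
    compute_me_ratios(emb_tpm, mat_tpm[, mt$sample_id[mt$dam_strain == gt]], gt)
  }))
  bias <- suppressMessages(ase_bias_table(sim$allele_counts, sim$meta, "dom_x_dom"))
  balanced <- suppressMessages(select_balanced_genes(bias, ann,
                                                     pi_config(min_balanced_genes = 50)))
  set.seed(99)
  err <- sapply(c(50, 200, 1000), function(k) {
    sub <- sample(balanced, k)
    est <- estimate_contamination(sim$allele_counts, sim$meta, sub, me)
    mean(abs(est$c_median - 0.07))
  })
  expect_lt(err[3], 0.01)
  expect_lt(err[3], err[1] + 0.005)
})
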