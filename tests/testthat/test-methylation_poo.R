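test_that("read partitioning respects conversion-aware informativeness", {
  variants <- data.frame(pos = c(10, 30), maternal = c("G", "C"),
                         paternal = c("A", "T"), stringsAsFactors = FALSE)
  seq40 <- function(base10, base30) {
    s <- rep("T", 40)
    s[11] <- base10; s[31] <- base30
    paste(s, collapse = "")
  }
  # plus-strand read: A/G site informative, C/T site skipped
  r <- data.frame(read_id = "r1", chrom = "c", pos = 0, strand = "+",
                  sequence = seq40("G", "T"), stringsAsFactors = FALSE)
  out <- partition_reads(r, variants)
  expect_equal(out$parent, "maternal")
  expect_equal(out$informative_sites_used, 1L)  # C/T site not counted

  # the same C/T site on a minus-strand read IS informative
  r2 <- r; r2$strand <- "-"; r2$sequence <- seq40("G", "C")
  out2 <- partition_reads(r2, variants)
  expect_equal(out2$parent, "maternal")
  expect_equal(out2$informative_sites_used, 1L)  # A/G skipped instead

  # a converted maternal C reads as T on the plus strand and must not be
  # mistaken for the paternal T allele: the C/T site is skipped, and with no
  # other informative site the read stays ambiguous
  r3 <- r; r3$sequence <- seq40("T", "T")
  out3 <- partition_reads(r3, variants)
  expect_equal(out3$parent, "ambiguous")
  expect_false(out3$conflict)
  # sites supporting different parents conflict
  variants4 <- data.frame(pos = c(5, 20), maternal = c("G", "C"),
                          paternal = c("A", "G"), stringsAsFactors = FALSE)
  s <- rep("T", 40); s[6] <- "G"; s[21] <- "G"
  r4 <- data.frame(read_id = "r4", chrom = "c", pos = 0, strand = "+",
                   sequence = paste(s, collapse = ""), stringsAsFactors = FALSE)
  out4 <- partition_reads(r4, variants4)
  expect_equal(out4$parent, "ambiguous")
  expect_true(out4$conflict)

  # read spanning no variant: ambiguous without conflict
  r5 <- data.frame(read_id = "r5", chrom = "c", pos = 100, strand = "+",
                   sequence = "TTTT", stringsAsFactors = FALSE)
  out5 <- partition_reads(r5, variants)
  expect_equal(out5$parent, "ambiguous")
  expect_false(out5$conflict)
})

test_that("partitioning is perfect with conversion-safe sites at rate 1.0", {
  bs <- simulate_bisulfite_set(region_length = 4000, n_cpgs = 40, n_snvs = 30,
                               conversion = 1.0, seed = 5)
  reads <- simulate_bisulfite_reads(bs, n_reads = 800, seed = 6)
  pr <- partition_reads(reads, bs$variants)
  assigned <- pr$parent %in% c("maternal", "paternal")
  expect_gt(mean(assigned), 0.3)
  expect_equal(mean(pr$parent[assigned] == pr$true_parent[assigned]), 1)
  # realistic conversion: error below 0.5%
  bs99 <- simulate_bisulfite_set(region_length = 4000, n_cpgs = 40, n_snvs = 30,
                                 conversion = 0.99, seed = 5)
  reads99 <- simulate_bisulfite_reads(bs99, n_reads = 2000, seed = 7)
  pr99 <- partition_reads(reads99, bs99$variants)
  a99 <- pr99$parent %in% c("maternal", "paternal")
  expect_lt(mean(pr99$parent[a99] != pr99$true_parent[a99]), 0.005)
})

test_that("CpG levels pool strands and enforce the coverage filter", {
  # hand-built reads over one CpG at position 10 (C at 10, G at 11)
  mk_read <- function(id, strand, meth) {
    base <- if (strand == "+") { if (meth) "C" else "T" }
            else { if (meth) "G" else "A" }
    s <- rep("A", 20)
    s[if (strand == "+") 11 else 12] <- base
    data.frame(read_id = id, chrom = "c", pos = 0, strand = strand,
               sequence = paste(s, collapse = ""), parent = "maternal",
               stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, c(
    lapply(1:6, function(i) mk_read(paste0("p", i), "+", i <= 3)),
    lapply(1:6, function(i) mk_read(paste0("m", i), "-", i <= 3))
  ))
  rec <- call_cpg_levels(reads, cpg_positions = 10, chrom = "c")
  expect_equal(rec$total_reads, 12)   # 6 + 6 pooled across strands
  expect_equal(rec$level, 0.5)
  # 9 reads: filtered out by the coverage rule
  rec9 <- call_cpg_levels(reads[1:9, ], cpg_positions = 10)
  expect_equal(nrow(rec9), 0)
})

test_that("the DMR caller merges significant CpGs and respects minima", {
  mk_rec <- function(pos, meth, tot, parent) {
    data.frame(chromosome = "c", position = pos, parent = parent,
               methylated_reads = meth, total_reads = tot,
               level = meth / tot, stringsAsFactors = FALSE)
  }
  pos <- seq(0, 900, by = 100)
  m <- mk_rec(pos, 27, 30, "maternal")   # level 0.9
  p <- mk_rec(pos, 3, 30, "paternal")    # level 0.1
  dmrs <- call_poo_dmrs(m, p)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$direction, "maternal_methylated")
  expect_equal(dmrs$n_cpgs, 10)
  expect_equal(dmrs$start, 0)
  expect_equal(dmrs$end, 902)
  # identical levels: nothing called
  expect_equal(nrow(call_poo_dmrs(m, m)), 0)
  # only 4 significant CpGs: below the minimum
  dmr4 <- call_poo_dmrs(mk_rec(pos[1:4], 27, 30, "maternal"),
                        mk_rec(pos[1:4], 3, 30, "paternal"))
  expect_equal(nrow(dmr4), 0)
  # a gap beyond 300 bp splits regions
  pos2 <- c(seq(0, 500, by = 100), seq(2000, 2500, by = 100))
  dmr2 <- call_poo_dmrs(mk_rec(pos2, 27, 30, "maternal"),
                        mk_rec(pos2, 3, 30, "paternal"))
  expect_equal(nrow(dmr2), 2)
})

test_that("implanted DMRs are recovered from simulated bisulfite reads", {
  # four implanted maternal-methylated blocks (delta 0.8) on a background of
  # equal methylation; coverage far above 20 per parent per CpG
  n_cpgs <- 60
  m_prob <- rep(0.5, n_cpgs)
  p_prob <- rep(0.5, n_cpgs)
  blocks <- list(6:13, 20:27, 34:41, 48:55)
  for (b in blocks) { m_prob[b] <- 0.9; p_prob[b] <- 0.1 }
  bs <- simulate_bisulfite_set(region_length = 8000, n_cpgs = n_cpgs,
                               n_snvs = 80, meth_maternal = m_prob,
                               meth_paternal = p_prob, conversion = 0.99,
                               seed = 8)
  reads <- simulate_bisulfite_reads(bs, n_reads = 16000, seed = 9)
  pd <- partition_reads(reads, bs$variants)
  cpg <- call_cpg_levels(pd, bs$cpg_positions, chrom = bs$chrom)
  dmrs <- call_poo_dmrs(cpg[cpg$parent == "maternal", ],
                        cpg[cpg$parent == "paternal", ])
  expect_true(all(dmrs$direction == "maternal_methylated"))
  hit <- vapply(blocks, function(b) {
    lo <- bs$cpg_positions[min(b)]; hi <- bs$cpg_positions[max(b)]
    any(dmrs$start <= hi & dmrs$end > lo)
  }, logical(1))
  expect_equal(mean(hit), 1)  # every implanted block recovered
  # no calls outside the implanted blocks
  inside <- vapply(seq_len(nrow(dmrs)), function(i) {
    any(vapply(blocks, function(b) {
      dmrs$start[i] >= bs$cpg_positions[min(b)] - 150 &&
        dmrs$end[i] <= bs$cpg_positions[max(b)] + 150
    }, logical(1)))
  }, logical(1))
  expect_true(all(inside))
})

test_that("no directional artifact on a symmetric methylation simulation", {
  bs <- simulate_bisulfite_set(region_length = 3000, n_cpgs = 30, n_snvs = 40,
                               meth_maternal = 0.5, meth_paternal = 0.5,
                               conversion = 0.99, seed = 10)
  reads <- simulate_bisulfite_reads(bs, n_reads = 5000, seed = 11)
  pd <- partition_reads(reads, bs$variants)
  cpg <- call_cpg_levels(pd, bs$cpg_positions, chrom = bs$chrom)
  lm_ <- cpg$level[cpg$parent == "maternal"]
  lp <- cpg$level[cpg$parent == "paternal"]
  se <- sqrt(stats::var(lm_) / length(lm_) + stats::var(lp) / length(lp))
  expect_lt(abs(mean(lm_) - mean(lp)), 3 * se)
  expect_equal(nrow(call_poo_dmrs(cpg[cpg$parent == "maternal", ],
                                  cpg[cpg$parent == "paternal", ])), 0)
})

test_that("DMRs link to genes within the 2 kb window and inherit clusters", {
  dmrs <- data.frame(chromosome = "chr7", start = c(10000, 10000, 25000),
                     end = c(10500, 10500, 25500),
                     direction = "maternal_methylated", n_cpgs = 6,
                     mean_level_diff = 0.5, stringsAsFactors = FALSE)
  ann <- make_annotations(c("near", "far", "inside"), chromosome = "chr7")
  ann$start <- c(12000, 13000, 25100); ann$end <- c(14000, 15000, 25300)
  ann$imprinted_cluster_id <- c(NA, NA, "Kcnq1_cluster")
  linked <- link_dmrs(dmrs[c(1, 3), ], ann)
  # DMR ends 1,500 bp upstream of "near" (12000 - 10500): linked;
  # 2,500 bp upstream of "far": not linked
  expect_equal(linked$linked_genes[1], "near")
  expect_equal(linked$linked_genes[2], "inside")
  expect_equal(linked$linked_cluster[2], "Kcnq1_cluster")
  expect_true(is.na(linked$linked_cluster[1]))
})

test_that("maternal methylation correction matches the worked arithmetic", {
  rec <- data.frame(chromosome = "c", position = 0, parent = "maternal",
                    methylated_reads = 60, total_reads = 100, level = 0.6)
  out <- correct_maternal_methylation(rec, 0.068)
  expect_equal(out$methylated_reads, 53.2)
  expect_equal(out$total_reads, 93.2)
  expect_equal(out$level, 53.2 / 93.2, tolerance = 1e-12)
  # idempotent at c = 0
  expect_identical(correct_maternal_methylation(rec, 0), rec)
  # floor rule
  rec2 <- transform(rec, methylated_reads = 5, level = 0.05)
  out2 <- correct_maternal_methylation(rec2, 0.068)
  expect_equal(out2$methylated_reads, 0)
  expect_equal(out2$total_reads, 93.2)
  expect_error(correct_maternal_methylation(rec, 1), "\\[0, 1\\)")
})
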