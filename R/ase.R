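#' Power filter for allele-specific expression
#'
#' A replicate is powered for a gene when it carries at least
#' `min_diag_variants` diagnostic variants with assigned reads whose maximum
#' pairwise separation is at least `min_variant_separation_bp` (one read
#' length, so the variants tag independent reads) and the total assigned
#' reads across variants reach `min_ase_coverage`. A gene is powered when at
#' least `min_powered_replicates` replicates pass.
#'
#' @param sites `data.frame` with columns `gene_id, sample_id, position,
#'   assigned_reads` (diagnostic-variant coverage per replicate).
#' @param cfg [pi_config()].
#' @return `data.frame` per gene: `gene_id, n_powered_replicates, powered`.
#' @export
power_filter <- function(sites, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  dt <- data.table::as.data.table(sites)[assigned_reads > 0]
  rep_pass <- dt[, .(
    n_var = .N,
    span = max(position) - min(position),
    total = sum(assigned_reads)
  ), by = .(gene_id, sample_id)]
  rep_pass[, pass := n_var >= cfg$min_diag_variants &
             span >= cfg$min_variant_separation_bp &
             total >= cfg$min_ase_coverage]
  out <- rep_pass[, .(n_powered_replicates = sum(pass)), by = gene_id]
  out[, powered := n_powered_replicates >= cfg$min_powered_replicates]
  res <- as.data.frame(out)
  # genes present in `sites` only with zero-read records
  all_genes <- unique(sites$gene_id)
  absent <- setdiff(all_genes, res$gene_id)
  if (length(absent)) {
    res <- rbind(res, data.frame(gene_id = absent, n_powered_replicates = 0L,
                                 powered = FALSE))
  }
  res
}

#' Pearson chi-square test for parent-of-origin expression
#'
#' Pearson chi-square with one degree of freedom and no continuity
#' correction on the 2x2 contingency table of (TPM-normalized) allele
#' expression by cross direction. Cells need not be integers; the statistic
#' is computed directly from observed and expected values. A zero row or
#' column makes the test undefined: the statistic is 0 and p = 1, with a
#' `degenerate` flag.
#'
#' @param tab 2x2 numeric matrix: rows = cross directions, columns = alleles.
#' @return List: `stat`, `p`, `degenerate`.
#' @examples
#' chisq_poo_test(rbind(c(70, 30), c(30, 70)))  # stat = 32
#' @export
chisq_poo_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0)) stop("negative cell in contingency table")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(stat = 0, p = 1, degenerate = TRUE))
  }
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Parent-of-origin bias scores for one cross type
#'
#' For each gene, P1 is the proportion of allelic expression from the
#' reference allele when it is maternally inherited (forward direction) and
#' P2 the proportion from the same allele when paternally inherited (reverse
#' direction); the reference allele is the dam strain of the forward
#' direction. The bias score P1 - P2 ranges from -1 (complete paternal
#' expression) to +1 (complete maternal expression); a cis effect shifts P1
#' and P2 equally and cancels in the difference. Each replicate's assigned
#' counts are scaled by its per-million assigned-library factor before being
#' summed across replicates, and the chi-square test is run on the pooled
#' direction-by-allele table.
#'
#' @param allele_counts Allele count table (see [read_allele_counts()]).
#' @param meta Sample metadata; only `whole_fetal_placenta` samples of
#'   `cross_type` are used.
#' @param cross_type Cross to analyse.
#' @param sites Diagnostic-variant records for the power filter, or `NULL`
#'   to skip it (all genes treated as powered).
#' @param cfg [pi_config()].
#' @return `data.frame` per gene: `gene_id, cross_type, P1, P2, raw_bias,
#'   chisq_stat, p_value, p_bonferroni, degenerate, powered,
#'   n_powered_replicates`. P1/P2 and the test are `NA` for unpowered genes;
#'   the Bonferroni factor is the number of powered, testable genes.
#' @export
ase_bias_table <- function(allele_counts, meta, cross_type, sites = NULL,
                           cfg = NULL) {
  cfg <- as_pi_config(cfg)
  emb <- meta[meta$cross_type == cross_type &
                meta$tissue == "whole_fetal_placenta", ]
  if (!nrow(emb)) stop("no embryonic placenta samples for ", cross_type)
  if (!all(c("forward", "reverse") %in% emb$direction)) {
    stop("reciprocal design requires both cross directions")
  }
  dt <- data.table::as.data.table(allele_counts)
  dt <- dt[sample_id %in% emb$sample_id]
  dt[, direction := emb$direction[match(sample_id, emb$sample_id)]]
  # reference allele = dam strain of the forward direction: its reads are the
  # maternal reads in forward samples and the paternal reads in reverse ones
  dt[, ref := ifelse(direction == "forward", maternal, paternal)]
  dt[, alt := ifelse(direction == "forward", paternal, maternal)]
  # per-sample TPM-style scaling of assigned counts
  lib <- dt[, .(lib = sum(ref + alt)), by = sample_id]
  dt[, scale := 1e6 / lib$lib[match(sample_id, lib$sample_id)]]
  pooled <- dt[, .(
    ref_fwd = sum(ref[direction == "forward"] * scale[direction == "forward"]),
    alt_fwd = sum(alt[direction == "forward"] * scale[direction == "forward"]),
    ref_rev = sum(ref[direction == "reverse"] * scale[direction == "reverse"]),
    alt_rev = sum(alt[direction == "reverse"] * scale[direction == "reverse"])
  ), by = gene_id]

  if (!is.null(sites)) {
    pw <- power_filter(sites[sites$sample_id %in% emb$sample_id, ], cfg)
    pooled[, n_powered_replicates :=
             pw$n_powered_replicates[match(gene_id, pw$gene_id)]]
    pooled[is.na(n_powered_replicates), n_powered_replicates := 0L]
    pooled[, powered := n_powered_replicates >= cfg$min_powered_replicates]
  } else {
    pooled[, n_powered_replicates := NA_integer_]
    pooled[, powered := TRUE]
  }
  # a direction with zero assigned expression leaves P undefined
  pooled[, testable := powered & (ref_fwd + alt_fwd) > 0 & (ref_rev + alt_rev) > 0]

  res <- as.data.frame(pooled)
  n <- nrow(res)
  P1 <- P2 <- stat <- p <- rep(NA_real_, n)
  degen <- rep(NA, n)
  idx <- which(res$testable)
  P1[idx] <- res$ref_fwd[idx] / (res$ref_fwd[idx] + res$alt_fwd[idx])
  P2[idx] <- res$ref_rev[idx] / (res$ref_rev[idx] + res$alt_rev[idx])
  for (i in idx) {
    ct <- chisq_poo_test(rbind(c(res$ref_fwd[i], res$alt_fwd[i]),
                               c(res$ref_rev[i], res$alt_rev[i])))
    stat[i] <- ct$stat; p[i] <- ct$p; degen[i] <- ct$degenerate
  }
  n_tested <- length(idx)
  out <- data.frame(
    gene_id = res$gene_id,
    cross_type = cross_type,
    P1 = P1, P2 = P2,
    raw_bias = P1 - P2,
    chisq_stat = stat,
    p_value = p,
    p_bonferroni = pmin(1, p * n_tested),
    degenerate = degen,
    powered = res$powered & res$testable,
    n_powered_replicates = res$n_powered_replicates,
    stringsAsFactors = FALSE
  )
  log_filter(paste0("power filter (", cross_type, ")"), n, sum(out$powered))
  out
}

#' Classify a gene's parent-of-origin bias
#'
#' Maternal when the (corrected) bias score reaches `+bias_cutoff` with a
#' Bonferroni-corrected p-value below `chisq_alpha`; paternal when it reaches
#' `-bias_cutoff` with the same significance; otherwise none. The score
#' cutoff is inclusive ("equal to or greater than 0.4").
#'
#' @param bias Numeric vector of bias scores.
#' @param p_bonferroni Matching Bonferroni-corrected p-values.
#' @param cfg [pi_config()].
#' @return Character vector in `c("maternal", "paternal", "none")`; `NA`
#'   bias or p yields `NA`.
#' @export
call_biased <- function(bias, p_bonferroni, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  out <- rep(NA_character_, length(bias))
  ok <- !is.na(bias) & !is.na(p_bonferroni)
  sig <- ok & p_bonferroni < cfg$chisq_alpha
  out[ok] <- "none"
  out[sig & bias >= cfg$bias_cutoff] <- "maternal"
  out[sig & bias <= -cfg$bias_cutoff] <- "paternal"
  out
}
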