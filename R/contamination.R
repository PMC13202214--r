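#' Maternal:embryonic expression ratios
#'
#' For each gene, the ratio r = m/e of its median TPM in maternal-tissue
#' dissections of a given maternal genotype to its median TPM in embryonic
#' placenta. The ratio multiplies the impact of maternal contamination on a
#' gene's apparent maternal bias; genes with r > `me_ratio_max` are flagged
#' `high_me`. A gene expressed in maternal tissue but not in the embryonic
#' placenta gets an infinite ratio (always `high_me`).
#'
#' @param embryonic_tpm TPM matrix of embryonic placenta samples (genes x
#'   samples).
#' @param maternal_tpm TPM matrix of maternal-tissue samples of one maternal
#'   genotype; at least two replicates.
#' @param maternal_genotype Label stored with the ratios.
#' @param cfg [pi_config()].
#' @return `data.frame`: `gene_id, maternal_genotype, m, e, ratio, high_me`.
#' @export
compute_me_ratios <- function(embryonic_tpm, maternal_tpm,
                              maternal_genotype = "NA", cfg = NULL) {
  cfg <- as_pi_config(cfg)
  if (ncol(maternal_tpm) < 2) {
    stop("need >= 2 maternal-tissue replicates for genotype ", maternal_genotype)
  }
  genes <- intersect(rownames(embryonic_tpm), rownames(maternal_tpm))
  if (!length(genes)) stop("no shared genes between matrices")
  e <- apply(embryonic_tpm[genes, , drop = FALSE], 1, stats::median)
  m <- apply(maternal_tpm[genes, , drop = FALSE], 1, stats::median)
  ratio <- ifelse(e > 0, m / e, ifelse(m > 0, Inf, 0))
  data.frame(gene_id = genes, maternal_genotype = maternal_genotype,
             m = m, e = e, ratio = ratio,
             high_me = ratio > cfg$me_ratio_max,
             stringsAsFactors = FALSE)
}

#' Select balanced genes for contamination estimation
#'
#' Contamination is estimated from genes whose allelic expression is
#' expected to be 1:1 absent contamination: powered autosomal genes, not on
#' the validated-imprint list, whose mean allelic fraction (P1 + P2)/2 falls
#' inside the configured window (default \[0.45, 0.55\], i.e. no appreciable
#' cis imbalance). Any observed deviation of such a gene's maternal-allele
#' fraction from 1/2 is then attributable to maternal contamination.
#'
#' @param bias Raw bias table from [ase_bias_table()].
#' @param annotations Gene annotations (needs `gene_id, chromosome,
#'   validated_imprinted`).
#' @param cfg [pi_config()].
#' @return Character vector of balanced gene ids (errors if fewer than
#'   `cfg$min_balanced_genes`).
#' @export
select_balanced_genes <- function(bias, annotations, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  ann <- annotations[match(bias$gene_id, annotations$gene_id), ]
  mean_frac <- (bias$P1 + bias$P2) / 2
  keep <- bias$powered &
    !is.na(mean_frac) &
    mean_frac >= cfg$balanced_window[1] &
    mean_frac <= cfg$balanced_window[2] &
    !(ann$chromosome %in% c("chrX", "X", "chrY", "Y")) &
    is.na(ann$validated_imprinted)
  genes <- bias$gene_id[keep]
  log_filter("balanced gene selection", nrow(bias), length(genes))
  if (length(genes) < cfg$min_balanced_genes) {
    stop("only ", length(genes), " balanced genes found (need >= ",
         cfg$min_balanced_genes, "); check power and the balanced window")
  }
  genes
}

#' Per-sample maternal contamination estimates
#'
#' Under the mixture model, a balanced gene's observed maternal-allele
#' fraction in a sample with contamination c is
#' `f(c) = (0.5 (1 - c) e + c m) / ((1 - c) e + c m)`, which inverts to
#' `c = e (2 f - 1) / (m (2 - 2 f) + e (2 f - 1))`. Each balanced gene
#' yields one estimate per sample (clipped to \[0, 1\]); the sample summary
#' is the median, with the maximum taken after trimming the top
#' `cmax_trim` fraction of per-gene estimates as an outlier guard. The
#' inversion is monotone in the observed fraction, so per-gene medians are
#' centred on the true contamination even for weakly informative genes.
#'
#' @param allele_counts Allele count table.
#' @param meta Sample metadata; estimates are produced for embryonic
#'   placenta samples present in `allele_counts`.
#' @param balanced_genes Gene ids from [select_balanced_genes()].
#' @param me `data.frame` of M:E ratios, one row per (gene, maternal
#'   genotype) from [compute_me_ratios()]; the genotype matching each
#'   sample's dam strain is used.
#' @param cfg [pi_config()].
#' @return `data.frame` per sample: `sample_id, c_median, c_max,
#'   n_balanced_genes`.
#' @export
estimate_contamination <- function(allele_counts, meta, balanced_genes, me,
                                   cfg = NULL) {
  cfg <- as_pi_config(cfg)
  emb <- meta[meta$tissue == "whole_fetal_placenta" &
                meta$sample_id %in% allele_counts$sample_id, ]
  dt <- data.table::as.data.table(allele_counts)
  dt <- dt[gene_id %in% balanced_genes & sample_id %in% emb$sample_id]
  dt[, dam := emb$dam_strain[match(sample_id, emb$sample_id)]]
  me_dt <- data.table::as.data.table(me)
  dt <- merge(dt, me_dt[, .(gene_id, maternal_genotype, m, e)],
              by.x = c("gene_id", "dam"), by.y = c("gene_id", "maternal_genotype"))
  dt <- dt[(maternal + paternal) > 0 & e > 0]
  dt[, f := maternal / (maternal + paternal)]
  dt[, chat := e * (2 * f - 1) / (m * (2 - 2 * f) + e * (2 * f - 1))]
  dt[, chat := pmin(pmax(chat, 0), 1)]
  # genes with no maternal-tissue expression carry no contamination signal
  dt <- dt[is.finite(chat) & m > 0]
  summ <- dt[, {
    ok <- chat[chat <= stats::quantile(chat, 1 - cfg$cmax_trim)]
    .(c_median = stats::median(chat), c_max = max(ok), n_balanced_genes = .N)
  }, by = sample_id]
  out <- merge(data.frame(sample_id = emb$sample_id), as.data.frame(summ),
               by = "sample_id", all.x = TRUE)
  if (anyNA(out$c_median)) {
    warning("no informative balanced genes for some samples; contamination set to 0")
    out$c_median[is.na(out$c_median)] <- 0
    out$c_max[is.na(out$c_max)] <- 0
    out$n_balanced_genes[is.na(out$n_balanced_genes)] <- 0L
  }
  out
}

#' Predicted contamination contribution to a bias score
#'
#' The exact mixture form `D(c, r) = c r / ((1 - c) + c r)`: the fraction of
#' a gene's observed expression contributed by maternal contamination, which
#' is exactly the inflation of the bias score for a biallelically expressed
#' gene. The first-order form `D = c r` (the product of sample contamination
#' and the gene's M:E ratio) is available via `method = "product"`; it
#' over-corrects when `c r` is large.
#'
#' @param c Contamination fraction(s) in \[0, 1).
#' @param r M:E ratio(s) (non-negative; `Inf` allowed).
#' @param method `"exact"` (default) or `"product"`.
#' @return Numeric vector of predicted contributions.
#' @examples
#' contamination_contribution(0.069, 1)  # 0.069
#' contamination_contribution(0.069, 3)  # ~0.182
#' @export
contamination_contribution <- function(c, r, method = c("exact", "product")) {
  method <- match.arg(method)
  if (any(c < 0 | c >= 1)) stop("contamination must be in [0, 1)")
  if (any(r < 0, na.rm = TRUE)) stop("M:E ratio must be non-negative")
  if (method == "product") return(c * r)
  ifelse(is.infinite(r), 1, c * r / ((1 - c) + c * r))
}

#' Contamination-corrected bias scores
#'
#' Subtracts the predicted contribution of maternal contamination from each
#' gene's raw bias score and clips the result to \[-1, 1\]. Genes with an
#' infinite M:E ratio cannot be corrected and are returned as `NA` with the
#' `high_me` flag.
#'
#' @param bias Bias table from [ase_bias_table()].
#' @param me M:E ratio table; when it contains several maternal genotypes
#'   the per-gene mean finite ratio is used (both reciprocal directions
#'   contribute to the pooled score).
#' @param contamination Scalar contamination fraction for this cross
#'   (typically the mean of per-sample medians, or of per-sample maxima for
#'   the stringent filter).
#' @param cfg [pi_config()]; `correction` selects exact vs product form.
#' @return `bias` with added columns `me_ratio, D, corrected_bias, high_me`.
#' @export
corrected_bias <- function(bias, me, contamination, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  me_dt <- data.table::as.data.table(me)
  r_gene <- me_dt[, .(ratio = mean(ratio), high_me = any(high_me)), by = gene_id]
  idx <- match(bias$gene_id, r_gene$gene_id)
  r <- r_gene$ratio[idx]
  bias$me_ratio <- r
  bias$high_me <- r_gene$high_me[idx]
  D <- contamination_contribution(contamination, ifelse(is.na(r), 0, r),
                                  method = cfg$correction)
  D[is.na(r)] <- NA_real_
  bias$D <- D
  corrected <- pmin(pmax(bias$raw_bias - D, -1), 1)
  corrected[is.infinite(r)] <- NA_real_
  bias$corrected_bias <- corrected
  bias
}
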