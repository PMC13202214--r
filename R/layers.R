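#' zFPKM transform of one sample
#'
#' Standardizes log2 FPKM against the background of actively transcribed
#' genes: the mode mu of a Gaussian kernel density fit (Silverman bandwidth)
#' to log2 FPKM of genes with nonzero FPKM, and a half-Gaussian spread fit to
#' the right shoulder, sigma = sqrt(pi/2) * mean(log2 FPKM - mu | log2 FPKM >
#' mu). zFPKM = (log2 FPKM - mu) / sigma. Genes with zero FPKM get -Inf.
#'
#' @param fpkm Numeric vector of FPKM values for one sample.
#' @param min_nonzero Minimum number of genes with FPKM > 0 required for a
#'   stable density fit.
#' @return List with `zfpkm` (same length/names as `fpkm`), `mu`, `sigma`.
#' @export
zfpkm_transform <- function(fpkm, min_nonzero = 500) {
  pos <- fpkm > 0
  if (sum(pos) < min_nonzero) {
    stop("need at least ", min_nonzero, " genes with FPKM > 0, got ", sum(pos))
  }
  lf <- log2(fpkm[pos])
  dens <- stats::density(lf, bw = "nrd0")
  mu <- dens$x[which.max(dens$y)]
  right <- lf[lf > mu]
  sigma <- sqrt(pi / 2) * mean(right - mu)
  z <- rep(-Inf, length(fpkm))
  names(z) <- names(fpkm)
  z[pos] <- (lf - mu) / sigma
  list(zfpkm = z, mu = mu, sigma = sigma)
}

#' zFPKM transform of a matrix, sample by sample
#'
#' @param fpkm Matrix of FPKM, genes x samples.
#' @inheritParams zfpkm_transform
#' @return Matrix of zFPKM with the same dimnames.
#' @export
zfpkm_matrix <- function(fpkm, min_nonzero = 500) {
  out <- apply(fpkm, 2, function(col) zfpkm_transform(col, min_nonzero)$zfpkm)
  dimnames(out) <- dimnames(fpkm)
  out
}

#' Call genes expressed per layer
#'
#' A gene is expressed in a layer when its median zFPKM across that layer's
#' replicates is strictly above the threshold.
#'
#' @param zfpkm Matrix of zFPKM, genes x samples.
#' @param layer Character/factor vector of layer labels, one per column.
#' @param threshold Expression threshold on zFPKM (default -3).
#' @return Logical matrix genes x layers.
#' @export
call_expressed <- function(zfpkm, layer, threshold = -3) {
  layers <- unique(as.character(layer))
  med <- sapply(layers, function(L) {
    apply(zfpkm[, layer == L, drop = FALSE], 1, stats::median)
  })
  med > threshold
}

#' Per-layer median expression
#'
#' @param mat Expression matrix (TPM or zFPKM), genes x samples.
#' @param layer Layer label per column.
#' @return Matrix genes x layers of medians.
#' @export
layer_medians <- function(mat, layer) {
  layers <- unique(as.character(layer))
  sapply(layers, function(L) {
    apply(mat[, layer == L, drop = FALSE], 1, stats::median)
  })
}

#' Call layer-induced genes
#'
#' A gene is induced in a layer when it is expressed there and its median
#' expression in that layer is at least `fold` times the sum of its median
#' expression in the other two layers ("at least" is inclusive). At most one
#' layer can satisfy the rule with `fold >= 2`.
#'
#' @param medians Matrix genes x 3 layers of median TPM.
#' @param expressed Logical matrix genes x 3 layers (see [call_expressed()]).
#' @param fold Induction fold (default 2).
#' @return Character vector, per gene the induced layer name or `NA`.
#' @export
call_induced <- function(medians, expressed, fold = 2) {
  if (ncol(medians) != 3) stop("induction rule is defined for exactly three layers")
  stopifnot(identical(dim(medians), dim(expressed)))
  out <- rep(NA_character_, nrow(medians))
  for (j in seq_len(3)) {
    others <- rowSums(medians[, -j, drop = FALSE])
    hit <- expressed[, j] & medians[, j] >= fold * others
    out[hit] <- colnames(medians)[j]
  }
  names(out) <- rownames(medians)
  out
}

#' Continuous layer-specificity score
#'
#' The difference between a gene's median expression in the focal layer and
#' the sum of its median expression in the other two layers. Positive scores
#' approach layer-specific expression; a flat profile scores negative.
#'
#' @param medians Matrix genes x 3 layers of median expression.
#' @return Matrix genes x 3 layers of scores.
#' @export
specificity_score <- function(medians) {
  if (ncol(medians) != 3) stop("specificity score is defined for exactly three layers")
  out <- medians
  for (j in seq_len(3)) {
    out[, j] <- medians[, j] - rowSums(medians[, -j, drop = FALSE])
  }
  out
}

#' Layer-induced expression calls for one species
#'
#' Convenience wrapper: normalizes counts, computes zFPKM, and applies the
#' expressed/induced rules and the specificity score.
#'
#' @param counts Count matrix genes x samples.
#' @param lengths Effective transcript lengths (bp).
#' @param layer Layer label per column (three layers expected).
#' @param cfg [pi_config()].
#' @return A list with `calls` (data.frame: gene_id, induced_layer, per-layer
#'   expressed flags), `medians` (TPM), `specificity`, `zfpkm`.
#' @export
layer_calls <- function(counts, lengths, layer, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  norm <- compute_tpm_fpkm(counts, lengths)
  z <- zfpkm_matrix(norm$fpkm)
  expressed <- call_expressed(z, layer, cfg$zfpkm_expressed)
  med <- layer_medians(norm$tpm, layer)
  zmed <- layer_medians(z, layer)
  induced <- call_induced(med, expressed, cfg$induced_fold)
  spec <- specificity_score(med)
  calls <- data.frame(gene_id = rownames(counts),
                      induced_layer = induced,
                      stringsAsFactors = FALSE)
  colnames(expressed) <- paste0("expressed_", colnames(expressed))
  calls <- cbind(calls, as.data.frame(expressed))
  list(calls = calls, medians = med, zfpkm_medians = zmed,
       specificity = spec, zfpkm = z)
}

#' Compare layer induction between two species
#'
#' Restricted to the shared gene universe after removing genes with very low
#' expression (all-layer median zFPKM below the expressed threshold) in
#' either species. Reports, per layer, the fraction of species-A induced
#' genes that are induced in the same layer in species B, the transcriptome-
#' wide Pearson correlation of specificity scores, and the fraction of the
#' discordance attributable to threshold effects (gene induced in A whose
#' fold-ratio in B falls inside the configured margin just below the
#' induction cutoff).
#'
#' @param calls_A,calls_B Results of [layer_calls()] for the two species.
#' @param cfg [pi_config()]; uses `threshold_margin` and `induced_fold`.
#' @return List with `overlap` (per layer), `correlation` (per layer, Pearson
#'   on specificity scores), `threshold_fraction` (per layer), `n_genes`.
#' @export
compare_species_induction <- function(calls_A, calls_B, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  shared <- intersect(rownames(calls_A$medians), rownames(calls_B$medians))
  keep <- shared[
    apply(calls_A$zfpkm_medians[shared, , drop = FALSE], 1, max) > cfg$zfpkm_expressed &
    apply(calls_B$zfpkm_medians[shared, , drop = FALSE], 1, max) > cfg$zfpkm_expressed
  ]
  if (!length(keep)) stop("no shared expressed genes between species")
  layers <- colnames(calls_A$medians)
  indA <- calls_A$calls$induced_layer[match(keep, calls_A$calls$gene_id)]
  indB <- calls_B$calls$induced_layer[match(keep, calls_B$calls$gene_id)]

  fold_ratio <- function(med, j) {
    others <- rowSums(med[, -j, drop = FALSE])
    ifelse(others > 0, med[, j] / others, Inf)
  }
  overlap <- thr_frac <- corr <- stats::setNames(numeric(length(layers)), layers)
  for (j in seq_along(layers)) {
    L <- layers[j]
    inA <- !is.na(indA) & indA == L
    if (any(inA)) {
      agree <- inA & !is.na(indB) & indB == L
      overlap[L] <- sum(agree) / sum(inA)
      discord <- inA & !agree
      frB <- fold_ratio(calls_B$medians[keep, , drop = FALSE], j)
      near <- discord & frB >= cfg$threshold_margin[1] & frB < cfg$threshold_margin[2]
      thr_frac[L] <- if (any(discord)) sum(near) / sum(inA) else 0
    } else {
      overlap[L] <- NA_real_
      thr_frac[L] <- NA_real_
    }
    corr[L] <- stats::cor(calls_A$specificity[keep, j], calls_B$specificity[keep, j])
  }
  list(overlap = overlap, correlation = corr,
       threshold_fraction = thr_frac, n_genes = length(keep))
}
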