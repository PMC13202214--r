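#' Expression filter for differential expression testing
#'
#' A gene enters DE testing when it is expressed (zFPKM above the threshold)
#' in at least `expressed_replicate_fraction` of the biological replicates of
#' each group.
#'
#' @param zfpkm Matrix of zFPKM, genes x samples.
#' @param group Group label per column (two groups expected).
#' @param cfg [pi_config()].
#' @return Character vector of gene ids kept.
#' @export
filter_expressed_for_de <- function(zfpkm, group, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  groups <- unique(as.character(group))
  if (length(groups) < 2) stop("need both groups present")
  pass <- rep(TRUE, nrow(zfpkm))
  for (gr in groups) {
    sub <- zfpkm[, group == gr, drop = FALSE]
    frac <- rowMeans(sub > cfg$zfpkm_expressed)
    pass <- pass & frac >= cfg$expressed_replicate_fraction
  }
  kept <- rownames(zfpkm)[pass]
  log_filter("DE expression filter", nrow(zfpkm), length(kept))
  kept
}

#' Classify differential expression
#'
#' Threshold rule on an upstream DE result table: differentially expressed
#' when |log2FC| is at least `de_abs_log2fc` and the adjusted p-value is at
#' most `de_padj` (both boundaries inclusive) and the gene is not flagged as
#' a transcript-length artifact.
#'
#' @param de `data.frame` with `gene_id, log2fc, padj` and optionally
#'   `length_flagged`.
#' @param cfg [pi_config()].
#' @return `de` with a logical `is_de` column added.
#' @export
classify_de <- function(de, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  flagged <- if ("length_flagged" %in% names(de)) de$length_flagged else FALSE
  de$is_de <- !is.na(de$log2fc) & !is.na(de$padj) &
    abs(de$log2fc) >= cfg$de_abs_log2fc & de$padj <= cfg$de_padj & !flagged
  de
}

#' Polarize expression changes with an outgroup
#'
#' A gene DE between the two ingroup lineages is assigned to the lineage in
#' which the change arose: derived in lineage A when it is also DE between A
#' and the outgroup but not between B and the outgroup (and symmetrically).
#' Genes DE in both outgroup contrasts, or in neither, show a gradient with
#' the outgroup intermediate and stay unpolarized. Polarity only depends on
#' which contrasts are DE, so it is invariant to the sign convention of the
#' fold changes.
#'
#' @param ingroup_de DE table for lineage A vs lineage B (with `is_de`).
#' @param a_vs_out_de,b_vs_out_de DE tables for each lineage against the
#'   outgroup.
#' @return `data.frame`: `gene_id, polarity`
#'   (`derived_A`/`derived_B`/`unpolarized`); only genes DE in the ingroup
#'   contrast receive a derived polarity.
#' @export
polarize <- function(ingroup_de, a_vs_out_de, b_vs_out_de) {
  genes <- ingroup_de$gene_id
  de_in <- ingroup_de$is_de
  de_a <- a_vs_out_de$is_de[match(genes, a_vs_out_de$gene_id)]
  de_b <- b_vs_out_de$is_de[match(genes, b_vs_out_de$gene_id)]
  de_a[is.na(de_a)] <- FALSE
  de_b[is.na(de_b)] <- FALSE
  polarity <- rep("unpolarized", length(genes))
  polarity[de_in & de_a & !de_b] <- "derived_A"
  polarity[de_in & de_b & !de_a] <- "derived_B"
  data.frame(gene_id = genes, polarity = polarity, stringsAsFactors = FALSE)
}

#' Empirical transcript length from RNA-seq contigs
#'
#' The covered transcript length is the total size of the intersection of
#' the exon union with the union of RNA-seq contigs overlapping the gene
#' (all intervals 0-based half-open).
#'
#' @param exons Two-column matrix/data.frame of exon `start`, `end`.
#' @param contigs Two-column matrix/data.frame of contig `start`, `end`.
#' @return Covered length in bp.
#' @examples
#' recalc_transcript_length(rbind(c(0, 100), c(200, 300)), rbind(c(50, 250)))
#' @export
recalc_transcript_length <- function(exons, contigs) {
  to_ir <- function(x) {
    x <- as.matrix(x)
    if (!nrow(x)) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(start = x[, 1] + 1L, end = x[, 2]))
  }
  sum(IRanges::width(IRanges::intersect(to_ir(exons), to_ir(contigs))))
}

#' Flag DE genes explained by transcript-length differences
#'
#' Re-derives the fold change on length-renormalized abundance
#' (count / empirical length) and flags a DE gene when the renormalized
#' |log2FC| no longer reaches the DE threshold — the apparent expression
#' difference is then attributable to a transcript-structure difference
#' between species rather than to expression. Genes with a zero empirical
#' length in either species are flagged with a sentinel.
#'
#' @param de DE table with `gene_id, log2fc` (log2 of A over B).
#' @param lengths_A,lengths_B Named vectors of empirical transcript lengths
#'   (bp) per species.
#' @param cfg [pi_config()].
#' @return `de` with `length_flagged` (logical) and `log2fc_lengthnorm`
#'   columns added.
#' @export
length_confound_flag <- function(de, lengths_A, lengths_B, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  lA <- lengths_A[de$gene_id]
  lB <- lengths_B[de$gene_id]
  zero <- is.na(lA) | is.na(lB) | lA == 0 | lB == 0
  # count/length renormalization shifts log2fc by log2(lB/lA)
  adj <- de$log2fc + log2(ifelse(zero, NA, lB / lA))
  de$log2fc_lengthnorm <- adj
  # only a gene that met the DE fold threshold can lose it to length
  was_de <- abs(de$log2fc) >= cfg$de_abs_log2fc
  de$length_flagged <- was_de &
    (zero | (!is.na(adj) & abs(adj) < cfg$de_abs_log2fc))
  de
}

#' One-sided hypergeometric overrepresentation test
#'
#' Tests whether a query gene set overlaps an annotated set more than
#' expected under random draws from the background (upper-tail
#' hypergeometric, equivalent to one-sided Fisher's exact test), with
#' Bonferroni correction over the number of sets tested in the batch.
#'
#' @param query Query gene ids (subset of `background`).
#' @param annotated Annotated-set gene ids (subset of `background`).
#' @param background Background gene universe.
#' @param n_tests Number of tests in the batch for Bonferroni correction.
#' @return List: `overlap`, `expected`, `odds`, `p`, `p_bonferroni`.
#' @export
overrepresentation_test <- function(query, annotated, background, n_tests = 1) {
  if (!length(background)) stop("empty background")
  query <- intersect(query, background)
  annotated <- intersect(annotated, background)
  N <- length(background)
  K <- length(annotated)
  n <- length(query)
  k <- length(intersect(query, annotated))
  p <- if (n == 0 || K == 0) 1 else {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  odds <- {
    a <- k; b <- n - k; c0 <- K - k; d <- N - K - n + k
    if (b * c0 == 0) Inf else (a * d) / (b * c0)
  }
  list(overlap = k, expected = n * K / N, odds = odds,
       p = p, p_bonferroni = min(1, p * n_tests))
}

#' Minimal internal DE engine for synthetic runs
#'
#' Plumbing for hermetic end-to-end exercises: a per-gene negative-binomial
#' exact test (edgeR) with Benjamini-Hochberg adjustment, returning the
#' table shape [classify_de()] consumes. Real analyses should supply result
#' tables from a full DE pipeline.
#'
#' @param counts Count matrix genes x samples.
#' @param group Two-level group label per column; log2FC is group 2 over
#'   group 1.
#' @return `data.frame`: `gene_id, log2fc, pvalue, padj`.
#' @export
run_de <- function(counts, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  y <- edgeR::DGEList(counts = counts, group = group)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y)
  tab <- et$table
  data.frame(gene_id = rownames(tab),
             log2fc = tab$logFC,
             pvalue = tab$PValue,
             padj = stats::p.adjust(tab$PValue, method = "BH"),
             stringsAsFactors = FALSE)
}
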