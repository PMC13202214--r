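#' Analysis configuration with published defaults
#'
#' Builds the configuration list shared by all pipeline stages. Every
#' threshold defaults to the value conventional in placental imprintome
#' analysis; overrides are recorded in the returned object so a
#' run is auditable.
#'
#' @param ... Named overrides for any threshold, e.g. `bias_cutoff = 0.5`.
#' @param rng_seed Integer seed recorded alongside the thresholds.
#'
#' @return A list of class `pi_config` with elements:
#' \describe{
#'   \item{zfpkm_expressed}{zFPKM above which a gene is called expressed (-3).}
#'   \item{induced_fold}{Fold of the sum of the other layers' medians a focal
#'     layer must reach to be called induced (2).}
#'   \item{bias_cutoff}{Minimum absolute parent-of-origin bias score (0.4,
#'     corresponding to >= 70% expression from one parental allele).}
#'   \item{stringent_bias}{Bias score required under the maximum (rather than
#'     median) contamination estimate for novel maternal candidates (0.7).}
#'   \item{chisq_alpha}{Bonferroni-corrected p-value cutoff (0.01).}
#'   \item{me_ratio_max}{Maternal:embryonic expression ratio above which a
#'     gene is excluded as contamination-prone (3).}
#'   \item{min_ase_coverage}{Minimum assigned reads per replicate (20).}
#'   \item{min_diag_variants}{Minimum diagnostic variants per replicate (2).}
#'   \item{min_variant_separation_bp}{Minimum span between diagnostic
#'     variants, one read length (150).}
#'   \item{min_powered_replicates}{Replicates that must pass the power filter
#'     (4).}
#'   \item{min_replication_crosses}{Cross types in which a call must
#'     replicate (2).}
#'   \item{cpg_min_coverage}{Reads required at a CpG site (10).}
#'   \item{dmr_link_window_bp}{Flank around a gene body within which a DMR is
#'     linked (2000).}
#'   \item{de_abs_log2fc}{Minimum |log2 fold change| for differential
#'     expression (1).}
#'   \item{de_padj}{Maximum adjusted p-value for differential expression
#'     (0.05).}
#'   \item{expressed_replicate_fraction}{Fraction of replicates in which a
#'     gene must be expressed to enter DE testing (0.8).}
#'   \item{divergence_delta_bias}{Between-lineage bias-score difference
#'     declaring imprinting divergence (0.4).}
#' }
#' Additional tunables with package-chosen defaults: `balanced_window`
#' (allelic-fraction window for balanced genes, `c(0.45, 0.55)`),
#' `min_balanced_genes` (200), `cmax_trim` (fraction of top per-gene
#' contamination estimates trimmed before taking the maximum, 0.01),
#' `correction` (`"exact"` or `"product"` mixture correction),
#' `dmr_cpg_alpha` (0.01), `dmr_min_delta` (0.3), `dmr_merge_bp` (300),
#' `dmr_min_cpgs` (5), `threshold_margin` (fold-ratio window `[1.5, 2)`
#' counted as a threshold effect in cross-species comparisons).
#'
#' @examples
#' cfg <- pi_config()
#' cfg$bias_cutoff
#' @export
pi_config <- function(..., rng_seed = 1L) {
  defaults <- list(
    zfpkm_expressed = -3,
    induced_fold = 2,
    bias_cutoff = 0.4,
    stringent_bias = 0.7,
    chisq_alpha = 0.01,
    me_ratio_max = 3,
    min_ase_coverage = 20,
    min_diag_variants = 2,
    min_variant_separation_bp = 150,
    min_powered_replicates = 4,
    min_replication_crosses = 2,
    cpg_min_coverage = 10,
    dmr_link_window_bp = 2000,
    de_abs_log2fc = 1,
    de_padj = 0.05,
    expressed_replicate_fraction = 0.8,
    divergence_delta_bias = 0.4,
    # package-level tunables (not published constants)
    balanced_window = c(0.45, 0.55),
    min_balanced_genes = 200,
    cmax_trim = 0.01,
    correction = "exact",
    dmr_cpg_alpha = 0.01,
    dmr_min_delta = 0.3,
    dmr_merge_bp = 300,
    dmr_min_cpgs = 5,
    threshold_margin = c(1.5, 2)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    }
    defaults[names(overrides)] <- overrides
  }
  defaults$rng_seed <- as.integer(rng_seed)
  defaults$overridden <- names(overrides)
  structure(defaults, class = "pi_config")
}

#' @export
print.pi_config <- function(x, ...) {
  cat("placimprint configuration\n")
  for (nm in setdiff(names(x), c("overridden"))) {
    tag <- if (nm %in% x$overridden) "  [override]" else ""
    cat(sprintf("  %-28s %s%s\n", nm, paste(format(x[[nm]]), collapse = ", "), tag))
  }
  invisible(x)
}

# internal: accept either a pi_config or NULL (-> defaults)
as_pi_config <- function(cfg) {
  if (is.null(cfg)) pi_config() else if (inherits(cfg, "pi_config")) cfg else
    stop("cfg must be a pi_config (see pi_config())")
}
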