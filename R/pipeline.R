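#' Annotation table for a simulated truth
#'
#' Derives the gene annotation the pipeline consumes from a simulation
#' truth, including a validated-imprint list covering a configurable
#' fraction of the truly imprinted genes (the imprinted-gene catalogs cover
#' most but not all of the canonical imprintome) and optional blood-high
#' flags on non-imprinted genes.
#'
#' @param truth A `sim_truth`.
#' @param validated_fraction Fraction of truly imprinted genes present on
#'   the validated list.
#' @param n_blood_high Non-imprinted genes flagged as blood-high.
#' @param seed Integer seed for the random subsets.
#' @return Annotation `data.frame` compatible with [select_balanced_genes()]
#'   and [call_imprintome()].
#' @export
build_annotations <- function(truth, validated_fraction = 0.7,
                              n_blood_high = 20, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  g <- truth$genes
  imp <- which(g$imprinted)
  val <- sample(imp, round(validated_fraction * length(imp)))
  validated <- rep(NA_character_, nrow(g))
  validated[val] <- g$imprint_direction[val]
  blood <- rep(FALSE, nrow(g))
  blood[sample(which(!g$imprinted & g$chromosome != "chrX"), n_blood_high)] <- TRUE
  data.frame(gene_id = g$gene_id,
             chromosome = g$chromosome,
             start = 0L,
             end = g$length,
             strand = "+",
             annotated_length = g$length,
             validated_imprinted = validated,
             blood_high = blood,
             imprinted_cluster_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Full ASE and contamination analysis of one reciprocal cross
#'
#' Runs the per-cross pipeline on simulated or real inputs: TPM
#' normalization, power filtering and bias scores, maternal:embryonic
#' ratios per maternal genotype, balanced-gene contamination estimation,
#' and contamination-corrected bias under both the median and the maximum
#' (stringent) per-sample contamination summaries.
#'
#' @param sim Output of [simulate_reciprocal_cross()], or a list with the
#'   same elements built from real data.
#' @param annotations Gene annotations.
#' @param cfg [pi_config()].
#' @return List: `bias` (raw), `corrected`, `corrected_cmax`,
#'   `contamination` (per sample), `me` (all genotypes), `balanced_genes`,
#'   `c_median`, `c_max` (cross-level summaries).
#' @export
analyze_cross <- function(sim, annotations, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  lengths <- stats::setNames(annotations$annotated_length, annotations$gene_id)
  emb_tpm <- compute_tpm_fpkm(sim$counts, lengths)$tpm
  mat_tpm <- compute_tpm_fpkm(sim$maternal_counts, lengths)$tpm

  mt_meta <- sim$meta[sim$meta$tissue == "maternal_tissue", ]
  me <- do.call(rbind, lapply(unique(mt_meta$dam_strain), function(gt) {
    cols <- mt_meta$sample_id[mt_meta$dam_strain == gt]
    compute_me_ratios(emb_tpm, mat_tpm[, cols, drop = FALSE], gt, cfg)
  }))

  cross_type <- sim$meta$cross_type[1]
  bias <- ase_bias_table(sim$allele_counts, sim$meta, cross_type,
                         sites = sim$sites, cfg = cfg)
  balanced <- select_balanced_genes(bias, annotations, cfg)
  contam <- estimate_contamination(sim$allele_counts, sim$meta, balanced,
                                   me, cfg)
  # cross-level summaries of the per-sample estimates: the correction uses
  # the median sample contamination, the stringent triage the maximum
  c_median <- stats::median(contam$c_median)
  c_max <- max(contam$c_median)
  list(bias = bias,
       corrected = corrected_bias(bias, me, c_median, cfg),
       corrected_cmax = corrected_bias(bias, me, c_max, cfg),
       contamination = contam,
       me = me,
       balanced_genes = balanced,
       c_median = c_median,
       c_max = c_max)
}

#' End-to-end imprintome analysis over several reciprocal crosses
#'
#' Simulates (or accepts) the configured cross types, analyses each with
#' [analyze_cross()], and produces the hierarchical imprintome calls and the
#' X-linked classification.
#'
#' @param truth A `sim_truth`.
#' @param annotations Annotations (default [build_annotations()] on `truth`).
#' @param cross_types Cross types to simulate.
#' @param n_per_direction,library_size Passed to
#'   [simulate_reciprocal_cross()].
#' @param cfg [pi_config()].
#' @param seed Integer base seed; cross i uses `seed + i`.
#' @return List: `imprintome` (autosomal calls), `x_calls`, `per_cross`
#'   (list of [analyze_cross()] results), `annotations`.
#' @export
run_imprintome_pipeline <- function(truth, annotations = NULL,
                                    cross_types = c("dom_x_dom", "mus_x_mus",
                                                    "mus_x_dom"),
                                    n_per_direction = 10,
                                    library_size = 15e6,
                                    cfg = NULL, seed = 1L) {
  cfg <- as_pi_config(cfg)
  if (is.null(annotations)) annotations <- build_annotations(truth, seed = seed)
  per_cross <- lapply(seq_along(cross_types), function(i) {
    sim <- simulate_reciprocal_cross(truth, cross_types[i],
                                     n_per_direction = n_per_direction,
                                     library_size = library_size,
                                     seed = seed + i)
    analyze_cross(sim, annotations, cfg)
  })
  names(per_cross) <- cross_types
  bias_list <- lapply(per_cross, `[[`, "corrected")
  bias_list_cmax <- lapply(per_cross, `[[`, "corrected_cmax")
  me_list <- lapply(per_cross, `[[`, "me")
  imprintome <- call_imprintome(bias_list, bias_list_cmax, me_list,
                                annotations, cfg)
  x_genes <- annotations$gene_id[annotations$chromosome %in% c("chrX", "X")]
  x_bias <- bias_list[[1]][bias_list[[1]]$gene_id %in% x_genes, ]
  x_calls <- classify_x_linked(x_bias, cfg)
  list(imprintome = imprintome, x_calls = x_calls,
       per_cross = per_cross, annotations = annotations)
}
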