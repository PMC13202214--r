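#' Replication of parent-of-origin calls across cross types
#'
#' A gene's call replicates when it is classified as biased in the same
#' direction in at least `min_replication_crosses` of the analysed cross
#' types. Genes called in opposite directions in different crosses are
#' excluded with a conflict flag rather than majority-voted.
#'
#' @param calls `data.frame` with columns `gene_id, cross_type, call`
#'   (`maternal`/`paternal`/`none`/`NA`).
#' @param cfg [pi_config()].
#' @return `data.frame` per gene: `gene_id, direction, n_supporting,
#'   supporting_crosses, replicated, conflict`.
#' @export
replicate_calls <- function(calls, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  dt <- data.table::as.data.table(calls)
  summ <- dt[, {
    mat <- cross_type[!is.na(call) & call == "maternal"]
    pat <- cross_type[!is.na(call) & call == "paternal"]
    conflict <- length(mat) > 0 && length(pat) > 0
    if (conflict || (length(mat) == 0 && length(pat) == 0)) {
      dir <- NA_character_; sup <- character(0)
    } else if (length(mat) >= length(pat)) {
      dir <- "maternal"; sup <- mat
    } else {
      dir <- "paternal"; sup <- pat
    }
    .(direction = dir,
      n_supporting = length(sup),
      supporting_crosses = paste(sort(sup), collapse = ","),
      replicated = !conflict && length(sup) >= cfg$min_replication_crosses,
      conflict = conflict)
  }, by = gene_id]
  as.data.frame(summ)
}

#' Exclude genes with high maternal:embryonic expression ratio
#'
#' Genes with M:E ratio strictly above `me_ratio_max` in any contributing
#' cross are removed: their apparent bias is most sensitive to maternal
#' contamination.
#'
#' @param gene_ids Genes entering the filter.
#' @param me_list List (one element per cross) of M:E tables from
#'   [compute_me_ratios()].
#' @param cfg [pi_config()].
#' @return List: `kept` and `excluded` gene id vectors.
#' @export
exclude_high_me <- function(gene_ids, me_list, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  if (!is.list(me_list) || is.data.frame(me_list)) me_list <- list(me_list)
  high <- unique(unlist(lapply(me_list, function(me) {
    me$gene_id[me$ratio > cfg$me_ratio_max]
  })))
  kept <- setdiff(gene_ids, high)
  log_filter("M:E ratio filter", length(gene_ids), length(kept))
  list(kept = kept, excluded = intersect(gene_ids, high))
}

#' Call the autosomal imprintome
#'
#' Hierarchical calling across reciprocal cross types. Per cross, genes are
#' classified from contamination-corrected bias scores; calls must replicate
#' in the same direction in at least two crosses; genes with M:E > 3 in any
#' cross are excluded; validated and paternally biased genes are classified
#' as imprinted; remaining (novel) maternally biased genes are kept as
#' tentative candidates only when their corrected bias under the most
#' stringent contamination estimate (per-sample maximum instead of median)
#' exceeds `stringent_bias` in at least two crosses and they are not highly
#' expressed in blood. Every input gene lands in exactly one final status.
#'
#' @param bias_list Named list (by cross type) of corrected bias tables
#'   (from [corrected_bias()] under the median contamination estimate).
#' @param bias_list_cmax Same tables corrected under the maximum
#'   contamination estimate.
#' @param me_list Named list of M:E tables matching `bias_list`.
#' @param annotations Gene annotations with `validated_imprinted` and
#'   `blood_high`.
#' @param cfg [pi_config()].
#' @return `data.frame` per autosomal gene tested in any cross: `gene_id,
#'   direction, status, supporting_crosses`, with status one of
#'   `validated_imprinted, candidate_maternal, excluded_high_me,
#'   excluded_blood, excluded_unreplicated, excluded_contamination_sensitive,
#'   biallelic`.
#' @export
call_imprintome <- function(bias_list, bias_list_cmax, me_list, annotations,
                            cfg = NULL) {
  cfg <- as_pi_config(cfg)
  stopifnot(length(bias_list) >= 2, identical(names(bias_list), names(me_list)))
  auto <- annotations$gene_id[!(annotations$chromosome %in% c("chrX", "X", "chrY", "Y"))]

  calls <- do.call(rbind, lapply(names(bias_list), function(ct) {
    b <- bias_list[[ct]]
    b <- b[b$gene_id %in% auto, ]
    data.frame(gene_id = b$gene_id, cross_type = ct,
               call = call_biased(b$corrected_bias, b$p_bonferroni, cfg),
               stringsAsFactors = FALSE)
  }))
  rep_res <- replicate_calls(calls, cfg)

  status <- rep(NA_character_, nrow(rep_res))
  names(status) <- rep_res$gene_id

  biased <- rep_res$replicated
  status[!biased] <- ifelse(
    is.na(rep_res$direction[!biased]) & !rep_res$conflict[!biased] &
      rep_res$n_supporting[!biased] == 0,
    "biallelic", "excluded_unreplicated")

  # contamination-sensitivity filter on replicated genes
  me_excl <- exclude_high_me(rep_res$gene_id[biased], me_list, cfg)
  status[me_excl$excluded] <- "excluded_high_me"
  surviving <- me_excl$kept

  ann_idx <- match(rep_res$gene_id, annotations$gene_id)
  validated <- !is.na(annotations$validated_imprinted[ann_idx])
  names(validated) <- rep_res$gene_id
  blood <- annotations$blood_high[ann_idx]
  names(blood) <- rep_res$gene_id
  dir <- stats::setNames(rep_res$direction, rep_res$gene_id)

  for (gid in surviving) {
    if (validated[gid] || identical(dir[[gid]], "paternal")) {
      status[gid] <- "validated_imprinted"
    } else if (blood[gid]) {
      status[gid] <- "excluded_blood"
    } else {
      # stringent contamination triage: corrected bias under c_max must stay
      # strong in >= 2 crosses
      n_strong <- sum(vapply(bias_list_cmax, function(b) {
        cb <- b$corrected_bias[match(gid, b$gene_id)]
        !is.na(cb) && cb > cfg$stringent_bias
      }, logical(1)))
      status[gid] <- if (n_strong >= cfg$min_replication_crosses) {
        "candidate_maternal"
      } else {
        "excluded_contamination_sensitive"
      }
    }
  }
  stopifnot(!anyNA(status))  # pure cascade: every gene gets exactly one status
  data.frame(gene_id = rep_res$gene_id,
             direction = rep_res$direction,
             status = status,
             supporting_crosses = rep_res$supporting_crosses,
             conflict = rep_res$conflict,
             stringsAsFactors = FALSE)
}

#' Classify X-linked genes in female conceptuses
#'
#' Applies the autosomal thresholds to X-linked genes from female samples.
#' Under imprinted X-chromosome inactivation the expected pattern is
#' near-complete maternal expression; powered genes failing the bias cutoff
#' are XCI escapers (biallelic), and paternally biased genes (Xist) are
#' called paternal.
#'
#' @param bias Corrected bias table restricted to X-linked genes.
#' @param cfg [pi_config()].
#' @return `data.frame`: `gene_id, class` (`maternal`/`biallelic`/
#'   `paternal`); unpowered genes are dropped with a warning when none are
#'   powered.
#' @export
classify_x_linked <- function(bias, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  b <- bias[bias$powered & !is.na(bias$corrected_bias), ]
  if (!nrow(b)) {
    warning("no powered X-linked genes")
    return(data.frame(gene_id = character(0), class = character(0)))
  }
  call <- call_biased(b$corrected_bias, b$p_bonferroni, cfg)
  class <- ifelse(call == "maternal", "maternal",
                  ifelse(call == "paternal", "paternal", "biallelic"))
  data.frame(gene_id = b$gene_id, class = class, stringsAsFactors = FALSE)
}

#' Divergence of imprinted expression between lineages
#'
#' A gene imprinted in the ingroup is divergent when the difference in
#' corrected bias score between lineages exceeds `divergence_delta_bias`, or
#' when it shows significant parent-of-origin bias in exactly one lineage.
#' The design cannot detect gain of imprinting in the outgroup, because only
#' genes already imprinted in the ingroup are tested.
#'
#' @param bias_ingroup,bias_outgroup Corrected bias tables for the two
#'   lineages (matched by `gene_id`).
#' @param genes Genes to test (imprinted in the ingroup model and powered in
#'   all crosses compared).
#' @param cfg [pi_config()].
#' @return `data.frame`: `gene_id, bias_ingroup, bias_outgroup, delta,
#'   sig_ingroup, sig_outgroup, status`
#'   (`divergent`/`conserved`/`not_testable`).
#' @export
imprinting_divergence <- function(bias_ingroup, bias_outgroup, genes,
                                  cfg = NULL) {
  cfg <- as_pi_config(cfg)
  i1 <- match(genes, bias_ingroup$gene_id)
  i2 <- match(genes, bias_outgroup$gene_id)
  b1 <- bias_ingroup$corrected_bias[i1]
  b2 <- bias_outgroup$corrected_bias[i2]
  p1 <- bias_ingroup$p_bonferroni[i1]
  p2 <- bias_outgroup$p_bonferroni[i2]
  pow <- !is.na(b1) & !is.na(b2) &
    bias_ingroup$powered[i1] & bias_outgroup$powered[i2]
  sig1 <- !is.na(p1) & p1 < cfg$chisq_alpha & abs(b1) >= cfg$bias_cutoff
  sig2 <- !is.na(p2) & p2 < cfg$chisq_alpha & abs(b2) >= cfg$bias_cutoff
  delta <- abs(b1 - b2)
  status <- ifelse(!pow, "not_testable",
                   ifelse(delta > cfg$divergence_delta_bias | xor(sig1, sig2),
                          "divergent", "conserved"))
  data.frame(gene_id = genes, bias_ingroup = b1, bias_outgroup = b2,
             delta = delta, sig_ingroup = sig1, sig_outgroup = sig2,
             status = status, stringsAsFactors = FALSE)
}

#' Overrepresentation of imprinted genes among layer-induced genes
#'
#' One-sided hypergeometric (Fisher) test of the overlap between the
#' imprinted set and each layer's induced set, against the background of all
#' genes powered for allele-specific expression, Bonferroni-corrected across
#' layers.
#'
#' @param imprinted Gene ids called imprinted.
#' @param induced_sets Named list of per-layer induced gene id vectors.
#' @param background All powered genes (must contain the imprinted set).
#' @return `data.frame`: `layer, overlap, n_induced, p, p_bonferroni`.
#' @export
enrichment_in_layers <- function(imprinted, induced_sets, background) {
  if (!length(background)) stop("empty background")
  if (!all(imprinted %in% background)) {
    stop("imprinted set must be contained in the background")
  }
  res <- lapply(names(induced_sets), function(L) {
    ind <- intersect(induced_sets[[L]], background)
    ov <- overrepresentation_test(imprinted, ind, background,
                                  n_tests = length(induced_sets))
    data.frame(layer = L, overlap = ov$overlap, n_induced = length(ind),
               p = ov$p, p_bonferroni = ov$p_bonferroni,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
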