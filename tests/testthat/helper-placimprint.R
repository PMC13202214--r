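# Shared fixture builders: small reciprocal-cross tables constructed in code.

# metadata for one reciprocal cross with n embryonic replicates per direction
make_meta <- function(n = 2, cross_type = "dom_x_dom",
                      strains = c("WSB", "LEW")) {
  data.frame(
    sample_id = c(sprintf("F%02d", seq_len(n)), sprintf("R%02d", seq_len(n))),
    cross_type = cross_type,
    direction = rep(c("forward", "reverse"), each = n),
    dam_strain = rep(strains, each = n),
    sire_strain = rep(rev(strains), each = n),
    tissue = "whole_fetal_placenta",
    sex = "F",
    replicate = rep(seq_len(n), 2),
    stringsAsFactors = FALSE
  )
}

# allele counts for genes whose maternal-read fraction is f_fwd in forward
# samples and f_rev in reverse samples, at a fixed per-sample total
make_allele_counts <- function(gene_ids, f_fwd, f_rev, total = 1000, n = 2) {
  meta <- make_meta(n)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    f <- if (meta$direction[i] == "forward") f_fwd else f_rev
    data.frame(gene_id = gene_ids,
               sample_id = meta$sample_id[i],
               maternal = round(f * total),
               paternal = round((1 - f) * total),
               unassigned = 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# minimal annotation frame for a set of genes
make_annotations <- function(gene_ids, chromosome = "chr1",
                             validated = NA_character_, blood = FALSE,
                             length = 1000) {
  data.frame(gene_id = gene_ids, chromosome = chromosome, start = 0L,
             end = length, strand = "+", annotated_length = length,
             validated_imprinted = validated, blood_high = blood,
             imprinted_cluster_id = NA_character_, stringsAsFactors = FALSE)
}

# corrected-bias-shaped frame for classifier tests
make_bias_frame <- function(gene_ids, bias, p_bonf, powered = TRUE) {
  data.frame(gene_id = gene_ids, corrected_bias = bias, raw_bias = bias,
             p_bonferroni = p_bonf, powered = powered, stringsAsFactors = FALSE)
}
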