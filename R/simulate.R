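#' Ground-truth parameters for a simulated placental transcriptome
#'
#' Builds the gene-level truth table driving all simulators. Defaults mirror
#' the scale of a reciprocal-cross placental RNA-seq study: ~5,000 genes, ~40
#' truly imprinted autosomal genes split between maternal and paternal
#' expression, imprinted X-chromosome inactivation on the X (near-complete
#' maternal expression in female conceptuses, with a few escapers and one
#' Xist-like paternally expressed gene), per-sample maternal contamination
#' drawn from a Beta distribution centred at 7%, log-normal baseline
#' expression, modest cis-regulatory effects, and log-normal maternal:embryonic
#' expression ratios so that a realistic minority of genes exceeds M:E = 3.
#'
#' @param n_genes Total genes (autosomes + X).
#' @param n_imprinted True imprinted autosomal genes (half maternal, half
#'   paternal; `theta` drawn in \[0.85, 1\] resp. \[0, 0.15\]).
#' @param n_x X-linked genes; all but `n_x_escapers` get `theta = 0.97`
#'   (imprinted XCI), escapers 0.5, plus one Xist-like gene at `theta = 0.02`.
#' @param n_x_escapers XCI escapers.
#' @param contamination_beta Shape parameters of the Beta distribution of
#'   per-sample contamination (default mean 0.07).
#' @param dispersion Negative-binomial dispersion shared by all genes.
#' @param cis_sd_shape Beta shape for cis effects `rho` (symmetric around
#'   0.5; default `60` gives s.d. ~0.045).
#' @param me_sdlog Log-sd of the maternal:embryonic expression ratio.
#' @param informativeness_beta Beta shapes for the per-gene fraction of reads
#'   assignable to a parent.
#' @param frac_induced Fraction of genes with layer-induced expression truth.
#' @param seed Integer seed; the truth is fully reproducible from it.
#'
#' @return A list of class `sim_truth`: `genes` (data.frame with gene_id,
#'   chromosome, length, base_tpm, maternal_tpm, theta, rho, informativeness,
#'   imprinted, imprint_direction, induced_layer truth, per-layer TPM
#'   profile), plus the scalar simulation parameters.
#' @export
simulate_truth <- function(n_genes = 5000,
                           n_imprinted = 40,
                           n_x = 200,
                           n_x_escapers = 8,
                           contamination_beta = c(14, 186),
                           dispersion = 0.1,
                           cis_sd_shape = 60,
                           me_sdlog = 0.8,
                           informativeness_beta = c(5, 5),
                           frac_induced = 0.2,
                           seed = 1L) {
  set.seed(seed)
  n_auto <- n_genes - n_x
  if (n_auto <= n_imprinted) stop("n_genes too small for n_imprinted + n_x")
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  chromosome <- c(paste0("chr", sample(1:19, n_auto, replace = TRUE)),
                  rep("chrX", n_x))
  length_bp <- round(exp(stats::rnorm(n_genes, log(2000), 0.6)))
  length_bp <- pmax(length_bp, 300)

  # both profiles live on the TPM scale (each sums to 1e6) so that the
  # contamination fraction c is well-defined for the (1-c) e + c m mixture
  base_tpm <- exp(stats::rnorm(n_genes, log(50), 1.5))
  base_tpm <- base_tpm / sum(base_tpm) * 1e6
  maternal_tpm <- base_tpm * exp(stats::rnorm(n_genes, 0, me_sdlog))
  maternal_tpm <- maternal_tpm / sum(maternal_tpm) * 1e6

  theta <- rep(0.5, n_genes)
  imprinted <- rep(FALSE, n_genes)
  imprint_direction <- rep(NA_character_, n_genes)
  imp_idx <- sample(seq_len(n_auto), n_imprinted)
  n_mat <- ceiling(n_imprinted / 2)
  mat_idx <- imp_idx[seq_len(n_mat)]
  pat_idx <- imp_idx[-seq_len(n_mat)]
  # canonical imprinting is near-monoallelic
  theta[mat_idx] <- stats::runif(length(mat_idx), 0.9, 1)
  theta[pat_idx] <- stats::runif(length(pat_idx), 0, 0.1)
  imprinted[imp_idx] <- TRUE
  imprint_direction[mat_idx] <- "maternal"
  imprint_direction[pat_idx] <- "paternal"

  # imprinted XCI: X-linked genes near-fully maternal in female conceptuses
  x_class <- rep(NA_character_, n_genes)
  x_idx <- which(chromosome == "chrX")
  if (length(x_idx)) {
    theta[x_idx] <- 0.97
    x_class[x_idx] <- "maternal"
    esc <- x_idx[sample.int(length(x_idx), min(n_x_escapers, length(x_idx)))]
    theta[esc] <- 0.5
    x_class[esc] <- "escaper"
    rest <- setdiff(x_idx, esc)
    if (length(rest)) {
      xist_like <- rest[1]
      theta[xist_like] <- 0.02
      x_class[xist_like] <- "paternal"
    }
  }

  rho <- stats::rbeta(n_genes, cis_sd_shape, cis_sd_shape)
  informativeness <- stats::rbeta(n_genes, informativeness_beta[1],
                                  informativeness_beta[2])

  # layer truth: three layers (junctional, labyrinth, maternal tissue)
  layers <- c("junctional_zone", "labyrinth_zone", "maternal_tissue")
  w <- matrix(stats::rgamma(n_genes * 3, shape = 8), ncol = 3)
  w <- w / rowSums(w)
  induced_layer <- rep(NA_character_, n_genes)
  ind <- stats::runif(n_genes) < frac_induced
  focal <- sample.int(3, n_genes, replace = TRUE)
  profile <- w * 3 * base_tpm  # non-induced: mild Dirichlet variation around base
  for (g in which(ind)) {
    j <- focal[g]
    others <- profile[g, -j]
    fold <- stats::runif(1, 2.2, 6)
    profile[g, j] <- fold * sum(others)
    induced_layer[g] <- layers[j]
  }
  colnames(profile) <- layers

  genes <- data.frame(gene_id, chromosome, length = length_bp,
                      base_tpm, maternal_tpm, theta, rho, informativeness,
                      imprinted, imprint_direction, x_class,
                      induced_layer, stringsAsFactors = FALSE)
  genes <- cbind(genes, as.data.frame(profile))
  structure(list(genes = genes,
                 layers = layers,
                 contamination_beta = contamination_beta,
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

# expected maternal-allele fraction of embryonic reads given imprinting
# theta and cis effect rho; `ref_is_maternal` encodes the cross direction.
embryonic_maternal_fraction <- function(theta, rho, ref_is_maternal) {
  # maternal-allele weight: imprinting effect theta times the cis weight of
  # the strain the maternal allele comes from (reference strain weight rho)
  w_mat <- if (ref_is_maternal) rho else 1 - rho
  w_pat <- 1 - w_mat
  theta * w_mat / (theta * w_mat + (1 - theta) * w_pat)
}

#' Simulate a reciprocal cross
#'
#' Forward model: the observed expression of gene g in an embryonic placenta
#' sample s is the mixture `(1 - c_s) * e_g + c_s * m_g` on the TPM scale,
#' where `c_s` is the sample's maternal-tissue contamination fraction, `e_g`
#' the embryonic and `m_g` the maternal-tissue expression. Counts are
#' negative binomial around the mixture; a binomial thinning with the gene's
#' informativeness yields parentally assigned reads. Contaminating reads are
#' entirely maternal-allele (maternal tissue carries the dam genotype);
#' embryonic assigned reads are maternal with the probability implied by the
#' imprinting effect `theta` and cis effect `rho` for the direction of the
#' cross. Maternal-tissue dissections are simulated from `m_g` alone.
#'
#' @param truth A `sim_truth` from [simulate_truth()].
#' @param cross_type One of `dom_x_dom`, `mus_x_mus`, `mus_x_dom`,
#'   `spret_x_spret`.
#' @param n_per_direction Embryonic replicates per cross direction.
#' @param n_maternal Maternal-tissue replicates per maternal genotype.
#' @param library_size Reads per library.
#' @param n_sites_mean Mean number of diagnostic variants per gene (>= 1
#'   sites are drawn; positions fixed per gene across samples).
#' @param contamination Optional per-sample contamination fractions (scalar
#'   or vector of length 2 * `n_per_direction`) overriding the Beta draw.
#' @param seed Integer seed for this cross (distinct crosses should use
#'   distinct seeds).
#'
#' @return List: `allele_counts` (gene_id, sample_id, maternal, paternal,
#'   unassigned), `sites` (gene_id, sample_id, position, assigned_reads),
#'   `counts` (matrix genes x embryonic samples), `maternal_counts` (matrix
#'   genes x maternal-tissue samples), `meta` (sample metadata for all
#'   samples), `sample_truth` (sample_id, contamination).
#' @export
simulate_reciprocal_cross <- function(truth,
                                      cross_type = "dom_x_dom",
                                      n_per_direction = 10,
                                      n_maternal = 3,
                                      library_size = 15e6,
                                      n_sites_mean = 3,
                                      contamination = NULL,
                                      seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  g <- truth$genes
  if (any(g$theta < 0 | g$theta > 1)) stop("theta outside [0, 1]")
  if (any(g$rho < 0 | g$rho > 1)) stop("rho outside [0, 1]")
  if (n_per_direction < 1) stop("need at least one replicate per direction")
  set.seed(seed)
  n_genes <- nrow(g)
  strains <- switch(cross_type,
                    dom_x_dom = c("WSB", "LEW"),
                    mus_x_mus = c("PWK", "CZE"),
                    mus_x_dom = c("PWK", "WSB"),
                    spret_x_spret = c("SPRET1", "SPRET2"),
                    stop("unknown cross_type: ", cross_type))

  n_emb <- 2 * n_per_direction
  direction <- rep(c("forward", "reverse"), each = n_per_direction)
  sample_id <- sprintf("%s_%s%02d", cross_type,
                       ifelse(direction == "forward", "F", "R"),
                       c(seq_len(n_per_direction), seq_len(n_per_direction)))
  c_s <- if (is.null(contamination)) {
    stats::rbeta(n_emb, truth$contamination_beta[1], truth$contamination_beta[2])
  } else {
    rep_len(contamination, n_emb)
  }
  if (any(c_s < 0 | c_s >= 0.5)) stop("contamination must be in [0, 0.5)")

  size <- 1 / truth$dispersion
  counts <- matrix(0L, n_genes, n_emb, dimnames = list(g$gene_id, sample_id))
  mat_reads <- pat_reads <- una_reads <- counts
  for (s in seq_len(n_emb)) {
    mix_tpm <- (1 - c_s[s]) * g$base_tpm + c_s[s] * g$maternal_tpm
    frag <- mix_tpm * g$length            # reads scale with transcript length
    mu <- frag / sum(frag) * library_size
    n <- stats::rnbinom(n_genes, mu = mu, size = size)
    assigned <- stats::rbinom(n_genes, n, g$informativeness)
    ref_is_maternal <- direction[s] == "forward"
    f_emb <- embryonic_maternal_fraction(g$theta, g$rho, ref_is_maternal)
    emb_part <- (1 - c_s[s]) * g$base_tpm
    con_part <- c_s[s] * g$maternal_tpm
    f_obs <- (emb_part * f_emb + con_part) / (emb_part + con_part)
    m <- stats::rbinom(n_genes, assigned, f_obs)
    counts[, s] <- n
    mat_reads[, s] <- m
    pat_reads[, s] <- assigned - m
    una_reads[, s] <- n - assigned
  }

  allele_counts <- data.frame(
    gene_id = rep(g$gene_id, n_emb),
    sample_id = rep(sample_id, each = n_genes),
    maternal = as.vector(mat_reads),
    paternal = as.vector(pat_reads),
    unassigned = as.vector(una_reads),
    stringsAsFactors = FALSE
  )

  # diagnostic variant positions are a property of the gene (fixed across
  # samples); assigned reads are spread over them multinomially
  n_sites <- 1L + stats::rpois(n_genes, n_sites_mean - 1)
  positions <- lapply(seq_len(n_genes), function(i) {
    sort(sample.int(max(g$length[i], 160L), n_sites[i]))
  })
  site_gene <- rep(seq_len(n_genes), n_sites)
  sites_list <- vector("list", n_emb)
  total_sites <- sum(n_sites)
  pos_vec <- unlist(positions)
  for (s in seq_len(n_emb)) {
    assigned <- mat_reads[, s] + pat_reads[, s]
    reads <- integer(total_sites)
    # multinomial split of each gene's assigned reads over its sites
    split_reads <- function(a, k) if (k == 1) a else stats::rmultinom(1, a, rep(1, k))[, 1]
    reads <- unlist(lapply(seq_len(n_genes), function(i) {
      split_reads(assigned[i], n_sites[i])
    }))
    sites_list[[s]] <- data.frame(
      gene_id = g$gene_id[site_gene],
      sample_id = sample_id[s],
      position = pos_vec,
      assigned_reads = reads,
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, sites_list)

  # maternal-tissue dissections, one set per maternal genotype (dam strain)
  mt_ids <- c(sprintf("%s_MT_%s%02d", cross_type, strains[1], seq_len(n_maternal)),
              sprintf("%s_MT_%s%02d", cross_type, strains[2], seq_len(n_maternal)))
  maternal_counts <- matrix(0L, n_genes, 2 * n_maternal,
                            dimnames = list(g$gene_id, mt_ids))
  for (s in seq_len(2 * n_maternal)) {
    frag <- g$maternal_tpm * g$length
    mu <- frag / sum(frag) * library_size
    maternal_counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = size)
  }

  meta <- data.frame(
    sample_id = c(sample_id, mt_ids),
    cross_type = cross_type,
    direction = c(direction, rep(c("forward", "reverse"), each = n_maternal)),
    dam_strain = c(ifelse(direction == "forward", strains[1], strains[2]),
                   rep(strains, each = n_maternal)),
    sire_strain = c(ifelse(direction == "forward", strains[2], strains[1]),
                    rep(rev(strains), each = n_maternal)),
    tissue = c(rep("whole_fetal_placenta", n_emb),
               rep("maternal_tissue", 2 * n_maternal)),
    sex = "F",
    replicate = c(rep(seq_len(n_per_direction), 2),
                  rep(seq_len(n_maternal), 2)),
    stringsAsFactors = FALSE
  )
  validate_sample_meta(meta)

  list(allele_counts = allele_counts,
       sites = sites,
       counts = counts,
       maternal_counts = maternal_counts,
       meta = meta,
       sample_truth = data.frame(sample_id, contamination = c_s,
                                 stringsAsFactors = FALSE))
}

#' Simulate layer-enriched expression matrices
#'
#' Draws negative-binomial counts for each placental layer around the truth's
#' per-layer TPM profile.
#'
#' @inheritParams simulate_reciprocal_cross
#' @param n_per_layer Replicates per layer.
#' @return List: `counts` (genes x samples), `layer` (label per column),
#'   `lengths` (per-gene bp).
#' @export
simulate_layer_matrices <- function(truth, n_per_layer = 6,
                                    library_size = 15e6, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  g <- truth$genes
  layers <- truth$layers
  size <- 1 / truth$dispersion
  n_genes <- nrow(g)
  cols <- unlist(lapply(layers, function(L) sprintf("%s_%02d", L, seq_len(n_per_layer))))
  layer <- rep(layers, each = n_per_layer)
  counts <- matrix(0L, n_genes, length(cols), dimnames = list(g$gene_id, cols))
  for (s in seq_along(cols)) {
    tpm <- g[[layer[s]]]
    # per-kb read rate: expected counts scale with length
    frag <- tpm * g$length
    mu <- frag / sum(frag) * library_size
    counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = size)
  }
  list(counts = counts, layer = layer,
       lengths = stats::setNames(g$length, g$gene_id))
}
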