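#' Simulate a pair of parental haplotypes for bisulfite sequencing
#'
#' Builds two haplotypes of one region differing only at diagnostic SNVs,
#' with CpG dinucleotides planted at known positions and per-CpG, per-parent
#' methylation probabilities. SNVs never disrupt a CpG, so CpG positions are
#' identical across haplotypes.
#'
#' @param region_length Region size in bp.
#' @param n_cpgs Number of CpG dinucleotides.
#' @param n_snvs Number of diagnostic SNVs.
#' @param meth_maternal,meth_paternal Per-CpG methylation probabilities
#'   (recycled to `n_cpgs`).
#' @param conversion Bisulfite conversion rate of unmethylated cytosines.
#' @param read_length Read length used by the read simulator.
#' @param seed Integer seed.
#' @return List of class `sim_bisulfite`: `maternal`, `paternal` (character
#'   vectors of bases), `cpg_positions` (0-based C positions),
#'   `meth_maternal`, `meth_paternal`, `variants` (`pos, maternal,
#'   paternal`), `conversion`, `read_length`, `chrom`.
#' @export
simulate_bisulfite_set <- function(region_length = 5000, n_cpgs = 60,
                                   n_snvs = 25, meth_maternal = 0.5,
                                   meth_paternal = 0.5, conversion = 0.99,
                                   read_length = 100, seed = 1L) {
  if (conversion <= 0.5 || conversion > 1) stop("conversion rate must be in (0.5, 1]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seq_ref <- sample(bases, region_length, replace = TRUE)
  # remove incidental CpGs so the planted set is exhaustive
  for (pass in 1:3) {
    cg <- which(seq_ref[-region_length] == "C" & seq_ref[-1] == "G")
    if (!length(cg)) break
    seq_ref[cg] <- sample(c("A", "T"), length(cg), replace = TRUE)
  }
  # plant CpGs on an even grid with jitter, away from the edges; jitter is
  # clamped below half the grid spacing so exactly n_cpgs sites survive and
  # stay aligned with the supplied methylation-probability vectors
  grid <- round(seq(read_length, region_length - read_length, length.out = n_cpgs))
  jit_max <- max(0, min(3, floor(min(diff(grid)) / 3)))
  cpg_pos <- sort(grid + sample(seq(-jit_max, jit_max), n_cpgs, replace = TRUE))
  cpg_pos <- pmin(pmax(cpg_pos, 2), region_length - 3)
  stopifnot(!anyDuplicated(cpg_pos))
  seq_ref[cpg_pos + 1] <- "C"   # 0-based position -> R index pos+1
  seq_ref[cpg_pos + 2] <- "G"

  maternal <- paternal <- seq_ref
  # diagnostic SNVs: avoid CpG dinucleotides and their neighbours
  forbidden <- unique(c(cpg_pos, cpg_pos + 1, cpg_pos - 1))
  candidates <- setdiff(seq(read_length, region_length - read_length), forbidden + 1)
  snv_at <- sort(sample(candidates, n_snvs))
  var_m <- var_p <- character(n_snvs)
  for (k in seq_len(n_snvs)) {
    i <- snv_at[k]
    var_m[k] <- seq_ref[i]
    var_p[k] <- sample(setdiff(bases, seq_ref[i]), 1)
    paternal[i] <- var_p[k]
  }
  n_cpg <- length(cpg_pos)
  structure(list(
    maternal = maternal, paternal = paternal,
    cpg_positions = cpg_pos,
    meth_maternal = rep_len(meth_maternal, n_cpg),
    meth_paternal = rep_len(meth_paternal, n_cpg),
    variants = data.frame(pos = snv_at - 1L, maternal = var_m,
                          paternal = var_p, stringsAsFactors = FALSE),
    conversion = conversion, read_length = read_length, chrom = "chrSim"
  ), class = "sim_bisulfite")
}

#' Simulate bisulfite reads from a haplotype pair
#'
#' Draws reads from the maternal haplotype with probability `maternal_frac`,
#' applies per-read methylation states at CpGs and bisulfite conversion:
#' on plus-strand reads every unprotected C reads as T with the conversion
#' rate; on minus-strand reads every unprotected G reads as A (the read is
#' reported in forward-strand coordinates, as after alignment). Methylated
#' CpG cytosines are protected. The true parent of each read is returned for
#' scoring but is not used by any pipeline stage.
#'
#' @param set A `sim_bisulfite` from [simulate_bisulfite_set()].
#' @param n_reads Number of reads.
#' @param maternal_frac Probability a read derives from the maternal
#'   haplotype.
#' @param seed Integer seed.
#' @return `data.frame`: `read_id, chrom, pos` (0-based), `strand`,
#'   `sequence`, `true_parent`.
#' @export
simulate_bisulfite_reads <- function(set, n_reads = 1000, maternal_frac = 0.5,
                                     seed = 1L) {
  stopifnot(inherits(set, "sim_bisulfite"))
  L <- length(set$maternal)
  rl <- set$read_length
  if (rl > L) stop("read length exceeds haplotype length")
  set.seed(seed)
  starts <- sample.int(L - rl + 1, n_reads, replace = TRUE) - 1L  # 0-based
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  parents <- ifelse(stats::runif(n_reads) < maternal_frac, "maternal", "paternal")
  cpg <- set$cpg_positions
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    hap <- if (parents[i] == "maternal") set$maternal else set$paternal
    pmeth <- if (parents[i] == "maternal") set$meth_maternal else set$meth_paternal
    s <- starts[i]
    frag <- hap[(s + 1):(s + rl)]
    # CpGs whose C (plus strand) or G (minus strand) falls inside the read
    in_span <- which(cpg >= s - 1 & cpg < s + rl)
    meth_state <- stats::runif(length(in_span)) < pmeth[in_span]
    if (strands[i] == "+") {
      keep <- cpg[in_span] >= s & cpg[in_span] < s + rl
      protected <- (cpg[in_span][keep & meth_state] - s) + 1
      is_c <- which(frag == "C")
      convert <- setdiff(is_c, protected)
      conv <- convert[stats::runif(length(convert)) < set$conversion]
      frag[conv] <- "T"
    } else {
      # minus strand: the complementary C sits under the G at cpg + 1
      keep <- cpg[in_span] + 1 >= s & cpg[in_span] + 1 < s + rl
      protected <- (cpg[in_span][keep & meth_state] + 1 - s) + 1
      is_g <- which(frag == "G")
      convert <- setdiff(is_g, protected)
      conv <- convert[stats::runif(length(convert)) < set$conversion]
      frag[conv] <- "A"
    }
    seqs[i] <- paste(frag, collapse = "")
  }
  data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
             chrom = set$chrom, pos = starts, strand = strands,
             sequence = seqs, true_parent = parents,
             stringsAsFactors = FALSE)
}
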