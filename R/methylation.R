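#' Partition bisulfite reads by parent of origin
#'
#' Assigns each aligned bisulfite read to the maternal or paternal haplotype
#' from the diagnostic variants on its span, accounting for the sequence
#' changes induced by bisulfite treatment: on a C-to-T-converted (plus
#' strand) read a C/T allele difference is uninformative, and on a
#' G-to-A-converted (minus strand) read a G/A difference is uninformative;
#' at the remaining sites an allele C is allowed to read as T (plus strand)
#' and an allele G as A (minus strand). A read is assigned when at least one
#' informative site supports one haplotype and none supports the other;
#' sites supporting different parents make the read ambiguous with a
#' conflict flag, as does a read spanning no informative site.
#'
#' @param reads `data.frame` with columns `read_id, chrom, pos` (0-based
#'   leftmost aligned position), `strand` (`+`/`-`), `sequence` (aligned
#'   forward-strand bases).
#' @param variants `data.frame` of diagnostic SNVs: `pos` (0-based),
#'   `maternal`, `paternal` (forward-strand alleles).
#' @return `reads` with added columns `parent`
#'   (`maternal`/`paternal`/`ambiguous`), `informative_sites_used`,
#'   `conflict`.
#' @export
partition_reads <- function(reads, variants) {
  n <- nrow(reads)
  parent <- rep("ambiguous", n)
  used <- integer(n)
  conflict <- rep(FALSE, n)
  vpos <- variants$pos
  for (i in seq_len(n)) {
    seq_chars <- strsplit(reads$sequence[i], "")[[1]]
    start <- reads$pos[i]
    end <- start + length(seq_chars)  # half-open
    idx <- which(vpos >= start & vpos < end)
    if (!length(idx)) next
    strand <- reads$strand[i]
    n_mat <- 0L; n_pat <- 0L
    for (j in idx) {
      a_m <- variants$maternal[j]
      a_p <- variants$paternal[j]
      pair <- sort(c(a_m, a_p))
      # allele distinction destroyed by conversion on this strand
      if (strand == "+" && identical(pair, c("C", "T"))) next
      if (strand == "-" && identical(pair, c("A", "G"))) next
      base <- seq_chars[vpos[j] - start + 1]
      matches <- function(allele) {
        base == allele ||
          (strand == "+" && allele == "C" && base == "T") ||
          (strand == "-" && allele == "G" && base == "A")
      }
      hit_m <- matches(a_m)
      hit_p <- matches(a_p)
      if (hit_m && !hit_p) n_mat <- n_mat + 1L
      if (hit_p && !hit_m) n_pat <- n_pat + 1L
    }
    used[i] <- n_mat + n_pat
    if (n_mat > 0 && n_pat > 0) {
      conflict[i] <- TRUE
    } else if (n_mat > 0) {
      parent[i] <- "maternal"
    } else if (n_pat > 0) {
      parent[i] <- "paternal"
    }
  }
  reads$parent <- parent
  reads$informative_sites_used <- used
  reads$conflict <- conflict
  reads
}

#' CpG methylation calls from partitioned reads
#'
#' Counts methylated and total observations per parent at each reference CpG
#' (position of the C on the plus strand). Plus-strand reads report the C
#' itself (C = methylated, T = unmethylated); minus-strand reads report the
#' complementary G at the next base (G = methylated, A = unmethylated); both
#' strands of a symmetric CpG are pooled. Sites covered by fewer than
#' `cpg_min_coverage` reads in a parent are filtered out.
#'
#' @param reads Partitioned reads (see [partition_reads()]); only reads with
#'   `parent` maternal or paternal contribute.
#' @param cpg_positions Integer vector of 0-based CpG C positions.
#' @param chrom Chromosome label for the output records.
#' @param cfg [pi_config()].
#' @return `data.frame`: `chromosome, position, parent, methylated_reads,
#'   total_reads, level`.
#' @export
call_cpg_levels <- function(reads, cpg_positions, chrom = "chr1", cfg = NULL) {
  cfg <- as_pi_config(cfg)
  reads <- reads[reads$parent %in% c("maternal", "paternal"), ]
  acc <- list()
  for (i in seq_len(nrow(reads))) {
    seq_chars <- strsplit(reads$sequence[i], "")[[1]]
    start <- reads$pos[i]
    end <- start + length(seq_chars)
    strand <- reads$strand[i]
    for (cp in cpg_positions) {
      look <- if (strand == "+") cp else cp + 1L  # minus strand reads the G
      if (look < start || look >= end) next
      base <- seq_chars[look - start + 1]
      meth <- if (strand == "+") {
        if (base == "C") 1L else if (base == "T") 0L else NA_integer_
      } else {
        if (base == "G") 1L else if (base == "A") 0L else NA_integer_
      }
      if (is.na(meth)) next
      key <- paste(cp, reads$parent[i])
      prev <- acc[[key]]
      if (is.null(prev)) prev <- c(0L, 0L)
      acc[[key]] <- prev + c(meth, 1L)
    }
  }
  if (!length(acc)) {
    return(data.frame(chromosome = character(0), position = integer(0),
                      parent = character(0), methylated_reads = integer(0),
                      total_reads = integer(0), level = numeric(0)))
  }
  keys <- do.call(rbind, strsplit(names(acc), " "))
  vals <- do.call(rbind, acc)
  out <- data.frame(chromosome = chrom,
                    position = as.integer(keys[, 1]),
                    parent = keys[, 2],
                    methylated_reads = vals[, 1],
                    total_reads = vals[, 2],
                    stringsAsFactors = FALSE)
  out <- out[out$total_reads >= cfg$cpg_min_coverage, ]
  out$level <- out$methylated_reads / out$total_reads
  out[order(out$position, out$parent), ]
}

#' Call parent-of-origin differentially methylated regions
#'
#' At each CpG covered in both parents, a one-sided Fisher exact test (in
#' the direction of the observed level difference) compares methylated vs
#' unmethylated counts between parents. CpGs with p below `dmr_cpg_alpha`
#' and an absolute level difference of at least `dmr_min_delta` are merged
#' into a region when they share direction and lie within `dmr_merge_bp` of
#' the previous member; regions with at least `dmr_min_cpgs` member CpGs are
#' reported.
#'
#' @param maternal,paternal CpG records (from [call_cpg_levels()], already
#'   coverage-filtered) for each parent.
#' @param cfg [pi_config()].
#' @return `data.frame`: `chromosome, start, end` (0-based half-open over
#'   member CpGs, end = last CpG + 2 to cover the dinucleotide), `direction`
#'   (`maternal_methylated`/`paternal_methylated`), `n_cpgs`,
#'   `mean_level_diff`.
#' @export
call_poo_dmrs <- function(maternal, paternal, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  m <- maternal[, c("chromosome", "position", "methylated_reads", "total_reads")]
  p <- paternal[, c("chromosome", "position", "methylated_reads", "total_reads")]
  names(m)[3:4] <- c("meth_m", "tot_m")
  names(p)[3:4] <- c("meth_p", "tot_p")
  both <- merge(m, p, by = c("chromosome", "position"))
  if (!nrow(both)) return(empty_dmr_frame())
  both <- both[order(both$chromosome, both$position), ]
  both$lvl_m <- both$meth_m / both$tot_m
  both$lvl_p <- both$meth_p / both$tot_p
  both$delta <- both$lvl_m - both$lvl_p
  both$pval <- vapply(seq_len(nrow(both)), function(i) {
    tab <- matrix(c(both$meth_m[i], both$tot_m[i] - both$meth_m[i],
                    both$meth_p[i], both$tot_p[i] - both$meth_p[i]), 2,
                  byrow = TRUE)
    alt <- if (both$delta[i] >= 0) "greater" else "less"
    stats::fisher.test(tab, alternative = alt)$p.value
  }, numeric(1))
  both$sig <- both$pval < cfg$dmr_cpg_alpha & abs(both$delta) >= cfg$dmr_min_delta

  dmrs <- list()
  for (chr in unique(both$chromosome)) {
    sub <- both[both$chromosome == chr & both$sig, ]
    if (!nrow(sub)) next
    run_start <- 1
    i <- 2
    flush <- function(a, b) {
      if (b - a + 1 < cfg$dmr_min_cpgs) return(NULL)
      mem <- sub[a:b, ]
      data.frame(chromosome = chr,
                 start = min(mem$position),
                 end = max(mem$position) + 2L,
                 direction = if (mean(mem$delta) > 0) "maternal_methylated"
                             else "paternal_methylated",
                 n_cpgs = nrow(mem),
                 mean_level_diff = mean(abs(mem$delta)),
                 stringsAsFactors = FALSE)
    }
    while (i <= nrow(sub) + 1) {
      extend <- i <= nrow(sub) &&
        sub$position[i] - sub$position[i - 1] <= cfg$dmr_merge_bp &&
        sign(sub$delta[i]) == sign(sub$delta[i - 1])
      if (!extend) {
        dmrs[[length(dmrs) + 1]] <- flush(run_start, i - 1)
        run_start <- i
      }
      i <- i + 1
    }
  }
  dmrs <- dmrs[!vapply(dmrs, is.null, logical(1))]
  if (!length(dmrs)) return(empty_dmr_frame())
  do.call(rbind, dmrs)
}

empty_dmr_frame <- function() {
  data.frame(chromosome = character(0), start = integer(0), end = integer(0),
             direction = character(0), n_cpgs = integer(0),
             mean_level_diff = numeric(0))
}

#' Link DMRs to genes and imprinted clusters
#'
#' A DMR is physically linked to every gene whose body, extended by
#' `dmr_link_window_bp` on both flanks, it overlaps; a cluster link is
#' propagated from any linked gene belonging to a known imprinted cluster.
#'
#' @param dmrs DMR table from [call_poo_dmrs()].
#' @param annotations Gene annotations (`gene_id, chromosome, start, end`,
#'   optional `imprinted_cluster_id`).
#' @param cfg [pi_config()].
#' @return `dmrs` with added columns `linked_genes` (comma-separated) and
#'   `linked_cluster`.
#' @export
link_dmrs <- function(dmrs, annotations, cfg = NULL) {
  cfg <- as_pi_config(cfg)
  w <- cfg$dmr_link_window_bp
  dmrs$linked_genes <- ""
  dmrs$linked_cluster <- NA_character_
  if (!nrow(dmrs)) return(dmrs)
  gr_dmr <- GenomicRanges::GRanges(
    dmrs$chromosome, IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  gr_gene <- GenomicRanges::GRanges(
    annotations$chromosome,
    IRanges::IRanges(pmax(annotations$start - w, 0) + 1L, annotations$end + w))
  hits <- GenomicRanges::findOverlaps(gr_dmr, gr_gene)
  for (i in seq_len(nrow(dmrs))) {
    genes <- annotations$gene_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
    dmrs$linked_genes[i] <- paste(genes, collapse = ",")
    if ("imprinted_cluster_id" %in% names(annotations)) {
      cl <- annotations$imprinted_cluster_id[
        match(genes, annotations$gene_id)]
      cl <- cl[!is.na(cl)]
      if (length(cl)) dmrs$linked_cluster[i] <- cl[1]
    }
  }
  dmrs
}

#' Correct maternal methylation counts for contamination
#'
#' Removes the contamination fraction of maternal read counts,
#' conservatively assuming contaminating (maternal-tissue) reads are fully
#' methylated: corrected methylated = max(0, methylated - c * total),
#' corrected total = total * (1 - c); levels are recomputed.
#'
#' @param records Maternal CpG records ([call_cpg_levels()] output).
#' @param c Contamination fraction in \[0, 1).
#' @return `records` with corrected `methylated_reads`, `total_reads`,
#'   `level`.
#' @examples
#' rec <- data.frame(chromosome = "chr1", position = 0, parent = "maternal",
#'                   methylated_reads = 60, total_reads = 100, level = 0.6)
#' correct_maternal_methylation(rec, 0.068)$level  # ~0.571
#' @export
correct_maternal_methylation <- function(records, c) {
  if (c < 0 || c >= 1) stop("contamination must be in [0, 1)")
  records$methylated_reads <- pmax(0, records$methylated_reads -
                                     c * records$total_reads)
  records$total_reads <- records$total_reads * (1 - c)
  records$level <- ifelse(records$total_reads > 0,
                          records$methylated_reads / records$total_reads, NA)
  records
}
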