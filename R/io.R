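#' Read a gene-level allele count table
#'
#' Reads a TSV of per-gene, per-sample read counts assigned to the maternal
#' and paternal haplotypes. Reads that could not be assigned to a parent are
#' kept (they carry information about diagnostic-variant informativeness) but
#' are excluded from all allelic proportions downstream.
#'
#' @param path Path to a TSV with header
#'   `gene_id, sample_id, maternal, paternal, unassigned`.
#' @param meta Optional sample metadata (see [read_sample_meta()]); when
#'   supplied, rows with sample ids absent from `meta` are rejected.
#'
#' @return A `data.frame` with the five columns above, validated: all counts
#'   are non-negative integers.
#' @export
read_allele_counts <- function(path, meta = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene_id", "sample_id", "maternal", "paternal", "unassigned")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("allele count table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tab <- tab[required]
  validate_allele_counts(tab, meta)
}

#' Write an allele count table
#'
#' @param counts Allele count table as returned by [read_allele_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_allele_counts <- function(tab, meta = NULL) {
  cnt <- c("maternal", "paternal", "unassigned")
  for (col in cnt) {
    if (!is.numeric(tab[[col]])) stop("column '", col, "' must be numeric")
    if (anyNA(tab[[col]])) stop("column '", col, "' contains NA")
    if (any(tab[[col]] < 0)) stop("negative counts in column '", col, "'")
  }
  if (!is.null(meta)) {
    unknown <- setdiff(unique(tab$sample_id), meta$sample_id)
    if (length(unknown)) {
      stop("unknown sample id(s) in allele counts: ", paste(unknown, collapse = ", "))
    }
  }
  tab
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id, cross_type, direction, dam_strain,
#'   sire_strain, tissue, sex, replicate`. `direction` is `forward` when the
#'   first-named strain of the cross type is the dam.
#' @return Validated `data.frame`.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_meta(meta)
}

valid_cross_types <- c("dom_x_dom", "mus_x_mus", "mus_x_dom", "spret_x_spret")
valid_tissues <- c("whole_fetal_placenta", "maternal_tissue",
                   "junctional_zone", "labyrinth_zone")

validate_sample_meta <- function(meta) {
  required <- c("sample_id", "cross_type", "direction", "dam_strain",
                "sire_strain", "tissue", "sex", "replicate")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("sample metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(meta$cross_type %in% valid_cross_types)) {
    stop("invalid cross_type; expected one of ", paste(valid_cross_types, collapse = ", "))
  }
  if (!all(meta$direction %in% c("forward", "reverse"))) {
    stop("direction must be 'forward' or 'reverse'")
  }
  if (!all(meta$tissue %in% valid_tissues)) {
    stop("invalid tissue; expected one of ", paste(valid_tissues, collapse = ", "))
  }
  if (!all(meta$sex %in% c("F", "M", "unknown"))) stop("sex must be F, M or unknown")
  if (any(meta$dam_strain == meta$sire_strain)) {
    stop("dam and sire strain must differ (reciprocal cross design)")
  }
  if (any(meta$replicate < 1)) stop("replicate must be a positive integer")
  meta
}

#' Read gene annotations from GFF3 or BED12
#'
#' Parses gene models with `rtracklayer` and converts them to the package's
#' internal convention: 0-based half-open coordinates. GFF3 (1-based closed)
#' and BED12 (already 0-based half-open) yield identical annotations for the
#' same gene model. Overlapping exons are merged before the annotated length
#' is computed, so the length is the size of the exon union.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file. GFF3 files must carry
#'   `gene` features with `ID` attributes and `exon` features with `Parent`
#'   attributes; BED12 blocks are taken as exons.
#' @param validated Optional `data.frame` with columns `gene_id, direction`
#'   (`maternal`/`paternal`) flagging genes with experimentally validated
#'   imprinted status.
#' @param blood_high Optional character vector of gene ids highly expressed
#'   in blood relative to all other tissues.
#' @param clusters Optional `data.frame` with columns `gene_id, cluster_id`
#'   assigning genes to known imprinted clusters.
#'
#' @return A `data.frame` with columns `gene_id, chromosome, start, end,
#'   strand, annotated_length, validated_imprinted, blood_high,
#'   imprinted_cluster_id` and a list-column `exons` of two-column matrices
#'   (`start`, `end`, 0-based half-open).
#' @export
read_annotations <- function(path, validated = NULL, blood_high = NULL,
                             clusters = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[gr$type == "gene"]
    exons <- gr[gr$type == "exon"]
    if (!length(genes)) stop("no gene features in ", path)
    gene_ids <- as.character(genes$ID)
    parent <- as.character(S4Vectors::unstrsplit(exons$Parent, ","))
    ex_by_gene <- split(exons, factor(parent, levels = gene_ids))
    ann <- data.frame(
      gene_id = gene_ids,
      chromosome = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes) - 1L,  # GFF3 1-based closed -> 0-based half-open
      end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes)),
      stringsAsFactors = FALSE
    )
    ann$exons <- lapply(seq_along(gene_ids), function(i) {
      ex <- ex_by_gene[[i]]
      if (!length(ex)) {
        return(cbind(start = ann$start[i], end = ann$end[i]))
      }
      red <- IRanges::reduce(IRanges::ranges(ex))
      cbind(start = IRanges::start(red) - 1L, end = IRanges::end(red))
    })
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ann <- data.frame(
      gene_id = as.character(gr$name),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    blocks <- gr$blocks
    ann$exons <- lapply(seq_along(gr), function(i) {
      if (is.null(blocks) || !length(blocks[[i]])) {
        return(cbind(start = ann$start[i], end = ann$end[i]))
      }
      # blocks are relative 1-based within the BED record
      red <- IRanges::reduce(blocks[[i]])
      cbind(start = ann$start[i] + IRanges::start(red) - 1L,
            end = ann$start[i] + IRanges::end(red))
    })
  } else {
    stop("unsupported annotation format: .", ext, " (expected GFF3 or BED12)")
  }

  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids in annotation")
  if (any(ann$start >= ann$end)) stop("gene with start >= end in annotation")
  for (i in seq_len(nrow(ann))) {
    ex <- ann$exons[[i]]
    if (any(ex[, "start"] < ann$start[i]) || any(ex[, "end"] > ann$end[i])) {
      stop("exon outside gene bounds for ", ann$gene_id[i])
    }
  }
  ann$annotated_length <- vapply(
    ann$exons, function(ex) sum(ex[, "end"] - ex[, "start"]), numeric(1)
  )

  ann$validated_imprinted <- NA_character_
  if (!is.null(validated)) {
    idx <- match(ann$gene_id, validated$gene_id)
    ann$validated_imprinted <- validated$direction[idx]
  }
  ann$blood_high <- if (is.null(blood_high)) FALSE else ann$gene_id %in% blood_high
  ann$imprinted_cluster_id <- NA_character_
  if (!is.null(clusters)) {
    idx <- match(ann$gene_id, clusters$gene_id)
    ann$imprinted_cluster_id <- clusters$cluster_id[idx]
  }
  ann
}

#' Flag genes highly expressed in blood
#'
#' A gene is blood-high when its blood expression exceeds the maximum of its
#' expression in all other tissues in a supplied tissue-expression table.
#'
#' @param tissue_expr `data.frame` whose first column is `gene_id` and whose
#'   remaining columns are per-tissue expression values; one column must be
#'   named `blood`.
#' @return Character vector of blood-high gene ids.
#' @export
blood_high_genes <- function(tissue_expr) {
  if (!"blood" %in% names(tissue_expr)) stop("tissue table needs a 'blood' column")
  other <- setdiff(names(tissue_expr), c("gene_id", "blood"))
  if (!length(other)) stop("tissue table needs at least one non-blood tissue")
  other_max <- do.call(pmax, tissue_expr[other])
  tissue_expr$gene_id[tissue_expr$blood > other_max]
}

# structured filter logging -----------------------------------------------

#' Report a filtering step
#'
#' The pipeline is a cascade of filters; each step reports how many items it
#' received and kept so a run can be audited. Emitted as a message; silence
#' with [suppressMessages()].
#' @param step Name of the filter.
#' @param n_in,n_out Item counts before and after.
#' @keywords internal
log_filter <- function(step, n_in, n_out) {
  message(sprintf("[placimprint] %s: %d in, %d kept (%d removed)",
                  step, n_in, n_out, n_in - n_out))
  invisible(NULL)
}
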