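#' TPM and FPKM normalization
#'
#' Converts a raw count matrix to transcripts-per-million and fragments per
#' kilobase per million mapped reads. TPM first divides each count by gene
#' length (in kb) and then rescales each sample to sum to one million, so it
#' is invariant to library size; FPKM divides by length and by the sample's
#' total mapped reads in millions.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param lengths Named numeric vector of effective transcript lengths (bp);
#'   must be positive for every gene with a nonzero count.
#'
#' @return A list with matrices `tpm` and `fpkm` (same dimnames as `counts`)
#'   and the `lengths` used.
#' @examples
#' m <- matrix(c(100, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' compute_tpm_fpkm(m, c(a = 1000, b = 2000))$tpm
#' @export
compute_tpm_fpkm <- function(counts, lengths) {
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths)) stop("lengths missing for some genes in counts")
  nonzero <- rowSums(counts) > 0
  if (any(lengths[nonzero] <= 0)) stop("non-positive length for expressed gene")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("zero library size in sample(s): ",
                              paste(colnames(counts)[libsize == 0], collapse = ", "))
  rate <- counts / (lengths / 1e3)                     # per-kb rate
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  fpkm <- sweep(rate, 2, libsize / 1e6, "/")
  list(tpm = tpm, fpkm = fpkm, lengths = lengths)
}
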