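#' Crop and subsample reads
#'
#' Read sets are harmonized before divergence and fusion scans: every read is
#' truncated to its first `crop_to` bases (reads shorter than that are
#' dropped, never padded) and the set is optionally downsampled to a fixed
#' size without replacement. Both steps are deterministic for a fixed seed.
#'
#' The study conditions this mirrors: cropping to 36 nt for fusion-junction
#' scanning, and cropping to 48 nt with downsampling to a common read count
#' for cross-accession divergence estimation.
#'
#' @param reads Tibble with columns `id`, `seq` and optionally `qual`.
#' @param crop_to Keep the first `crop_to` bases of each read (`NULL` to skip).
#' @param sample_n Downsample to this many reads (`NULL` to skip).
#' @param seed Integer seed for the subsampling draw.
#' @return The transformed read tibble; the number of reads dropped for being
#'   shorter than `crop_to` is attached as attribute `"n_dropped_short"`.
#' @examples
#' r <- tibble::tibble(id = "r1", seq = strrep("ACGT", 10), qual = strrep("I", 40))
#' nchar(transform_reads(r, crop_to = 36)$seq)
#' @export
transform_reads <- function(reads, crop_to = NULL, sample_n = NULL,
                            seed = 1L) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  n_dropped <- 0L
  if (!is.null(crop_to)) {
    stopifnot(crop_to >= 1)
    keep <- nchar(reads$seq) >= crop_to
    n_dropped <- sum(!keep)
    reads <- reads[keep, ]
    reads$seq <- substr(reads$seq, 1L, crop_to)
    if ("qual" %in% names(reads)) {
      reads$qual <- substr(reads$qual, 1L, crop_to)
    }
  }
  if (!is.null(sample_n) && sample_n < nrow(reads)) {
    idx <- withr::with_seed(seed, sample.int(nrow(reads), sample_n))
    reads <- reads[sort(idx), ]
  }
  attr(reads, "n_dropped_short") <- n_dropped
  reads
}
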