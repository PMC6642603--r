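#' Plant SNVs (and optional indels) into a genome
#'
#' Substitutions are planted at a Poisson-distributed count
#' (`rate_per_mbp` x region megabases) at uniform distinct positions inside
#' `region_track` (whole genome when `NULL`); transitions are chosen with
#' probability `titv_ratio / (titv_ratio + 1)`. Optional short indels use
#' the left-aligned anchored-base VCF representation.
#'
#' @param genome FASTA tibble.
#' @param rate_per_mbp Expected SNVs per megabase of the region.
#' @param titv_ratio Target transition/transversion ratio.
#' @param region_track Optional interval tibble restricting planting.
#' @param indel_rate_per_mbp Expected indels per megabase (default 0).
#' @param indel_max_len Maximum inserted/deleted length.
#' @param seed Integer seed.
#' @return List with `genome` (mutated FASTA tibble) and `truth` (variant
#'   tibble with `chrom`, `pos`, `ref`, `alt`, `vtype`, `af`). Coordinates
#'   are on the input reference; when indels are planted the mutated
#'   sequence is shifted downstream of each indel.
#' @export
plant_variants <- function(genome, rate_per_mbp, titv_ratio = 1.4,
                           region_track = NULL, indel_rate_per_mbp = 0,
                           indel_max_len = 5L, seed = 1L) {
  stopifnot(rate_per_mbp >= 0, titv_ratio > 0)
  regions <- if (is.null(region_track)) {
    interval_tbl(genome$id, 1L, nchar(genome$seq))
  } else {
    interval_merge(region_track)
  }
  if (!nrow(regions) && rate_per_mbp > 0) {
    stop("empty region track with positive planting rate", call. = FALSE)
  }
  widths <- regions$end - regions$start + 1L
  mbp <- sum(as.numeric(widths)) / 1e6
  withr::with_seed(seed, {
    n_snv <- stats::rpois(1, rate_per_mbp * mbp)
    n_ind <- stats::rpois(1, indel_rate_per_mbp * mbp)
    offs <- sample(sum(widths), min(n_snv + n_ind, sum(widths)))
    ridx <- findInterval(offs - 1L, cumsum(c(0L, widths))[-(nrow(regions) + 1)],
                         rightmost.closed = FALSE)
    pos <- regions$start[ridx] + (offs - c(0L, cumsum(widths))[ridx] - 1L)
    chrom <- regions$chrom[ridx]
    is_ind <- rep(FALSE, length(offs))
    if (n_ind > 0 && length(offs)) {
      is_ind[seq_len(min(n_ind, length(offs)))] <- TRUE
    }
    seqs <- stats::setNames(lapply(genome$seq, function(s) {
      strsplit(s, "", fixed = TRUE)[[1]]
    }), genome$id)
    ref <- vapply(seq_along(pos), function(i) seqs[[chrom[i]]][pos[i]],
                  character(1))
    keep <- ref %in% c("A", "C", "G", "T")
    pos <- pos[keep]; chrom <- chrom[keep]; ref <- ref[keep]
    is_ind <- is_ind[keep]
    # SNVs
    ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
    snv_i <- which(!is_ind)
    is_ti <- stats::runif(length(snv_i)) < titv_ratio / (titv_ratio + 1)
    alt_snv <- vapply(seq_along(snv_i), function(k) {
      b <- ref[snv_i[k]]
      if (is_ti[k]) ti_partner[[b]] else
        sample(setdiff(c("A", "C", "G", "T"), c(b, ti_partner[[b]])), 1)
    }, character(1))
    truth_snv <- tibble(chrom = chrom[snv_i], pos = as.integer(pos[snv_i]),
                        ref = ref[snv_i], alt = alt_snv, vtype = "SNV")
    # indels (anchored-base representation)
    ind_i <- which(is_ind)
    truth_ind <- NULL
    if (length(ind_i)) {
      lens <- sample(indel_max_len, length(ind_i), replace = TRUE)
      del <- stats::runif(length(ind_i)) < 0.5
      rows <- lapply(seq_along(ind_i), function(k) {
        i <- ind_i[k]; p <- pos[i]; sc <- seqs[[chrom[i]]]
        if (del[k] && p + lens[k] <= length(sc)) {
          tibble(chrom = chrom[i], pos = as.integer(p),
                 ref = paste(sc[p:(p + lens[k])], collapse = ""),
                 alt = sc[p], vtype = "DEL")
        } else {
          tibble(chrom = chrom[i], pos = as.integer(p), ref = sc[p],
                 alt = paste0(sc[p], random_dna(lens[k])), vtype = "INS")
        }
      })
      truth_ind <- dplyr::bind_rows(rows)
    }
    truth <- dplyr::bind_rows(truth_snv, truth_ind) %>%
      dplyr::arrange(.data$chrom, .data$pos)
    truth$af <- 1.0
    # apply SNVs, then indels right-to-left so coordinates stay valid
    for (ch in unique(truth_snv$chrom)) {
      sel <- truth_snv[truth_snv$chrom == ch, ]
      seqs[[ch]][sel$pos] <- sel$alt
    }
    out_seq <- vapply(seqs, paste, character(1), collapse = "")
    if (!is.null(truth_ind) && nrow(truth_ind)) {
      for (ch in unique(truth_ind$chrom)) {
        sel <- truth_ind[truth_ind$chrom == ch, ]
        sel <- sel[order(-sel$pos), ]
        s <- out_seq[[ch]]
        for (r in seq_len(nrow(sel))) {
          s <- paste0(substr(s, 1, sel$pos[r] - 1L), sel$alt[r],
                      substr(s, sel$pos[r] + nchar(sel$ref[r]), nchar(s)))
        }
        out_seq[[ch]] <- s
      }
    }
    mut <- genome
    mut$seq <- unname(out_seq[mut$id])
    list(genome = mut, truth = truth)
  })
}
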