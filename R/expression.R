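#' Count sequenced fragments per gene (union mode)
#'
#' A fragment (template) counts once for the single gene whose exons its
#' aligned blocks overlap; fragments overlapping exons of more than one gene
#' are discarded as ambiguous, and fragments touching no exon (e.g. purely
#' intronic) are not counted. Only primary alignments are used.
#'
#' @param aln Spliced alignment tibble against the genome.
#' @param models Gene-model tibble.
#' @param sample_label Sample name for the output column.
#' @return Tidy count tibble: `gene_id`, `sample`, `count` (all genes in
#'   `models`, zero-filled), with the library size (total distinct
#'   templates) in attribute `"library_sizes"` (named vector).
#' @export
count_fragments <- function(aln, models, sample_label = "sample1") {
  prim <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_unmapped, ]
  genes <- sort(unique(models$gene_id))
  lib <- length(unique(prim$qname))
  if (!nrow(prim)) {
    out <- tibble(gene_id = genes, sample = sample_label, count = 0L)
    attr(out, "library_sizes") <- stats::setNames(lib, sample_label)
    return(out)
  }
  blocks <- alignment_blocks(prim)
  blocks$qname <- prim$qname[blocks$row_id]
  ex <- models[models$type == "exon", ]
  hits <- overlap_join(blocks, ex)
  assign <- hits %>%
    dplyr::distinct(.data$qname, .data$gene_id) %>%
    dplyr::group_by(.data$qname) %>%
    dplyr::filter(dplyr::n() == 1L) %>%
    dplyr::ungroup() %>%
    dplyr::count(.data$gene_id, name = "count")
  out <- tibble(gene_id = genes) %>%
    dplyr::left_join(assign, by = "gene_id") %>%
    dplyr::mutate(sample = sample_label,
                  count = as.integer(dplyr::coalesce(.data$count, 0L))) %>%
    dplyr::select("gene_id", "sample", "count")
  attr(out, "library_sizes") <- stats::setNames(lib, sample_label)
  out
}

# pairs of (blocks row, exon row) that overlap, as a joined tibble
overlap_join <- function(blocks, exons) {
  res <- list()
  for (ch in intersect(unique(blocks$chrom), unique(exons$chrom))) {
    b <- blocks[blocks$chrom == ch, ]
    e <- exons[exons$chrom == ch, ]
    h <- IRanges::findOverlaps(
      IRanges::IRanges(b$start, b$end),
      IRanges::IRanges(e$start, e$end)
    )
    if (length(h)) {
      res[[ch]] <- dplyr::bind_cols(
        b[S4Vectors::queryHits(h), c("qname", "start", "end")],
        e[S4Vectors::subjectHits(h), c("gene_id", "transcript_id")]
      )
    }
  }
  if (!length(res)) {
    return(tibble(qname = character(), start = integer(), end = integer(),
                  gene_id = character(), transcript_id = character()))
  }
  dplyr::bind_rows(res)
}

#' Remove fragments overlapping knock-down target regions
#'
#' Transgene-derived reads map onto the regions the RNAi constructs target;
#' counting them would bias the targeted genes' fold changes. This drops
#' every template with an aligned block overlapping a target interval.
#'
#' @param aln Alignment tibble.
#' @param targets Interval tibble; an optional `gene_id` column triggers a
#'   consistency warning when a target interval lies outside that gene's
#'   annotated exons.
#' @param models Optional gene-model tibble for the consistency check.
#' @return Filtered alignment tibble.
#' @export
mask_target_regions <- function(aln, targets, models = NULL) {
  validate_intervals(targets)
  if (!is.null(models) && "gene_id" %in% names(targets)) {
    for (i in seq_len(nrow(targets))) {
      ex <- models[models$gene_id == targets$gene_id[i] &
                     models$type == "exon", ]
      ov <- interval_overlap_length(targets[i, ], ex)
      if (ov < targets$end[i] - targets$start[i] + 1L) {
        warning("target interval ", i, " not fully inside exons of ",
                targets$gene_id[i], call. = FALSE)
      }
    }
  }
  prim <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_unmapped, ]
  blocks <- alignment_blocks(prim)
  ov <- interval_overlap_length(blocks, targets) > 0
  bad_templates <- unique(prim$qname[blocks$row_id[ov]])
  out <- aln[!(aln$qname %in% bad_templates), ]
  attr(out, "sq") <- attr(aln, "sq")
  out
}

#' Normalize a count table
#'
#' `depth` scales each sample's counts by `mean(library sizes) / library
#' size`; `median_of_ratios` uses the median ratio to the per-gene geometric
#' mean (the standard size-factor estimator).
#'
#' @param counts Tidy count tibble (`gene_id`, `sample`, `count`).
#' @param method `"depth"` or `"median_of_ratios"`.
#' @param library_sizes Named vector (required for `depth`; defaults to the
#'   `"library_sizes"` attribute, then to column sums).
#' @return List: `normalized` (tidy tibble with `norm_count`),
#'   `size_factors` (tibble `sample`, `size_factor`; counts are divided by
#'   the factor).
#' @export
normalize_counts <- function(counts, method = c("depth", "median_of_ratios"),
                             library_sizes = NULL) {
  method <- match.arg(method)
  wide <- tidyr::pivot_wider(counts, id_cols = "gene_id",
                             names_from = "sample",
                             values_from = "count")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$gene_id
  if (method == "depth") {
    if (is.null(library_sizes)) {
      library_sizes <- attr(counts, "library_sizes")
    }
    if (is.null(library_sizes)) {
      library_sizes <- colSums(mat)
    }
    library_sizes <- library_sizes[colnames(mat)]
    sf <- library_sizes / mean(library_sizes)
  } else {
    pos <- mat[apply(mat > 0, 1, all), , drop = FALSE]
    if (!nrow(pos)) {
      stop("median-of-ratios needs at least one gene with nonzero counts ",
           "in every sample", call. = FALSE)
    }
    geo <- exp(rowMeans(log(pos)))
    sf <- apply(pos / geo, 2, stats::median)
  }
  norm <- sweep(mat, 2, sf, "/")
  normalized <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(gene_id = rownames(mat)),
                     as_tibble(norm)),
    cols = -"gene_id", names_to = "sample", values_to = "norm_count")
  list(normalized = normalized,
       size_factors = tibble(sample = colnames(mat),
                             size_factor = unname(sf)))
}

#' Merged exonic length per gene
#'
#' @param models Gene-model tibble.
#' @return Tibble `gene_id`, `exonic_length_nt` (union of exon bases).
#' @export
gene_exonic_lengths <- function(models) {
  models[models$type == "exon", ] %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::group_modify(function(tb, key) {
      m <- interval_merge(tb)
      tibble(exonic_length_nt = sum(m$end - m$start + 1L))
    }) %>%
    dplyr::ungroup()
}

#' FPKM, TPM and the sample-specific TPM threshold
#'
#' `FPKM = count * 1e9 / (library_size * exonic_length_nt)`;
#' `TPM_i = FPKM_i / sum_j FPKM_j * 1e6`. The sample-specific expression
#' threshold is the TPM value corresponding to `FPKM = 1`:
#' `1e6 / sum_j FPKM_j`.
#'
#' @param counts Tidy count tibble (`gene_id`, `sample`, `count`).
#' @param exonic_lengths Tibble `gene_id`, `exonic_length_nt` (see
#'   [gene_exonic_lengths()]).
#' @param library_sizes Named vector of fragments per sample (defaults to
#'   the `"library_sizes"` attribute, then to column sums).
#' @return List: `abundance` (tidy tibble `gene_id`, `sample`, `fpkm`,
#'   `tpm`), `thresholds` (tibble `sample`, `tpm_threshold`).
#' @export
fpkm_tpm <- function(counts, exonic_lengths, library_sizes = NULL) {
  if (is.null(library_sizes)) {
    library_sizes <- attr(counts, "library_sizes")
  }
  if (is.null(library_sizes)) {
    library_sizes <- counts %>%
      dplyr::group_by(.data$sample) %>%
      dplyr::summarise(n = sum(.data$count)) %>%
      (function(x) stats::setNames(x$n, x$sample))
  }
  ab <- counts %>%
    dplyr::left_join(exonic_lengths, by = "gene_id") %>%
    dplyr::mutate(lib = unname(library_sizes[.data$sample]))
  if (any(is.na(ab$exonic_length_nt) | ab$exonic_length_nt <= 0)) {
    stop("missing or non-positive exonic length", call. = FALSE)
  }
  if (any(ab$lib <= 0)) stop("zero library size", call. = FALSE)
  ab <- ab %>%
    dplyr::mutate(fpkm = as.numeric(.data$count) * 1e9 /
                    (as.numeric(.data$lib) *
                       as.numeric(.data$exonic_length_nt))) %>%
    dplyr::group_by(.data$sample) %>%
    dplyr::mutate(tpm = .data$fpkm / sum(.data$fpkm) * 1e6) %>%
    dplyr::ungroup()
  thresholds <- ab %>%
    dplyr::group_by(.data$sample) %>%
    dplyr::summarise(tpm_threshold = 1e6 / sum(.data$fpkm))
  list(abundance = ab %>%
         dplyr::select("gene_id", "sample", "fpkm", "tpm"),
       thresholds = thresholds)
}

#' Threshold-gated differential expression calls
#'
#' Reproduces the deterministic gates of the expression comparison: genes
#' with mean normalized count (across all replicates and conditions) below
#' `mean_min` are removed; `lfc = log2((mean_trt + pc) / (mean_ref + pc))`
#' on normalized counts; genes must reach the sample-specific TPM threshold
#' (every replicate of at least one condition) to be kept; a DEG passes
#' both gates with `|lfc| >= lfc_threshold`. No dispersion model or p-value
#' is computed.
#'
#' @param normalized Tidy normalized counts (`gene_id`, `sample`,
#'   `norm_count`), see [normalize_counts()].
#' @param samples Tibble `sample`, `condition` (exactly two conditions).
#' @param ref_condition Reference (e.g. wild type); positive LFC means
#'   up in the other condition.
#' @param abundance,thresholds Output of [fpkm_tpm()] (optional; without
#'   them the TPM gate passes all genes and is reported `NA`).
#' @param mean_min Minimum mean normalized count.
#' @param lfc_threshold Minimum absolute log2 fold change.
#' @param pseudocount Added to both means before the ratio.
#' @return A `tg_degs` object; `tidy()` gives the per-gene table
#'   (`gene_id`, `mean_count`, `lfc`, `passed_mean_filter`,
#'   `passed_tpm_filter`, `called_deg`), `glance()` the gate summary.
#' @export
call_degs <- function(normalized, samples, ref_condition,
                      abundance = NULL, thresholds = NULL,
                      mean_min = 10, lfc_threshold = 0.5, pseudocount = 1) {
  conds <- unique(samples$condition)
  if (length(conds) != 2L) {
    stop("exactly two conditions required", call. = FALSE)
  }
  stopifnot(ref_condition %in% conds)
  trt <- setdiff(conds, ref_condition)
  x <- normalized %>% dplyr::left_join(samples, by = "sample")
  per_gene <- x %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      mean_count = mean(.data$norm_count),
      mean_ref = mean(.data$norm_count[.data$condition == ref_condition]),
      mean_trt = mean(.data$norm_count[.data$condition == trt])
    ) %>%
    dplyr::mutate(
      lfc = log2((.data$mean_trt + pseudocount) /
                   (.data$mean_ref + pseudocount)),
      passed_mean_filter = .data$mean_count >= mean_min
    )
  if (!is.null(abundance) && !is.null(thresholds)) {
    tpm_gate <- abundance %>%
      dplyr::left_join(thresholds, by = "sample") %>%
      dplyr::left_join(samples, by = "sample") %>%
      dplyr::group_by(.data$gene_id, .data$condition) %>%
      dplyr::summarise(cond_pass = all(.data$tpm >= .data$tpm_threshold),
                       .groups = "drop") %>%
      dplyr::group_by(.data$gene_id) %>%
      dplyr::summarise(passed_tpm_filter = any(.data$cond_pass))
    per_gene <- per_gene %>%
      dplyr::left_join(tpm_gate, by = "gene_id") %>%
      dplyr::mutate(passed_tpm_filter =
                      dplyr::coalesce(.data$passed_tpm_filter, FALSE))
  } else {
    per_gene$passed_tpm_filter <- NA
  }
  per_gene <- per_gene %>%
    dplyr::mutate(called_deg = .data$passed_mean_filter &
                    dplyr::coalesce(.data$passed_tpm_filter, TRUE) &
                    abs(.data$lfc) >= lfc_threshold) %>%
    dplyr::select("gene_id", "mean_count", "mean_ref", "mean_trt", "lfc",
                  "passed_mean_filter", "passed_tpm_filter", "called_deg")
  structure(list(results = per_gene,
                 params = list(ref_condition = ref_condition,
                               mean_min = mean_min,
                               lfc_threshold = lfc_threshold,
                               pseudocount = pseudocount)),
            class = "tg_degs")
}

#' @export
tidy.tg_degs <- function(x, ...) x$results

#' @export
glance.tg_degs <- function(x, ...) {
  tibble(
    n_genes = nrow(x$results),
    n_passed_mean = sum(x$results$passed_mean_filter),
    n_degs = sum(x$results$called_deg),
    lfc_threshold = x$params$lfc_threshold,
    mean_min = x$params$mean_min
  )
}

#' @export
print.tg_degs <- function(x, ...) {
  cat("Threshold-gated DEG analysis:", nrow(x$results), "genes,",
      sum(x$results$called_deg), "DEGs (|LFC| >=",
      x$params$lfc_threshold, ")\n")
  invisible(x)
}
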