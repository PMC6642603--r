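#' Read GFF3 features and gene models
#'
#' `read_gff3()` imports any GFF3 file into a flat feature tibble (via
#' rtracklayer, coordinates stay 1-based closed). `read_gene_models()`
#' additionally resolves `gene -> mRNA -> exon/CDS` `ID`/`Parent` linkage into
#' the gene-model tibble used throughout the package: one row per exon or CDS
#' part with columns `chrom`, `type` (`"exon"`/`"cds"`), `start`, `end`,
#' `strand`, `gene_id`, `transcript_id`, `valid`.
#'
#' A transcript whose CDS is not fully contained in its exons is kept but
#' flagged `valid = FALSE`.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble (see Details).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p) {
      if (length(p)) as.character(p[1]) else NA_character_
    }, character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    source = if ("source" %in% names(md)) as.character(md$source) else ".",
    type = as.character(md$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    score = if ("score" %in% names(md)) as.numeric(md$score) else NA_real_,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    id = if ("ID" %in% names(md)) as.character(md$ID) else NA_character_,
    parent = parent
  )
}

#' @rdname read_gff3
#' @export
read_gene_models <- function(path) {
  as_gene_models(read_gff3(path))
}

#' @rdname read_gff3
#' @param gff A feature tibble from `read_gff3()`.
#' @export
as_gene_models <- function(gff) {
  mrna <- gff[gff$type %in% c("mRNA", "transcript"), ]
  tx2gene <- stats::setNames(mrna$parent, mrna$id)
  parts <- gff[tolower(gff$type) %in% c("exon", "cds"), ]
  parts <- parts[!is.na(parts$parent) & parts$parent %in% names(tx2gene), ]
  models <- tibble(
    chrom = parts$chrom,
    type = ifelse(tolower(parts$type) == "cds", "cds", "exon"),
    start = parts$start,
    end = parts$end,
    strand = parts$strand,
    gene_id = unname(tx2gene[parts$parent]),
    transcript_id = parts$parent
  ) %>%
    dplyr::arrange(.data$chrom, .data$transcript_id, .data$start)
  flag_invalid_models(models)
}

# CDS parts must be contained in an exon of the same transcript
flag_invalid_models <- function(models) {
  bad_tx <- models %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::group_map(function(tb, key) {
      cds <- tb[tb$type == "cds", ]
      ex <- tb[tb$type == "exon", ]
      ok <- !nrow(cds) ||
        all(interval_overlap_length(cds, ex) == cds$end - cds$start + 1L)
      if (ok) NULL else key$transcript_id
    }) %>%
    unlist()
  models$valid <- !(models$transcript_id %in% bad_tx)
  models
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` rows with `ID`/`Parent` linkage
#' from a gene-model tibble.
#'
#' @param models Gene-model tibble (see [read_gene_models()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(models, path, source = "tgscan") {
  tx <- models %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$chrom,
                    .data$strand) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  genes <- tx %>%
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  row <- function(chrom, type, start, end, strand, attrs) {
    paste(chrom, source, type, start, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  lines <- c("##gff-version 3")
  for (g in seq_len(nrow(genes))) {
    gn <- genes[g, ]
    lines <- c(lines, row(gn$chrom, "gene", gn$start, gn$end, gn$strand,
                          paste0("ID=", gn$gene_id)))
    gtx <- tx[tx$gene_id == gn$gene_id, ]
    for (t in seq_len(nrow(gtx))) {
      tr <- gtx[t, ]
      lines <- c(lines, row(tr$chrom, "mRNA", tr$start, tr$end, tr$strand,
                            paste0("ID=", tr$transcript_id, ";Parent=",
                                   tr$gene_id)))
      parts <- models[models$transcript_id == tr$transcript_id, ]
      parts <- parts[order(parts$start), ]
      gtype <- c(exon = "exon", cds = "CDS")[parts$type]
      lines <- c(lines, row(parts$chrom, gtype, parts$start, parts$end,
                            parts$strand,
                            paste0("ID=", parts$transcript_id, ".",
                                   tolower(gtype),
                                   stats::ave(parts$start, parts$type,
                                              FUN = seq_along),
                                   ";Parent=", parts$transcript_id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write BED intervals
#'
#' BED is 0-based half-open on disk; rows are shifted to the package's
#' 1-based closed convention on read and back on write.
#'
#' @param path Path to a BED3+ file.
#' @return `read_bed()`: an interval tibble.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#") & !startsWith(ln, "track")]
  if (!length(ln)) return(interval_tbl(character(), integer(), integer()))
  f <- stringr::str_split_fixed(ln, "\t", 6)
  interval_tbl(f[, 1], as.integer(f[, 2]) + 1L, as.integer(f[, 3]),
               strand = ifelse(f[, 6] %in% c("+", "-"), f[, 6], "."))
}

#' @rdname read_bed
#' @param x Interval tibble.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  writeLines(paste(x$chrom, x$start - 1L, x$end, ".", 0L,
                   if (!is.null(x$strand)) x$strand else ".",
                   sep = "\t"), path)
  invisible(path)
}
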