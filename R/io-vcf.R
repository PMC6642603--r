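#' Read and write the VCF subset used by the variant filter cascades
#'
#' Only the annotations the filter cascades test are materialized:
#' `INFO:DP,MQ,MQ0F` and `FORMAT:AD,ADF,ADR` of the first sample. Any other
#' INFO content is preserved as an opaque string and written back verbatim.
#' Multi-allelic rows are not supported (the upstream caller emits
#' biallelic records).
#'
#' @param path Path to a VCF v4.x file.
#' @return `read_vcf()`: a variant tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `depth`, `ref_count`, `alt_count`, `alt_fwd`, `alt_rev`,
#'   `mq_mean`, `mq0f`, `vtype` (`SNV`/`INS`/`DEL`), `info`.
#' @export
read_vcf <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(body)) return(empty_variants())
  f <- stringr::str_split_fixed(body, "\t", 10)
  info <- f[, 8]
  geti <- function(key) {
    as.numeric(stringr::str_match(info, paste0("(?:^|;)", key,
                                               "=([-0-9.eE]+)"))[, 2])
  }
  fmt_keys <- stringr::str_split(f[, 9], ":")
  fmt_vals <- stringr::str_split(f[, 10], ":")
  pick2 <- function(key) {
    purrr::map2_int(fmt_keys, fmt_vals, function(k, v) {
      i <- match(key, k)
      if (is.na(i)) return(NA_integer_)
      parts <- strsplit(v[i], ",", fixed = TRUE)[[1]]
      out <- suppressWarnings(as.integer(parts))
      c(out, NA_integer_)[min(2L, length(out) + 1L)]
    })
  }
  pick1 <- function(key) {
    purrr::map2_int(fmt_keys, fmt_vals, function(k, v) {
      i <- match(key, k)
      if (is.na(i)) return(NA_integer_)
      suppressWarnings(as.integer(strsplit(v[i], ",")[[1]][1]))
    })
  }
  ref <- toupper(f[, 4]); alt <- toupper(f[, 5])
  out <- tibble(
    chrom = f[, 1], pos = as.integer(f[, 2]), ref = ref, alt = alt,
    qual = suppressWarnings(as.numeric(f[, 6])),
    depth = as.integer(geti("DP")),
    ref_count = pick1("AD"), alt_count = pick2("AD"),
    alt_fwd = pick2("ADF"), alt_rev = pick2("ADR"),
    mq_mean = geti("MQ"), mq0f = geti("MQ0F"),
    vtype = variant_type(ref, alt),
    info = strip_known_info(info)
  )
  if (any(out$ref == out$alt)) stop("VCF row with REF == ALT", call. = FALSE)
  out
}

variant_type <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1 & nchar(alt) == 1 ~ "SNV",
    nchar(alt) > nchar(ref) ~ "INS",
    TRUE ~ "DEL"
  )
}

strip_known_info <- function(info) {
  out <- gsub("(?:^|;)(DP|MQ|MQ0F)=[^;]*", "", info)
  out <- gsub("^;+|;+$", "", out)
  ifelse(nzchar(out), out, ".")
}

empty_variants <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), qual = numeric(), depth = integer(),
         ref_count = integer(), alt_count = integer(), alt_fwd = integer(),
         alt_rev = integer(), mq_mean = numeric(), mq0f = numeric(),
         vtype = character(), info = character())
}

#' @rdname read_vcf
#' @param variants Variant tibble.
#' @param sample Sample column label.
#' @export
write_vcf <- function(variants, path, sample = "sample1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"Fraction of MQ0 reads\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Forward allelic depths\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  if (!nrow(variants)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE,
                                                  trim = TRUE))
  extra <- if ("info" %in% names(variants)) variants$info else "."
  info <- paste0("DP=", num(variants$depth), ";MQ=", num(variants$mq_mean),
                 ";MQ0F=", num(variants$mq0f),
                 ifelse(extra == "." | is.na(extra), "",
                        paste0(";", extra)))
  smp <- paste0(num(variants$ref_count), ",", num(variants$alt_count), ":",
                ".,", num(variants$alt_fwd), ":",
                ".,", num(variants$alt_rev))
  writeLines(c(hdr, paste(variants$chrom, variants$pos, ".", variants$ref,
                          variants$alt, num(variants$qual), "PASS", info,
                          "AD:ADF:ADR", smp, sep = "\t")), path)
  invisible(path)
}
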