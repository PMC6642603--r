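#' Variant filter profiles
#'
#' Named parameter sets governing variant retention. The `genomic` dialect
#' applies calling-quality, coverage, MQ0-fraction and per-strand rules; the
#' `transcriptomic` dialect additionally applies positional exclusions
#' (SNVs near indels, indel pairs, SNV clusters) and a minimum alternative
#' allele fraction. Defaults are the published cascades: minimum calling and
#' mean mapping quality 20, minimum coverage 4, maximum MQ0 fraction 0.10,
#' minimum one alternative read per strand (genomic), alt fraction >= 0.9
#' and exclusion distances 10 nt (SNV-indel), 100 nt (indel pair) and
#' 3 SNVs in 10 nt (transcriptomic). `max_cov` is sample-specific for the
#' genomic dialect (about 1.45x mean depth; 30 and 38 for the two
#' characterized libraries).
#'
#' The transcriptomic MQ0F rule is enforced as a maximum (<= 0.10),
#' consistent with the genomic dialect; `mq0f_literal_min = TRUE` restores a
#' literal minimum reading.
#'
#' @param name `"genomic"` or `"transcriptomic"`.
#' @param max_cov Maximum coverage (genomic; `NULL` disables).
#' @param mq0f_literal_min See Details.
#' @param ... Override any default field.
#' @return A `filter_profile` list.
#' @export
filter_profile <- function(name = c("genomic", "transcriptomic"),
                           max_cov = NULL, mq0f_literal_min = FALSE, ...) {
  name <- match.arg(name)
  prof <- list(
    name = name, min_qual = 20, min_avg_mq = 20, min_cov = 4L,
    max_cov = max_cov, max_mq0f = 0.10,
    mq0f_literal_min = mq0f_literal_min,
    min_reads_per_strand = if (name == "genomic") 1L else 0L,
    min_alt_fraction = if (name == "transcriptomic") 0.9 else 0,
    snv_indel_distance = if (name == "transcriptomic") 10L else NA_integer_,
    indel_pair_distance = if (name == "transcriptomic") 100L else NA_integer_,
    snv_cluster_count = if (name == "transcriptomic") 3L else NA_integer_,
    snv_cluster_span = if (name == "transcriptomic") 10L else NA_integer_
  )
  dots <- list(...)
  prof[names(dots)] <- dots
  structure(prof, class = "filter_profile")
}

#' Apply a filter cascade to a call set
#'
#' Positional exclusions (transcriptomic dialect) are evaluated on the raw
#' candidate set before per-variant quality rules, so artifact clusters
#' suppress their neighbors even when some members independently fail other
#' rules. Rules whose annotation is missing (`NA`) on a variant do not
#' reject it. The full audit trail (every input variant with the first rule
#' that removed it) is attached as attribute `"audit"`.
#'
#' @param variants Variant tibble (see [read_vcf()] / [pileup_genotype()]).
#' @param profile A [filter_profile()].
#' @return The retained variants, sorted by `(chrom, pos)`, with an
#'   `"audit"` attribute.
#' @export
filter_callset <- function(variants, profile) {
  if (!inherits(profile, "filter_profile")) {
    stop("unknown filter profile", call. = FALSE)
  }
  v <- variants %>% dplyr::arrange(.data$chrom, .data$pos)
  rule <- rep(NA_character_, nrow(v))
  mark <- function(rej, label) {
    ifelse(is.na(rule) & rej, label, rule)
  }
  if (profile$name == "transcriptomic") {
    pe <- positional_exclusions(v, profile)
    rule <- mark(pe$near_indel, "snv_near_indel")
    rule <- mark(pe$indel_pair, "indel_pair")
    rule <- mark(pe$snv_cluster, "snv_cluster")
  }
  pass_na <- function(x) dplyr::coalesce(x, TRUE)
  rule <- mark(!pass_na(v$qual >= profile$min_qual), "min_qual")
  rule <- mark(!pass_na(v$mq_mean >= profile$min_avg_mq), "min_avg_mq")
  rule <- mark(!pass_na(v$depth >= profile$min_cov), "min_cov")
  if (!is.null(profile$max_cov)) {
    rule <- mark(!pass_na(v$depth <= profile$max_cov), "max_cov")
  }
  if (profile$mq0f_literal_min) {
    rule <- mark(!pass_na(v$mq0f >= profile$max_mq0f), "mq0f")
  } else {
    rule <- mark(!pass_na(v$mq0f <= profile$max_mq0f), "mq0f")
  }
  if (profile$min_reads_per_strand > 0) {
    rule <- mark(!pass_na(v$alt_fwd >= profile$min_reads_per_strand &
                            v$alt_rev >= profile$min_reads_per_strand),
                 "min_reads_per_strand")
  }
  if (profile$min_alt_fraction > 0) {
    rule <- mark(!pass_na(v$alt_count / v$depth >= profile$min_alt_fraction),
                 "min_alt_fraction")
  }
  audit <- v
  audit$removed_by <- rule
  out <- v[is.na(rule), ]
  attr(out, "audit") <- audit
  out
}

positional_exclusions <- function(v, profile) {
  near_indel <- indel_pair <- snv_cluster <- rep(FALSE, nrow(v))
  for (ch in unique(v$chrom)) {
    i <- which(v$chrom == ch)
    pos <- v$pos[i]
    is_snv <- v$vtype[i] == "SNV"
    ipos <- pos[!is_snv]
    if (length(ipos)) {
      d <- vapply(pos, function(p) min(abs(p - ipos)), numeric(1))
      near_indel[i] <- is_snv & d <= profile$snv_indel_distance
      if (length(ipos) >= 2) {
        dd <- vapply(ipos, function(p) {
          min(abs(p - setdiff(ipos, p)))
        }, numeric(1))
        # a position present twice still counts as a close pair
        dup <- duplicated(ipos) | duplicated(ipos, fromLast = TRUE)
        indel_pair[i[!is_snv]] <- dd <= profile$indel_pair_distance | dup
      }
    }
    spos <- sort(pos[is_snv])
    if (length(spos) >= profile$snv_cluster_count) {
      k <- profile$snv_cluster_count
      bad <- rep(FALSE, length(spos))
      for (j in seq_len(length(spos) - k + 1)) {
        if (spos[j + k - 1] - spos[j] <= profile$snv_cluster_span) {
          bad[j:(j + k - 1)] <- TRUE
        }
      }
      snv_cluster[i] <- is_snv & v$pos[i] %in% spos[bad]
    }
  }
  list(near_indel = near_indel, indel_pair = indel_pair,
       snv_cluster = snv_cluster)
}

#' Remove assembly consensus-error positions from a call set
#'
#' Subtraction is position-level and allele-agnostic: any variant whose
#' `(chrom, pos)` also varies in the self-mapping call set (reads of the
#' reference genotype mapped against its own assembly) is removed.
#'
#' @param variants,selfmap Variant tibbles on the same reference.
#' @return Filtered variant tibble.
#' @export
subtract_selfmap <- function(variants, selfmap) {
  if (!nrow(selfmap)) return(variants)
  key <- paste(variants$chrom, variants$pos)
  bad <- paste(selfmap$chrom, selfmap$pos)
  variants[!(key %in% unique(bad)), ]
}

#' Partition two call sets into shared and unique variants
#'
#' Matching is on `(chrom, pos, ref, alt)`.
#'
#' @param a,b Variant tibbles.
#' @return List with `shared` (rows of `a` also in `b`), `unique_a`,
#'   `unique_b`.
#' @export
set_partition <- function(a, b) {
  ka <- paste(a$chrom, a$pos, a$ref, a$alt)
  kb <- paste(b$chrom, b$pos, b$ref, b$alt)
  list(shared = a[ka %in% kb, ], unique_a = a[!(ka %in% kb), ],
       unique_b = b[!(kb %in% ka), ])
}

#' Transition/transversion ratio of a call set
#'
#' Transitions are A<->G and C<->T. Returns `NA` when no transversions are
#' present (undefined ratio).
#'
#' @param variants Variant tibble.
#' @return Numeric ratio.
#' @export
titv_ratio <- function(variants) {
  snv <- variants[variants$vtype == "SNV", ]
  if (!nrow(snv)) return(NA_real_)
  ti <- (snv$ref == "A" & snv$alt == "G") |
    (snv$ref == "G" & snv$alt == "A") |
    (snv$ref == "C" & snv$alt == "T") |
    (snv$ref == "T" & snv$alt == "C")
  n_tv <- sum(!ti)
  if (n_tv == 0) return(NA_real_)
  sum(ti) / n_tv
}

#' CDS-restricted SNV density per covered megabase
#'
#' The denominator counts CDS positions with depth of at least `min_cov`;
#' the numerator counts SNVs at such positions. The density is reported per
#' megabase, with a display value rounded to the nearest integer
#' (half-to-even) alongside the full-precision value.
#'
#' @param variants Variant tibble.
#' @param depth Depth tibble (`chrom`, `pos`, `depth`), e.g. from
#'   [profile_coverage()] (add the `chrom` column), or `NULL` when
#'   `covered_positions` is given directly.
#' @param cds_track Interval tibble of coding regions.
#' @param min_cov Minimum depth for a position to count as covered.
#' @param covered_positions Optionally bypass the depth computation with a
#'   precomputed denominator (positions); `variants` then supplies the
#'   numerator as its SNV count.
#' @return One-row tibble: `covered_positions`, `snv_count`, `snv_per_mbp`
#'   (display integer), `snv_per_mbp_raw`.
#' @export
divergence_snv_per_mbp <- function(variants, depth = NULL, cds_track = NULL,
                                   min_cov = 4L, covered_positions = NULL) {
  if (is.null(covered_positions)) {
    stopifnot(!is.null(depth), !is.null(cds_track))
    cds <- interval_merge(cds_track)
    d <- depth[depth$depth >= min_cov, ]
    pos_iv <- interval_tbl(d$chrom, d$pos, d$pos)
    in_cds <- interval_overlap_length(pos_iv, cds) > 0
    covered_positions <- sum(in_cds)
    covered_key <- paste(d$chrom[in_cds], d$pos[in_cds])
    snv <- variants[variants$vtype == "SNV", ]
    snv_count <- sum(paste(snv$chrom, snv$pos) %in% covered_key)
  } else {
    snv_count <- sum(variants$vtype == "SNV")
  }
  if (covered_positions == 0) {
    stop("no covered CDS positions; cannot compute SNV density",
         call. = FALSE)
  }
  raw <- snv_count / (covered_positions / 1e6)
  tibble(covered_positions = as.integer(covered_positions),
         snv_count = as.integer(snv_count),
         snv_per_mbp = round(raw), snv_per_mbp_raw = raw)
}
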