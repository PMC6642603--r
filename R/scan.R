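#' End-to-end transgene insertion scan
#'
#' Runs the full integration-site pipeline on one genomic alignment set:
#' classify bridging pairs, cluster them into candidates (dropping those
#' under `min_support` P + T pairs), call junctions from chimeric reads,
#' infer the lesion between the junction pair, and call insertion zygosity
#' from wild-type junction-spanning reads.
#'
#' @param aln Alignment tibble against the combined host + construct
#'   reference.
#' @param constructs List of [transgene_spec()] objects.
#' @param min_support Minimum bridging-pair support per candidate.
#' @param window Cluster window; defaults to twice the upper insert bound
#'   estimated from proper pairs (fallback 1550 bp when none).
#' @return A `tg_insertion_scan` object; `tidy()` gives the candidate table
#'   with junctions, lesion and zygosity, `glance()` a one-row summary.
#' @export
insertion_scan <- function(aln, constructs, min_support = 10L,
                           window = NULL) {
  if (is.null(window)) {
    window <- tryCatch(2L * as.integer(estimate_insert_bounds(aln)[2]),
                       error = function(e) 1550L)
  }
  bp <- classify_bridging_pairs(aln, constructs)
  cand <- cluster_candidates(bp, min_support = min_support, window = window)
  details <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    reg <- c(max(1L, cand$anchor_start[i] - window),
             cand$anchor_end[i] + window)
    jn <- call_junctions(aln, cand$scaffold[i], constructs, region = reg)
    jp <- jn$position[jn$side == "P"]
    jt <- jn$position[jn$side == "T"]
    if (length(jp) == 1 && length(jt) == 1) {
      les <- infer_lesion(jp, jt)
      zy <- call_insertion_zygosity(aln, cand$scaffold[i], min(jp, jt))
      tibble(junction_p = jp, junction_t = jt, lesion = les$lesion,
             deleted = les$deleted, zygosity = zy$zygosity,
             wildtype_spanning = zy$wildtype_spanning)
    } else {
      one <- c(jp, jt)
      zy <- if (length(one)) {
        call_insertion_zygosity(aln, cand$scaffold[i], one[1])
      } else {
        tibble(zygosity = "undetermined", wildtype_spanning = NA_integer_)
      }
      tibble(junction_p = if (length(jp)) jp else NA_integer_,
             junction_t = if (length(jt)) jt else NA_integer_,
             lesion = "complex", deleted = NA_integer_,
             zygosity = zy$zygosity,
             wildtype_spanning = zy$wildtype_spanning)
    }
  })
  candidates <- if (nrow(cand)) dplyr::bind_cols(cand, details) else cand
  structure(list(candidates = candidates, bridge_pairs = bp,
                 params = list(min_support = min_support, window = window)),
            class = "tg_insertion_scan")
}

#' @export
tidy.tg_insertion_scan <- function(x, ...) x$candidates

#' @export
glance.tg_insertion_scan <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$candidates),
    n_bridge_pairs = nrow(x$bridge_pairs),
    n_with_both_junctions = sum(!is.na(x$candidates$junction_p) &
                                  !is.na(x$candidates$junction_t)),
    min_support = x$params$min_support,
    window = x$params$window
  )
}

#' @export
print.tg_insertion_scan <- function(x, ...) {
  cat("Transgene insertion scan:", nrow(x$candidates),
      "candidate site(s) from", nrow(x$bridge_pairs), "bridging pairs\n")
  if (nrow(x$candidates)) print(x$candidates)
  invisible(x)
}
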