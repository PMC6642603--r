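#' Plot bridging-pair evidence of an insertion scan
#'
#' Host-anchor positions of promoter- and terminator-bridging pairs per
#' scaffold, with called junctions as dashed lines — the standard evidence
#' view for an integration site.
#'
#' @param object A `tg_insertion_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tg_insertion_scan <- function(object, ...) {
  bp <- object$bridge_pairs
  p <- ggplot2::ggplot(bp, ggplot2::aes(x = .data$start, y = .data$segment,
                                        colour = .data$segment)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(P = "#4477AA", C = "#777777", T = "#EE7733")) +
    ggplot2::labs(x = "host anchor position (bp)", y = "construct segment",
                  colour = "segment") +
    ggplot2::theme_bw()
  jn <- object$candidates
  if (nrow(jn)) {
    lines <- tidyr::pivot_longer(
      jn[, c("scaffold", "junction_p", "junction_t")],
      cols = c("junction_p", "junction_t"), values_to = "position")
    lines <- lines[!is.na(lines$position), ]
    names(lines)[names(lines) == "scaffold"] <- "chrom"
    p <- p + ggplot2::geom_vline(data = lines,
                                 ggplot2::aes(xintercept = .data$position),
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' Per-exon coverage plot of a (possibly disrupted) gene
#'
#' Bar profile of mean exon depth per sample; a disrupted gene driven by a
#' strong constitutive promoter shows a coverage step at the fusion exon.
#'
#' @param profiles One or more [per_exon_coverage()] tibbles row-bound
#'   together (distinguish samples via `sample_label`).
#' @return A ggplot object.
#' @export
plot_exon_coverage <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = factor(.data$exon_index),
                               y = .data$mean_depth,
                               fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "exon (transcript orientation)",
                  y = "mean depth", fill = "sample") +
    ggplot2::theme_bw()
}

#' MA-style plot of threshold-gated expression calls
#'
#' Log2 fold change against mean normalized count, DEGs highlighted.
#'
#' @param object A `tg_degs` object from [call_degs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tg_degs <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$mean_count, y = .data$lfc,
                                    colour = .data$called_deg)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#CC3311")) +
    ggplot2::geom_hline(yintercept = c(-1, 1) *
                          object$params$lfc_threshold,
                        linetype = "dashed", colour = "grey30") +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change",
                  colour = "DEG") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
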