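# ggplot2 views of the benchmarking outputs.

#' Plot stratified precision/recall/F1
#'
#' Bar panels of the three metrics per stratum, with the number of true
#' variants per stratum printed above the recall bar.
#'
#' @param metrics Output of [stratified_metrics()] or
#'   [coverage_sweep_metrics()]; the first column is taken as the stratum.
#' @return A ggplot object.
#' @export
plot_stratified_metrics <- function(metrics) {
  stratum <- names(metrics)[1L]
  long <- metrics |>
    mutate(.stratum = factor(.data[[stratum]], levels = unique(.data[[stratum]]))) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = factor(.data$metric, levels = c("precision", "recall", "f1")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.stratum, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(
      data = distinct(long, .data$.stratum, .data$n_true),
      ggplot2::aes(label = paste0("n=", .data$n_true), y = 1.04),
      size = 3
    ) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_y_continuous(limits = c(0, 1.08), breaks = seq(0, 1, 0.25)) +
    ggplot2::labs(x = stratum, y = NULL) +
    ggplot2::theme_bw()
}

#' Plot intersection (UpSet-style) pattern counts
#'
#' Descending bar chart of membership-pattern counts; patterns not containing
#' the truth set (pure false-positive patterns) are highlighted.
#'
#' @param counts Output of [intersection_counts()].
#' @return A ggplot object.
#' @export
plot_intersection_counts <- function(counts) {
  counts <- counts |>
    mutate(pattern = factor(.data$pattern, levels = .data$pattern[order(-.data$count)]))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$pattern, y = .data$count,
                                       fill = .data$in_truth)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey35", `FALSE` = "firebrick"),
                               name = "contains truth") +
    ggplot2::labs(x = NULL, y = "variant sites") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the read profile around a site
#'
#' Horizontal segments of each read's aligned blocks (solid) and intron
#' skips (thin line) around a site, in the style of a genome-browser
#' screenshot; the site is a vertical dashed line.
#'
#' @param aln A sam tibble.
#' @param chrom,pos The site.
#' @param flank Bases to show on either side (default 200).
#' @return A ggplot object.
#' @export
plot_site_reads <- function(aln, chrom, pos, flank = 200L) {
  validate_sam_tbl(aln)
  aln <- mapped_only(aln)
  sub <- aln[aln$rname == chrom, , drop = FALSE]
  ends <- sub$pos + cigar_ref_width(sub$cigar) - 1L
  sub <- sub[sub$pos <= pos + flank & ends >= pos - flank, , drop = FALSE]
  if (nrow(sub) == 0L) abort("no reads overlap the requested window")
  mb <- cigar_ref_ranges(sub$cigar, sub$pos, ALN_OPS)
  nb <- cigar_ref_ranges(sub$cigar, sub$pos, "N")
  mb$y <- mb$idx
  nb$y <- nb$idx
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = nb, linewidth = 0.3, colour = "grey60",
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y)) +
    ggplot2::geom_segment(data = mb, linewidth = 2, colour = "grey20",
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y)) +
    ggplot2::geom_vline(xintercept = pos, linetype = "dashed", colour = "red") +
    ggplot2::coord_cartesian(xlim = c(pos - flank, pos + flank)) +
    ggplot2::labs(x = chrom, y = "read") +
    ggplot2::theme_minimal()
}
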