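#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Association map of a QTL scan
#'
#' One point per significant association, marker position (y) against trait
#' position (x) with genome-wide cumulative coordinates, colored by which
#' parental allele increases the trait. Hotspot loci appear as horizontal
#' bands.
#'
#' @param object A `qtl_map`.
#' @param markers Wide marker tibble (coordinates).
#' @param trait_positions Tibble: trait id, `chrom`, `start`, `end`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qtl_map
#' @export
autoplot.qtl_map <- function(object, markers, trait_positions, ...) {
  offs <- .genome_offsets(markers, trait_positions)
  sig <- object$significant
  mi <- match(sig$marker, markers$marker)
  ti <- match(sig$trait, trait_positions[[1]])
  df <- tibble::tibble(
    marker_pos = offs[markers$chrom[mi]] + markers$start[mi],
    trait_pos = offs[trait_positions$chrom[ti]] + trait_positions$start[ti],
    sign = sig$sign)
  ggplot2::ggplot(df, ggplot2::aes(.data$trait_pos, .data$marker_pos,
                                   color = .data$sign)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(BY = "#c0392b", RM = "#2980b9")) +
    ggplot2::labs(x = "trait position (genome, bp)",
                  y = "marker position (genome, bp)",
                  color = "allele up") +
    ggplot2::theme_minimal()
}

.genome_offsets <- function(markers, trait_positions) {
  chroms <- sort(unique(c(markers$chrom, trait_positions$chrom)))
  maxima <- vapply(chroms, function(cn) {
    max(c(markers$end[markers$chrom == cn],
          trait_positions$end[trait_positions$chrom == cn], 0))
  }, numeric(1))
  stats::setNames(cumsum(c(0, utils::head(maxima, -1))), chroms)
}

#' Trans- vs cis-variation overview of a variation decomposition
#'
#' Scatter of the two per-group trans-variation measures (BY-group SD vs
#' RM-group SD), one point per eligible OCR, colored by cis-test
#' significance.
#'
#' @param object An `ocr_variation`.
#' @param alpha Cis-test significance threshold for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ocr_variation
#' @export
autoplot.ocr_variation <- function(object, alpha = 0.01, ...) {
  df <- tibble::as_tibble(object)
  df$cis_significant <- df$p < alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$sd_by, .data$sd_rm,
                                   color = .data$cis_significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::labs(x = "trans-variation, BY group (SD)",
                  y = "trans-variation, RM group (SD)",
                  color = sprintf("cis p < %g", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a telomere-distance profile
#'
#' @param profile Output of [telomere_profile()].
#' @param near Distance marked by a vertical reference line, bp.
#' @return A ggplot.
#' @export
plot_telomere_profile <- function(profile, near = 1e4) {
  ggplot2::ggplot(profile$profile, ggplot2::aes(.data$mid / 1000, .data$mean)) +
    ggplot2::geom_line(color = "#2c3e50") +
    ggplot2::geom_vline(xintercept = near / 1000, linetype = 2,
                        color = "grey50") +
    ggplot2::labs(x = "distance from chromosome end (kb)",
                  y = "mean statistic (2 kb windows)") +
    ggplot2::theme_minimal()
}

#' Plot the per-locus target-count architecture
#'
#' @param loci Locus tibble from [build_regulatory_loci()].
#' @param hotspot_threshold Threshold marked by a reference line.
#' @return A ggplot.
#' @export
plot_locus_targets <- function(loci, hotspot_threshold = 65) {
  ggplot2::ggplot(loci, ggplot2::aes(stats::reorder(.data$locus, -.data$n_targets),
                                     .data$n_targets, fill = .data$hotspot)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = hotspot_threshold, linetype = 2,
                        color = "grey40") +
    ggplot2::labs(x = "regulatory locus", y = "distinct target traits",
                  fill = "hotspot") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
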