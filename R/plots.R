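#' LD triangle plot
#'
#' Haploview-style lower-triangle heat map of pairwise D' for one
#' chromosome.
#'
#' @param ld Tibble from [ld_pairwise()].
#' @param chrom Chromosome to draw (default: the first present).
#' @return A ggplot object.
#' @export
plot_ld <- function(ld, chrom = NULL) {
  chrom <- chrom %||% ld$chrom[1]
  dd <- ld |> filter(.data$chrom == !!chrom)
  ord <- unique(c(dd$snp1, dd$snp2))
  dd <- dd |>
    mutate(x = match(.data$snp1, ord), y = match(.data$snp2, ord),
           label = ifelse(is.na(.data$dprime), "",
                          sprintf("%.2f", .data$dprime)))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$dprime)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.7) +
    ggplot2::scale_fill_gradient(low = "white", high = "red", limits = c(0, 1),
                                 na.value = "grey85", name = "D'") +
    ggplot2::scale_x_continuous(breaks = seq_along(ord), labels = ord) +
    ggplot2::scale_y_continuous(breaks = seq_along(ord), labels = ord) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Pairwise D', chromosome", chrom)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' LS-mean plot for association results
#'
#' Genotype (or haplotype-combination) least-squares means with +/- SE bars,
#' facetted by trait and marker.
#'
#' @param object An association tibble from [assoc_single_snp()] or
#'   [haplotype_association()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lactsnp_assoc <- function(object, ...) {
  unit <- if ("snp" %in% names(object)) "snp" else "block"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$level, y = .data$estimate,
                               color = factor(.data$lactation))) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$se,
                                        ymax = .data$estimate + .data$se),
                           width = 0.2,
                           position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$trait),
                        cols = ggplot2::vars(.data[[unit]]), scales = "free") +
    ggplot2::labs(x = NULL, y = "LS-mean", color = "lactation") +
    ggplot2::theme_minimal()
}
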