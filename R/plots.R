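#' Volcano plot of a differential-expression result
#'
#' @param object An [nb_wald_test()] result.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change against -log10 adjusted p,
#'   coloured by call, with the fold-change and FDR thresholds drawn.
#' @export
autoplot.rt_de_result <- function(object, ...) {
  lfc <- attr(object, "lfc_threshold", exact = TRUE) %||% 0.5
  alpha <- attr(object, "alpha", exact = TRUE) %||% 0.05
  df <- mutate(as_tibble(object),
               neglog10_padj = -log10(pmax(.data$padj, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = .data$neglog10_padj,
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2c63a8",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (mutant / reference)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Stranded coverage track around a region
#'
#' @param cov A [coverage_from_reads()] result.
#' @param chrom,start,end Region to draw.
#' @return A ggplot object with forward coverage above and reverse coverage
#'   below the axis, the usual way stranded RNA-seq tracks are shown.
#' @export
plot_coverage <- function(cov, chrom, start, end) {
  df <- filter(as_tibble(cov), .data$chrom == !!chrom,
               .data$end > !!start, .data$start < !!end) |>
    mutate(start = pmax(.data$start, !!start),
           end = pmin(.data$end, !!end),
           signed = if_else(.data$strand == "+", .data$depth, -.data$depth))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = pmin(0, .data$signed),
                                    ymax = pmax(0, .data$signed),
                                    fill = .data$strand)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`+` = "#c0392b", `-` = "#2c63a8")) +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom),
                  y = "coverage (reverse strand negative)", fill = "strand") +
    ggplot2::theme_minimal()
}

#' Bar chart of an orientation composition
#'
#' @param composition An [orientation_composition()] result.
#' @return A ggplot comparing the gene set's orientation fractions with the
#'   genome background.
#' @export
plot_orientation_composition <- function(composition) {
  df <- tidyr::pivot_longer(composition, c("frac_set", "frac_genome"),
                            names_to = "population", values_to = "fraction") |>
    mutate(population = if_else(.data$population == "frac_set",
                                "gene set", "genome"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$orientation, y = .data$fraction,
                                   fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of genes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a DE result into a plain tibble
#'
#' @param x An [nb_wald_test()] result.
#' @param ... Unused.
#' @return A tibble with one row per feature (attributes dropped).
#' @export
tidy.rt_de_result <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a DE result
#'
#' @param x An [nb_wald_test()] result.
#' @param ... Unused.
#' @return One-row tibble: contrast, thresholds, feature and call counts.
#' @export
glance.rt_de_result <- function(x, ...) {
  ct <- attr(x, "contrast", exact = TRUE)
  tibble(contrast = paste(ct, collapse = " vs "),
         lfc_threshold = attr(x, "lfc_threshold", exact = TRUE),
         alternative = attr(x, "alternative", exact = TRUE),
         alpha = attr(x, "alpha", exact = TRUE),
         n_features = nrow(x),
         n_up = sum(x$call == "up"),
         n_down = sum(x$call == "down"))
}

#' Tidy a transcriptome comparison
#'
#' @param x A [summarise_comparison()] result.
#' @param ... Unused.
#' @return The one-row summary tibble.
#' @export
tidy.rt_comparison <- function(x, ...) x$summary
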