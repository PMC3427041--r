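# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram geom_bar
#'   facet_wrap labs theme_minimal scale_y_continuous coord_flip
#' @export
ggplot2::autoplot

#' Plot per-contig dN/dS components
#'
#' Histograms of per-contig dS, dN and dN/dS for one pairwise contrast.
#'
#' @param object A `dnds_survey`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dnds_survey <- function(object, bins = 40, ...) {
  df <- object$per_contig |>
    select("contig_id", "dS", "dN", "ratio") |>
    pivot_longer(c("dS", "dN", "ratio"),
                 names_to = "statistic", values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot(df, aes(x = .data$value)) +
    geom_histogram(bins = bins, fill = "grey35") +
    facet_wrap(~ .data$statistic, scales = "free") +
    labs(title = paste(object$pair, collapse = " vs "),
         x = NULL, y = "contigs") +
    theme_minimal()
}

#' Plot platform agreement classes
#'
#' @param object A `platform_reconciliation`.
#' @param ... Unused.
#' @return A ggplot of SNP counts per agreement class.
#' @exportS3Method ggplot2::autoplot
autoplot.platform_reconciliation <- function(object, ...) {
  df <- count(object$snps, .data$agreement)
  ggplot(df, aes(x = .data$agreement, y = .data$n)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = "SNPs") +
    theme_minimal()
}

#' Plot NRHR events by phylogenetic placement
#'
#' Event counts per placement (each species and the shared/ancestral class),
#' echoing the phylogeny-mapped event summary.
#'
#' @param events Placed event tibble from [place_events()] or
#'   [detect_nrhr()].
#' @return A ggplot.
#' @export
plot_nrhr_placement <- function(events) {
  df <- count(events, .data$placement)
  ggplot(df, aes(x = .data$placement, y = .data$n)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = "events") +
    theme_minimal()
}

#' Plot species-membership Venn cells
#'
#' Bar chart over the non-empty species subsets (an unrolled Venn diagram).
#'
#' @param venn Tibble from [species_venn()].
#' @param drop_empty Hide zero cells.
#' @return A ggplot.
#' @export
plot_species_venn <- function(venn, drop_empty = FALSE) {
  df <- if (drop_empty) venn[venn$n_contigs > 0, ] else venn
  df$subset <- factor(df$subset, levels = venn$subset)
  ggplot(df, aes(x = .data$subset, y = .data$n_contigs)) +
    geom_col(fill = "grey35") +
    coord_flip() +
    labs(x = NULL, y = "contigs") +
    theme_minimal()
}
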