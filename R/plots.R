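#' Plot a barcoding-gap histogram
#'
#' Paired bar histogram of intra- (blue) and interspecific (grey) K2P
#' distances, the standard way the barcoding gap is displayed.
#'
#' @param object A [gap_histogram()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gap_histogram
#' @export
autoplot.gap_histogram <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_low + (.data$bin_high - .data$bin_low) / 2,
                                   y = .data$count, fill = .data$type)) +
    ggplot2::geom_col(position = "identity", alpha = 0.75,
                      width = df$bin_high[1L] - df$bin_low[1L]) +
    ggplot2::scale_fill_manual(values = c(intra = "#2166ac", inter = "grey45"),
                               name = NULL,
                               labels = c(intra = "intraspecific",
                                          inter = "interspecific")) +
    ggplot2::labs(x = "K2P distance", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a gap report
#'
#' Histogram of the underlying partition with the reported gap interval
#' shaded.
#'
#' @param object A [gap_report()] object.
#' @param bin_width Histogram bin width (default 0.001).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gap_report
#' @export
autoplot.gap_report <- function(object, bin_width = 0.001, ...) {
  p <- autoplot(gap_histogram(object$partition, bin_width))
  if (!object$undefined && !object$overlap) {
    p <- p + ggplot2::annotate("rect", xmin = object$gap_low,
                               xmax = object$gap_high,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "#1b7837")
  }
  p
}

#' Plot per-helix substitution-event counts
#'
#' @param object An [enumerate_events()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot event_table
#' @export
autoplot.event_table <- function(object, ...) {
  df <- count(as_tibble(object), .data$helix, .data$class, name = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$helix, y = .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_brewer(palette = "Set2", name = NULL) +
    ggplot2::labs(x = "helix", y = "events") +
    ggplot2::theme_minimal()
}

#' Plot per-species distribution types and climate profiles
#'
#' Stacked proportions of Koppen-Geiger climate groups per species, labelled
#' with the assigned distribution type.
#'
#' @param summaries A [summarize_species()] tibble.
#' @return A ggplot object.
#' @export
plot_distribution_types <- function(summaries) {
  rows <- purrr::map(seq_len(nrow(summaries)), function(i) {
    tab <- summaries$climate_zones[[i]]
    if (length(tab) == 0L) return(NULL)
    tibble(species = summaries$species[i],
           group = koppen_group(names(tab)),
           n = as.integer(tab))
  })
  df <- bind_rows(rows) %>%
    group_by(.data$species, .data$group) %>%
    summarise(n = sum(.data$n), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$n,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_brewer(palette = "Dark2", name = "climate group") +
    ggplot2::labs(x = NULL, y = "proportion of samples") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
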