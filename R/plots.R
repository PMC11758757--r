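# ggplot2 displays for the main result types.

#' Plot pan-genome composition
#'
#' Bar chart of family counts per category, annotated with percentages.
#'
#' @param object A `pan_partition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pan_partition <- function(object, ...) {
  s <- partition_summary(object)
  s <- s[s$category != "total", , drop = FALSE]
  s$category <- factor(s$category, levels = partition_categories)
  ggplot(s, aes(x = .data$category, y = .data$n_families,
                fill = .data$category)) +
    geom_col(show.legend = FALSE) +
    geom_text(aes(label = paste0(.data$pct_families, "%")), vjust = -0.4,
              size = 3) +
    labs(x = NULL, y = "Gene families",
         title = "Pan-genome composition") +
    theme_minimal()
}

#' @rdname autoplot.pan_partition
#' @export
autoplot.pan_rga <- function(object, ...) {
  autoplot(object$partition) + labs(title = "Pan-RGA composition")
}

#' Plot a window track along the genome
#'
#' Per-chromosome facets of the windowed statistic (FST or SV count) with
#' an optional horizontal percentile-threshold line.
#'
#' @param track A window track tibble.
#' @param threshold Optional numeric threshold to draw (e.g. the
#'   `threshold` attribute of [call_hdr()] output).
#' @return A ggplot object.
#' @export
plot_window_track <- function(track, threshold = NULL) {
  p <- ggplot(track, aes(x = (.data$start + .data$end) / 2, y = .data$value)) +
    geom_step(na.rm = TRUE) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "Position (bp)", y = attr(track, "stat") %||% "value") +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red")
  }
  p
}

#' Plot per-group SV frequency profiles
#'
#' Frequencies of the supplied SVs (typically a favored set) per group,
#' ordered by focal-group frequency — the mean line and range ribbon view
#' of a favored-SV screen.
#'
#' @param freqs Frequency tibble from [group_sv_frequencies()].
#' @param focal Group used to order the SVs.
#' @return A ggplot object.
#' @export
plot_sv_frequencies <- function(freqs, focal) {
  grps <- attr(freqs, "freq_groups") %||% setdiff(names(freqs), .cohort_meta)
  long <- freqs |>
    mutate(rank = rank(.data[[focal]], ties.method = "first")) |>
    tidyr::pivot_longer(cols = dplyr::all_of(grps), names_to = "group",
                        values_to = "freq")
  ggplot(long, aes(x = .data$rank, y = .data$freq, colour = .data$group)) +
    geom_line(na.rm = TRUE) +
    labs(x = paste0("SVs ordered by ", focal, " frequency"),
         y = "Allele frequency", colour = "Group") +
    theme_minimal()
}
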