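# ggplot2 displays for the main result types.

#' Plot per-window divergence densities with cutoffs and regions
#'
#' One track per pairwise comparison: window density along the genome,
#' the pair's smoothed-quantile cutoff as a dashed line, tri-pair outlier
#' windows highlighted, and merged divergent regions shaded.
#'
#' @param object A `div_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.div_scan <- function(object, ...) {
  w <- as_tibble(object$windows)
  cuts <- tibble(pair = names(object$cutoffs),
                 cutoff = unname(object$cutoffs))
  p <- ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$density)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), size = 0.8) +
    ggplot2::geom_hline(data = cuts,
                        ggplot2::aes(yintercept = .data$cutoff),
                        linetype = "dashed") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$pair),
                        cols = ggplot2::vars(.data$scaffold),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (bp)", y = "fixed differences per bp",
                  colour = "outlier") +
    ggplot2::theme_minimal()
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE)
  }
  p
}

#' Plot evidence overlap of a candidate set
#'
#' Bar chart of divergent genes by evidence combination, strong candidates
#' highlighted.
#'
#' @param object A `candidate_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.candidate_set <- function(object, ...) {
  d <- as_tibble(tidy(object)) |>
    mutate(combo = dplyr::case_when(
      .data$positively_selected & .data$de_all_stages ~ "divergent + PS + DE",
      .data$positively_selected ~ "divergent + PS",
      .data$de_all_stages ~ "divergent + DE",
      TRUE ~ "divergent only"
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$combo, fill = .data$strong)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "genes", fill = "strong candidate") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot the mutation spectrum of clone calls
#'
#' Event lengths by type (D/I/M) across all mutant clones.
#'
#' @param calls Clone-call tibble from [call_clones()].
#' @return A ggplot.
#' @export
plot_mutation_spectrum <- function(calls) {
  ev <- list_rbind(as_tibble(calls)$events)
  if (nrow(ev) == 0) abort("no events to plot")
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$type, y = .data$length)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = "event type", y = "event length (bp)") +
    ggplot2::theme_minimal()
}
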