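# broom-style tidiers for the scan and candidate objects.

#' Tidy a divergence scan
#'
#' @param x A `div_scan` object.
#' @param ... Unused.
#' @return The long per-window tibble (`scaffold`, `start`, `end`, `count`,
#'   `density`, `pair`, `outlier`).
#' @export
tidy.div_scan <- function(x, ...) {
  as_tibble(x$windows)
}

#' One-row summary of a divergence scan
#'
#' @param x A `div_scan` object.
#' @param ... Unused.
#' @return One-row tibble: windows per pair, per-pair cutoffs, outlier
#'   window count (tri-pair), region count and total region span.
#' @export
glance.div_scan <- function(x, ...) {
  n_pairs <- length(x$cutoffs)
  cuts <- as.list(setNames(x$cutoffs, paste0("cutoff_", names(x$cutoffs))))
  tri <- if (nrow(x$windows) > 0) {
    x$windows |>
      group_by(.data$scaffold, .data$start) |>
      summarise(all_out = all(.data$outlier), .groups = "drop") |>
      pull(.data$all_out) |> sum()
  } else 0L
  bind_cols(
    tibble(n_windows = nrow(x$windows) / n_pairs,
           quantile = x$params$quantile),
    as_tibble(cuts),
    tibble(n_outlier_windows = tri,
           n_regions = nrow(x$regions),
           region_span_bp = sum(x$regions$end - x$regions$start))
  )
}

#' Tidy a candidate set
#'
#' @param x A `candidate_set`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.candidate_set <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "candidate_set")
  as_tibble(out)
}

#' Counts per evidence combination of a candidate set
#'
#' @param x A `candidate_set`.
#' @param ... Unused.
#' @return One-row tibble: total divergent genes, counts with each extra
#'   evidence flag, each combination, and strong candidates.
#' @export
glance.candidate_set <- function(x, ...) {
  tibble(
    n_divergent = nrow(x),
    n_positively_selected = sum(x$positively_selected),
    n_de_all_stages = sum(x$de_all_stages),
    n_ps_and_de = sum(x$positively_selected & x$de_all_stages),
    n_ps_only = sum(x$positively_selected & !x$de_all_stages),
    n_de_only = sum(!x$positively_selected & x$de_all_stages),
    n_strong = sum(x$strong)
  )
}
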