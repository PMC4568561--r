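# Windowed fixed-difference divergence scan: call fixed differences between
# two taxa against a shared reference, tile the genome, compute per-window
# densities, derive a smoothed empirical-quantile cutoff per comparison, and
# intersect outlier windows across all three comparisons.

#' Call fixed-difference sites between two taxa
#'
#' Both variant tables are calls against the same reference. A site is a
#' fixed difference iff both taxa carry homozygous calls with differing
#' alleles, or exactly one taxon carries a homozygous non-reference call and
#' the other has no record (i.e. matches the reference). Any heterozygous or
#' missing genotype at a site excludes it: fixation requires homozygosity,
#' which matters for highly heterozygous wild-caught insects.
#'
#' @param variants_x,variants_y Tibbles with columns `scaffold`, `pos`
#'   (0-based), `alt`, `genotype` (`"1/1"` homozygous alt, `"0/1"`/`"1/0"`
#'   heterozygous, `"./."` missing; phased separators accepted).
#' @param scaffold_lengths Named numeric vector of reference scaffold lengths;
#'   used to validate scaffold names and positions.
#' @param pair_label Optional label attached to the result.
#' @return Tibble of fixed-difference sites: `scaffold`, `pos`, and `pair` if
#'   `pair_label` was given.
#' @export
#' @examples
#' x <- tibble::tibble(scaffold = "s1", pos = 10, alt = "T", genotype = "1/1")
#' y <- x[0, ]
#' call_fixed_differences(x, y, c(s1 = 100))
call_fixed_differences <- function(variants_x, variants_y, scaffold_lengths,
                                   pair_label = NULL) {
  vx <- normalize_variants(variants_x)
  vy <- normalize_variants(variants_y)
  both <- bind_rows(vx, vy)
  bad <- setdiff(unique(both$scaffold), names(scaffold_lengths))
  if (length(bad) > 0) {
    abort(paste0("scaffold(s) absent from reference: ",
                 paste(bad, collapse = ", ")))
  }
  if (nrow(both) > 0) {
    lens <- scaffold_lengths[both$scaffold]
    if (any(both$pos < 0 | both$pos >= lens)) {
      abort("variant position outside scaffold bounds")
    }
  }
  j <- full_join(vx, vy, by = c("scaffold", "pos"),
                 suffix = c("_x", "_y"))
  gx <- j$gt_class_x
  gy <- j$gt_class_y
  gx[is.na(gx)] <- "ref"   # no record = matches reference
  gy[is.na(gy)] <- "ref"
  ok <- !(gx %in% c("het", "missing")) & !(gy %in% c("het", "missing"))
  hom_hom <- gx == "hom" & gy == "hom" & j$alt_x != j$alt_y
  hom_hom[is.na(hom_hom)] <- FALSE
  hom_ref <- (gx == "hom" & gy == "ref") | (gx == "ref" & gy == "hom")
  keep <- ok & (hom_hom | hom_ref)
  out <- j[keep, c("scaffold", "pos")] |>
    arrange(.data$scaffold, .data$pos) |>
    as_tibble()
  if (!is.null(pair_label)) out$pair <- pair_label
  out
}

normalize_variants <- function(v) {
  v <- as_tibble(v)
  need <- c("scaffold", "pos", "alt", "genotype")
  if (!all(need %in% names(v))) {
    abort(paste0("variant table needs columns: ", paste(need, collapse = ", ")))
  }
  gt <- gsub("|", "/", v$genotype, fixed = TRUE)
  v$gt_class <- dplyr::case_when(
    gt %in% c("1/1") ~ "hom",
    gt %in% c("0/1", "1/0") ~ "het",
    gt %in% c("0/0") ~ "ref",
    TRUE ~ "missing"
  )
  v[, c("scaffold", "pos", "alt", "gt_class")]
}

#' Tile scaffolds into non-overlapping windows
#'
#' Windows of `window_length` bp are tiled from position 0 of each scaffold.
#' A terminal partial window is kept iff its length is at least
#' `min_window_fraction * window_length`.
#'
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp).
#' @param window_length Window length in bp (default 50,000).
#' @param min_window_fraction Minimum terminal-window fraction (default 0.5).
#' @return Tibble with `scaffold`, `start`, `end` (0-based half-open).
#' @export
#' @examples
#' tile_windows(c(s1 = 149000), window_length = 50000)
tile_windows <- function(scaffold_lengths, window_length = 5e4,
                         min_window_fraction = 0.5) {
  if (any(scaffold_lengths < 1)) abort("scaffold lengths must be >= 1")
  stopifnot_scalar_number(window_length, "window_length", min = 1)
  out <- imap(as.list(scaffold_lengths), function(len, scaf) {
    starts <- seq(0, max(len - 1, 0), by = window_length)
    ends <- pmin(starts + window_length, len)
    tibble(scaffold = scaf, start = starts, end = ends)
  }) |> list_rbind()
  out |>
    filter(.data$end - .data$start >= min_window_fraction * window_length |
             .data$end - .data$start == window_length)
}

#' Per-window fixed-difference counts and densities
#'
#' Each difference site is counted in the unique window containing it;
#' density is count divided by the actual (possibly terminal-short) window
#' length. Sites falling outside all retained windows are counted nowhere and
#' reported via a message.
#'
#' @param diffs Tibble of difference sites (`scaffold`, `pos`), e.g. from
#'   [call_fixed_differences()].
#' @param windows Window tibble from [tile_windows()].
#' @param pair_label Optional label attached to the result.
#' @return Tibble with `scaffold`, `start`, `end`, `count`, `density` (and
#'   `pair`), one row per window.
#' @export
window_density <- function(diffs, windows, pair_label = NULL) {
  windows <- as_tibble(windows) |> arrange(.data$scaffold, .data$start)
  diffs <- as_tibble(diffs)
  counts <- integer(nrow(windows))
  dropped <- 0L
  if (nrow(diffs) > 0) {
    for (s in unique(diffs$scaffold)) {
      w <- which(windows$scaffold == s)
      p <- diffs$pos[diffs$scaffold == s]
      if (length(w) == 0) {
        dropped <- dropped + length(p)
        next
      }
      idx <- findInterval(p, windows$start[w])
      inside <- idx >= 1 & p < windows$end[w][pmax(idx, 1)]
      dropped <- dropped + sum(!inside)
      tab <- tabulate(idx[inside], nbins = length(w))
      counts[w] <- counts[w] + tab
    }
  }
  if (dropped > 0) {
    inform(sprintf("%d difference site(s) fell outside retained windows", dropped))
  }
  out <- windows |>
    mutate(count = counts, density = counts / (.data$end - .data$start))
  if (!is.null(pair_label)) out$pair <- pair_label
  out
}

#' Smoothed empirical-quantile cutoff for window densities
#'
#' Estimates the distribution of window densities with a Gaussian-kernel
#' smoothed empirical CDF, `F(x) = mean(pnorm((x - d_i)/h))`, and returns the
#' smallest `x` with `F(x) >= quantile`. Bandwidth `"auto"` uses Silverman's
#' rule-of-thumb ([stats::bw.nrd0()]); bandwidth 0 degenerates to the plain
#' empirical quantile (type-7 interpolation).
#'
#' @param densities Numeric vector of per-window densities (>= 10 values).
#' @param quantile Quantile in (0, 1), default 0.95.
#' @param bandwidth `"auto"`, or a non-negative bandwidth in density units.
#' @return The cutoff density (scalar).
#' @export
#' @examples
#' smoothed_quantile_cutoff(seq(0.01, 1, by = 0.01), bandwidth = 0)
smoothed_quantile_cutoff <- function(densities, quantile = 0.95,
                                     bandwidth = "auto") {
  if (length(densities) < 10) {
    abort("need at least 10 windows for a reliable cutoff")
  }
  stopifnot_scalar_number(quantile, "quantile")
  if (quantile <= 0 || quantile >= 1) abort("`quantile` must be in (0, 1)")
  h <- if (identical(bandwidth, "auto")) bw.nrd0(densities) else bandwidth
  stopifnot_scalar_number(h, "bandwidth", min = 0)
  if (!is.finite(h) || h <= 0) {
    return(unname(stats::quantile(densities, quantile, type = 7)))
  }
  f <- function(x) mean(pnorm(x, mean = densities, sd = h)) - quantile
  lo <- min(densities) - 10 * h
  hi <- max(densities) + 10 * h
  uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.5)$root
}

#' Intersect per-pair outlier windows into divergent regions
#'
#' A window is an outlier iff its density strictly exceeds the pair's cutoff
#' in all three comparisons; runs of adjacent outlier windows on a scaffold
#' merge into one region.
#'
#' @param window_stats Tibble of per-window stats for all pairs (long format,
#'   columns `scaffold`, `start`, `end`, `density`, `pair`); the three pairs
#'   must cover identical window grids.
#' @param cutoffs Named numeric vector of per-pair cutoffs (names = pair
#'   labels present in `window_stats`).
#' @param strict If `TRUE` (default) outliers require density strictly above
#'   the cutoff; if `FALSE`, `>=` is used.
#' @return Tibble of regions: `scaffold`, `start`, `end`, `n_windows`,
#'   `member_windows` (list column of window row indices into the shared
#'   grid) and one mean-density column per pair.
#' @export
divergent_regions <- function(window_stats, cutoffs, strict = TRUE) {
  ws <- as_tibble(window_stats)
  pairs <- sort(unique(ws$pair))
  if (!setequal(pairs, names(cutoffs))) {
    abort("`cutoffs` must be named by the pair labels in `window_stats`")
  }
  wide <- ws |>
    select("scaffold", "start", "end", "pair", "density") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "density") |>
    arrange(.data$scaffold, .data$start)
  if (anyNA(wide[pairs]) || nrow(wide) * length(pairs) != nrow(ws)) {
    abort("the three pairs must cover identical window grids")
  }
  cmp <- if (strict) `>` else `>=`
  out_mat <- vapply(pairs, function(p) cmp(wide[[p]], cutoffs[[p]]),
                    logical(nrow(wide)))
  wide$outlier <- rowSums(as.matrix(out_mat)) == length(pairs)
  wide$window_id <- seq_len(nrow(wide))
  o <- wide |> filter(.data$outlier)
  if (nrow(o) == 0) {
    return(tibble(scaffold = character(), start = numeric(), end = numeric(),
                  n_windows = integer(), member_windows = list()))
  }
  o <- o |>
    group_by(.data$scaffold) |>
    mutate(new_run = .data$start != dplyr::lag(.data$end,
                                               default = -Inf)) |>
    ungroup() |>
    mutate(region = cumsum(.data$new_run))
  regions <- o |>
    group_by(.data$region, .data$scaffold) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = n(),
              member_windows = list(.data$window_id),
              across(all_of(pairs), mean, .names = "density_{.col}"),
              .groups = "drop") |>
    select(-"region") |>
    arrange(.data$scaffold, .data$start)
  regions
}

#' Flag per-window outlier status against per-pair cutoffs
#'
#' @inheritParams divergent_regions
#' @return `window_stats` with an added logical `outlier` column (per pair).
#' @export
flag_outliers <- function(window_stats, cutoffs, strict = TRUE) {
  ws <- as_tibble(window_stats)
  cmp <- if (strict) `>` else `>=`
  ws |> mutate(outlier = cmp(.data$density, unname(cutoffs[.data$pair])))
}

#' Run the full three-way divergence scan
#'
#' Tiles the reference, computes per-window fixed-difference densities for
#' each pair, derives one smoothed-quantile cutoff per comparison, and
#' intersects outlier windows into divergent regions.
#'
#' @param diffs Tibble of fixed-difference sites for all three pairs
#'   (columns `scaffold`, `pos`, `pair`), e.g. three
#'   [call_fixed_differences()] results row-bound together.
#' @param scaffold_lengths Named numeric vector of scaffold lengths.
#' @param window_length,min_window_fraction See [tile_windows()].
#' @param quantile,bandwidth See [smoothed_quantile_cutoff()].
#' @param strict See [divergent_regions()].
#' @return An object of class `div_scan`: list with `windows` (long tibble
#'   with `outlier` flags), `cutoffs` (named vector), `regions` (tibble) and
#'   `params`. Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
divergence_scan <- function(diffs, scaffold_lengths, window_length = 5e4,
                            quantile = 0.95, bandwidth = "auto",
                            min_window_fraction = 0.5, strict = TRUE) {
  diffs <- as_tibble(diffs)
  if (!"pair" %in% names(diffs)) abort("`diffs` needs a `pair` column")
  windows <- tile_windows(scaffold_lengths, window_length,
                          min_window_fraction)
  pairs <- sort(unique(diffs$pair))
  stats <- map(pairs, function(p) {
    window_density(diffs |> filter(.data$pair == p), windows, pair_label = p)
  }) |> list_rbind()
  cutoffs <- vapply(pairs, function(p) {
    smoothed_quantile_cutoff(stats$density[stats$pair == p],
                             quantile = quantile, bandwidth = bandwidth)
  }, numeric(1))
  regions <- divergent_regions(stats, cutoffs, strict = strict)
  structure(list(
    windows = flag_outliers(stats, cutoffs, strict = strict),
    cutoffs = cutoffs,
    regions = regions,
    params = list(window_length = window_length, quantile = quantile,
                  bandwidth = bandwidth,
                  min_window_fraction = min_window_fraction,
                  strict = strict)
  ), class = "div_scan")
}

#' @export
print.div_scan <- function(x, ...) {
  cat("<div_scan>\n")
  cat(sprintf("  %d windows x %d comparisons, window length %g bp\n",
              nrow(x$windows) / length(x$cutoffs), length(x$cutoffs),
              x$params$window_length))
  cat(sprintf("  cutoffs (q = %.2f): %s\n", x$params$quantile,
              paste(sprintf("%s = %.3g", names(x$cutoffs), x$cutoffs),
                    collapse = ", ")))
  cat(sprintf("  %d divergent region(s) spanning %d window(s)\n",
              nrow(x$regions), sum(x$regions$n_windows)))
  invisible(x)
}
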