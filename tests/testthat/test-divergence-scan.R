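# Fixed-difference calling, tiling, densities, cutoffs, region intersection.

test_that("fixed-difference rule handles the definitional cases", {
  sl <- c(s1 = 1000)
  empty <- tibble::tibble(scaffold = character(), pos = numeric(),
                          ref = character(), alt = character(),
                          genotype = character())
  expect_equal(nrow(call_fixed_differences(empty, empty, sl)), 0)

  x <- tibble::tibble(scaffold = "s1", pos = 10, ref = "A", alt = "T",
                      genotype = "1/1")
  d <- call_fixed_differences(x, empty, sl)
  expect_equal(d$pos, 10)                          # hom alt vs reference
  # both hom, same allele: not a difference
  expect_equal(nrow(call_fixed_differences(x, x, sl)), 0)
  # both hom, different alleles: difference
  y <- dplyr::mutate(x, alt = "G")
  expect_equal(call_fixed_differences(x, y, sl)$pos, 10)
  # heterozygous or missing on either side excludes the site
  for (g in c("0/1", "1/0", "0|1", "./.")) {
    expect_equal(nrow(call_fixed_differences(x, dplyr::mutate(x, genotype = g),
                                             sl)), 0)
  }
  expect_error(call_fixed_differences(
    dplyr::mutate(x, scaffold = "sX"), empty, sl), "sX")
})

test_that("fixed-difference calls equal the site-by-site oracle", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      vx <- random_genotype_table(sample.int(500, 200) - 1)
      vy <- random_genotype_table(sample.int(500, 200) - 1)
      got <- call_fixed_differences(vx, vy, c(s1 = 500))
      want <- oracle_fixed_diffs(vx, vy)
      expect_equal(got$pos, want$pos)
    }
  })
})

test_that("window tiling keeps terminal windows by the half-length rule", {
  expect_equal(nrow(tile_windows(c(s = 150000), 50000)), 3)
  w <- tile_windows(c(s = 149000), 50000)
  expect_equal(nrow(w), 3)
  expect_equal(w$end[3] - w$start[3], 49000)
  # 10-kb remainder dropped at min fraction 0.5
  expect_equal(nrow(tile_windows(c(s = 110000), 50000)), 2)
  # but kept when the fraction is lowered
  expect_equal(nrow(tile_windows(c(s = 110000), 50000,
                                 min_window_fraction = 0.1)), 3)
})

test_that("window densities match a brute-force membership count", {
  expect_equal(
    window_density(tibble::tibble(scaffold = character(), pos = numeric()),
                   tile_windows(c(s = 2e5), 5e4))$density,
    rep(0, 4))
  withr::with_seed(7, {
    d <- tibble::tibble(scaffold = sample(c("s1", "s2"), 500, replace = TRUE),
                        pos = sample.int(95000, 500, replace = TRUE) - 1)
    w <- tile_windows(c(s1 = 95000, s2 = 95000), 2e4)
    got <- window_density(d, w)
    for (i in seq_len(nrow(got))) {
      expect_equal(got$count[i],
                   sum(d$scaffold == got$scaffold[i] &
                         d$pos >= got$start[i] & d$pos < got$end[i]))
    }
    expect_equal(got$density, got$count / (got$end - got$start))
    # conservation: every retained-window site counted exactly once
    retained <- sum(vapply(seq_len(nrow(w)), function(i)
      sum(d$scaffold == w$scaffold[i] & d$pos >= w$start[i] &
            d$pos < w$end[i]), numeric(1)))
    expect_equal(sum(got$count), retained)
  })
  # 50 diffs uniform in one 50-kb window -> density 1e-3
  d50 <- tibble::tibble(scaffold = "s", pos = seq(0, 49000, length.out = 50))
  expect_equal(window_density(d50, tile_windows(c(s = 5e4), 5e4))$density, 1e-3)
})

test_that("sites outside retained windows are dropped with a message", {
  d <- tibble::tibble(scaffold = "s", pos = c(10, 60000))
  w <- tile_windows(c(s = 70000), 5e4)   # terminal 20-kb window dropped
  expect_message(res <- window_density(d, w), "outside retained windows")
  expect_equal(sum(res$count), 1)
})

test_that("smoothed quantile cutoff: degenerate, type-7 and bandwidth limit", {
  expect_equal(smoothed_quantile_cutoff(rep(0.5, 20), bandwidth = 0), 0.5)
  x <- (1:100) / 1000
  expect_equal(smoothed_quantile_cutoff(x, bandwidth = 0),
               unname(stats::quantile(x, 0.95, type = 7)))
  # shrinking bandwidth converges monotonically to the empirical quantile
  emp <- unname(stats::quantile(x, 0.95, type = 7))
  errs <- vapply(10^-(1:6) * stats::sd(x), function(bw) {
    abs(smoothed_quantile_cutoff(x, bandwidth = bw) - emp)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[6], 1e-6)
  expect_error(smoothed_quantile_cutoff(1:5 / 10), "at least 10")
  expect_error(smoothed_quantile_cutoff(x, quantile = 1.2), "in \\(0, 1\\)")
})

test_that("tri-pair intersection and adjacency merging follow the rule", {
  w <- tile_windows(c(s = 5e5), 5e4)
  mk <- function(dens, pair) dplyr::mutate(w, count = NA, density = dens,
                                           pair = pair)
  base <- rep(1e-3, 10)
  dens_a <- base; dens_b <- base; dens_c <- base
  dens_a[c(3, 4, 5, 9)] <- 1e-2
  dens_b[c(3, 4, 5, 9)] <- 1e-2
  dens_c[c(3, 4, 5)] <- 1e-2          # window 9 fails in pair C
  ws <- dplyr::bind_rows(mk(dens_a, "A"), mk(dens_b, "B"), mk(dens_c, "C"))
  cuts <- c(A = 5e-3, B = 5e-3, C = 5e-3)
  reg <- divergent_regions(ws, cuts)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, w$start[3])
  expect_equal(reg$end, w$end[5])
  expect_equal(reg$n_windows, 3)
  expect_equal(reg$member_windows[[1]], 3:5)
  # no window above any cutoff -> empty
  expect_equal(nrow(divergent_regions(ws, c(A = 1, B = 1, C = 1))), 0)
  # one pair's cutoff above its max density -> empty intersection
  expect_equal(nrow(divergent_regions(ws, c(A = 5e-3, B = 5e-3, C = 1))), 0)
  # strict inequality at the cutoff: ties are not outliers
  expect_equal(nrow(divergent_regions(ws, c(A = 1e-2, B = 1e-2, C = 1e-2))), 0)
  expect_equal(nrow(divergent_regions(ws, c(A = 1e-2, B = 1e-2, C = 1e-2),
                                      strict = FALSE)), 1)
  # mismatched grids error
  expect_error(divergent_regions(ws[-1, ], cuts), "identical window grids")
})

test_that("raising the quantile never increases the outlier-window count", {
  withr::with_seed(19, {
    cfg <- sim_config(seed = 19, scaffold_length = 3e6, n_genes = 0,
                      hotspot_windows_per_pair = 3L)
    div <- simulate_divergence(c(s1 = 3e6), cfg)
    diffs <- dplyr::bind_rows(lapply(
      utils::combn(sort(names(div$variants)), 2, simplify = FALSE),
      function(p) call_fixed_differences(div$variants[[p[1]]],
                                         div$variants[[p[2]]],
                                         c(s1 = 3e6),
                                         paste(p, collapse = "_"))))
    counts <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(q) {
      sc <- divergence_scan(diffs, c(s1 = 3e6), quantile = q)
      sum(sc$regions$n_windows)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    # intersection is a subset of every single-pair outlier set
    sc <- divergence_scan(diffs, c(s1 = 3e6))
    tri <- sc$regions$member_windows
    per_pair <- split(sc$windows$outlier, sc$windows$pair)
    for (p in per_pair) expect_true(all(p[unlist(tri)]))
  })
})

test_that("the whole scan matches a naive reimplementation", {
  withr::with_seed(23, {
    for (s in 1:3) {
      cfg <- sim_config(seed = 200 + s, scaffold_length = 5e5, n_genes = 0,
                        window_length = 5e4, hotspot_windows_per_pair = 1L,
                        hotspot_rate = 3e-2)
      lens <- c(sA = 5e5, sB = 3e5)
      div <- simulate_divergence(lens, cfg)
      diffs <- dplyr::bind_rows(lapply(
        utils::combn(sort(names(div$variants)), 2, simplify = FALSE),
        function(p) call_fixed_differences(div$variants[[p[1]]],
                                           div$variants[[p[2]]], lens,
                                           paste(p, collapse = "_"))))
      got <- divergence_scan(diffs, lens, bandwidth = 0)
      want <- oracle_scan(diffs, lens, 5e4)
      expect_equal(nrow(got$regions), nrow(want$regions))
      if (nrow(want$regions) > 0) {
        expect_equal(got$regions$start, want$regions$start)
        expect_equal(got$regions$end, want$regions$end)
      }
      # per-window outlier flags agree (tri-pair)
      tri_got <- got$windows |>
        dplyr::group_by(scaffold, start) |>
        dplyr::summarise(out = all(outlier), .groups = "drop") |>
        dplyr::arrange(scaffold, start)
      expect_equal(tri_got$out,
                   want$outlier[order(want$windows$scaffold,
                                      want$windows$start)])
    }
  })
})
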