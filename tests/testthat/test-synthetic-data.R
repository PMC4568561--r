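# Generators: determinism, bounds, conservation, and the null models.

test_that("reference simulation respects bounds, strands and determinism", {
  cfg <- sim_config(seed = 11, n_scaffolds = 2, scaffold_length = 2e5,
                    n_genes = 40, window_length = 5e4)
  ref1 <- simulate_reference(cfg)
  ref2 <- simulate_reference(cfg)
  expect_identical(ref1, ref2)

  expect_equal(nrow(ref1$genes), 40)
  expect_setequal(unique(nchar(ref1$genome)), 2e5)
  # independent interval check: every exon inside its gene, inside its
  # scaffold; genes non-overlapping per scaffold
  for (i in seq_len(nrow(ref1$exons))) {
    e <- ref1$exons[i, ]
    g <- ref1$genes[ref1$genes$gene_id == e$gene_id, ]
    expect_true(e$start >= g$start && e$end <= g$end && e$start < e$end)
    expect_true(e$end <= nchar(ref1$genome[[e$scaffold]]))
  }
  by_scaf <- split(ref1$genes, ref1$genes$scaffold)
  for (g in by_scaf) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_setequal(unique(ref1$genes$strand), c("+", "-"))
})

test_that("zero genes gives an empty annotation; infeasible packing errors", {
  ref <- simulate_reference(sim_config(seed = 1, n_scaffolds = 1,
                                       scaffold_length = 1000, n_genes = 0))
  expect_equal(nrow(ref$genes), 0)
  expect_equal(nrow(ref$exons), 0)
  expect_equal(nchar(ref$genome[[1]]), 1000)
  expect_error(
    simulate_reference(sim_config(seed = 1, n_scaffolds = 1,
                                  scaffold_length = 500, n_genes = 20)),
    "cannot place")
})

test_that("divergence simulation: conservation and per-pair binomial counts", {
  cfg <- sim_config(seed = 21, scaffold_length = 1e6, n_genes = 0,
                    background_rate = 1e-3, hotspot_rate = 2e-2,
                    hotspot_windows_per_pair = 0L)
  div <- simulate_divergence(c(s1 = 1e6), cfg)
  # conservation: homozygous-alt records across taxa == drawn sites
  n_hom <- sum(vapply(div$variants,
                      function(v) sum(v$genotype == "1/1"), numeric(1)))
  expect_equal(n_hom, nrow(div$truth$sites))
  # per-pair counts within 4 SD of Binomial(1e6, 1e-3)
  per_pair <- table(div$truth$sites$pair)
  expect_length(per_pair, 3)
  sd <- sqrt(1e6 * 1e-3 * (1 - 1e-3))
  expect_true(all(abs(per_pair - 1000) < 4 * sd))
  # every drawn site is realized as a fixed difference for its pair, and the
  # third taxon's heterozygous record excludes it from the other two pairs
  sl <- c(s1 = 1e6)
  taxa <- names(div$variants)
  for (pr in utils::combn(sort(taxa), 2, simplify = FALSE)) {
    lbl <- paste(pr, collapse = "_")
    d <- call_fixed_differences(div$variants[[pr[1]]], div$variants[[pr[2]]],
                                sl, lbl)
    truth <- div$truth$sites[div$truth$sites$pair == lbl, ]
    expect_equal(nrow(d), nrow(truth))
    expect_setequal(d$pos, truth$pos)
  }
})

test_that("null divergence model yields zero variants", {
  cfg <- sim_config(seed = 3, scaffold_length = 1e5, n_genes = 0,
                    background_rate = 0, hotspot_rate = 1e-2,
                    hotspot_windows_per_pair = 0L)
  div <- simulate_divergence(c(s1 = 1e5), cfg)
  expect_true(all(vapply(div$variants, nrow, numeric(1)) == 0))
  expect_equal(nrow(div$truth$sites), 0)
})

test_that("planted windows dominate background densities (Mann-Whitney)", {
  pvals <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 100 + s, scaffold_length = 5e6, n_genes = 0,
                      window_length = 5e4, background_rate = 1e-3,
                      hotspot_rate = 1e-2, hotspot_windows_per_pair = 5L)
    div <- simulate_divergence(c(s1 = 5e6), cfg)
    d <- call_fixed_differences(div$variants$taxonA, div$variants$taxonB,
                                c(s1 = 5e6))
    w <- window_density(d, tile_windows(c(s1 = 5e6), 5e4))
    planted <- div$truth$planted_regions
    planted <- planted[planted$pair == "taxonA_taxonB", ]
    hot <- w$start %in% planted$start
    suppressWarnings(
      stats::wilcox.test(w$density[hot], w$density[!hot],
                         alternative = "greater")$p.value)
  }, numeric(1))
  expect_true(all(pvals < 0.01))
})

test_that("expression simulation: determinism, null model and planted shifts", {
  genes <- tibble::tibble(gene_id = sprintf("gene%03d", 1:50))
  cfg <- sim_config(seed = 31, n_de_genes = 5)
  ex1 <- simulate_expression(genes, cfg)
  ex2 <- simulate_expression(genes, cfg)
  expect_identical(ex1, ex2)
  expect_length(ex1$truth$de_genes, 5)
  expect_equal(setdiff(names(ex1$rpkm_a), "gene_id"),
               paste0("stage", sprintf("%02d", 1:10)))
  # no-effect null: fold change 1 -> empty truth set
  ex0 <- simulate_expression(genes, sim_config(seed = 31, de_fold_change = 1))
  expect_length(ex0$truth$de_genes, 0)
  # planted genes shifted in a consistent direction at every stage
  ma <- as.matrix(ex1$rpkm_a[-1]); rownames(ma) <- ex1$rpkm_a$gene_id
  mb <- as.matrix(ex1$rpkm_b[-1]); rownames(mb) <- ex1$rpkm_b$gene_id
  for (g in ex1$truth$de_genes) {
    gb <- ex1$orthologs$gene_b[ex1$orthologs$gene_a == g]
    lr <- log2(ma[g, ] / mb[gb, ])
    expect_true(all(lr > 0) || all(lr < 0))
  }
})

test_that("editing simulation: null model, length bookkeeping, conservation", {
  set.seed(1)
  amp <- random_dna(300)
  wt <- simulate_editing_experiment(amp, cut_sites = 150, n_individuals = 4,
                                    clones_per_individual = 3,
                                    mutation_prob = 0, seed = 5)
  expect_equal(length(wt$clones), 12)  # n_individuals x clones_per_individual
  expect_true(all(wt$clones == amp))
  expect_true(all(wt$truth$status == "WT"))

  del <- simulate_editing_experiment(
    amp, cut_sites = 150, n_individuals = 2, clones_per_individual = 5,
    mutation_prob = 1, seed = 6,
    event_spec = tibble::tibble(type = "D", length = 12, prob = 1))
  expect_true(all(nchar(del$clones) == 300 - 12))
  expect_true(all(del$truth$type == "D" & del$truth$length == 12))

  expect_error(simulate_editing_experiment(amp, cut_sites = 400, seed = 1),
               "within the amplicon")
  expect_error(simulate_editing_experiment(
    amp, cut_sites = 10, seed = 1,
    event_spec = tibble::tibble(type = "D", length = 300, prob = 1)),
    "amplicon length")
})

test_that("phenotype counts follow the injected-individual binomial", {
  amp <- strrep("ACGT", 30)
  draws <- vapply(1:200, function(s) {
    simulate_editing_experiment(amp, cut_sites = 60,
                                n_individuals = 25, clones_per_individual = 1,
                                phenotype_prob = 0.88, mutation_prob = 0,
                                seed = s)$counts$n_mutant_individuals
  }, numeric(1))
  # mean of Binomial(25, 0.88) is 22
  expect_lt(abs(mean(draws) - 22), 3 * sqrt(25 * 0.88 * 0.12 / 200))
  expect_true(all(draws <= 25))
})
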