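# Alignment, event extraction, clone classification and the summary table.

test_that("identity alignment scores 2L with no events", {
  s <- "ACGTACGTACGTACGT"
  a <- global_align(s, s)
  expect_equal(a$score, 2 * nchar(s))
  expect_equal(nrow(a$events), 0)
  expect_error(global_align("", s), "non-empty")
  expect_error(global_align("ACGTX", s), "alphabet")
})

test_that("a clean middle deletion is recovered as one D event", {
  wt <- "ACGTTGCAATCGGCTA"
  clone <- paste0(substr(wt, 1, 6), substr(wt, 11, 16))  # drop 4 bp
  a <- global_align(clone, wt)
  expect_equal(a$events$type, "D")
  expect_equal(a$events$length, 4)
  expect_equal(a$events$ref_start, 6)
  # de-gapped aligned rows equal the inputs
  expect_equal(gsub("-", "", a$clone_aln), clone)
  expect_equal(gsub("-", "", a$ref_aln), wt)
})

test_that("alignment scores equal the Gotoh DP oracle on random pairs", {
  withr::with_seed(71, {
    for (i in 1:100) {
      n <- sample(5:50, 1)
      a <- random_dna(n)
      b <- a
      # random perturbation: substitution, deletion or insertion
      op <- sample(c("sub", "del", "ins", "none"), 1)
      if (op == "sub" && n > 3) {
        k <- sample.int(n - 2, 1)
        substr(b, k, k) <- sample(c("A", "C", "G", "T"), 1)
      } else if (op == "del" && n > 10) {
        k <- sample.int(n - 6, 1)
        b <- paste0(substr(b, 1, k), substr(b, k + 4, n))
      } else if (op == "ins") {
        k <- sample.int(n, 1)
        b <- paste0(substr(b, 1, k), random_dna(3), substr(b, k + 1, n))
      }
      expect_equal(global_align(a, b)$score, oracle_align_score(a, b),
                   info = paste(a, b))
    }
  })
})

test_that("gap runs are left-aligned within repeats", {
  # deleting any one A from a homopolymer must report the leftmost placement
  wt <- "ACGTAAAAACGT"
  clone <- "ACGTAAAACGT"
  a <- global_align(clone, wt)
  expect_equal(a$events$type, "D")
  expect_equal(a$events$ref_start, 4)
})

test_that("long substitution runs are reported as M despite gap-gap optima", {
  withr::with_seed(73, {
    wt <- random_dna(200)
    for (L in c(3, 21, 29)) {
      seg <- strsplit(substr(wt, 91, 90 + L), "")[[1]]
      repl <- vapply(seg, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      clone <- paste0(substr(wt, 1, 90), paste(repl, collapse = ""),
                      substr(wt, 91 + L, 200))
      a <- global_align(clone, wt)
      expect_equal(a$events$type, "M", info = paste("L =", L))
      expect_equal(a$events$length, L)
    }
  })
})

test_that("classification windows gate events by span intersection", {
  wt <- "ACGTTGCAATCGGCTAACGTTGCAATCGGCTAACGTTGCAATCGGCTA"
  clone <- paste0(substr(wt, 1, 6), substr(wt, 11, nchar(wt)))  # D:4 at 6
  a <- global_align(clone, wt)
  expect_equal(classify_clone(a, cut_sites = 8, window_radius = 5)$status,
               "mutant")
  expect_equal(classify_clone(a, cut_sites = 40, window_radius = 5)$status,
               "WT")
  # min_event_length filter
  expect_equal(classify_clone(a, cut_sites = 8, window_radius = 5,
                              min_event_length = 5)$status, "WT")
  # no events at all -> WT
  expect_equal(classify_clone(global_align(wt, wt), cut_sites = 8)$status,
               "WT")
})

test_that("a 3-bp substitution run at the cut classifies as M:3", {
  withr::with_seed(79, {
    wt <- random_dna(120)
    cut <- 60
    seg <- strsplit(substr(wt, cut, cut + 2), "")[[1]]
    repl <- vapply(seg, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    clone <- paste0(substr(wt, 1, cut - 1), paste(repl, collapse = ""),
                    substr(wt, cut + 3, 120))
    call <- classify_clone(global_align(clone, wt), cut_sites = cut)
    expect_equal(call$status, "mutant")
    expect_equal(call$events[[1]]$type, "M")
    expect_equal(call$events[[1]]$length, 3)
  })
})

test_that("alignment score is invariant under joint reverse-complement", {
  withr::with_seed(83, {
    for (i in 1:10) {
      a <- random_dna(40)
      b <- paste0(substr(a, 1, 15), substr(a, 22, 40))
      expect_equal(global_align(a, b)$score,
                   global_align(revcomp(a), revcomp(b))$score)
    }
  })
})

test_that("phenotype rate: published count pairs, bounds and scale invariance", {
  expect_equal(phenotype_rate(123, 134), 100 * 123 / 134)
  expect_equal(format_rate(phenotype_rate(123, 134)), "91.79")
  expect_equal(format_rate(phenotype_rate(22, 25)), "88")
  expect_equal(format_rate(phenotype_rate(0, 50)), "0")
  expect_equal(format_rate(phenotype_rate(7, 88)), "7.95")
  expect_equal(phenotype_rate(7, 88), phenotype_rate(70, 880))
  expect_error(phenotype_rate(1, 0), "> 0")
  expect_error(phenotype_rate(5, 3), "<=")
})

test_that("the summary table formats type ranges and pools consistently", {
  wt <- withr::with_seed(89, random_dna(300))
  sim <- simulate_editing_experiment(
    wt, cut_sites = c(100, 200), n_individuals = 4, clones_per_individual = 10,
    mutation_prob = 0.6, seed = 97,
    event_spec = tibble::tibble(type = c("D", "D", "I", "I"),
                                length = c(5, 59, 3, 19),
                                prob = c(0.3, 0.3, 0.2, 0.2)))
  calls <- call_clones(sim$clones, wt, cut_sites = c(100, 200))
  calls$experiment <- 1L
  experiments <- tibble::tibble(gene = "geneX", target_sites = "T1/T2",
                                concentration = "50/50;100",
                                n_mutant_individuals = 6, n_observed = 100,
                                experiment = 1L)
  tab <- summarize_mutagenesis(experiments, calls)
  expect_equal(tab$phenotype_display, "6")
  expect_equal(tab$n_clones, 40)
  expect_equal(tab$mutation_rate, 100 * tab$n_mutant_clones / tab$n_clones)
  expect_match(tab$type_ranges, "^D: 5–59; I: 3–19$")
  # zero-mutant experiment: rate 0, empty ranges
  wt_calls <- call_clones(sim$clones[sim$truth$status == "WT"], wt,
                          cut_sites = c(100, 200))
  wt_calls$experiment <- 2L
  ex2 <- tibble::tibble(gene = "geneX", target_sites = "T1",
                        concentration = "200;300",
                        n_mutant_individuals = 0, n_observed = 10,
                        experiment = 2L)
  tab2 <- summarize_mutagenesis(ex2, wt_calls)
  expect_equal(tab2$mutation_rate, 0)
  expect_equal(tab2$type_ranges, "")
  # pooled rate equals rate of pooled counts
  pooled <- phenotype_rate(sum(experiments$n_mutant_individuals,
                               ex2$n_mutant_individuals),
                           sum(experiments$n_observed, ex2$n_observed))
  expect_equal(pooled, 100 * (6 + 0) / 110)
})

test_that("single-length types print without a range", {
  ev <- tibble::tibble(type = c("D", "M"), length = c(12, 40),
                       ref_start = c(0, 0), ref_end = c(12, 40))
  calls <- tibble::tibble(experiment = 1L, status = c("mutant"),
                          n_events = 2L, events = list(ev))
  ex <- tibble::tibble(n_mutant_individuals = 10, n_observed = 121,
                       experiment = 1L)
  tab <- summarize_mutagenesis(ex, calls)
  expect_equal(tab$phenotype_display, "8.26")
  expect_equal(tab$type_ranges, "D: 12; M: 40")
})
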