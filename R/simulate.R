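# Synthetic-data generators. Every generator is deterministic given the seed
# it is handed (withr::with_seed, so the caller's RNG state is untouched) and
# returns its ground truth alongside the data.

#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic-data generators. Defaults encode
#' the study conditions of a three-species butterfly divergence scan: 50-kb
#' windows, a genome-wide background fixed-difference rate of 1e-3 per bp with
#' planted hotspot windows at 2e-2 per bp, expression over ten developmental
#' stages (egg, five larval instars, male/female pupa, male/female adult) with
#' planted four-fold differential-expression genes, and editing events spanning
#' the deletion/insertion/substitution length ranges observed in injected
#' clones.
#'
#' @param seed Integer RNG seed.
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Length of each scaffold (bp).
#' @param n_genes Number of genes to place across the genome.
#' @param window_length Scan window length in bp (default 50,000).
#' @param background_rate Genome-wide fixed-difference rate per bp.
#' @param hotspot_rate Fixed-difference rate per bp inside planted windows;
#'   must exceed `background_rate`.
#' @param hotspot_windows_per_pair Number of planted high-divergence windows
#'   per species pair.
#' @param hotspots_shared If `TRUE` (default) the same windows are planted for
#'   all three pairs (tri-pair hotspots); otherwise windows are drawn
#'   independently per pair.
#' @param n_stages Number of developmental stages (default 10).
#' @param de_fold_change Planted expression fold change (1 = no effect).
#' @param n_de_genes Number of planted differentially expressed genes.
#' @param rpkm_noise_cv Coefficient of variation of multiplicative RPKM noise.
#' @param edit_event_spec Data frame with columns `type` (one of `"D"`,
#'   `"I"`, `"M"`), `length` (bp) and `prob` (sampling weight) describing the
#'   editing events planted in mutant clones.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_scaffolds = 1, scaffold_length = 2e5,
#'                   n_genes = 10)
sim_config <- function(seed = 1L,
                       n_scaffolds = 2L,
                       scaffold_length = 5e5,
                       n_genes = 40L,
                       window_length = 5e4,
                       background_rate = 1e-3,
                       hotspot_rate = 2e-2,
                       hotspot_windows_per_pair = 5L,
                       hotspots_shared = TRUE,
                       n_stages = 10L,
                       de_fold_change = 4,
                       n_de_genes = 20L,
                       rpkm_noise_cv = 0.2,
                       edit_event_spec = default_event_spec()) {
  stopifnot_scalar_number(seed, "seed")
  stopifnot_scalar_number(n_scaffolds, "n_scaffolds", min = 1)
  stopifnot_scalar_number(scaffold_length, "scaffold_length", min = 1)
  stopifnot_scalar_number(n_genes, "n_genes", min = 0)
  stopifnot_scalar_number(window_length, "window_length", min = 1)
  stopifnot_scalar_number(background_rate, "background_rate", min = 0, max = 1)
  stopifnot_scalar_number(hotspot_rate, "hotspot_rate", min = 0, max = 1)
  if (hotspot_rate <= background_rate) {
    abort("`hotspot_rate` must exceed `background_rate`")
  }
  stopifnot_scalar_number(n_stages, "n_stages", min = 1)
  stopifnot_scalar_number(de_fold_change, "de_fold_change", min = 1)
  stopifnot_scalar_number(rpkm_noise_cv, "rpkm_noise_cv", min = 0)
  es <- as_tibble(edit_event_spec)
  if (!all(c("type", "length", "prob") %in% names(es)) ||
      !all(es$type %in% c("D", "I", "M")) ||
      any(es$prob < 0 | es$prob > 1)) {
    abort("`edit_event_spec` needs columns type (D/I/M), length, prob in [0,1]")
  }
  structure(list(
    seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
    scaffold_length = scaffold_length, n_genes = as.integer(n_genes),
    window_length = window_length, background_rate = background_rate,
    hotspot_rate = hotspot_rate,
    hotspot_windows_per_pair = as.integer(hotspot_windows_per_pair),
    hotspots_shared = isTRUE(hotspots_shared),
    n_stages = as.integer(n_stages), de_fold_change = de_fold_change,
    n_de_genes = as.integer(n_de_genes), rpkm_noise_cv = rpkm_noise_cv,
    edit_event_spec = es
  ), class = "sim_config")
}

#' Default editing-event spectrum
#'
#' Deletions, insertions and substitution runs with lengths spanning the
#' ranges typically recovered from injected clones (deletions 3-73 bp,
#' insertions 3-64 bp, substitution runs 3-29 bp), weighted towards deletions
#' as is usual for Cas9 repair outcomes.
#'
#' @return Tibble with columns `type`, `length`, `prob`.
#' @export
default_event_spec <- function() {
  tibble(
    type   = c(rep("D", 5), rep("I", 3), rep("M", 2)),
    length = c(3, 12, 25, 50, 73, 3, 19, 64, 3, 29),
    prob   = c(rep(0.12, 5), rep(0.1, 3), rep(0.05, 2))
  )
}

#' Simulate a multi-scaffold reference genome with exonic gene models
#'
#' Scaffolds are uniform-random A/C/G/T. Genes are placed without overlap on
#' either strand, each with 1-5 exons partitioning part of the gene span.
#' Coordinates are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return List with elements `genome` (named character vector of scaffold
#'   sequences), `genes` (tibble: `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`) and `exons` (tibble: `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `exon_rank`).
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(seed = 1, n_scaffolds = 1,
#'                                      scaffold_length = 5e4, n_genes = 3))
#' ref$genes
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    scafs <- sprintf("scaf%02d", seq_len(config$n_scaffolds))
    genome <- setNames(
      vapply(scafs, function(s) random_dna(config$scaffold_length),
             character(1)),
      scafs
    )
    if (config$n_genes == 0) {
      return(list(
        genome = genome,
        genes = tibble(gene_id = character(), scaffold = character(),
                       start = numeric(), end = numeric(),
                       strand = character()),
        exons = tibble(gene_id = character(), scaffold = character(),
                       start = numeric(), end = numeric(),
                       strand = character(), exon_rank = integer())
      ))
    }
    # spread genes across scaffolds as evenly as possible
    per_scaf <- diff(round(seq(0, config$n_genes,
                               length.out = config$n_scaffolds + 1)))
    genes <- list()
    exons <- list()
    gid <- 0L
    for (i in seq_along(scafs)) {
      k <- per_scaf[i]
      if (k == 0) next
      # gene sizes scale down with density so moderately gene-dense
      # scaffolds remain feasible
      l_max <- max(50, min(5000, floor(0.6 * config$scaffold_length / k)))
      l_min <- max(20, min(500, floor(l_max / 2)))
      lens <- sample(seq(l_min, l_max), k, replace = TRUE)
      free <- config$scaffold_length - sum(lens)
      if (free < k) {
        abort(sprintf(
          "cannot place %d genes on scaffold %s: %d bp of gene models exceed scaffold space",
          k, scafs[i], sum(lens)))
      }
      # random partition of the free space into k+1 gaps
      cuts <- sort(sample.int(free, k))
      gaps <- diff(c(0, cuts))
      starts <- cumsum(gaps) + cumsum(c(0, lens[-k]))
      ends <- starts + lens
      strand <- sample(c("+", "-"), k, replace = TRUE)
      ids <- sprintf("gene%04d", gid + seq_len(k))
      gid <- gid + k
      genes[[i]] <- tibble(gene_id = ids, scaffold = scafs[i],
                           start = starts, end = ends, strand = strand)
      exons[[i]] <- pmap(list(ids, starts, ends, strand), function(id, s, e, st) {
        n_ex <- sample.int(5, 1)
        if (n_ex == 1) {
          bounds <- c(s, e)
        } else {
          inner <- sort(sample(seq(s + 1, e - 1), 2 * (n_ex - 1)))
          bounds <- c(s, inner, e)
        }
        idx <- seq(1, length(bounds) - 1, by = 2)
        tibble(gene_id = id, scaffold = scafs[i],
               start = bounds[idx], end = bounds[idx + 1],
               strand = st, exon_rank = seq_along(idx))
      }) |> list_rbind()
    }
    list(genome = genome,
         genes = list_rbind(genes),
         exons = list_rbind(exons))
  })
}

# taxon / pair naming shared by the divergence simulator and the scan wrapper
SIM_TAXA <- c("taxonA", "taxonB", "taxonC")
SIM_PAIRS <- c("taxonA_taxonB", "taxonA_taxonC", "taxonB_taxonC")
pair_members <- function(pair) strsplit(pair, "_", fixed = TRUE)[[1]]

#' Simulate per-taxon variant tables with planted divergence hotspots
#'
#' For each of the three pairwise comparisons, fixed-difference sites are
#' drawn per window: at `background_rate` per bp genome-wide and at
#' `hotspot_rate` per bp inside the windows planted for that pair. Each drawn
#' site becomes a homozygous biallelic substitution in one taxon of the pair
#' (the other taxon stays reference there); the third taxon receives a
#' heterozygous record at the site, so the site is excluded from the other two
#' comparisons by the fixed-difference rule and realized per-pair densities
#' match the drawn rates exactly.
#'
#' @param genome Named character vector / `DNAStringSet` of scaffolds, or a
#'   named numeric vector of scaffold lengths (reference bases are then drawn
#'   at random, which is sufficient when only densities matter).
#' @param config A [sim_config()].
#' @return List with `variants` (named list of per-taxon tibbles: `scaffold`,
#'   `pos` 0-based, `ref`, `alt`, `genotype`), and `truth` with
#'   `planted_regions` (tibble: `scaffold`, `start`, `end`, `pair`) and
#'   `sites` (tibble of every drawn fixed-difference site: `pair`, `scaffold`,
#'   `pos`, `carrier`).
#' @export
simulate_divergence <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.numeric(genome)) {
    lens <- genome
    seqs <- NULL
  } else {
    seqs <- as_genome(genome)
    lens <- scaffold_lengths(seqs)
  }
  if (length(lens) == 0) abort("`genome` is empty")
  withr::with_seed(config$seed + 1L, {
    # segment the genome: scan windows plus terminal remainders, so the whole
    # genome carries background signal
    segs <- tile_windows(lens, window_length = config$window_length,
                         min_window_fraction = 0)
    segs$window_id <- seq_len(nrow(segs))
    # plant hotspots in full-length windows only, so truth regions coincide
    # with scan windows
    full_ids <- segs$window_id[segs$end - segs$start == config$window_length]
    if (length(full_ids) == 0) full_ids <- segs$window_id
    n_hot <- min(config$hotspot_windows_per_pair, length(full_ids))
    shared_hot <- sample(full_ids, n_hot)
    hot_ids <- map(setNames(SIM_PAIRS, SIM_PAIRS), function(pair) {
      if (config$hotspots_shared) shared_hot else sample(full_ids, n_hot)
    })
    # draw per-pair counts window by window, then place all three pairs'
    # sites jointly without replacement: no two drawn sites share a position,
    # so every drawn site is realized as a fixed difference for its pair
    sites <- map(seq_len(nrow(segs)), function(i) {
      len <- segs$end[i] - segs$start[i]
      counts <- vapply(SIM_PAIRS, function(pair) {
        rate <- if (segs$window_id[i] %in% hot_ids[[pair]])
          config$hotspot_rate else config$background_rate
        rbinom(1, size = len, prob = rate)
      }, integer(1))
      total <- sum(counts)
      if (total == 0) return(NULL)
      if (total > len) {                       # degenerate, extreme rates
        counts <- pmin(counts, diff(floor(seq(0, len, length.out = 4))))
        total <- sum(counts)
      }
      pos <- segs$start[i] + sample.int(len, total) - 1
      tibble(pair = rep(SIM_PAIRS, counts),
             scaffold = segs$scaffold[i],
             pos = pos)
    }) |> list_rbind()
    if (is.null(sites) || nrow(sites) == 0) {
      sites <- tibble(pair = character(), scaffold = character(),
                      pos = numeric())
    }
    planted <- list_rbind(map(SIM_PAIRS, function(pair) {
      segs |>
        filter(.data$window_id %in% hot_ids[[pair]]) |>
        mutate(pair = pair) |>
        select("scaffold", "start", "end", "pair")
    }))
    all_sites <- sites |> arrange(.data$pair, .data$scaffold, .data$pos)
    # allele assignment
    if (is.null(seqs)) {
      ref <- sample(DNA_BASES, nrow(all_sites), replace = TRUE)
    } else {
      ref <- map2_chr_fast(all_sites$scaffold, all_sites$pos, seqs)
    }
    alt <- random_alt_base(ref)
    carrier_idx <- sample.int(2, nrow(all_sites), replace = TRUE)
    members <- strsplit(all_sites$pair, "_", fixed = TRUE)
    carrier <- map2_chr(members, carrier_idx, function(m, i) m[i])
    third <- map_chr(members, function(m) setdiff(SIM_TAXA, m))
    all_sites$carrier <- carrier
    variants <- map(setNames(SIM_TAXA, SIM_TAXA), function(tx) {
      hom <- tibble(scaffold = all_sites$scaffold, pos = all_sites$pos,
                    ref = ref, alt = alt, genotype = "1/1")[carrier == tx, ]
      het <- tibble(scaffold = all_sites$scaffold, pos = all_sites$pos,
                    ref = ref, alt = alt, genotype = "0/1")[third == tx, ]
      bind_rows(hom, het) |>
        arrange(.data$scaffold, .data$pos, .data$genotype) |>
        distinct(.data$scaffold, .data$pos, .keep_all = TRUE)
    })
    list(
      variants = variants,
      truth = list(
        planted_regions = planted,
        sites = all_sites |> select("pair", "scaffold", "pos", "carrier")
      )
    )
  })
}

map2_chr <- function(x, y, f) mapply(f, x, y, USE.NAMES = FALSE)

# fast base lookup: substr per scaffold group
map2_chr_fast <- function(scaffold, pos, seqs) {
  out <- character(length(pos))
  for (s in unique(scaffold)) {
    i <- which(scaffold == s)
    out[i] <- strsplit(seqs[[s]], "")[[1]][pos[i] + 1]
  }
  out
}

#' Simulate stage-structured RPKM matrices for two species
#'
#' Baseline expression is log-normal (meanlog log(50), sdlog 1, i.e. a
#' right-skewed abundance distribution with a typical gene around 50 RPKM).
#' Planted differentially expressed genes are drawn among clearly expressed
#' genes (baseline >= 20 RPKM) and one species -- chosen at random per gene --
#' is elevated by `de_fold_change` over the shared baseline, identically at
#' every stage; all genes carry multiplicative log-normal noise with
#' coefficient of variation `rpkm_noise_cv` independently per species, gene
#' and stage.
#'
#' @param annotation Gene tibble with a `gene_id` column (e.g.
#'   `simulate_reference(...)$genes`).
#' @param config A [sim_config()].
#' @return List with `rpkm_a`, `rpkm_b` (tibbles: `gene_id` + one column per
#'   stage), `orthologs` (tibble `gene_a`, `gene_b`) and `truth` with the
#'   planted DE gene ids (A-side) and directions.
#' @export
simulate_expression <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- as_tibble(annotation)
  if (nrow(genes) < 1) abort("need at least one gene")
  if (config$n_stages < 1) abort("`n_stages` must be >= 1")
  withr::with_seed(config$seed + 2L, {
    ids_a <- genes$gene_id
    ids_b <- sub("^gene", "geneB", ids_a)
    if (identical(ids_b, ids_a)) ids_b <- paste0(ids_a, "_B")
    n <- length(ids_a)
    stages <- paste0("stage", sprintf("%02d", seq_len(config$n_stages)))
    base <- rlnorm(n, meanlog = log(50), sdlog = 1)
    n_de <- if (config$de_fold_change == 1) 0L else
      min(config$n_de_genes, n)
    # plant DE among clearly expressed genes (baseline >= 20 RPKM): a
    # fold change on a gene near the pseudocount floor is not a resolvable
    # all-stage signal, and the candidates this emulates are robustly
    # expressed developmental genes
    de_idx <- integer()
    if (n_de > 0) {
      eligible <- which(base >= 20)
      if (length(eligible) < n_de) {
        eligible <- order(base, decreasing = TRUE)[seq_len(min(n, n_de))]
      }
      de_idx <- sort(sample(eligible, n_de))
    }
    direction <- setNames(rep(1, n), ids_a)
    if (n_de > 0) {
      direction[de_idx] <- sample(c(1, -1), n_de, replace = TRUE)
    }
    # the shifted species is elevated by the fold change over the shared
    # baseline (direction +1: species A higher; -1: species B higher)
    fold_a <- rep(1, n); fold_b <- rep(1, n)
    fold_a[de_idx][direction[de_idx] == 1] <- config$de_fold_change
    fold_b[de_idx][direction[de_idx] == -1] <- config$de_fold_change
    sdlog <- sqrt(log(1 + config$rpkm_noise_cv^2))
    noise <- function() {
      matrix(rlnorm(n * config$n_stages, meanlog = -sdlog^2 / 2, sdlog = sdlog),
             nrow = n)
    }
    mat_a <- base * fold_a * noise()
    mat_b <- base * fold_b * noise()
    colnames(mat_a) <- colnames(mat_b) <- stages
    list(
      rpkm_a = bind_cols(tibble(gene_id = ids_a), as_tibble(mat_a)),
      rpkm_b = bind_cols(tibble(gene_id = ids_b), as_tibble(mat_b)),
      orthologs = tibble(gene_a = ids_a, gene_b = ids_b),
      truth = list(
        de_genes = ids_a[de_idx],
        direction = direction[de_idx]
      )
    )
  })
}

#' Simulate a CRISPR editing experiment: clones, counts and truth
#'
#' Each sequenced clone is a wild-type copy of the amplicon or carries exactly
#' one planted event at a randomly chosen cut site: a deletion of L bp
#' centred on the cut, an insertion of L random bp at the cut, or a
#' substitution run of L bp (every base changed) centred on the cut.
#' Injected-individual phenotype counts are drawn binomially.
#'
#' @param amplicon Wild-type amplicon sequence (single string).
#' @param cut_sites Integer vector of expected cut positions (0-based,
#'   reference coordinates).
#' @param n_individuals Number of injected individuals observed.
#' @param clones_per_individual Sequenced TA clones per individual.
#' @param phenotype_prob Probability an injected individual shows the mutant
#'   phenotype.
#' @param mutation_prob Probability a sequenced clone carries an event.
#' @param event_spec Event spectrum tibble (`type`, `length`, `prob`); see
#'   [default_event_spec()].
#' @param seed Integer RNG seed.
#' @return List with `clones` (named character vector), `counts` (tibble:
#'   `n_mutant_individuals`, `n_observed`) and `truth` (tibble: `clone_id`,
#'   `status`, `type`, `length`, `position`).
#' @export
simulate_editing_experiment <- function(amplicon, cut_sites,
                                        n_individuals = 25,
                                        clones_per_individual = 12,
                                        phenotype_prob = 0.88,
                                        mutation_prob = 0.3,
                                        event_spec = default_event_spec(),
                                        seed = 1L) {
  amplicon <- toupper(amplicon)
  len <- nchar(amplicon)
  if (len == 0) abort("`amplicon` must be non-empty")
  if (any(cut_sites < 0 | cut_sites >= len)) {
    abort("`cut_sites` must lie within the amplicon")
  }
  es <- as_tibble(event_spec)
  if (any(es$length >= len)) {
    abort("event length must be smaller than the amplicon length")
  }
  withr::with_seed(seed, {
    n_clones <- n_individuals * clones_per_individual
    clone_ids <- sprintf("clone%04d", seq_len(n_clones))
    is_mut <- runif(n_clones) < mutation_prob
    truth <- tibble(clone_id = clone_ids,
                    status = if_else(is_mut, "mutant", "WT"),
                    type = NA_character_, length = NA_real_,
                    position = NA_real_)
    clones <- setNames(rep(amplicon, n_clones), clone_ids)
    for (i in which(is_mut)) {
      row <- es[sample.int(nrow(es), 1, prob = es$prob), ]
      cut <- sample(cut_sites, 1)
      L <- row$length
      if (row$type == "D") {
        start <- max(0, min(cut - floor(L / 2), len - L))
        clones[i] <- paste0(seq_window(amplicon, 0, start),
                            seq_window(amplicon, start + L, len))
      } else if (row$type == "I") {
        start <- cut
        ins <- random_dna(L)
        clones[i] <- paste0(seq_window(amplicon, 0, start), ins,
                            seq_window(amplicon, start, len))
      } else {
        start <- max(0, min(cut - floor(L / 2), len - L))
        seg <- strsplit(seq_window(amplicon, start, start + L), "")[[1]]
        clones[i] <- paste0(seq_window(amplicon, 0, start),
                            paste(random_alt_base(seg), collapse = ""),
                            seq_window(amplicon, start + L, len))
      }
      truth$type[i] <- row$type
      truth$length[i] <- L
      truth$position[i] <- start
    }
    counts <- tibble(
      n_mutant_individuals = rbinom(1, n_individuals, phenotype_prob),
      n_observed = n_individuals
    )
    list(clones = clones, counts = counts, truth = truth)
  })
}
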