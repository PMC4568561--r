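# End-to-end wrappers: discovery (divergence scan + evidence integration),
# design (sgRNA enumeration + filters + off-target audit), and fixture
# writing. Every stage logs a funnel count so the number of windows, genes
# and sites surviving each rule is visible.

#' Run the discovery workflow: divergence scan plus evidence integration
#'
#' Calls fixed differences for the three pairwise comparisons, runs the
#' windowed scan with per-pair smoothed-quantile cutoffs, maps divergent
#' regions to genes, flags all-stage differential expression between the
#' ortholog pairs, and integrates the three evidence layers into ranked
#' candidates.
#'
#' @param variants Named list of three per-taxon variant tibbles (see
#'   [call_fixed_differences()]); pairs are formed from the names in sorted
#'   order.
#' @param scaffold_lengths Named numeric vector of reference scaffold
#'   lengths.
#' @param genes Gene tibble (`gene_id`, `scaffold`, `start`, `end`).
#' @param rpkm_a,rpkm_b,orthologs Expression inputs for
#'   [de_across_all_stages()]; all three may be `NULL` to skip the DE layer.
#' @param positively_selected Character vector of positively selected gene
#'   ids (may be empty).
#' @param window_length,quantile,bandwidth,min_window_fraction,strict Scan
#'   parameters, see [divergence_scan()].
#' @param min_fold_change,pseudocount DE parameters, see
#'   [de_across_all_stages()].
#' @param out_dir Optional output directory; when given, writes
#'   `windows.tsv`, `regions.bed`, `candidates.tsv` and `manifest.json`.
#' @return List of class `discovery_result`: `scan` (a `div_scan`),
#'   `divergent_genes`, `de_genes`, `candidates` (a `candidate_set`), and
#'   `manifest` (parameters plus the funnel counts).
#' @export
run_discovery <- function(variants, scaffold_lengths, genes,
                          rpkm_a = NULL, rpkm_b = NULL, orthologs = NULL,
                          positively_selected = character(),
                          window_length = 5e4, quantile = 0.95,
                          bandwidth = "auto", min_window_fraction = 0.5,
                          strict = TRUE, min_fold_change = 2,
                          pseudocount = 1, out_dir = NULL) {
  if (length(variants) != 3 || is.null(names(variants))) {
    abort("`variants` must be a named list of three per-taxon tables")
  }
  if (!is.null(rpkm_a) && (is.null(rpkm_b) || is.null(orthologs))) {
    abort("`rpkm_b` and `orthologs` are required with `rpkm_a`")
  }
  taxa <- sort(names(variants))
  pair_defs <- utils::combn(taxa, 2, simplify = FALSE)
  diffs <- map(pair_defs, function(p) {
    call_fixed_differences(variants[[p[1]]], variants[[p[2]]],
                           scaffold_lengths,
                           pair_label = paste(p, collapse = "_"))
  }) |> list_rbind()
  scan <- divergence_scan(diffs, scaffold_lengths,
                          window_length = window_length, quantile = quantile,
                          bandwidth = bandwidth,
                          min_window_fraction = min_window_fraction,
                          strict = strict)
  div_genes <- genes_in_regions(scan$regions, genes)
  de <- character()
  if (!is.null(rpkm_a)) {
    de <- de_across_all_stages(rpkm_a, rpkm_b, orthologs,
                               min_fold_change = min_fold_change,
                               pseudocount = pseudocount)
  }
  candidates <- integrate_candidates(div_genes,
                                     positively_selected = positively_selected,
                                     de_genes = de)
  manifest <- list(
    package_version = as.character(utils::packageVersion("divedit")),
    parameters = list(window_length = window_length, quantile = quantile,
                      bandwidth = bandwidth,
                      min_window_fraction = min_window_fraction,
                      strict = strict, min_fold_change = min_fold_change,
                      pseudocount = pseudocount),
    funnel = list(
      n_diff_sites = nrow(diffs),
      n_windows = nrow(scan$windows) / length(scan$cutoffs),
      n_outlier_windows_per_pair = scan$windows |>
        group_by(.data$pair) |>
        summarise(n = sum(.data$outlier), .groups = "drop") |>
        tibble::deframe() |> as.list(),
      n_regions = nrow(scan$regions),
      n_divergent_genes = nrow(div_genes),
      n_de_genes = length(de),
      n_strong_candidates = sum(candidates$strong)
    )
  )
  res <- structure(list(scan = scan, divergent_genes = div_genes,
                        de_genes = de, candidates = candidates,
                        manifest = manifest),
                   class = "discovery_result")
  if (!is.null(out_dir)) write_discovery(res, out_dir)
  res
}

#' @export
print.discovery_result <- function(x, ...) {
  f <- x$manifest$funnel
  cat("<discovery_result>\n")
  cat(sprintf("  %d fixed differences -> %d windows -> %d regions -> %d genes -> %d strong candidate(s)\n",
              f$n_diff_sites, f$n_windows, f$n_regions, f$n_divergent_genes,
              f$n_strong_candidates))
  invisible(x)
}

write_discovery <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$scan$windows |> select(-dplyr::any_of("window_id")),
                   file.path(out_dir, "windows.tsv"))
  regions <- res$scan$regions
  if (nrow(regions) > 0) {
    regions$name <- sprintf("region%03d", seq_len(nrow(regions)))
  }
  write_bed(regions[, c("scaffold", "start", "end",
                        if (nrow(regions) > 0) "name")],
            file.path(out_dir, "regions.bed"))
  cand <- as_tibble(res$candidates)
  cand$region_ids <- NULL
  readr::write_tsv(cand, file.path(out_dir, "candidates.tsv"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the design workflow for one gene
#'
#' Enumerates candidate sgRNA sites on the gene's exons, applies the 5'
#' dinucleotide filter and the genome-wide seed-uniqueness filter, builds
#' forward synthesis oligos for the surviving sites, and reports candidate
#' off-target sites for each surviving protospacer.
#'
#' @param genome Named character vector / `DNAStringSet`.
#' @param exons Exon tibble with `gene_id`.
#' @param gene_id Gene to design against.
#' @param five_prime Allowed 5' dinucleotides (see [filter_five_prime()]).
#' @param max_mismatches,allowed_pams Off-target settings (see
#'   [find_offtargets()]).
#' @param out_dir Optional output directory; writes `sites.tsv`,
#'   `oligos.fasta`, `offtargets.tsv`.
#' @return List: `sites` (all enumerated sites with filter flags), `oligos`
#'   (tibble `site_id`, `forward`, `reverse` for seed-unique, 5'-passing
#'   sites), `offtargets` (hit tibble with `site_id`).
#' @export
run_design <- function(genome, exons, gene_id,
                       five_prime = c("GG", "GA", "AG"),
                       max_mismatches = 5, allowed_pams = c("NGG", "NAG"),
                       out_dir = NULL) {
  exons <- as_tibble(exons)
  gx <- exons |> filter(.data$gene_id == !!gene_id)
  if (nrow(gx) == 0) abort(paste0("gene not found in annotation: ", gene_id))
  sites <- enumerate_targets(genome, gx)
  if (nrow(sites) > 0) {
    sites <- sites |>
      mutate(five_prime_ok = .data$five_prime_class %in% five_prime) |>
      seed_uniqueness(genome) |>
      mutate(site_id = sprintf("%s_site%02d", gene_id, row_number()))
  } else {
    sites$five_prime_ok <- logical()
    sites$seed_unique <- logical()
    sites$site_id <- character()
  }
  chosen <- sites |> filter(.data$five_prime_ok, .data$seed_unique)
  if (nrow(chosen) == 0) {
    warn(paste0("no designable site for gene ", gene_id,
                " (after 5' and seed-uniqueness filters)"))
  }
  oligos <- tibble(site_id = chosen$site_id,
                   protospacer = chosen$protospacer,
                   forward = if (nrow(chosen) > 0)
                     forward_oligo(chosen$protospacer) else character(),
                   reverse = rep(sgrna_reverse_oligo(), nrow(chosen)))
  offt <- map(seq_len(nrow(chosen)), function(i) {
    h <- find_offtargets(chosen$protospacer[i], genome,
                         max_mismatches = max_mismatches,
                         allowed_pams = allowed_pams,
                         exclude = chosen[i, c("scaffold", "start", "strand")])
    if (nrow(h) > 0) h$site_id <- chosen$site_id[i]
    h
  }) |> list_rbind()
  if (is.null(offt)) offt <- finalize_hits(NULL, NULL)
  res <- list(sites = sites, oligos = oligos, offtargets = offt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(sites, file.path(out_dir, "sites.tsv"))
    if (nrow(oligos) > 0) {
      write_fasta(setNames(oligos$forward, oligos$site_id),
                  file.path(out_dir, "oligos.fasta"))
    }
    flat <- offt
    if (nrow(flat) > 0) {
      flat$mismatch_positions <- map_chr(flat$mismatch_positions,
                                         paste, collapse = ",")
    }
    readr::write_tsv(flat, file.path(out_dir, "offtargets.tsv"))
  }
  res
}

#' Write a complete synthetic fixture directory
#'
#' Generates a reference genome with annotation, three-taxon variant tables
#' with planted divergence hotspots, two-species stage RPKM matrices with
#' planted DE genes, a positively-selected gene list drawn from the planted
#' truth, and writes everything in standard formats (FASTA, GFF3, TSV)
#' together with the ground-truth tables.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @return Invisibly, the list of generated objects.
#' @export
write_fixture <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  div <- simulate_divergence(ref$genome, config)
  expr <- simulate_expression(ref$genes, config)
  write_fasta(ref$genome, file.path(dir, "genome.fasta"))
  write_gff3(ref[c("genes", "exons")], file.path(dir, "annotation.gff3"))
  for (tx in names(div$variants)) {
    write_variants_tsv(div$variants[[tx]],
                       file.path(dir, paste0("variants_", tx, ".tsv")))
  }
  write_rpkm(expr$rpkm_a, file.path(dir, "rpkm_a.tsv"))
  write_rpkm(expr$rpkm_b, file.path(dir, "rpkm_b.tsv"))
  readr::write_tsv(expr$orthologs, file.path(dir, "orthologs.tsv"))
  readr::write_tsv(div$truth$planted_regions,
                   file.path(dir, "truth_planted_regions.tsv"))
  readr::write_tsv(tibble(gene_id = expr$truth$de_genes),
                   file.path(dir, "truth_de_genes.tsv"))
  invisible(list(reference = ref, divergence = div, expression = expr))
}
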