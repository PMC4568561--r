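# Evidence integration: divergent regions -> genes, all-stage differential
# expression between orthologs, and the three-flag candidate table.

#' Genes overlapping divergent regions
#'
#' A gene is included iff its genomic span (gene start to gene end, i.e.
#' min exon start to max exon end) overlaps any region by at least 1 bp.
#' Span overlap, rather than exon-only overlap, deliberately captures
#' regulatory-adjacent signal such as divergence confined to a UTR window.
#'
#' @param regions Tibble with `scaffold`, `start`, `end` (0-based half-open),
#'   e.g. `divergence_scan(...)$regions`.
#' @param genes Gene tibble with `gene_id`, `scaffold`, `start`, `end`.
#' @return Tibble `gene_id`, `region_ids` (list column of overlapping region
#'   row indices); one row per overlapping gene, sorted by `gene_id`.
#' @export
genes_in_regions <- function(regions, genes) {
  regions <- as_tibble(regions)
  genes <- as_tibble(genes)
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character(), region_ids = list()))
  }
  gr_regions <- GenomicRanges::GRanges(
    regions$scaffold, IRanges::IRanges(regions$start + 1, regions$end))
  gr_genes <- GenomicRanges::GRanges(
    genes$scaffold, IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_regions)
  if (length(hits) == 0) {
    return(tibble(gene_id = character(), region_ids = list()))
  }
  tibble(gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
         region = S4Vectors::subjectHits(hits)) |>
    group_by(.data$gene_id) |>
    summarise(region_ids = list(sort(unique(.data$region))),
              .groups = "drop") |>
    arrange(.data$gene_id)
}

#' All-stage differential expression between ortholog pairs
#'
#' Flags a gene iff the absolute log2 ratio of pseudocounted RPKM between the
#' two species is at least `log2(min_fold_change)` at every matched stage,
#' and (by default) the ratio has the same sign at every stage. This
#' fold-change rule is used because replicate-free per-stage RPKM matrices do
#' not support count-based tests.
#'
#' @param rpkm_a,rpkm_b Expression tibbles: `gene_id` column plus one
#'   non-negative RPKM column per stage; stage columns must match 1:1 between
#'   the two species (same names, same order).
#' @param orthologs Tibble `gene_a`, `gene_b` mapping ids of `rpkm_a` to ids
#'   of `rpkm_b`.
#' @param min_fold_change Minimum per-stage fold change (default 2).
#' @param pseudocount RPKM pseudocount added to both species (default 1).
#' @param require_consistent_direction Require the same sign at every stage
#'   (default `TRUE`).
#' @return Character vector of flagged A-side gene ids.
#' @export
de_across_all_stages <- function(rpkm_a, rpkm_b, orthologs,
                                 min_fold_change = 2, pseudocount = 1,
                                 require_consistent_direction = TRUE) {
  stopifnot_scalar_number(min_fold_change, "min_fold_change", min = 1)
  stopifnot_scalar_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) abort("`pseudocount` must be > 0")
  rpkm_a <- as_tibble(rpkm_a)
  rpkm_b <- as_tibble(rpkm_b)
  orthologs <- as_tibble(orthologs)
  stages_a <- setdiff(names(rpkm_a), "gene_id")
  stages_b <- setdiff(names(rpkm_b), "gene_id")
  if (!identical(stages_a, stages_b)) {
    abort("stage columns of the two matrices must match 1:1")
  }
  missing_a <- setdiff(orthologs$gene_a, rpkm_a$gene_id)
  missing_b <- setdiff(orthologs$gene_b, rpkm_b$gene_id)
  if (length(missing_a) + length(missing_b) > 0) {
    abort(paste0("ortholog pairs reference missing genes: ",
                 paste(c(missing_a, missing_b), collapse = ", ")))
  }
  ma <- as.matrix(rpkm_a[match(orthologs$gene_a, rpkm_a$gene_id), stages_a])
  mb <- as.matrix(rpkm_b[match(orthologs$gene_b, rpkm_b$gene_id), stages_a])
  if (any(ma < 0) || any(mb < 0)) abort("RPKM values must be non-negative")
  lr <- log2((ma + pseudocount) / (mb + pseudocount))
  thr <- log2(min_fold_change)
  pass_mag <- rowSums(abs(lr) >= thr) == ncol(lr)
  if (require_consistent_direction) {
    consistent <- rowSums(lr > 0) == ncol(lr) | rowSums(lr < 0) == ncol(lr)
    pass_mag <- pass_mag & consistent
  }
  sort(unique(orthologs$gene_a[pass_mag]))
}

#' Integrate divergence, positive selection and differential expression
#'
#' Every divergent gene is emitted with three evidence flags. A *strong
#' candidate* is a divergent gene that is also positively selected or
#' differentially expressed across all stages (OR logic; the flags are
#' exposed so the stricter AND can be audited).
#'
#' @param divergent_genes Character vector of divergent gene ids, or the
#'   tibble returned by [genes_in_regions()] (its `region_ids` are carried
#'   through).
#' @param positively_selected Character vector of positively selected gene
#'   ids.
#' @param de_genes Character vector of all-stage DE gene ids.
#' @return A tibble of class `candidate_set`: `gene_id`, logical flags
#'   `divergent`, `positively_selected`, `de_all_stages`, `evidence_count`,
#'   `strong`, optional `region_ids`; ranked by `evidence_count` (desc) then
#'   id. [glance()] gives the per-flag-combination counts.
#' @export
#' @examples
#' integrate_candidates(c("g1", "g2"), positively_selected = "g2",
#'                      de_genes = c("g2", "g3"))
integrate_candidates <- function(divergent_genes, positively_selected = character(),
                                 de_genes = character()) {
  region_ids <- NULL
  if (is.data.frame(divergent_genes)) {
    region_ids <- divergent_genes
    divergent_genes <- divergent_genes$gene_id
  }
  out <- tibble(
    gene_id = sort(unique(divergent_genes)),
    divergent = TRUE
  ) |>
    mutate(
      positively_selected = .data$gene_id %in% positively_selected,
      de_all_stages = .data$gene_id %in% de_genes,
      evidence_count = 1L + as.integer(.data$positively_selected) +
        as.integer(.data$de_all_stages),
      strong = .data$divergent &
        (.data$positively_selected | .data$de_all_stages)
    ) |>
    arrange(dplyr::desc(.data$evidence_count), .data$gene_id)
  if (!is.null(region_ids) && "region_ids" %in% names(region_ids)) {
    out <- left_join(out, region_ids, by = "gene_id")
  }
  class(out) <- c("candidate_set", class(out))
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d divergent gene(s), %d strong candidate(s)\n",
              nrow(x), sum(x$strong)))
  NextMethod()
}
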