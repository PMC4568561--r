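# Readers/writers for the standard formats. Internal coordinates are
# 0-based half-open everywhere; GFF3 and VCF (1-based) are converted here at
# the boundary. FASTA goes through Biostrings, GFF3/BED through rtracklayer,
# VCF through vcfR, plain tables through readr.

#' Read / write FASTA
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  as_genome(Biostrings::readDNAStringSet(path))
}

#' @param seqs Named character vector (or `DNAStringSet`).
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_genome(seqs)), path)
  invisible(path)
}

#' Read / write gene annotation as GFF3
#'
#' GFF3 is 1-based closed; returned tibbles are 0-based half-open. Gene
#' features carry `ID=<gene_id>`, exon features `Parent=<gene_id>`.
#'
#' @param path File path.
#' @return `read_gff3()`: list with `genes` and `exons` tibbles (columns as
#'   in [simulate_reference()]).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$scaffold <- as.character(df$seqnames)
  df$start0 <- df$start - 1
  genes <- df |>
    filter(.data$type == "gene") |>
    mutate(gene_id = as.character(.data$ID)) |>
    select("gene_id", "scaffold", start = "start0", "end",
           strand = "strand") |>
    mutate(strand = as.character(.data$strand))
  exons <- df |>
    filter(.data$type == "exon") |>
    mutate(gene_id = map_chr(.data$Parent, function(p) as.character(p)[1])) |>
    group_by(.data$gene_id) |>
    mutate(exon_rank = row_number()) |>
    ungroup() |>
    select("gene_id", "scaffold", start = "start0", "end",
           strand = "strand", "exon_rank") |>
    mutate(strand = as.character(.data$strand))
  list(genes = genes, exons = exons)
}

#' @param annotation List with `genes` and `exons` tibbles.
#' @rdname read_gff3
#' @export
write_gff3 <- function(annotation, path) {
  genes <- as_tibble(annotation$genes)
  exons <- as_tibble(annotation$exons)
  gr_genes <- GenomicRanges::GRanges(
    genes$scaffold, IRanges::IRanges(genes$start + 1, genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  gr_exons <- GenomicRanges::GRanges(
    exons$scaffold, IRanges::IRanges(exons$start + 1, exons$end),
    strand = exons$strand, type = "exon",
    Parent = as.character(exons$gene_id))
  rtracklayer::export(c(gr_genes, gr_exons), path, format = "gff3")
  invisible(path)
}

#' Read / write region BED files
#'
#' BED is natively 0-based half-open, matching internal coordinates.
#'
#' @param path File path.
#' @return `read_bed()`: tibble with `scaffold`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = "bed")
  tibble(scaffold = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1,
         end = GenomicRanges::end(gr),
         name = if (!is.null(gr$name)) gr$name else NA_character_)
}

#' @param regions Tibble with `scaffold`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  regions <- as_tibble(regions)
  gr <- GenomicRanges::GRanges(
    regions$scaffold, IRanges::IRanges(regions$start + 1, regions$end))
  gr$name <- if ("name" %in% names(regions)) regions$name else
    sprintf("region%03d", seq_len(nrow(regions)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a per-taxon variant table (TSV or VCF)
#'
#' TSV input needs columns `scaffold`, `pos` (0-based), `ref`, `alt`,
#' `genotype`. VCF (v4.x, single sample) positions are converted from
#' 1-based; the first sample's `GT` field is used.
#'
#' @param path Path to a `.tsv` or `.vcf`/`.vcf.gz` file.
#' @return Variant tibble (`scaffold`, `pos`, `ref`, `alt`, `genotype`).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- as_tibble(as.data.frame(vcfR::getFIX(v),
                                   stringsAsFactors = FALSE))
    tibble(scaffold = fix$CHROM,
           pos = as.numeric(fix$POS) - 1,
           ref = fix$REF, alt = fix$ALT,
           genotype = unname(gt[, 1]))
  } else {
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      scaffold = "c", pos = "d", ref = "c", alt = "c",
                      genotype = "c"))
  }
}

#' Write a variant table as TSV
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(as_tibble(variants), path)
  invisible(path)
}

#' Read / write an RPKM matrix
#'
#' @param path File path (TSV with a `gene_id` column plus stage columns).
#' @return Tibble.
#' @export
read_rpkm <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @param rpkm RPKM tibble.
#' @rdname read_rpkm
#' @export
write_rpkm <- function(rpkm, path) {
  readr::write_tsv(as_tibble(rpkm), path)
  invisible(path)
}

#' Published mutagenesis-efficiency counts
#'
#' The injected-individual accounting of the three knockout genes
#' (*Abdominal-B*, *ebony*, *frizzled*) as published: per experiment the
#' sgRNA target sites, injected sgRNA;Cas9 concentrations (ng/ul), the
#' mutant and observed injected-individual counts behind the printed
#' phenotype rates, the printed phenotype and mutation rates, and the
#' printed mutation-type ranges. The *frizzled* row's printed phenotype rate
#' (4.12) is inconsistent with its own counts (4/96 = 4.17); the
#' `printed_rate_consistent` flag records this.
#'
#' @return Tibble, one row per experiment.
#' @export
#' @examples
#' mutagenesis_counts()
mutagenesis_counts <- function() {
  path <- system.file("extdata", "mutagenesis_counts.tsv",
                      package = "divedit", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene = "c", target_sites = "c", concentration = "c",
                    n_mutant_individuals = "i", n_observed = "i",
                    printed_phenotype_rate = "d", printed_mutation_rate = "d",
                    printed_mutation_types = "c",
                    printed_rate_consistent = "l"))
}
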