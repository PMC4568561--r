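# CRISPR/Cas9 target design: enumerate N20-NGG sites on exons of either
# strand, filter by 5' dinucleotide (T7 transcription efficiency), require
# genome-wide uniqueness of the 12-nt PAM-proximal seed, and emit
# synthesis-ready PCR oligos.

T7_PREFIX <- "GAAATTAATACGACTCACTATA"            # 22 nt T7 promoter
SCAFFOLD_OVERLAP <- "GTTTTAGAGCTAGAAATAGC"       # 20 nt sgRNA scaffold overlap
SGRNA_REVERSE <- paste0(
  "AAAAGCACCGACTCGGTGCCACTTTTTCAAGTTGATAACGGACTAGCCT",
  "TATTTTAACTTGCTATTTCTAGCTCTAAAAC")             # 80 nt common reverse oligo

#' Enumerate candidate sgRNA target sites on exons
#'
#' Finds every position, on either strand, where a 20-nt protospacer is
#' immediately followed by an NGG PAM and the full 23-nt site lies inside a
#' single exon interval (set `protospacer_only = TRUE` to require only the
#' 20-nt protospacer inside the exon). Reverse-strand sites report
#' protospacer and PAM in their own strand's sequence; `start` is always the
#' 0-based + strand coordinate of the 23-nt footprint, so
#' `genome[start, start+23)`, reverse-complemented for `-` sites, reproduces
#' `protospacer + pam`.
#'
#' @param genome Named character vector / `DNAStringSet` of scaffolds.
#' @param exons Exon tibble with `scaffold`, `start`, `end` (0-based
#'   half-open) and optionally `gene_id`.
#' @param protospacer_only If `TRUE`, only the protospacer (not the PAM) must
#'   lie inside the exon.
#' @return Tibble of sites: `gene_id` (if supplied), `scaffold`, `start`,
#'   `strand`, `protospacer` (20 nt), `pam` (3 nt, `NGG`),
#'   `five_prime_class` (first two protospacer bases), `seed` (12
#'   PAM-proximal protospacer nt).
#' @export
enumerate_targets <- function(genome, exons, protospacer_only = FALSE) {
  g <- as_genome(genome)
  lens <- scaffold_lengths(g)
  exons <- as_tibble(exons)
  bad <- setdiff(unique(exons$scaffold), names(g))
  if (length(bad) > 0) {
    abort(paste0("exon scaffold(s) absent from genome: ",
                 paste(bad, collapse = ", ")))
  }
  if (nrow(exons) > 0 &&
      any(exons$start < 0 | exons$end > lens[exons$scaffold])) {
    abort("exon exceeds scaffold bounds")
  }
  res <- pmap(list(exons$scaffold,
                   exons$start,
                   exons$end,
                   if ("gene_id" %in% names(exons)) exons$gene_id else
                     rep(NA_character_, nrow(exons))),
              function(scaf, es, ee, gid) {
    # scan a context padded by 3 bp so PAMs just outside the exon are seen
    # when protospacer_only is set
    pad <- if (protospacer_only) 3 else 0
    cs <- max(0, es - pad)
    ce <- min(lens[[scaf]], ee + pad)
    ctx <- seq_window(g[[scaf]], cs, ce)
    plus <- scan_strand(ctx)
    minus <- scan_strand(revcomp(ctx))
    n <- nchar(ctx)
    rows <- list()
    if (length(plus) > 0) {
      rows$plus <- tibble(strand = "+", local = plus - 1)  # 0-based in ctx
    }
    if (length(minus) > 0) {
      rows$minus <- tibble(strand = "-", local = n - (minus - 1) - 23)
    }
    sites <- list_rbind(rows)
    if (is.null(sites) || nrow(sites) == 0) return(NULL)
    sites$start <- cs + sites$local
    # containment rule relative to the exon proper
    if (protospacer_only) {
      proto_start <- if_else(sites$strand == "+", sites$start,
                             sites$start + 3)
      keep <- proto_start >= es & proto_start + 20 <= ee
    } else {
      keep <- sites$start >= es & sites$start + 23 <= ee
    }
    sites <- sites[keep, , drop = FALSE]
    if (nrow(sites) == 0) return(NULL)
    site_seq <- vapply(seq_len(nrow(sites)), function(i) {
      s <- seq_window(g[[scaf]], sites$start[i], sites$start[i] + 23)
      if (sites$strand[i] == "-") revcomp(s) else s
    }, character(1))
    tibble(gene_id = gid, scaffold = scaf, start = sites$start,
           strand = sites$strand,
           protospacer = substr(site_seq, 1, 20),
           pam = substr(site_seq, 21, 23))
  }) |> list_rbind()
  if (is.null(res) || nrow(res) == 0) {
    res <- tibble(gene_id = character(), scaffold = character(),
                  start = numeric(), strand = character(),
                  protospacer = character(), pam = character())
  }
  res |>
    distinct(.data$scaffold, .data$start, .data$strand, .keep_all = TRUE) |>
    mutate(five_prime_class = substr(.data$protospacer, 1, 2),
           seed = substr(.data$protospacer, 9, 20)) |>
    arrange(.data$scaffold, .data$start, .data$strand)
}

# 1-based start positions of 23-mers whose positions 22-23 are "GG"
scan_strand <- function(s) {
  n <- nchar(s)
  if (n < 23) return(integer())
  gg <- gregexpr("(?=GG)", s, perl = TRUE)[[1]]
  if (gg[1] == -1) return(integer())
  starts <- gg - 21          # site start so that PAM GG sits at 22-23
  starts[starts >= 1 & starts + 22 <= n]
}

#' Keep sites whose protospacer starts with GG, GA or AG
#'
#' The 5' dinucleotide constraint reflects efficient initiation of in-vitro
#' T7 transcription of the sgRNA.
#'
#' @param sites Site tibble from [enumerate_targets()].
#' @param allowed Allowed 5' dinucleotides (default `GG`, `GA`, `AG`).
#' @return The filtered tibble.
#' @export
filter_five_prime <- function(sites, allowed = c("GG", "GA", "AG")) {
  as_tibble(sites) |> filter(.data$five_prime_class %in% allowed)
}

#' Genome-wide uniqueness of a 12-nt seed + NGG pattern
#'
#' A site passes iff the 15-nt pattern `seed + NGG` (with the first PAM
#' position treated as any base, since Cas9 specificity ignores it) occurs
#' exactly once across both strands of the whole genome -- that single
#' occurrence being the on-target site itself.
#'
#' @param seed 12-nt PAM-proximal protospacer segment.
#' @param genome Named character vector / `DNAStringSet`.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return `TRUE` iff the pattern occurs exactly once genome-wide.
#' @export
seed_is_unique <- function(seed, genome, both_strands = TRUE) {
  count_seed_pattern(seed, as_genome(genome), both_strands) == 1L
}

count_seed_pattern <- function(seed, g, both_strands = TRUE) {
  if (nchar(seed) != 12) abort("`seed` must be 12 nt")
  pat <- Biostrings::DNAString(paste0(seed, "NGG"))
  n <- sum(vapply(g, function(s) {
    subj <- Biostrings::DNAString(s)
    k <- Biostrings::countPattern(pat, subj, fixed = FALSE)
    if (both_strands) {
      k <- k + Biostrings::countPattern(pat,
                                        Biostrings::reverseComplement(subj),
                                        fixed = FALSE)
    }
    k
  }, numeric(1)))
  as.integer(n)
}

#' Annotate sites with their seed-uniqueness flag
#'
#' @param sites Site tibble from [enumerate_targets()].
#' @inheritParams seed_is_unique
#' @return `sites` with an added logical `seed_unique` column.
#' @export
seed_uniqueness <- function(sites, genome, both_strands = TRUE) {
  sites <- as_tibble(sites)
  g <- as_genome(genome)
  seeds <- unique(sites$seed)
  counts <- setNames(
    vapply(seeds, count_seed_pattern, integer(1), g = g,
           both_strands = both_strands),
    seeds)
  sites |> mutate(seed_unique = unname(counts[.data$seed]) == 1L)
}

#' Forward synthesis oligo for a protospacer
#'
#' Concatenates the 22-nt T7 promoter prefix, the 20-nt protospacer and the
#' 20-nt sgRNA scaffold overlap into the 62-nt forward PCR oligo used for
#' PCR-based sgRNA template synthesis.
#'
#' @param protospacer 20-nt protospacer sequence(s) (ACGT).
#' @return Character vector of 62-nt forward oligos.
#' @export
#' @examples
#' nchar(forward_oligo(strrep("G", 20)))
forward_oligo <- function(protospacer) {
  if (any(nchar(protospacer) != 20)) {
    abort("protospacer must be exactly 20 nt")
  }
  if (any(!grepl("^[ACGT]+$", protospacer))) {
    abort("protospacer must contain only A/C/G/T")
  }
  paste0(T7_PREFIX, protospacer, SCAFFOLD_OVERLAP)
}

#' The common 80-nt reverse oligo encoding the sgRNA scaffold
#'
#' @return A single 80-nt string.
#' @export
sgrna_reverse_oligo <- function() SGRNA_REVERSE
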