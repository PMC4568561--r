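# Genome-wide off-target enumeration for a protospacer: every 20-mer on
# either strand followed by an allowed PAM and within a Hamming-distance
# budget of the guide. Two independent implementations share one contract:
# find_offtargets() (vectorised base-wise accumulation) and
# offtarget_oracle() (per-candidate naive scan), which must agree bit-exactly.

#' Off-target scan configuration defaults
#'
#' @param max_mismatches Maximum Hamming distance (default 5).
#' @param allowed_pams Allowed PAM patterns of the form `N??` (default
#'   `NGG` and `NAG`, the canonical strict and lax Cas9 PAMs).
#' @return List with the validated settings.
#' @export
offtarget_config <- function(max_mismatches = 5,
                             allowed_pams = c("NGG", "NAG")) {
  stopifnot_scalar_number(max_mismatches, "max_mismatches", min = 0)
  if (any(nchar(allowed_pams) != 3 | substr(allowed_pams, 1, 1) != "N")) {
    abort("`allowed_pams` must be 3-nt patterns starting with N")
  }
  list(max_mismatches = as.integer(max_mismatches),
       allowed_pams = toupper(allowed_pams))
}

#' Find candidate off-target sites for a protospacer
#'
#' Reports every genomic 20-mer (both strands) that is followed by an
#' allowed PAM and lies within `max_mismatches` Hamming distance of the
#' protospacer. Mismatch positions are indexed 1-20 from the PAM-distal
#' (5') end of the protospacer. Bulges (indels) are not modelled. Ordering
#' is deterministic: scaffold, start, strand.
#'
#' @param protospacer 20-nt guide sequence (ACGT only; ambiguity codes are an
#'   error).
#' @param genome Named character vector / `DNAStringSet`.
#' @param max_mismatches,allowed_pams See [offtarget_config()].
#' @param exclude Optional data frame with `scaffold`, `start`, `strand`
#'   rows to drop (typically the on-target locus).
#' @return Tibble of hits: `scaffold`, `start` (0-based + strand start of
#'   the 23-nt footprint), `strand`, `site` (23 nt in the site's own
#'   strand), `pam`, `mismatch_count`, `mismatch_positions` (list column).
#' @export
find_offtargets <- function(protospacer, genome, max_mismatches = 5,
                            allowed_pams = c("NGG", "NAG"),
                            exclude = NULL) {
  cfg <- offtarget_config(max_mismatches, allowed_pams)
  proto <- check_protospacer(protospacer)
  g <- as_genome(genome)
  p_int <- utf8ToInt(proto)
  pam2 <- utf8ToInt(paste(substr(cfg$allowed_pams, 2, 2), collapse = ""))
  pam3 <- utf8ToInt(paste(substr(cfg$allowed_pams, 3, 3), collapse = ""))
  hits <- imap(as.list(g), function(seq, scaf) {
    n <- nchar(seq)
    if (n < 23) return(NULL)
    per_strand <- map(c("+", "-"), function(strand) {
      s <- if (strand == "+") seq else revcomp(seq)
      v <- utf8ToInt(s)
      m <- n - 22                       # number of candidate footprints
      matches <- integer(m)
      for (k in 1:20) {
        matches <- matches + (v[k:(k + m - 1)] == p_int[k])
      }
      mism <- 20L - matches
      ok_pam <- logical(m)
      p2 <- v[22:(21 + m)]
      p3 <- v[23:(22 + m)]
      for (j in seq_along(pam2)) {
        ok_pam <- ok_pam | (p2 == pam2[j] & p3 == pam3[j])
      }
      idx <- which(ok_pam & mism <= cfg$max_mismatches)
      if (length(idx) == 0) return(NULL)
      start0 <- if (strand == "+") idx - 1 else n - (idx - 1) - 23
      site <- substring(s, idx, idx + 22)
      tibble(scaffold = scaf, start = start0, strand = strand,
             site = substr(site, 1, 23),
             pam = substr(site, 21, 23),
             mismatch_count = mism[idx],
             mismatch_positions = map(site, function(x) {
               which(strsplit(substr(x, 1, 20), "")[[1]] !=
                       strsplit(proto, "")[[1]])
             }))
    })
    list_rbind(per_strand)
  }) |> list_rbind()
  finalize_hits(hits, exclude)
}

#' Naive off-target oracle (reference implementation)
#'
#' Same contract as [find_offtargets()], implemented as a direct
#' per-candidate scan: every PAM-bearing footprint is located independently
#' and its Hamming distance computed by elementwise comparison. Intended as
#' the test oracle.
#'
#' @inheritParams find_offtargets
#' @return As [find_offtargets()].
#' @export
offtarget_oracle <- function(protospacer, genome, max_mismatches = 5,
                             allowed_pams = c("NGG", "NAG"),
                             exclude = NULL) {
  cfg <- offtarget_config(max_mismatches, allowed_pams)
  proto <- check_protospacer(protospacer)
  g <- as_genome(genome)
  p_int <- utf8ToInt(proto)
  pam_class <- paste0("[", paste(substr(cfg$allowed_pams, 2, 2),
                                 collapse = ""), "]")
  pam3_class <- paste0("[", paste(substr(cfg$allowed_pams, 3, 3),
                                  collapse = ""), "]")
  pam_re <- paste0("(?=[ACGTN]", pam_class, pam3_class, ")")
  hits <- imap(as.list(g), function(seq, scaf) {
    n <- nchar(seq)
    if (n < 23) return(NULL)
    per_strand <- map(c("+", "-"), function(strand) {
      s <- if (strand == "+") seq else revcomp(seq)
      v <- utf8ToInt(s)
      pam_at <- gregexpr(pam_re, s, perl = TRUE)[[1]]   # PAM start, 1-based
      if (pam_at[1] == -1) return(NULL)
      starts <- pam_at - 20                             # footprint start
      starts <- starts[starts >= 1 & starts + 22 <= n]
      if (length(starts) == 0) return(NULL)
      idx_mat <- outer(starts, 0:19, `+`)
      mm_mat <- matrix(v[idx_mat], nrow = length(starts)) !=
        matrix(p_int, nrow = length(starts), ncol = 20, byrow = TRUE)
      mism <- rowSums(mm_mat)
      keep <- mism <= cfg$max_mismatches
      if (!any(keep)) return(NULL)
      starts <- starts[keep]
      mm_mat <- mm_mat[keep, , drop = FALSE]
      site <- substring(s, starts, starts + 22)
      tibble(scaffold = scaf,
             start = if (strand == "+") starts - 1 else n - (starts - 1) - 23,
             strand = strand,
             site = site,
             pam = substr(site, 21, 23),
             mismatch_count = as.integer(mism[keep]),
             mismatch_positions = map(seq_len(nrow(mm_mat)),
                                      function(i) which(mm_mat[i, ])))
    })
    list_rbind(per_strand)
  }) |> list_rbind()
  finalize_hits(hits, exclude)
}

check_protospacer <- function(protospacer) {
  proto <- toupper(protospacer)
  if (length(proto) != 1 || nchar(proto) != 20) {
    abort("`protospacer` must be a single 20-nt sequence")
  }
  if (!grepl("^[ACGT]+$", proto)) {
    abort("ambiguity codes are not allowed in the protospacer")
  }
  proto
}

finalize_hits <- function(hits, exclude) {
  empty <- tibble(scaffold = character(), start = numeric(),
                  strand = character(), site = character(), pam = character(),
                  mismatch_count = integer(), mismatch_positions = list())
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  hits <- hits |>
    mutate(mismatch_count = as.integer(.data$mismatch_count)) |>
    arrange(.data$scaffold, .data$start, .data$strand)
  if (!is.null(exclude) && nrow(as_tibble(exclude)) > 0) {
    hits <- anti_join(hits, as_tibble(exclude)[, c("scaffold", "start", "strand")],
                      by = c("scaffold", "start", "strand"))
  }
  hits
}
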