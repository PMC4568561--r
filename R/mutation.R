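# Mutation typing of Sanger-sequenced amplicon clones: global affine-gap
# alignment against the wild-type amplicon, canonical (left-shifted) gap
# placement, event extraction (D = deleted fragment, I = inserted fragment,
# M = substituted run), classification against expected Cas9 cut sites, and
# the mutagenesis-efficiency summary table.

#' Globally align a clone to the wild-type amplicon
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (match +2, mismatch -2, gap of length L costs `gap_open + L *
#' gap_extend`; defaults 10 and 0.5). Gap runs are left-shifted within
#' repeats afterwards so event coordinates are canonical and reproducible.
#' Adjacent equal-length deletion/insertion runs are reported as one
#' substitution (M) event: under these scores an optimal alignment represents
#' a substitution run longer than 20 bp as a deletion plus an insertion, and
#' the merge restores the biological reading.
#'
#' @param clone,wildtype Sequences (ACGTN, non-empty).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return An object of class `alignment_result`: list with `clone_aln`,
#'   `ref_aln` (gapped strings), `score`, and `events` (tibble: `type`,
#'   `length`, `ref_start`, `ref_end`, 0-based reference coordinates; an
#'   insertion has `ref_start == ref_end`).
#' @export
#' @examples
#' aln <- global_align("ACGTACGT", "ACGTTTACGT")
#' aln$events
global_align <- function(clone, wildtype, match = 2, mismatch = -2,
                         gap_open = 10, gap_extend = 0.5) {
  clone <- toupper(clone)
  wildtype <- toupper(wildtype)
  if (nchar(clone) == 0 || nchar(wildtype) == 0) {
    abort("sequences must be non-empty")
  }
  if (!grepl("^[ACGTN]+$", clone) || !grepl("^[ACGTN]+$", wildtype)) {
    abort("sequences must be over the ACGTN alphabet")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = clone, subject = wildtype, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  ca <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  shifted <- left_shift_gaps(ca, ra)
  structure(list(
    clone_aln = paste(shifted$a, collapse = ""),
    ref_aln = paste(shifted$b, collapse = ""),
    score = Biostrings::score(pa),
    events = extract_events(shifted$a, shifted$b)
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> score", x$score, "\n")
  cat(" ref:  ", x$ref_aln, "\n")
  cat(" clone:", x$clone_aln, "\n")
  if (nrow(x$events)) print(x$events) else cat(" no events\n")
  invisible(x)
}

# shift every gap run leftwards while score-equivalent (the character jumped
# over matches the character at the run's right edge in the opposite row)
left_shift_gaps <- function(a, b) {
  shift_one <- function(gapped, other) {
    repeat {
      moved <- FALSE
      r <- rle(gapped == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (i in which(r$values)) {
        s <- starts[i]; e <- ends[i]
        while (s > 1 && gapped[s - 1] != "-" &&
               other[s - 1] == other[e] && other[s - 1] != "-") {
          gapped[e] <- gapped[s - 1]
          gapped[s - 1] <- "-"
          s <- s - 1; e <- e - 1
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    gapped
  }
  a <- shift_one(a, b)
  b <- shift_one(b, a)
  list(a = a, b = b)
}

# classify alignment columns and collapse runs into events
extract_events <- function(ca, ra) {
  stopifnot(length(ca) == length(ra))
  cls <- rep("=", length(ca))
  cls[ca == "-"] <- "D"
  cls[ra == "-"] <- "I"
  cls[cls == "=" & ca != ra] <- "M"
  ref_pos <- cumsum(ra != "-")          # 1-based ref coord of each column
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- tibble(
    type = r$values, col_start = starts, col_end = ends
  ) |> filter(.data$type != "=")
  if (nrow(ev) == 0) {
    return(tibble(type = character(), length = numeric(),
                  ref_start = numeric(), ref_end = numeric()))
  }
  ev <- ev |>
    mutate(length = .data$col_end - .data$col_start + 1,
           ref_start = if_else(.data$type == "I",
                               ref_pos[.data$col_start] * 1.0,
                               ref_pos[.data$col_start] - 1.0),
           ref_end = if_else(.data$type == "I", .data$ref_start,
                             .data$ref_start + .data$length))
  # Normalise alignment artifacts around substitution runs: a
  # length-preserving tract of all-changed bases may be represented by the
  # optimal alignment as an insertion and a deletion of equal total length
  # with interleaved mismatch/accidental-match columns (cheaper than a long
  # mismatch run under affine scores). Cluster events separated by at most
  # `merge_sep` match columns; a cluster whose inserted and deleted lengths
  # balance (net indel 0, > 0 gaps) is one substitution run over its
  # reference span.
  merge_sep <- 12
  ref_chars <- ra[ra != "-"]
  clone_chars <- ca[ca != "-"]
  cl_id <- cumsum(c(1, (ev$col_start[-1] - ev$col_end[-nrow(ev)] - 1) >
                      merge_sep))
  merged <- map(split(ev, cl_id), function(cl) {
    d_len <- sum(cl$length[cl$type == "D"])
    i_len <- sum(cl$length[cl$type == "I"])
    if (nrow(cl) > 1 && d_len > 0 && d_len == i_len) {
      # net indel zero: the tract is length-preserving, so re-read it from
      # the direct (gapless) comparison and trim accidental flank matches
      s <- min(cl$ref_start)
      e <- max(cl$ref_end)
      c0 <- cl$col_start[1]
      offset <- if (c0 > 1) {
        sum(ca[1:(c0 - 1)] != "-") - sum(ra[1:(c0 - 1)] != "-")
      } else 0
      idx_ref <- (s + 1):e
      idx_clone <- idx_ref + offset
      ok <- idx_ref >= 1 & idx_ref <= length(ref_chars) &
        idx_clone >= 1 & idx_clone <= length(clone_chars)
      mism <- ref_chars[idx_ref[ok]] != clone_chars[idx_clone[ok]]
      if (!any(mism)) return(NULL)
      lo <- min(which(mism)); hi <- max(which(mism))
      tibble(type = "M", length = hi - lo + 1,
             ref_start = s + lo - 1, ref_end = s + hi)
    } else {
      cl[, c("type", "length", "ref_start", "ref_end")]
    }
  })
  out <- list_rbind(merged)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(type = character(), length = numeric(),
                  ref_start = numeric(), ref_end = numeric()))
  }
  out |> arrange(.data$ref_start)
}

#' Classify a clone as wild type or mutant near expected cut sites
#'
#' An event qualifies iff its reference span intersects
#' `[cut - window_radius, cut + window_radius]` for any cut site and its
#' length is at least `min_event_length`. The clone is mutant iff at least
#' one event qualifies. The Cas9 blunt cut is expected 3 bp 5' of the PAM;
#' pass those positions as `cut_sites`.
#'
#' @param alignment An [global_align()] result.
#' @param cut_sites Integer vector of expected cut positions (0-based
#'   reference coordinates).
#' @param window_radius Classification window half-width in bp (default 20;
#'   generous enough that a fragment dropped between two paired cut sites
#'   still qualifies through the span-intersection rule).
#' @param min_event_length Minimum qualifying event length in bp (default 1).
#' @return One-row tibble: `status` (`"WT"`/`"mutant"`), `n_events`, and
#'   `events` (list column with the qualifying events).
#' @export
classify_clone <- function(alignment, cut_sites, window_radius = 20,
                           min_event_length = 1) {
  stopifnot(inherits(alignment, "alignment_result"))
  ev <- alignment$events
  if (nrow(ev) > 0) {
    qual <- map_lgl(seq_len(nrow(ev)), function(i) {
      if (ev$length[i] < min_event_length) return(FALSE)
      any(ev$ref_start[i] <= cut_sites + window_radius &
            ev$ref_end[i] >= cut_sites - window_radius)
    })
    ev <- ev[qual, , drop = FALSE]
  }
  tibble(status = if (nrow(ev) > 0) "mutant" else "WT",
         n_events = nrow(ev), events = list(ev))
}

#' Call every clone of an experiment
#'
#' Aligns each clone to the wild-type amplicon and classifies it against the
#' expected cut sites.
#'
#' @param clones Named character vector (or `DNAStringSet`) of clone
#'   sequences.
#' @param wildtype Wild-type amplicon sequence.
#' @inheritParams classify_clone
#' @param ... Passed to [global_align()].
#' @return Tibble: `clone_id`, `status`, `n_events`, `events` (list column),
#'   `event_string` (e.g. `"D:12"`).
#' @export
call_clones <- function(clones, wildtype, cut_sites, window_radius = 20,
                        min_event_length = 1, ...) {
  clones <- as_genome(clones)
  calls <- imap(as.list(clones), function(seq, id) {
    aln <- global_align(seq, wildtype, ...)
    cl <- classify_clone(aln, cut_sites, window_radius, min_event_length)
    cl$clone_id <- id
    cl
  }) |> list_rbind()
  calls |>
    mutate(event_string = map_chr(.data$events, function(e) {
      if (nrow(e) == 0) "" else
        paste(sprintf("%s:%d", e$type, as.integer(e$length)), collapse = "; ")
    })) |>
    select("clone_id", "status", "n_events", "events", "event_string")
}

#' Phenotype (or mutation) rate in percent
#'
#' @param n_mutant,n_observed Counts with `0 <= n_mutant <= n_observed`,
#'   `n_observed > 0`. Vectorised.
#' @return Numeric percentages, `100 * n_mutant / n_observed`.
#' @export
#' @examples
#' phenotype_rate(22, 25)
phenotype_rate <- function(n_mutant, n_observed) {
  if (any(n_observed <= 0)) abort("`n_observed` must be > 0")
  if (any(n_mutant < 0 | n_mutant > n_observed)) {
    abort("need 0 <= n_mutant <= n_observed")
  }
  100 * n_mutant / n_observed
}

#' Display form of a percentage
#'
#' Rounds half-up to two decimals, then strips trailing zeros (and a
#' trailing decimal point), matching the conventional table display:
#' 91.791 -> "91.79", 88 -> "88", 7.954 -> "7.95".
#'
#' @param percent Numeric percentages.
#' @return Character vector.
#' @export
format_rate <- function(percent) {
  r <- floor(percent * 100 + 0.5) / 100
  out <- sprintf("%.2f", r)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

#' Summarise mutagenesis experiments into an efficiency table
#'
#' One row per experiment: phenotype rate from injected-individual counts,
#' mutation rate from sequenced-clone calls (when supplied), and per-type
#' min-max event-length ranges formatted like `"D: 3-73; I: 3-64; M: 3-29"`
#' (en dash; a type observed at a single length prints that length alone;
#' absent types are omitted).
#'
#' @param experiments Tibble with one row per experiment: identifying columns
#'   (e.g. `gene`, `target_sites`, `concentration`), plus
#'   `n_mutant_individuals` and `n_observed`. An `experiment` id column is
#'   added if absent.
#' @param calls Optional clone-call tibble from [call_clones()] with an
#'   added `experiment` column matching `experiments$experiment`.
#' @return Tibble with the identifying columns plus `phenotype_rate`,
#'   `phenotype_display`, `n_clones`, `n_mutant_clones`, `mutation_rate`,
#'   `type_ranges`.
#' @export
summarize_mutagenesis <- function(experiments, calls = NULL) {
  ex <- as_tibble(experiments)
  if (!"experiment" %in% names(ex)) ex$experiment <- seq_len(nrow(ex))
  out <- ex |>
    mutate(phenotype_rate = phenotype_rate(.data$n_mutant_individuals,
                                           .data$n_observed),
           phenotype_display = format_rate(.data$phenotype_rate))
  per_exp <- map(out$experiment, function(id) {
    if (is.null(calls)) {
      return(tibble(n_clones = NA_integer_, n_mutant_clones = NA_integer_,
                    mutation_rate = NA_real_, type_ranges = ""))
    }
    cc <- as_tibble(calls) |> filter(.data$experiment == id)
    n <- nrow(cc)
    nm <- sum(cc$status == "mutant")
    ev <- list_rbind(cc$events)
    tibble(n_clones = n, n_mutant_clones = nm,
           mutation_rate = if (n > 0) 100 * nm / n else NA_real_,
           type_ranges = format_type_ranges(ev))
  }) |> list_rbind()
  bind_cols(out, per_exp)
}

format_type_ranges <- function(events) {
  if (is.null(events) || nrow(events) == 0) return("")
  parts <- events |>
    group_by(.data$type) |>
    summarise(lo = min(.data$length), hi = max(.data$length),
              .groups = "drop") |>
    arrange(factor(.data$type, levels = c("D", "I", "M"))) |>
    mutate(txt = if_else(.data$lo == .data$hi,
                         sprintf("%s: %d", .data$type, as.integer(.data$lo)),
                         sprintf("%s: %d\u2013%d", .data$type,
                                 as.integer(.data$lo), as.integer(.data$hi))))
  paste(parts$txt, collapse = "; ")
}

#' Expected Cas9 cut positions for designed sites
#'
#' The blunt cut is taken 3 bp 5' of the PAM: for a `+` strand site with
#' footprint start `s`, the cut falls between positions `s+16` and `s+17`
#' (returned as 0-based position `s + 17`); for a `-` strand site, at
#' `s + 6`.
#'
#' @param sites Site tibble from [enumerate_targets()].
#' @return Integer vector of 0-based cut positions.
#' @export
cut_positions <- function(sites) {
  sites <- as_tibble(sites)
  as.integer(if_else(sites$strand == "+", sites$start + 17, sites$start + 6))
}
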