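# Shared sequence / coordinate helpers. Everything works on plain character
# vectors at the edges; Biostrings objects are accepted and normalised.

DNA_BASES <- c("A", "C", "G", "T")

#' Coerce a genome to a named character vector of scaffold sequences
#'
#' Accepts a named character vector, a [Biostrings::DNAStringSet], or a path
#' to a FASTA file.
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @return Named character vector of upper-case scaffold sequences.
#' @export
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1 &&
             !grepl("^[ACGTNacgtn]+$", genome) && file.exists(genome)) {
    out <- as.character(Biostrings::readDNAStringSet(genome))
  } else if (is.character(genome)) {
    out <- genome
  } else {
    abort("`genome` must be a named character vector, DNAStringSet or FASTA path.")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    abort("every scaffold sequence must be named")
  }
  toupper(out)
}

#' Scaffold lengths of a genome
#'
#' @inheritParams as_genome
#' @return Named numeric vector of scaffold lengths in bp.
#' @export
scaffold_lengths <- function(genome) {
  g <- as_genome(genome)
  setNames(nchar(g), names(g))
}

#' Reverse-complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN, either case).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence
#'
#' Uniform base composition; consumes the current RNG stream.
#'
#' @param n Length in bp.
#' @return A single DNA string of length `n`.
#' @export
random_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# random base different from `ref` (vectorised)
random_alt_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

# 0-based half-open substring of a scaffold string
seq_window <- function(seq, start, end) {
  substr(seq, start + 1, end)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
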