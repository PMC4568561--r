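# Independent reference implementations used only as test oracles. Each is a
# direct, unoptimised transcription of the rule it checks, sharing no code
# with the package internals.

# --- affine-gap global alignment score (Gotoh three-state DP) ---------------
oracle_align_score <- function(a, b, match = 2, mismatch = -2,
                               gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  GA <- matrix(NEG, n + 1, m + 1)  # gap in b (a char vs '-')
  GB <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) GA[i + 1, 1] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) GB[1, j + 1] <- -(gap_open + j * gap_extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], GA[i, j], GB[i, j])
      GA[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              GA[i, j + 1] - gap_extend,
                              GB[i, j + 1] - gap_open - gap_extend)
      GB[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              GB[i + 1, j] - gap_extend,
                              GA[i + 1, j] - gap_open - gap_extend)
    }
  }
  max(M[n + 1, m + 1], GA[n + 1, m + 1], GB[n + 1, m + 1])
}

# --- site-by-site fixed-difference rule -------------------------------------
oracle_fixed_diffs <- function(vx, vy) {
  gt <- function(v, scaf, p) {
    r <- v[v$scaffold == scaf & v$pos == p, ]
    if (nrow(r) == 0) return(list(class = "ref", alt = NA))
    g <- gsub("|", "/", r$genotype[1], fixed = TRUE)
    cls <- if (g == "1/1") "hom" else if (g %in% c("0/1", "1/0")) "het"
    else if (g == "0/0") "ref" else "missing"
    list(class = cls, alt = r$alt[1])
  }
  sites <- unique(rbind(vx[, c("scaffold", "pos")], vy[, c("scaffold", "pos")]))
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    x <- gt(vx, sites$scaffold[i], sites$pos[i])
    y <- gt(vy, sites$scaffold[i], sites$pos[i])
    if (x$class %in% c("het", "missing") || y$class %in% c("het", "missing")) next
    keep[i] <- (x$class == "hom" && y$class == "hom" && x$alt != y$alt) ||
      (x$class == "hom" && y$class == "ref") ||
      (x$class == "ref" && y$class == "hom")
  }
  out <- sites[keep, , drop = FALSE]
  out[order(out$scaffold, out$pos), , drop = FALSE]
}

# --- position-by-position N20-NGG site scan over one sequence ---------------
oracle_scan_sites <- function(seq) {
  hits <- list()
  scan_one <- function(s, strand, L) {
    n <- nchar(s)
    for (p in seq_len(max(n - 22, 0))) {
      site <- substr(s, p, p + 22)
      if (substr(site, 22, 23) == "GG") {
        start0 <- if (strand == "+") p - 1 else L - (p - 1) - 23
        hits[[length(hits) + 1]] <<- data.frame(
          start = start0, strand = strand,
          protospacer = substr(site, 1, 20), pam = substr(site, 21, 23))
      }
    }
  }
  L <- nchar(seq)
  scan_one(seq, "+", L)
  scan_one(divedit::revcomp(seq), "-", L)
  out <- do.call(rbind, hits)
  if (is.null(out)) return(data.frame(start = numeric(), strand = character(),
                                      protospacer = character(),
                                      pam = character()))
  out[order(out$start, out$strand), , drop = FALSE]
}

# --- naive two-strand string count of seed+NGG ------------------------------
oracle_seed_count <- function(seed, genome) {
  pat <- paste0("(?=", seed, "[ACGT]GG)")
  sum(vapply(genome, function(s) {
    k <- 0L
    for (str in c(s, divedit::revcomp(s))) {
      m <- gregexpr(pat, str, perl = TRUE)[[1]]
      k <- k + if (m[1] == -1) 0L else length(m)
    }
    k
  }, integer(1)))
}

# --- naive one-pair window scan (density + type-7 quantile + merge) ---------
oracle_scan <- function(diffs, scaffold_lengths, window_length, q = 0.95) {
  wins <- list()
  for (scaf in names(scaffold_lengths)) {
    len <- scaffold_lengths[[scaf]]
    s <- 0
    while (s < len) {
      e <- min(s + window_length, len)
      if (e - s >= 0.5 * window_length) {
        wins[[length(wins) + 1]] <- data.frame(scaffold = scaf, start = s,
                                               end = e)
      }
      s <- s + window_length
    }
  }
  wins <- do.call(rbind, wins)
  dens <- function(pairdiffs) {
    d <- numeric(nrow(wins))
    for (i in seq_len(nrow(wins))) {
      d[i] <- sum(pairdiffs$scaffold == wins$scaffold[i] &
                    pairdiffs$pos >= wins$start[i] &
                    pairdiffs$pos < wins$end[i]) / (wins$end[i] - wins$start[i])
    }
    d
  }
  pairs <- sort(unique(diffs$pair))
  dmat <- sapply(pairs, function(p) dens(diffs[diffs$pair == p, ]))
  cuts <- apply(dmat, 2, stats::quantile, probs = q, type = 7)
  out <- apply(sweep(dmat, 2, cuts, `>`), 1, all)
  # merge adjacent outliers
  regions <- list()
  i <- 1
  while (i <= nrow(wins)) {
    if (out[i]) {
      j <- i
      while (j + 1 <= nrow(wins) && out[j + 1] &&
             wins$scaffold[j + 1] == wins$scaffold[j] &&
             wins$start[j + 1] == wins$end[j]) j <- j + 1
      regions[[length(regions) + 1]] <- data.frame(
        scaffold = wins$scaffold[i], start = wins$start[i], end = wins$end[j])
      i <- j + 1
    } else i <- i + 1
  }
  list(windows = wins, outlier = out,
       regions = if (length(regions)) do.call(rbind, regions) else
         data.frame(scaffold = character(), start = numeric(),
                    end = numeric()))
}

# small random variant-table generator for the fixed-difference oracle tests
random_genotype_table <- function(positions, scaffold = "s1") {
  n <- length(positions)
  gts <- sample(c("1/1", "0/1", "0/0", "./.", "absent"), n, replace = TRUE,
                prob = c(0.35, 0.2, 0.1, 0.1, 0.25))
  alt <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  keep <- gts != "absent"
  tibble::tibble(scaffold = scaffold, pos = positions, ref = "N",
                 alt = alt, genotype = gts)[keep, ]
}
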