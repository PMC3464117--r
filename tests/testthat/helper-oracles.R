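# Independent oracles, deliberately naive: straightforward string
# manipulation, no shared code with the package internals they check.

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(lapply(strsplit(s, ""), rev), paste, character(1), collapse = ""))
}

# collapse all 65,536 ordered 4-mer pairs by brute force
oracle_pattern_classes <- function() {
  b <- c("A", "C", "G", "T")
  f4 <- sort(do.call(paste0, expand.grid(b, b, b, b,
                                         stringsAsFactors = FALSE)[, 4:1]))
  left <- rep(f4, each = 256)
  right <- rep(f4, times = 256)
  pat <- paste0(left, right)
  rcpat <- paste0(oracle_revcomp(right), oracle_revcomp(left))
  canon <- ifelse(pat <= rcpat, pat, rcpat)
  reps <- sort(unique(canon))
  list(
    n_classes = length(reps),
    n_palindromic = sum(pat == rcpat) ,
    representatives = reps,
    cg_continuous = grepl("CG", reps),
    cg_split = grepl("CG", substr(reps, 1, 4)) | grepl("CG", substr(reps, 5, 8))
  )
}

# character-by-character motif scanner (both strands, overlapping matches)
oracle_find_occurrences <- function(motif, genome) {
  rc <- oracle_revcomp(motif)
  w <- nchar(motif)
  out <- list()
  for (i in seq_len(nrow(genome))) {
    s <- genome$sequence[i]
    for (p in seq_len(nchar(s) - w + 1)) {
      win <- substr(s, p, p + w - 1)
      if (win == motif) {
        out[[length(out) + 1]] <- data.frame(
          chrom = genome$id[i], start = p - 1L, strand = "+")
      }
      if (win == rc && rc != motif) {
        out[[length(out) + 1]] <- data.frame(
          chrom = genome$id[i], start = p - 1L, strand = "-")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), ]
}

# per-position, per-site split 8-mer counter over a promoter set
oracle_scan <- function(seqs, k, bin_width = 20) {
  counts <- new.env()
  for (s in seqs) {
    L <- nchar(s)
    for (o in seq_len(L - 8 - k + 1)) {
      site <- substr(s, o, o + 8 + k - 1)
      if (grepl("N", site, fixed = TRUE)) next
      left <- substr(site, 1, 4)
      right <- substr(site, 4 + k + 1, 8 + k)
      pat <- paste0(left, right)
      rcpat <- paste0(oracle_revcomp(right), oracle_revcomp(left))
      canon <- if (pat <= rcpat) pat else rcpat
      bin <- (o - 1) %/% bin_width + 1
      key <- paste(canon, bin)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  as.list(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive mean-score profile around occurrences
oracle_position_profile <- function(occurrences, score_vectors, flank) {
  width <- nchar(occurrences$site[1]) + 2 * flank
  acc <- matrix(NA_real_, nrow = nrow(occurrences), ncol = width)
  for (i in seq_len(nrow(occurrences))) {
    v <- score_vectors[[occurrences$chrom[i]]]
    for (j in seq_len(width)) {
      pos1 <- occurrences$start[i] - flank + j   # 1-based genomic
      if (pos1 >= 1 && pos1 <= length(v)) acc[i, j] <- v[pos1]
    }
    if (occurrences$strand[i] == "-") acc[i, ] <- rev(acc[i, ])
  }
  colMeans(acc, na.rm = TRUE)
}
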