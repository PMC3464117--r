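# membership of single base positions (0-based) in a BED-style region set
positions_in_regions <- function(chrom, pos, regions) {
  if (length(chrom) == 0) return(logical(0))
  if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  GenomicRanges::countOverlaps(q, s) > 0
}

# per-chromosome sorted masked/N positions (1-based) for overlap tests
masked_positions <- function(genome) {
  mask <- genome[["mask"]] %||% rep(list(integer(0)), nrow(genome))
  lapply(seq_len(nrow(genome)), function(i) {
    npos <- as.integer(gregexpr("N", genome$sequence[i], fixed = TRUE)[[1]])
    npos <- npos[npos > 0]
    sort(unique(c(mask[[i]], npos)))
  })
}

# does any excluded position fall in [from, to] (1-based, vectorised)?
overlaps_sorted <- function(excluded, from, to) {
  if (length(excluded) == 0) return(rep(FALSE, length(from)))
  findInterval(to, excluded) - findInterval(from - 1L, excluded) > 0
}

#' Find genomic occurrences of a literal motif on both strands
#'
#' Reports forward matches of `motif` and of its reverse complement, each
#' at its leftmost plus-strand coordinate; palindromic motifs are reported
#' once per site. Overlapping occurrences are all reported. With
#' `unmasked_only` (the default) sites containing a soft-masked (lowercase
#' in the source FASTA) or `N` base are skipped -- the "unmasked" counting
#' universe of repeat-filtered genome scans.
#'
#' @param motif Literal motif (A,C,G,T; length >= 4).
#' @param genome Tibble with `id`, `sequence` and optionally `mask` (as
#'   from [read_fasta()]).
#' @param unmasked_only Exclude sites overlapping masked or `N` bases.
#' @return A tibble of class `motif_occurrences`: `chrom`, `start`
#'   (0-based leftmost base), `end` (exclusive), `strand`, `motif`, `site`
#'   (matched substring in plus-strand orientation).
#' @export
find_occurrences <- function(motif, genome, unmasked_only = TRUE) {
  stopifnot(nchar(motif) >= 4, grepl("^[ACGT]+$", motif))
  rc <- revcomp(motif)
  palindromic <- rc == motif
  excl <- if (unmasked_only) masked_positions(genome) else NULL
  out <- lapply(seq_len(nrow(genome)), function(i) {
    seq_i <- genome$sequence[i]
    subject <- Biostrings::DNAString(seq_i)
    hit_tbl <- function(query, strand) {
      # matchPattern reports overlapping matches; N in the subject never
      # matches a concrete base under fixed = TRUE
      hits <- IRanges::start(
        Biostrings::matchPattern(query, subject, fixed = TRUE)
      )
      if (length(hits) == 0) return(NULL)
      tibble(chrom = genome$id[i], start = hits - 1L,
             end = hits - 1L + nchar(query), strand = strand,
             motif = motif, site = query)
    }
    res <- bind_rows(
      hit_tbl(motif, "+"),
      if (!palindromic) hit_tbl(rc, "-")
    )
    if (!is.null(res) && nrow(res) > 0 && unmasked_only) {
      bad <- overlaps_sorted(excl[[i]], res$start + 1L, res$end)
      res <- res[!bad, , drop = FALSE]
    }
    res
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), motif = character(), site = character())
  }
  res <- arrange(res, .data$chrom, .data$start, .data$strand)
  class(res) <- c("motif_occurrences", class(res))
  res
}

#' Fraction of occurrences falling inside a region set
#'
#' An occurrence is in-region when its start base (leftmost plus-strand
#' base) lies inside some interval; overlapping intervals are not merged
#' first, membership in any interval counts once.
#'
#' @param occurrences A [find_occurrences()] result.
#' @param regions BED-style tibble (`chrom`, `start`, `end`).
#' @return One-row tibble with `count` (in-region occurrences) and
#'   `fraction` (of all occurrences; 0 when there are none).
#' @export
fraction_in_regions <- function(occurrences, regions) {
  if (nrow(occurrences) == 0) return(tibble(count = 0L, fraction = 0))
  inside <- positions_in_regions(occurrences$chrom, occurrences$start, regions)
  tibble(count = sum(inside),
         fraction = if (nrow(occurrences) == 0) 0 else mean(inside))
}

#' Occurrence and region-enrichment table for a set of motifs
#'
#' One row per motif: the genome-wide occurrence count and, for every named
#' region set, the in-region count, raw fraction, and the percentage
#' rounded half-up to a whole number (the form printed in enrichment
#' tables).
#'
#' @param motifs Character vector of literal motifs.
#' @param genome Genome tibble (see [find_occurrences()]).
#' @param region_sets Named list of BED-style region tibbles.
#' @param unmasked_only Passed to [find_occurrences()].
#' @return Tibble with `motif`, `n_mer`, `genome_count`, then
#'   `<set>_count`, `<set>_fraction`, `<set>_percent` per region set.
#' @export
enrichment_table <- function(motifs, genome, region_sets = list(),
                             unmasked_only = TRUE) {
  rows <- lapply(motifs, function(mo) {
    occ <- find_occurrences(mo, genome, unmasked_only)
    row <- tibble(motif = mo, n_mer = nchar(mo), genome_count = nrow(occ))
    for (set_name in names(region_sets)) {
      fr <- fraction_in_regions(occ, region_sets[[set_name]])
      row[[paste0(set_name, "_count")]] <- fr$count
      row[[paste0(set_name, "_fraction")]] <- fr$fraction
      row[[paste0(set_name, "_percent")]] <- percent_round(fr$fraction)
    }
    row
  })
  bind_rows(rows)
}

#' Base-by-base motif extension scan
#'
#' Starting from a core motif, extends one base at a time toward one end
#' along a target sequence; at each extension length all four choices of
#' the newly added base are evaluated (occurrence count and region-overlap
#' fraction), with the target's own base marked `on_target`. This traces
#' how enrichment jumps when an extension completes a discriminating
#' element (such as the second CG of the ETS-CRE 11-mer).
#'
#' @param core Core motif (must be a prefix of `target` for
#'   `direction = "right"`, a suffix for `"left"`).
#' @param target Full target sequence the trajectory follows.
#' @param direction `"right"` or `"left"`.
#' @param genome Genome tibble.
#' @param regions BED-style region tibble used for the overlap fraction.
#' @param max_extension Number of extension steps (default: to the end of
#'   `target`).
#' @param unmasked_only Passed to [find_occurrences()].
#' @return Tibble with `extension`, `candidate`, `final_base`,
#'   `on_target`, `genome_count`, `region_count`, `fraction`, `percent`.
#' @export
extension_scan <- function(core, target, direction = c("right", "left"),
                           genome, regions, max_extension = NULL,
                           unmasked_only = TRUE) {
  direction <- match.arg(direction)
  stopifnot(nchar(core) >= 4, nchar(target) >= nchar(core))
  if (direction == "right" && !startsWith(target, core)) {
    abort("`core` must be a prefix of `target` for a rightward extension")
  }
  if (direction == "left" && !endsWith(target, core)) {
    abort("`core` must be a suffix of `target` for a leftward extension")
  }
  room <- nchar(target) - nchar(core)
  max_extension <- max_extension %||% room
  if (max_extension > room) {
    abort(sprintf("extension by %d goes beyond the %d-base target",
                  max_extension, nchar(target)))
  }
  eval_candidate <- function(cand, ext, final_base, on_target) {
    occ <- find_occurrences(cand, genome, unmasked_only)
    fr <- fraction_in_regions(occ, regions)
    tibble(extension = ext, candidate = cand, final_base = final_base,
           on_target = on_target, genome_count = nrow(occ),
           region_count = fr$count, fraction = fr$fraction,
           percent = percent_round(fr$fraction))
  }
  rows <- list(eval_candidate(core, 0L, NA_character_, TRUE))
  for (ext in seq_len(max_extension)) {
    if (direction == "right") {
      stem <- substr(target, 1, nchar(core) + ext - 1L)
      target_base <- substr(target, nchar(core) + ext, nchar(core) + ext)
      cands <- paste0(stem, DNA_BASES)
    } else {
      stem <- substr(target, nchar(target) - nchar(core) - ext + 2L, nchar(target))
      pos <- nchar(target) - nchar(core) - ext + 1L
      target_base <- substr(target, pos, pos)
      cands <- paste0(DNA_BASES, stem)
    }
    rows <- c(rows, lapply(seq_along(DNA_BASES), function(b) {
      eval_candidate(cands[b], as.integer(ext), DNA_BASES[b],
                     DNA_BASES[b] == target_base)
    }))
  }
  bind_rows(rows)
}

#' All single-base variants of a motif
#'
#' Enumerates the `3 * nchar(motif)` sequences differing from the motif at
#' exactly one position. `disrupts_cg` flags variants whose substitution
#' destroys a CG dinucleotide present in the original motif.
#'
#' @param motif Literal motif.
#' @return Tibble with `variant`, `changed_position` (1-based),
#'   `original_base`, `new_base`, `disrupts_cg`.
#' @export
one_bp_variants <- function(motif) {
  stopifnot(grepl("^[ACGT]+$", motif))
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  cg_at <- as.integer(gregexpr("CG", motif, fixed = TRUE)[[1]])
  cg_at <- cg_at[cg_at > 0]
  cg_positions <- unique(c(cg_at, cg_at + 1L))  # bases that are part of a CG
  rows <- lapply(seq_along(chars), function(p) {
    subs <- setdiff(DNA_BASES, chars[p])
    vars <- vapply(subs, function(b) {
      v <- chars; v[p] <- b; paste(v, collapse = "")
    }, character(1))
    tibble(variant = unname(vars), changed_position = p,
           original_base = chars[p], new_base = subs,
           disrupts_cg = p %in% cg_positions)
  })
  bind_rows(rows)
}

#' Scan for pairs of CG dinucleotides at fixed gaps
#'
#' Counts plus-strand matches of `CG-Ng-CG` (two CG dinucleotides separated
#' by `g` arbitrary bases) for each gap in `gaps`, together with the
#' fraction of matches whose start base lies in a region set. Overlapping
#' windows all count. With `exclude_internal_cg`, windows whose gap bases
#' contain a complete CG are skipped, isolating sequences with exactly the
#' flanking pair.
#'
#' @param genome Genome tibble.
#' @param regions Optional BED-style region tibble.
#' @param gaps Integer vector of gap lengths (default 0 to 9).
#' @param exclude_internal_cg Skip windows with a CG inside the gap.
#' @param unmasked_only Exclude windows overlapping masked or `N` bases.
#' @return Tibble with `gap`, `genome_count`, `region_count`, `fraction`.
#' @examples
#' g <- tibble::tibble(id = "m", sequence = "CGGAAGTGACG")
#' cg_pair_scan(g)  # registers only at gap 7
#' @export
cg_pair_scan <- function(genome, regions = NULL, gaps = 0:9,
                         exclude_internal_cg = FALSE, unmasked_only = TRUE) {
  stopifnot(all(gaps >= 0))
  excl <- if (unmasked_only) masked_positions(genome) else NULL
  per_chrom <- lapply(seq_len(nrow(genome)), function(i) {
    s <- genome$sequence[i]
    L <- nchar(s)
    cg1 <- as.integer(gregexpr("CG", s, fixed = TRUE)[[1]])
    cg1 <- cg1[cg1 > 0]
    is_cg <- rep(FALSE, max(L, 1L))
    is_cg[cg1] <- TRUE
    rows <- lapply(gaps, function(g) {
      span <- g + 4L
      if (L < span || length(cg1) == 0) {
        return(tibble(chrom = genome$id[i], gap = as.integer(g),
                      start = integer(0)))
      }
      p <- cg1[cg1 + g + 2L <= L]
      p <- p[is_cg[p + g + 2L]]
      if (exclude_internal_cg && g >= 2 && length(p) > 0) {
        internal <- vapply(p, function(q) any(is_cg[(q + 2L):(q + g)]),
                           logical(1))
        p <- p[!internal]
      }
      if (unmasked_only && length(p) > 0) {
        bad <- overlaps_sorted(excl[[i]], p, p + span - 1L)
        p <- p[!bad]
      }
      tibble(chrom = genome$id[i], gap = as.integer(g), start = p - 1L)
    })
    bind_rows(rows)
  })
  hits <- bind_rows(per_chrom)
  out <- lapply(gaps, function(g) {
    h <- hits[hits$gap == g, , drop = FALSE]
    in_reg <- if (is.null(regions)) rep(FALSE, nrow(h)) else
      positions_in_regions(h$chrom, h$start, regions)
    tibble(gap = as.integer(g), genome_count = nrow(h),
           region_count = sum(in_reg),
           fraction = if (nrow(h) == 0) 0 else mean(in_reg))
  })
  bind_rows(out)
}

#' Tally the two bases following a motif prefix
#'
#' For every occurrence of `prefix` on either strand, reads the next two
#' bases in the orientation of the match and tallies the 16 dinucleotides.
#' Occurrences too close to a sequence end (or whose following bases are
#' masked or `N`) are skipped. Optionally restricted to occurrences whose
#' start base lies in a region set.
#'
#' @param prefix Literal motif prefix (length >= 4).
#' @param genome Genome tibble.
#' @param regions Optional BED-style region tibble restricting occurrences.
#' @param unmasked_only Passed to [find_occurrences()] and applied to the
#'   following bases.
#' @return Tibble with `dinucleotide` (all 16) and `count`; counts sum to
#'   the number of tallied occurrences.
#' @export
following_dinucleotides <- function(prefix, genome, regions = NULL,
                                    unmasked_only = TRUE) {
  occ <- find_occurrences(prefix, genome, unmasked_only)
  if (!is.null(regions) && nrow(occ) > 0) {
    occ <- occ[positions_in_regions(occ$chrom, occ$start, regions), ,
               drop = FALSE]
  }
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  counts <- setNames(rep(0L, 16L), sort(dinucs))
  excl <- if (unmasked_only) masked_positions(genome) else NULL
  chrom_idx <- match(occ$chrom, genome$id)
  for (i in seq_len(nrow(occ))) {
    ci <- chrom_idx[i]
    s <- genome$sequence[ci]
    if (occ$strand[i] == "+") {
      from <- occ$end[i] + 1L; to <- occ$end[i] + 2L      # 1-based
      if (to > nchar(s)) next
      d <- substr(s, from, to)
    } else {
      to <- occ$start[i]; from <- occ$start[i] - 1L       # 1-based
      if (from < 1L) next
      d <- revcomp(substr(s, from, to))
    }
    if (grepl("N", d, fixed = TRUE)) next
    if (unmasked_only && overlaps_sorted(excl[[ci]], from, to)) next
    counts[d] <- counts[d] + 1L
  }
  tibble(dinucleotide = names(counts), count = as.integer(counts))
}
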