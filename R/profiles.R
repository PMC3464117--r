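#' Per-position score profile around motif occurrences
#'
#' Averages a per-base score track (conservation, typically) over all
#' occurrences of a motif, position by position, including `flank` bases on
#' each side. Minus-strand occurrences contribute their window reversed, so
#' profile position 1 is always the 5' flank end in motif orientation.
#' Bases without track data are skipped for that occurrence only; a profile
#' position with no contributing occurrence is reported with `mean_score`
#' absent (`NA`), never 0. Negative scores pass through unchanged (in
#' phyloP terms, faster-than-neutral evolution).
#'
#' @param occurrences A [find_occurrences()] result (single motif).
#' @param track Score track tibble (`chrom`, `start`, `values`) as from
#'   [read_fixedstep_track()] or [generate_track()].
#' @param flank Bases of flank on each side (default 15).
#' @return A tibble of class `position_profile`: `position` (offset from
#'   the motif's first base, motif orientation; flanks negative / beyond
#'   motif length), `in_motif`, `mean_score`, `n_contributing`.
#' @export
position_profile <- function(occurrences, track, flank = 15L) {
  stopifnot(flank >= 0)
  if (nrow(occurrences) == 0) abort("no occurrences to profile")
  motif_len <- unique(nchar(occurrences$site))
  if (length(motif_len) != 1) {
    abort("occurrences must all have the same site length")
  }
  width <- motif_len + 2L * flank
  scores <- track_score_vectors(track)
  sum_v <- rep(0, width)
  n_v <- rep(0L, width)
  for (i in seq_len(nrow(occurrences))) {
    v <- scores[[occurrences$chrom[i]]]
    if (is.null(v)) next
    from0 <- occurrences$start[i] - flank          # 0-based window start
    idx <- from0 + seq_len(width)                  # 1-based positions
    w <- rep(NA_real_, width)
    ok <- idx >= 1L & idx <= length(v)
    w[ok] <- v[idx[ok]]
    if (occurrences$strand[i] == "-") w <- rev(w)
    have <- !is.na(w)
    sum_v[have] <- sum_v[have] + w[have]
    n_v[have] <- n_v[have] + 1L
  }
  out <- tibble(
    position = seq_len(width) - flank - 1L,
    in_motif = seq_len(width) > flank & seq_len(width) <= flank + motif_len,
    mean_score = ifelse(n_v > 0, sum_v / n_v, NA_real_),
    n_contributing = n_v
  )
  attr(out, "motif") <- occurrences$motif[1]
  attr(out, "flank") <- as.integer(flank)
  class(out) <- c("position_profile", class(out))
  out
}

#' Classify the CpG methylation status of motif occurrences
#'
#' For each occurrence, looks up the methylation call of every CG in its
#' plus-strand site (keyed by the 0-based position of the C) and derives a
#' status: `unmethylated` when every CG has coverage of at least
#' `min_coverage` reads and methylation fraction at most
#' `unmethylated_max`; `methylated` when every CG has such coverage and
#' fraction at least `1 - unmethylated_max`; `insufficient` when any CG
#' lacks coverage (or the site contains no CG at all); `mixed` otherwise.
#' Only plus-strand C positions are keyed; merge strand-symmetric bisulfite
#' calls upstream if needed.
#'
#' @param occurrences A [find_occurrences()] result.
#' @param calls Methylation call tibble (`chrom`, `pos`, `meth_reads`,
#'   `total_reads`).
#' @param unmethylated_max Fraction at or below which a CG counts as
#'   unmethylated (default 0.2).
#' @param min_coverage Minimum reads for a usable call (default 5).
#' @return The occurrences tibble with added columns `n_cg`, `status` and
#'   `cg_calls` (list of per-CG tibbles: `offset`, `pos`, `meth_reads`,
#'   `total_reads`, `fraction`).
#' @export
classify_methylation <- function(occurrences, calls, unmethylated_max = 0.2,
                                 min_coverage = 5L) {
  stopifnot(unmethylated_max >= 0, unmethylated_max <= 1, min_coverage >= 0)
  key <- paste(calls$chrom, calls$pos)
  statuses <- character(nrow(occurrences))
  cg_list <- vector("list", nrow(occurrences))
  n_cg <- integer(nrow(occurrences))
  for (i in seq_len(nrow(occurrences))) {
    site <- occurrences$site[i]
    offs <- as.integer(gregexpr("CG", site, fixed = TRUE)[[1]])
    offs <- offs[offs > 0] - 1L                      # 0-based within site
    n_cg[i] <- length(offs)
    if (length(offs) == 0) {
      statuses[i] <- "insufficient"
      cg_list[[i]] <- tibble(offset = integer(), pos = integer(),
                             meth_reads = integer(), total_reads = integer(),
                             fraction = numeric())
      next
    }
    pos <- occurrences$start[i] + offs
    j <- match(paste(occurrences$chrom[i], pos), key)
    meth <- ifelse(is.na(j), NA_integer_, calls$meth_reads[j])
    total <- ifelse(is.na(j), 0L, calls$total_reads[j])
    frac <- ifelse(total > 0, meth / total, NA_real_)
    cg_list[[i]] <- tibble(offset = offs, pos = pos,
                           meth_reads = meth, total_reads = total,
                           fraction = frac)
    covered <- total >= min_coverage
    statuses[i] <- if (!all(covered)) {
      "insufficient"
    } else if (isTRUE(all(frac <= unmethylated_max))) {
      "unmethylated"
    } else if (isTRUE(all(frac >= 1 - unmethylated_max))) {
      "methylated"
    } else {
      "mixed"
    }
  }
  out <- occurrences
  out$n_cg <- n_cg
  out$status <- factor(statuses, levels = methylation_status_levels())
  out$cg_calls <- cg_list
  class(out) <- setdiff(class(out), "motif_occurrences")
  class(out) <- c("occurrence_methylation", class(out))
  out
}

methylation_status_levels <- function() {
  c("unmethylated", "methylated", "mixed", "insufficient")
}

#' Methylation summary of a motif across cell types
#'
#' Scans the genome for a motif, classifies every occurrence's methylation
#' status in each supplied cell type, cross-tabulates statuses across
#' cell-type pairs, and reports the region-overlap fraction per status
#' (testing whether unmethylated occurrences concentrate in regulatory
#' regions).
#'
#' @param motif Literal motif.
#' @param genome Genome tibble.
#' @param calls Named list of methylation call tibbles, one per cell type.
#' @param regions Optional BED-style region tibble.
#' @param unmethylated_max,min_coverage Passed to [classify_methylation()].
#' @param unmasked_only Passed to [find_occurrences()].
#' @return An object of class `methylation_summary`: list with
#'   `occurrences` (per cell type classification columns),
#'   `status_counts`, `cross_tab` (all cell-type pairs) and
#'   `region_fraction` (per cell type and status).
#' @export
methylation_summary <- function(motif, genome, calls, regions = NULL,
                                unmethylated_max = 0.2, min_coverage = 5L,
                                unmasked_only = TRUE) {
  stopifnot(is.list(calls), length(calls) >= 1, !is.null(names(calls)))
  occ <- find_occurrences(motif, genome, unmasked_only)
  per_type <- lapply(calls, function(ct) {
    classify_methylation(occ, ct, unmethylated_max, min_coverage)$status
  })
  status_tbl <- occ
  for (nm in names(per_type)) status_tbl[[paste0("status_", nm)]] <- per_type[[nm]]
  status_counts <- bind_rows(lapply(names(per_type), function(nm) {
    tibble(cell_type = nm, status = factor(methylation_status_levels(),
                                           levels = methylation_status_levels()),
           n = as.integer(table(per_type[[nm]])))
  }))
  cross <- list()
  nms <- names(per_type)
  if (length(nms) >= 2) {
    for (a in seq_along(nms)) {
      for (b in seq_along(nms)) {
        if (a >= b) next
        tab <- as.data.frame(table(per_type[[nms[a]]], per_type[[nms[b]]]),
                             stringsAsFactors = FALSE)
        names(tab) <- c("status_a", "status_b", "n")
        cross[[length(cross) + 1L]] <-
          mutate(as_tibble(tab), cell_a = nms[a], cell_b = nms[b],
                 .before = 1)
      }
    }
  }
  inside <- positions_in_regions(occ$chrom, occ$start, regions)
  region_fraction <- bind_rows(lapply(nms, function(nm) {
    st <- per_type[[nm]]
    bind_rows(lapply(methylation_status_levels(), function(lev) {
      sel <- st == lev
      tibble(cell_type = nm, status = lev, n = sum(sel),
             in_region = sum(inside[sel]),
             fraction = if (sum(sel) == 0) NA_real_ else mean(inside[sel]))
    }))
  }))
  structure(
    list(motif = motif, occurrences = status_tbl,
         status_counts = status_counts,
         cross_tab = if (length(cross)) bind_rows(cross) else NULL,
         region_fraction = region_fraction),
    class = "methylation_summary"
  )
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat(sprintf("<methylation_summary> %s: %d occurrences, %d cell type(s)\n",
              x$motif, nrow(x$occurrences),
              length(unique(x$status_counts$cell_type))))
  print(x$status_counts)
  invisible(x)
}

#' @rdname methylation_summary
#' @param x A `methylation_summary`.
#' @param ... Unused.
#' @export
tidy.methylation_summary <- function(x, ...) x$status_counts

#' @rdname methylation_summary
#' @export
glance.methylation_summary <- function(x, ...) {
  tibble(motif = x$motif, n_occurrences = nrow(x$occurrences),
         n_cell_types = length(unique(x$status_counts$cell_type)))
}
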