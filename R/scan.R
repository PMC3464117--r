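#' Count split 8-mer occurrences in TSS-aligned promoters
#'
#' Slides over every promoter offset `o` (0-based) where a full site of
#' length `8 + k` fits, reads the 4-mers at `o` and `o + 4 + k`, collapses
#' the ordered pair into its reverse-complement canonical class, and adds
#' one count at the bin of `o`. A forward match of a class and a forward
#' match of its reverse-complement pattern therefore both count toward the
#' class, each at the leftmost base of its site (the position of the first
#' nucleotide of the sequence, or of the last nucleotide of its
#' complement); palindromic classes count each site once. Sites containing
#' `N` anywhere (half-sites or insert) are skipped. Counting is by
#' position-indexed table lookup -- one pass over the promoters per insert
#' length, never a per-pattern rescan.
#'
#' @param promoters Tibble with a `sequence` column; all sequences must
#'   share one length divisible by `bin_width` (1500 for the standard
#'   -1000..+500 promoter window).
#' @param k Insert length (0 to 30).
#' @param bin_width Bin width in bases (default 20, giving 75 bins for a
#'   1500-base window).
#' @return An object of class `promoter_scan`: counts matrix (32,896
#'   canonical classes by bins) plus metadata. Use [tidy()] for a tibble,
#'   [bin_distribution()] for one pattern's bins, [localize_all()] for
#'   localization statistics.
#' @export
scan_promoters <- function(promoters, k, bin_width = 20L) {
  stopifnot(is_scalar_number(k), k >= 0, k <= 30)
  tb <- pattern_tables()
  n_class <- length(tb$class_ids)
  seqs <- promoters$sequence
  if (length(seqs) == 0) {
    return(new_promoter_scan(matrix(0L, n_class, 0), k, bin_width, 0L, 0L))
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1) abort("all promoter sequences must share one length")
  site_len <- 8L + as.integer(k)
  P <- L - site_len + 1L
  if (P < 1) abort(sprintf("promoters of length %d are too short for k=%d", L, k))
  n_bins <- bin_count(L, bin_width)
  m <- encode_dna_matrix(seqs)
  n <- nrow(m)
  # 4-mer codes starting at each column
  f4 <- m[, 1:(L - 3L), drop = FALSE] * 64L + m[, 2:(L - 2L), drop = FALSE] * 16L +
    m[, 3:(L - 1L), drop = FALSE] * 4L + m[, 4:L, drop = FALSE]
  ids <- f4[, 1:P, drop = FALSE] * 256L + f4[, (5L + k):(L - 3L), drop = FALSE]
  if (k > 0) {
    # cumulative N counts along each promoter; a site is dropped when its
    # insert contains N (half-site N already propagates as NA)
    cn <- t(apply(is.na(m), 1, cumsum))
    gap_n <- cn[, (1:P) + 3L + k, drop = FALSE] - cn[, (1:P) + 3L, drop = FALSE]
    ids[gap_n > 0L] <- NA_integer_
  }
  rows <- matrix(tb$row_of_id[ids + 1L], nrow = n)
  bins <- rep(((seq_len(P) - 1L) %/% bin_width) + 1L, each = n)
  comb <- as.vector(rows) + n_class * (bins - 1L)
  comb <- comb[!is.na(comb)]
  counts <- matrix(tabulate(comb, nbins = n_class * n_bins),
                   nrow = n_class, ncol = n_bins)
  new_promoter_scan(counts, k, bin_width, n, length(comb))
}

new_promoter_scan <- function(counts, k, bin_width, n_promoters, n_sites) {
  structure(
    list(counts = counts, k = as.integer(k), bin_width = as.integer(bin_width),
         n_promoters = as.integer(n_promoters), n_sites = as.integer(n_sites)),
    class = "promoter_scan"
  )
}

#' @export
print.promoter_scan <- function(x, ...) {
  cat(sprintf(
    "<promoter_scan> k=%d: %s sites from %s promoters in %d bins x %s classes\n",
    x$k, format(x$n_sites, big.mark = ","),
    format(x$n_promoters, big.mark = ","), ncol(x$counts),
    format(nrow(x$counts), big.mark = ",")
  ))
  invisible(x)
}

#' Scan promoters across a range of insert lengths
#'
#' @inheritParams scan_promoters
#' @param k_min,k_max Insert-length range (defaults 0 and 30).
#' @return A named list of [scan_promoters()] results (class
#'   `promoter_scan_set`), element `"k<k>"` for each insert length.
#' @export
scan_insert_range <- function(promoters, k_min = 0L, k_max = 30L,
                              bin_width = 20L) {
  stopifnot(k_min >= 0, k_max >= k_min)
  scans <- lapply(k_min:k_max, function(k) scan_promoters(promoters, k, bin_width))
  names(scans) <- paste0("k", k_min:k_max)
  structure(scans, class = "promoter_scan_set")
}

#' @rdname scan_promoters
#' @param x A `promoter_scan`.
#' @param ... Unused.
#' @export
tidy.promoter_scan <- function(x, ...) {
  info <- enumerate_patterns(x$k)
  totals <- as.integer(rowSums(x$counts))
  peak <- max.col(x$counts, ties.method = "first")
  info |>
    mutate(
      total = totals,
      peak_bin = as.integer(peak),
      peak_count = x$counts[cbind(seq_len(nrow(x$counts)), peak)]
    )
}

#' @rdname scan_promoters
#' @export
glance.promoter_scan <- function(x, ...) {
  tibble(
    k = x$k, n_promoters = x$n_promoters, n_sites = x$n_sites,
    n_bins = ncol(x$counts),
    n_classes = nrow(x$counts),
    n_classes_observed = sum(rowSums(x$counts) > 0)
  )
}

#' Binned positional distribution of one pattern
#'
#' @param scan A [scan_promoters()] result.
#' @param left,right 4-mers identifying the pattern (any class member; the
#'   pair is canonicalised first).
#' @return Tibble with `bin`, `bin_label` (TSS-relative) and `count`.
#' @export
bin_distribution <- function(scan, left, right) {
  stopifnot(inherits(scan, "promoter_scan"))
  cp <- canonical_pattern(left, right, scan$k)
  tb <- pattern_tables()
  f <- all_fourmers()
  id <- (match(cp$left, f) - 1L) * 256L + (match(cp$right, f) - 1L)
  row <- tb$row_of_id[id + 1L]
  n_bins <- ncol(scan$counts)
  tibble(
    bin = seq_len(n_bins),
    bin_label = bin_labels(n_bins * scan$bin_width, scan$bin_width),
    count = as.integer(scan$counts[row, ])
  )
}
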