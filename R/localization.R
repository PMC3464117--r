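#' Localization factor of a binned distribution
#'
#' The localization factor (LF) is the peak bin count divided by the mean
#' bin count: 1 for a perfectly uniform distribution, equal to the number
#' of bins when every occurrence falls in one bin, and 0 for an empty
#' distribution. It is invariant under scaling all bin counts by a common
#' factor.
#'
#' @param counts Integer vector of per-bin counts, or a matrix with one
#'   row per pattern (the statistic is computed row-wise).
#' @return Numeric LF value(s).
#' @examples
#' localization_factor(rep(4, 75))            # 1
#' localization_factor(c(30, rep(0, 74)))     # 75
#' @export
localization_factor <- function(counts) {
  if (is.matrix(counts)) {
    total <- rowSums(counts)
    mx <- do.call(pmax, lapply(seq_len(ncol(counts)), function(j) counts[, j]))
    ifelse(total == 0, 0, mx / (total / ncol(counts)))
  } else {
    total <- sum(counts)
    if (total == 0) return(0)
    max(counts) / (total / length(counts))
  }
}

#' Non-uniformity P-value of a binned distribution
#'
#' Bonferroni-corrected exact binomial tail: with `B` bins and `n` total
#' occurrences, `P = min(1, B * Pr[Binomial(n, 1/B) >= max(counts)])`.
#' Returns 1 for an empty distribution. Monotonically decreasing in the
#' peak count at fixed total.
#'
#' @inheritParams localization_factor
#' @return Numeric P-value(s) in `[0, 1]`.
#' @examples
#' localization_pvalue(c(10, rep(0, 74)))   # 75 * (1/75)^10
#' @export
localization_pvalue <- function(counts) {
  if (is.matrix(counts)) {
    nb <- ncol(counts)
    total <- rowSums(counts)
    mx <- do.call(pmax, lapply(seq_len(nb), function(j) counts[, j]))
    p <- pmin(1, nb * pbinom(mx - 1, total, 1 / nb, lower.tail = FALSE))
    ifelse(total == 0, 1, p)
  } else {
    nb <- length(counts)
    total <- sum(counts)
    if (total == 0) return(1)
    min(1, nb * pbinom(max(counts) - 1, total, 1 / nb, lower.tail = FALSE))
  }
}

#' Localization statistics for every pattern class of one scan
#'
#' Computes LF, the non-uniformity P-value, and the peak bin for every
#' canonical pattern class. Classes with fewer than `min_total` occurrences
#' are reported with `lf`/`p_value` absent (`NA`): LF on tiny totals is
#' dominated by shot noise. Results are sorted by descending LF, ties
#' broken lexicographically by pattern; peak-bin ties take the smallest bin
#' index.
#'
#' @param scan A [scan_promoters()] result.
#' @param min_total Minimum occurrences for a reported statistic
#'   (default 50).
#' @return A tibble of class `localization_results`: `pattern`, `left`,
#'   `right`, `insert_len`, `contains_cg`, `total`, `lf`, `p_value`,
#'   `neg_log10_p`, `peak_bin`.
#' @export
localize_all <- function(scan, min_total = 50L) {
  stopifnot(inherits(scan, "promoter_scan"))
  if (scan$n_promoters == 0 || ncol(scan$counts) == 0) {
    out <- tibble(pattern = character(), left = character(),
                  right = character(), insert_len = integer(),
                  contains_cg = logical(), total = integer(), lf = numeric(),
                  p_value = numeric(), neg_log10_p = numeric(),
                  peak_bin = integer())
    class(out) <- c("localization_results", class(out))
    return(out)
  }
  info <- tidy(scan)
  lf <- localization_factor(scan$counts)
  p <- localization_pvalue(scan$counts)
  ok <- info$total >= min_total
  out <- info |>
    mutate(
      lf = ifelse(ok, lf, NA_real_),
      p_value = ifelse(ok, p, NA_real_),
      neg_log10_p = -log10(.data$p_value),
      peak_bin = .data$peak_bin
    ) |>
    select("pattern", "left", "right", "insert_len", "contains_cg",
           "total", "lf", "p_value", "neg_log10_p", "peak_bin") |>
    arrange(desc(.data$lf), .data$pattern)
  class(out) <- c("localization_results", class(out))
  out
}

#' Insert-length LF profiles for every 4-mer pair
#'
#' For each canonical pair of 4-mers, takes the LF of its class at every
#' scanned insert length (classes below `min_total` occurrences contribute
#' LF 0), finds the insert length with the maximal LF, and forms the
#' ratio of the maximal LF to the second-highest. A ratio near 1 marks a
#' pair that co-occurs at many spacings; a large ratio marks localization
#' at one precise spacing. When only one insert length has any signal the
#' ratio is `Inf` (serialised as the string `"inf"` in TSV output and
#' ordered above every finite ratio); a pair with no signal anywhere has
#' `lf_max` 0 and an undefined (`NA`) ratio.
#'
#' @param scans A [scan_insert_range()] result (scans over consecutive
#'   insert lengths).
#' @param min_total Minimum occurrences for a class to contribute its LF.
#' @return A tibble of class `insert_profiles`: `left`, `right`,
#'   `lf_by_k` (matrix column, one column per insert length), `k_max`,
#'   `lf_max`, `lf_second`, `ratio`, `p_at_kmax`, `total_at_kmax`.
#' @export
insert_profiles <- function(scans, min_total = 50L) {
  stopifnot(length(scans) >= 2)
  ks <- unname(vapply(scans, function(s) s$k, integer(1)))
  tb <- pattern_tables()
  n_class <- length(tb$class_ids)
  lf_mat <- matrix(0, nrow = n_class, ncol = length(ks),
                   dimnames = list(NULL, paste0("k", ks)))
  p_mat <- matrix(NA_real_, nrow = n_class, ncol = length(ks))
  tot_mat <- matrix(0L, nrow = n_class, ncol = length(ks))
  for (j in seq_along(scans)) {
    s <- scans[[j]]
    tot <- rowSums(s$counts)
    lf <- localization_factor(s$counts)
    lf[tot < min_total] <- 0
    lf_mat[, j] <- lf
    p_mat[, j] <- localization_pvalue(s$counts)
    tot_mat[, j] <- as.integer(tot)
  }
  k_idx <- max.col(lf_mat, ties.method = "first")
  lf_max <- lf_mat[cbind(seq_len(n_class), k_idx)]
  second <- vapply(seq_len(n_class), function(i) {
    max(lf_mat[i, -k_idx[i]])
  }, numeric(1))
  ratio <- ifelse(lf_max == 0, NA_real_,
                  ifelse(second == 0, Inf, lf_max / second))
  out <- tibble(
    left = tb$left,
    right = tb$right,
    k_max = ks[k_idx],
    lf_max = lf_max,
    lf_second = second,
    ratio = ratio,
    p_at_kmax = p_mat[cbind(seq_len(n_class), k_idx)],
    total_at_kmax = tot_mat[cbind(seq_len(n_class), k_idx)]
  )
  out$lf_by_k <- lf_mat
  attr(out, "ks") <- ks
  attr(out, "min_total") <- min_total
  class(out) <- c("insert_profiles", class(out))
  out
}

#' Insert profile of one 4-mer pair
#'
#' @param profiles An [insert_profiles()] result.
#' @param left,right 4-mers (any class member; canonicalised first).
#' @return Tibble with `insert_len` and `lf` (long format, one row per
#'   scanned insert length), plus the pair's summary as attributes.
#' @export
insert_profile <- function(profiles, left, right) {
  stopifnot(inherits(profiles, "insert_profiles"))
  cp <- canonical_pattern(left, right, 0)
  i <- which(profiles$left == cp$left & profiles$right == cp$right)
  if (length(i) != 1) abort("pair not found in profiles")
  ks <- attr(profiles, "ks")
  out <- tibble(left = cp$left, right = cp$right, insert_len = ks,
                lf = as.numeric(profiles$lf_by_k[i, ]))
  attr(out, "summary") <- profiles[i, setdiff(names(profiles), "lf_by_k")]
  class(out) <- c("insert_profile", class(out))
  out
}

#' Select patterns that localize at a unique insert length
#'
#' Filters insert profiles to those with a high maximal LF, a high
#' max-to-second ratio (localization at one precise spacing), and a
#' significant non-uniformity P-value at the best insert length; sorts by
#' descending ratio then LF. `Inf` ratios (signal at a single insert
#' length only) order above every finite ratio.
#'
#' @param profiles An [insert_profiles()] result.
#' @param lf_min Minimum `lf_max`.
#' @param ratio_min Minimum `ratio`.
#' @param p_max Maximum P-value at the best insert length.
#' @return Filtered and sorted `insert_profiles` tibble.
#' @export
select_unique_localizers <- function(profiles, lf_min = 2, ratio_min = 2,
                                     p_max = 0.01) {
  stopifnot(lf_min >= 0, ratio_min >= 0, p_max > 0)
  out <- profiles |>
    filter(.data$lf_max >= lf_min,
           !is.na(.data$ratio), .data$ratio >= ratio_min,
           !is.na(.data$p_at_kmax), .data$p_at_kmax <= p_max) |>
    arrange(desc(.data$ratio), desc(.data$lf_max))
  out
}

#' @rdname insert_profiles
#' @param x An `insert_profiles` object.
#' @param ... Unused.
#' @export
tidy.insert_profiles <- function(x, ...) {
  ks <- attr(x, "ks")
  lf <- x$lf_by_k
  tibble(
    left = rep(x$left, times = length(ks)),
    right = rep(x$right, times = length(ks)),
    insert_len = rep(ks, each = nrow(x)),
    lf = as.numeric(lf)
  )
}

#' @rdname insert_profiles
#' @export
glance.insert_profiles <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    k_min = min(attr(x, "ks")), k_max = max(attr(x, "ks")),
    min_total = attr(x, "min_total"),
    n_with_signal = sum(x$lf_max > 0)
  )
}

# serialise Inf ratios as "inf" for TSV output
format_ratio <- function(ratio) {
  ifelse(is.na(ratio), NA_character_,
         ifelse(is.infinite(ratio), "inf", format(ratio, digits = 6)))
}
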