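#' Plot the binned promoter distribution of one pattern
#'
#' Bar chart of a pattern's occurrence counts across the promoter bins,
#' with TSS-relative bin boundaries on the x axis.
#'
#' @param scan A [scan_promoters()] result.
#' @param left,right 4-mers identifying the pattern.
#' @return A ggplot object.
#' @export
plot_bin_distribution <- function(scan, left, right) {
  d <- bin_distribution(scan, left, right)
  lab <- canonical_pattern(left, right, scan$k)$pattern
  breaks <- d$bin[seq(1, nrow(d), by = max(1, nrow(d) %/% 10))]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::scale_x_continuous(breaks = breaks,
                                labels = d$bin_label[breaks]) +
    ggplot2::labs(x = "promoter bin (TSS-relative)", y = "occurrences",
                  title = lab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname insert_profile
#' @param object An `insert_profile` (single pair).
#' @param ... Unused.
#' @export
autoplot.insert_profile <- function(object, ...) {
  s <- attr(object, "summary")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$insert_len, y = .data$lf)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object[object$insert_len == s$k_max, ],
                        colour = "red", size = 2) +
    ggplot2::labs(x = "insert length (bp)", y = "localization factor",
                  title = sprintf("%s-Nk-%s (peak at k=%d)",
                                  object$left[1], object$right[1], s$k_max)) +
    ggplot2::theme_minimal()
}

#' @rdname localize_all
#' @param object A `localization_results` tibble.
#' @param ... Unused.
#' @export
autoplot.localization_results <- function(object, ...) {
  d <- object[!is.na(object$lf), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lf, y = .data$neg_log10_p,
                                  colour = .data$contains_cg)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::labs(x = "localization factor", y = "-log10 P",
                  colour = "contains CG") +
    ggplot2::theme_minimal()
}

#' @rdname insert_profiles
#' @param object An `insert_profiles` tibble.
#' @export
autoplot.insert_profiles <- function(object, ...) {
  d <- object[object$lf_max > 0 & !is.na(object$ratio), , drop = FALSE]
  cap <- max(d$ratio[is.finite(d$ratio)], 1)
  d$ratio_capped <- pmin(d$ratio, cap)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lf_max, y = .data$ratio_capped)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "LF(Max)", y = "LF(Max) / LF(Max-1)") +
    ggplot2::theme_minimal()
}

#' @rdname position_profile
#' @param object A `position_profile`.
#' @param ... Unused.
#' @export
autoplot.position_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$mean_score)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_motif), size = 1,
                        na.rm = TRUE) +
    ggplot2::labs(x = "position (motif orientation)", y = "mean score",
                  colour = "in motif",
                  title = attr(object, "motif")) +
    ggplot2::theme_minimal()
}
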