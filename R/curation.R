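#' Promoter set curation
#'
#' Five sequential filters clean a raw TSS-aligned promoter set before
#' positional analysis: (1) drop exact sequence duplicates, keeping the
#' first copy; (2) drop promoters containing a run of at least 150
#' consecutive N; (3) drop every record whose identifier occurs more than
#' once; (4) collapse "closely identical" promoters -- records linked by an
#' exact shared substring of at least 250 bases -- keeping one
#' representative per connected component, after removing records with more
#' than 10 such links; (5) drop promoters whose coding start lies within 30
#' bases of the TSS. [curate()] runs all five in order and returns an
#' accounting report alongside the curated records.
#'
#' @name promoter-curation
NULL

#' Drop promoters with 100% identical sequences
#'
#' Exactly one record per distinct sequence is kept (the first encountered).
#'
#' @param records Tibble with at least `id` and `sequence`.
#' @return Filtered tibble.
#' @export
drop_identical_duplicates <- function(records) {
  records[!duplicated(records$sequence), , drop = FALSE]
}

#' Drop promoters containing long runs of unknown bases
#'
#' Removes records containing a maximal run of at least `min_run`
#' consecutive `N` (a run, not a total count).
#'
#' @param records Tibble with `sequence`.
#' @param min_run Minimum run length triggering removal (default 150).
#' @return Filtered tibble.
#' @export
drop_long_n_runs <- function(records, min_run = 150L) {
  bad <- grepl(sprintf("N{%d,}", min_run), records$sequence)
  records[!bad, , drop = FALSE]
}

#' Drop all records with duplicated identifiers
#'
#' Every record whose `id` occurs more than once is removed entirely.
#'
#' @param records Tibble with `id`.
#' @return Filtered tibble.
#' @export
drop_duplicate_ids <- function(records) {
  dup <- records$id %in% records$id[duplicated(records$id)]
  records[!dup, , drop = FALSE]
}

# all distinct substrings of length k of one sequence
substrings_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# union-find root lookup (pure; components are tiny, no compression needed)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Collapse closely identical promoters
#'
#' Two records are linked when they share an exact common substring of at
#' least `min_shared` bases. Records linked to more than `max_links` other
#' records are removed before grouping. Remaining linked records are
#' grouped into connected components, and one representative per component
#' (the lexicographically smallest `id`) is kept; records named in
#' `keep_list` are retained even when they are non-representative members
#' (the escape hatch for promoters admitted despite mixed overlapping
#' sequence, for which no mechanical rule exists).
#'
#' @param records Tibble with `id`, `sequence`.
#' @param min_shared Minimum shared exact substring length (default 250).
#' @param max_links Maximum allowed duplication links per record
#'   (default 10).
#' @param keep_list Character vector of ids to retain regardless.
#' @return A list with `records` (filtered tibble) and `groups` (tibble
#'   `group`, `id`, `representative`, `kept`).
#' @export
collapse_near_duplicates <- function(records, min_shared = 250L,
                                     max_links = 10L, keep_list = NULL) {
  n <- nrow(records)
  empty_groups <- tibble(group = integer(), id = character(),
                         representative = character(), kept = logical())
  if (n < 2) return(list(records = records, groups = empty_groups))
  # a shared substring >= min_shared exists iff some window of exactly
  # min_shared bases is shared
  kmer_tbl <- bind_rows(lapply(seq_len(n), function(i) {
    km <- substrings_of(records$sequence[i], min_shared)
    if (length(km) == 0) return(NULL)
    tibble(kmer = km, idx = i)
  }))
  if (is.null(kmer_tbl) || nrow(kmer_tbl) == 0) {
    return(list(records = records, groups = empty_groups))
  }
  pairs <- kmer_tbl |>
    dplyr::inner_join(kmer_tbl, by = "kmer", relationship = "many-to-many") |>
    filter(.data$idx.x < .data$idx.y) |>
    distinct(.data$idx.x, .data$idx.y)
  if (nrow(pairs) == 0) return(list(records = records, groups = empty_groups))
  links_per <- tabulate(c(pairs$idx.x, pairs$idx.y), nbins = n)
  hub <- links_per > max_links
  pairs <- pairs[!hub[pairs$idx.x] & !hub[pairs$idx.y], , drop = FALSE]
  parent <- seq_len(n)
  for (r in seq_len(nrow(pairs))) {
    a <- uf_find(parent, pairs$idx.x[r])
    b <- uf_find(parent, pairs$idx.y[r])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  linked <- tabulate(root, nbins = n)[root] > 1L
  if (!any(linked)) {
    kept <- if (any(hub)) records[-which(hub), , drop = FALSE] else records
    return(list(records = kept, groups = empty_groups))
  }
  groups <- tibble(idx = which(linked), root = root[linked]) |>
    mutate(id = records$id[.data$idx]) |>
    group_by(.data$root) |>
    mutate(representative = min(.data$id)) |>
    ungroup() |>
    mutate(group = match(.data$root, unique(.data$root)),
           kept = .data$id == .data$representative |
             .data$id %in% (keep_list %||% character(0))) |>
    select("group", "id", "representative", "kept")
  drop_idx <- which(hub)
  drop_idx <- union(drop_idx, which(linked)[!groups$kept])
  kept_records <- if (length(drop_idx)) records[-drop_idx, , drop = FALSE] else records
  list(records = kept_records, groups = groups)
}

#' Drop promoters whose coding start is TSS-proximal
#'
#' Removes records with `|cds_offset| <= max_offset`; records lacking a
#' coding-start annotation are kept.
#'
#' @param records Tibble with optional column `cds_offset` (bases relative
#'   to the TSS).
#' @param max_offset Inclusive threshold (default 30).
#' @return Filtered tibble.
#' @export
drop_tss_proximal_cds <- function(records, max_offset = 30L) {
  if (is.null(records[["cds_offset"]])) return(records)
  bad <- !is.na(records$cds_offset) & abs(records$cds_offset) <= max_offset
  records[!bad, , drop = FALSE]
}

#' Curate a promoter set and account for every removal
#'
#' Applies the five filters of [promoter-curation] in order and returns the
#' curated records together with a one-row accounting report. Every removal
#' is logged, so `input_count` always equals `final_count` plus the sum of
#' all removals.
#'
#' @param records Tibble with `id`, `sequence`, optional `cds_offset`.
#' @param min_run,min_shared,max_links,max_offset Filter thresholds (see
#'   the individual filter functions).
#' @param keep_list Ids retained through near-duplicate collapsing despite
#'   being non-representative group members.
#' @return An object of class `curation`: a list with `records`, `report`
#'   (one-row tibble) and `groups`.
#' @export
curate <- function(records, min_run = 150L, min_shared = 250L,
                   max_links = 10L, max_offset = 30L, keep_list = NULL) {
  input_count <- nrow(records)
  r1 <- drop_identical_duplicates(records)
  r2 <- drop_long_n_runs(r1, min_run)
  r3 <- drop_duplicate_ids(r2)
  cc <- collapse_near_duplicates(r3, min_shared, max_links, keep_list)
  r4 <- cc$records
  hub_removed <- nrow(r3) - nrow(r4) -
    (sum(!cc$groups$kept))
  reps_kept <- sum(cc$groups$kept & cc$groups$id == cc$groups$representative)
  mixed_kept <- sum(cc$groups$kept & cc$groups$id != cc$groups$representative)
  r5 <- drop_tss_proximal_cds(r4, max_offset)
  report <- tibble(
    input_count = input_count,
    removed_identical = input_count - nrow(r1),
    removed_n_runs = nrow(r1) - nrow(r2),
    removed_dup_refseq = nrow(r2) - nrow(r3),
    removed_many_overlaps = hub_removed,
    linked_members = nrow(cc$groups),
    group_representatives_kept = reps_kept,
    retained_mixed = mixed_kept,
    removed_group_members = sum(!cc$groups$kept),
    removed_tss_proximal_cds = nrow(r4) - nrow(r5),
    final_count = nrow(r5)
  )
  structure(list(records = r5, report = report, groups = cc$groups),
            class = "curation")
}

#' @export
print.curation <- function(x, ...) {
  cat("Promoter curation:", x$report$input_count, "->",
      x$report$final_count, "records\n")
  print(x$report)
  invisible(x)
}

#' @rdname curate
#' @param x A `curation` object.
#' @param ... Unused.
#' @export
tidy.curation <- function(x, ...) {
  tidyr::pivot_longer(x$report, dplyr::everything(),
                      names_to = "step", values_to = "count")
}

#' @rdname curate
#' @export
glance.curation <- function(x, ...) x$report

#' Curation accounting arithmetic
#'
#' The curated set size implied by the step counts: promoters with unique
#' sequences, plus duplicated-group promoters retained (representatives and
#' explicitly kept members), minus promoters removed for a TSS-proximal
#' coding start.
#'
#' @param unique_kept Count of promoters with unique sequences.
#' @param retained_duplicates Duplicated-group promoters retained.
#' @param removed_tss_proximal_cds Promoters removed for TSS-proximal CDS.
#' @return Integer final count.
#' @examples
#' curation_accounting(18451, 1176, 2484)  # 17143
#' @export
curation_accounting <- function(unique_kept, retained_duplicates,
                                removed_tss_proximal_cds) {
  as.integer(unique_kept + retained_duplicates - removed_tss_proximal_cds)
}
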