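#' Split 8-mer pattern classes
#'
#' A split 8-mer is an ordered pair of 4-mers separated by an insert of `k`
#' unspecified bases (`X4-Nk-X4`; a continuous 8-mer when `k = 0`). Because a
#' double-stranded site is read equally well on either strand, each pattern
#' `(left, right)` is identified with its reverse-complement partner
#' `(revcomp(right), revcomp(left))`. The canonical representative of a class
#' is the member whose 8-character concatenation `left + right` is
#' lexicographically smallest; palindromic patterns (where
#' `left == revcomp(right)`) are their own representative. Collapsing all
#' 65,536 ordered pairs this way yields 32,896 classes, of which 256 are
#' palindromic, at every insert length.
#'
#' @section CG classification:
#' A class is CG-containing when its representative contains the CG
#' dinucleotide: for continuous 8-mers (`k = 0`) the test is on the full
#' 8-character word, so a CG spanning the junction of the two 4-mers counts;
#' for split patterns (`k >= 1`) only a CG inside either 4-mer counts. The
#' property is reverse-complement invariant, so it does not depend on which
#' class member is the representative.
#'
#' @name pattern-classes
NULL

# all 256 4-mers in lexicographic order; index i corresponds to code i-1
# under A=0, C=1, G=2, T=3 base-4 encoding (so string order == code order)
all_fourmers <- function() {
  cache <- .splitkmer_env$fourmers
  if (!is.null(cache)) return(cache)
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, DNA_BASES,
                   stringsAsFactors = FALSE)
  f <- do.call(paste0, g[, 4:1])
  .splitkmer_env$fourmers <- f
  f
}

# reverse-complement code of each 4-mer code (0-based, vectorised)
rc4_codes <- function() {
  cache <- .splitkmer_env$rc4
  if (!is.null(cache)) return(cache)
  code <- 0:255
  a <- code %/% 64
  b <- (code %/% 16) %% 4
  c_ <- (code %/% 4) %% 4
  d <- code %% 4
  rc <- (3 - d) * 64 + (3 - c_) * 16 + (3 - b) * 4 + (3 - a)
  .splitkmer_env$rc4 <- as.integer(rc)
  .splitkmer_env$rc4
}

# Lookup tables over all 65,536 ordered pair ids (id = left*256 + right):
#   canon : canonical pair id of each id
#   row   : class row index (1..32896) of each id, rows ordered by canonical id
pattern_tables <- function() {
  cache <- .splitkmer_env$tables
  if (!is.null(cache)) return(cache)
  rc4 <- rc4_codes()
  id <- 0:65535
  left <- id %/% 256
  right <- id %% 256
  rcid <- rc4[right + 1L] * 256L + rc4[left + 1L]
  canon <- pmin(id, rcid)
  class_ids <- sort(unique(canon))
  row_of_id <- match(canon, class_ids)
  f <- all_fourmers()
  rep_left <- class_ids %/% 256
  rep_right <- class_ids %% 256
  left_str <- f[rep_left + 1L]
  right_str <- f[rep_right + 1L]
  # palindromic class <=> the pair is its own reverse complement
  palindromic <- class_ids == (rc4[rep_right + 1L] * 256L + rc4[rep_left + 1L])
  cg_in <- grepl("CG", f, fixed = TRUE)
  cg_split <- cg_in[rep_left + 1L] | cg_in[rep_right + 1L]
  cg_continuous <- grepl("CG", paste0(left_str, right_str), fixed = TRUE)
  cache <- list(
    canon = as.integer(canon),
    row_of_id = as.integer(row_of_id),
    class_ids = as.integer(class_ids),
    left = left_str,
    right = right_str,
    palindromic = palindromic,
    cg_split = cg_split,
    cg_continuous = cg_continuous
  )
  .splitkmer_env$tables <- cache
  cache
}

pattern_label <- function(left, right, k) {
  n <- max(length(left), length(right), length(k))
  left <- rep_len(left, n)
  right <- rep_len(right, n)
  k <- rep_len(k, n)
  ifelse(k == 0, paste0(left, right), paste0(left, "-N", k, "-", right))
}

#' Enumerate canonical split 8-mer pattern classes
#'
#' Enumerates every reverse-complement equivalence class of ordered 4-mer
#' pairs at insert length `k`. There are always 32,896 classes (256 of them
#' palindromic): the class structure does not depend on `k`, only the CG
#' classification does (see [pattern-classes]).
#'
#' @param k Insert length (0 to 30).
#' @return A tibble with one row per class: `pattern`, `left`, `right`,
#'   `insert_len`, `palindromic`, `contains_cg`.
#' @seealso [pattern_class_count()] for the closed-form class-count formula.
#' @examples
#' nrow(enumerate_patterns(0))    # 32896
#' sum(enumerate_patterns(4)$palindromic)    # 256
#' @export
enumerate_patterns <- function(k) {
  stopifnot(is_scalar_number(k), k >= 0, k <= 30)
  tb <- pattern_tables()
  tibble(
    pattern = pattern_label(tb$left, tb$right, k),
    left = tb$left,
    right = tb$right,
    insert_len = as.integer(k),
    palindromic = tb$palindromic,
    contains_cg = if (k == 0) tb$cg_continuous else tb$cg_split
  )
}

#' Closed-form count of pattern classes
#'
#' The number of reverse-complement classes of ordered 4-mer pairs is
#' `(4^8 - m)/2 + m` where `m` is the number of palindromic (self
#' reverse-complement) pairs. Direct enumeration gives `m = 256` at every
#' insert length, hence 32,896 classes. A published variant of this formula
#' sets `m = 0` for odd insert lengths (giving 32,768); that convention
#' contradicts enumeration -- a pair such as `ACGT-Nk-ACGT` is its own
#' reverse complement for every `k` -- but is available through
#' `palindromes = "none_when_odd"` for comparison with tabulations that
#' used it.
#'
#' @param k Insert length.
#' @param palindromes Either `"enumerated"` (default; `m = 256` always) or
#'   `"none_when_odd"` (`m = 0` for odd `k`).
#' @return Integer class count.
#' @examples
#' pattern_class_count(0)   # 32896
#' pattern_class_count(1, palindromes = "none_when_odd")  # 32768
#' @export
pattern_class_count <- function(k, palindromes = c("enumerated", "none_when_odd")) {
  palindromes <- match.arg(palindromes)
  stopifnot(is_scalar_number(k), k >= 0)
  m <- if (palindromes == "none_when_odd" && k %% 2 == 1) 0L else 256L
  as.integer((65536L - m) / 2L + m)
}

#' Canonical representative of a split 8-mer pattern
#'
#' Collapses a pattern with its reverse-complement partner
#' `(revcomp(right), revcomp(left))` and returns the class representative
#' (the member whose concatenated 8-mer is lexicographically smallest).
#' Vectorised; idempotent.
#'
#' @param left,right 4-mers over A,C,G,T (character vectors).
#' @param k Insert length(s).
#' @return A tibble with `pattern`, `left`, `right`, `insert_len`,
#'   `palindromic`, `contains_cg`.
#' @examples
#' canonical_pattern("CGGA", "ACGT", 4)   # representative ACGT-N4-TCCG
#' @export
canonical_pattern <- function(left, right, k) {
  n <- max(length(left), length(right), length(k))
  left <- rep_len(toupper(left), n)
  right <- rep_len(toupper(right), n)
  k <- rep_len(as.integer(k), n)
  if (!all(grepl("^[ACGT]{4}$", c(left, right)))) {
    abort("`left` and `right` must be 4-mers over A,C,G,T")
  }
  tb <- pattern_tables()
  f <- all_fourmers()
  id <- (match(left, f) - 1L) * 256L + (match(right, f) - 1L)
  canon <- tb$canon[id + 1L]
  row <- tb$row_of_id[id + 1L]
  tibble(
    pattern = pattern_label(tb$left[row], tb$right[row], k),
    left = tb$left[row],
    right = tb$right[row],
    insert_len = k,
    palindromic = tb$palindromic[row],
    contains_cg = ifelse(k == 0, tb$cg_continuous[row], tb$cg_split[row])
  )
}

#' Does a pattern class contain the CG dinucleotide?
#'
#' For continuous 8-mers (`k = 0`) the test is on the concatenated 8-mer, so
#' a CG spanning the junction counts; for split patterns (`k >= 1`) only CG
#' inside either 4-mer counts. The result is a class property (invariant
#' under reverse complement).
#'
#' @inheritParams canonical_pattern
#' @return Logical vector.
#' @examples
#' contains_cg("TGAC", "GTCA", 0)  # TRUE (junction CG)
#' contains_cg("TGAC", "GTCA", 2)  # FALSE
#' @export
contains_cg <- function(left, right, k) {
  canonical_pattern(left, right, k)$contains_cg
}
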