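DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input. Accepts the alphabet `A`, `C`, `G`, `T`, `N`
#' (uppercase); `N` is its own complement.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("CGGA")       # "TCCG"
#' revcomp("TGACGTCA")   # palindromic: returns itself
#' @export
revcomp <- function(seq) {
  if (!is.character(seq)) abort("`seq` must be a character vector.")
  bad <- !grepl("^[ACGTN]*$", seq)
  if (any(bad)) {
    abort(sprintf(
      "illegal character in DNA string %s (alphabet is A,C,G,T,N)",
      deparse(seq[which(bad)[1]])
    ))
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""),
    character(1)
  )
}

# Encode an uppercase DNA string vector into a matrix of integer codes
# (A=0, C=1, G=2, T=3, N/other = NA). All strings must share one length.
encode_dna_matrix <- function(seqs) {
  if (length(seqs) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  len <- unique(nchar(seqs))
  if (length(len) != 1) abort("all sequences must have the same length")
  codes <- match(unlist(strsplit(seqs, "", fixed = TRUE)), DNA_BASES) - 1L
  matrix(codes, nrow = length(seqs), ncol = len, byrow = TRUE)
}

# Derive a deterministic per-stream seed from a root seed, so that adding
# one generator call never shifts the random stream of another.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629) + 1L
}

# round-half-up to integer percent, as printed in enrichment tables
percent_round <- function(fraction) {
  as.integer(floor(fraction * 100 + 0.5))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
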