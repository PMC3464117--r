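#' Read a FASTA file, preserving soft-masking
#'
#' Sequences are returned uppercase; soft-masked (lowercase) bases are kept
#' as a per-record list of 1-based masked positions. Only the alphabet
#' A, C, G, T, N (either case) is accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (full header text), `sequence`
#'   (uppercase) and `mask` (list of integer vectors of masked positions).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  x <- Biostrings::readBStringSet(path)
  raw <- as.character(x)
  bad <- grepl("[^ACGTNacgtn]", raw)
  if (any(bad)) {
    abort(sprintf(
      "FASTA format error in %s: record '%s' contains characters outside A,C,G,T,N",
      path, names(x)[which(bad)[1]]
    ))
  }
  mask <- lapply(raw, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] %in% c("a", "c", "g", "t", "n"))
  })
  tibble(
    id = as.character(names(x)),
    sequence = unname(toupper(raw)),
    mask = unname(mask)
  )
}

#' Write sequences to FASTA, restoring soft-masking
#'
#' @param records Tibble with `id`, `sequence` and optionally `mask` (as
#'   produced by [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  seqs <- records$sequence
  if (!is.null(records[["mask"]])) {
    seqs <- mapply(function(s, m) {
      if (length(m) == 0) return(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch[m] <- tolower(ch[m])
      paste(ch, collapse = "")
    }, seqs, records$mask, USE.NAMES = FALSE)
  }
  out <- Biostrings::BStringSet(seqs)
  names(out) <- records$id
  Biostrings::writeXStringSet(out, path, width = width)
  invisible(path)
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' Intervals are kept exactly as in the file: 0-based, half-open, with no
#' merging of overlapping lines. Lines starting with `track`, `browser` or
#' `#` are skipped. A line with `start >= end` is a format error.
#'
#' @param path Path to a BED file (tab-separated, 3 or more columns).
#' @return A tibble with `chrom`, `start`, `end`, `name` (`NA` for BED3).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  if (length(lineno) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), name = character()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED format error in %s, line %d: fewer than 3 fields",
                  path, lineno[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("BED format error in %s, line %d: non-integer coordinate",
                  path, lineno[which(is.na(start) | is.na(end))[1]]))
  }
  bad <- start >= end | start < 0
  if (any(bad)) {
    abort(sprintf("BED format error in %s, line %d: start >= end (or negative)",
                  path, lineno[which(bad)[1]]))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                 character(1)), NA_character_)
  tibble(chrom = chrom, start = start, end = end, name = name)
}

#' Write intervals to BED
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  has_name <- !is.null(regions[["name"]]) && !all(is.na(regions$name))
  cols <- if (has_name) {
    cbind(regions$chrom, regions$start, regions$end, regions$name)
  } else {
    cbind(regions$chrom, regions$start, regions$end)
  }
  writeLines(apply(cols, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a fixedStep wiggle track (step 1 only)
#'
#' Parses the fixedStep dialect of the wiggle format. Declaration starts are
#' 1-based per the wiggle standard and are converted to 0-based on read.
#' Only `step=1` (and `span=1`) is supported; anything else is an
#' unsupported-dialect error. Missing bases are simply absent from the
#' blocks (never stored as 0).
#'
#' @param path Path to a wiggle file.
#' @return A tibble with one row per block: `chrom`, `start` (0-based) and
#'   `values` (list of numeric vectors, one value per base).
#' @export
read_fixedstep_track <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  decl <- grepl("^fixedStep", lines)
  if (any(grepl("^variableStep", lines))) {
    abort("unsupported wiggle dialect: variableStep (only fixedStep step=1)")
  }
  if (length(lines) > 0 && !decl[1]) {
    abort(sprintf("wiggle format error in %s: data before first fixedStep line", path))
  }
  starts_at <- which(decl)
  if (length(starts_at) == 0) {
    return(tibble(chrom = character(), start = integer(), values = list()))
  }
  ends_at <- c(starts_at[-1] - 1L, length(lines))
  blocks <- lapply(seq_along(starts_at), function(i) {
    d <- lines[starts_at[i]]
    get_field <- function(key) {
      m <- regmatches(d, regexpr(paste0(key, "=[^ \t]+"), d))
      if (length(m) == 0) NA_character_ else sub(paste0(key, "="), "", m)
    }
    chrom <- get_field("chrom")
    start1 <- as.integer(get_field("start"))
    step <- get_field("step")
    span <- get_field("span")
    if (is.na(chrom) || is.na(start1)) {
      abort(sprintf("wiggle format error in %s: bad declaration '%s'", path, d))
    }
    if (!is.na(step) && as.integer(step) != 1L) {
      abort(sprintf("unsupported wiggle dialect in %s: step=%s (only step=1)",
                    path, step))
    }
    if (!is.na(span) && as.integer(span) != 1L) {
      abort(sprintf("unsupported wiggle dialect in %s: span=%s (only span=1)",
                    path, span))
    }
    vals <- as.numeric(lines[seq(starts_at[i] + 1L, ends_at[i])])
    if (starts_at[i] == ends_at[i]) vals <- numeric(0)
    tibble(chrom = chrom, start = start1 - 1L, values = list(vals))
  })
  bind_rows(blocks)
}

#' Write a score track as fixedStep wiggle
#'
#' @param track Tibble as returned by [read_fixedstep_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixedstep_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(track))) {
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                       track$chrom[i], track$start[i] + 1L), con)
    writeLines(format(track$values[[i]], trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' Read a per-CpG methylation call table
#'
#' Tab-separated with a header line and columns `chrom`, `pos` (0-based
#' position of the C of a plus-strand CG), `meth_reads`, `total_reads`.
#' Rows with `total_reads == 0` are retained (they signal no coverage);
#' `meth_reads > total_reads` is a format error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the four columns above.
#' @export
read_methylation_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  calls <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             chrom = readr::col_character(),
                             pos = readr::col_integer(),
                             meth_reads = readr::col_integer(),
                             total_reads = readr::col_integer()
                           ))
  need <- c("chrom", "pos", "meth_reads", "total_reads")
  if (!all(need %in% names(calls))) {
    abort(sprintf("methylation table %s must have header columns %s",
                  path, paste(need, collapse = ", ")))
  }
  bad <- calls$meth_reads > calls$total_reads
  if (any(bad)) {
    abort(sprintf(
      "methylation table format error in %s, data row %d: meth_reads > total_reads",
      path, which(bad)[1]
    ))
  }
  calls[need]
}

#' Write a methylation call table
#'
#' @param calls Tibble with `chrom`, `pos`, `meth_reads`, `total_reads`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(calls, path) {
  readr::write_tsv(calls[c("chrom", "pos", "meth_reads", "total_reads")], path)
  invisible(path)
}

# Expand a block track into per-chromosome score vectors (NA where absent).
# Returns a named list of numeric vectors sized to cover the last scored base
# (or chrom_lengths when given).
track_score_vectors <- function(track, chrom_lengths = NULL) {
  chroms <- unique(track$chrom)
  out <- list()
  for (ch in chroms) {
    rows <- which(track$chrom == ch)
    upper <- max(vapply(rows, function(i) {
      track$start[i] + length(track$values[[i]])
    }, numeric(1)))
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      max(upper, chrom_lengths[[ch]])
    } else {
      upper
    }
    v <- rep(NA_real_, len)
    for (i in rows) {
      vals <- track$values[[i]]
      if (length(vals)) v[track$start[i] + seq_along(vals)] <- vals
    }
    out[[ch]] <- v
  }
  out
}
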