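#' Background sequence model
#'
#' Order-0 (independent bases) or order-1 (first-order Markov) background
#' for synthetic sequence. The order-1 model accepts a multiplicative
#' depletion factor on the C->G transition, emulating the CG scarcity of
#' bulk genomic DNA outside regulatory regions; the C row is renormalised
#' after depletion.
#'
#' @param order 0 or 1.
#' @param base_probs Named numeric of length 4 (A, C, G, T); normalised.
#' @param cg_depletion Multiplier on the C->G transition probability
#'   (order-1 only; 1 = no depletion).
#' @return An object of class `background_model`.
#' @examples
#' background_model()                               # uniform order 0
#' background_model(order = 1, cg_depletion = 0.1)  # CG-depleted Markov chain
#' @export
background_model <- function(order = 0,
                             base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             cg_depletion = 1) {
  stopifnot(order %in% c(0, 1), length(base_probs) == 4, all(base_probs >= 0))
  base_probs <- base_probs / sum(base_probs)
  names(base_probs) <- DNA_BASES
  if (order == 0 && cg_depletion != 1) {
    abort("`cg_depletion` applies to order-1 backgrounds only")
  }
  trans <- matrix(rep(base_probs, each = 4), nrow = 4,
                  dimnames = list(DNA_BASES, DNA_BASES))
  if (order == 1) {
    trans["C", "G"] <- trans["C", "G"] * cg_depletion
    trans["C", ] <- trans["C", ] / sum(trans["C", ])
  }
  structure(
    list(order = order, base_probs = base_probs, trans = trans,
         cg_depletion = cg_depletion),
    class = "background_model"
  )
}

# n background sequences of a given length as a character matrix (rows =
# sequences, one base per cell); assumes the RNG state is already set
sample_background_matrix <- function(n, len, background) {
  if (n == 0 || len == 0) return(matrix(character(0), nrow = n, ncol = len))
  if (background$order == 0) {
    return(matrix(sample(DNA_BASES, n * len, replace = TRUE,
                         prob = background$base_probs),
                  nrow = n, ncol = len))
  }
  m <- matrix("", nrow = n, ncol = len)
  cum <- t(apply(background$trans, 1, cumsum))
  state <- sample.int(4, n, replace = TRUE, prob = background$base_probs)
  m[, 1] <- DNA_BASES[state]
  for (j in seq_len(len)[-1]) {
    r <- runif(n)
    state <- 1L + (r > cum[state, 1]) + (r > cum[state, 2]) + (r > cum[state, 3])
    m[, j] <- DNA_BASES[state]
  }
  m
}

#' Specify a motif to plant in synthetic promoters
#'
#' Either a literal motif, or a split pattern given as two 4-mers plus an
#' insert length whose insert bases are filled uniformly at random per
#' planted instance. Positions are 0-based offsets of the site's leftmost
#' base; the position law is uniform over a window, or a discretised normal
#' (mean, sd) truncated to the window.
#'
#' @param motif Literal DNA string (or `NULL` when `left`/`right` given).
#' @param left,right 4-mers of a split pattern (used when `motif` is `NULL`).
#' @param insert_len Insert length of the split pattern.
#' @param plant_probability Probability that a given promoter receives one
#'   instance.
#' @param window Integer vector `c(min, max)` of allowed 0-based offsets
#'   (`max` may be `NA` meaning "as far right as the site fits").
#' @param position_law `"uniform"` or `"normal"`.
#' @param position_mean,position_sd Parameters of the discretised normal law.
#' @param strand_probability Probability of planting the reverse complement.
#' @return One-row tibble describing the plant.
#' @export
plant_spec <- function(motif = NULL, left = NULL, right = NULL, insert_len = 0,
                       plant_probability = 1,
                       window = c(0L, NA_integer_),
                       position_law = c("uniform", "normal"),
                       position_mean = NULL, position_sd = NULL,
                       strand_probability = 0.5) {
  position_law <- match.arg(position_law)
  if (is.null(motif) && (is.null(left) || is.null(right))) {
    abort("give either `motif` or both `left` and `right`")
  }
  if (!is.null(motif)) {
    stopifnot(grepl("^[ACGT]+$", motif))
    site_len <- nchar(motif)
    left <- NA_character_; right <- NA_character_; insert_len <- NA_integer_
  } else {
    stopifnot(grepl("^[ACGT]{4}$", left), grepl("^[ACGT]{4}$", right))
    site_len <- 8L + as.integer(insert_len)
    motif <- NA_character_
  }
  if (position_law == "normal" &&
      (is.null(position_mean) || is.null(position_sd))) {
    abort("normal position law needs `position_mean` and `position_sd`")
  }
  stopifnot(plant_probability >= 0, plant_probability <= 1,
            strand_probability >= 0, strand_probability <= 1)
  tibble(
    motif = motif, left = left, right = right,
    insert_len = as.integer(insert_len), site_len = as.integer(site_len),
    plant_probability = plant_probability,
    window_min = as.integer(window[1]), window_max = as.integer(window[2]),
    position_law = position_law,
    position_mean = position_mean %||% NA_real_,
    position_sd = position_sd %||% NA_real_,
    strand_probability = strand_probability
  )
}

sample_offsets <- function(spec, n, seq_len_) {
  wmax_fit <- seq_len_ - spec$site_len
  wmin <- spec$window_min
  wmax <- if (is.na(spec$window_max)) wmax_fit else min(spec$window_max, wmax_fit)
  if (wmin > wmax || wmin < 0) {
    abort(sprintf("infeasible plant window [%d, %s] for a site of length %d in %d bases",
                  spec$window_min, spec$window_max, spec$site_len, seq_len_))
  }
  offs <- wmin:wmax
  if (spec$position_law == "uniform") {
    offs[sample.int(length(offs), n, replace = TRUE)]
  } else {
    # discretised truncated normal over the window
    w <- stats::dnorm(offs, mean = spec$position_mean, sd = spec$position_sd)
    if (sum(w) == 0) w <- rep(1, length(offs))
    offs[sample.int(length(offs), n, replace = TRUE, prob = w)]
  }
}

#' Generate TSS-aligned synthetic promoters with planted motifs
#'
#' Draws `n` background promoters and overwrites them with motif instances
#' according to the plant specifications (overwriting keeps every sequence
#' exactly `length` bases, so the TSS alignment is never shifted). A fixed
#' seed gives byte-identical output; per-stage random streams are derived
#' from the root seed so runs are reproducible stage by stage.
#'
#' @param n Number of promoters.
#' @param plants Tibble of plant specifications ([plant_spec()] rows).
#' @param background A [background_model()].
#' @param seed Integer root seed.
#' @param length Promoter length in bases (default 1500, spanning
#'   -1000..+500 around the TSS).
#' @return A list with `promoters` (tibble `id`, `sequence`) and `truth`
#'   (tibble `id`, `motif`, `offset` (0-based), `strand`, `site`).
#' @export
generate_promoters <- function(n, plants = NULL, background = background_model(),
                               seed = 1L, length = 1500L) {
  stopifnot(n >= 0)
  withr::with_seed(derive_seed(seed, "promoters"), {
    m <- sample_background_matrix(n, length, background)
    truth <- list()
    ids <- sprintf("synthetic_promoter_%05d", seq_len(n))
    if (!is.null(plants) && n > 0) {
      for (i in seq_len(nrow(plants))) {
        spec <- plants[i, ]
        hit <- which(runif(n) < spec$plant_probability)
        if (length(hit) == 0) next
        offs <- sample_offsets(spec, length(hit), length)
        minus <- runif(length(hit)) < spec$strand_probability
        if (is.na(spec$motif)) {
          gaps <- vapply(seq_along(hit), function(j) {
            paste(sample(DNA_BASES, spec$insert_len, replace = TRUE),
                  collapse = "")
          }, character(1))
          sites <- paste0(spec$left, gaps, spec$right)
          label <- pattern_label(spec$left, spec$right, spec$insert_len)
        } else {
          sites <- rep(spec$motif, length(hit))
          label <- spec$motif
        }
        planted <- ifelse(minus, revcomp(sites), sites)
        for (j in seq_along(hit)) {
          cols <- offs[j] + seq_len(spec$site_len)
          m[hit[j], cols] <- strsplit(planted[j], "", fixed = TRUE)[[1]]
        }
        truth[[i]] <- tibble(
          id = ids[hit], motif = label, offset = as.integer(offs),
          strand = ifelse(minus, "-", "+"), site = planted
        )
      }
    }
    promoters <- tibble(
      id = ids,
      sequence = if (n > 0) apply(m, 1, paste, collapse = "") else character(0)
    )
    truth <- if (length(truth)) bind_rows(truth) else
      tibble(id = character(), motif = character(), offset = integer(),
             strand = character(), site = character())
    list(promoters = promoters, truth = truth)
  })
}

place_without_overlap <- function(candidates, occupied, site_len, n_target,
                                  max_tries = 50L) {
  # sample plant start positions from `candidates`, rejecting overlaps
  chosen <- integer(0)
  tries <- 0L
  while (length(chosen) < n_target && tries < max_tries) {
    tries <- tries + 1L
    need <- n_target - length(chosen)
    prop <- candidates[sample.int(length(candidates),
                                  min(need * 2L, length(candidates)))]
    for (p in prop) {
      span <- p:(p + site_len - 1L)
      if (!any(occupied[span])) {
        occupied[span] <- TRUE
        chosen <- c(chosen, p)
        if (length(chosen) == n_target) break
      }
    }
  }
  if (length(chosen) < n_target) {
    abort("could not place all motif instances without overlap; lower the density")
  }
  list(starts = chosen, occupied = occupied)
}

#' Generate a synthetic genome with region-biased motif placement
#'
#' Builds background chromosomes, designates non-overlapping regions
#' covering about `regions_fraction` of each chromosome, and plants motif
#' instances so the expected per-base planting rate is `in_region_density`
#' inside regions and `background_density` outside. Instances never overlap
#' one another (rejection sampling).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param regions_fraction Fraction of each chromosome covered by regions.
#' @param in_region_density Expected plants per base inside regions.
#' @param background_density Expected plants per base outside regions.
#' @param motifs Character vector of literal motifs to plant (sampled
#'   uniformly per instance).
#' @param background A [background_model()].
#' @param seed Integer root seed.
#' @param region_length Length of each designated region.
#' @param strand_probability Probability an instance is planted as its
#'   reverse complement.
#' @return A list with `genome` (tibble `id`, `sequence`), `regions`
#'   (BED-style tibble), and `truth` (tibble `chrom`, `start`, `motif`,
#'   `strand`, `site`, `in_region`).
#' @export
generate_genome <- function(chrom_lengths, regions_fraction = 0.1,
                            in_region_density = 0, background_density = 0,
                            motifs, background = background_model(),
                            seed = 1L, region_length = 500L,
                            strand_probability = 0.5) {
  stopifnot(regions_fraction > 0, regions_fraction < 1,
            in_region_density >= 0, background_density >= 0,
            all(nchar(motifs) >= 4))
  withr::with_seed(derive_seed(seed, "genome"), {
    genome <- list(); regions <- list(); truth <- list()
    max_len <- max(nchar(motifs))
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      chars <- sample_background_matrix(1, L, background)[1, ]
      # tile regions on a fixed grid, then sample the target coverage
      n_slots <- L %/% region_length
      n_regions <- max(1L, round(n_slots * regions_fraction))
      slots <- sort(sample.int(n_slots, min(n_regions, n_slots)))
      reg <- tibble(chrom = ch,
                    start = (slots - 1L) * region_length,
                    end = pmin((slots - 1L) * region_length + region_length, L),
                    name = sprintf("%s_region_%03d", ch, seq_along(slots)))
      in_reg <- rep(FALSE, L)
      for (i in seq_len(nrow(reg))) in_reg[(reg$start[i] + 1):reg$end[i]] <- TRUE
      # candidate start positions (1-based) where a site fits
      fits <- seq_len(L - max_len + 1L)
      cand_in <- fits[in_reg[fits]]
      cand_out <- fits[!in_reg[fits]]
      n_in <- rbinom(1, length(cand_in), min(1, in_region_density))
      n_out <- rbinom(1, length(cand_out), min(1, background_density))
      occupied <- rep(FALSE, L)
      starts <- integer(0); where <- logical(0)
      if (n_in > 0) {
        pl <- place_without_overlap(cand_in, occupied, max_len, n_in)
        occupied <- pl$occupied
        starts <- c(starts, pl$starts); where <- c(where, rep(TRUE, n_in))
      }
      if (n_out > 0) {
        pl <- place_without_overlap(cand_out, occupied, max_len, n_out)
        occupied <- pl$occupied
        starts <- c(starts, pl$starts); where <- c(where, rep(FALSE, n_out))
      }
      if (length(starts)) {
        motif_i <- motifs[sample.int(length(motifs), length(starts),
                                     replace = TRUE)]
        minus <- runif(length(starts)) < strand_probability
        site <- ifelse(minus, revcomp(motif_i), motif_i)
        for (j in seq_along(starts)) {
          span <- starts[j]:(starts[j] + nchar(site[j]) - 1L)
          chars[span] <- strsplit(site[j], "", fixed = TRUE)[[1]]
        }
        truth[[ch]] <- tibble(
          chrom = ch, start = starts - 1L, motif = motif_i,
          strand = ifelse(minus, "-", "+"), site = site, in_region = where
        )
      }
      genome[[ch]] <- tibble(id = ch, sequence = paste(chars, collapse = ""))
      regions[[ch]] <- reg
    }
    truth <- if (length(truth)) bind_rows(truth) else
      tibble(chrom = character(), start = integer(), motif = character(),
             strand = character(), site = character(), in_region = logical())
    list(genome = bind_rows(genome), regions = bind_rows(regions),
         truth = truth)
  })
}

#' Generate a conservation-style score track over a synthetic genome
#'
#' Every base covered by a planted motif instance scores
#' `inside_score + noise`; every other base scores `outside_score + noise`,
#' with independent Gaussian noise of standard deviation `noise_sd`.
#'
#' @param truth Truth table from [generate_genome()] (columns `chrom`,
#'   `start`, `site`).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param inside_score,outside_score Scores for covered/uncovered bases.
#' @param noise_sd Standard deviation of additive noise (0 = noiseless).
#' @param seed Integer root seed.
#' @return A track tibble (`chrom`, `start`, `values`) in the same shape as
#'   [read_fixedstep_track()].
#' @export
generate_track <- function(truth, chrom_lengths, inside_score = 2,
                           outside_score = 0, noise_sd = 0, seed = 1L) {
  stopifnot(is.finite(inside_score), is.finite(outside_score), noise_sd >= 0)
  withr::with_seed(derive_seed(seed, "track"), {
    out <- lapply(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      v <- rep(outside_score, L)
      rows <- which(truth$chrom == ch)
      for (i in rows) {
        span <- (truth$start[i] + 1):(truth$start[i] + nchar(truth$site[i]))
        v[span] <- inside_score
      }
      if (noise_sd > 0) v <- v + rnorm(L, sd = noise_sd)
      tibble(chrom = ch, start = 0L, values = list(v))
    })
    bind_rows(out)
  })
}

#' Generate methylation calls with region-dependent methylation levels
#'
#' Emits one row per plus-strand CG in the genome. Methylated read counts
#' are binomial with success probability `inside_fraction` for CGs whose C
#' lies inside a region and `outside_fraction` elsewhere, at fixed
#' `coverage` (emulating hypomethylated regulatory regions in an otherwise
#' methylated genome).
#'
#' @param genome Tibble `id`, `sequence`.
#' @param regions BED-style tibble (`chrom`, `start`, `end`).
#' @param inside_fraction,outside_fraction Methylation fractions in `[0,1]`.
#' @param coverage Reads per CG.
#' @param seed Integer root seed.
#' @return Methylation call tibble (`chrom`, `pos`, `meth_reads`,
#'   `total_reads`).
#' @export
generate_methylation <- function(genome, regions, inside_fraction = 0,
                                 outside_fraction = 0.8, coverage = 10L,
                                 seed = 1L) {
  stopifnot(inside_fraction >= 0, inside_fraction <= 1,
            outside_fraction >= 0, outside_fraction <= 1, coverage >= 0)
  withr::with_seed(derive_seed(seed, "methylation"), {
    rows <- lapply(seq_len(nrow(genome)), function(i) {
      hits <- gregexpr("CG", genome$sequence[i], fixed = TRUE)[[1]]
      if (hits[1] == -1) return(NULL)
      pos0 <- as.integer(hits) - 1L
      tibble(chrom = genome$id[i], pos = pos0)
    })
    calls <- bind_rows(rows)
    if (nrow(calls) == 0) {
      return(tibble(chrom = character(), pos = integer(),
                    meth_reads = integer(), total_reads = integer()))
    }
    inside <- positions_in_regions(calls$chrom, calls$pos, regions)
    p <- ifelse(inside, inside_fraction, outside_fraction)
    calls$meth_reads <- rbinom(nrow(calls), coverage, p)
    calls$total_reads <- as.integer(coverage)
    calls
  })
}
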