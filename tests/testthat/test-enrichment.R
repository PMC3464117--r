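probe_genome <- function(seq, id = "probe", mask = list(integer(0))) {
  tibble::tibble(id = id, sequence = seq, mask = mask)
}

test_that("literal motif occurrences are found on both strands at plus-strand coordinates", {
  # EMSA probe carrying the composite ETS-CRE site
  probe <- "GTCAGTCAGACCGGAAGTGACGTCATATCGGTCAG"
  occ <- find_occurrences("CGGAAGTGACG", probe_genome(probe))
  expect_equal(nrow(occ), 1)
  expect_equal(occ$start, 11L)
  expect_equal(occ$strand, "+")
  expect_equal(occ$site, "CGGAAGTGACG")

  # palindromic motif: one report per site
  occ_pal <- find_occurrences("TGACGTCA", probe_genome("TGACGTCA"))
  expect_equal(nrow(occ_pal), 1)

  # minus-strand match reported at its leftmost plus-strand base
  occ_rc <- find_occurrences("CGGAAGTGACG",
                             probe_genome(revcomp("CGGAAGTGACG")))
  expect_equal(occ_rc$start, 0L)
  expect_equal(occ_rc$strand, "-")
})

test_that("soft-masked and N bases define the unmasked counting universe", {
  g <- probe_genome("CGGAAGTGACG", mask = list(1:11))
  expect_equal(nrow(find_occurrences("CGGAAGTGACG", g)), 0)
  expect_equal(nrow(find_occurrences("CGGAAGTGACG", g,
                                     unmasked_only = FALSE)), 1)
  g2 <- probe_genome("CGGAANTGACG")
  expect_equal(nrow(find_occurrences("CGGAAGTGACG", g2)), 0)
})

test_that("occurrence sets are invariant under querying the reverse complement", {
  withr::with_seed(31, {
    g <- generate_genome(c(c1 = 30000L), regions_fraction = 0.2,
                         in_region_density = 1e-3, background_density = 5e-4,
                         motifs = "CGGAAGTG", seed = 31)
    a <- find_occurrences("CGGAAGTG", g$genome)
    b <- find_occurrences(revcomp("CGGAAGTG"), g$genome)
    expect_equal(a[c("chrom", "start", "end")], b[c("chrom", "start", "end")])
    expect_equal(nrow(a), nrow(b))
  })
})

test_that("the scanner agrees exactly with a character-by-character oracle", {
  withr::with_seed(37, {
    seqs <- vapply(1:2, function(i) {
      paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    }, character(1))
    genome <- tibble::tibble(id = c("c1", "c2"), sequence = seqs)
    for (motif in c("TGACGTCA", "ACGT", "CGGAA")) {
      mine <- find_occurrences(motif, genome)
      oracle <- oracle_find_occurrences(motif, genome)
      expect_equal(nrow(mine), nrow(oracle))
      expect_equal(mine$start, oracle$start)
      expect_equal(mine$strand, oracle$strand)
    }
  })
})

test_that("region-overlap fractions follow start-base membership", {
  occ <- find_occurrences("TGACGTCA",
                          probe_genome(strrep("TGACGTCAAA", 10)))
  expect_equal(nrow(occ), 10)
  none <- fraction_in_regions(occ, tibble::tibble(chrom = character(),
                                                  start = integer(),
                                                  end = integer()))
  expect_equal(none$count, 0L)
  expect_equal(none$fraction, 0)
  all_r <- fraction_in_regions(occ, tibble::tibble(chrom = "probe",
                                                   start = 0L, end = 100L))
  expect_equal(all_r$fraction, 1)
  # membership is by the start base: an interval covering only the site tail
  # does not capture it
  tail_only <- fraction_in_regions(occ[1, ], tibble::tibble(chrom = "probe",
                                                            start = 1L,
                                                            end = 8L))
  expect_equal(tail_only$count, 0L)
  # invariant under chromosome renaming and interval order
  occ2 <- occ; occ2$chrom <- "renamed"
  reg <- tibble::tibble(chrom = "renamed", start = c(50L, 0L), end = c(60L, 10L))
  expect_equal(fraction_in_regions(occ2, reg)$count,
               fraction_in_regions(occ2, reg[2:1, ])$count)
})

test_that("enrichment tables match generator truth on a fixture with no background occurrences", {
  g <- generate_genome(c(cA = 8000L, cB = 8000L), regions_fraction = 0.25,
                       in_region_density = 1.5e-3, background_density = 5e-4,
                       motifs = "CGGAAGTGACG",
                       background = background_model(base_probs = c(A = 1, C = 0, G = 0, T = 0)),
                       seed = 41)
  expect_gt(nrow(g$truth), 5)
  tab <- enrichment_table("CGGAAGTGACG", g$genome,
                          region_sets = list(dhs = g$regions))
  expect_equal(tab$genome_count, nrow(g$truth))
  expect_equal(tab$dhs_count, sum(g$truth$in_region))
  expect_equal(tab$dhs_percent,
               as.integer(floor(100 * mean(g$truth$in_region) + 0.5)))
  absent <- enrichment_table("TTTTGGGG", g$genome,
                             region_sets = list(dhs = g$regions))
  expect_equal(absent$genome_count, 0L)
  expect_equal(absent$dhs_fraction, 0)
})

test_that("palindromic and non-palindromic motifs of equal density count without bias", {
  g <- generate_genome(c(c1 = 40000L), regions_fraction = 0.2,
                       in_region_density = 1e-3, background_density = 1e-3,
                       motifs = c("TGACGTCA", "CGGAAGTG"),
                       background = background_model(base_probs = c(A = 1, C = 0, G = 0, T = 0)),
                       seed = 43)
  tab <- enrichment_table(c("TGACGTCA", "CGGAAGTG"), g$genome)
  truth_counts <- table(g$truth$motif)
  expect_equal(tab$genome_count[tab$motif == "TGACGTCA"],
               as.integer(truth_counts[["TGACGTCA"]]))
  expect_equal(tab$genome_count[tab$motif == "CGGAAGTG"],
               as.integer(truth_counts[["CGGAAGTG"]]))
})

test_that("extension scans trace the target and expose enrichment jumps", {
  # inside regions: the full 11-mer; outside: only the 8-mer core
  region_part <- strrep(paste0("CGGAAGTGACG", strrep("A", 9)), 5)   # 100 bases
  outside_part <- strrep(paste0("CGGAAGTGAAA", strrep("A", 9)), 10)
  genome <- probe_genome(paste0(region_part, outside_part))
  regions <- tibble::tibble(chrom = "probe", start = 0L, end = 100L)
  ext <- extension_scan("CGGAAGTG", "CGGAAGTGACG", "right", genome, regions)
  expect_equal(ext$candidate[1], "CGGAAGTG")
  expect_equal(ext$extension[1], 0L)
  expect_equal(nrow(ext), 1 + 3 * 4)
  on_target <- ext[ext$on_target, ]
  expect_equal(on_target$candidate[on_target$extension == 3], "CGGAAGTGACG")
  # fraction jumps when the second CG completes the 11-mer
  f_core <- ext$fraction[ext$extension == 0]
  f_11 <- ext$fraction[ext$extension == 3 & ext$on_target]
  expect_lt(f_core, 0.5)
  expect_equal(f_11, 1)
  # leftward extension follows the suffix
  ext_l <- extension_scan("AGTGACG", "CGGAAGTGACG", "left", genome, regions)
  expect_equal(ext_l$candidate[ext_l$on_target & ext_l$extension == 4],
               "CGGAAGTGACG")
  expect_error(
    extension_scan("CGGAAGTG", "CGGAAGTGACG", "right", genome, regions,
                   max_extension = 5),
    "beyond"
  )
  expect_error(extension_scan("ACGT", "CGGAAGTGACG", "right", genome, regions),
               "prefix")
})

test_that("1-bp variant enumeration flags CG-disrupting substitutions", {
  v <- one_bp_variants("CGGAAGTGACG")
  expect_equal(nrow(v), 33)
  expect_equal(anyDuplicated(v$variant), 0)
  expect_true("CGGAAGTGGCG" %in% v$variant)   # most abundant variant in vivo
  expect_true(v$disrupts_cg[v$variant == "TGGAAGTGACG"])
  expect_false(v$disrupts_cg[v$variant == "CGGACGTGACG"])
  # two CGs cover 4 positions -> 12 disrupting variants
  expect_equal(sum(v$disrupts_cg), 12)
})

test_that("CG-pair scans count plus-strand windows at each gap", {
  expect_equal(cg_pair_scan(probe_genome("CGACG"))$genome_count,
               c(0, 1, rep(0, 8)))
  g6 <- probe_genome("CGCGCG")
  counts <- cg_pair_scan(g6)$genome_count
  expect_equal(counts[1], 2)   # gap 0 at offsets 0 and 2
  expect_equal(counts[3], 1)   # gap 2: CG..CG with internal CG
  excl <- cg_pair_scan(g6, exclude_internal_cg = TRUE)$genome_count
  expect_equal(excl[3], 0)     # internal CG excluded
  # the composite 11-mer registers at gap 7 only
  counts11 <- cg_pair_scan(probe_genome("CGGAAGTGACG"))$genome_count
  expect_equal(counts11, c(rep(0, 7), 1, 0, 0))
  # region fractions by start base
  cg_reg <- cg_pair_scan(probe_genome("CGACGTTTCGACG"),
                         regions = tibble::tibble(chrom = "probe",
                                                  start = 0L, end = 5L))
  expect_equal(cg_reg$genome_count[2], 2)
  expect_equal(cg_reg$region_count[2], 1)
})

test_that("following-dinucleotide tallies read in match orientation on both strands", {
  d <- following_dinucleotides("TGACGT", probe_genome("TGACGTCA"))
  # plus strand: TGACGT followed by CA; minus strand (revcomp match at
  # offset 2) reads the two preceding bases reverse-complemented: also CA
  expect_equal(d$count[d$dinucleotide == "CA"], 2)
  expect_equal(sum(d$count), 2)
  absent <- following_dinucleotides("TGACGT", probe_genome("AAAAAAAA"))
  expect_equal(sum(absent$count), 0)
  expect_equal(nrow(absent), 16)
  # an occurrence lacking two following bases is skipped
  edge <- following_dinucleotides("TGACGT", probe_genome("TGACGTC"))
  expect_equal(sum(edge$count), 0)
})
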