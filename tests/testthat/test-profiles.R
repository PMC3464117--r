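flat_track <- function(chrom, len, value) {
  tibble::tibble(chrom = chrom, start = 0L, values = list(rep(value, len)))
}

test_that("a constant track yields a constant profile; one occurrence returns its raw window", {
  genome <- tibble::tibble(id = "c1",
                           sequence = paste0(strrep("A", 30), "CGGAAGTGACG",
                                             strrep("A", 30)))
  occ <- find_occurrences("CGGAAGTGACG", genome)
  tr <- flat_track("c1", 71, 0.7)
  prof <- position_profile(occ, tr, flank = 15)
  expect_equal(nrow(prof), 11 + 30)
  expect_true(all(prof$mean_score == 0.7))
  expect_equal(sum(prof$in_motif), 11)

  withr::with_seed(3, {
    vals <- rnorm(71)
    tr2 <- tibble::tibble(chrom = "c1", start = 0L, values = list(vals))
    prof2 <- position_profile(occ, tr2, flank = 15)
    # single plus-strand occurrence at 0-based 30: raw 41-value window
    expect_equal(prof2$mean_score, vals[(30 - 15 + 1):(30 + 11 + 15)])
  })
})

test_that("minus-strand occurrences contribute reversed windows (profile equivariance)", {
  withr::with_seed(47, {
    g <- generate_genome(c(c1 = 20000L), regions_fraction = 0.2,
                         in_region_density = 1.5e-3, background_density = 0,
                         motifs = "CGGAAGTGACG", seed = 47)
    vals <- rnorm(20000)
    tr <- tibble::tibble(chrom = "c1", start = 0L, values = list(vals))
    occ_f <- find_occurrences("CGGAAGTGACG", g$genome)
    occ_r <- find_occurrences(revcomp("CGGAAGTGACG"), g$genome)
    p_f <- position_profile(occ_f, tr, flank = 10)
    p_r <- position_profile(occ_r, tr, flank = 10)
    expect_equal(p_f$mean_score, rev(p_r$mean_score), tolerance = 1e-12)
  })
})

test_that("profiles match a naive per-occurrence loop oracle", {
  withr::with_seed(53, {
    g <- generate_genome(c(c1 = 15000L, c2 = 15000L), regions_fraction = 0.3,
                         in_region_density = 2e-3, background_density = 1e-3,
                         motifs = "TGACGTCA", seed = 53)
    tr <- generate_track(g$truth, c(c1 = 15000L, c2 = 15000L),
                         inside_score = 1.5, outside_score = -0.2,
                         noise_sd = 0.3, seed = 53)
    occ <- find_occurrences("TGACGTCA", g$genome)
    expect_gt(nrow(occ), 10)
    prof <- position_profile(occ, tr, flank = 15)
    vecs <- list(c1 = tr$values[[which(tr$chrom == "c1")]],
                 c2 = tr$values[[which(tr$chrom == "c2")]])
    oracle <- oracle_position_profile(occ, vecs, flank = 15)
    expect_equal(prof$mean_score, oracle, tolerance = 1e-9)
  })
})

test_that("bases without track data are skipped per occurrence, not zeroed", {
  genome <- tibble::tibble(id = "c1",
                           sequence = paste0("TGACGTCA", strrep("A", 12),
                                             "TGACGTCA"))
  occ <- find_occurrences("TGACGTCA", genome)
  expect_equal(nrow(occ), 2)
  # track covers only the first site and its right flank
  tr <- tibble::tibble(chrom = "c1", start = 0L, values = list(rep(1, 12)))
  prof <- position_profile(occ, tr, flank = 2)
  expect_equal(prof$n_contributing[1], 0)   # left flank of site 1 has no data
  expect_true(is.na(prof$mean_score[1]))
  expect_equal(prof$n_contributing[3], 1)   # only site 1 contributes
  expect_equal(prof$mean_score[3], 1)
})

test_that("noiseless synthetic tracks recover the exact step profile", {
  g <- generate_genome(c(c1 = 30000L), regions_fraction = 0.2,
                       in_region_density = 1.5e-3, background_density = 0,
                       motifs = "CGGAAGTGACG", seed = 59)
  tr <- generate_track(g$truth, c(c1 = 30000L), inside_score = 2,
                       outside_score = 0, noise_sd = 0, seed = 59)
  occ <- find_occurrences("CGGAAGTGACG", g$genome)
  prof <- position_profile(occ, tr, flank = 15)
  expect_true(all(prof$mean_score[prof$in_motif] == 2))
  expect_true(all(prof$mean_score[!prof$in_motif] < 2))
})

test_that("methylation status classification follows the coverage and fraction rules", {
  genome <- tibble::tibble(id = "c1",
                           sequence = paste0(strrep("A", 10), "CGGAAGTGACG",
                                             strrep("A", 10)))
  occ <- find_occurrences("CGGAAGTGACG", genome)
  # CGs at site offsets 0 and 9 -> genomic 10 and 19
  calls <- function(m1, t1, m2, t2) {
    tibble::tibble(chrom = "c1", pos = c(10L, 19L),
                   meth_reads = c(m1, m2), total_reads = c(t1, t2))
  }
  expect_equal(as.character(classify_methylation(occ, calls(0, 10, 1, 10))$status),
               "unmethylated")
  expect_equal(as.character(classify_methylation(occ, calls(10, 10, 9, 10))$status),
               "methylated")
  expect_equal(as.character(classify_methylation(occ, calls(0, 10, 10, 10))$status),
               "mixed")
  expect_equal(as.character(classify_methylation(occ, calls(0, 10, 1, 3))$status),
               "insufficient")
  # a missing call row is lacking coverage
  one_call <- tibble::tibble(chrom = "c1", pos = 10L, meth_reads = 0L,
                             total_reads = 10L)
  expect_equal(as.character(classify_methylation(occ, one_call)$status),
               "insufficient")
  # a site without CG cannot be classified
  occ_nocg <- find_occurrences("AAATTTAAA",
                               tibble::tibble(id = "c1",
                                              sequence = "AAATTTAAAC"))
  res <- classify_methylation(occ_nocg, one_call)
  expect_equal(as.character(res$status), "insufficient")
  expect_equal(nrow(res$cg_calls[[1]]), 0)
})

test_that("raising the unmethylated threshold never shrinks the unmethylated class", {
  withr::with_seed(61, {
    g <- generate_genome(c(c1 = 30000L), regions_fraction = 0.3,
                         in_region_density = 2e-3, background_density = 1e-3,
                         motifs = "CGGAAGTGACG", seed = 61)
    m <- generate_methylation(g$genome, g$regions, inside_fraction = 0.1,
                              outside_fraction = 0.7, coverage = 12, seed = 61)
    occ <- find_occurrences("CGGAAGTGACG", g$genome)
    st1 <- classify_methylation(occ, m, unmethylated_max = 0.15)$status
    st2 <- classify_methylation(occ, m, unmethylated_max = 0.35)$status
    expect_true(all(which(st1 == "unmethylated") %in%
                      which(st2 == "unmethylated")))
  })
})

test_that("methylation summaries recover the generator's region contract", {
  g <- generate_genome(c(c1 = 40000L), regions_fraction = 0.25,
                       in_region_density = 1.5e-3, background_density = 7e-4,
                       motifs = "CGGAAGTGACG", seed = 67)
  m1 <- generate_methylation(g$genome, g$regions, inside_fraction = 0,
                             outside_fraction = 0.95, coverage = 10, seed = 67)
  m2 <- generate_methylation(g$genome, g$regions, inside_fraction = 0,
                             outside_fraction = 0.95, coverage = 10, seed = 68)
  ms <- methylation_summary("CGGAAGTGACG", g$genome,
                            calls = list(fibroblast = m1, keratinocyte = m2),
                            regions = g$regions)
  occ <- ms$occurrences
  inside <- g$truth$in_region[match(occ$start, g$truth$start)]
  # at noise 0 inside / 0.95 outside, in-region occurrences are unmethylated
  expect_true(all(occ$status_fibroblast[inside] == "unmethylated"))
  expect_true(all(occ$status_fibroblast[!inside] %in%
                    c("methylated", "mixed")))
  # unmethylated occurrences concentrate in regions
  rf <- ms$region_fraction
  expect_equal(rf$fraction[rf$cell_type == "fibroblast" &
                             rf$status == "unmethylated"], 1)
  # identical call tables give a diagonal cross-tabulation
  ms_same <- methylation_summary("CGGAAGTGACG", g$genome,
                                 calls = list(a = m1, b = m1),
                                 regions = g$regions)
  ct <- ms_same$cross_tab
  expect_equal(sum(ct$n[ct$status_a != ct$status_b]), 0)
  # an empty call table leaves everything insufficient
  empty <- m1[0, ]
  ms_empty <- methylation_summary("CGGAAGTGACG", g$genome,
                                  calls = list(none = empty))
  sc <- ms_empty$status_counts
  expect_equal(sc$n[sc$status == "insufficient"], nrow(occ))
})
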