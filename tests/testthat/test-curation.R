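rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

test_that("identical-duplicate removal keeps the first copy per sequence", {
  r <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "ACGT"))
  expect_equal(drop_identical_duplicates(r)$id, "a")
  r <- tibble::tibble(id = letters[1:3], sequence = c("AA", "CC", "GG"))
  expect_equal(drop_identical_duplicates(r), r)
  r <- tibble::tibble(id = letters[1:4], sequence = c("AC", "AC", "AC", "GT"))
  out <- drop_identical_duplicates(r)
  expect_equal(nrow(out), 2)
  expect_equal(nrow(r) - nrow(out), 2)
  # outcome size is order-insensitive
  withr::with_seed(5, {
    shuffled <- r[sample(nrow(r)), ]
    expect_equal(nrow(drop_identical_duplicates(shuffled)), 2)
  })
})

test_that("N-run filter triggers on a 150-base run, not on a split total", {
  pad <- function(core) paste0(strrep("A", 10), core, strrep("C", 10))
  r <- tibble::tibble(
    id = c("run150", "run149", "split"),
    sequence = c(pad(strrep("N", 150)), pad(strrep("N", 149)),
                 pad(paste0(strrep("N", 100), "A", strrep("N", 50))))
  )
  out <- drop_long_n_runs(r)
  expect_equal(out$id, c("run149", "split"))
})

test_that("duplicated identifiers are removed entirely", {
  r <- tibble::tibble(id = c("a", "a", "b"), sequence = c("AA", "CC", "GG"))
  expect_equal(drop_duplicate_ids(r)$id, "b")
  r2 <- tibble::tibble(id = c("x", "y"), sequence = c("AA", "CC"))
  expect_equal(drop_duplicate_ids(r2), r2)
  empty <- r2[0, ]
  expect_equal(nrow(drop_duplicate_ids(empty)), 0)
})

test_that("near-duplicate collapse links on shared exact substrings at the 250 boundary", {
  withr::with_seed(9, {
    shared <- rand_seq(1, 250)
    core249 <- rand_seq(1, 249)   # independent of `shared`
    mk <- function(core) paste0(rand_seq(1, 40), core, rand_seq(1, 40))
    r <- tibble::tibble(
      id = c("p1", "p2", "q1", "q2", "solo"),
      sequence = c(mk(shared), mk(shared),
                   # fixed distinct flank letters pin the shared run at 249
                   paste0(strrep("A", 40), core249, strrep("A", 40)),
                   paste0(strrep("T", 40), core249, strrep("T", 40)),
                   rand_seq(1, 330))
    )
    # q1/q2 share only 249 consecutive bases (their flanks never extend it)
    out <- collapse_near_duplicates(r)
    expect_true(all(c("q1", "q2", "solo") %in% out$records$id))
    expect_equal(sum(out$records$id %in% c("p1", "p2")), 1)
    expect_equal(out$records$id[out$records$id %in% c("p1", "p2")], "p1")
    expect_equal(nrow(out$groups), 2)
    expect_equal(unique(out$groups$representative), "p1")
  })
})

test_that("records with more than max_links duplication links are removed before grouping", {
  withr::with_seed(10, {
    blocks <- rand_seq(11, 250)
    hub <- paste(blocks, collapse = "")
    partners <- vapply(blocks, function(b) {
      paste0(rand_seq(1, 30), b, rand_seq(1, 30))
    }, character(1))
    r <- tibble::tibble(id = c("hub", sprintf("s%02d", 1:11)),
                        sequence = c(hub, unname(partners)))
    out <- collapse_near_duplicates(r)
    expect_false("hub" %in% out$records$id)
    # partners only linked through the hub: all kept once the hub is gone
    expect_equal(sum(grepl("^s", out$records$id)), 11)
  })
})

test_that("TSS-proximal coding starts are removed at the inclusive 30-base boundary", {
  r <- tibble::tibble(id = c("at30", "at31", "none", "minus30"),
                      sequence = rep("ACGT", 4),
                      cds_offset = c(30L, 31L, NA, -30L))
  out <- drop_tss_proximal_cds(r)
  expect_equal(out$id, c("at31", "none"))
})

test_that("curate applies the five filters in order with a complete accounting", {
  withr::with_seed(21, {
    shared <- rand_seq(1, 250)
    base <- rand_seq(6, 400)
    r <- tibble::tibble(
      id = c("u1", "u1dup", "nrun", "refA", "refA", "near1", "near2",
             "clean1", "clean2", "cds"),
      sequence = c(
        base[1], base[1],                                   # identical pair
        paste0(strrep("N", 200), rand_seq(1, 200)),         # long N run
        base[2], base[3],                                   # duplicated id
        paste0(rand_seq(1, 50), shared, rand_seq(1, 50)),   # near-dup pair
        paste0(rand_seq(1, 60), shared, rand_seq(1, 60)),
        base[4], base[5],                                   # untouched
        base[6]                                             # proximal CDS
      ),
      cds_offset = c(NA, NA, NA, NA, NA, NA, NA, 500L, NA, 12L)
    )
    cur <- curate(r)
    rep <- cur$report
    expect_equal(rep$input_count, 10)
    expect_equal(rep$removed_identical, 1)       # u1dup
    expect_equal(rep$removed_n_runs, 1)          # nrun
    expect_equal(rep$removed_dup_refseq, 2)      # both refA
    expect_equal(rep$removed_many_overlaps, 0)
    expect_equal(rep$group_representatives_kept, 1)
    expect_equal(rep$removed_group_members, 1)
    expect_equal(rep$removed_tss_proximal_cds, 1)
    expect_equal(rep$final_count, 4)
    expect_setequal(cur$records$id, c("u1", "near1", "clean1", "clean2"))
    # every removal is accounted for
    expect_equal(
      rep$input_count,
      rep$final_count + rep$removed_identical + rep$removed_n_runs +
        rep$removed_dup_refseq + rep$removed_many_overlaps +
        rep$removed_group_members + rep$removed_tss_proximal_cds
    )
  })
})

test_that("clean input passes curation unchanged and keep-lists retain group members", {
  withr::with_seed(33, {
    clean <- tibble::tibble(id = c("a", "b"), sequence = rand_seq(2, 300))
    cur <- curate(clean)
    expect_equal(cur$report$final_count, cur$report$input_count)
    shared <- rand_seq(1, 260)
    dup <- tibble::tibble(
      id = c("g1", "g2", "g3"),
      sequence = paste0(rand_seq(3, 20), shared, rand_seq(3, 20))
    )
    kept <- curate(dup, keep_list = "g3")
    expect_setequal(kept$records$id, c("g1", "g3"))
    expect_equal(kept$report$retained_mixed, 1)
  })
})

test_that("the published-scale accounting arithmetic holds", {
  expect_identical(curation_accounting(18451, 1176, 2484), 17143L)
})
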