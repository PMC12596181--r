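make_table <- function(...) {
  args <- list(...)
  do.call(metadata_table, args)
}

test_that("metadata_table enforces entry invariants", {
  expect_error(metadata_table(c("EMD-1", "EMD-1")), "duplicate emdb_id")
  expect_error(metadata_table("EMD-1", resolution = -2), "resolution")
  tab <- metadata_table("EMD-1", xrefs_uniprot = "U1;U2;U1")
  expect_identical(xref_set(tab, 1), c("U1", "U2"))
})

test_that("clean_entries removes incomplete entries and keeps best-resolution duplicate titles", {
  tab <- make_table(
    emdb_id = c("EMD-1", "EMD-2", "EMD-3", "EMD-4"),
    title = c("apo ribosome", "apo ribosome", "holo", "broken"),
    resolution = c(3.5, 3.0, 3.2, 3.3),
    pdb_id = c("1AAA", "2BBB", "3CCC", NA),
    contour_level = c(0.1, 0.1, 0.1, 0.1))
  out <- clean_entries(tab)
  expect_setequal(out$table$emdb_id, c("EMD-2", "EMD-3"))
  disc <- out$report$stages[[1]]$discarded
  expect_match(disc$reason[disc$emdb_id == "EMD-4"], "fitted PDB ID")
  expect_match(disc$reason[disc$emdb_id == "EMD-1"], "duplicate title")
  # all-complete, all-unique table passes through unchanged
  clean2 <- clean_entries(out$table)
  expect_identical(as.data.frame(clean2$table), as.data.frame(out$table))
})

test_that("Q-score filter is strictly-below and treats absence as failure", {
  tab <- make_table(emdb_id = sprintf("EMD-%d", 1:6),
                    title = sprintf("t%d", 1:6), resolution = 3,
                    pdb_id = "1AAA", contour_level = 0.1,
                    q_score = c(0.30, 0.40, 0.45, 0.39, 0.50, NA))
  out <- filter_qscore(tab, 0.4)
  expect_setequal(out$table$emdb_id, c("EMD-2", "EMD-3", "EMD-5"))
  disc <- out$report$stages[[1]]$discarded
  expect_identical(disc$reason[disc$emdb_id == "EMD-6"], "missing Q-score")
  expect_equal(nrow(disc), 3)
  # threshold 0: nothing with a non-negative score is discarded
  out0 <- filter_qscore(tab[1:5, ], 0)
  expect_equal(nrow(out0$report$stages[[1]]$discarded), 0)
})

test_that("xref similarity obeys the containment and jaccard definitions", {
  expect_equal(xref_similarity(c("U1"), c("U1")), 1)
  expect_equal(xref_similarity(c("U1"), c("U2"), "jaccard"), 0)
  expect_equal(xref_similarity(c("U1", "U2", "U3"), c("U2", "U3")), 1)
  expect_equal(xref_similarity(c("U1", "U2", "U3"), c("U2", "U3"), "jaccard"),
               2 / 3)
  # symmetry
  expect_equal(xref_similarity(c("U2", "U3"), c("U1", "U2", "U3")), 1)
  expect_error(xref_similarity(character(0), "U1"), "empty")
})

test_that("uniqueness filter keeps the best-resolution member of identical-set groups and flags empty sets", {
  tab <- make_table(
    emdb_id = c("EMD-A", "EMD-B", "EMD-C", "EMD-D"),
    title = sprintf("t%d", 1:4),
    resolution = c(3.2, 3.0, 3.5, 3.1),
    pdb_id = "1AAA", contour_level = 0.1,
    xrefs_uniprot = c("U1;U2", "U1;U2", "U3", ""))
  out <- uniqueness_filter(tab)
  expect_setequal(out$table$emdb_id, c("EMD-B", "EMD-C"))
  expect_identical(out$report$stages[[1]]$flagged, "EMD-D")
  expect_identical(out$report$stages[[1]]$discarded$emdb_id, "EMD-A")
  # pairwise-distinct sets, no empties: identity
  again <- uniqueness_filter(out$table)
  expect_identical(again$table$emdb_id, out$table$emdb_id)
})

test_that("similarity filter sweeps best-resolution-first and enforces the threshold on retained pairs", {
  tab <- make_table(
    emdb_id = c("EMD-A", "EMD-B", "EMD-C"),
    title = sprintf("t%d", 1:3),
    resolution = c(3.0, 3.2, 3.4),
    pdb_id = "1AAA", contour_level = 0.1,
    xrefs_uniprot = c("U1;U2", "U1;U2;U3", "U4"))
  out <- similarity_filter(tab, 0.7)
  expect_setequal(out$table$emdb_id, c("EMD-A", "EMD-C"))
  expect_match(out$report$stages[[1]]$discarded$reason, "overlap 1.000")
  # threshold 1.0 discards nothing once duplicates are gone
  out1 <- similarity_filter(tab, 1.0)
  expect_equal(nrow(out1$table), 3)
})

test_that("pairwise similarity matrix is symmetric with unit diagonal", {
  sets <- list(c("a", "b"), c("b", "c"), "d")
  m <- pairwise_similarity_matrix(sets)
  expect_equal(diag(m), rep(1, 3))
  expect_equal(m, t(m))
  expect_equal(m[1, 2], 0.5)
  expect_equal(m[1, 3], 0)
  expect_equal(m[2, 3], 0)
  ident <- pairwise_similarity_matrix(list(c("x", "y"), c("x", "y")))
  expect_true(all(ident == 1))
  expect_error(pairwise_similarity_matrix(list("a", character(0))), "non-empty")
})

test_that("filters are idempotent and account for every entry", {
  for (seed in 1:5) {
    tab <- synth_metadata(30, structure = list(
      n_duplicate_groups = 2, duplicate_group_size = 3,
      n_subset_chains = 2, subset_chain_length = 3, n_empty = 2),
      seed = seed)
    u1 <- uniqueness_filter(tab)
    expect_equal(stage_accounts(u1$report$stages[[1]]), nrow(tab))
    u2 <- uniqueness_filter(u1$table)
    expect_identical(u2$table$emdb_id, u1$table$emdb_id)
    s1 <- similarity_filter(u1$table, 0.6)
    expect_equal(stage_accounts(s1$report$stages[[1]]), nrow(u1$table))
    s2 <- similarity_filter(s1$table, 0.6)
    expect_identical(s2$table$emdb_id, s1$table$emdb_id)
    # post-similarity guarantee, brute force
    expect_lte(max_retained_similarity(s1$table), 0.6)
    # greedy justification: every discarded entry is too similar to a
    # retained entry of better-or-equal resolution
    disc_ids <- s1$report$stages[[1]]$discarded$emdb_id
    for (id in disc_ids) {
      i <- match(id, u1$table$emdb_id)
      sims <- vapply(seq_len(nrow(s1$table)), function(j)
        xref_similarity(xref_set(u1$table, i), xref_set(s1$table, j)),
        numeric(1))
      ok <- sims > 0.6 &
        (s1$table$resolution <= u1$table$resolution[i] |
           sims == max(sims))
      expect_true(any(sims > 0.6))
    }
  }
})

test_that("metadata CSV round-trips entries including xref sets", {
  tab <- synth_metadata(12, structure = list(n_empty = 2), seed = 9)
  tf <- tempfile(fileext = ".csv")
  write_metadata_csv(tab, tf)
  back <- read_metadata_csv(tf)
  expect_equal(as.data.frame(back)[names(back) != "title"],
               as.data.frame(tab)[names(tab) != "title"])
  expect_identical(xref_set(back, 1), xref_set(tab, 1))
})
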