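test_that("difference positions honour both modes and their containment relation", {
  rows <- c(r = "AAAAAAAAAA", b1 = "AAAAAAAAAA", b2 = "AAAAAAAAAA",
            b3 = "AAAAAAAAAA")
  aln0 <- alignment(rows)
  expect_length(difference_positions(aln0, "r", c("b1", "b2", "b3")), 0)
  # planted 9-column divergent block
  m <- aln0$mat; m["r", 2:10] <- "G"
  alnp <- alignment(m)
  expect_equal(difference_positions(alnp, "r", c("b1", "b2", "b3")), 1:9)
  # background-internal variation: consensus mode sees it, unanimous does not
  m2 <- m; m2[c("b1", "b2"), 1] <- "T"   # column 0 (0-based)
  alnq <- alignment(m2)
  dc <- difference_positions(alnq, "r", c("b1", "b2", "b3"), "consensus")
  du <- difference_positions(alnq, "r", c("b1", "b2", "b3"), "unanimous")
  expect_true(all(du %in% dc))
  expect_true(0 %in% dc && !(0 %in% du))
  expect_error(difference_positions(alnp, "r", character(0)), "value")
  expect_error(difference_positions(alnp, "r", c("r", "b1")), "value")
})

test_that("cluster scan finds planted clusters and its Monte Carlo p matches exact enumeration", {
  # isolated differences: no clusters
  r0 <- cluster_scan(c(0, 50, 100, 150), 300, mc_replicates = 100, seed = 1)
  expect_equal(nrow(r0$clusters), 0L)
  r00 <- cluster_scan(integer(0), 300, mc_replicates = 10, seed = 1)
  expect_equal(r00$p_cluster, 1)
  # the planted two-cluster geometry: 8-in-27 and 4-in-19 among scattered noise
  cols <- c(75, 79, 83, 87, 91, 95, 99, 101, 150, 156, 162, 168)
  r1 <- cluster_scan(cols, 300, mc_replicates = 10000, seed = 2)
  expect_equal(r1$clusters$m, c(8L, 4L))
  expect_equal(r1$clusters$start, c(75L, 150L))
  expect_equal(r1$clusters$end, c(102L, 169L))
  expect_lt(r1$p_cluster, 0.05)
  # exact enumeration oracle at enumerable sizes
  for (case in list(c(k = 4, L = 18, w = 5), c(k = 5, L = 24, w = 6))) {
    set.seed(case[["k"]])
    pos <- sort(sample.int(case[["L"]], case[["k"]])) - 1
    r <- cluster_scan(pos, case[["L"]], scan_window = case[["w"]],
                      mc_replicates = 20000, seed = 3)
    pexact <- exact_scan_p(case[["k"]], case[["L"]], case[["w"]], r$m_max)
    expect_lt(abs(r$p_cluster - pexact), 0.02)
  }
  # independently coded Monte Carlo oracle at the larger size
  set.seed(8)
  pos <- sort(sample.int(60, 12)) - 1
  r <- cluster_scan(pos, 60, scan_window = 10, mc_replicates = 20000, seed = 5)
  pmc <- mc_scan_oracle(12, 60, 10, r$m_max, reps = 20000, seed = 6)
  expect_lt(abs(r$p_cluster - pmc), 0.02)
  expect_error(cluster_scan(cols, 20, scan_window = 30), "value")
})

test_that("cassette intervals span clusters and pad to codon boundaries", {
  rep1 <- cluster_scan(10:18, 100, mc_replicates = 10, seed = 1)
  iv <- cassette_intervals(rep1)
  expect_equal(iv, column_interval(10, 19))
  ivp <- cassette_intervals(rep1, frame = 0L, pad_to_codon = TRUE)
  expect_equal(ivp, column_interval(9, 21))
  empty <- cluster_scan(integer(0), 100, mc_replicates = 10, seed = 1)
  expect_equal(nrow(cassette_intervals(empty)), 0L)
})

test_that("excision never leaves a reported difference inside an excised interval", {
  fx <- cassette_family_fixture(seed = 3)
  iv <- fx$truth
  out <- excise_columns(fx$aln, iv)
  d <- difference_positions(out, fx$recipient, fx$background)
  # remap excised intervals into the new coordinate system: nothing may
  # fall where the cassettes used to be, and the recipient now matches
  # its family there
  expect_equal(aln_length(out), 300L - sum(iv$end - iv$start))
  expect_lt(length(d), length(difference_positions(fx$aln, fx$recipient,
                                                   fx$background)))
  expect_false(any(d %in% fx$diff_columns))
})

test_that("donor attribution counts interval mismatches and reports ties", {
  fx <- cassette_family_fixture(seed = 1)
  att <- donor_attribution(fx$aln, fx$recipient, fx$truth,
                           c(fx$donor, fx$background))
  expect_equal(att$best_donor, "D")
  expect_equal(unname(att$mismatches["D"]), 1L)
  expect_gt(att$margin, 0)
  # candidate identical to the recipient inside intervals scores 0
  m <- fx$aln$mat
  m2 <- rbind(m, clone = m[fx$recipient, ])
  aln2 <- alignment(m2)
  att2 <- donor_attribution(aln2, fx$recipient, fx$truth,
                            c("clone", fx$donor))
  expect_equal(unname(att2$mismatches["clone"]), 0L)
  expect_equal(att2$best_donor, "clone")
  # exact ties are reported, not broken
  m3 <- rbind(m, clone1 = m[fx$donor, ], clone2 = m[fx$donor, ])
  att3 <- donor_attribution(alignment(m3), fx$recipient, fx$truth,
                            c("clone1", "clone2"))
  expect_setequal(att3$best_donor, c("clone1", "clone2"))
  expect_equal(att3$margin, 0L)
  expect_error(donor_attribution(fx$aln, "R", fx$truth, character(0)),
               "value")
})

test_that("topology shift reports the sister change caused by cassette excision", {
  fx <- cassette_family_fixture(seed = 1)
  iv <- fx$truth
  ts <- topology_shift(fx$aln, fx$recipient, iv, outgroup = NULL,
                       boot_replicates = 100, seed = 5)
  expect_true(fx$donor %in% ts$sister_before)
  expect_true(any(fx$background %in% ts$sister_after))
  expect_gte(ts$rf_distance, 0)
  # empty intervals: before == after
  ts0 <- topology_shift(fx$aln, fx$recipient, NULL, outgroup = NULL,
                        boot_replicates = 20, seed = 5)
  expect_equal(ts0$sister_before, ts0$sister_after)
  expect_equal(ts0$rf_distance, 0)
})

test_that("repeat-unit decomposition tiles greedily and recovers copy number", {
  units <- c(u1 = "ACGTACGTAAGG", rep1 = "TTGACCTGAGCA", u3 = "GGCATTCGATCA")
  seq <- paste0(units["u1"], units["rep1"], units["rep1"], units["u3"])
  dec <- repeat_unit_decomposition(seq, units, "rep1")
  expect_equal(dec$units, c("u1", "rep1", "rep1", "u3"))
  expect_equal(dec$copy_number, 2L)
  expect_equal(dec$remainder, "")
  # a single unit decomposes to itself
  one <- repeat_unit_decomposition(unname(units["rep1"]), units, "rep1")
  expect_equal(one$units, "rep1")
  expect_equal(one$copy_number, 1L)
  # un-tileable remainder is reported
  tail <- repeat_unit_decomposition(paste0(units["u1"], "ACGT"), units, "rep1")
  expect_equal(tail$remainder, "ACGT")
  # ambiguity (two units tying) is an error, and indistinguishable unit
  # libraries are refused
  amb <- c(a = "AAAA", b = "AAAT")
  expect_error(repeat_unit_decomposition("AAAA", amb, "a",
                                         max_mismatch_per_unit = 1),
               "distinguishable")
  expect_error(repeat_unit_decomposition("AAAA", c(a = "AAAA", b = "AAAA"),
                                         "a"), "distinguishable|ambiguity")
  expect_error(repeat_unit_decomposition("AAAA", character(0), "a"), "value")
})
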