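test_that("the family simulator is deterministic and respects degenerate settings", {
  cfg <- family_sim_config(n_genes = 5, seq_length = 120, subst_rate = 0.1,
                           seed = 21)
  s1 <- simulate_family(cfg); s2 <- simulate_family(cfg)
  expect_identical(s1$aln$mat, s2$aln$mat)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  # zero substitution rate and no events: all sequences identical
  cfg0 <- family_sim_config(n_genes = 4, seq_length = 60, subst_rate = 0,
                            seed = 3)
  s0 <- simulate_family(cfg0)
  expect_equal(length(unique(aln_strings(s0$aln))), 1L)
  expect_error(family_sim_config(seq_length = 2), "value")
  expect_error(family_sim_config(subst_rate = -1), "value")
})

test_that("pairwise divergence follows the JC69 closed form", {
  # two tips separated by total path mu*t = 0.1; average over seeds
  ps <- vapply(1:40, function(i) {
    cfg <- family_sim_config(tree = "(a:0.5,b:0.5);", seq_length = 1500,
                             subst_rate = 0.1, seed = case_seed(5, i))
    unclass(p_distance_matrix(simulate_family(cfg)$aln))["a", "b"]
  }, 0)
  expected <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  mc_se <- sqrt(expected * (1 - expected) / (1500 * 40))
  expect_lt(abs(mean(ps) - expected), 4 * mc_se)
})

test_that("planted conversion tracts copy the donor exactly when no time remains", {
  cfg <- family_sim_config(
    tree = "((a:0.2,b:0.2):0.2,(c:0.2,d:0.2):0.2);", seq_length = 300,
    subst_rate = 0.3,
    conversion_events = list(list(donor = "c", recipient = "a",
                                  start = 100, end = 130, time = 1)),
    seed = 9)
  sim <- simulate_family(cfg)
  sa <- sim$aln$mat["a", 101:130]; sc <- sim$aln$mat["c", 101:130]
  expect_equal(unname(sa), unname(sc))
  expect_equal(sim$events$start, 100L)
  expect_equal(sim$events$end, 130L)
  # truth consistency: an event at time < 1 can differ, but the event
  # table always stays within bounds
  expect_true(all(sim$events$start >= 0 & sim$events$end <= 300))
  # invalid events are refused
  bad <- family_sim_config(tree = "(a:1,b:1);", seq_length = 30,
                           conversion_events = list(list(
                             donor = "zz", recipient = "a",
                             start = 0, end = 10, time = 1)), seed = 1)
  expect_error(simulate_family(bad), "config")
  bad2 <- family_sim_config(tree = "(a:1,b:1);", seq_length = 30,
                            conversion_events = list(list(
                              donor = "b", recipient = "a",
                              start = 0, end = 40, time = 1)), seed = 1)
  expect_error(simulate_family(bad2), "config")
})

test_that("events drawn by rate are recorded with full truth", {
  cfg <- family_sim_config(n_genes = 6, seq_length = 200, subst_rate = 0.05,
                           conversion_events = 0.8, tract_mean = 30, seed = 13)
  sim <- simulate_family(cfg)
  ev <- sim$events
  if (nrow(ev)) {
    expect_true(all(ev$donor != ev$recipient))
    expect_true(all(ev$start >= 0 & ev$end <= 200 & ev$start < ev$end))
    expect_true(all(ev$time >= 0 & ev$time <= 1))
  }
  expect_identical(simulate_family(cfg)$events, ev)
})

test_that("neutral coding simulation preserves the frame and contains no stops", {
  cfg <- family_sim_config(n_genes = 6, seq_length = 300, subst_rate = 0.25,
                           coding = TRUE, seed = 31)
  aln <- simulate_neutral_coding(cfg)
  expect_equal(aln$frame_offset, 0L)
  for (s in aln_strings(aln)) {
    cods <- substring(s, seq(1, 298, 3), seq(3, 300, 3))
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  }
  expect_error(simulate_neutral_coding(family_sim_config(seed = 1)), "value")
})

test_that("repeat CNV variants mirror the declared copy range and decompose to truth", {
  units <- c(u1 = "ACGTACGTAAGG", rep1 = "TTGACCTGAGCA", u3 = "GGCATTCGATCA")
  cn <- simulate_repeat_cnv(units, "rep1", 1:3, flank_left = "u1",
                            flank_right = "u3", n_variants = 8, seed = 4)
  expect_true(all(cn$truth %in% 1:3))
  rec <- vapply(cn$sequences, function(s)
    repeat_unit_decomposition(s, units, "rep1")$copy_number, 0L)
  expect_equal(unname(rec), cn$truth)
  # k = 1 gives the minimal-length variant
  lens <- nchar(cn$sequences)
  expect_equal(unname(lens == min(lens)), cn$truth == min(cn$truth))
  cn2 <- simulate_repeat_cnv(units, "rep1", 1:3, flank_left = "u1",
                             flank_right = "u3", n_variants = 8, seed = 4)
  expect_identical(cn2$sequences, cn$sequences)
  expect_error(simulate_repeat_cnv(character(0), "x"), "value")
  expect_error(simulate_repeat_cnv(units, "rep1", copy_range = 0:2), "value")
})

test_that("synthetic stand-in families plant their documented geometry", {
  fx <- cassette_family_fixture(seed = 6)
  du <- difference_positions(fx$aln, fx$recipient, fx$background, "unanimous")
  expect_identical(du, fx$diff_columns)
  expect_length(fx$diff_columns, 12L)
  expect_equal(fx$truth$end - fx$truth$start, c(27L, 21L))
  # donor matches the recipient across both cassettes except one base
  att <- donor_attribution(fx$aln, fx$recipient, fx$truth, fx$donor)
  expect_equal(unname(att$mismatches), 1L)
  # seeds change the background but not the planted geometry
  fx2 <- cassette_family_fixture(seed = 7)
  expect_false(identical(fx2$aln$mat, fx$aln$mat))
  expect_identical(difference_positions(fx2$aln, "R", fx2$background,
                                        "unanimous"), fx$diff_columns)

  m <- monomorphic_family_fixture(seed = 2)
  vc <- variant_census(m$aln, m$coding_range, m$frame)
  expect_equal(nrow(vc), 7L)
  p <- point_mutation_family_fixture(seed = 2)
  vc2 <- variant_census(p$aln, p$coding_range, p$frame)
  expect_equal(sum(vc2$effect == "non-synonymous"), p$n_nonsyn)
  expect_equal(sum(vc2$effect == "synonymous"), p$n_syn)
})
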