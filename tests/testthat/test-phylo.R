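test_that("p-distance uses pairwise deletion and direct proportions", {
  aln <- alignment(c(a = "ACGTACGTAC", b = "ACGTACGTTT", c = "ACGTACGTAC"))
  D <- p_distance_matrix(aln)
  expect_equal(D["a", "b"], 0.2)
  expect_equal(D["a", "c"], 0)
  expect_true(isSymmetric(unclass(D)))
  # gap column excluded from both numerator and denominator
  D2 <- p_distance_matrix(alignment(c(a = "AC-T", b = "ACGT")))
  expect_equal(D2["a", "b"], 0)
  expect_error(p_distance_matrix(alignment(c(a = "A"))), "size")
  expect_error(p_distance_matrix(alignment(c(a = "--A", b = "AA-"))),
               "undefined")
})

test_that("NJ reproduces closed-form branch lengths and additive matrices", {
  D3 <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 0.05, b = 0.15, c = 0.25))

  # additive 4-taxon example with exact expected branch lengths
  ids <- LETTERS[1:4]
  D4 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D4["A", "B"] <- 3; D4["A", "C"] <- 5; D4["A", "D"] <- 6
  D4["B", "C"] <- 6; D4["B", "D"] <- 7; D4["C", "D"] <- 7
  D4 <- D4 + t(D4)
  t4 <- nj_tree(D4)
  expect_equal(four_point_split(D4), "B")            # oracle: AB|CD
  expect_equal(unname(tree_bipartitions(t4)), "C|D") # AB|CD recovered
  expect_equal(patristic(t4, ids), D4, tolerance = 1e-12)
  tipl <- setNames(t4$edge.length[t4$edge[, 2] <= 4],
                   t4$tip.label[t4$edge[t4$edge[, 2] <= 4, 2]])
  expect_equal(tipl[ids], c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(sum(t4$edge.length) - sum(tipl), 1)   # internal edge

  expect_error(nj_tree(D3[1:2, 1:2]), "size")
  Dbad <- D4; Dbad[1, 2] <- Dbad[2, 1] <- NA
  expect_error(nj_tree(Dbad), "value")
  # all-equal distances resolve deterministically via the index tie-break
  De <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(De) <- 0
  expect_identical(ape::write.tree(nj_tree(De)), ape::write.tree(nj_tree(De)))
})

test_that("NJ recovers the generating topology from any additive 4-6 leaf matrix", {
  for (i in 1:20) {
    set.seed(case_seed(11, i))
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(D)
    expect_equal(robinson_foulds(rec, tr), 0)
    expect_equal(patristic(rec, tr$tip.label),
                 D[tr$tip.label, tr$tip.label], tolerance = 1e-9)
    if (n == 4) {
      ids <- sort(rownames(D))
      grouped_with_first <- four_point_split(D[ids, ids])
      key <- unname(tree_bipartitions(rec))
      side <- strsplit(key, "|", fixed = TRUE)[[1]]
      # the canonical split side excludes the first taxon, hence its partner
      expect_false(grouped_with_first %in% side)
    }
  }
})

test_that("Robinson-Foulds matches an independent bipartition comparison", {
  tA <- ape::read.tree(text = "((A,B),C,D);")
  tB <- ape::read.tree(text = "((A,C),B,D);")
  expect_equal(robinson_foulds(tA, tA), 0)
  expect_equal(robinson_foulds(tA, tB), 2)
  expect_error(robinson_foulds(tA, ape::read.tree(text = "((A,B),C,E);")),
               "value")
  for (i in 1:10) {
    set.seed(case_seed(23, i))
    t1 <- ape::unroot(ape::rtree(6))
    t2 <- ape::unroot(ape::rtree(6))
    expect_equal(robinson_foulds(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
    expect_equal(robinson_foulds(t1, t2), robinson_foulds(t2, t1))
  }
  # triangle inequality spot-check
  set.seed(1)
  ts <- replicate(3, ape::unroot(ape::rtree(6)), simplify = FALSE)
  expect_lte(robinson_foulds(ts[[1]], ts[[3]]),
             robinson_foulds(ts[[1]], ts[[2]]) + robinson_foulds(ts[[2]], ts[[3]]))
})

test_that("bootstrap support is deterministic, saturates for a clean split, and is row-order invariant", {
  rows <- c(A = paste0(strrep("A", 20), strrep("C", 80)),
            B = paste0(strrep("A", 20), strrep("C", 80)),
            C = paste0(strrep("G", 20), strrep("C", 60), strrep("T", 20)),
            D = paste0(strrep("G", 20), strrep("C", 60), strrep("T", 20)))
  bt <- bootstrap_support(alignment(rows), 100, seed = 11)
  expect_equal(unname(attr(bt, "edge_support")["C|D"]), 1)
  bt2 <- bootstrap_support(alignment(rows), 100, seed = 11)
  expect_identical(attr(bt, "edge_support"), attr(bt2, "edge_support"))
  bt3 <- bootstrap_support(alignment(rows[c(3, 1, 4, 2)]), 100, seed = 11)
  expect_equal(unname(attr(bt3, "edge_support")["C|D"]), 1)
  # single replicate forces supports into {0, 1}
  b1 <- bootstrap_support(random_alignment(5, 60, seed = 2), 1, seed = 3)
  expect_true(all(attr(b1, "edge_support") %in% c(0, 1)))
  expect_error(bootstrap_support(alignment(rows), 0, seed = 1), "value")
})

test_that("duplicating the columns defining a split cannot decrease its support", {
  set.seed(31)
  aln <- random_alignment(6, 80, seed = 31)
  m <- aln$mat
  m[c("s1", "s2"), 1:6] <- "A"; m[c("s3", "s4", "s5", "s6"), 1:6] <- "G"
  base <- alignment(m)
  boosted <- alignment(cbind(m, m[, 1:6], m[, 1:6]))
  # the {s1,s2} split is stored under its canonical key: the side that
  # does not contain the alphabetically first leaf
  key <- paste(c("s3", "s4", "s5", "s6"), collapse = "|")
  for (sd in 1:3) {
    s0 <- attr(bootstrap_support(base, 60, seed = sd), "edge_support")[key]
    s1 <- attr(bootstrap_support(boosted, 60, seed = sd), "edge_support")[key]
    expect_false(is.na(s1))
    expect_gte(unname(s1), unname(s0) - 1e-12)
  }
})

test_that("sister groups are read off the outgroup-rooted tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(sister_group(tr, "A", "C"), "B")
  tr2 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:1,E:1):1);")
  expect_equal(sister_group(tr2, "C", c("D", "E")), c("A", "B"))
  expect_equal(sister_group(tr2, "A", c("D", "E")), "B")
  expect_error(sister_group(tr2, "Z", "D"), "lookup")
  expect_error(sister_group(tr2, "A", character(0)), "value")
  # incompatible outgroup (not a clade) is refused
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  expect_error(sister_group(tr3, "A", c("C", "E")), "rooting")
})
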