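# Independent oracles and small generators used across the suite.

# random gap-free alignment
random_alignment <- function(n, L, seed) {
  set.seed(seed)
  rows <- vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  names(rows) <- paste0("s", seq_len(n))
  alignment(rows)
}

# brute-force minimum extra homoplasy of a pair of characters over every
# unrooted tree on <= 6 taxa (phangorn tree enumeration + Fitch parsimony)
bf_pair_incompat <- function(col_a, col_b) {
  keep <- !(col_a %in% c("-", "N")) & !(col_b %in% c("-", "N"))
  a <- col_a[keep]; b <- col_b[keep]
  n <- length(a)
  stopifnot(n >= 3, n <= 6)
  mat <- rbind(a, b)
  colnames(mat) <- paste0("t", seq_len(n))
  dat <- phangorn::phyDat(t(mat), type = "USER",
                          levels = sort(unique(c(a, b))))
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = colnames(mat))
  best <- min(vapply(trees, function(tr)
    sum(phangorn::fitch(tr, dat, site = "site")), 0))
  lower <- (length(unique(a)) - 1L) + (length(unique(b)) - 1L)
  as.integer(best - lower)
}

# exact scan-statistic tail probability by exhaustive placement
# enumeration: P(max count in any `window`-column window >= m) for k
# distinct uniform positions among L columns
exact_scan_p <- function(k, L, window, m) {
  combos <- utils::combn(L, k) - 1L
  hits <- 0L
  for (i in seq_len(ncol(combos))) {
    pos <- combos[, i]
    best <- 1L; j <- 1L
    for (q in seq_along(pos)) {
      while (pos[q] - pos[j] >= window) j <- j + 1L
      best <- max(best, q - j + 1L)
    }
    if (best >= m) hits <- hits + 1L
  }
  hits / ncol(combos)
}

# independently coded Monte Carlo scan oracle (explicit window sweep,
# different algorithm and RNG stream than cluster_scan)
mc_scan_oracle <- function(k, L, window, m, reps, seed) {
  set.seed(seed)
  hits <- 0L
  starts <- 0:(L - window)
  for (r in seq_len(reps)) {
    pos <- sort(sample.int(L, k) - 1L)
    counts <- vapply(starts, function(s)
      sum(pos >= s & pos < s + window), 0L)
    if (max(counts) >= m) hits <- hits + 1L
  }
  hits / reps
}

# four-point-condition oracle for the split of an additive 4-taxon matrix:
# returns the pair grouped together with the first taxon
four_point_split <- function(D) {
  ids <- rownames(D)
  sums <- c(AB_CD = D[1, 2] + D[3, 4],
            AC_BD = D[1, 3] + D[2, 4],
            AD_BC = D[1, 4] + D[2, 3])
  small <- names(which.min(sums))
  switch(small, AB_CD = ids[2], AC_BD = ids[3], AD_BC = ids[4])
}

# patristic distance matrix of a phylo, ordered by the given ids
patristic <- function(tree, ids) {
  pd <- ape::cophenetic.phylo(tree)
  pd[ids, ids]
}

digest_file <- function(p) unname(tools::md5sum(p))

# independent neighbour enumeration of codon site counts against the
# standard genetic code
enumerate_codon_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  sp <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), sp[pos])) {
    mut <- sp; mut[pos] <- b
    aa <- code[[paste0(mut, collapse = "")]]
    if (aa != "*" && aa == code[[codon]]) s <- s + 1 / 3
  }
  c(S = s, N = 3 - s)
}

# interval-union Jaccard overlap between reported and true tracts
interval_jaccard <- function(iv, truth) {
  cover <- function(df) {
    out <- integer(0)
    if (!is.null(df) && nrow(df))
      for (r in seq_len(nrow(df))) out <- c(out, df$start[r]:(df$end[r] - 1L))
    out
  }
  a <- cover(iv); b <- cover(truth)
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# deterministic per-case seed fan-out for property loops
case_seed <- function(base, i) as.integer((base * 1009 + i * 9973) %% 2147483647)
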