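# Pairwise homoplasy index (PHI): recombination is inferred when
# parsimoniously informative sites that are close together in the
# alignment are systematically more compatible with each other than a
# random ordering of the sites would predict.

#' Parsimoniously informative columns
#'
#' Columns with at least two states that are each carried by at least two
#' sequences; gaps and N are missing data.
#'
#' @param aln a \code{seg_alignment}
#' @return integer vector of 0-based column indices
#' @export
informative_sites <- function(aln) {
  m <- aln$mat
  keep <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j][!(m[, j] %in% c("-", "N"))])
    sum(tab >= 2L) >= 2L
  }, TRUE)
  which(keep) - 1L
}

#' Refined incompatibility score of two site columns
#'
#' The minimum number of extra state changes that the pair of characters
#' forces on any single tree. Computed from the bipartite state
#' co-occurrence graph (vertices: observed states of each column; edges:
#' observed joint state pairs) as E - V + C (edges minus vertices plus
#' connected components). Zero iff the two characters are compatible; the
#' classic four-gamete violation of two binary sites scores 1. Rows missing
#' in either column are dropped pairwise.
#'
#' @param col_a,col_b character vectors of states for the same sequences
#' @return integer score, or \code{NA} if fewer than 2 rows remain
#' @export
pair_incompatibility <- function(col_a, col_b) {
  ok <- !(col_a %in% c("-", "N")) & !(col_b %in% c("-", "N"))
  a <- col_a[ok]; b <- col_b[ok]
  if (length(a) < 2L) return(NA_integer_)
  joint <- unique(paste(a, b))
  va <- unique(a); vb <- unique(b)
  E <- length(joint)
  V <- length(va) + length(vb)
  # connected components of the bipartite graph via label propagation
  comp_a <- stats::setNames(seq_along(va), va)
  comp_b <- stats::setNames(rep(NA_integer_, length(vb)), vb)
  edges <- do.call(rbind, strsplit(joint, " ", fixed = TRUE))
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      ca <- comp_a[[edges[e, 1]]]; cb <- comp_b[[edges[e, 2]]]
      if (is.na(cb) || cb > ca) { comp_b[[edges[e, 2]]] <- ca; changed <- TRUE }
      else if (cb < ca) { comp_a[[edges[e, 1]]] <- cb; changed <- TRUE }
    }
    if (!changed) break
  }
  C <- length(unique(c(comp_a, comp_b)))
  as.integer(E - V + C)
}

# symmetric matrix of pairwise incompatibility scores among the given
# informative columns (0-based); NA where a pair has < 2 complete rows
incompat_matrix <- function(aln, cols0) {
  k <- length(cols0)
  s <- matrix(0, k, k)
  if (k < 2L) return(s)
  colmat <- aln$mat[, cols0 + 1L, drop = FALSE]
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s[i, j] <- s[j, i] <- pair_incompatibility(colmat[, i], colmat[, j])
    }
  }
  s
}

#' The PHI statistic
#'
#' Mean refined incompatibility over unordered pairs of informative sites
#' whose column separation is at most \code{window_w}.
#'
#' @param aln a \code{seg_alignment}
#' @param window_w maximum column separation for "nearby" pairs (default
#'   100, the method's conventional window)
#' @return list: phi, n_informative, window_w, n_pairs, degenerate flag
#'   (TRUE when no qualifying pair exists, in which case phi = 0)
#' @export
phi_statistic <- function(aln, window_w = 100L) {
  cols0 <- informative_sites(aln)
  k <- length(cols0)
  res <- list(phi = 0, n_informative = k, window_w = window_w,
              n_pairs = 0L, degenerate = TRUE)
  if (k < 2L) return(res)
  s <- incompat_matrix(aln, cols0)
  sep <- abs(outer(cols0, cols0, `-`))
  mask <- upper.tri(sep) & sep <= window_w & !is.na(s)
  if (!any(mask)) return(res)
  res$phi <- mean(s[mask])
  res$n_pairs <- sum(mask)
  res$degenerate <- FALSE
  res
}

# exact permutation-null mean and variance of the PHI statistic, from the
# score matrix s (k x k symmetric, 0 diagonal) and the logical window mask
# over site slots (upper triangle). U-statistic moments over a uniformly
# random relabelling of sites.
phi_null_moments <- function(s, mask) {
  k <- nrow(s)
  M <- sum(mask)
  P <- sum(s[upper.tri(s)])
  Q <- sum(s[upper.tri(s)]^2)
  R <- rowSums(s)
  n2 <- k * (k - 1) / 2
  mu1 <- P / n2
  Ex2 <- Q / n2
  # ordered sums over pairs (A, B) of unordered index pairs:
  # sharing exactly one index -> for shared index a, ordered (b, c), b != c:
  # sum_a (R_a^2 - sum_b s_ab^2); count = k (k-1)(k-2)
  share1_ord <- sum(R^2) - 2 * Q
  disj_ord <- P^2 - Q - share1_ord              # fully disjoint ordered pairs
  mu2 <- if (k > 2) share1_ord / (k * (k - 1) * (k - 2)) else 0
  n_disj <- n2 * (k - 2) * (k - 3) / 2
  mu3 <- if (k > 3 && n_disj > 0) disj_ord / n_disj else 0
  # slot-mask overlap counts
  idx <- which(mask, arr.ind = TRUE)
  deg <- tabulate(c(idx[, 1], idx[, 2]), nbins = k)
  c1 <- sum(deg * (deg - 1))                    # ordered distinct masked pairs sharing a slot
  c0 <- M * (M - 1) - c1
  Ephi2 <- (M * Ex2 + c1 * mu2 + c0 * mu3) / M^2
  list(mean = mu1, var = max(Ephi2 - mu1^2, 0))
}

#' The PHI test for recombination
#'
#' The null distribution is generated by uniformly permuting the order of
#' the informative sites (column separations recomputed under the permuted
#' order); recombination compresses compatibility into nearby pairs, so the
#' test is one-sided towards small observed PHI. The permutation p-value
#' uses the add-one estimator \eqn{(1 + \#\{\Phi_{perm} \le \Phi_{obs}\}) /
#' (permutations + 1)} and therefore never returns 0. An optional analytic
#' p-value uses a normal approximation with the permutation-null mean and
#' variance computed exactly from the pairwise scores.
#'
#' @inheritParams phi_statistic
#' @param permutations number of permutations (default 1000)
#' @param seed integer seed; fixed seed gives identical output
#' @param analytic also compute the normal-approximation p-value
#' @return list: phi, n_informative, window_w, p_perm, p_analytic (or NA),
#'   permutations, seed, applicable flag (FALSE when too few informative
#'   sites or no qualifying pairs; then p_perm = 1)
#' @export
phi_test <- function(aln, window_w = 100L, permutations = 1000L, seed = 1L,
                     analytic = TRUE) {
  permutations <- as.integer(permutations)
  if (permutations < 1L) stop("value error: permutations must be >= 1",
                              call. = FALSE)
  cols0 <- informative_sites(aln)
  k <- length(cols0)
  base <- list(phi = 0, n_informative = k, window_w = window_w,
               p_perm = 1, p_analytic = NA_real_,
               permutations = permutations, seed = seed, applicable = FALSE)
  if (k < 3L) return(base)
  s <- incompat_matrix(aln, cols0)
  if (anyNA(s)) s[is.na(s)] <- 0   # pairs with <2 complete rows carry no signal
  sep <- abs(outer(cols0, cols0, `-`))
  mask <- upper.tri(sep) & sep <= window_w
  if (!any(mask)) return(base)
  midx <- which(mask, arr.ind = TRUE)
  phi_obs <- mean(s[midx])
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  nle <- 0L
  for (b in seq_len(permutations)) {
    sig <- sample.int(k)
    phi_b <- mean(s[cbind(sig[midx[, 1]], sig[midx[, 2]])])
    if (phi_b <= phi_obs + 1e-12) nle <- nle + 1L
  }
  p_perm <- (1 + nle) / (permutations + 1)
  p_analytic <- NA_real_
  if (analytic) {
    mom <- phi_null_moments(s, mask)
    p_analytic <- if (mom$var > 0)
      stats::pnorm((phi_obs - mom$mean) / sqrt(mom$var)) else 1
  }
  modifyList(base, list(phi = phi_obs, p_perm = p_perm,
                        p_analytic = p_analytic, applicable = TRUE))
}
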