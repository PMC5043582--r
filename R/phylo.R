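#' Pairwise p-distance matrix
#'
#' Uncorrected proportion of differing sites among sites where both
#' sequences have a non-missing state (pairwise deletion of gaps and N).
#'
#' @param aln a \code{seg_alignment} with at least two rows
#' @return a symmetric numeric matrix with dimnames = ids; class
#'   \code{"seg_dist"} is prepended for printing
#' @export
p_distance_matrix <- function(aln) {
  m <- aln$mat
  n <- nrow(m)
  if (n < 2L) stop("size error: need >= 2 sequences", call. = FALSE)
  miss <- m == "-" | m == "N"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !miss[i, ] & !miss[j, ]
      nc <- sum(ok)
      if (nc == 0L)
        stop("undefined distance: no shared non-missing columns for pair ",
             rownames(m)[i], " / ", rownames(m)[j], call. = FALSE)
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
    }
  }
  class(d) <- c("seg_dist", class(d))
  d
}

#' Neighbour-joining tree
#'
#' Saitou–Nei agglomeration on a distance matrix using the Q criterion.
#' Ties in the Q minimisation are broken by the smallest (row, column) index
#' pair so output is deterministic. Negative intermediate branch lengths are
#' clamped to zero with the deficit transferred to the partner branch (the
#' joined pair's total \code{d_ij} is preserved); the clamped total is
#' recorded in the \code{"clamped"} attribute.
#'
#' On an additive matrix the tree's patristic distances reproduce the input
#' exactly (to numerical precision).
#'
#' @param D symmetric distance matrix with dimnames (e.g. from
#'   [p_distance_matrix()]); n >= 3 taxa
#' @return an unrooted \code{ape::phylo} tree with branch lengths
#' @export
nj_tree <- function(D) {
  D <- unclass(D)
  n <- nrow(D)
  if (is.null(rownames(D))) stop("distance matrix needs dimnames", call. = FALSE)
  if (n < 3L) stop("size error: neighbour joining needs >= 3 taxa", call. = FALSE)
  if (any(!is.finite(D))) stop("value error: non-finite distances", call. = FALSE)
  labels <- rownames(D)
  # each active node is a newick fragment (subtree string without final ;)
  frag <- labels
  clamped <- 0
  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest (i,j), i<j, tie-break by row-major order
    qmin <- min(Q)
    idx <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped - li; lj <- lj + li; li <- 0 }
    if (lj < 0) { clamped <- clamped - lj; li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(D2) <- colnames(D2) <- seq_len(n - 1L)
    D <- D2
    n <- n - 1L
  }
  # final 3-node star: closed-form branch lengths
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (v in c("a", "b", "c3")) {
    if (get(v) < 0) { clamped <- clamped - get(v); assign(v, 0) }
  }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(a), frag[2], fmt(b), frag[3], fmt(c3))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is canonicalised
#' as the sorted leaf-label set on the side NOT containing the
#' alphabetically first leaf. Trivial splits (single leaf) are omitted.
#'
#' @param tree an \code{ape::phylo}
#' @return a character vector of canonical split keys (labels joined by
#'   \code{"|"}); names are per-edge indices into \code{tree$edge}
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  # descendant tips of every node
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  ord <- rev(ape::postorder(tree))        # parent before child
  for (e in rev(ord)) {                   # child-complete order
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) next                  # trivial split
    side <- desc[[ch]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    keys[as.character(e)] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' Robinson–Foulds distance
#'
#' Cardinality of the symmetric difference of the two trees' non-trivial
#' bipartition sets.
#'
#' @param t1,t2 \code{ape::phylo} trees over the same leaf set
#' @return integer RF distance
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("value error: leaf sets differ", call. = FALSE)
  b1 <- unique(unname(tree_bipartitions(t1)))
  b2 <- unique(unname(tree_bipartitions(t2)))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap support for the point-estimate NJ tree
#'
#' Columns are resampled with replacement per replicate; each replicate's
#' NJ tree is reduced to its bipartitions, and the support of each internal
#' edge of the point-estimate tree is the fraction of replicates containing
#' the same bipartition. Supports decorate the fixed point-estimate
#' topology (no consensus tree is formed).
#'
#' @param aln a \code{seg_alignment}
#' @param replicates number of bootstrap replicates (>= 1)
#' @param seed integer seed; same seed gives identical output
#' @return the point-estimate \code{phylo} with \code{node.label} set to the
#'   support fractions (root label empty) and an \code{"edge_support"}
#'   attribute mapping split keys to fractions
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L) {
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("value error: replicates must be >= 1", call. = FALSE)
  point <- nj_tree(p_distance_matrix(aln))
  keys <- tree_bipartitions(point)
  hits <- stats::setNames(numeric(length(keys)), unname(keys))
  L <- aln_length(aln)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    baln <- alignment(aln$mat[, cols, drop = FALSE],
                      frame_offset = NULL)
    btree <- tryCatch(nj_tree(p_distance_matrix(baln)), error = function(e) NULL)
    if (is.null(btree)) next
    bk <- unique(unname(tree_bipartitions(btree)))
    seen <- names(hits) %in% bk
    hits[seen] <- hits[seen] + 1
  }
  supp <- hits / replicates
  # decorate node labels: node.label[k] corresponds to internal node ntip+k
  ntip <- length(point$tip.label)
  labs <- rep("", point$Nnode)
  for (e in names(keys)) {
    ch <- point$edge[as.integer(e), 2]
    labs[ch - ntip] <- sprintf("%g", supp[[keys[[e]]]])
  }
  point$node.label <- labs
  attr(point, "edge_support") <- supp
  point
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sister group of a focal leaf under outgroup rooting
#'
#' Roots the tree on the outgroup edge and returns the leaf set of the
#' focal leaf's sibling subtree.
#'
#' @param tree unrooted \code{ape::phylo}
#' @param focal leaf id
#' @param outgroup one or more leaf ids, disjoint from \code{focal}
#' @return character vector of sister-group leaf ids
#' @export
sister_group <- function(tree, focal, outgroup) {
  if (!focal %in% tree$tip.label)
    stop("lookup error: focal leaf not in tree: ", focal, call. = FALSE)
  if (length(outgroup) == 0L || focal %in% outgroup)
    stop("value error: outgroup must be non-empty and exclude focal",
         call. = FALSE)
  if (!all(outgroup %in% tree$tip.label))
    stop("lookup error: outgroup leaf absent from tree", call. = FALSE)
  if (length(outgroup) > 1L && !ape::is.monophyletic(tree, outgroup))
    stop("rooting error: outgroup is not a clade in the unrooted tree",
         call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ntip <- length(rooted$tip.label)
  focal_i <- match(focal, rooted$tip.label)
  parent <- rooted$edge[rooted$edge[, 2] == focal_i, 1]
  sibs <- rooted$edge[rooted$edge[, 1] == parent & rooted$edge[, 2] != focal_i, 2]
  out <- character(0)
  for (s in sibs) out <- c(out, tips_below(rooted, s))
  setdiff(out, outgroup)
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}
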