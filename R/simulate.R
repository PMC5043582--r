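# Gene-family simulator: point mutation under JC69 along a tree, planted
# conversion (segmental-exchange) tracts with ground truth, neutral coding
# evolution for calibrating the selection test, and tandem repeat-unit
# copy-number variants. Every generator is deterministic under a fixed
# seed.

BASES <- c("A", "C", "G", "T")

#' Configuration for a gene-family simulation
#'
#' @param n_genes number of genes (tips) when no tree is supplied
#' @param tree newick string for a fixed tree, or NULL for a Yule tree of
#'   \code{n_genes} tips with the given \code{birth} rate
#' @param birth Yule birth rate (used when \code{tree} is NULL)
#' @param seq_length alignment length in columns (multiple of 3 when
#'   \code{coding})
#' @param subst_rate substitutions per site per unit branch length (JC69)
#' @param conversion_events either a list of explicit events — each a list
#'   with \code{donor}, \code{recipient} (tip ids), \code{start},
#'   \code{end} (0-based half-open columns) and \code{time} (fraction of
#'   the recipient's terminal branch, 1 = at the tip) — or a single
#'   numeric rate of events per tip lineage
#' @param tract_mean mean of the geometric tract-length distribution (nt),
#'   used when events are drawn by rate
#' @param coding evolve as codons, rejecting stop-creating mutations
#' @param seed integer seed
#' @return a list of class \code{family_sim_config}
#' @export
family_sim_config <- function(n_genes = 5L, tree = NULL, birth = 1,
                              seq_length = 300L, subst_rate = 0.05,
                              conversion_events = list(), tract_mean = 30,
                              coding = FALSE, seed = 1L) {
  if (subst_rate < 0 || tract_mean < 1 || seq_length < 3L)
    stop("value error: rates >= 0, tract_mean >= 1, seq_length >= 3",
         call. = FALSE)
  if (coding && seq_length %% 3L != 0L)
    stop("value error: coding sequences need length divisible by 3",
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), tree = tree, birth = birth,
                 seq_length = as.integer(seq_length),
                 subst_rate = subst_rate,
                 conversion_events = conversion_events,
                 tract_mean = tract_mean, coding = coding,
                 seed = as.integer(seed)),
            class = "family_sim_config")
}

# JC69 single-branch evolution of a base vector; expected fraction of
# changed sites is (3/4)(1 - exp(-4 mu t / 3))
jc69_mutate <- function(seq, mu_t) {
  if (mu_t <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * mu_t / 3))
  hit <- which(stats::runif(length(seq)) < p)
  for (i in hit) seq[i] <- sample(setdiff(BASES, seq[i]), 1L)
  seq
}

# codon-aware variant: substitutions that would create an internal stop
# are redrawn among the remaining bases (or skipped if none is viable)
jc69_mutate_coding <- function(seq, mu_t) {
  if (mu_t <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * mu_t / 3))
  hit <- which(stats::runif(length(seq)) < p)
  for (i in hit) {
    cod_start <- ((i - 1L) %/% 3L) * 3L + 1L
    for (b in sample(setdiff(BASES, seq[i]))) {
      cand <- seq[cod_start:(cod_start + 2L)]
      cand[i - cod_start + 1L] <- b
      if (!is_stop(paste0(cand, collapse = ""))) { seq[i] <- b; break }
    }
  }
  seq
}

sim_tree <- function(cfg) {
  if (!is.null(cfg$tree)) {
    tr <- ape::read.tree(text = cfg$tree)
  } else {
    tr <- ape::rphylo(cfg$n_genes, birth = cfg$birth, death = 0)
    tr$tip.label <- paste0("g", seq_len(cfg$n_genes))
    # rescale to unit height so subst_rate is per site per tree depth
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  }
  tr
}

random_seq <- function(L) sample(BASES, L, replace = TRUE)

random_coding_seq <- function(L) {
  tab <- ng_tables()
  codons <- sample(tab$sense, L %/% 3L, replace = TRUE)
  unlist(strsplit(codons, ""))
}

#' Simulate a gene family with planted conversion tracts
#'
#' Sequences evolve by JC69 along the tree; each conversion event copies
#' the donor's present-day tract into the recipient at the stated fraction
#' of the recipient's terminal branch, after which the recipient finishes
#' the remainder of its branch (so tracts can accrue post-event
#' mutations; an event with \code{time = 1} leaves the tract identical to
#' the donor's).
#'
#' @param cfg a [family_sim_config()]
#' @return list: \code{aln} (a \code{seg_alignment}), \code{events}
#'   (data.frame donor, recipient, start, end, time), \code{tree}
#' @export
simulate_family <- function(cfg) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  tr <- sim_tree(cfg)
  ntip <- length(tr$tip.label)
  mutate <- if (cfg$coding) jc69_mutate_coding else jc69_mutate
  rootseq <- if (cfg$coding) random_coding_seq(cfg$seq_length) else
    random_seq(cfg$seq_length)
  seqs <- vector("list", ntip + tr$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- rootseq
  edges <- ape::reorder.phylo(tr, "cladewise")$edge
  elen <- ape::reorder.phylo(tr, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    seqs[[ch]] <- mutate(seqs[[p]], cfg$subst_rate * elen[e])
  }
  # resolve events
  ev <- cfg$conversion_events
  if (is.numeric(ev) && length(ev) == 1L) {
    rate <- ev; ev <- list()
    for (tip in tr$tip.label) {
      for (r in seq_len(stats::rpois(1L, rate))) {
        donor <- sample(setdiff(tr$tip.label, tip), 1L)
        len <- min(cfg$seq_length,
                   1L + stats::rgeom(1L, 1 / cfg$tract_mean))
        start <- sample.int(cfg$seq_length - len + 1L, 1L) - 1L
        ev[[length(ev) + 1L]] <- list(donor = donor, recipient = tip,
                                      start = start, end = start + len,
                                      time = stats::runif(1L))
      }
    }
  }
  if (length(ev)) {
    by_recip <- split(ev, vapply(ev, `[[`, "", "recipient"))
    for (recip in names(by_recip)) {
      if (!recip %in% tr$tip.label)
        stop("config error: unknown recipient ", recip, call. = FALSE)
      tip_i <- match(recip, tr$tip.label)
      eidx <- which(edges[, 2] == tip_i)
      parent <- edges[eidx, 1]; blen <- elen[eidx]
      evs <- by_recip[[recip]]
      evs <- evs[order(vapply(evs, `[[`, 0, "time"))]
      cur <- seqs[[parent]]; tprev <- 0
      for (x in evs) {
        if (!x$donor %in% tr$tip.label)
          stop("config error: unknown donor ", x$donor, call. = FALSE)
        if (x$donor == recip)
          stop("config error: donor equals recipient", call. = FALSE)
        if (x$start < 0L || x$end > cfg$seq_length || x$start >= x$end)
          stop("config error: tract outside sequence bounds", call. = FALSE)
        cur <- mutate(cur, cfg$subst_rate * blen * (x$time - tprev))
        dseq <- seqs[[match(x$donor, tr$tip.label)]]
        cur[(x$start + 1L):x$end] <- dseq[(x$start + 1L):x$end]
        tprev <- x$time
      }
      cur <- mutate(cur, cfg$subst_rate * blen * (1 - tprev))
      seqs[[tip_i]] <- cur
    }
  }
  rows <- vapply(seq_len(ntip), function(i) paste0(seqs[[i]], collapse = ""),
                 "")
  names(rows) <- tr$tip.label
  events <- if (length(ev)) {
    data.frame(donor = vapply(ev, `[[`, "", "donor"),
               recipient = vapply(ev, `[[`, "", "recipient"),
               start = vapply(ev, function(x) as.integer(x$start), 0L),
               end = vapply(ev, function(x) as.integer(x$end), 0L),
               time = vapply(ev, `[[`, 0, "time"))
  } else {
    data.frame(donor = character(), recipient = character(),
               start = integer(), end = integer(), time = numeric())
  }
  list(aln = alignment(rows,
                       frame_offset = if (cfg$coding) 0L else NULL),
       events = events, tree = tr)
}

#' Simulate a neutral coding alignment
#'
#' All mutations are accepted regardless of amino-acid effect, except that
#' stop-creating substitutions are redrawn; the reading frame is
#' preserved, so the output contains no internal stop codons. Calibration
#' input for [selection_z_test()].
#'
#' @param cfg a [family_sim_config()] with \code{coding = TRUE}
#' @return a \code{seg_alignment} with \code{frame_offset = 0}
#' @export
simulate_neutral_coding <- function(cfg) {
  if (!cfg$coding) stop("value error: cfg$coding must be TRUE", call. = FALSE)
  simulate_family(cfg)$aln
}

#' Simulate tandem repeat-unit copy-number variants
#'
#' Each variant is \code{flank_left + k copies of the repeat unit +
#' flank_right}, with k drawn uniformly from \code{copy_range}; the truth
#' is recorded. Mirrors repeat-block expansion/contraction of a multi-exon
#' unit in a cytoplasmic tail.
#'
#' @param unit_library named character vector of unit sequences
#' @param repeat_unit id of the unit subject to copy-number variation
#' @param copy_range integer vector of permitted copy numbers (within
#'   1..10)
#' @param flank_left,flank_right ids of the fixed flanking units (in
#'   order)
#' @param n_variants number of variants to draw
#' @param seed integer seed
#' @return list: sequences (named character vector), truth (integer copy
#'   numbers)
#' @export
simulate_repeat_cnv <- function(unit_library, repeat_unit,
                                copy_range = 1:3,
                                flank_left = character(),
                                flank_right = character(),
                                n_variants = 5L, seed = 1L) {
  if (length(unit_library) == 0L)
    stop("value error: empty unit library", call. = FALSE)
  if (any(copy_range < 1L) || any(copy_range > 10L))
    stop("value error: copy_range must lie in 1..10", call. = FALSE)
  stopifnot(repeat_unit %in% names(unit_library),
            all(c(flank_left, flank_right) %in% names(unit_library)))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  ks <- sample(rep(copy_range, 2L), n_variants, replace = TRUE)
  seqs <- vapply(ks, function(k) {
    paste0(c(unit_library[flank_left],
             rep(unit_library[[repeat_unit]], k),
             unit_library[flank_right]), collapse = "")
  }, "")
  names(seqs) <- paste0("variant", seq_len(n_variants))
  list(sequences = seqs, truth = as.integer(ks))
}
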