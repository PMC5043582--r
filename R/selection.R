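# Nei-Gojobori (1986) synonymous/non-synonymous counting with p-distance
# proportions, pathway averaging for multi-hit codons, and a bootstrap
# Z-test of selection. Site/difference tables for all 64 x 64 codon pairs
# are precomputed once per session and cached.

ng_env <- new.env(parent = emptyenv())

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

is_stop <- function(codon) codon_aa(codon) == "*"

#' Synonymous and non-synonymous site counts of a codon
#'
#' For each of the three positions, the synonymous contribution is the
#' fraction of the three possible single-base substitutions that preserve
#' the amino acid; substitutions creating stop codons count as
#' non-synonymous. S + N = 3 exactly.
#'
#' @param codon a 3-mer over A,C,G,T that is not a stop codon
#' @return named numeric vector \code{c(S = ..., N = ...)}
#' @export
codon_sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("skipped codon: ambiguous or invalid codon ", codon, call. = FALSE)
  if (is_stop(codon))
    stop("value error: stop codon ", codon, call. = FALSE)
  aa <- codon_aa(codon)
  s <- 0
  bases <- c("A", "C", "G", "T")
  sp <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(bases, sp[pos])) {
      mut <- sp; mut[pos] <- b
      maa <- codon_aa(paste0(mut, collapse = ""))
      if (maa == aa) s <- s + 1 / 3   # stops (maa == "*") are non-synonymous
    }
  }
  c(S = s, N = 3 - s)
}

# classify one mutational step c1 -> c2 (1 when synonymous, 0 otherwise);
# steps touching a stop codon are non-synonymous
step_syn <- function(c1, c2) {
  a1 <- codon_aa(c1); a2 <- codon_aa(c2)
  if (a1 == "*" || a2 == "*") return(0)
  as.numeric(a1 == a2)
}

#' Synonymous and non-synonymous differences between two codons
#'
#' A single difference is classified directly. Two (three) differences are
#' averaged over the 2 (6) mutational pathways; pathways passing through a
#' stop codon are excluded and the rest re-weighted equally. If every
#' pathway passes through a stop, all pathways are used with stop steps
#' counted as non-synonymous (documented fallback).
#'
#' @param c1,c2 valid non-stop codons
#' @return named numeric vector \code{c(Sd = ..., Nd = ...)}
#' @export
codon_differences <- function(c1, c2) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  for (cc in c(c1, c2)) {
    if (!grepl("^[ACGT]{3}$", cc))
      stop("skipped codon: ambiguous or invalid codon ", cc, call. = FALSE)
    if (is_stop(cc)) stop("value error: stop codon ", cc, call. = FALSE)
  }
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  dpos <- which(s1 != s2)
  nd <- length(dpos)
  if (nd == 0L) return(c(Sd = 0, Nd = 0))
  perms <- switch(nd,
                  list(dpos),
                  list(dpos, rev(dpos)),
                  {p <- dpos; list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                                   p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])})
  path_scores <- lapply(perms, function(ord) {
    cur <- s1; syn <- 0; via_stop <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- s2[pos]
      ccur <- paste0(cur, collapse = ""); cnxt <- paste0(nxt, collapse = "")
      if (is_stop(cnxt)) via_stop <- TRUE
      syn <- syn + step_syn(ccur, cnxt)
      cur <- nxt
    }
    list(syn = syn, via_stop = via_stop)
  })
  ok <- !vapply(path_scores, `[[`, TRUE, "via_stop")
  use <- if (any(ok)) path_scores[ok] else path_scores
  sd_mean <- mean(vapply(use, `[[`, 0, "syn"))
  c(Sd = sd_mean, Nd = nd - sd_mean)
}

# lazy 64-codon lookup tables: sites (64 x 2) and pairwise differences
# (64 x 64 matrices), indexed by codon string
ng_tables <- function() {
  if (!is.null(ng_env$tab)) return(ng_env$tab)
  cods <- all_codons()
  sense <- cods[!vapply(cods, is_stop, TRUE)]
  sites <- t(vapply(sense, codon_sites, c(S = 0, N = 0)))
  Sd <- Nd <- matrix(NA_real_, length(sense), length(sense),
                     dimnames = list(sense, sense))
  for (i in seq_along(sense)) {
    for (j in i:length(sense)) {
      d <- codon_differences(sense[i], sense[j])
      Sd[i, j] <- Sd[j, i] <- d[["Sd"]]
      Nd[i, j] <- Nd[j, i] <- d[["Nd"]]
    }
  }
  ng_env$tab <- list(sense = sense, sites = sites, Sd = Sd, Nd = Nd)
  ng_env$tab
}

# split coding columns of an alignment into codon strings: returns an
# n_seq x n_codon character matrix ("---"-style codons left intact)
codon_matrix <- function(aln, coding_range = NULL, frame = 0L) {
  L <- aln_length(aln)
  if (is.null(coding_range)) coding_range <- c(0L, L)
  start <- coding_range[1] + frame
  len <- coding_range[2] - start
  ncod <- len %/% 3L
  if (ncod < 1L) stop("empty input: no complete codon columns", call. = FALSE)
  cols <- start + seq_len(ncod * 3L)      # 1-based column indices
  m <- aln$mat[, cols, drop = FALSE]
  n <- nrow(m)
  cm <- matrix("", n, ncod, dimnames = list(rownames(m), NULL))
  for (k in seq_len(ncod)) {
    cm[, k] <- paste0(m[, 3 * k - 2], m[, 3 * k - 1], m[, 3 * k])
  }
  cm
}

# per-pair, per-codon-column contributions; invalid codons (gap/N/stop in
# either member) contribute zero everywhere for that pair
ng_pair_tables <- function(cm) {
  tab <- ng_tables()
  n <- nrow(cm); ncod <- ncol(cm)
  pairs <- utils::combn(n, 2)
  P <- ncol(pairs)
  Sx <- Nx <- Sdx <- Ndx <- matrix(0, P, ncod)
  valid <- matrix(FALSE, P, ncod)
  for (p in seq_len(P)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ci <- cm[i, ]; cj <- cm[j, ]
    ok <- ci %in% tab$sense & cj %in% tab$sense
    if (any(ok)) {
      Sx[p, ok] <- (tab$sites[ci[ok], "S"] + tab$sites[cj[ok], "S"]) / 2
      Nx[p, ok] <- (tab$sites[ci[ok], "N"] + tab$sites[cj[ok], "N"]) / 2
      Sdx[p, ok] <- tab$Sd[cbind(ci[ok], cj[ok])]
      Ndx[p, ok] <- tab$Nd[cbind(ci[ok], cj[ok])]
      valid[p, ok] <- TRUE
    }
  }
  list(pairs = pairs, S = Sx, N = Nx, Sd = Sdx, Nd = Ndx, valid = valid)
}

aggregate_ng <- function(pt, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(ncol(pt$S))
  P <- nrow(pt$S)
  S_tot <- sum(pt$S[, cols]); N_tot <- sum(pt$N[, cols])
  Sd <- sum(pt$Sd[, cols]); Nd <- sum(pt$Nd[, cols])
  list(S = S_tot / P, N = N_tot / P, Sd = Sd, Nd = Nd,
       pS = if (S_tot > 0) Sd / S_tot else 0,
       pN = if (N_tot > 0) Nd / N_tot else 0)
}

#' Overall-average Nei–Gojobori counts for an alignment
#'
#' Sums synonymous/non-synonymous differences and averages site counts over
#' all unordered sequence pairs; codons containing gaps, N, or a stop in
#' either member of a pair are excluded for that pair. Proportions pS, pN
#' are uncorrected (p-distance).
#'
#' @param aln a \code{seg_alignment} (>= 2 sequences)
#' @param coding_range \code{c(start, end)} 0-based half-open column range
#'   of the coding region (default: whole alignment)
#' @param frame 0-based offset within the range where codon 1 begins
#' @return list with S, N (pair-averaged sites), Sd, Nd (pair-summed
#'   differences), pS, pN (pooled proportions)
#' @export
ng_overall <- function(aln, coding_range = NULL, frame = 0L) {
  if (nrow(aln$mat) < 2L) stop("size error: need >= 2 sequences", call. = FALSE)
  cm <- codon_matrix(aln, coding_range, frame)
  pt <- ng_pair_tables(cm)
  if (!any(pt$valid)) stop("empty input: no complete codon columns", call. = FALSE)
  aggregate_ng(pt)
}

#' Codon-based Z-test of selection
#'
#' Z = (pN - pS) / sqrt(Var_boot(pN - pS)), with the variance estimated by
#' bootstrap over codon columns; the two-tailed p-value comes from the
#' standard normal. With identical sequences Z = 0 and p = 1; zero bootstrap
#' variance with pN != pS is reported as infinite |Z| with a warning.
#'
#' @inheritParams ng_overall
#' @param replicates bootstrap replicates (default 500)
#' @param seed integer seed (same seed, same Z)
#' @return list extending [ng_overall()] with Z, p, boot_replicates, seed
#' @export
selection_z_test <- function(aln, coding_range = NULL, frame = 0L,
                             replicates = 500L, seed = 1L) {
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("value error: replicates must be >= 2", call. = FALSE)
  cm <- codon_matrix(aln, coding_range, frame)
  pt <- ng_pair_tables(cm)
  obs <- aggregate_ng(pt)
  ncod <- ncol(pt$S)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  diffs <- vapply(seq_len(replicates), function(b) {
    cols <- sample.int(ncod, ncod, replace = TRUE)
    a <- aggregate_ng(pt, cols)
    a$pN - a$pS
  }, 0)
  v <- stats::var(diffs)
  delta <- obs$pN - obs$pS
  if (delta == 0) {
    Z <- 0; p <- 1
  } else if (v <= 0) {
    warning("zero bootstrap variance with pN != pS; |Z| infinite")
    Z <- sign(delta) * Inf; p <- 0
  } else {
    Z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(Z))
  }
  c(obs, list(Z = Z, p = p, boot_replicates = replicates, seed = seed))
}

#' Classify variant sites of a focal sequence against a background
#'
#' One record per column where the focal sequence differs from the strict
#' consensus of the background set. The effect is computed by substituting
#' the focal base into the background consensus codon context:
#' \code{synonymous} / \code{non-synonymous} inside the coding range,
#' \code{non-coding} outside it, \code{indel} when either state is a gap,
#' and \code{ambiguous} when the codon context is incomplete. Columns where
#' either state is missing (N) are skipped.
#'
#' @param aln a \code{seg_alignment}
#' @param focal focal sequence id
#' @param background background ids (consensus reference)
#' @param coding_range \code{c(start, end)} 0-based half-open coding range
#'   (NULL: everything non-coding)
#' @param frame 0-based offset of codon 1 within the coding range
#' @return data.frame: column (0-based), focal_state, background_state,
#'   effect
#' @export
classify_variants <- function(aln, focal, background,
                              coding_range = NULL, frame = 0L) {
  check_ids(aln, c(focal, background))
  cons <- consensus(aln, background)
  cvec <- strsplit(unclass(cons), "")[[1]]
  fvec <- aln$mat[focal, ]
  L <- aln_length(aln)
  diffc <- which(fvec != cvec & fvec != "N" & cvec != "N")
  if (!length(diffc))
    return(data.frame(column = integer(), focal_state = character(),
                      background_state = character(), effect = character()))
  in_coding <- function(col0) {
    !is.null(coding_range) && col0 >= coding_range[1] && col0 < coding_range[2]
  }
  eff <- character(length(diffc))
  for (k in seq_along(diffc)) {
    col <- diffc[k]; col0 <- col - 1L
    if (fvec[col] == "-" || cvec[col] == "-") { eff[k] <- "indel"; next }
    if (!in_coding(col0)) { eff[k] <- "non-coding"; next }
    cod_idx <- (col0 - coding_range[1] - frame) %/% 3L
    cstart <- coding_range[1] + frame + 3L * cod_idx    # 0-based codon start
    if (cod_idx < 0L || cstart + 3L > min(coding_range[2], L)) {
      eff[k] <- "ambiguous"; next
    }
    ref_codon <- paste0(cvec[(cstart + 1L):(cstart + 3L)], collapse = "")
    pos_in <- col0 - cstart + 1L
    alt <- strsplit(ref_codon, "")[[1]]; alt[pos_in] <- fvec[col]
    alt_codon <- paste0(alt, collapse = "")
    if (!grepl("^[ACGT]{3}$", ref_codon) || !grepl("^[ACGT]{3}$", alt_codon)) {
      eff[k] <- "ambiguous"
    } else {
      eff[k] <- if (codon_aa(ref_codon) == codon_aa(alt_codon))
        "synonymous" else "non-synonymous"
    }
  }
  data.frame(column = diffc - 1L, focal_state = unname(fvec[diffc]),
             background_state = cvec[diffc], effect = eff)
}

#' Variant census across an alignment
#'
#' Classifies, for every sequence, its differences from the all-sequence
#' consensus, and returns the union of variable columns with effects.
#' A column is counted once even when several sequences share the variant.
#'
#' @inheritParams classify_variants
#' @return data.frame: column, effect (per unique variable column; if two
#'   alternative states at one column disagree in effect the column is
#'   listed once per effect)
#' @export
variant_census <- function(aln, coding_range = NULL, frame = 0L) {
  ids <- aln_ids(aln)
  rows <- lapply(ids, function(id)
    classify_variants(aln, id, setdiff(ids, id), coding_range, frame))
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(column = integer(), effect = character()))
  u <- unique(all[, c("column", "effect")])
  u[order(u$column), , drop = FALSE]
}
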