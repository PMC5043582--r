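# Deterministic synthetic stand-in families. These are NOT real gene
# sequences: each constructor plants, into random background sequence, the
# variant geometry reported for the corresponding study system, so that
# every pipeline stage can be exercised against known truth without any
# external data.

derive1 <- c(A = "G", C = "T", G = "A", T = "C")   # donor/derived state
derive2 <- c(A = "C", C = "A", G = "T", T = "G")   # independent third state

#' Synthetic five-gene family with two exchanged cassettes
#'
#' A deterministic stand-in for a small gene family in which a recipient
#' gene \code{R} carries two short cassettes copied from a distant donor
#' \code{D}, against a background of three close relatives \code{B1, B2,
#' B3}. The planted geometry: over L = 300 columns (one V-domain exon,
#' frame 0), the recipient differs from the background consensus at
#' exactly 12 columns — 8 inside a 27-nt tract and 4 inside a 21-nt tract
#' — and the donor matches the recipient across both cassettes except at
#' one nucleotide (a post-exchange mutation). The donor additionally
#' carries scattered private substitutions plus substitutions shared with
#' \code{B3}, and \code{B1}/\code{B3} share another set, giving the family
#' realistic conflicting phylogenetic signal outside the cassettes.
#'
#' @param seed integer seed for the random background sequence
#' @return list: \code{aln}, \code{recipient}, \code{donor},
#'   \code{background}, \code{truth} (data.frame of true tract intervals),
#'   \code{diff_columns} (the 12 planted difference columns)
#' @export
cassette_family_fixture <- function(seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  L <- 300L
  base <- random_seq(L)
  # planted coordinates (0-based)
  tract1 <- c(75L, 102L)   # 27 nt
  tract2 <- c(150L, 171L)  # 21 nt
  diff1 <- c(75L, 79L, 83L, 87L, 91L, 95L, 99L, 101L)   # 8 columns
  diff2 <- c(150L, 156L, 162L, 168L)                    # 4 columns
  mut_col <- 91L            # post-exchange mutation (third state in R)
  x_cols <- c(2L, 7L, 13L, 19L, 24L, 30L, 35L, 44L)     # shared D + B3
  y_cols <- c(225L, 233L, 240L, 248L, 255L, 263L, 270L, 278L, 285L, 293L) # B1 + B3
  d_priv <- c(55L, 110L, 190L)
  b_priv <- list(B1 = c(65L, 205L), B2 = c(70L, 210L), B3 = c(72L, 215L))

  seqs <- list(D = base, R = base, B1 = base, B2 = base, B3 = base)
  set_at <- function(s, cols0, map) { s[cols0 + 1L] <- map[s[cols0 + 1L]]; s }
  donor_cols <- c(diff1, diff2)
  seqs$D <- set_at(seqs$D, donor_cols, derive1)
  seqs$D <- set_at(seqs$D, c(x_cols, d_priv), derive1)
  seqs$R <- set_at(seqs$R, donor_cols, derive1)
  seqs$R <- set_at(seqs$R, mut_col, derive2)            # the one mismatch vs D
  seqs$B3 <- set_at(seqs$B3, x_cols, derive1)
  seqs$B1 <- set_at(seqs$B1, y_cols, derive1)
  seqs$B3 <- set_at(seqs$B3, y_cols, derive1)
  for (b in names(b_priv)) seqs[[b]] <- set_at(seqs[[b]], b_priv[[b]], derive2)

  aln <- alignment(vapply(seqs, paste0, "", collapse = ""), frame_offset = 0L)
  list(aln = aln, recipient = "R", donor = "D",
       background = c("B1", "B2", "B3"),
       truth = column_interval(c(tract1[1], tract2[1]),
                               c(tract1[2], tract2[2])),
       diff_columns = sort(c(diff1, diff2)))
}

# place a single-base variant into specific rows of a sequence matrix
plant_variant <- function(mat, col0, rows, state) {
  mat[rows, col0 + 1L] <- state
  mat
}

#' Synthetic nearly monomorphic allele set
#'
#' Stand-in for a virtually monomorphic housekeeping gene sequenced from a
#' reference plus six lines: exactly seven variable positions, all
#' isolated SNPs — one in the 5'UTR, four in the 3'UTR, and two
#' non-synonymous coding SNPs (one shared by the reference and line 1,
#' one private to line 1).
#'
#' @param seed integer seed for the random background sequence
#' @return list: \code{aln}, \code{coding_range} (c(start, end), 0-based
#'   half-open), \code{frame}, \code{expected} (data.frame of the planted
#'   variant columns and effects)
#' @export
monomorphic_family_fixture <- function(seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  utr5 <- 60L; cds <- 900L; utr3 <- 150L
  L <- utr5 + cds + utr3
  ids <- c("ref", paste0("line", 1:6))
  coding <- random_coding_seq(cds)
  row <- c(random_seq(utr5), coding, random_seq(utr3))
  mat <- matrix(rep(row, each = length(ids)), nrow = length(ids),
                dimnames = list(ids, NULL))
  # non-coding singletons: one 5'UTR, four 3'UTR
  nc_cols <- c(20L, utr5 + cds + c(10L, 45L, 80L, 120L))
  carriers <- c("line2", "line3", "line4", "line5", "line6")
  for (i in seq_along(nc_cols)) {
    col0 <- nc_cols[i]
    mat <- plant_variant(mat, col0, carriers[i],
                         derive1[[mat[1, col0 + 1L]]])
  }
  # non-synonymous SNP 1: Lys (AAG) consensus vs Met (ATG) in ref + line1
  cod_i <- 40L                                  # codon index (0-based)
  cstart <- utr5 + 3L * cod_i
  mat[, cstart + (1:3)] <- matrix(rep(c("A", "A", "G"), each = nrow(mat)),
                                  nrow = nrow(mat))
  mat <- plant_variant(mat, cstart + 1L, c("ref", "line1"), "T")
  # non-synonymous SNP 2: Ile (ATT) consensus vs Ser (AGT) in line1
  cod_j <- 200L
  cstart2 <- utr5 + 3L * cod_j
  mat[, cstart2 + (1:3)] <- matrix(rep(c("A", "T", "T"), each = nrow(mat)),
                                   nrow = nrow(mat))
  mat <- plant_variant(mat, cstart2 + 1L, "line1", "G")
  expected <- data.frame(
    column = c(nc_cols, cstart + 1L, cstart2 + 1L),
    effect = c(rep("non-coding", 5L), "non-synonymous", "non-synonymous"))
  list(aln = alignment(mat, frame_offset = NULL),
       coding_range = c(utr5, utr5 + cds), frame = 0L,
       expected = expected[order(expected$column), ])
}

#' Synthetic polymorphic allele set evolving by point mutation
#'
#' Stand-in for a six-allele gene whose variation is isolated SNPs (no
#' segmental exchange): six variable positions in the 5'UTR, seven in the
#' 3'UTR, and in the coding region 39 non-synonymous and 9 synonymous
#' variant positions, most carried by one divergent allele. A handful of
#' variants are shared by one fixed allele pair so that informative sites
#' exist but are mutually compatible — the homoplasy-index test therefore
#' returns p = 1.
#'
#' @param seed integer seed
#' @return list: \code{aln}, \code{coding_range}, \code{frame},
#'   \code{n_nonsyn}, \code{n_syn}, \code{n_utr5}, \code{n_utr3}
#' @export
point_mutation_family_fixture <- function(seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  utr5 <- 90L; cds <- 1200L; utr3 <- 210L
  L <- utr5 + cds + utr3
  ids <- paste0("allele", 1:6)
  divergent <- "allele6"
  coding <- random_coding_seq(cds)
  row <- c(random_seq(utr5), coding, random_seq(utr3))
  mat <- matrix(rep(row, each = 6L), nrow = 6L, dimnames = list(ids, NULL))

  # UTR singletons
  utr5_cols <- c(5L, 18L, 33L, 47L, 61L, 80L)
  utr3_cols <- utr5 + cds + c(8L, 35L, 62L, 95L, 130L, 165L, 195L)
  nc_carriers <- rep(c("allele2", "allele3", "allele4", divergent), length.out = 13L)
  for (i in seq_along(c(utr5_cols, utr3_cols))) {
    col0 <- c(utr5_cols, utr3_cols)[i]
    mat <- plant_variant(mat, col0, nc_carriers[i],
                         derive1[[mat[1, col0 + 1L]]])
  }

  # coding variants on dedicated codons: GGT placed at chosen codon
  # indices; first-position G->A is non-synonymous (Gly->Ser), third
  # position T->C is synonymous (Gly->Gly)
  n_nonsyn <- 39L; n_syn <- 9L
  cod_idx <- seq(2L, by = 8L, length.out = n_nonsyn + n_syn)  # spread out
  for (k in seq_along(cod_idx)) {
    cstart <- utr5 + 3L * cod_idx[k]
    mat[, cstart + (1:3)] <- matrix(rep(c("G", "G", "T"), each = 6L), nrow = 6L)
  }
  # carriers: most variants on the divergent allele; four of the
  # remainder shared by the fixed pair {allele1, allele2}
  carrier_of <- function(k, n_total) {
    if (k <= round(0.75 * n_total)) divergent
    else if (k <= round(0.75 * n_total) + 4L) c("allele1", "allele2")
    else c("allele3", "allele4", "allele5")[1L + (k %% 3L)]
  }
  for (k in seq_len(n_nonsyn)) {
    cstart <- utr5 + 3L * cod_idx[k]
    mat <- plant_variant(mat, cstart, carrier_of(k, n_nonsyn), "A")
  }
  for (k in seq_len(n_syn)) {
    cstart <- utr5 + 3L * cod_idx[n_nonsyn + k]
    mat <- plant_variant(mat, cstart + 2L, carrier_of(k, n_syn), "C")
  }
  list(aln = alignment(mat, frame_offset = NULL),
       coding_range = c(utr5, utr5 + cds), frame = 0L,
       n_nonsyn = n_nonsyn, n_syn = n_syn,
       n_utr5 = length(utr5_cols), n_utr3 = length(utr3_cols))
}
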