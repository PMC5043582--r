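# Cassette detection: locate clustered differences between a recipient
# gene and its family background, assess clustering against a uniform
# placement null, excise the cassette intervals, compare the recipient's
# tree placement before and after, and attribute a donor.

#' Columns where a recipient differs from its background
#'
#' \code{consensus} mode reports columns where the recipient differs from
#' the strict consensus of the background set; \code{unanimous} mode only
#' columns where the background members all agree and the recipient
#' differs from every one of them. Missing states (gap/N) in the recipient
#' never count as differences.
#'
#' @param aln a \code{seg_alignment}
#' @param recipient recipient id
#' @param background non-empty id vector, excluding the recipient
#' @param mode \code{"consensus"} or \code{"unanimous"}
#' @return integer vector of 0-based columns
#' @export
difference_positions <- function(aln, recipient, background,
                                 mode = c("consensus", "unanimous")) {
  mode <- match.arg(mode)
  if (length(background) == 0L || recipient %in% background)
    stop("value error: background must be non-empty and exclude recipient",
         call. = FALSE)
  check_ids(aln, c(recipient, background))
  r <- aln$mat[recipient, ]
  bg <- aln$mat[background, , drop = FALSE]
  miss_r <- r %in% c("-", "N")
  if (mode == "consensus") {
    cvec <- strsplit(unclass(consensus(aln, background)), "")[[1]]
    hit <- r != cvec & !miss_r & cvec != "N"
  } else {
    agree <- apply(bg, 2L, function(col) {
      obs <- unique(col[!(col %in% c("-", "N"))])
      length(obs) == 1L
    })
    first <- apply(bg, 2L, function(col) {
      obs <- col[!(col %in% c("-", "N"))]
      if (length(obs)) obs[1] else "N"
    })
    hit <- agree & !miss_r & first != "N" & r != first
  }
  which(hit) - 1L
}

# maximum number of the sorted positions falling in any window of
# `window` consecutive columns
max_window_count <- function(pos, window) {
  if (!length(pos)) return(0L)
  pos <- sort(pos)
  best <- 1L
  j <- 1L
  for (i in seq_along(pos)) {
    while (pos[i] - pos[j] >= window) j <- j + 1L
    best <- max(best, i - j + 1L)
  }
  best
}

#' Scan for clusters of difference columns
#'
#' Clusters are maximal runs of difference columns in which consecutive
#' members are at most \code{gap_max} columns apart and the run span stays
#' within \code{scan_window}; runs with fewer than \code{min_count} members
#' are discarded. Significance: the Monte Carlo probability, under uniform
#' placement of the k observed differences among the L columns, that some
#' \code{scan_window}-column window contains at least as many differences
#' as the densest observed window (add-one estimator).
#'
#' @param columns 0-based difference columns (e.g. from
#'   [difference_positions()])
#' @param L alignment length
#' @param scan_window window length in columns (default 30)
#' @param gap_max maximum spacing between consecutive cluster members
#'   (default 6)
#' @param min_count minimum cluster size (default 3)
#' @param mc_replicates Monte Carlo replicates (default 10000)
#' @param seed integer seed
#' @return list of class \code{seg_cluster_report}: difference_columns,
#'   clusters (data.frame start, end, m — 0-based half-open spans),
#'   scan_window, m_max, p_cluster, mc_replicates, seed
#' @export
cluster_scan <- function(columns, L, scan_window = 30L, gap_max = 6L,
                         min_count = 3L, mc_replicates = 10000L, seed = 1L) {
  if (L < scan_window || scan_window < 1L)
    stop("value error: need L >= scan_window >= 1", call. = FALSE)
  if (mc_replicates < 1L)
    stop("value error: mc_replicates must be >= 1", call. = FALSE)
  columns <- sort(unique(as.integer(columns)))
  rep_empty <- list(difference_columns = columns,
                    clusters = data.frame(start = integer(), end = integer(),
                                          m = integer()),
                    scan_window = scan_window, m_max = 0L, p_cluster = 1,
                    mc_replicates = mc_replicates, seed = seed)
  class(rep_empty) <- "seg_cluster_report"
  if (!length(columns)) return(rep_empty)
  # greedy run formation under both the gap and span constraints
  runs <- list(); cur <- columns[1]
  for (x in columns[-1]) {
    if (x - cur[length(cur)] <= gap_max && x - cur[1] < scan_window) {
      cur <- c(cur, x)
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- x
    }
  }
  runs[[length(runs) + 1L]] <- cur
  keep <- runs[vapply(runs, length, 0L) >= min_count]
  clusters <- if (length(keep)) {
    data.frame(start = vapply(keep, min, 0L),
               end = vapply(keep, max, 0L) + 1L,
               m = vapply(keep, length, 0L))
  } else data.frame(start = integer(), end = integer(), m = integer())
  k <- length(columns)
  m_max <- max_window_count(columns, scan_window)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(mc_replicates)) {
    pos <- sample.int(L, k) - 1L
    if (max_window_count(pos, scan_window) >= m_max) hits <- hits + 1L
  }
  out <- rep_empty
  out$clusters <- clusters
  out$m_max <- m_max
  out$p_cluster <- (1 + hits) / (mc_replicates + 1)
  out
}

#' Cassette intervals from a cluster report
#'
#' One interval per cluster, spanning the first to last member column
#' (half-open); optionally widened outwards to codon boundaries.
#'
#' @param report a \code{seg_cluster_report}
#' @param frame 0-based column where codon 1 begins (used when padding)
#' @param pad_to_codon widen each interval to whole codons
#' @return data.frame of intervals (start, end), possibly empty
#' @export
cassette_intervals <- function(report, frame = 0L, pad_to_codon = FALSE) {
  cl <- report$clusters
  if (nrow(cl) == 0L) return(data.frame(start = integer(), end = integer()))
  start <- cl$start; end <- cl$end
  if (pad_to_codon) {
    start <- frame + ((start - frame) %/% 3L) * 3L
    end <- frame + ((end - frame + 2L) %/% 3L) * 3L
  }
  column_interval(pmax(start, 0L), end)
}

#' Remove column intervals from an alignment
#'
#' All rows are sliced identically; intervals must be disjoint and within
#' bounds. Removing nothing returns an identical alignment.
#'
#' @param aln a \code{seg_alignment}
#' @param intervals data.frame of 0-based half-open intervals (start, end)
#' @return a \code{seg_alignment} of length \code{L - sum(lengths)}
#' @export
excise_columns <- function(aln, intervals) {
  iv <- validate_intervals(intervals, aln_length(aln))
  if (nrow(iv) == 0L) return(aln)
  drop <- unlist(mapply(function(s, e) (s + 1L):e, iv$start, iv$end,
                        SIMPLIFY = FALSE))
  keep <- setdiff(seq_len(aln_length(aln)), drop)
  if (!length(keep))
    stop("empty alignment: all columns excised", call. = FALSE)
  alignment(aln$mat[, keep, drop = FALSE], frame_offset = aln$frame_offset)
}

#' Attribute a donor for cassette intervals
#'
#' Counts Hamming mismatches between the recipient and each candidate
#' within the union of the cassette intervals (columns where either state
#' is missing are excluded pairwise). The best donor minimises the
#' mismatch count; ties are reported, never silently broken.
#'
#' @param aln a \code{seg_alignment}
#' @param recipient recipient id
#' @param intervals non-empty data.frame of intervals (start, end)
#' @param candidates candidate donor ids (excluding the recipient)
#' @return list: mismatches (named integer vector), best_donor (character
#'   vector; length > 1 on ties), margin (runner-up minus best; 0 on ties)
#' @export
donor_attribution <- function(aln, recipient, intervals, candidates) {
  if (length(candidates) == 0L || recipient %in% candidates)
    stop("value error: candidates must be non-empty and exclude recipient",
         call. = FALSE)
  iv <- validate_intervals(intervals, aln_length(aln))
  if (nrow(iv) == 0L) stop("value error: intervals must be non-empty",
                           call. = FALSE)
  check_ids(aln, c(recipient, candidates))
  cols <- unlist(mapply(function(s, e) (s + 1L):e, iv$start, iv$end,
                        SIMPLIFY = FALSE))
  r <- aln$mat[recipient, cols]
  mm <- vapply(candidates, function(cand) {
    c0 <- aln$mat[cand, cols]
    ok <- !(r %in% c("-", "N")) & !(c0 %in% c("-", "N"))
    sum(r[ok] != c0[ok])
  }, 0L)
  best <- min(mm)
  winners <- names(mm)[mm == best]
  margin <- if (length(mm) > 1L && length(winners) == 1L)
    sort(mm)[2L] - best else 0L
  list(mismatches = mm, best_donor = winners, margin = as.integer(margin))
}

#' Topology shift after cassette excision
#'
#' Builds bootstrap NJ trees on the full alignment and on the alignment
#' with the cassette intervals excised (same bootstrap settings and seed),
#' and reports the recipient's sister group and its support before and
#' after, plus the Robinson–Foulds distance between the two point trees.
#'
#' @param aln a \code{seg_alignment}
#' @param recipient recipient id
#' @param intervals cassette intervals (may be empty: before == after)
#' @param outgroup outgroup id(s) used to root for sister-group reading;
#'   NULL roots on the leaf farthest from the recipient in the before tree
#' @param boot_replicates bootstrap replicates per tree (default 1000)
#' @param seed integer seed
#' @return list of class \code{seg_topology_shift}: sister_before,
#'   support_before, sister_after, support_after, rf_distance, intervals,
#'   tree_before, tree_after
#' @export
topology_shift <- function(aln, recipient, intervals, outgroup = NULL,
                           boot_replicates = 1000L, seed = 1L) {
  check_ids(aln, recipient)
  t_before <- bootstrap_support(aln, boot_replicates, seed)
  aln2 <- excise_columns(aln, intervals)
  t_after <- bootstrap_support(aln2, boot_replicates, seed)
  if (is.null(outgroup)) {
    D <- p_distance_matrix(aln)
    far <- names(which.max(D[recipient, setdiff(aln_ids(aln), recipient)]))
    outgroup <- far
  }
  sister_support <- function(tree, focal, og) {
    sg <- sister_group(tree, focal, og)
    supp <- attr(tree, "edge_support")
    # support of the split separating {focal + sister} is the focal
    # parent-edge split in the rooted reading; approximate by the best
    # matching bipartition {focal, sg} or its complement
    key1 <- paste(sort(c(focal, sg)), collapse = "|")
    ref <- sort(tree$tip.label)[1L]
    comp <- setdiff(tree$tip.label, c(focal, sg))
    key2 <- paste(sort(comp), collapse = "|")
    val <- supp[names(supp) %in% c(key1, key2)]
    list(sister = sg, support = if (length(val)) unname(val[1]) else NA_real_)
  }
  b <- sister_support(t_before, recipient, outgroup)
  a <- sister_support(t_after, recipient, outgroup)
  structure(list(sister_before = b$sister, support_before = b$support,
                 sister_after = a$sister, support_after = a$support,
                 rf_distance = robinson_foulds(t_before, t_after),
                 intervals = validate_intervals(intervals, aln_length(aln)),
                 outgroup = outgroup,
                 tree_before = t_before, tree_after = t_after),
            class = "seg_topology_shift")
}

#' Decompose a sequence into tandem repeat units
#'
#' Greedy left-to-right tiling by the best-matching unit from a unit
#' library (at most \code{max_mismatch_per_unit} mismatches per unit). The
#' copy number is the longest run of consecutive occurrences of the
#' declared repeat-block unit. Any un-tileable remainder is reported.
#'
#' @param seq nucleotide string
#' @param unit_library named character vector: unit id -> unit sequence
#' @param repeat_unit id of the repeat-block unit whose copy number is
#'   wanted (default: first unit)
#' @param max_mismatch_per_unit mismatch tolerance per tiled unit
#' @return list: units (ordered id vector), copy_number, remainder
#'   (possibly ""), offsets (0-based start of each tiled unit)
#' @export
repeat_unit_decomposition <- function(seq, unit_library,
                                      repeat_unit = names(unit_library)[1],
                                      max_mismatch_per_unit = 0L) {
  if (length(unit_library) == 0L)
    stop("value error: empty unit library", call. = FALSE)
  seq <- toupper(seq)
  units <- toupper(unit_library)
  # units must stay distinguishable at the tolerance
  if (length(units) > 1L) {
    for (i in seq_len(length(units) - 1L)) for (j in (i + 1L):length(units)) {
      if (nchar(units[i]) == nchar(units[j])) {
        mm <- sum(strsplit(units[i], "")[[1]] != strsplit(units[j], "")[[1]])
        if (mm <= max_mismatch_per_unit)
          stop("value error: units ", names(units)[i], " and ",
               names(units)[j], " are not distinguishable at tolerance ",
               max_mismatch_per_unit, call. = FALSE)
      }
    }
  }
  pos <- 0L; n <- nchar(seq)
  tiled <- character(0); offs <- integer(0)
  while (pos < n) {
    cand_mm <- vapply(units, function(u) {
      ul <- nchar(u)
      if (pos + ul > n) return(NA_integer_)
      frag <- substr(seq, pos + 1L, pos + ul)
      sum(strsplit(frag, "")[[1]] != strsplit(u, "")[[1]])
    }, 0L)
    ok <- which(!is.na(cand_mm) & cand_mm <= max_mismatch_per_unit)
    if (!length(ok)) break
    best <- min(cand_mm[ok])
    winners <- ok[cand_mm[ok] == best]
    if (length(winners) > 1L)
      stop("ambiguity error: units ",
           paste(names(units)[winners], collapse = ", "),
           " tie at position ", pos, call. = FALSE)
    w <- winners[1]
    tiled <- c(tiled, names(units)[w]); offs <- c(offs, pos)
    pos <- pos + nchar(units[w])
  }
  remainder <- if (pos < n) substr(seq, pos + 1L, n) else ""
  copy <- 0L
  if (length(tiled)) {
    r <- rle(tiled == repeat_unit)
    hits <- r$lengths[r$values]
    copy <- if (length(hits)) max(hits) else 0L
  }
  list(units = tiled, copy_number = as.integer(copy),
       remainder = remainder, offsets = offs)
}
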