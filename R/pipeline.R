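# End-to-end orchestration: variant census, selection test, PHI test,
# cassette scan with topology shift and donor attribution, written as
# plain TSV/JSON/newick reports with a manifest of every seed and setting.

# deterministic per-stage seed derived from the master seed and the stage
# name (31-polynomial string hash, kept inside 32-bit integer range)
stage_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(master) * 10007 + h) %% 2147483647L)
}

#' Pipeline configuration
#'
#' @param alignment a \code{seg_alignment} (or path to an aligned FASTA)
#' @param recipient recipient gene id
#' @param background background ids (the recipient's close family)
#' @param candidates donor-candidate ids
#' @param outgroup outgroup id(s) for rooted sister-group reading, or NULL
#' @param coding_range c(start, end) 0-based half-open coding range (NULL:
#'   treat the whole alignment as coding for the selection test)
#' @param frame 0-based codon offset within the coding range
#' @param window_w PHI window (columns)
#' @param permutations PHI permutations
#' @param boot_replicates bootstrap replicates for trees and selection
#' @param scan_window,gap_max,min_count cluster-scan settings
#' @param mc_replicates Monte Carlo replicates for the cluster p-value
#' @param seed master seed; all stage seeds are derived from it
#' @param out_dir output directory (created if missing)
#' @return list of class \code{seg_run_config}
#' @export
pipeline_config <- function(alignment, recipient, background, candidates,
                            outgroup = NULL, coding_range = NULL,
                            frame = 0L, window_w = 100L,
                            permutations = 1000L, boot_replicates = 1000L,
                            scan_window = 30L, gap_max = 6L, min_count = 3L,
                            mc_replicates = 10000L, seed = 1L,
                            out_dir = tempfile("segscan_run_")) {
  if (is.character(alignment)) alignment <- read_alignment(alignment)
  check_ids(alignment, c(recipient, background, candidates, outgroup))
  stopifnot(window_w >= 1L, permutations >= 1L, boot_replicates >= 1L,
            scan_window >= 1L, mc_replicates >= 1L)
  structure(list(alignment = alignment, recipient = recipient,
                 background = background, candidates = candidates,
                 outgroup = outgroup, coding_range = coding_range,
                 frame = frame, window_w = window_w,
                 permutations = permutations,
                 boot_replicates = boot_replicates,
                 scan_window = scan_window, gap_max = gap_max,
                 min_count = min_count, mc_replicates = mc_replicates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "seg_run_config")
}

#' Run the full segmental-exchange analysis
#'
#' Stages: (1) variant census of the recipient against the background,
#' (2) Nei–Gojobori selection Z-test over the coding range, (3) PHI
#' recombination test, (4) cluster scan of the recipient's difference
#' columns with cassette intervals, donor attribution, and (5) topology
#' shift before/after cassette excision. Writes \code{census.tsv},
#' \code{selection.tsv}, \code{phi.tsv}, \code{cassette.json},
#' \code{tree_before.nwk}, \code{tree_after.nwk} and \code{manifest.json}
#' into the output directory; re-running the same config reproduces all
#' outputs bit-identically.
#'
#' @param cfg a [pipeline_config()]
#' @return (invisibly) a list with all stage results and output paths
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "seg_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- cfg$alignment
  paths <- list()
  stage <- "census"
  res <- withCallingHandlers({
    out <- list()

    ## 1. variant census
    census <- classify_variants(aln, cfg$recipient, cfg$background,
                                cfg$coding_range, cfg$frame)
    paths$census <- file.path(cfg$out_dir, "census.tsv")
    utils::write.table(census, paths$census, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$census <- census

    ## 2. selection
    stage <- "selection"
    sel <- selection_z_test(aln, cfg$coding_range, cfg$frame,
                            replicates = max(cfg$boot_replicates, 2L),
                            seed = stage_seed(cfg$seed, "selection"))
    seltab <- data.frame(region = "coding", S = sel$S, N = sel$N,
                         Sd = sel$Sd, Nd = sel$Nd, pN = sel$pN, pS = sel$pS,
                         Z = sel$Z, p = sel$p,
                         replicates = sel$boot_replicates, seed = sel$seed)
    paths$selection <- file.path(cfg$out_dir, "selection.tsv")
    utils::write.table(seltab, paths$selection, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$selection <- sel

    ## 3. PHI test
    stage <- "phi"
    phi <- phi_test(aln, cfg$window_w, cfg$permutations,
                    seed = stage_seed(cfg$seed, "phi"))
    phitab <- data.frame(region = "all", n_informative = phi$n_informative,
                         window = phi$window_w, phi = phi$phi,
                         p_perm = phi$p_perm, p_analytic = phi$p_analytic,
                         permutations = phi$permutations, seed = phi$seed)
    paths$phi <- file.path(cfg$out_dir, "phi.tsv")
    utils::write.table(phitab, paths$phi, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$phi <- phi

    ## 4. cassette scan + donor attribution
    stage <- "cassette"
    diffs <- difference_positions(aln, cfg$recipient, cfg$background)
    scan <- cluster_scan(diffs, aln_length(aln), cfg$scan_window,
                         cfg$gap_max, cfg$min_count, cfg$mc_replicates,
                         seed = stage_seed(cfg$seed, "cassette"))
    intervals <- cassette_intervals(scan)
    attribution <- if (nrow(intervals))
      donor_attribution(aln, cfg$recipient, intervals, cfg$candidates)
    else NULL
    out$scan <- scan; out$intervals <- intervals
    out$attribution <- attribution

    ## 5. topology shift
    stage <- "topology"
    shift <- topology_shift(aln, cfg$recipient, intervals, cfg$outgroup,
                            cfg$boot_replicates,
                            seed = stage_seed(cfg$seed, "topology"))
    out$shift <- shift
    paths$tree_before <- file.path(cfg$out_dir, "tree_before.nwk")
    paths$tree_after <- file.path(cfg$out_dir, "tree_after.nwk")
    write_support_tree(shift$tree_before, paths$tree_before)
    write_support_tree(shift$tree_after, paths$tree_after)

    cass <- list(
      recipient = cfg$recipient,
      difference_columns = diffs,
      clusters = scan$clusters,
      m_max = scan$m_max,
      p_cluster = scan$p_cluster,
      intervals = intervals,
      attribution = if (is.null(attribution)) NULL else list(
        mismatches = as.list(attribution$mismatches),
        best_donor = attribution$best_donor,
        margin = attribution$margin),
      topology = list(sister_before = shift$sister_before,
                      support_before = shift$support_before,
                      sister_after = shift$sister_after,
                      support_after = shift$support_after,
                      rf_distance = shift$rf_distance))
    paths$cassette <- file.path(cfg$out_dir, "cassette.json")
    jsonlite::write_json(cass, paths$cassette, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    manifest <- list(
      recipient = cfg$recipient, background = cfg$background,
      candidates = cfg$candidates, outgroup = cfg$outgroup,
      coding_range = cfg$coding_range, frame = cfg$frame,
      window_w = cfg$window_w, permutations = cfg$permutations,
      boot_replicates = cfg$boot_replicates,
      scan_window = cfg$scan_window, gap_max = cfg$gap_max,
      min_count = cfg$min_count, mc_replicates = cfg$mc_replicates,
      master_seed = cfg$seed,
      stage_seeds = list(selection = stage_seed(cfg$seed, "selection"),
                         phi = stage_seed(cfg$seed, "phi"),
                         cassette = stage_seed(cfg$seed, "cassette"),
                         topology = stage_seed(cfg$seed, "topology")))
    paths$manifest <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res$paths <- paths
  invisible(res)
}

#' Write a tree with bootstrap supports as newick
#'
#' Branch lengths are written with six decimals and internal-node supports
#' as integer percents.
#'
#' @param tree a \code{phylo} with optional node labels holding support
#'   fractions
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_support_tree <- function(tree, path) {
  t2 <- tree
  if (!is.null(t2$node.label)) {
    lab <- suppressWarnings(as.numeric(t2$node.label))
    t2$node.label <- ifelse(is.na(lab), "", sprintf("%d", round(100 * lab)))
  }
  t2$edge.length <- round(t2$edge.length, 6)
  ape::write.tree(t2, file = path)
  invisible(path)
}
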