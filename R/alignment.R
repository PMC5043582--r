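#' Aligned nucleotide sequences
#'
#' The universal substrate of the pipeline: an immutable set of equal-length
#' nucleotide rows over the alphabet \code{A,C,G,T,-,N}, with unique
#' identifiers and an optional codon frame offset. Internally the rows are
#' held as an \code{n x L} character matrix so that column operations
#' (consensus, excision, site scans) are cheap.
#'
#' @param seqs named character vector of aligned sequences (equal length),
#'   or a character matrix of single characters with rownames as ids.
#' @param frame_offset optional 0-based column at which codon position 1
#'   begins; must be in \code{0:2}.
#'
#' @return an object of class \code{seg_alignment}: a list with elements
#'   \code{mat} (character matrix, rows named by id), \code{frame_offset}.
#' @export
alignment <- function(seqs, frame_offset = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (length(seqs) == 0L) stop("empty input: no sequences", call. = FALSE)
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("identifier error: all sequences must be named", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment shape error: rows have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("identifier error: ids must be present and unique", call. = FALSE)
  if (ncol(mat) < 1L) stop("alignment shape error: zero columns", call. = FALSE)
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("alignment alphabet error: unexpected state(s) ",
         paste(bad, collapse = ","), call. = FALSE)
  if (!is.null(frame_offset)) {
    frame_offset <- as.integer(frame_offset)
    if (frame_offset < 0L || frame_offset > 2L)
      stop("frame_offset must be in 0:2", call. = FALSE)
  }
  structure(list(mat = mat, frame_offset = frame_offset),
            class = "seg_alignment")
}

#' @export
print.seg_alignment <- function(x, ...) {
  cat(sprintf("<seg_alignment: %d sequences x %d columns>\n",
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Number of columns / sequence ids of an alignment
#' @param aln a \code{seg_alignment}
#' @return integer column count / character vector of ids
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' @rdname aln_length
#' @export
aln_ids <- function(aln) rownames(aln$mat)

#' Extract rows as strings
#' @param aln a \code{seg_alignment}
#' @param ids ids to extract (default all)
#' @return named character vector
#' @export
aln_strings <- function(aln, ids = aln_ids(aln)) {
  m <- aln$mat[ids, , drop = FALSE]
  stats::setNames(apply(m, 1L, paste0, collapse = ""), ids)
}

check_ids <- function(aln, ids) {
  missing <- setdiff(ids, aln_ids(aln))
  if (length(missing))
    stop("lookup error: id(s) not in alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read an aligned FASTA file
#'
#' Rows are uppercased and U is mapped to T; identifiers are taken from the
#' header line up to the first whitespace.
#'
#' @param path path to an aligned FASTA file
#' @param format only \code{"fasta"}
#' @param frame_offset optional codon frame offset, see [alignment()]
#' @return a \code{seg_alignment}
#' @export
read_alignment <- function(path, format = "fasta", frame_offset = NULL) {
  format <- match.arg(format, "fasta")
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty input: no FASTA records in ", path,
                              call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(names(seqs)))
    stop("identifier error: duplicate FASTA ids in ", path, call. = FALSE)
  alignment(seqs, frame_offset = frame_offset)
}

#' Write an alignment as FASTA
#'
#' Round-trips with [read_alignment()]; ids containing whitespace are a
#' documented lossy case (only the part before the first whitespace
#' survives a round trip).
#'
#' @param aln a \code{seg_alignment}
#' @param path output path
#' @param format only \code{"fasta"}
#' @return \code{path}, invisibly
#' @export
write_alignment <- function(aln, path, format = "fasta") {
  format <- match.arg(format, "fasta")
  set <- Biostrings::BStringSet(aln_strings(aln))
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Strict-majority consensus of a subset of rows
#'
#' Per column, the strict-majority nucleotide among non-gap, non-N states.
#' Ties are resolved deterministically in alphabetical order (A < C < G < T)
#' and flagged in the \code{"ambiguous"} attribute; columns that are all
#' missing yield \code{"N"} and are also flagged.
#'
#' @param aln a \code{seg_alignment}
#' @param subset ids to form the consensus over (default: all)
#' @return a single consensus string with a logical attribute
#'   \code{"ambiguous"} (one flag per column)
#' @export
consensus <- function(aln, subset = aln_ids(aln)) {
  if (length(subset) == 0L) stop("empty input: empty subset", call. = FALSE)
  check_ids(aln, subset)
  m <- aln$mat[subset, , drop = FALSE]
  states <- c("A", "C", "G", "T")
  counts <- vapply(states, function(s) colSums(m == s),
                   numeric(ncol(m)))                     # L x 4
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, states))
  top <- max.col(counts, ties.method = "first")          # alphabetical tie-break
  best <- counts[cbind(seq_len(nrow(counts)), top)]
  nties <- rowSums(counts == best & counts > 0)
  cons <- states[top]
  allmiss <- rowSums(counts) == 0
  cons[allmiss] <- "N"
  amb <- (nties > 1L) | allmiss
  structure(paste0(cons, collapse = ""), ambiguous = amb)
}

#' Column intervals (0-based, half-open)
#'
#' The coordinate convention used throughout: \code{start} is a 0-based
#' inclusive column index, \code{end} is exclusive, so the interval length
#' is \code{end - start}.
#'
#' @param start,end integer vectors of equal length
#' @return a data.frame with columns \code{start}, \code{end}
#' @export
column_interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end))
    stop("start and end must have equal length", call. = FALSE)
  if (any(start < 0L) || any(start >= end))
    stop("interval error: require 0 <= start < end", call. = FALSE)
  data.frame(start = start, end = end)
}

validate_intervals <- function(intervals, L) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(data.frame(start = integer(), end = integer()))
  iv <- column_interval(intervals$start, intervals$end)
  if (any(iv$end > L))
    stop("interval error: interval exceeds alignment length ", L,
         call. = FALSE)
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
    stop("interval error: overlapping intervals", call. = FALSE)
  iv
}

#' Read / write interval tables
#'
#' Tab-separated text with columns \code{id}, \code{start}, \code{end}
#' (0-based half-open; stated in a leading comment line).
#'
#' @param x data.frame with columns id, start, end
#' @param path file path
#' @return the data.frame (read) or \code{path} invisibly (write)
#' @export
write_intervals <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: id, start, end (0-based, half-open)", con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
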