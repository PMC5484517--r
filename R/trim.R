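# BLOSUM-based removal of gap-rich / poorly conserved alignment columns,
# in the spirit of BMGE (Criscuolo & Gribaldo 2010) but with a fully
# specified, testable contract rather than a bit-compatible re-implementation.

#' Per-column conservation scores
#'
#' For each column the score is the mean, over all ungapped residue pairs
#' (pairs involving `'-'` or `'X'` are excluded), of the similarity score
#' rescaled to `[0, 1]`: each pair score is shifted by the matrix minimum and
#' divided by the shifted self-score of the weaker partner, so a column of
#' identical residues scores exactly 1 whatever the residue. All-gap columns
#' score 0.
#'
#' @param aln an [aa_alignment()].
#' @param matrix a [similarity_matrix()].
#' @param rows optional subset of taxon ids to score over (default all).
#' @return numeric vector of length `n_columns(aln)`.
#' @export
column_conservation <- function(aln, matrix = similarity_matrix("BLOSUM30"),
                                rows = NULL) {
  if (!is.null(rows)) aln <- aln[rows, , drop = FALSE]
  lo <- min(matrix)
  selfs <- diag(matrix) - lo
  nm <- (matrix - lo) / outer(selfs, selfs, pmin)
  nm[nm > 1] <- 1
  nm[nm < 0] <- 0
  codes <- match(aln, AA_ALPHABET)
  dim(codes) <- dim(aln)
  vapply(seq_len(ncol(aln)), function(j) {
    cc <- codes[, j]
    cc <- cc[!is.na(cc)]
    if (length(cc) < 2L) return(0)
    tab <- tabulate(cc, 20L)
    # sum over unordered pairs via the residue count vector
    tot <- (sum((tab %*% nm) * tab) - sum(diag(nm) * tab)) / 2
    npair <- (length(cc)^2 - length(cc)) / 2
    tot / npair
  }, 0)
}

#' Trim ambiguously aligned / gap-rich columns
#'
#' A column is kept when its gap fraction is at most `gap_max` and its
#' conservation score, smoothed with a centered moving average of width
#' `smooth_window` (truncated at the alignment edges), is at least
#' `score_min`. The smoothing neighborhood is the surviving column sequence,
#' so the selection is iterated until it reaches a fixed point; trimming a
#' trimmed alignment therefore removes nothing further. The procedure is
#' deterministic.
#'
#' @param aln an [aa_alignment()].
#' @param matrix a [similarity_matrix()]; the default mirrors common practice
#'   for deep protein alignments (BLOSUM30).
#' @param gap_max maximum tolerated gap fraction per column.
#' @param score_min minimum smoothed conservation score.
#' @param smooth_window odd moving-average width.
#' @return a `trim_result`: list with `kept_columns` (sorted 0-based indices),
#'   `trimmed` (the trimmed [aa_alignment()]) and `parameters`.
#' @export
trim_columns <- function(aln, matrix = similarity_matrix("BLOSUM30"),
                         gap_max = 0.2, score_min = 0.5, smooth_window = 3L) {
  if (nrow(aln) == 0L || ncol(aln) == 0L) stop("empty alignment")
  stopifnot(gap_max >= 0, gap_max <= 1, score_min >= 0, score_min <= 1)
  if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
  g <- colMeans(aln == "-")
  c_raw <- column_conservation(aln, matrix)
  h <- (smooth_window - 1L) %/% 2L
  keep <- seq_len(ncol(aln))
  repeat {
    m <- length(keep)
    c_smooth <- vapply(seq_len(m), function(j) {
      mean(c_raw[keep[max(1L, j - h):min(m, j + h)]])
    }, 0)
    keep2 <- keep[g[keep] <= gap_max & c_smooth >= score_min]
    if (length(keep2) == length(keep)) break
    keep <- keep2
    if (!length(keep)) break
  }
  structure(list(
    kept_columns = keep - 1L,
    trimmed = aa_alignment(aln[, keep, drop = FALSE]),
    parameters = list(matrix = attr(matrix, "name"), gap_max = gap_max,
                      score_min = score_min, smooth_window = smooth_window)
  ), class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat("trim_result: kept", length(x$kept_columns), "columns (",
      x$parameters$matrix, ", gap_max", x$parameters$gap_max,
      ", score_min", x$parameters$score_min, ")\n")
  invisible(x)
}

#' Write kept columns as TSV
#' @param x a `trim_result`.
#' @param path output path.
#' @export
write_trim_result <- function(x, path) {
  utils::write.table(data.frame(kept_column = x$kept_columns), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
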