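# Screening marker alignments for foreign-origin patches: anchored
# insertions (indels private to focal taxa flanked by conserved regions),
# donor attribution by Smith-Waterman local alignment, and sliding-window
# clade-affinity breakpoint scanning.

#' Detect anchored insertions
#'
#' A hit is a maximal run of at least `min_len` columns where the focal taxon
#' carries residues while at least `ref_gap_min` of the reference rows are
#' gapped, flanked on both sides by `anchor_len` columns whose mean
#' conservation over the reference rows (see [column_conservation()]) reaches
#' `anchor_min_conservation`. Runs whose anchors would extend past the
#' alignment edge are dropped with a warning.
#'
#' @param aln an [aa_alignment()].
#' @param focal focal taxon ids (disjoint from `reference`).
#' @param reference reference taxon ids.
#' @param min_len minimum insertion length (columns); the default reflects
#'   the 5-31 residue range of reported archaeal EF2 insertions.
#' @param anchor_len anchor width in columns.
#' @param anchor_min_conservation minimum mean anchor conservation.
#' @param ref_gap_min minimum fraction of gapped reference rows inside a run.
#' @param matrix similarity matrix for the conservation score.
#' @return data.frame of hits (class `insertion_hits`): focal_taxon, start,
#'   end (0-based half-open), length, anchor intervals and scores, reference
#'   gap fraction.
#' @export
detect_anchored_insertions <- function(aln, focal, reference, min_len = 5L,
                                       anchor_len = 40L,
                                       anchor_min_conservation = 0.7,
                                       ref_gap_min = 0.8,
                                       matrix = similarity_matrix("BLOSUM30")) {
  stopifnot(length(intersect(focal, reference)) == 0L,
            all(c(focal, reference) %in% rownames(aln)))
  cons <- column_conservation(aln, matrix, rows = reference)
  ref_gap <- colMeans(aln[reference, , drop = FALSE] == "-")
  n <- ncol(aln)
  hits <- list()
  for (f in focal) {
    mask <- aln[f, ] != "-" & ref_gap >= ref_gap_min
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= min_len)) {
      s <- starts[i]; e <- ends[i]
      if (s - anchor_len < 1L || e + anchor_len > n) {
        warning("insertion run at columns [", s - 1L, ",", e,
                ") for '", f, "' touches the alignment edge; dropped")
        next
      }
      left <- (s - anchor_len):(s - 1L)
      right <- (e + 1L):(e + anchor_len)
      lc <- mean(cons[left]); rc <- mean(cons[right])
      if (lc < anchor_min_conservation || rc < anchor_min_conservation) next
      hits[[length(hits) + 1L]] <- data.frame(
        focal_taxon = f, start = s - 1L, end = e,
        length = sum(aln[f, s:e] != "-"),
        left_anchor_start = s - anchor_len - 1L, left_anchor_end = s - 1L,
        right_anchor_start = e, right_anchor_end = e + anchor_len,
        left_anchor_conservation = lc, right_anchor_conservation = rc,
        ref_gap_fraction = mean(ref_gap[s:e]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    focal_taxon = character(0), start = integer(0), end = integer(0),
    length = integer(0), left_anchor_start = integer(0),
    left_anchor_end = integer(0), right_anchor_start = integer(0),
    right_anchor_end = integer(0), left_anchor_conservation = numeric(0),
    right_anchor_conservation = numeric(0), ref_gap_fraction = numeric(0))
  class(out) <- c("insertion_hits", class(out))
  out
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Deterministic traceback (best cell first in row-major order; move ties
#' prefer diagonal, then up, then left); a gap of length L costs
#' `gap_open + L * gap_extend`; the score never drops below 0.
#'
#' @param query,subject peptide strings over the 20 amino-acid letters.
#' @param matrix a [similarity_matrix()] (BLOSUM62 is the usual choice for
#'   database-search-style scoring).
#' @param gap_open,gap_extend affine gap parameters.
#' @return list: `score`, `query_interval` and `subject_interval` (0-based
#'   half-open), `identity` (matches / alignment length), `alignment`
#'   (two-element character vector).
#' @export
local_align <- function(query, subject, matrix = similarity_matrix("BLOSUM62"),
                        gap_open = 11, gap_extend = 1) {
  enc <- function(s) {
    v <- match(strsplit(s, "")[[1L]], AA_ALPHABET)
    if (!length(v)) stop("empty sequence")
    if (anyNA(v)) stop("illegal character in peptide: ", s)
    v
  }
  q <- enc(query); s <- enc(subject)
  res <- cpp_smith_waterman(q, s, unclass(matrix), gap_open, gap_extend)
  len <- length(res$aligned_q)
  decode <- function(v) paste(ifelse(v == 0L, "-", AA_ALPHABET[pmax(v, 1L)]),
                              collapse = "")
  list(score = res$score,
       query_interval = c(res$q_start, res$q_end),
       subject_interval = c(res$s_start, res$s_end),
       identity = if (len > 0L) res$matches / len else 0,
       alignment = if (len > 0L) c(decode(res$aligned_q), decode(res$aligned_s))
                   else c("", ""))
}

#' Attribute an anchored insertion to a donor
#'
#' The focal insertion plus both anchors (gaps stripped) is aligned against
#' every candidate donor peptide; candidates are ranked by local-alignment
#' score. Donors may be given as a named character vector of peptides, or as
#' a named list of taxon sets whose (degapped) rows of `aln` are used.
#'
#' @param hit one row of [detect_anchored_insertions()] output.
#' @param aln the alignment the hit refers to.
#' @param donors named peptides, or named list mapping donor-set label to
#'   taxon ids present in `aln`.
#' @param matrix,gap_open,gap_extend passed to [local_align()].
#' @return a `donor_attribution`: data.frame ranked by score (donor_id,
#'   donor_label, score, identity) with the top label as attribute
#'   `top_label`.
#' @export
attribute_insertion_donor <- function(hit, aln, donors,
                                      matrix = similarity_matrix("BLOSUM62"),
                                      gap_open = 11, gap_extend = 1) {
  if (length(donors) == 0L) stop("empty donor set")
  f <- hit$focal_taxon
  cols <- (hit$left_anchor_start + 1L):hit$right_anchor_end
  query <- paste(aln[f, cols][aln[f, cols] != "-"], collapse = "")
  if (is.list(donors)) {
    ids <- unlist(donors, use.names = FALSE)
    labels <- rep(names(donors), lengths(donors))
    peps <- vapply(ids, function(tx) degap(aln, tx), "")
  } else {
    ids <- names(donors)
    labels <- names(donors)
    peps <- donors
  }
  rows <- lapply(seq_along(ids), function(i) {
    al <- local_align(query, peps[[i]], matrix, gap_open, gap_extend)
    data.frame(donor_id = ids[i], donor_label = labels[i], score = al$score,
               identity = al$identity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, top_label = out$donor_label[1L],
            class = c("donor_attribution", class(out)))
}

# Poisson-corrected distance between two rows over a column subset
row_distance <- function(aln, a, b, cols) {
  ra <- aln[a, cols]; rb <- aln[b, cols]
  ok <- ra != "-" & ra != "X" & rb != "-" & rb != "X"
  if (!any(ok)) return(NA_real_)
  p <- sum(ra[ok] != rb[ok]) / sum(ok)
  if (p >= 1 - exp(-10)) 10 else -log(1 - p)
}

#' Sliding-window clade-affinity scan with breakpoint detection
#'
#' Per window, the affinity of the focal taxon to each reference clade is the
#' mean Poisson-corrected distance to the clade members over the window's
#' shared ungapped columns. The breakpoint maximizes the two-segment score
#' `delta(b)`: the reduction in total best-clade distance achieved by
#' assigning the windows left and right of `b` to clades independently rather
#' than jointly. Its significance is assessed by permuting the window order.
#'
#' @param aln an [aa_alignment()].
#' @param focal_taxon focal taxon (member of no clade).
#' @param clades named list clade label -> taxon ids (>= 2 clades).
#' @param window window width (columns).
#' @param step window step.
#' @param n_permutations permutations for the p-value (add-one corrected).
#' @param seed RNG seed for the permutations.
#' @return an `affinity_profile`: `windows` (start/end, 0-based half-open),
#'   `affinity` (windows x clades), `breakpoint` (0-based column or `NA`),
#'   `delta`, `p_value`, `left_clade`, `right_clade`, `joint_clade`.
#' @export
segment_affinity_scan <- function(aln, focal_taxon, clades, window = 50L,
                                  step = 10L, n_permutations = 199L,
                                  seed = 1L) {
  stopifnot(length(clades) >= 2L, !is.null(names(clades)))
  if (focal_taxon %in% unlist(clades)) stop("focal taxon is inside a clade")
  if (window > ncol(aln)) stop("window exceeds the alignment width")
  starts <- seq(1L, ncol(aln) - window + 1L, by = step)
  W <- length(starts)
  G <- length(clades)
  aff <- matrix(NA_real_, W, G, dimnames = list(NULL, names(clades)))
  for (w in seq_len(W)) {
    cols <- starts[w]:(starts[w] + window - 1L)
    for (g in seq_len(G)) {
      d <- vapply(clades[[g]], function(tx) row_distance(aln, focal_taxon, tx, cols),
                  0)
      aff[w, g] <- if (all(is.na(d))) 10 else mean(d, na.rm = TRUE)
    }
  }
  seg_score <- function(rows) min(colSums(aff[rows, , drop = FALSE]))
  seg_clade <- function(rows) names(clades)[which.min(colSums(aff[rows, , drop = FALSE]))]
  delta_profile <- function(a) { # a: windows x clades
    joint <- min(colSums(a))
    vapply(seq_len(nrow(a) - 1L), function(b) {
      joint - (min(colSums(a[seq_len(b), , drop = FALSE])) +
                 min(colSums(a[(b + 1L):nrow(a), , drop = FALSE])))
    }, 0)
  }
  if (W < 2L) {
    out <- list(windows = data.frame(start = starts - 1L,
                                     end = starts + window - 1L),
                affinity = aff, breakpoint = NA_integer_, delta = 0,
                p_value = 1, left_clade = seg_clade(1L),
                right_clade = seg_clade(1L), joint_clade = seg_clade(1L))
    return(structure(out, class = "affinity_profile"))
  }
  dp <- delta_profile(aff)
  b <- which.max(dp)
  delta <- dp[b]
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- sample.int(W)
    if (max(delta_profile(aff[perm, , drop = FALSE])) >= delta) {
      exceed <- exceed + 1L
    }
  }
  left_cl <- seg_clade(seq_len(b))
  right_cl <- seg_clade((b + 1L):W)
  if (left_cl != right_cl) {
    # column-level refinement: the shared changepoint maximizing the joint
    # binomial profile likelihood of the focal taxon's per-column mismatch
    # series against the best-matching member of each segment's clade (the
    # closest relative carries the sharpest rate change at the boundary)
    mism_row <- function(tx) {
      r <- aln[tx, ]
      f <- aln[focal_taxon, ]
      ok <- r != "-" & r != "X" & f != "-" & f != "X"
      ifelse(ok, as.numeric(r != f), NA_real_)
    }
    pick_best <- function(cl) {
      rates <- vapply(clades[[cl]], function(tx) mean(mism_row(tx), na.rm = TRUE), 0)
      clades[[cl]][which.min(rates)]
    }
    bin_ll_profile <- function(x) {
      n <- length(x)
      k <- cumsum(ifelse(is.na(x), 0, x))
      m <- cumsum(!is.na(x))
      nl <- seq_len(n - 2L)
      seg <- function(kk, mm) {
        p <- ifelse(mm > 0, kk / mm, 0)
        ifelse(mm > 0 & p > 0 & p < 1,
               kk * log(p) + (mm - kk) * log(1 - p), 0)
      }
      seg(k[nl], m[nl]) + seg(k[n] - k[nl], m[n] - m[nl])
    }
    ll <- bin_ll_profile(mism_row(pick_best(left_cl))) +
      bin_ll_profile(mism_row(pick_best(right_cl)))
    bp_col <- which.max(ll) # 0-based first right-segment column
  } else {
    # fall back to the boundary between the centers of windows b and b+1
    bp_col <- as.integer(round((starts[b] - 1L) + window / 2 +
                                 (starts[b + 1L] - starts[b]) / 2))
  }
  structure(list(
    windows = data.frame(start = starts - 1L, end = starts + window - 1L),
    affinity = aff, breakpoint = as.integer(bp_col), delta = delta,
    p_value = (1 + exceed) / (n_permutations + 1),
    left_clade = left_cl, right_clade = right_cl,
    joint_clade = seg_clade(seq_len(W))), class = "affinity_profile")
}

#' @export
print.affinity_profile <- function(x, ...) {
  cat("affinity_profile:", nrow(x$windows), "windows;",
      if (is.na(x$breakpoint)) "no breakpoint"
      else paste0("breakpoint ~column ", x$breakpoint, " (", x$left_clade,
                  " | ", x$right_clade, "), delta ",
                  formatC(x$delta, digits = 4, format = "g"), ", p ",
                  formatC(x$p_value, digits = 3, format = "g")), "\n")
  invisible(x)
}

#' Split an alignment at a column boundary
#'
#' @param aln an [aa_alignment()].
#' @param column 0-based boundary, `0 < column < n_columns`; the left part
#'   gets columns `[0, column)`, the right part `[column, n_columns)`.
#' @return list of two [aa_alignment()]s (`left`, `right`).
#' @export
split_alignment_at <- function(aln, column) {
  if (column <= 0L || column >= ncol(aln)) {
    stop("split column must satisfy 0 < column < ", ncol(aln))
  }
  list(left = aa_alignment(aln[, seq_len(column), drop = FALSE]),
       right = aa_alignment(aln[, (column + 1L):ncol(aln), drop = FALSE]))
}
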