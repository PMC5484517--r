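# Poisson-corrected pairwise distances and neighbor joining.

#' Pairwise Poisson-corrected distances
#'
#' The mismatch fraction `p` is computed over columns where both rows carry a
#' residue (no `'-'`, no `'X'`); the distance is `-ln(1 - p)`, capped at 10.
#'
#' @param aln an [aa_alignment()] with at least two taxa.
#' @return symmetric numeric matrix with zero diagonal, taxon ids as dimnames.
#' @export
pairwise_distances <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 taxa")
  ok <- aln != "-" & aln != "X"
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  cap <- 10
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- ok[i, ] & ok[j, ]
      ns <- sum(shared)
      if (ns == 0L) {
        stop("no shared ungapped columns between '", rownames(aln)[i],
             "' and '", rownames(aln)[j], "'")
      }
      p <- sum(aln[i, shared] != aln[j, shared]) / ns
      d <- if (p >= 1 - exp(-cap)) cap else -log(1 - p)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration (Studier-Keppler Q criterion). Ties in
#' the Q criterion are broken by the lowest `(i, j)` index pair; negative
#' intermediate branch lengths are clamped to 0. Used as the starting tree
#' for [nni_search()].
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an unrooted ape `phylo`.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  stopifnot(!is.null(labels))
  frag <- labels # newick fragment per active cluster
  d <- D
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest (i, j) among minima, i < j
    idx <- which(Q == min(Q[upper.tri(Q)]), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
  }
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- d[1, 2] - a
  cc <- d[1, 3] - a
  nwk <- paste0("(", frag[1], ":", fmt(a), ",", frag[2], ":", fmt(b), ",",
                frag[3], ":", fmt(cc), ");")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
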