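# Approximately-unbiased topology test (Shimodaira 2002): multiscale RELL
# bootstrap of per-site log-likelihoods, weighted least-squares fit of the
# normal-quantile-transformed winning frequencies against signed distance and
# curvature, p = 1 - Phi(d - c).

# winning counts per tree for B replicates of m sites; RNG must already be
# seeded by the caller so naive RELL and the AU scale-1 draw coincide. Exact
# ties are broken uniformly at random (within the seeded stream) so that
# byte-identical topologies split their wins symmetrically.
rell_winners <- function(m, msize, B) {
  n <- nrow(m)
  idx <- matrix(sample.int(n, msize * B, replace = TRUE), msize, B)
  sums <- vapply(seq_len(ncol(m)),
                 function(k) colSums(matrix(m[idx, k], msize, B)), numeric(B))
  if (B == 1L) sums <- matrix(sums, nrow = 1L)
  max.col(sums, ties.method = "random")
}

#' Plain RELL bootstrap proportions
#'
#' Resamples whole-site log-likelihood rows (scale 1) and reports, per tree,
#' the fraction of replicates it wins.
#'
#' @param table a [site_loglik_table()] or a sites-x-trees numeric matrix.
#' @param B replicates.
#' @param seed RNG seed (the AU test's scale-1 draw uses
#'   `derive_seed(seed, "au-scale-<index of scale 1>")`).
#' @return named numeric vector of winning proportions.
#' @export
rell_bp <- function(table, B = 1000L, seed = 1L) {
  m <- if (inherits(table, "site_loglik_table")) table$matrix else table
  set.seed(seed)
  w <- rell_winners(m, nrow(m), B)
  setNames(tabulate(w, ncol(m)) / B, colnames(m))
}

#' Approximately-unbiased test over candidate topologies
#'
#' @param table a [site_loglik_table()] (or sites-x-trees matrix) with at
#'   least 10 sites.
#' @param scales resampling scale factors r (replicate size `round(r * n)`).
#' @param B_per_scale bootstrap replicates per scale.
#' @param seed master seed; scale `i` draws from
#'   `derive_seed(seed, sprintf("au-scale-%02d", i))`.
#' @param alpha confidence-set level: trees with `p >= alpha` are retained.
#' @return an `au_result`: data.frame `table` (tree_id, p, degenerate),
#'   `confidence_set`, the `bp` matrix (trees x scales) and `scales`.
#' @export
au_test <- function(table, scales = seq(0.5, 1.4, by = 0.1),
                    B_per_scale = 1000L, seed = 1L, alpha = 0.05) {
  m <- if (inherits(table, "site_loglik_table")) table$matrix else table
  if (is.null(dim(m)) || ncol(m) < 1L) stop("need at least one tree")
  n <- nrow(m)
  if (n < 10L) stop("need at least 10 sites")
  K <- ncol(m)
  ids <- colnames(m) %||% paste0("tree", seq_len(K))
  bp <- matrix(0, K, length(scales), dimnames = list(ids, scales))
  for (i in seq_along(scales)) {
    set.seed(derive_seed(seed, sprintf("au-scale-%02d", i)))
    w <- rell_winners(m, max(1L, round(scales[i] * n)), B_per_scale)
    bp[, i] <- tabulate(w, K) / B_per_scale
  }
  eps <- 0.5 / B_per_scale
  p <- numeric(K)
  degenerate <- logical(K)
  for (k in seq_len(K)) {
    if (all(bp[k, ] <= 0)) {
      p[k] <- 0
      degenerate[k] <- TRUE
    } else if (all(bp[k, ] >= 1)) {
      p[k] <- 1
      degenerate[k] <- TRUE
    } else {
      bpc <- pmin(pmax(bp[k, ], eps), 1 - eps)
      z <- qnorm(1 - bpc)
      X <- cbind(sqrt(scales), 1 / sqrt(scales))
      wts <- B_per_scale * dnorm(z)^2 / (bpc * (1 - bpc))
      coefs <- solve(crossprod(X, wts * X), crossprod(X, wts * z))
      p[k] <- min(1, max(0, 1 - pnorm(coefs[1L] - coefs[2L])))
    }
  }
  res <- data.frame(tree_id = ids, p = p, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  structure(list(table = res, confidence_set = ids[p >= alpha], bp = bp,
                 scales = scales, alpha = alpha), class = "au_result")
}

#' @export
print.au_result <- function(x, ...) {
  cat("au_result (alpha ", x$alpha, "):\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("confidence set:", paste(x$confidence_set, collapse = ", "), "\n")
  invisible(x)
}
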