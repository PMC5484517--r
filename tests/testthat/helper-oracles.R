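# Independent oracles used across the suite. Each reimplements the target
# quantity by brute force or a closed form, sharing no code with the package
# paths it checks.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_alignment <- function(n_taxa, n_cols, seed, gap_frac = 0) {
  set.seed(seed)
  m <- matrix(sample(AA, n_taxa * n_cols, replace = TRUE), n_taxa, n_cols)
  if (gap_frac > 0) m[runif(length(m)) < gap_frac] <- "-"
  rownames(m) <- paste0("t", seq_len(n_taxa))
  aa_alignment(m)
}

# exhaustive ancestral-state summation for the likelihood of small trees:
# every joint assignment of internal-node states is enumerated (vectorized
# over the assignment grid), nothing is pruned
brute_force_loglik <- function(tree, aln, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  internals <- (ntip + 1L):nn
  codes <- match(aln, AA)
  dim(codes) <- dim(aln)
  rownames(codes) <- rownames(aln)
  codes <- codes[tr$tip.label, , drop = FALSE]
  K <- model$n_categories
  G <- as.matrix(expand.grid(rep(list(1:20), length(internals)),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(G) <- as.character(internals)
  per_site <- numeric(ncol(aln))
  sitelik <- matrix(0, ncol(aln), K)
  for (k in seq_len(K)) {
    P <- lapply(seq_len(nrow(tr$edge)), function(e) {
      prob_matrix(model, tr$edge.length[e] * model$rates[k])
    })
    for (s in seq_len(ncol(aln))) {
      lik <- model$pi[G[, as.character(ntip + 1L)]]
      for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
        gp <- G[, as.character(p)]
        if (ch <= ntip) {
          obs <- codes[ch, s]
          if (!is.na(obs)) lik <- lik * P[[e]][cbind(gp, obs)]
        } else {
          lik <- lik * P[[e]][cbind(gp, G[, as.character(ch)])]
        }
      }
      sitelik[s, k] <- sum(lik)
    }
  }
  sum(log(rowMeans(sitelik)))
}

# exhaustive minimum-change count over all internal labelings
brute_force_min_changes <- function(tree, states) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  alph <- sort(unique(states))
  internals <- (ntip + 1L):(ntip + tr$Nnode)
  grids <- expand.grid(rep(list(seq_along(alph)), length(internals)))
  best <- Inf
  leaf_state <- match(states[tr$tip.label], alph)
  for (g in seq_len(nrow(grids))) {
    st <- integer(ntip + tr$Nnode)
    st[seq_len(ntip)] <- leaf_state
    st[internals] <- as.integer(grids[g, ])
    ch <- sum(st[tr$edge[, 1L]] != st[tr$edge[, 2L]])
    best <- min(best, ch)
  }
  best
}

# all minimum-change labelings (for MPR comparison)
brute_force_mprs <- function(tree, states) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  alph <- sort(unique(states))
  internals <- (ntip + 1L):(ntip + tr$Nnode)
  grids <- expand.grid(rep(list(seq_along(alph)), length(internals)))
  leaf_state <- match(states[tr$tip.label], alph)
  costs <- apply(grids, 1L, function(g) {
    st <- integer(ntip + tr$Nnode)
    st[seq_len(ntip)] <- leaf_state
    st[internals] <- as.integer(g)
    sum(st[tr$edge[, 1L]] != st[tr$edge[, 2L]])
  })
  list(min = min(costs), labelings = grids[costs == min(costs), , drop = FALSE],
       alph = alph)
}

# plain-R affine-gap local alignment score (no shared code with the C++ DP)
r_affine_local_score <- function(q, s, mat, open, extend) {
  qi <- match(strsplit(q, "")[[1L]], AA)
  si <- match(strsplit(s, "")[[1L]], AA)
  n <- length(qi); m <- length(si)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      F[i, j] <- max(H[i - 1, j] - (open + extend), F[i - 1, j] - extend)
      E[i, j] <- max(H[i, j - 1] - (open + extend), E[i, j - 1] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qi[i - 1], si[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# random unrooted binary tree with exponential branch lengths
random_tree <- function(n, seed, mean_len = 0.3) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) rexp(k, 1 / mean_len))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

small_model <- function(shape = 1, k = 2L) {
  substitution_model(gamma_shape = shape, n_categories = k)
}
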