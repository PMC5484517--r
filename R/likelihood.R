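# Maximum-likelihood machinery: pruning log-likelihood, branch-length
# optimization, NNI hill climbing, nonparametric bootstrap, and per-site
# log-likelihood tables for topology testing.

# Validate tree/alignment/model and put the tree in postorder with encoded
# tip data aligned to the tip numbering. Identical site patterns are
# collapsed to one weighted column (`w`, with `map` from original sites to
# pattern columns) so the pruning passes touch each pattern once.
engine_data <- function(tree, aln, model) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "aa_alignment"),
            inherits(model, "substitution_model"))
  if (!setequal(tree$tip.label, rownames(aln))) {
    stop("tree leaves and alignment taxa differ: ",
         paste(c(setdiff(tree$tip.label, rownames(aln)),
                 setdiff(rownames(aln), tree$tip.label)), collapse = ", "))
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tr <- ape::reorder.phylo(tree, "postorder")
  codes <- encode_alignment(aln)[tr$tip.label, , drop = FALSE]
  keys <- apply(codes, 2L, paste, collapse = ",")
  uniq <- !duplicated(keys)
  map <- match(keys, keys[uniq])
  list(tree = tr, tips = codes[, uniq, drop = FALSE],
       w = as.numeric(tabulate(map, sum(uniq))), map = map)
}

eng_sites <- function(tr, tips, model, lengths = tr$edge.length) {
  cpp_site_loglik(tr$edge, lengths, length(tr$tip.label), tr$Nnode, tips,
                  model$rates, model$evec, model$evec_inv, model$evals,
                  model$pi)
}

eng_arrays <- function(tr, tips, model) {
  cpp_edge_arrays(tr$edge, tr$edge.length, length(tr$tip.label), tr$Nnode,
                  tips, model$rates, model$evec, model$evec_inv, model$evals,
                  model$pi)
}

#' Tree log-likelihood under LG+Gamma
#'
#' Felsenstein pruning with per-site averaging over the equal-weight
#' discrete-gamma categories; gap and `'X'` cells contribute all-ones partial
#' vectors.
#'
#' @param tree an ape `phylo` whose leaves match the alignment taxa.
#' @param aln an [aa_alignment()].
#' @param model a [substitution_model()].
#' @return list with `total` and `per_site` log-likelihoods.
#' @export
tree_log_likelihood <- function(tree, aln, model = substitution_model()) {
  ed <- engine_data(tree, aln, model)
  per_pattern <- eng_sites(ed$tree, ed$tips, model)
  if (any(!is.finite(per_pattern))) stop("non-finite site log-likelihood")
  per_site <- as.numeric(per_pattern)[ed$map]
  list(total = sum(per_site), per_site = per_site)
}

#' Optimize branch lengths on a fixed topology
#'
#' Round-robin single-branch optimization: each sweep computes the cached
#' conditional-likelihood arrays once, optimizes every branch as a 1-D
#' bounded problem against those arrays, applies the joint update (falling
#' back to the single best branch if the joint step does not dominate it),
#' and stops when a full sweep improves the total log-likelihood by less than
#' `tol`. The total log-likelihood is non-decreasing across sweeps.
#'
#' @inheritParams tree_log_likelihood
#' @param tol convergence threshold on the per-sweep improvement (log units).
#' @param max_sweeps sweep cap; non-convergence returns the best tree so far
#'   with a warning and `converged = FALSE`.
#' @param bounds branch-length search interval.
#' @return list: `tree` (postorder, optimized lengths), `log_likelihood`,
#'   `sweeps`, `converged`.
#' @export
optimize_branch_lengths <- function(tree, aln, model = substitution_model(),
                                    tol = 1e-4, max_sweeps = 50L,
                                    bounds = c(1e-8, 20)) {
  ed <- engine_data(tree, aln, model)
  tr <- ed$tree
  tips <- ed$tips
  w <- ed$w
  ntip <- length(tr$tip.label)
  ll <- sum(w * eng_sites(tr, tips, model))
  converged <- FALSE
  sweeps <- 0L
  E <- nrow(tr$edge)
  for (sweep in seq_len(max_sweeps)) {
    sweeps <- sweep
    arr <- eng_arrays(tr, tips, model)
    f_edge <- function(e, t) {
      cpp_edge_loglik(e - 1L, t, tr$edge, ntip, tr$Nnode, tips, model$rates,
                      model$evec, model$evec_inv, model$evals, model$pi,
                      arr$down, arr$dsc, arr$upe, arr$upesc, w)
    }
    newlen <- tr$edge.length
    single <- numeric(E)
    for (e in seq_len(E)) {
      cur <- f_edge(e, tr$edge.length[e])
      t0 <- tr$edge.length[e]
      # search a window around the current length; the next sweep re-centers,
      # and the monotone guard keeps any mis-window harmless
      win <- c(max(bounds[1L], t0 / 5), min(bounds[2L], max(5 * t0, 0.3)))
      opt <- stats::optimize(function(t) f_edge(e, t), interval = win,
                             maximum = TRUE, tol = 1e-5)
      if (opt$objective > cur) {
        newlen[e] <- opt$maximum
        single[e] <- opt$objective
      } else {
        single[e] <- cur
      }
    }
    ll_joint <- sum(w * eng_sites(tr, tips, model, lengths = newlen))
    e_best <- which.max(single)
    if (ll_joint >= single[e_best]) {
      cand <- newlen
      ll_new <- ll_joint
    } else {
      cand <- tr$edge.length
      cand[e_best] <- newlen[e_best]
      ll_new <- single[e_best]
    }
    if (ll_new < ll) break # guard: never accept a decrease
    improved <- ll_new - ll
    tr$edge.length <- cand
    ll <- ll_new
    if (improved < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && sweeps == max_sweeps) {
    warning("branch-length optimization did not converge in ", max_sweeps,
            " sweeps")
  } else {
    converged <- TRUE
  }
  list(tree = tr, log_likelihood = ll, sweeps = sweeps, converged = converged)
}

# NNI candidate bookkeeping: for internal edge row e = (p, c) return the four
# units around it (two child edges of c; on the p side either two sibling
# edges, when p is the root trifurcation, or one sibling edge plus the
# outside-subtree array of p).
nni_units <- function(tr, e) {
  ntip <- length(tr$tip.label)
  p <- tr$edge[e, 1L]
  ch <- tr$edge[e, 2L]
  if (ch <= ntip) return(NULL)
  cedges <- which(tr$edge[, 1L] == ch)
  pedges <- setdiff(which(tr$edge[, 1L] == p), e)
  if (length(cedges) != 2L) return(NULL)
  if (p == ntip + 1L) { # root
    if (length(pedges) != 2L) return(NULL)
    list(type = c(0L, 0L, 0L, 0L),
         idx = c(cedges - 1L, pedges - 1L),
         swap_edges = cedges, partner = pedges[1L])
  } else {
    if (length(pedges) != 1L) return(NULL)
    list(type = c(0L, 0L, 0L, 1L),
         idx = c(cedges - 1L, pedges - 1L, p - ntip - 1L),
         swap_edges = cedges, partner = pedges)
  }
}

#' NNI hill-climbing topology search
#'
#' Starting from an unrooted tree (branch lengths are first optimized), every
#' internal edge's two nearest-neighbor-interchange alternatives are scored
#' by re-optimizing the central branch length against cached arrays; the
#' single best improving move per round is applied, branch lengths are
#' re-optimized, and the search stops at a local optimum. The log-likelihood
#' trace is strictly increasing.
#'
#' @inheritParams optimize_branch_lengths
#' @param tree starting tree with >= 4 leaves (unrooted; rooted input is
#'   unrooted first).
#' @param tol minimum log-likelihood improvement to accept a move.
#' @param bl_tol branch-length re-optimization tolerance between moves.
#' @param max_rounds cap on NNI rounds.
#' @param move_sweeps branch-length sweep cap between moves (a final full
#'   optimization runs when the search stops).
#' @return a `search_result`: list with `tree`, `log_likelihood`,
#'   `accepted_moves`, `trace`.
#' @export
nni_search <- function(tree, aln, model = substitution_model(), tol = 1e-6,
                       bl_tol = 1e-3, max_rounds = 50L, move_sweeps = 2L) {
  if (length(tree$tip.label) < 4L) stop("NNI search needs >= 4 leaves")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree$node.label <- NULL
  fit <- optimize_branch_lengths(tree, aln, model, tol = bl_tol)
  tr <- fit$tree
  ll <- fit$log_likelihood
  trace <- ll
  moves <- 0L
  ed <- engine_data(tr, aln, model)
  tips <- ed$tips
  w <- ed$w
  ntip <- length(tr$tip.label)
  for (round in seq_len(max_rounds)) {
    arr <- eng_arrays(tr, tips, model)
    cands <- list()
    for (e in seq_len(nrow(tr$edge))) {
      un <- nni_units(tr, e)
      if (is.null(un)) next
      for (alt in 1:2) {
        ty <- un$type
        ix <- un$idx
        # exchange child-side unit `alt` with the first parent-side unit
        ty[c(alt, 3L)] <- ty[c(3L, alt)]
        ix[c(alt, 3L)] <- ix[c(3L, alt)]
        f <- function(t) {
          cpp_quartet_loglik(t, ty, ix, ntip, tr$Nnode, ncol(tips),
                             model$rates, model$evec, model$evec_inv,
                             model$evals, model$pi, arr$msg, arr$msgsc,
                             arr$upn, arr$upnsc, w)
        }
        opt <- stats::optimize(f, interval = c(1e-8,
                                               max(1, 5 * tr$edge.length[e])),
                               maximum = TRUE, tol = 1e-5)
        cands[[length(cands) + 1L]] <-
          list(gain = opt$objective - ll, e = e, alt = alt,
               t = opt$maximum, units = un)
      }
    }
    if (!length(cands)) break
    gains <- vapply(cands, `[[`, 0, "gain")
    # the quartet score is a lower bound (only the central branch is
    # re-optimized), so when nothing clears the threshold the top candidates
    # still get a full re-optimization before the search gives up
    try_order <- if (max(gains) > tol) which.max(gains)
                 else utils::head(order(gains, decreasing = TRUE), 2L)
    accepted <- FALSE
    for (ci in try_order) {
      best <- cands[[ci]]
      cand <- tr
      ce <- best$units$swap_edges[best$alt] # child edge moving to p
      se <- best$units$partner              # sibling edge moving to c
      cand$edge[ce, 1L] <- cand$edge[best$e, 1L]
      cand$edge[se, 1L] <- cand$edge[best$e, 2L]
      cand$edge.length[best$e] <- best$t
      attr(cand, "order") <- NULL # surgery invalidated the stored order
      cand <- ape::reorder.phylo(cand, "postorder")
      fit <- suppressWarnings(optimize_branch_lengths(cand, aln, model,
                                                      tol = bl_tol,
                                                      max_sweeps = move_sweeps))
      if (fit$log_likelihood > ll + tol) {
        tr <- fit$tree
        ed <- engine_data(tr, aln, model)
        tips <- ed$tips
        w <- ed$w
        ll <- fit$log_likelihood
        trace <- c(trace, ll)
        moves <- moves + 1L
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  if (moves > 0L) { # settle branch lengths fully at the final topology
    fit <- optimize_branch_lengths(tr, aln, model, tol = bl_tol)
    if (fit$log_likelihood > ll) {
      tr <- fit$tree
      ll <- fit$log_likelihood
      trace[length(trace)] <- ll
    }
  }
  structure(list(tree = tr, log_likelihood = ll, accepted_moves = moves,
                 trace = trace), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result: logL", format(x$log_likelihood), "after",
      x$accepted_moves, "accepted NNI move(s)\n")
  invisible(x)
}

#' One-stop ML tree inference
#'
#' Neighbor joining on Poisson-corrected distances followed by NNI
#' hill-climbing under the model (for >= 4 taxa; smaller trees get their
#' branch lengths optimized on the NJ topology).
#'
#' @inheritParams optimize_branch_lengths
#' @param tol minimum log-likelihood improvement to accept an NNI move.
#' @param bl_tol branch-length optimization tolerance.
#' @return a `search_result`.
#' @export
infer_ml_tree <- function(aln, model = substitution_model(), tol = 1e-6,
                          bl_tol = 1e-3) {
  start <- neighbor_joining(pairwise_distances(aln))
  if (length(start$tip.label) >= 4L) {
    nni_search(start, aln, model, tol = tol, bl_tol = bl_tol)
  } else {
    fit <- optimize_branch_lengths(start, aln, model, tol = bl_tol)
    structure(list(tree = fit$tree, log_likelihood = fit$log_likelihood,
                   accepted_moves = 0L, trace = fit$log_likelihood),
              class = "search_result")
  }
}

#' Nonparametric bootstrap supports
#'
#' Column-resampled pseudo-alignments are each re-analyzed from scratch
#' (neighbor joining + NNI search) and the support of every internal edge of
#' the maximum-likelihood tree is the percentage of replicate trees
#' containing the same bipartition. Fully seeded and reproducible.
#'
#' @inheritParams optimize_branch_lengths
#' @param B number of replicates (the study-scale default is 100).
#' @param seed master seed; replicate `b` draws from
#'   `derive_seed(seed, "boot-<b>")`.
#' @param ml_tree optional precomputed ML tree for the full alignment.
#' @param bl_tol branch-length optimization tolerance used per replicate.
#' @return the ML tree with supports in `node.label` (root label empty).
#' @export
bootstrap_support <- function(aln, model = substitution_model(), B = 100L,
                              seed = 1L, ml_tree = NULL, bl_tol = 1e-3) {
  if (B < 1L) stop("B must be >= 1")
  if (is.null(ml_tree)) ml_tree <- infer_ml_tree(aln, model, bl_tol = bl_tol)$tree
  target <- tree_bipartitions(ml_tree)
  counts <- setNames(numeric(length(target)), names(target))
  S <- ncol(aln)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, paste0("boot-", b)))
    cols <- sample.int(S, S, replace = TRUE)
    rep_aln <- aa_alignment(aln[, cols, drop = FALSE])
    rep_tree <- infer_ml_tree(rep_aln, model, bl_tol = bl_tol)$tree
    hit <- names(tree_bipartitions(rep_tree))
    counts[names(counts) %in% hit] <- counts[names(counts) %in% hit] + 1
  }
  attach_supports(ml_tree, target, 100 * counts / B)
}

#' Per-site log-likelihood table for candidate topologies
#'
#' For each candidate topology (identical leaf sets required) branch lengths
#' are optimized with the topology fixed and the per-site log-likelihoods
#' recorded; the input to [au_test()].
#'
#' @param trees list of ape `phylo` topologies (named or not).
#' @inheritParams optimize_branch_lengths
#' @param marker_id optional identifier carried in the result.
#' @param bl_tol branch-length optimization tolerance per topology.
#' @return a `site_loglik_table`: list with `matrix` (sites x trees),
#'   `tree_ids`, `totals`, `marker_id`.
#' @export
site_loglik_table <- function(trees, aln, model = substitution_model(),
                              marker_id = NA_character_, bl_tol = 1e-4) {
  if (length(trees) == 0L) stop("need at least one tree")
  ids <- names(trees) %||% paste0("tree", seq_along(trees))
  ids[!nzchar(ids)] <- paste0("tree", which(!nzchar(ids)))
  ref <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), ref)) stop("leaf sets differ across trees")
  }
  cols <- lapply(trees, function(tr) {
    fit <- optimize_branch_lengths(tr, aln, model, tol = bl_tol)
    eng <- engine_data(fit$tree, aln, model)
    as.numeric(eng_sites(eng$tree, eng$tips, model))[eng$map]
  })
  m <- do.call(cbind, cols)
  colnames(m) <- ids
  structure(list(matrix = m, tree_ids = ids, totals = colSums(m),
                 marker_id = marker_id), class = "site_loglik_table")
}

#' @export
print.site_loglik_table <- function(x, ...) {
  cat("site_loglik_table:", nrow(x$matrix), "sites x", length(x$tree_ids),
      "trees; totals:", paste(format(x$totals), collapse = " "), "\n")
  invisible(x)
}

#' Write a site log-likelihood table as TSV
#' @param x a `site_loglik_table`.
#' @param path output path.
#' @export
write_site_loglik_table <- function(x, path) {
  utils::write.table(x$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
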