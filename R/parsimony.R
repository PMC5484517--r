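# Minimum-change analysis of discrete characters (gene fusion/fission states)
# on trees: Fitch/Hartigan counting, exhaustive most-parsimonious
# reconstruction via Sankoff backtracking, and outgroup-attachment scans.

validate_states <- function(tree, states) {
  stopifnot(is.character(states), !is.null(names(states)))
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    stop("unmapped leaf/leaves: ", paste(missing, collapse = ", "))
  }
  states[tree$tip.label]
}

#' Minimum number of character changes (Fitch count)
#'
#' Bottom-up state-set pass with unit costs; polytomies are handled by the
#' multi-child generalization (a node keeps the states carried by the largest
#' number of children and pays one change for each child outside that set),
#' which reduces to the classic intersection/union rule on binary nodes. The
#' count is invariant to the rooting of the underlying unrooted topology.
#'
#' @param tree an ape `phylo` (any rooting, polytomies allowed).
#' @param states named character vector taxon -> state covering all leaves.
#' @return integer minimum change count.
#' @export
fitch_min_changes <- function(tree, states) {
  states <- validate_states(tree, states)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- states[tr$tip.label[i]]
  changes <- 0L
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  # children are ready once a parent's LAST edge has passed in postorder
  last_pos <- tapply(seq_len(nrow(tr$edge)), tr$edge[, 1L], max)
  for (p in as.integer(names(sort(last_pos)))) {
    ch <- kids[[as.character(p)]]
    counts <- table(unlist(sets[ch]))
    k <- max(counts)
    sets[[p]] <- names(counts)[counts == k]
    changes <- changes + length(ch) - k
  }
  as.integer(changes)
}

#' All most-parsimonious reconstructions and typed change events
#'
#' Sankoff dynamic programming with unit costs, followed by exhaustive
#' backtracking over every cost-minimal ancestral labeling. For the binary
#' fused/split gene-architecture character each change is typed `split`
#' (fused -> split) or `fusion` (split -> fused); other alphabets get
#' `from->to` labels.
#'
#' @inheritParams fitch_min_changes
#' @param max_reconstructions cap on the number of enumerated MPRs; when
#'   exceeded the list is truncated and flagged.
#' @return a `parsimony_result`: `min_changes`, `node_state_sets` (states
#'   possible at each node across MPRs), `reconstructions` (list of event
#'   data.frames), `truncated`.
#' @export
reconstruct_events <- function(tree, states, max_reconstructions = 10000L) {
  states <- validate_states(tree, states)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  alph <- sort(unique(states))
  S <- length(alph)
  nn <- ntip + tr$Nnode
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(INF, nn, S)
  for (i in seq_len(ntip)) cost[i, match(states[tr$tip.label[i]], alph)] <- 0L
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  last_pos <- tapply(seq_len(nrow(tr$edge)), tr$edge[, 1L], max)
  for (p in as.integer(names(sort(last_pos)))) {
    acc <- integer(S)
    for (ch in kids[[as.character(p)]]) {
      acc <- acc + vapply(seq_len(S), function(s) {
        min(cost[ch, ] + as.integer(seq_len(S) != s))
      }, 0L)
    }
    cost[p, ] <- acc
  }
  root <- ntip + 1L
  minc <- min(cost[root, ])

  event_type <- function(from, to) {
    if (identical(from, "fused") && identical(to, "split")) "split"
    else if (identical(from, "split") && identical(to, "fused")) "fusion"
    else paste0(from, "->", to)
  }
  # enumerate assignments: list of integer state per node
  truncated <- FALSE
  assignments <- list()
  expand <- function(partial, frontier) {
    # partial: named int vector node -> state index; frontier: nodes whose
    # children still need states
    if (length(assignments) >= max_reconstructions) {
      truncated <<- TRUE
      return()
    }
    if (!length(frontier)) {
      assignments[[length(assignments) + 1L]] <<- partial
      return()
    }
    p <- frontier[[1L]]
    rest <- frontier[-1L]
    ch <- kids[[as.character(p)]]
    opts <- lapply(ch, function(cnode) {
      s <- partial[[as.character(p)]]
      v <- cost[cnode, ] + as.integer(seq_len(S) != s)
      which(v == min(v))
    })
    grid <- expand.grid(opts, KEEP.OUT.ATTRS = FALSE)
    for (g in seq_len(nrow(grid))) {
      part2 <- partial
      front2 <- rest
      for (ci in seq_along(ch)) {
        cnode <- ch[ci]
        part2[[as.character(cnode)]] <- grid[g, ci]
        if (cnode > ntip) front2 <- c(front2, cnode)
      }
      expand(part2, front2)
    }
  }
  for (rs in which(cost[root, ] == minc)) {
    expand(setNames(list(rs), as.character(root)), list(root))
  }
  recons <- lapply(assignments, function(a) {
    ev <- list()
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      sp <- alph[a[[as.character(p)]]]
      sc <- alph[a[[as.character(ch)]]]
      if (sp != sc) {
        lab <- if (ch <= ntip) tr$tip.label[ch]
               else bipart_key(sort(node_tip_sets(tr)[[ch]]))
        ev[[length(ev) + 1L]] <- data.frame(
          edge_child = lab, from_state = sp, to_state = sc,
          type = event_type(sp, sc), stringsAsFactors = FALSE)
      }
    }
    if (length(ev)) do.call(rbind, ev)
    else data.frame(edge_child = character(0), from_state = character(0),
                    to_state = character(0), type = character(0))
  })
  node_sets <- lapply(seq_len(nn), function(node) {
    if (node <= ntip) return(states[tr$tip.label[node]])
    sort(unique(vapply(assignments, function(a) {
      alph[a[[as.character(node)]]]
    }, "")))
  })
  structure(list(min_changes = as.integer(minc),
                 node_state_sets = node_sets,
                 reconstructions = recons, truncated = truncated,
                 tree = tr), class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("parsimony_result:", x$min_changes, "change(s),",
      length(x$reconstructions), "most-parsimonious reconstruction(s)",
      if (x$truncated) "(truncated)" else "", "\n")
  invisible(x)
}

# attach a new pendant tip at the midpoint of edge e (row of tree$edge)
attach_tip_at_edge <- function(tree, e, label, pendant_length = 0.1) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  edge <- tree$edge
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  el <- tree$edge.length %||% rep(1, nrow(edge))
  newint <- nn + 2L
  parent <- edge[e, 1L]
  child <- edge[e, 2L]
  edge2 <- rbind(edge[-e, , drop = FALSE],
                 c(parent, newint), c(newint, child),
                 c(newint, ntip + 1L))
  el2 <- c(el[-e], el[e] / 2, el[e] / 2, pendant_length)
  obj <- list(edge = edge2, tip.label = c(tree$tip.label, label),
              edge.length = el2, Nnode = tree$Nnode + 1L)
  class(obj) <- "phylo"
  ape::reorder.phylo(obj, "postorder")
}

#' Scan outgroup attachment points by parsimony cost
#'
#' For every edge of the unrooted ingroup tree, a pendant outgroup leaf
#' carrying `outgroup_state` is attached at that edge's midpoint and the
#' Fitch minimum-change count of the resulting tree is recorded. The argmin
#' edges are the rootings requiring the fewest fusion/split events.
#'
#' @param ingroup_tree an ape `phylo` (treated as unrooted).
#' @param outgroup_state character state carried by the outgroup.
#' @param states named states for the ingroup leaves.
#' @param outgroup_label label given to the attached leaf.
#' @return a `rooting_scan`: data.frame `table` (edge, child_clade,
#'   min_changes) plus `best_edges` and `min_changes`.
#' @export
rooting_scan <- function(ingroup_tree, outgroup_state, states,
                         outgroup_label = "OUTGROUP") {
  if (ape::is.rooted(ingroup_tree)) ingroup_tree <- ape::unroot(ingroup_tree)
  validate_states(ingroup_tree, states)
  states2 <- c(states, setNames(outgroup_state, outgroup_label))
  sets <- node_tip_sets(ingroup_tree)
  res <- lapply(seq_len(nrow(ingroup_tree$edge)), function(e) {
    tr2 <- attach_tip_at_edge(ingroup_tree, e, outgroup_label)
    data.frame(edge = e,
               child_clade = bipart_key(sort(sets[[ingroup_tree$edge[e, 2L]]])),
               min_changes = fitch_min_changes(tr2, states2),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  structure(list(table = tab,
                 best_edges = tab$edge[tab$min_changes == min(tab$min_changes)],
                 min_changes = min(tab$min_changes)),
            class = "rooting_scan")
}

#' @export
print.rooting_scan <- function(x, ...) {
  cat("rooting_scan: minimum", x$min_changes, "change(s) at",
      length(x$best_edges), "attachment edge(s)\n")
  invisible(x)
}

#' Read/write fused-split character states
#' @param path TSV with columns `taxon`, `state`.
#' @return named character vector.
#' @export
read_states_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "state") %in% names(df)))
  setNames(df$state, df$taxon)
}

#' @rdname read_states_tsv
#' @param states named character vector.
#' @export
write_states_tsv <- function(states, path) {
  utils::write.table(data.frame(taxon = names(states), state = states),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
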