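# Topology interrogation: bipartitions, monophyly queries, outgroup rooting,
# sister groups, Woese/eocyte classification and the marker tabulation that
# mirrors a per-marker monophyly summary table.

canonical_side <- function(side, all_labels) {
  comp <- setdiff(all_labels, side)
  pick <- if (length(side) < length(comp)) side
          else if (length(comp) < length(side)) comp
          else if (min(all_labels) %in% side) side else comp
  sort(pick)
}

bipart_key <- function(side) paste(side, collapse = "|")

#' Non-trivial bipartitions of a tree
#'
#' One canonical bipartition per internal edge (the smaller side; ties go to
#' the side holding the lexicographically smallest label), with any numeric
#' support carried along.
#'
#' @param tree an ape `phylo` with >= 4 leaves.
#' @return named list of sorted leaf-label vectors (names are the `|`-joined
#'   sides) with a numeric `supports` attribute.
#' @export
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  ntip <- length(labs)
  if (ntip < 4L) stop("bipartitions need >= 4 leaves")
  sets <- node_tip_sets(tree)
  sup <- node_supports(tree)
  out <- list()
  supports <- numeric(0)
  for (node in seq_len(tree$Nnode - 1L) + ntip + 1L) {
    side <- sets[[node]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    canon <- canonical_side(side, labs)
    key <- bipart_key(canon)
    if (!key %in% names(out)) {
      out[[key]] <- canon
      supports[key] <- sup[node - ntip]
    } else if (is.na(supports[key])) {
      supports[key] <- sup[node - ntip]
    }
  }
  attr(out, "supports") <- supports
  out
}

# write supports (named by canonical bipartition key) onto node labels
attach_supports <- function(tree, biparts, values) {
  ntip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  nl <- character(tree$Nnode)
  for (node in seq_len(tree$Nnode - 1L) + ntip + 1L) {
    side <- sets[[node]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    key <- bipart_key(canonical_side(side, tree$tip.label))
    if (key %in% names(values)) {
      nl[node - ntip] <- formatC(values[[key]], digits = 6L, format = "g")
    }
  }
  tree$node.label <- nl
  tree
}

#' Test monophyly of a leaf set
#'
#' Unrooted semantics: the set is monophyletic when some edge's bipartition
#' side equals it exactly. Single leaves and the full leaf set are trivially
#' monophyletic (no support).
#'
#' @param tree an ape `phylo`.
#' @param taxa leaf labels to test (subset of the tree's leaves).
#' @return list with `present` (logical) and `support` (numeric or `NA`).
#' @export
test_monophyly <- function(tree, taxa) {
  labs <- tree$tip.label
  unknown <- setdiff(taxa, labs)
  if (length(unknown)) stop("unknown taxon: ", paste(unknown, collapse = ", "))
  taxa <- unique(taxa)
  if (length(taxa) == length(labs) || length(taxa) == 1L) {
    return(list(present = TRUE, support = NA_real_))
  }
  ntip <- length(labs)
  sets <- node_tip_sets(tree)
  sup <- node_supports(tree)
  present <- FALSE
  support <- NA_real_
  for (node in seq_len(ntip + tree$Nnode)) {
    if (node == ntip + 1L) next # root: side is the full leaf set
    side <- sets[[node]]
    hit <- (length(side) == length(taxa) && setequal(side, taxa)) ||
      (length(side) == length(labs) - length(taxa) &&
         setequal(setdiff(labs, side), taxa))
    if (hit) {
      present <- TRUE
      if (node > ntip && is.na(support)) support <- sup[node - ntip]
    }
  }
  list(present = present, support = support)
}

#' Root a tree with an outgroup
#'
#' When the outgroup is monophyletic (unrooted sense) the root is placed at
#' the midpoint of the subtending edge; otherwise the tree is rooted on the
#' edge whose bipartition side is most similar (Jaccard) to the outgroup,
#' with a warning.
#'
#' @param tree an ape `phylo` (rooted input is unrooted first).
#' @param outgroup proper non-empty subset of the leaves.
#' @return a rooted `phylo`; supports follow their bipartitions.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  labs <- tree$tip.label
  unknown <- setdiff(outgroup, labs)
  if (length(unknown)) stop("unknown taxon: ", paste(unknown, collapse = ", "))
  if (length(outgroup) == 0L) stop("empty outgroup")
  if (setequal(outgroup, labs)) stop("outgroup cannot be the full leaf set")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  side <- outgroup
  if (!test_monophyly(tree, outgroup)$present) {
    ntip <- length(labs)
    sets <- node_tip_sets(tree)
    best <- -1
    for (node in seq_len(ntip + tree$Nnode)) {
      if (node == ntip + 1L) next
      for (cand in list(sets[[node]], setdiff(labs, sets[[node]]))) {
        jac <- length(intersect(cand, outgroup)) / length(union(cand, outgroup))
        if (jac > best) {
          best <- jac
          side <- cand
        }
      }
    }
    warning("outgroup not monophyletic; rooting on the closest bipartition ",
            "(Jaccard ", formatC(best, digits = 3, format = "g"), ")")
  }
  rooted <- ape::root(tree, outgroup = side, resolve.root = TRUE,
                      edgelabel = TRUE)
  ch <- which(rooted$edge[, 1L] == length(labs) + 1L)
  if (length(ch) == 2L) { # split the rooted edge at its midpoint
    tot <- sum(rooted$edge.length[ch])
    rooted$edge.length[ch] <- tot / 2
  }
  if (!is.null(rooted$node.label)) rooted$node.label[1L] <- ""
  rooted
}

#' Sister group of a clade
#'
#' @param rooted_tree a rooted ape `phylo`.
#' @param taxa leaf set forming a clade of `rooted_tree`.
#' @return leaf labels of the sibling subtree of the clade's MRCA.
#' @export
sister_group <- function(rooted_tree, taxa) {
  if (!ape::is.rooted(rooted_tree)) stop("tree must be rooted")
  labs <- rooted_tree$tip.label
  unknown <- setdiff(taxa, labs)
  if (length(unknown)) stop("unknown taxon: ", paste(unknown, collapse = ", "))
  ntip <- length(labs)
  sets <- node_tip_sets(rooted_tree)
  node <- NULL
  for (i in seq_len(ntip + rooted_tree$Nnode)) {
    if (length(sets[[i]]) == length(taxa) && setequal(sets[[i]], taxa)) {
      node <- i
      break
    }
  }
  if (is.null(node)) stop("taxa do not form a clade")
  if (node == ntip + 1L) stop("clade is the whole tree; no sister")
  parent <- rooted_tree$edge[rooted_tree$edge[, 2L] == node, 1L]
  sibs <- setdiff(rooted_tree$edge[rooted_tree$edge[, 1L] == parent, 2L], node)
  sort(unique(unlist(sets[sibs])))
}

#' Classify a tree as Woese-like, eocyte-like or unresolved
#'
#' The tree is rooted with its Bacteria leaves; `woese` requires the archaeal
#' leaves to be monophyletic (with support at least `support_min` when
#' supports are present), `eocyte` requires the eukaryotic leaves to be
#' monophyletic and nested strictly inside the archaeal MRCA (Archaea
#' paraphyletic), anything else is `unresolved`.
#'
#' @param tree an ape `phylo` containing at least one leaf of each domain.
#' @param groups taxon group map (data.frame taxon/group/domain).
#' @param support_min minimum support for the Archaea clade (0 = topology
#'   only; missing supports satisfy the default threshold).
#' @return a `topology_class`: list with `label`
#'   (`woese`/`eocyte`/`unresolved`), `archaea_monophyly_support`,
#'   `sister_of_eukarya` (group labels), `eukarya_support`, `support_min`.
#' @export
classify_topology <- function(tree, groups, support_min = 0) {
  groups <- validate_taxon_groups(groups)
  labs <- tree$tip.label
  unmapped <- setdiff(labs, groups$taxon)
  if (length(unmapped)) stop("unmapped leaves: ", paste(unmapped, collapse = ", "))
  dom <- setNames(groups$domain, groups$taxon)[labs]
  bact <- labs[dom == "Bacteria"]
  arch <- labs[dom == "Archaea"]
  euk <- labs[dom == "Eukarya"]
  if (!length(bact) || !length(arch) || !length(euk)) {
    stop("tree must contain all three domains")
  }
  rooted <- suppressWarnings(root_with_outgroup(tree, bact))
  gmap <- setNames(groups$group, groups$taxon)
  arch_mono <- test_monophyly(rooted, arch)
  res <- list(label = "unresolved", archaea_monophyly_support = arch_mono$support,
              sister_of_eukarya = character(0), eukarya_support = NA_real_,
              support_min = support_min)
  arch_sup_ok <- is.na(arch_mono$support) || arch_mono$support >= support_min
  if (arch_mono$present && arch_sup_ok) {
    res$label <- "woese"
  } else {
    euk_mono <- test_monophyly(rooted, euk)
    sets <- node_tip_sets(rooted)
    euk_clade <- any(vapply(sets, function(s) {
      length(s) == length(euk) && setequal(s, euk)
    }, TRUE))
    if (euk_mono$present && euk_clade && !arch_mono$present) {
      # smallest clade containing all archaeal leaves
      cand <- Filter(function(s) all(arch %in% s), sets)
      mrca_set <- cand[[which.min(lengths(cand))]]
      if (all(euk %in% mrca_set)) {
        sis <- sister_group(rooted, euk)
        res$label <- "eocyte"
        res$sister_of_eukarya <- sort(unique(unname(gmap[sis])))
        res$eukarya_support <- euk_mono$support
      }
    }
  }
  structure(res, class = "topology_class")
}

#' @export
print.topology_class <- function(x, ...) {
  cat("topology_class:", x$label)
  if (x$label == "eocyte") {
    cat(" (Eukarya sister to ", paste(x$sister_of_eukarya, collapse = "+"), ")",
        sep = "")
  }
  if (!is.na(x$archaea_monophyly_support)) {
    cat(" [Archaea monophyly BS ", x$archaea_monophyly_support, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Tabulate per-marker trees in the style of a monophyly summary table
#'
#' One row per marker (class, per-phylum monophyly and support, sisterhood of
#' the Eukarya clade with the configured archaeal group) plus summary counts
#' binned by bootstrap-support thresholds. Phyla with fewer than two leaves
#' in a tree are scored `NA` and excluded from the denominators.
#'
#' @param marker_trees named list of ape `phylo` (names are marker ids).
#' @param groups taxon group map.
#' @param phyla_to_test archaeal group labels to score for monophyly.
#' @param thresholds support thresholds for the summary bins.
#' @param sister_group_label archaeal group whose sisterhood with the Eukarya
#'   clade is tallied (default Lokiarchaeota).
#' @return a `marker_table`: list with `rows` (data.frame) and `summary`.
#' @export
tabulate_marker_trees <- function(marker_trees, groups,
                                  phyla_to_test = c("Euryarchaeota",
                                                    "Crenarchaeota",
                                                    "Thaumarchaeota"),
                                  thresholds = c(50, 80, 100),
                                  sister_group_label = "Lokiarchaeota") {
  if (is.null(names(marker_trees)) && length(marker_trees)) {
    stop("marker_trees must be named by marker id")
  }
  if (anyDuplicated(names(marker_trees))) stop("duplicate marker ids")
  gmap <- setNames(groups$group, groups$taxon)
  rows <- lapply(names(marker_trees), function(id) {
    tr <- marker_trees[[id]]
    cls <- classify_topology(tr, groups)
    row <- data.frame(marker_id = id, class = cls$label,
                      archaea_support = cls$archaea_monophyly_support,
                      stringsAsFactors = FALSE)
    for (ph in phyla_to_test) {
      taxa <- intersect(group_taxa(groups, ph), tr$tip.label)
      if (length(taxa) < 2L) {
        row[[paste0("mono_", ph)]] <- NA
        row[[paste0("bs_", ph)]] <- NA_real_
      } else {
        q <- test_monophyly(tr, taxa)
        row[[paste0("mono_", ph)]] <- q$present
        row[[paste0("bs_", ph)]] <- q$support
      }
    }
    sis_hit <- FALSE
    sis_sup <- NA_real_
    if (cls$label == "eocyte" &&
        all(cls$sister_of_eukarya %in% sister_group_label)) {
      sis_hit <- TRUE
      sis_sup <- cls$eukarya_support
    }
    row$loki_euk_sister <- sis_hit
    row$loki_euk_support <- sis_sup
    row
  })
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker_id = character(0), class = character(0))
  count_bins <- function(flag, sup) {
    flag[is.na(flag)] <- FALSE
    c(any = sum(flag),
      setNames(vapply(thresholds[thresholds < 100], function(th) {
        sum(flag & !is.na(sup) & sup > th)
      }, 0), paste0("gt", thresholds[thresholds < 100])))
  }
  summary <- list()
  for (ph in phyla_to_test) {
    summary[[paste0("mono_", ph)]] <-
      count_bins(rows[[paste0("mono_", ph)]] %||% logical(0),
                 rows[[paste0("bs_", ph)]] %||% numeric(0))
  }
  arch_flag <- (rows$class %||% character(0)) == "woese"
  arch_sup <- rows$archaea_support %||% numeric(0)
  summary$archaea_bs100 <- sum(arch_flag & !is.na(arch_sup) & arch_sup >= 100)
  summary$loki_euk_sister <- count_bins(rows$loki_euk_sister %||% logical(0),
                                        rows$loki_euk_support %||% numeric(0))
  structure(list(rows = rows, summary = summary, thresholds = thresholds,
                 phyla = phyla_to_test), class = "marker_table")
}

#' @export
print.marker_table <- function(x, ...) {
  cat("marker_table:", nrow(x$rows), "markers\n")
  print(x$rows)
  invisible(x)
}

#' Write the per-marker table as TSV
#' @param x a `marker_table`.
#' @param path output path.
#' @export
write_marker_table <- function(x, path) {
  utils::write.table(x$rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition markers by AU-test outcome
#'
#' A marker is Woese-relevant when it significantly rejects the eocyte
#' topology while keeping the Woese topology in its confidence set (and
#' conversely for eocyte-relevant); everything else is unresolved, with a
#' flag when both topologies are rejected.
#'
#' @param au_results data.frame with columns `marker_id`, `p_woese`,
#'   `p_eocyte` (AU p-values in `[0, 1]`).
#' @param alpha significance level (default 0.05).
#' @return list with `woese_relevant`, `eocyte_relevant`, `unresolved`,
#'   `both_rejected` marker-id vectors.
#' @export
partition_markers_by_au <- function(au_results, alpha = 0.05) {
  stopifnot(all(c("marker_id", "p_woese", "p_eocyte") %in% names(au_results)),
            all(au_results$p_woese >= 0 & au_results$p_woese <= 1),
            all(au_results$p_eocyte >= 0 & au_results$p_eocyte <= 1))
  w <- au_results$p_eocyte < alpha & au_results$p_woese >= alpha
  e <- au_results$p_woese < alpha & au_results$p_eocyte >= alpha
  both <- au_results$p_woese < alpha & au_results$p_eocyte < alpha
  list(woese_relevant = au_results$marker_id[w],
       eocyte_relevant = au_results$marker_id[e],
       unresolved = au_results$marker_id[!w & !e],
       both_rejected = au_results$marker_id[both])
}
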