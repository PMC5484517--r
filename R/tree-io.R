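# Newick I/O on top of ape's "phylo" trees.
#
# Trees are plain ape phylo objects. Bootstrap supports live in node.label
# (the standard Newick internal-node-label convention); every re-rooting done
# by this package goes through ape with edgelabel = TRUE so the labels behave
# as edge (bipartition) properties, which is what a support is.

#' Read a Newick tree
#'
#' @param path path to a file whose first line holds one Newick string.
#' @param support_convention `"internal_label"` (numeric internal node labels
#'   are supports) or `"comment"` (supports in square-bracket comments after
#'   internal nodes, as in `...)[95]:0.1`).
#' @return an ape `phylo`; missing branch lengths default to 0.
#' @export
read_tree_newick <- function(path, support_convention = c("internal_label", "comment")) {
  support_convention <- match.arg(support_convention)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt, support_convention)
}

#' @rdname read_tree_newick
#' @param text a Newick string (terminal semicolon required).
#' @export
parse_newick <- function(text, support_convention = c("internal_label", "comment")) {
  support_convention <- match.arg(support_convention)
  text <- trimws(text)
  validate_newick_string(text)
  if (support_convention == "comment") {
    text <- gsub("\\)\\[([0-9.]+)\\]", ")\\1", text)
  }
  text <- gsub("\\[[^]]*\\]", "", text) # drop remaining comments
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("Newick parse failure")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tr
}

validate_newick_string <- function(text) {
  if (!nzchar(text)) stop("empty Newick string")
  if (!endsWith(text, ";")) stop("Newick string lacks terminal ';'")
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " '(' left open")
  for (m in regmatches(text, gregexpr(":[^,();\\[]+", text))[[1L]]) {
    v <- substring(m, 2L)
    if (is.na(suppressWarnings(as.numeric(v)))) {
      stop("non-numeric branch length '", v, "' at position ",
           regexpr(m, text, fixed = TRUE))
    }
  }
  invisible(text)
}

#' Per-edge bootstrap supports
#'
#' @param tree an ape `phylo`.
#' @return numeric vector over internal nodes (root first, ape numbering);
#'   `NA` where no numeric label is present.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Write a tree as canonical Newick
#'
#' Children are ordered by the smallest leaf label they contain, so two
#' topologically identical trees (same rooting) serialize byte-identically.
#' Branch lengths are printed with 6 significant digits; numeric supports are
#' written as internal node labels.
#'
#' @param tree an ape `phylo`.
#' @param path optional output file; when `NULL` the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_tree_newick <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0, nrow(tree$edge))
  sup <- node_supports(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) formatC(x, digits = 6L, format = "g")

  rec <- function(node, eidx) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      key <- lab
      str <- paste0(lab, ":", fmt(el[eidx]))
    } else {
      parts <- lapply(kids[[as.character(node)]], function(e) rec(tree$edge[e, 2L], e))
      keys <- vapply(parts, `[[`, "", "key")
      o <- order(keys, method = "radix")
      inner <- paste(vapply(parts[o], `[[`, "", "str"), collapse = ",")
      key <- min(keys)
      s <- sup[node - ntip]
      lab <- if (!is.na(s)) fmt(s) else ""
      str <- paste0("(", inner, ")", lab,
                    if (is.na(eidx)) "" else paste0(":", fmt(el[eidx])))
    }
    list(key = key, str = str)
  }
  root <- ntip + 1L
  out <- paste0(rec(root, NA_integer_)$str, ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# Descendant tip labels for every node, as a list indexed by ape node number.
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}
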