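# Seeded simulator for conflicting-history marker sets: sequences evolved
# under the substitution model on a species tree (no natural indels --
# sequences are born aligned), fast-evolving taxa via pendant-branch
# multipliers, and explicit chimeric contamination (segment replacements and
# anchored insertions) with machine-readable truth.

#' Simulate an alignment on a tree
#'
#' Root residues are drawn from the stationary frequencies; each site draws a
#' gamma category and evolves down every branch with `P(t * r_k * m_s)` where
#' `m_s` is an optional per-site rate multiplier (used by the generator to
#' carve conserved anchor regions).
#'
#' @param tree a rooted ape `phylo` with branch lengths (>= 0).
#' @param model a [substitution_model()].
#' @param n_sites number of columns.
#' @param seed RNG seed.
#' @param site_rate_multipliers optional numeric vector of length `n_sites`.
#' @return an [aa_alignment()] with rows in `tree$tip.label` order.
#' @export
simulate_alignment <- function(tree, model = substitution_model(), n_sites,
                               seed = 1L, site_rate_multipliers = NULL) {
  stopifnot(n_sites >= 1L, all(tree$edge.length >= 0))
  mult <- site_rate_multipliers %||% rep(1, n_sites)
  stopifnot(length(mult) == n_sites, all(mult > 0))
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise") # parents before children
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  K <- model$n_categories
  cats <- sample.int(K, n_sites, replace = TRUE)
  states <- matrix(0L, nn, n_sites)
  states[ntip + 1L, ] <- sample.int(20L, n_sites, replace = TRUE,
                                    prob = model$pi)
  groups <- interaction(cats, mult, drop = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]
    ch <- tr$edge[e, 2L]
    for (g in levels(groups)) {
      sites <- which(groups == g)
      t <- tr$edge.length[e] * model$rates[cats[sites[1L]]] * mult[sites[1L]]
      P <- prob_matrix(model, t)
      ps <- states[p, sites]
      for (a in sort(unique(ps))) {
        ss <- sites[ps == a]
        states[ch, ss] <- sample.int(20L, length(ss), replace = TRUE,
                                     prob = P[a, ])
      }
    }
  }
  m <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]], ntip,
              n_sites, dimnames = list(tr$tip.label, NULL))
  aa_alignment(m)
}

#' Scale pendant branches of named taxa
#'
#' Emulates fast-evolving species: the pendant branch of every listed taxon
#' is multiplied by `factor` (>= 1); all other branches are untouched.
#'
#' @param tree an ape `phylo`.
#' @param taxa taxon labels present in the tree.
#' @param factor multiplier, at least 1.
#' @return the scaled tree.
#' @export
scale_branches <- function(tree, taxa, factor) {
  stopifnot(factor >= 1)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) stop("unknown taxon: ", paste(unknown, collapse = ", "))
  tips <- match(taxa, tree$tip.label)
  rows <- which(tree$edge[, 2L] %in% tips)
  tree$edge.length[rows] <- tree$edge.length[rows] * factor
  tree
}

#' Replace a segment of one taxon's row with donor residues
#'
#' @param aln an [aa_alignment()].
#' @param spec list with `taxon`, `start`, `end` (0-based half-open interval
#'   within the alignment) and optionally `donor_label`.
#' @param donor_row residues covering the interval (string or character
#'   vector of single residues).
#' @return list with the modified `alignment` and a `truth` record.
#' @export
inject_segment_chimera <- function(aln, spec, donor_row) {
  stopifnot(spec$taxon %in% rownames(aln),
            spec$start >= 0L, spec$end <= ncol(aln), spec$start <= spec$end)
  if (is.character(donor_row) && length(donor_row) == 1L) {
    donor_row <- strsplit(donor_row, "")[[1L]]
  }
  width <- spec$end - spec$start
  if (length(donor_row) != width) {
    stop("donor_row length ", length(donor_row), " != interval width ", width)
  }
  if (width > 0L) {
    aln[spec$taxon, (spec$start + 1L):spec$end] <- toupper(donor_row)
  }
  truth <- list(kind = "segment", taxon = spec$taxon, start = spec$start,
                end = spec$end, donor_label = spec$donor_label %||% NA_character_,
                donor_peptide = paste(donor_row, collapse = ""))
  list(alignment = aa_alignment(unclass(aln)), truth = truth)
}

#' Insert donor-derived columns carrying residues only in the target taxon
#'
#' New columns are inserted at `spec$at` (0-based); they carry the donor
#' peptide in the target taxon and `'-'` in every other row. The generator is
#' expected to have kept the flanking `anchor_len` columns conserved (it
#' lowers their substitution rate when simulating).
#'
#' @param aln an [aa_alignment()].
#' @param spec list with `taxon`, `at` (0-based insertion point) and
#'   optionally `donor_label`; the insertion length is `nchar(donor_peptide)`.
#' @param donor_peptide residues to insert.
#' @param anchor_len flanking width that must exist on both sides.
#' @return list with the widened `alignment` and a `truth` record.
#' @export
inject_anchored_insertion <- function(aln, spec, donor_peptide,
                                      anchor_len = 40L) {
  stopifnot(spec$taxon %in% rownames(aln))
  at <- spec$at
  if (at - anchor_len < 0L || at + anchor_len > ncol(aln)) {
    stop("anchors unconstructible at insertion point ", at)
  }
  pep <- strsplit(toupper(donor_peptide), "")[[1L]]
  L <- length(pep)
  newcols <- matrix("-", nrow(aln), L,
                    dimnames = list(rownames(aln), NULL))
  newcols[spec$taxon, ] <- pep
  m <- cbind(aln[, seq_len(at), drop = FALSE], newcols,
             aln[, seq(at + 1L, length.out = ncol(aln) - at), drop = FALSE])
  truth <- list(kind = "insertion", taxon = spec$taxon, start = at,
                end = at + L, length = L,
                donor_label = spec$donor_label %||% NA_character_,
                donor_peptide = paste(pep, collapse = ""))
  list(alignment = aa_alignment(unclass(m)), truth = truth)
}

#' Simulation configuration
#'
#' @param trees named list of rooted ape `phylo` species trees, one per
#'   history label.
#' @param markers data.frame with columns `id`, `n_sites`, `history`.
#' @param model a [substitution_model()].
#' @param fes named numeric vector taxon -> pendant branch multiplier (>= 1).
#' @param chimeras list of chimera specs; each a list with `kind`
#'   (`"segment"`/`"insertion"`), `marker`, `taxon`, `donor_clade` (taxon
#'   ids; the donor lineage attaches at that clade's stem), `donor_branch`,
#'   and either `start`/`end` (segment) or `at`/`length` plus
#'   `anchor_rate_mult` (insertion).
#' @param seed master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(trees, markers, model = substitution_model(),
                       fes = numeric(0), chimeras = list(), seed = 1L) {
  stopifnot(is.list(trees), !is.null(names(trees)),
            all(c("id", "n_sites", "history") %in% names(markers)))
  bad <- setdiff(markers$history, names(trees))
  if (length(bad)) stop("marker history without a tree: ", paste(bad, collapse = ", "))
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  if (length(fes) && any(fes < 1)) stop("FES multipliers must be >= 1")
  for (ch in chimeras) {
    stopifnot(ch$kind %in% c("segment", "insertion"),
              ch$marker %in% markers$id)
    ns <- markers$n_sites[markers$id == ch$marker]
    if (ch$kind == "segment") {
      stopifnot(ch$start >= 0, ch$end <= ns, ch$start <= ch$end)
    } else {
      stopifnot(ch$at >= 0, ch$at <= ns, ch$length >= 1)
    }
  }
  structure(list(trees = trees, markers = markers, model = model, fes = fes,
                 chimeras = chimeras, seed = seed), class = "sim_config")
}

# edge subtending the MRCA of `clade` (pendant edge when |clade| == 1)
stem_edge <- function(tree, clade) {
  stopifnot(all(clade %in% tree$tip.label))
  sets <- node_tip_sets(tree)
  node <- NULL
  for (i in seq_along(sets)) {
    if (all(clade %in% sets[[i]]) &&
        (is.null(node) || length(sets[[i]]) < length(sets[[node]]))) {
      node <- i
    }
  }
  e <- which(tree$edge[, 2L] == node)
  if (!length(e)) stop("clade stem is the root; cannot attach a donor there")
  e
}

#' Generate a conflicting-history marker set with truth
#'
#' Each marker is simulated on its history's species tree (fast-evolving-taxon
#' scaling applied first); donor lineages for chimeras are simulated as extra
#' tips attached at the stem of their donor clade and removed from the
#' output; chimeras are injected and every event recorded in the truth set.
#' Fully reproducible from the master seed.
#'
#' @param config a [sim_config()].
#' @param anchor_len anchor width used when carving conserved regions around
#'   insertion points.
#' @return list with `markers` (named list of [aa_alignment()]s) and `truth`
#'   (`marker_history`, `chimeras`, `fes`).
#' @export
make_conflicting_marker_set <- function(config, anchor_len = 40L) {
  stopifnot(inherits(config, "sim_config"))
  markers <- list()
  truth <- list(marker_history = setNames(config$markers$history,
                                          config$markers$id),
                chimeras = list(), fes = config$fes)
  for (r in seq_len(nrow(config$markers))) {
    id <- config$markers$id[r]
    ns <- config$markers$n_sites[r]
    tree <- config$trees[[config$markers$history[r]]]
    for (tx in intersect(names(config$fes), tree$tip.label)) {
      tree <- scale_branches(tree, tx, config$fes[[tx]])
    }
    specs <- Filter(function(ch) ch$marker == id, config$chimeras)
    donor_label <- character(length(specs))
    simtree <- tree
    for (j in seq_along(specs)) {
      donor_label[j] <- paste0("..donor", j)
      simtree <- attach_tip_at_edge(simtree, stem_edge(simtree, specs[[j]]$donor_clade),
                                    donor_label[j],
                                    pendant_length = specs[[j]]$donor_branch %||% 0.05)
    }
    mult <- rep(1, ns)
    for (j in seq_along(specs)) {
      ch <- specs[[j]]
      if (ch$kind == "insertion") {
        lo <- max(1L, ch$at - anchor_len + 1L)
        hi <- min(ns, ch$at + anchor_len)
        mult[lo:hi] <- ch$anchor_rate_mult %||% 0.05
      }
    }
    aln_full <- simulate_alignment(simtree, config$model, ns,
                                   seed = derive_seed(config$seed,
                                                      paste0("marker-", id)),
                                   site_rate_multipliers = mult)
    aln <- aa_alignment(aln_full[setdiff(rownames(aln_full), donor_label), ,
                                 drop = FALSE])
    seg_truth <- list()
    # segments first (pre-insertion coordinates) ...
    for (j in seq_along(specs)) {
      ch <- specs[[j]]
      if (ch$kind != "segment") next
      donor_row <- aln_full[donor_label[j], (ch$start + 1L):ch$end]
      res <- inject_segment_chimera(aln, list(taxon = ch$taxon,
                                              start = ch$start, end = ch$end,
                                              donor_label = donor_label[j]),
                                    donor_row)
      aln <- res$alignment
      res$truth$marker <- id
      res$truth$donor_clade <- ch$donor_clade
      seg_truth[[length(seg_truth) + 1L]] <- res$truth
    }
    # ... then insertions, left to right, tracking the coordinate offset
    ins <- Filter(function(ch) ch$kind == "insertion", specs)
    ins_labels <- donor_label[vapply(specs, function(ch) ch$kind == "insertion",
                                     TRUE)]
    if (length(ins)) {
      ord <- order(vapply(ins, function(ch) ch$at, 0))
      offset <- 0L
      for (j in ord) {
        ch <- ins[[j]]
        pep_aln <- simulate_alignment(
          simtree, config$model, ch$length,
          seed = derive_seed(config$seed, paste0("ins-", id, "-", j)))
        pep <- paste(pep_aln[ins_labels[j], ], collapse = "")
        res <- inject_anchored_insertion(aln,
                                         list(taxon = ch$taxon,
                                              at = ch$at + offset,
                                              donor_label = ins_labels[j]),
                                         pep, anchor_len = anchor_len)
        aln <- res$alignment
        res$truth$marker <- id
        res$truth$donor_clade <- ch$donor_clade
        truth$chimeras[[length(truth$chimeras) + 1L]] <- res$truth
        # shift earlier segment records lying right of the insertion
        for (k in seq_along(seg_truth)) {
          if (seg_truth[[k]]$start >= res$truth$start) {
            seg_truth[[k]]$start <- seg_truth[[k]]$start + ch$length
            seg_truth[[k]]$end <- seg_truth[[k]]$end + ch$length
          } else if (seg_truth[[k]]$end > res$truth$start) {
            seg_truth[[k]]$end <- seg_truth[[k]]$end + ch$length
          }
        }
        offset <- offset + ch$length
      }
    }
    truth$chimeras <- c(truth$chimeras, seg_truth)
    markers[[id]] <- aln
  }
  list(markers = markers, truth = truth)
}
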