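# Concatenation with partition bookkeeping, taxon curation, and the
# perturbation experiments: leave-one-marker-out and leave-one-sequence-out.

validate_marker_set <- function(markers) {
  stopifnot(is.list(markers), length(markers) >= 1L)
  if (is.null(names(markers)) || any(!nzchar(names(markers)))) {
    stop("markers must be a named list of alignments")
  }
  if (anyDuplicated(names(markers))) stop("duplicate marker ids")
  for (m in markers) stopifnot(inherits(m, "aa_alignment"))
  markers
}

#' Concatenate marker alignments into a supermatrix
#'
#' Columns are appended in marker order; taxa absent from a marker receive
#' all-gap rows for that partition (unless `fill_missing` is `FALSE`, which
#' requires identical taxon sets). Partition intervals are 0-based half-open.
#'
#' @param markers named list of [aa_alignment()]s sharing a taxon namespace.
#' @param fill_missing pad missing taxa with gaps?
#' @return a `partitioned_alignment`: list with `alignment` and `partitions`
#'   (data.frame marker_id/start/end).
#' @export
concatenate_markers <- function(markers, fill_missing = TRUE) {
  markers <- validate_marker_set(markers)
  taxa <- unique(unlist(lapply(markers, rownames)))
  if (!fill_missing) {
    for (id in names(markers)) {
      if (!setequal(rownames(markers[[id]]), taxa)) {
        stop("taxon sets differ (fill_missing = FALSE): marker '", id,
             "' misses ", paste(setdiff(taxa, rownames(markers[[id]])),
                                collapse = ", "))
      }
    }
  }
  widths <- vapply(markers, ncol, 0L)
  total <- sum(widths)
  m <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  at <- 0L
  parts <- data.frame(marker_id = names(markers),
                      start = integer(length(markers)),
                      end = integer(length(markers)),
                      stringsAsFactors = FALSE)
  for (i in seq_along(markers)) {
    w <- widths[i]
    rows <- rownames(markers[[i]])
    m[rows, (at + 1L):(at + w)] <- markers[[i]]
    parts$start[i] <- at
    parts$end[i] <- at + w
    at <- at + w
  }
  structure(list(alignment = aa_alignment(m), partitions = parts),
            class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat("partitioned_alignment:", nrow(x$alignment), "taxa x",
      ncol(x$alignment), "columns in", nrow(x$partitions), "partition(s)\n")
  invisible(x)
}

#' Write a partition table as TSV
#' @param x a `partitioned_alignment`.
#' @param path output path.
#' @export
write_partitions <- function(x, path) {
  utils::write.table(x$partitions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove taxa from every marker
#'
#' Emulates fast-evolving-sequence curation: the named taxa are dropped from
#' all markers; absent taxa are ignored with a warning.
#'
#' @param markers named list of [aa_alignment()]s.
#' @param taxa taxon ids to remove.
#' @param min_taxa a marker falling below this many taxa is an error.
#' @return the curated marker list.
#' @export
remove_taxa <- function(markers, taxa, min_taxa = 4L) {
  markers <- validate_marker_set(markers)
  if (!length(taxa)) return(markers)
  everywhere <- unique(unlist(lapply(markers, rownames)))
  absent <- setdiff(taxa, everywhere)
  if (length(absent)) {
    warning("taxa not present in any marker: ", paste(absent, collapse = ", "))
  }
  out <- lapply(names(markers), function(id) {
    aln <- markers[[id]]
    keep <- setdiff(rownames(aln), taxa)
    if (length(keep) < min_taxa) {
      stop("removing taxa leaves marker '", id, "' with fewer than ",
           min_taxa, " taxa")
    }
    aa_alignment(aln[keep, , drop = FALSE])
  })
  names(out) <- names(markers)
  out
}

# trim + infer + (optional bootstrap) + classify one concatenation
classify_concatenation <- function(markers, config, seed_tag = "full") {
  pa <- concatenate_markers(markers)
  tr <- trim_columns(pa$alignment, similarity_matrix(config$trim_matrix),
                     gap_max = config$gap_max, score_min = config$score_min,
                     smooth_window = config$smooth_window)
  aln <- tr$trimmed
  empty <- rownames(aln)[rowSums(aln != "-") == 0L]
  if (length(empty)) {
    warning("taxa with no data after ablation/trim dropped: ",
            paste(empty, collapse = ", "))
    aln <- aa_alignment(aln[setdiff(rownames(aln), empty), , drop = FALSE])
  }
  model <- substitution_model(gamma_shape = config$gamma_shape,
                              n_categories = config$n_categories)
  sr <- infer_ml_tree(aln, model, bl_tol = config$bl_tol)
  tree <- sr$tree
  if (config$bootstrap_B > 0L) {
    tree <- bootstrap_support(aln, model, B = config$bootstrap_B,
                              seed = derive_seed(config$seed, seed_tag),
                              ml_tree = tree, bl_tol = config$bl_tol)
  }
  cls <- classify_topology(tree, config$groups, support_min = config$support_min)
  list(class = cls, tree = tree, log_likelihood = sr$log_likelihood)
}

ablation_record <- function(removed, before, after) {
  data.frame(removed = removed,
             class_before = before$class$label,
             class_after = after$class$label,
             support_before = before$class$archaea_monophyly_support,
             support_after = after$class$archaea_monophyly_support,
             flipped = before$class$label != after$class$label,
             stringsAsFactors = FALSE)
}

#' Leave-one-marker-out ablation
#'
#' The full concatenation is classified once, then each marker is removed in
#' turn and the trim/infer/classify pipeline re-run; per-item seeds derive
#' deterministically from the config's master seed.
#'
#' @param markers named list of [aa_alignment()]s (>= 2 markers).
#' @param config a [pipeline_config()].
#' @return data.frame of ablation records (one row per marker) with the full
#'   classification in attribute `before`.
#' @export
leave_one_marker_out <- function(markers, config) {
  markers <- validate_marker_set(markers)
  if (length(markers) < 2L) stop("need at least 2 markers")
  before <- classify_concatenation(markers, config, "full")
  recs <- lapply(names(markers), function(id) {
    after <- classify_concatenation(markers[setdiff(names(markers), id)],
                                    config, paste0("lomo-", id))
    ablation_record(id, before, after)
  })
  out <- do.call(rbind, recs)
  attr(out, "before") <- before
  out
}

#' Leave-one-sequence-out ablation
#'
#' The target taxon's row in the target marker is replaced by gaps (the taxon
#' keeps its other markers, mirroring single-protein sequence removal from a
#' supermatrix) and the pipeline re-run.
#'
#' @param markers named list of [aa_alignment()]s.
#' @param target `c(marker_id, taxon)`.
#' @param config a [pipeline_config()].
#' @return one ablation record (data.frame row).
#' @export
leave_one_sequence_out <- function(markers, target, config) {
  markers <- validate_marker_set(markers)
  mid <- target[[1L]]
  taxon <- target[[2L]]
  if (!mid %in% names(markers)) stop("unknown marker: ", mid)
  if (!taxon %in% rownames(markers[[mid]])) {
    stop("marker '", mid, "' has no sequence for taxon '", taxon, "'")
  }
  before <- classify_concatenation(markers, config, "full")
  markers2 <- markers
  markers2[[mid]][taxon, ] <- "-"
  after <- classify_concatenation(markers2, config,
                                  paste0("loso-", mid, "-", taxon))
  ablation_record(paste0(mid, ":", taxon), before, after)
}

#' Map kept columns back to their markers
#'
#' Partition bookkeeping survives trimming: given the partition table of a
#' concatenation and the kept (0-based) column indices of a trim, returns
#' the marker id owning each kept column.
#'
#' @param partitioned a `partitioned_alignment`.
#' @param kept_columns sorted 0-based indices into the concatenation.
#' @return character vector of marker ids, one per kept column.
#' @export
map_columns_to_markers <- function(partitioned, kept_columns) {
  parts <- partitioned$partitions
  stopifnot(all(kept_columns >= 0), all(kept_columns < max(parts$end)))
  idx <- findInterval(kept_columns, parts$start)
  parts$marker_id[idx]
}
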