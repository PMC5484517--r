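# Orchestration: one seeded configuration drives curation, trimming,
# per-marker inference, classification/tabulation, AU partitioning, ablation,
# chimera scanning and gene-architecture parsimony, and renders a combined
# report.

#' Pipeline configuration
#'
#' @param groups taxon group map (data.frame taxon/group/domain).
#' @param seed master seed (mandatory); every random stage derives its own
#'   stream via [derive_seed()].
#' @param trim_matrix,gap_max,score_min,smooth_window column-trimming
#'   settings (see [trim_columns()]).
#' @param gamma_shape,n_categories substitution-model settings.
#' @param bl_tol branch-length optimization tolerance used by inference.
#' @param bootstrap_B bootstrap replicates per tree (0 disables supports;
#'   the study-scale protocol uses 100).
#' @param support_min classification support threshold.
#' @param au_alpha,au_scales,au_B AU-test settings.
#' @param fes taxa to curate away before analysis.
#' @param loki_group archaeal group tallied for Eukarya sisterhood.
#' @param phyla archaeal groups scored for monophyly in the marker table.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(groups, seed, trim_matrix = "BLOSUM30",
                            gap_max = 0.2, score_min = 0.5,
                            smooth_window = 3L, gamma_shape = 1.0,
                            n_categories = 4L, bl_tol = 0.05,
                            bootstrap_B = 0L, support_min = 0,
                            au_alpha = 0.05,
                            au_scales = seq(0.5, 1.4, by = 0.1),
                            au_B = 1000L, fes = character(0),
                            loki_group = "Lokiarchaeota",
                            phyla = c("Euryarchaeota", "Crenarchaeota",
                                      "Thaumarchaeota")) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(groups = validate_taxon_groups(groups), seed = seed,
                 trim_matrix = trim_matrix, gap_max = gap_max,
                 score_min = score_min, smooth_window = smooth_window,
                 gamma_shape = gamma_shape, n_categories = n_categories,
                 bl_tol = bl_tol, bootstrap_B = bootstrap_B,
                 support_min = support_min, au_alpha = au_alpha,
                 au_scales = au_scales, au_B = au_B, fes = fes,
                 loki_group = loki_group, phyla = phyla),
            class = "pipeline_config")
}

#' Run the full conflict-diagnostics pipeline
#'
#' Stage order: curate (FES removal) -> trim -> per-marker inference ->
#' classification/tabulation -> AU partition (against the two reference
#' topologies) -> ablation (leave-one-marker-out) -> chimera scan ->
#' gene-architecture parsimony. Stages can be switched off; every enabled
#' stage contributes a section to the report. Identical config + seed gives
#' byte-identical serialized reports.
#'
#' @param markers named list of [aa_alignment()]s.
#' @param config a [pipeline_config()].
#' @param reference_trees optional named list with `woese` and `eocyte`
#'   topologies (required for the AU stage).
#' @param chimera_focal focal taxa for the chimera stage (default: the
#'   `loki_group` taxa).
#' @param states optional fused/split state map for the parsimony stage.
#' @param outgroup_state outgroup character state for the rooting scan.
#' @param stages character vector of enabled stages.
#' @param out_dir optional directory for artifacts (trees, tables, report).
#' @return a `run_report` list.
#' @export
run_pipeline <- function(markers, config, reference_trees = NULL,
                         chimera_focal = NULL, states = NULL,
                         outgroup_state = "fused",
                         stages = c("curate", "trim", "trees", "classify",
                                    "au", "ablation", "chimera", "parsimony"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  markers <- validate_marker_set(markers)
  report <- list(config = config[setdiff(names(config), "groups")],
                 stages = stages)
  log_msg <- function(...) message("[phyloconflict] ", ...)

  if ("curate" %in% stages && length(config$fes)) {
    log_msg("curating ", length(config$fes), " fast-evolving taxa")
    markers <- remove_taxa(markers, config$fes)
    report$curated <- config$fes
  }

  trimmed <- markers
  if ("trim" %in% stages) {
    log_msg("trimming ", length(markers), " markers")
    trims <- lapply(markers, trim_columns,
                    matrix = similarity_matrix(config$trim_matrix),
                    gap_max = config$gap_max, score_min = config$score_min,
                    smooth_window = config$smooth_window)
    trimmed <- lapply(trims, `[[`, "trimmed")
    report$trim <- data.frame(
      marker_id = names(markers),
      columns_in = vapply(markers, ncol, 0L),
      columns_kept = vapply(trims, function(x) length(x$kept_columns), 0L),
      row.names = NULL)
  }

  model <- substitution_model(gamma_shape = config$gamma_shape,
                              n_categories = config$n_categories)
  trees <- NULL
  if ("trees" %in% stages) {
    trees <- lapply(names(trimmed), function(id) {
      log_msg("inferring tree for ", id)
      sr <- infer_ml_tree(trimmed[[id]], model, bl_tol = config$bl_tol)
      tree <- sr$tree
      if (config$bootstrap_B > 0L) {
        tree <- bootstrap_support(trimmed[[id]], model,
                                  B = config$bootstrap_B,
                                  seed = derive_seed(config$seed,
                                                     paste0("boot-", id)),
                                  ml_tree = tree, bl_tol = config$bl_tol)
      }
      tree
    })
    names(trees) <- names(trimmed)
    report$trees <- vapply(trees, write_tree_newick, "")
  }

  if ("classify" %in% stages && !is.null(trees)) {
    log_msg("classifying and tabulating ", length(trees), " marker trees")
    report$marker_table <- tabulate_marker_trees(
      trees, config$groups, phyla_to_test = config$phyla,
      sister_group_label = config$loki_group)
  }

  if ("au" %in% stages && !is.null(reference_trees)) {
    log_msg("AU testing ", length(trimmed), " markers")
    au_rows <- lapply(names(trimmed), function(id) {
      taxa <- rownames(trimmed[[id]])
      refs <- lapply(reference_trees, function(tr) {
        ape::keep.tip(tr, intersect(tr$tip.label, taxa))
      })
      tab <- site_loglik_table(refs, trimmed[[id]], model, marker_id = id,
                               bl_tol = config$bl_tol)
      au <- au_test(tab, scales = config$au_scales, B_per_scale = config$au_B,
                    seed = derive_seed(config$seed, paste0("au-", id)),
                    alpha = config$au_alpha)
      data.frame(marker_id = id,
                 p_woese = au$table$p[au$table$tree_id == "woese"],
                 p_eocyte = au$table$p[au$table$tree_id == "eocyte"],
                 stringsAsFactors = FALSE)
    })
    report$au <- do.call(rbind, au_rows)
    report$au_partition <- partition_markers_by_au(report$au,
                                                   alpha = config$au_alpha)
  }

  if ("ablation" %in% stages && length(trimmed) >= 2L) {
    log_msg("leave-one-marker-out over ", length(trimmed), " markers")
    report$ablation <- leave_one_marker_out(markers, config)
  }

  if ("chimera" %in% stages) {
    gmap <- setNames(config$groups$group, config$groups$taxon)
    all_taxa <- unique(unlist(lapply(markers, rownames)))
    focal <- chimera_focal %||%
      intersect(group_taxa(config$groups, config$loki_group), all_taxa)
    if (length(focal)) {
      log_msg("chimera scan for ", paste(focal, collapse = ", "))
      hits <- list()
      scans <- list()
      for (id in names(markers)) {
        aln <- markers[[id]]
        pres <- intersect(focal, rownames(aln))
        if (!length(pres)) next
        refs <- setdiff(rownames(aln)[gmap[rownames(aln)] != "Eukarya" &
                                        gmap[rownames(aln)] != "Bacteria"],
                        focal)
        h <- suppressWarnings(detect_anchored_insertions(aln, pres, refs))
        if (nrow(h)) {
          h$marker_id <- id
          hits[[id]] <- h
        }
        doms <- setNames(config$groups$domain, config$groups$taxon)
        for (f in pres) {
          clades <- list(
            Archaea = setdiff(rownames(aln)[doms[rownames(aln)] == "Archaea"],
                              focal),
            Eukarya = rownames(aln)[doms[rownames(aln)] == "Eukarya"])
          if (any(lengths(clades) == 0L)) next
          scans[[paste0(id, ":", f)]] <- segment_affinity_scan(
            aln, f, clades,
            seed = derive_seed(config$seed, paste0("scan-", id, "-", f)))
        }
      }
      report$insertions <- if (length(hits)) do.call(rbind, hits) else NULL
      report$affinity <- lapply(scans, function(x) {
        list(breakpoint = x$breakpoint, delta = x$delta, p_value = x$p_value,
             left_clade = x$left_clade, right_clade = x$right_clade)
      })
    }
  }

  if ("parsimony" %in% stages && !is.null(states)) {
    log_msg("gene-architecture parsimony")
    tree_p <- if (!is.null(trees)) trees[[1L]] else NULL
    if (!is.null(tree_p)) {
      ingroup <- intersect(tree_p$tip.label, names(states))
      if (length(ingroup) >= 4L) {
        itree <- ape::keep.tip(tree_p, ingroup)
        report$parsimony <- list(
          min_changes = fitch_min_changes(itree, states),
          rooting = rooting_scan(itree, outgroup_state, states)$table)
      }
    }
  }

  report <- structure(report, class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(serialize_report(report), file.path(out_dir, "report.json"))
    writeLines(render_table1_style(report), file.path(out_dir, "summary.txt"))
    if (!is.null(trees)) {
      for (id in names(trees)) {
        write_tree_newick(trees[[id]], file.path(out_dir, paste0(id, ".nwk")))
      }
    }
  }
  report
}

#' Serialize a run report to canonical JSON
#' @param report a `run_report`.
#' @return a JSON string (single element character).
#' @export
serialize_report <- function(report) {
  x <- unclass(report)
  if (!is.null(x$marker_table)) x$marker_table <- unclass(x$marker_table)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   dataframe = "rows", force = TRUE)
}

#' Render a fixed-width monophyly summary table
#'
#' Rows mirror a per-marker tabulation: per-phylum monophyly counts (any /
#' BS > 50 / BS > 80), Archaea monophyly at BS = 100, and Eukarya sisterhood
#' with the configured archaeal group.
#'
#' @param report a `run_report` (or a `marker_table`).
#' @return character vector of report lines.
#' @export
render_table1_style <- function(report) {
  mt <- if (inherits(report, "marker_table")) report else report$marker_table
  lines <- c(sprintf("%-34s %5s %7s %7s", "Clade", "any", "BS>50", "BS>80"))
  if (is.null(mt)) {
    return(c(lines, "  (no marker table)"))
  }
  s <- mt$summary
  for (ph in mt$phyla) {
    v <- s[[paste0("mono_", ph)]]
    lines <- c(lines, sprintf("%-34s %5d %7d %7d",
                              paste("Monophyly of", ph),
                              v[["any"]], v[["gt50"]], v[["gt80"]]))
  }
  lines <- c(lines, sprintf("%-34s %5d", "Monophyly of Archaea (BS = 100)",
                            s$archaea_bs100))
  v <- s$loki_euk_sister
  lines <- c(lines, sprintf("%-34s %5d %7d %7d", "Loki-Eukarya sister group",
                            v[["any"]], v[["gt50"]], v[["gt80"]]))
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report with sections:", paste(setdiff(names(x), "config"),
                                         collapse = ", "), "\n")
  if (!is.null(x$marker_table)) {
    cat(render_table1_style(x), sep = "\n")
  }
  invisible(x)
}
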