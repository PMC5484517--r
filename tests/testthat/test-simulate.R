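test_that("zero-length trees give identical rows; seeds give identical bytes", {
  model <- small_model()
  tr <- parse_newick("((A:0,B:0):0,(C:0,D:0):0);")
  aln <- simulate_alignment(tr, model, 50, seed = 3)
  expect_true(all(apply(unclass(aln), 2, function(col) length(unique(col)) == 1)))
  tr2 <- parse_newick("((A:0.1,B:0.2):0.1,(C:0.1,D:0.3):0.1);")
  a1 <- simulate_alignment(tr2, model, 100, seed = 5)
  a2 <- simulate_alignment(tr2, model, 100, seed = 5)
  expect_identical(unclass(a1), unclass(a2))
  expect_false(identical(unclass(a1),
                         unclass(simulate_alignment(tr2, model, 100, seed = 6))))
})

test_that("simulated residue frequencies follow the stationary distribution", {
  model <- substitution_model()
  tr <- parse_newick("(A:10,B:10);") # long branch: B is a stationary draw
  aln <- simulate_alignment(tr, model, 10000, seed = 17)
  counts <- table(factor(aln["B", ], levels = rownames(similarity_matrix())))
  n <- sum(counts)
  for (i in seq_along(model$pi)) {
    se <- sqrt(model$pi[i] * (1 - model$pi[i]) * n)
    expect_lt(abs(counts[i] - n * model$pi[i]), 3.5 * se)
  }
})

test_that("pairwise mismatch matches the matrix-exponential expectation", {
  model <- substitution_model()
  t <- 0.4
  tr <- parse_newick(sprintf("(A:%f,B:%f);", t / 2, t / 2))
  aln <- simulate_alignment(tr, model, 10000, seed = 23)
  p_obs <- mean(aln["A", ] != aln["B", ])
  p_exp <- mean(vapply(model$rates, function(r) {
    P <- prob_matrix(model, t * r)
    1 - sum(model$pi * diag(P))
  }, 0))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3.5 * se)
})

test_that("pendant-branch scaling touches exactly the named taxa", {
  tr <- parse_newick("((A:0.1,B:0.2):0.1,(C:0.1,D:0.3):0.1);")
  expect_equal(scale_branches(tr, c("A", "C"), 1)$edge.length, tr$edge.length)
  s2 <- scale_branches(tr, c("A", "C"), 2)
  get_len <- function(t, tip) t$edge.length[t$edge[, 2] == match(tip, t$tip.label)]
  expect_equal(get_len(s2, "A"), 0.2)
  expect_equal(get_len(s2, "C"), 0.2)
  expect_equal(get_len(s2, "B"), 0.2)
  expect_equal(sum(s2$edge.length), sum(tr$edge.length) + 0.2)
  expect_error(scale_branches(tr, "Z", 2), "unknown taxon")
})

test_that("segment injection changes exactly the requested cells", {
  aln <- random_alignment(5, 40, 2)
  donor <- paste(rep("W", 10), collapse = "")
  res <- inject_segment_chimera(aln, list(taxon = "t2", start = 10L,
                                          end = 20L), donor)
  out <- res$alignment
  expect_equal(paste(out["t2", 11:20], collapse = ""), donor)
  expect_equal(out["t2", c(1:10, 21:40)], aln["t2", c(1:10, 21:40)])
  expect_identical(out[rownames(aln) != "t2", ], aln[rownames(aln) != "t2", ])
  # zero-width interval is a no-op
  nz <- inject_segment_chimera(aln, list(taxon = "t2", start = 5L, end = 5L),
                               "")
  expect_identical(unclass(nz$alignment), unclass(aln))
  expect_error(inject_segment_chimera(aln, list(taxon = "t2", start = 0L,
                                                end = 5L), "AA"),
               "width")
})

test_that("insertion injection gaps every non-target row", {
  aln <- random_alignment(5, 100, 4)
  res <- inject_anchored_insertion(aln, list(taxon = "t3", at = 50L),
                                   "MKVLITGA")
  out <- res$alignment
  expect_equal(ncol(out), 108L)
  expect_true(all(out[rownames(out) != "t3", 51:58] == "-"))
  expect_equal(paste(out["t3", 51:58], collapse = ""), "MKVLITGA")
  expect_identical(out[, 1:50], aln[, 1:50])
  expect_error(inject_anchored_insertion(aln, list(taxon = "t3", at = 10L),
                                         "MK"), "unconstructible")
})

test_that("the generator is reproducible and its truth is complete", {
  pre <- preset_ef2_like(seed = 42)
  g1 <- make_conflicting_marker_set(pre$config)
  g2 <- make_conflicting_marker_set(pre$config)
  expect_identical(lapply(g1$markers, unclass), lapply(g2$markers, unclass))
  expect_equal(length(g1$truth$chimeras), 3L)
  kinds <- vapply(g1$truth$chimeras, `[[`, "", "kind")
  expect_setequal(kinds, c("insertion", "insertion", "segment"))
  # every truth interval indexes real columns of its marker
  for (ch in g1$truth$chimeras) {
    aln <- g1$markers[[ch$marker]]
    expect_true(ch$start >= 0 && ch$end <= ncol(aln))
    if (ch$kind == "insertion") {
      expect_equal(paste(aln[ch$taxon, (ch$start + 1):ch$end], collapse = ""),
                   ch$donor_peptide)
    }
  }
  expect_equal(unname(g1$truth$marker_history["m1"]), "woese")
})

test_that("a clean one-history config yields trees matching that history", {
  sp <- parse_newick(paste0(
    "((A:0.15,(B:0.1,C:0.1):0.08):0.1,((D:0.1,E:0.12):0.07,",
    "(F:0.1,(G:0.08,H:0.08):0.06):0.07):0.06);"))
  cfg <- sim_config(trees = list(woese = sp),
                    markers = data.frame(id = "g1", n_sites = 500L,
                                         history = "woese"),
                    seed = 7)
  gen <- make_conflicting_marker_set(cfg)
  sr <- infer_ml_tree(gen$markers$g1)
  expect_equal(phangorn::RF.dist(ape::unroot(sr$tree), ape::unroot(sp)), 0)
})

test_that("fast-evolving taxa induce LBA under a misspecified model and
           curation repairs it", {
  # sequences evolve with strong rate heterogeneity (shape 0.4) but are
  # analyzed with a uniform-rate model: the classic setting in which a long
  # pendant branch gets attracted toward the distant outgroup
  groups <- data.frame(
    taxon = c("B1", "B2", "E1", "E2", "A1", "A2", "A3", "FES1"),
    group = c("Bacteria", "Bacteria", "Eukarya", "Eukarya", "Euryarchaeota",
              "Euryarchaeota", "Crenarchaeota", "Nanoarchaeota"),
    domain = c("Bacteria", "Bacteria", "Eukarya", "Eukarya",
               rep("Archaea", 4)))
  sp <- parse_newick(paste0(
    "((B1:0.9,B2:0.9):0.9,((E1:0.2,E2:0.2):0.25,",
    "(((A1:0.1,A2:0.1):0.04,A3:0.12):0.03,FES1:0.08):0.04):0.08);"))
  simmod <- substitution_model(gamma_shape = 0.4)
  run_arm <- function(fac, curate) {
    bad <- 0L
    for (seed in 1:6) {
      cfg <- sim_config(trees = list(woese = sp), model = simmod,
                        markers = data.frame(id = "m1", n_sites = 300L,
                                             history = "woese"),
                        fes = if (fac > 1) c(FES1 = fac) else numeric(0),
                        seed = seed)
      gen <- make_conflicting_marker_set(cfg)
      mk <- if (curate) remove_taxa(gen$markers, "FES1") else gen$markers
      pc <- pipeline_config(groups = groups, seed = seed, n_categories = 1L)
      cl <- phyloconflict:::classify_concatenation(mk, pc)
      if (cl$class$label != "woese") bad <- bad + 1L
    }
    bad
  }
  base <- run_arm(1, curate = FALSE)
  fast <- run_arm(6, curate = FALSE)
  cured <- run_arm(6, curate = TRUE)
  expect_gt(fast, base)   # misclassification rises with the FES factor
  expect_lt(cured, fast)  # removing the FES taxa repairs it
  expect_equal(base, 0L)
})

test_that("the default conflicting-histories preset is well formed", {
  pre <- preset_conflict(seed = 3)
  expect_equal(nrow(pre$groups), 30L)
  expect_setequal(pre$config$markers$history, c("woese", "eocyte"))
  gen <- make_conflicting_marker_set(pre$config)
  expect_equal(length(gen$markers), 9L)
  expect_true(all(vapply(gen$markers, nrow, 0L) == 30L))
  expect_equal(vapply(gen$markers, ncol, 0L),
               setNames(pre$config$markers$n_sites, pre$config$markers$id))
  expect_equal(length(gen$truth$chimeras), 0L)
  expect_equal(unname(gen$truth$fes[pre$fes_taxa]), c(4, 4))
  # both histories classify as designed directly from their species trees
  expect_equal(classify_topology(pre$config$trees$woese, pre$groups)$label,
               "woese")
  eo <- classify_topology(pre$config$trees$eocyte, pre$groups)
  expect_equal(eo$label, "eocyte")
  expect_equal(eo$sister_of_eukarya, "Lokiarchaeota")
})
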