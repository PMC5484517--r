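toy_groups <- function() {
  data.frame(
    taxon = c("B1", "B2", "E1", "E2", "A1", "A2", "L1"),
    group = c("Bacteria", "Bacteria", "Eukarya", "Eukarya",
              "Euryarchaeota", "Crenarchaeota", "Lokiarchaeota"),
    domain = c("Bacteria", "Bacteria", "Eukarya", "Eukarya",
               "Archaea", "Archaea", "Archaea"))
}

test_that("bipartition extraction matches edge counts", {
  t4 <- parse_newick("((A:1,B:1):1,C:1,D:1);")
  expect_equal(length(tree_bipartitions(t4)), 1L)
  star <- parse_newick("(A,B,C,D,E);")
  expect_equal(length(tree_bipartitions(star)), 0L)
  for (n in 5:8) {
    tr <- random_tree(n, seed = n)
    expect_equal(length(tree_bipartitions(tr)), n - 3L)
  }
})

test_that("monophyly queries agree with a brute-force side-set scan", {
  tr <- random_tree(6, seed = 2)
  labs <- tr$tip.label
  sides <- lapply(tree_bipartitions(tr), identity)
  for (bits in 1:(2^6 - 1)) {
    taxa <- labs[as.logical(bitwAnd(bits, 2^(0:5)))]
    got <- test_monophyly(tr, taxa)$present
    # singletons, complements of singletons (pendant edges) and the full
    # set are monophyletic by definition in the unrooted sense
    want <- length(taxa) %in% c(1L, 5L, 6L) ||
      any(vapply(sides, function(s) {
        setequal(s, taxa) || setequal(setdiff(labs, s), taxa)
      }, TRUE))
    expect_identical(got, want, info = paste("subset", bits))
  }
  expect_error(test_monophyly(tr, "nope"), "unknown taxon")
})

test_that("outgroup rooting preserves bipartitions and splits the root edge", {
  tr <- parse_newick("((A:1,B:1)80:2,(C:1,D:1)60:1,E:3);")
  r1 <- root_with_outgroup(tr, "E")
  expect_true(ape::is.rooted(r1))
  kids <- which(r1$edge[, 1] == length(r1$tip.label) + 1L)
  expect_equal(r1$edge.length[kids][1], r1$edge.length[kids][2])
  r2 <- root_with_outgroup(tr, c("C", "D"))
  expect_setequal(names(tree_bipartitions(r2)), names(tree_bipartitions(tr)))
  q <- test_monophyly(r2, c("A", "B"))
  expect_true(q$present)
  expect_equal(q$support, 80)
  expect_error(root_with_outgroup(tr, tr$tip.label), "full leaf set")
  expect_warning(root_with_outgroup(tr, c("A", "C")), "not monophyletic")
})

test_that("sister groups agree with brute-force parent lookup", {
  cat4 <- parse_newick("(((A:1,B:1):1,C:1):1,D:1);")
  expect_equal(sister_group(cat4, c("A", "B")), "C")
  expect_equal(sister_group(cat4, "A"), "B")
  expect_error(sister_group(cat4, c("A", "C")), "clade")
  for (seed in 1:25) {
    tr <- ape::rtree(7, rooted = TRUE)
    tr$tip.label <- paste0("t", 1:7)
    sets <- phyloconflict:::node_tip_sets(tr)
    node <- sample(9:13, 1) # internal, non-root
    taxa <- sets[[node]]
    parent <- tr$edge[tr$edge[, 2] == node, 1]
    sib_nodes <- setdiff(tr$edge[tr$edge[, 1] == parent, 2], node)
    want <- sort(unique(unlist(sets[sib_nodes])))
    expect_equal(sister_group(tr, taxa), want, info = paste("seed", seed))
  }
})

test_that("classification separates Woese, eocyte and unresolved trees", {
  g <- toy_groups()
  woese <- parse_newick(
    "((B1:1,B2:1):1,((E1:1,E2:1):1,((A1:1,A2:1):1,L1:1)95:0.5):1);")
  cw <- classify_topology(woese, g)
  expect_equal(cw$label, "woese")
  expect_equal(cw$archaea_monophyly_support, 95)
  eoc <- parse_newick(
    "((B1:1,B2:1):1,((A1:1,A2:1):1,(L1:1,(E1:1,E2:1)100:0.5):0.5):1);")
  ce <- classify_topology(eoc, g)
  expect_equal(ce$label, "eocyte")
  expect_equal(ce$sister_of_eukarya, "Lokiarchaeota")
  expect_equal(ce$eukarya_support, 100)
  # Eukarya split apart: neither class
  odd <- parse_newick(
    "((B1:1,B2:1):1,((A1:1,E1:1):1,((A2:1,E2:1):1,L1:1):1):1);")
  expect_equal(classify_topology(odd, g)$label, "unresolved")
  # classification is invariant to the input rooting
  re <- ape::root(eoc, outgroup = "E1", resolve.root = TRUE, edgelabel = TRUE)
  expect_equal(classify_topology(re, g)$label, "eocyte")
  noeuk <- ape::drop.tip(woese, c("E1", "E2"))
  expect_error(classify_topology(noeuk, g), "three domains")
})

test_that("marker tabulation matches hand counts and is internally consistent", {
  g <- toy_groups()
  g2 <- rbind(g, data.frame(taxon = c("A3", "A4"),
                            group = c("Euryarchaeota", "Crenarchaeota"),
                            domain = c("Archaea", "Archaea")))
  t1 <- parse_newick(paste0("((B1:1,B2:1):1,((E1:1,E2:1):1,(((A1:1,A3:1)90:1,",
                            "(A2:1,A4:1)60:1):1,L1:1)100:0.5):1);"))
  t2 <- parse_newick(paste0("((B1:1,B2:1):1,(((A1:1,A3:1)40:1,(A2:1,A4:1)85:1)",
                            ":1,(L1:1,(E1:1,E2:1)95:0.5):0.5):1);"))
  mt <- tabulate_marker_trees(list(w = t1, e = t2), g2,
                              phyla_to_test = c("Euryarchaeota",
                                                "Crenarchaeota"))
  expect_equal(unname(mt$summary$mono_Euryarchaeota),
               c(2, 1, 1)) # both trees; >50 only t1 (90); >80 only t1
  expect_equal(unname(mt$summary$mono_Crenarchaeota),
               c(2, 2, 1)) # 60 and 85; >80 only t2
  expect_equal(mt$summary$archaea_bs100, 1)
  expect_equal(unname(mt$summary$loki_euk_sister), c(1, 1, 1))
  # summary equals column-wise recount of rows
  expect_equal(mt$summary$archaea_bs100,
               sum(mt$rows$class == "woese" & !is.na(mt$rows$archaea_support) &
                     mt$rows$archaea_support >= 100))
  empty <- tabulate_marker_trees(setNames(list(), character(0)), g2)
  expect_equal(unname(empty$summary$mono_Euryarchaeota), c(0, 0, 0))
  expect_error(tabulate_marker_trees(list(a = t1, a = t2), g2), "duplicate")
})

test_that("AU-based marker partitioning follows the significance rules", {
  res <- data.frame(marker_id = c("w", "u", "b", "e"),
                    p_woese = c(0.9, 0.2, 0.01, 0.02),
                    p_eocyte = c(0.01, 0.2, 0.01, 0.6))
  p <- partition_markers_by_au(res)
  expect_equal(p$woese_relevant, "w")
  expect_equal(p$eocyte_relevant, "e")
  expect_setequal(p$unresolved, c("u", "b"))
  expect_equal(p$both_rejected, "b")
})
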