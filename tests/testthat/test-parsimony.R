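# Fused (single-polypeptide A-type) vs split (A'A"-type) RNA-polymerase
# large-subunit architectures as a binary parsimony character.

rnapol_thaum_rooted <- function() {
  parse_newick(paste0("(Bac:1,(Thaum:1,(Kor:1,(Cren:1,(Loki:1,Eury:1):1):1)",
                      ":1):1);"))
}
rnapol_thaum_states <- c(Bac = "fused", Thaum = "fused", Kor = "fused",
                         Cren = "split", Loki = "split", Eury = "split")

loki_ancestor_tree <- function() {
  # backbone of the concatenation tree with the fast-evolving basal
  # euryarchaeon and Eukarya nested next to the Loki lineage
  parse_newick(paste0("(Bac:1,(Mkan:1,(Eury:1,((Thaum:1,(Kor:1,Cren:1):1):1,",
                      "(Loki:1,Euk:1):1):1):1):1);"))
}
loki_ancestor_states <- c(Bac = "fused", Mkan = "split", Eury = "split",
                          Thaum = "fused", Kor = "fused", Cren = "split",
                          Loki = "split", Euk = "fused")

test_that("the two worked fused/split topologies give 1 and 4 changes", {
  expect_equal(fitch_min_changes(rnapol_thaum_rooted(), rnapol_thaum_states), 1L)
  expect_equal(fitch_min_changes(loki_ancestor_tree(), loki_ancestor_states), 4L)
  uniform <- setNames(rep("split", 6), names(rnapol_thaum_states))
  expect_equal(fitch_min_changes(rnapol_thaum_rooted(), uniform), 0L)
  expect_error(fitch_min_changes(rnapol_thaum_rooted(),
                                 rnapol_thaum_states[-1]), "unmapped")
})

test_that("Fitch counting equals exhaustive enumeration on random trees", {
  for (seed in 1:100) {
    set.seed(seed)
    tr <- ape::rtree(8, rooted = TRUE)
    tr$tip.label <- paste0("t", 1:8)
    states <- setNames(sample(c("fused", "split"), 8, TRUE), tr$tip.label)
    expect_equal(fitch_min_changes(tr, states),
                 brute_force_min_changes(tr, states),
                 info = paste("seed", seed))
  }
  # polytomies, via the multi-child generalization
  for (seed in 1:30) {
    set.seed(seed)
    tr <- ape::di2multi(ape::rtree(8, rooted = TRUE), tol = 0.4)
    tr$tip.label <- paste0("t", 1:8)
    states <- setNames(sample(c("fused", "split", "lost"), 8, TRUE),
                       tr$tip.label)
    expect_equal(fitch_min_changes(tr, states),
                 brute_force_min_changes(tr, states),
                 info = paste("poly seed", seed))
  }
})

test_that("Fitch counting is invariant to the rooting of the topology", {
  tr <- loki_ancestor_tree()
  states <- loki_ancestor_states
  ref <- fitch_min_changes(tr, states)
  un <- ape::unroot(tr)
  for (og in names(states)[1:5]) {
    re <- ape::root(un, outgroup = og, resolve.root = TRUE)
    expect_equal(fitch_min_changes(re, states), ref)
  }
})

test_that("MPR enumeration matches brute force and types events", {
  res <- reconstruct_events(rnapol_thaum_rooted(), rnapol_thaum_states)
  expect_equal(res$min_changes, 1L)
  expect_equal(length(res$reconstructions), 1L)
  ev <- res$reconstructions[[1]]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "split") # fused -> split below the Korarchaeum split
  expect_equal(ev$edge_child, "Cren|Eury|Loki")
  uniform <- setNames(rep("fused", 6), names(rnapol_thaum_states))
  expect_equal(nrow(reconstruct_events(rnapol_thaum_rooted(),
                                       uniform)$reconstructions[[1]]), 0L)
  for (seed in 1:20) {
    set.seed(seed)
    tr <- ape::rtree(7, rooted = TRUE)
    tr$tip.label <- paste0("t", 1:7)
    states <- setNames(sample(c("fused", "split"), 7, TRUE), tr$tip.label)
    mine <- reconstruct_events(tr, states)
    oracle <- brute_force_mprs(tr, states)
    expect_equal(mine$min_changes, oracle$min, info = paste("seed", seed))
    expect_equal(length(mine$reconstructions), nrow(oracle$labelings),
                 info = paste("seed", seed))
    expect_true(all(vapply(mine$reconstructions, nrow, 0L) ==
                      mine$min_changes))
  }
})

test_that("Fitch equals an independent parsimony implementation", {
  for (seed in 1:20) {
    set.seed(seed)
    tr <- ape::rtree(9, rooted = TRUE)
    tr$tip.label <- paste0("t", 1:9)
    states <- setNames(sample(c("fused", "split"), 9, TRUE), tr$tip.label)
    pd <- phangorn::phyDat(matrix(states, ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("fused", "split"))
    expect_equal(fitch_min_changes(tr, states),
                 as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("the rooting scan finds the single-event attachment", {
  ing <- ape::unroot(ape::drop.tip(rnapol_thaum_rooted(), "Bac"))
  states <- rnapol_thaum_states[ing$tip.label]
  scan <- rooting_scan(ing, "fused", states)
  expect_equal(scan$min_changes, 1L)
  best <- scan$table$child_clade[scan$table$edge %in% scan$best_edges]
  expect_true("Thaum" %in% best) # attachment on the Thaumarchaeota branch
  eury_edge <- scan$table$min_changes[scan$table$child_clade == "Eury"]
  expect_equal(eury_edge, 2L)
  # exhaustive agreement at every attachment
  for (e in scan$table$edge) {
    tr2 <- phyloconflict:::attach_tip_at_edge(ing, e, "OG")
    expect_equal(scan$table$min_changes[scan$table$edge == e],
                 brute_force_min_changes(tr2, c(states, OG = "fused")))
  }
  uniform <- setNames(rep("fused", length(ing$tip.label)), ing$tip.label)
  scan0 <- rooting_scan(ing, "fused", uniform)
  expect_true(all(scan0$table$min_changes == 0L))
  expect_gte(min(scan$table$min_changes), scan$min_changes)
})

test_that("states round trip through TSV", {
  tmp <- tempfile(fileext = ".tsv")
  write_states_tsv(rnapol_thaum_states, tmp)
  expect_equal(read_states_tsv(tmp), rnapol_thaum_states)
})
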