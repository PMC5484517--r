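mk <- function(...) {
  args <- list(...)
  lapply(args, aa_alignment)
}

test_that("concatenation arithmetic, gap fill and associativity", {
  m1 <- aa_alignment(c(a = "ARN", b = "ARD", cc = "ARC"))
  m2 <- aa_alignment(c(a = "QEGH", b = "QEGY"))
  pa <- concatenate_markers(list(m1 = m1, m2 = m2))
  expect_equal(ncol(pa$alignment), 7L)
  expect_equal(pa$partitions$start, c(0L, 3L))
  expect_equal(pa$partitions$end, c(3L, 7L))
  # taxon missing from m2 gets an all-gap block of the right width
  expect_equal(paste(pa$alignment["cc", 4:7], collapse = ""), "----")
  # single marker is itself
  single <- concatenate_markers(list(m1 = m1))
  expect_identical(unclass(single$alignment), unclass(m1))
  # associativity column-wise
  m3 <- aa_alignment(c(a = "WW", b = "WY", cc = "YY"))
  ab_c <- concatenate_markers(list(
    ab = concatenate_markers(list(m1 = m1, m2 = m2))$alignment, m3 = m3))
  abc <- concatenate_markers(list(m1 = m1, m2 = m2, m3 = m3))
  expect_identical(unclass(ab_c$alignment), unclass(abc$alignment))
  expect_error(concatenate_markers(list(m1 = m1, m2 = m2),
                                   fill_missing = FALSE), "differ")
})

test_that("taxon removal is exact and guards marker size", {
  ms <- list(
    m1 = random_alignment(6, 20, 1),
    m2 = random_alignment(6, 15, 2))
  expect_identical(remove_taxa(ms, character(0)), ms)
  out <- remove_taxa(ms, "t3")
  expect_false(any(vapply(out, function(a) "t3" %in% rownames(a), TRUE)))
  expect_false("t3" %in% rownames(concatenate_markers(out)$alignment))
  expect_warning(remove_taxa(ms, "zz"), "not present")
  expect_error(remove_taxa(ms, paste0("t", 1:3)), "fewer than")
})

test_that("ablation bookkeeping: counts, errors and record structure", {
  groups <- data.frame(
    taxon = c("B1", "B2", "E1", "E2", "A1", "A2", "A3", "L1"),
    group = c("Bacteria", "Bacteria", "Eukarya", "Eukarya", "Euryarchaeota",
              "Euryarchaeota", "Crenarchaeota", "Lokiarchaeota"),
    domain = c("Bacteria", "Bacteria", "Eukarya", "Eukarya", rep("Archaea", 4)))
  sp <- parse_newick(paste0(
    "((B1:0.3,B2:0.3):0.4,((E1:0.12,E2:0.12):0.15,(((A1:0.08,A2:0.08):0.04,",
    "A3:0.1):0.04,L1:0.1):0.08):0.08);"))
  cfg <- sim_config(trees = list(woese = sp),
                    markers = data.frame(id = c("m1", "m2", "m3"),
                                         n_sites = c(150L, 150L, 150L),
                                         history = "woese"),
                    seed = 31)
  gen <- make_conflicting_marker_set(cfg)
  pcfg <- pipeline_config(groups = groups, seed = 31)
  recs <- leave_one_marker_out(gen$markers, pcfg)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$removed, c("m1", "m2", "m3"))
  expect_equal(recs$flipped, recs$class_before != recs$class_after)
  # all markers share one history: no removal flips the class
  expect_false(any(recs$flipped))
  expect_equal(unique(recs$class_before), "woese")
  expect_error(leave_one_marker_out(gen$markers["m1"], pcfg), "at least 2")
  expect_error(leave_one_sequence_out(gen$markers, c("m1", "nope"), pcfg),
               "no sequence")
  expect_error(leave_one_sequence_out(gen$markers, c("zz", "A1"), pcfg),
               "unknown marker")
  # removing one clean row leaves the classification alone
  rec <- leave_one_sequence_out(gen$markers, c("m2", "A1"), pcfg)
  expect_false(rec$flipped)
})

test_that("partition bookkeeping survives trimming", {
  m1 <- random_alignment(5, 30, 7)
  m2 <- random_alignment(5, 20, 8)
  pa <- concatenate_markers(list(m1 = m1, m2 = m2))
  tr <- trim_columns(pa$alignment, score_min = 0.3)
  owners <- map_columns_to_markers(pa, tr$kept_columns)
  expect_equal(length(owners), length(tr$kept_columns))
  expect_true(all(owners[tr$kept_columns < 30] == "m1"))
  expect_true(all(owners[tr$kept_columns >= 30] == "m2"))
  expect_error(map_columns_to_markers(pa, 50L), "is not TRUE")
})
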