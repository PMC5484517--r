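test_that("local alignment matches closed forms, the floor, and oracles", {
  b62 <- similarity_matrix("BLOSUM62")
  # self-alignment: sum of diagonal entries
  pep <- "MKVLITWAGS"
  al <- local_align(pep, pep, b62)
  expect_equal(al$score, sum(diag(b62)[match(strsplit(pep, "")[[1]], rownames(b62))]))
  expect_equal(al$identity, 1)
  # all-negative pairs floor at 0 with an empty alignment
  z <- local_align("WWWW", "PPPP", b62)
  expect_equal(z$score, 0)
  expect_equal(z$alignment, c("", ""))
  # symmetry for a symmetric matrix
  a1 <- local_align("MKVLITGAG", "KVLMTGAGW", b62)
  a2 <- local_align("KVLMTGAGW", "MKVLITGAG", b62)
  expect_equal(a1$score, a2$score)
  expect_error(local_align("MK-A", "MKA", b62), "illegal")
})

test_that("local alignment equals an independent affine DP on short pairs", {
  b62 <- similarity_matrix("BLOSUM62")
  set.seed(7)
  for (i in 1:200) {
    q <- paste(sample(AA, sample(1:8, 1), TRUE), collapse = "")
    s <- paste(sample(AA, sample(1:8, 1), TRUE), collapse = "")
    expect_equal(local_align(q, s, b62)$score,
                 r_affine_local_score(q, s, b62, 11, 1),
                 info = paste(q, s))
  }
})

test_that("local alignment scores agree with Biostrings", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- similarity_matrix("BLOSUM62")
  set.seed(3)
  for (i in 1:25) {
    q <- paste(sample(AA, 30, TRUE), collapse = "")
    s <- paste(sample(AA, 35, TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                         substitutionMatrix = BLOSUM62,
                                         gapOpening = 11, gapExtension = 1)
    expect_equal(local_align(q, s, b62)$score, Biostrings::score(ref))
  }
})

make_insertion_fixture <- function(seed = 1, len = 12L, at = 60L,
                                   inject_anchor_len = 40L) {
  tr <- parse_newick(paste0(
    "((R1:0.05,R2:0.05):0.02,(R3:0.05,R4:0.05):0.02,(R5:0.05,F1:0.06):0.02);"))
  model <- small_model()
  aln <- simulate_alignment(ape::root(tr, outgroup = "R1",
                                      resolve.root = TRUE), model, 160,
                            seed = seed,
                            site_rate_multipliers = rep(0.05, 160))
  set.seed(seed + 1000)
  pep <- paste(sample(AA, len, TRUE), collapse = "")
  res <- inject_anchored_insertion(aln, list(taxon = "F1", at = at), pep,
                                   anchor_len = inject_anchor_len)
  list(aln = res$alignment, truth = res$truth, pep = pep)
}

test_that("anchored insertions are detected exactly where injected", {
  refs <- paste0("R", 1:5)
  # fully ungapped alignment: nothing to find
  clean <- random_alignment(6, 120, 5)
  expect_equal(nrow(detect_anchored_insertions(clean, "t1", paste0("t", 2:6))),
               0L)
  fx <- make_insertion_fixture(seed = 2, len = 12L)
  hits <- detect_anchored_insertions(fx$aln, "F1", refs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, fx$truth$start)
  expect_equal(hits$end, fx$truth$end)
  # the minimum reportable length (5 residues) is detectable at defaults
  fx5 <- make_insertion_fixture(seed = 3, len = 5L)
  hits5 <- detect_anchored_insertions(fx5$aln, "F1", refs)
  expect_equal(nrow(hits5), 1L)
  expect_equal(hits5$length, 5L)
  # an insertion hugging the alignment edge is dropped with a warning
  fxe <- make_insertion_fixture(seed = 4, len = 8L, at = 145L,
                                inject_anchor_len = 10L)
  expect_warning(
    he <- detect_anchored_insertions(fxe$aln, "F1", refs),
    "edge")
  expect_equal(nrow(he), 0L)
})

test_that("detection ignores row order and unrelated columns", {
  refs <- paste0("R", 1:5)
  fx <- make_insertion_fixture(seed = 6)
  perm <- fx$aln[rev(rownames(fx$aln)), , drop = FALSE]
  h1 <- detect_anchored_insertions(fx$aln, "F1", refs)
  h2 <- detect_anchored_insertions(aa_alignment(perm), "F1", refs)
  expect_equal(h1$start, h2$start)
  expect_equal(h1$end, h2$end)
})

test_that("donor attribution ranks the true donor first", {
  fx <- make_insertion_fixture(seed = 8, len = 14L)
  hits <- detect_anchored_insertions(fx$aln, "F1", paste0("R", 1:5))
  # database: true donor peptide in its anchor context plus shuffled decoys
  cols <- (hits$left_anchor_start + 1):hits$right_anchor_end
  context <- paste(fx$aln["F1", cols][fx$aln["F1", cols] != "-"],
                   collapse = "")
  set.seed(9)
  decoys <- vapply(1:10, function(i) {
    paste(sample(strsplit(context, "")[[1]]), collapse = "")
  }, "")
  donors <- c(truth = context, setNames(decoys, paste0("decoy", 1:10)))
  att <- attribute_insertion_donor(hits, fx$aln, donors)
  expect_equal(att$donor_id[1], "truth")
  expect_true(all(diff(att$score) <= 0))
  expect_error(attribute_insertion_donor(hits, fx$aln, character(0)), "empty")
})

test_that("segment scans find injected breakpoints and stay quiet on nulls", {
  model <- small_model()
  # the focal taxon is an archaeon; its tail segment is replaced by a
  # eukaryote row, so window affinities must switch clades at the boundary
  tr <- parse_newick(paste0(
    "(((A1:0.08,A2:0.08):0.05,(A3:0.08,A4:0.08):0.05):0.04,F1:0.06,",
    "(E1:0.1,E2:0.1):0.25);"))
  clades <- list(arch = paste0("A", 1:4), euk = c("E1", "E2"))
  hit <- 0L
  null_ok <- 0L
  for (seed in 1:5) {
    aln <- simulate_alignment(ape::root(tr, outgroup = "A1",
                                        resolve.root = TRUE), model, 400,
                              seed = seed)
    null_scan <- segment_affinity_scan(aln, "F1", clades, seed = seed + 500)
    if (null_scan$p_value >= 0.05) null_ok <- null_ok + 1L
    donor <- aln["E1", 201:400]
    res <- inject_segment_chimera(aln, list(taxon = "F1", start = 200L,
                                            end = 400L), donor)
    scan <- segment_affinity_scan(res$alignment, "F1", clades, seed = seed)
    if (!is.na(scan$breakpoint) && abs(scan$breakpoint - 200) <= 20 &&
        scan$p_value < 0.05 && scan$left_clade == "arch" &&
        scan$right_clade == "euk") {
      hit <- hit + 1L
    }
  }
  expect_gte(hit, 4L)
  expect_gte(null_ok, 4L)
})

test_that("a single full-width window reduces to plain clade distances", {
  aln <- random_alignment(6, 60, 12)
  clades <- list(g1 = c("t1", "t2"), g2 = c("t3", "t4"))
  scan <- segment_affinity_scan(aln, "t5", clades, window = 60L)
  expect_equal(nrow(scan$windows), 1L)
  d1 <- mean(c(phyloconflict:::row_distance(aln, "t5", "t1", 1:60),
               phyloconflict:::row_distance(aln, "t5", "t2", 1:60)))
  expect_equal(unname(scan$affinity[1, "g1"]), d1)
  expect_equal(scan$p_value, 1)
  expect_error(segment_affinity_scan(aln, "t1", clades), "inside a clade")
  expect_error(segment_affinity_scan(aln, "t5", clades, window = 100L),
               "exceeds")
})

test_that("alignment splitting is a lossless partition", {
  aln <- random_alignment(4, 30, 20)
  sp <- split_alignment_at(aln, 12L)
  expect_equal(ncol(sp$left) + ncol(sp$right), 30L)
  rejoined <- concatenate_markers(list(l = sp$left, r = sp$right))
  expect_identical(unclass(rejoined$alignment), unclass(aln))
  expect_error(split_alignment_at(aln, 0L), "split column")
  expect_error(split_alignment_at(aln, 30L), "split column")
})
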