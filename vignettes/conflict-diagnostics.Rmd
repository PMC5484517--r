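---
title: "Diagnosing conflicting signal in phylogenomic supermatrices"
author: "phyloconflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing conflicting signal in phylogenomic supermatrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconflict)
```

## The problem

Concatenating many protein markers into a supermatrix is the standard route
to resolving deep splits — for instance whether Archaea are monophyletic with
Eukarya as their sister group (the classical three-domain topology) or
whether Eukarya emerge from *within* Archaea next to a particular archaeal
lineage such as the Lokiarchaeota (an eocyte-style topology). The method's
premise is that most markers share one evolutionary history. When they do
not — because subsets of markers genuinely support different topologies,
because fast-evolving species (FES) drag long branches together, or because
a marker is a chimera carrying patches of foreign sequence — the
concatenated tree can be driven by a small part of the data, and in extreme
cases by a single gene. `phyloconflict` packages the diagnostics needed to
detect exactly this: per-marker tree inference and classification,
topology-test-based marker partitioning, chimera screening, ablation
experiments, and parsimony analysis of rare genomic characters, all
exercisable end-to-end on simulated data with known truth.

## Likelihood machinery

All tree inference uses the LG amino-acid substitution model with
discrete-gamma rate heterogeneity. The rate matrix is
$Q = S\,\mathrm{diag}(\pi)$ from the published LG exchangeabilities $S$ and
stationary frequencies $\pi$, rows filled to sum to zero and scaled so the
expected rate $\sum_i \pi_i |Q_{ii}| = 1$; branch lengths are therefore in
expected substitutions per site. Rate heterogeneity uses Yang's
equal-probability discrete gamma with $k = 4$ categories by default, each
category's rate being the mean of its quantile band (the rates average
exactly 1). The shape $\alpha$ is a configuration value with default 1.0 —
the package deliberately does not claim a per-marker estimate; an analysis
that needs $\hat\alpha$ can profile the likelihood over
`substitution_model(gamma_shape = ...)`.

Transition matrices come from the symmetric eigendecomposition of
$\mathrm{diag}(\pi)^{1/2} Q\, \mathrm{diag}(\pi)^{-1/2}$ (reversibility
guarantees a real spectrum), so $P(t) = U e^{\Lambda t} U^{-1}$ costs one
recombination per branch and category. Site likelihoods follow Felsenstein
pruning with per-node rescaling in log space; gaps and `X` contribute
all-ones partial vectors. Identical site patterns are collapsed to weighted
columns before the C++ passes. Two cached quantities make the search fast:
per-edge *messages* (the conditional likelihood of a subtree propagated
through its stem) and per-edge *outside* arrays (everything except the
subtree, as a function of the state at the parent). With these, the total
log-likelihood as a function of any single branch length — or of the central
branch of a nearest-neighbor-interchange (NNI) quartet — is a cheap 1-D
function.

Branch lengths are optimized by round-robin sweeps: one arrays computation
per sweep, a bounded Brent search per branch on a window around the current
length (bounds $[10^{-8}, 20]$), then a joint update with a guard that falls
back to the single best branch if the joint step does not dominate it; the
total log-likelihood is non-decreasing across sweeps by construction.
Topology search is NNI hill-climbing from a neighbor-joining start
(Poisson-corrected distances, Studier–Keppler criterion, ties broken by the
lowest index pair): every internal edge's two alternatives are scored via
the cached quartet, the best improving move is applied and branch lengths
re-optimized. Because the quartet score only re-optimizes the central branch
it is a lower bound; when no candidate clears the threshold the top two
still get a full re-optimization before the search stops. SPR moves are not
implemented — NNI keeps the search tractable at desk scale, at the cost of a
larger local-optimum risk on adversarial starts (the package's simulations
start from NJ, where this has not been limiting).

Bootstrap supports are plain nonparametric column resampling with full
NJ+NNI re-inference per replicate (the study-scale convention is 100
replicates); the support of an edge is the percentage of replicate trees
containing its bipartition. Every random stage derives its own stream from a
master seed via `derive_seed()`, so any replicate can be reproduced in
isolation.

## The AU test

Marker-level topology testing uses the approximately-unbiased test:
per-site log-likelihoods are computed for each candidate topology (branch
lengths re-optimized per topology), then resampled at scales
$r \in \{0.5, \dots, 1.4\}$ with $B = 1000$ replicates per scale (RELL — no
re-optimization inside the bootstrap). The winning frequency $BP_k(r)$ of
each tree is transformed as $z = \Phi^{-1}(1 - BP)$ and fitted by weighted
least squares to $d\sqrt{r} + c/\sqrt{r}$ with binomial delta-method
weights; $p_k = 1 - \Phi(d - c)$. Frequencies are clamped to
$[0.5/B,\, 1 - 0.5/B]$; a tree that wins every replicate at every scale (or
none) gets $p$ clamped to 1 (or 0) with a degeneracy flag. Exact ties in the
replicate winner are broken uniformly at random inside the seeded stream —
this is what makes two byte-identical topologies receive equal $p$-values up
to Monte-Carlo error, which would fail under a deterministic "first wins"
rule. The confidence set keeps trees with $p \ge \alpha$ (default 0.05), and
markers are called Woese-relevant when they significantly reject the eocyte
topology while retaining the Woese topology (and conversely).

## Column trimming

The trimming rule removes gap-rich and poorly conserved columns before
inference. A column's conservation is the mean over ungapped residue pairs
of the similarity score rescaled to $[0, 1]$ — each pair score is shifted by
the matrix minimum and divided by the shifted self-score of the weaker
partner, so a column of identical residues scores exactly 1 regardless of
which residue it is. (Normalizing by the global matrix range instead would
cap an all-alanine column near 0.4 under BLOSUM30, because the range is set
by the rare tryptophan self-score; thresholds like 0.5 would then be
meaningless.) Scores are smoothed with a centered moving average (width 3)
over the surviving column sequence, and the selection is iterated to a fixed
point: conservation is intrinsic to a column, only the smoothing
neighborhood updates, so the kept set shrinks monotonically and trimming a
trimmed alignment removes nothing further. Columns must also satisfy a gap
fraction of at most `gap_max` (default 0.2). The procedure is inspired by
block-mapping trimmers used in deep phylogenomics and defaults to BLOSUM30
as its similarity matrix, which is the appropriate choice for alignments
spanning domains of life; it is a specified, testable contract rather than a
re-implementation of any particular tool.

## Chimera screening

Three complementary screens target chimeric markers:

* **Anchored insertions.** A hit is a maximal run of at least 5 columns
  where a focal taxon carries residues while at least 80% of the reference
  rows are gapped, flanked on both sides by 40 conserved columns (mean
  reference conservation at least 0.7). The 5-residue floor reflects the
  smallest biologically reported private insertions worth chasing; the
  40-column anchors are what make the flanks usable as search queries.
* **Donor attribution.** The insertion plus anchors (gaps stripped) is
  aligned against candidate donor peptides by Smith–Waterman with affine
  gaps (gap of length $L$ costs $11 + L$; BLOSUM62), deterministic traceback
  (diagonal, then up, then left), and candidates ranked by score. This is an
  in-repository replacement for a database search: donors are supplied
  explicitly, so results are reproducible offline.
* **Segment affinity / breakpoints.** Sliding windows (width 50, step 10)
  record the focal taxon's mean Poisson-corrected distance to each reference
  clade. The two-segment score $\Delta(b)$ is the reduction in total
  best-clade distance when windows left and right of $b$ are assigned clades
  independently rather than jointly ($\Delta \ge 0$ always); its
  significance comes from permuting the window order (add-one corrected).
  When the two segments choose different clades, the breakpoint column is
  refined at single-column resolution: for each segment's clade, the member
  closest to the focal taxon is selected, and the changepoint maximizing the
  joint binomial profile likelihood of the two per-column mismatch series is
  taken. The closest relatives carry the sharpest rate change at the
  boundary, and the likelihood form handles the generally unequal mismatch
  rates of the two segments (a plain cumulative-sum argmin is biased toward
  the weaker side, and least-squares underweights the near-zero-variance
  segment; both alternatives were measurably less accurate on calibration
  simulations when this estimator was fixed).

## Gene-architecture parsimony

The fused vs split state of the RNA polymerase A subunit is analyzed as an
unordered, reversible binary character with unit costs. Counting uses the
multi-child generalization of the Fitch rule (a node keeps the states
carried by the largest number of children and pays one change per child
outside that set), which is exact on polytomies and reduces to
intersection/union on binary nodes; the count is invariant to rooting.
All most-parsimonious reconstructions are enumerated by Sankoff backtracking
(capped, default 10,000) and each change typed as a split (fused → split) or
fusion. `rooting_scan()` attaches a pendant outgroup carrying a fixed state
to every edge in turn and reports the minimum-change count per attachment —
the parsimony argument for where the outgroup (and hence the root) belongs.
When most-parsimonious reconstructions disagree they are reported
separately, not merged into a consensus: the scientific argument rests on
counts, not on a unique ancestral labeling.

## The simulator and its presets

`simulate_alignment()` evolves sequences down a species tree under the same
LG+Γ model used for inference: root states from $\pi$, one gamma category
per site, optional per-site rate multipliers. No natural indel process is
simulated — sequences are born aligned, and the only gaps are explicit
injections. This is a deliberate scope cut: the pipeline consumes
alignments, and indel realism would mostly exercise the upstream aligner
that this package does not implement. Fast-evolving taxa are emulated by
multiplying pendant branches; chimeras by replacing a column interval of one
taxon with the row of a *donor lineage* simulated as an extra tip attached
at a chosen clade's stem (so donor divergence is a modeled quantity, not
random noise), or by inserting donor-derived columns whose flanks were
simulated at 5% of the normal rate so that detection anchors exist. Every
event is recorded in a machine-readable truth set, and identical
configuration plus seed reproduces identical bytes.

Two presets define the package's study conditions:

* `preset_conflict()` — 30 taxa across the three domains (including a
  *M. kandleri*-like and a nanosized-archaeon-like FES pair at 4x pendant
  rate), nine markers of 300–600 columns, six on the Woese history and three
  on the eocyte history. This is the general-purpose instance for
  classification, tabulation, AU partitioning and curation experiments.
* `preset_ef2_like()` — 15 taxa, eight clean 100-column markers plus one
  900-column marker in which the single Lokiarchaeota taxon carries a
  eukaryote-donor segment over 94% of its length and two anchored insertions
  (12 and 7 residues). The deep inter-phylum stems of its species trees are
  deliberately short (0.015–0.03 substitutions/site): weakly resolved
  backbone splits are precisely the regime in which a single strongly
  conflicting marker can redirect a concatenation, and with comfortably long
  stems no realistic single-marker chimera could (the likelihood margin
  between the two topologies was checked in both directions when the preset
  was designed). On this preset the full concatenation classifies
  eocyte-like with Eukarya sister to the Lokiarchaeota taxon, and removing
  either the chimeric marker or just its contaminated row restores the
  Woese classification — the synthetic analogue of a published
  single-protein flip.

Passing tests on these presets demonstrates that the diagnostics recover
known, injected structure under the model's own assumptions. They do not
demonstrate robustness to what real data add on top: alignment error,
compositional heterogeneity, among-site and among-lineage model violations,
and incomplete marker coverage.

## Pipeline, classification and reporting

`run_pipeline()` chains curation → trimming → per-marker inference →
classification/tabulation → AU partitioning → ablation → chimera scan →
parsimony, with stage toggles and one master seed fanned out per stage and
item. Classification roots each tree with its Bacteria leaves (midpoint of
the subtending edge; a non-monophyletic outgroup falls back to the most
similar bipartition with a warning), then calls a tree Woese-like when the
archaeal leaves are monophyletic, eocyte-like when the eukaryotic leaves are
monophyletic and nested strictly inside the archaeal most recent common
ancestor, and unresolved otherwise. Monophyly at polytomies is strict — the
exact bipartition must exist — matching the semantics of bootstrap support.
Phyla with fewer than two leaves in a marker are scored not-applicable and
excluded from summary denominators. `render_table1_style()` prints the
per-phylum monophyly counts binned at bootstrap thresholds (any / >50 / >80),
the count of markers with Archaea monophyletic at 100, and the count with
the Eukarya clade sister to Lokiarchaeota leaves.

Ablation experiments re-run the full trim/infer/classify path after each
perturbation (the alignment is re-trimmed after removal, since removing rows
changes column statistics); sequence removal replaces one row of one marker
by gaps so the taxon keeps its other markers. Bootstrap supports are off by
default inside ablation runs (`bootstrap_B = 0`): the classification at
`support_min = 0` does not consume them, and the study-scale protocol
(`bootstrap_B = 100`) can be switched on when supports are the question.

## Numerical choices and limitations

* Branch-length bounds $[10^{-8}, 20]$; Brent tolerance $10^{-5}$ on a
  window around the current length, re-centered each sweep.
* Default convergence: `tol = 1e-4` per sweep for standalone optimization;
  the pipeline uses 0.05 (classification is insensitive to terminal
  branch-length polish).
* Per-node log-space rescaling makes likelihoods safe to a few thousand
  taxa-sites; non-finite values are errors, never silently patched.
* Canonical Newick output orders children by smallest contained leaf label
  and prints 6 significant digits, so topologically identical trees
  serialize byte-identically.
* Supports are treated as edge (bipartition) properties and survive
  re-rooting; the root node label is cleared.
* Not implemented, by design: SPR search, free-rate models, per-marker
  empirical frequencies (+F), Bayesian inference, profile-HMM chimera
  detection, and nucleotide alphabets.

## Reproducibility

Every exported stochastic operation takes a seed; `run_pipeline()` requires
one. The problem sizes used by the test suite and the acceptance script
(tens of taxa, hundreds of columns, hundreds to a thousand bootstrap or
permutation replicates) were chosen so a full run completes on a single
desktop core; all headline numbers in the repository are recomputed from
scratch by `scripts/acceptance.R`.
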