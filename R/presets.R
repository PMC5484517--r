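# Canned simulation presets: the three-domain study conditions at desk scale.
#
# Both presets use two species histories over the same taxa: a "woese" tree
# (Archaea monophyletic, sister to Eukarya, Bacteria as the distant outgroup)
# and an "eocyte" tree (Eukarya nested inside Archaea, sister to the
# Lokiarchaeota lineage). Branch lengths are in expected substitutions/site.

# Deep inter-phylum stems are deliberately short (0.02-0.03): the backbone
# splits are the weakly resolved part of real universal-marker data, which is
# what lets a single strongly conflicting marker redirect the concatenation.
ef2_woese_newick <- paste0(
  "((Bac1:0.25,(Bac2:0.2,Bac3:0.2):0.1):0.6,",
  "(((Euk1:0.12,Euk2:0.12):0.08,(Euk3:0.12,Euk4:0.12):0.08):0.12,",
  "((Thaum1:0.12,Thaum2:0.12):0.02,((Cren1:0.1,Cren2:0.1):0.02,",
  "((Eury1:0.08,(Eury2:0.08,Eury3:0.08):0.04):0.015,Loki1:0.1):0.015)",
  ":0.02):0.02):0.08);")

ef2_eocyte_newick <- paste0(
  "((Bac1:0.25,(Bac2:0.2,Bac3:0.2):0.1):0.6,",
  "((Thaum1:0.12,Thaum2:0.12):0.02,((Cren1:0.1,Cren2:0.1):0.02,",
  "((Eury1:0.08,(Eury2:0.08,Eury3:0.08):0.04):0.015,",
  "(Loki1:0.08,((Euk1:0.12,Euk2:0.12):0.08,(Euk3:0.12,Euk4:0.12):0.08):0.1)",
  ":0.015):0.015):0.02):0.1);")

ef2_groups <- function() {
  data.frame(
    taxon = c("Bac1", "Bac2", "Bac3", "Euk1", "Euk2", "Euk3", "Euk4",
              "Thaum1", "Thaum2", "Cren1", "Cren2", "Eury1", "Eury2",
              "Eury3", "Loki1"),
    group = c(rep("Bacteria", 3), rep("Eukarya", 4), rep("Thaumarchaeota", 2),
              rep("Crenarchaeota", 2), rep("Euryarchaeota", 3),
              "Lokiarchaeota"),
    domain = c(rep("Bacteria", 3), rep("Eukarya", 4), rep("Archaea", 8)),
    stringsAsFactors = FALSE)
}

#' The EF2-like chimeric-marker preset
#'
#' Fifteen taxa over the three domains; eight clean 100-column markers plus
#' one 900-column marker (the analogue of a long elongation-factor gene)
#' evolved on the Woese history, where the single Lokiarchaeota taxon carries
#' an extensive eukaryote-donor segment replacement (columns 50-900, donor
#' lineage attached at the Eukarya stem) and two donor-derived anchored
#' insertions (12 and 7 residues). The designed behavior: the full
#' concatenation classifies eocyte-like, and removing either the chimeric
#' marker or just its contaminated row restores the Woese classification.
#'
#' @param seed master seed for the generator.
#' @return list with `config` (a [sim_config()]), `groups` (taxon map),
#'   `chimeric_marker`, `chimeric_taxon`.
#' @export
preset_ef2_like <- function(seed = 1L) {
  trees <- list(woese = parse_newick(ef2_woese_newick),
                eocyte = parse_newick(ef2_eocyte_newick))
  euks <- paste0("Euk", 1:4)
  markers <- data.frame(
    id = c(paste0("m", 1:8), "ef2"),
    n_sites = c(rep(100L, 8), 900L),
    history = "woese", stringsAsFactors = FALSE)
  chimeras <- list(
    list(kind = "segment", marker = "ef2", taxon = "Loki1", start = 50L,
         end = 900L, donor_clade = euks, donor_branch = 0.02),
    list(kind = "insertion", marker = "ef2", taxon = "Loki1", at = 45L,
         length = 12L, donor_clade = euks, donor_branch = 0.02,
         anchor_rate_mult = 0.05),
    list(kind = "insertion", marker = "ef2", taxon = "Loki1", at = 860L,
         length = 7L, donor_clade = euks, donor_branch = 0.02,
         anchor_rate_mult = 0.05))
  list(config = sim_config(trees = trees, markers = markers,
                           fes = numeric(0), chimeras = chimeras,
                           seed = seed),
       groups = ef2_groups(), chimeric_marker = "ef2",
       chimeric_taxon = "Loki1")
}

conflict_woese_newick <- paste0(
  "((Bac1:0.3,(Bac2:0.25,(Bac3:0.2,(Bac4:0.2,Bac5:0.2):0.05):0.05):0.1):0.55,",
  "(((Euk1:0.15,(Euk2:0.12,Euk3:0.12):0.06):0.08,",
  "(Euk4:0.14,(Euk5:0.12,(Euk6:0.1,Euk7:0.1):0.05):0.05):0.08):0.16,",
  "((Thaum1:0.1,(Thaum2:0.1,Thaum3:0.1):0.05):0.08,",
  "(Kor1:0.14,((Cren1:0.1,(Cren2:0.1,(Cren3:0.08,Cren4:0.08):0.04):0.04):0.06,",
  "(((Eury1:0.1,((Eury2:0.08,FES1:0.1):0.04,(Eury3:0.08,(Eury4:0.08,Eury5:0.08)",
  ":0.03):0.04):0.04):0.05,FES2:0.12):0.04,",
  "(Loki1:0.1,(Loki2:0.1,Loki3:0.12):0.05):0.08):0.04):0.04):0.04):0.09):0.1);")

conflict_eocyte_newick <- paste0(
  "((Bac1:0.3,(Bac2:0.25,(Bac3:0.2,(Bac4:0.2,Bac5:0.2):0.05):0.05):0.1):0.55,",
  "((Thaum1:0.1,(Thaum2:0.1,Thaum3:0.1):0.05):0.08,",
  "(Kor1:0.14,((Cren1:0.1,(Cren2:0.1,(Cren3:0.08,Cren4:0.08):0.04):0.04):0.06,",
  "(((Eury1:0.1,((Eury2:0.08,FES1:0.1):0.04,(Eury3:0.08,(Eury4:0.08,Eury5:0.08)",
  ":0.03):0.04):0.04):0.05,FES2:0.12):0.04,",
  "((Loki1:0.1,(Loki2:0.1,Loki3:0.12):0.05):0.04,",
  "(((Euk1:0.15,(Euk2:0.12,Euk3:0.12):0.06):0.08,",
  "(Euk4:0.14,(Euk5:0.12,(Euk6:0.1,Euk7:0.1):0.05):0.05):0.08):0.14)",
  ":0.06):0.05):0.04):0.04):0.04):0.16);")

conflict_groups <- function() {
  data.frame(
    taxon = c(paste0("Bac", 1:5), paste0("Euk", 1:7),
              paste0("Thaum", 1:3), "Kor1", paste0("Cren", 1:4),
              paste0("Eury", 1:5), "FES1", "FES2", paste0("Loki", 1:3)),
    group = c(rep("Bacteria", 5), rep("Eukarya", 7),
              rep("Thaumarchaeota", 3), "Korarchaeota",
              rep("Crenarchaeota", 4), rep("Euryarchaeota", 5),
              "Euryarchaeota", "Nanoarchaeota", rep("Lokiarchaeota", 3)),
    domain = c(rep("Bacteria", 5), rep("Eukarya", 7), rep("Archaea", 18)),
    stringsAsFactors = FALSE)
}

#' The default conflicting-histories preset
#'
#' Thirty taxa across the three domains (with two fast-evolving archaea, a
#' *M. kandleri*-like euryarchaeon FES1 and a nanosized-archaeon-like FES2),
#' nine markers of 300-600 columns: six evolved on the Woese history and
#' three on the eocyte history. No chimeras; this preset exercises
#' per-marker classification, the AU partition, and FES curation.
#'
#' @param seed master seed.
#' @param fes_factor pendant-branch multiplier for the two FES taxa.
#' @return list with `config`, `groups`, `fes_taxa`.
#' @export
preset_conflict <- function(seed = 1L, fes_factor = 4) {
  trees <- list(woese = parse_newick(conflict_woese_newick),
                eocyte = parse_newick(conflict_eocyte_newick))
  markers <- data.frame(
    id = paste0("m", 1:9),
    n_sites = c(600L, 500L, 450L, 400L, 350L, 300L, 500L, 400L, 300L),
    history = c(rep("woese", 6), rep("eocyte", 3)),
    stringsAsFactors = FALSE)
  list(config = sim_config(trees = trees, markers = markers,
                           fes = c(FES1 = fes_factor, FES2 = fes_factor),
                           chimeras = list(), seed = seed),
       groups = conflict_groups(), fes_taxa = c("FES1", "FES2"))
}
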