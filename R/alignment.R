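# Alignment container and FASTA I/O.
#
# An alignment is stored as a character matrix (taxa x columns) of single
# upper-case residues over the 20 amino-acid letters plus '-' (gap) and
# 'X' (unknown). Row names are the taxon ids, in input order.

#' Construct an amino-acid alignment
#'
#' @param seqs either a named character vector of equal-length sequence
#'   strings, or a character matrix of single residues with row names.
#' @return an object of class `aa_alignment`: a character matrix with unique
#'   row names; lowercase input is upper-cased and `'.'` normalized to `'-'`.
#' @export
aa_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    n <- nchar(seqs)
    if (length(unique(n)) > 1L) {
      bad <- names(seqs)[which(n != n[1L])[1L]]
      stop("ragged alignment: record '", bad, "' has length ", n[n != n[1L]][1L],
           ", expected ", n[1L])
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named by taxon id")
  if (anyDuplicated(rownames(m))) {
    stop("duplicate taxon id: ", rownames(m)[duplicated(rownames(m))][1L])
  }
  m[] <- toupper(m)
  m[m == "."] <- "-"
  ok <- m %in% c(AA_ALPHABET, "-", "X")
  if (!all(ok)) {
    bad <- unique(m[!ok])
    stop("illegal residue character(s): ", paste(bad, collapse = " "))
  }
  class(m) <- c("aa_alignment", class(m))
  m
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", nrow(x), "taxa x", ncol(x), "columns\n")
  show <- utils::head(rownames(x), 6L)
  for (tx in show) {
    s <- paste(x[tx, seq_len(min(60L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", tx, s, if (ncol(x) > 60L) "..." else ""))
  }
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more taxa\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln an [aa_alignment()].
#' @return integer column count.
#' @export
n_columns <- function(aln) ncol(aln)

#' Read an aligned amino-acid FASTA file
#'
#' Records are kept in file order; sequences are upper-cased and `'.'` is
#' normalized to `'-'`. Ragged records or duplicate ids are errors.
#'
#' @param path path to a FASTA file with at least two records.
#' @return an [aa_alignment()].
#' @export
read_alignment_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- ape::read.FASTA(path, type = "AA")
  if (length(x) < 2L) stop("FASTA must contain at least 2 records: ", path)
  seqs <- vapply(as.character(x), paste, "", collapse = "")
  aa_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln an [aa_alignment()].
#' @param path output path.
#' @param width residues per line.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in rownames(aln)) {
    s <- paste(aln[tx, ], collapse = "")
    writeLines(paste0(">", tx), con)
    writeLines(substring(s, seq(1L, nchar(s), width),
                         pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Integer encoding used by the likelihood engine: 1..20 for residues in
# AA_ALPHABET order, 0 for gap/unknown (all-ones partial vector).
encode_alignment <- function(aln) {
  codes <- match(aln, AA_ALPHABET)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = nrow(aln), dimnames = dimnames(aln))
}

#' Extract a taxon's ungapped peptide
#' @param aln an [aa_alignment()].
#' @param taxon taxon id.
#' @return character scalar, gaps removed ('X' retained).
#' @export
degap <- function(aln, taxon) {
  if (!taxon %in% rownames(aln)) stop("unknown taxon: ", taxon)
  paste(aln[taxon, aln[taxon, ] != "-"], collapse = "")
}

#' Read/write a taxon group map
#'
#' The map is a TSV with columns `taxon`, `group`, `domain`; domains must be
#' drawn from the fixed three-domain set Archaea/Bacteria/Eukarya.
#'
#' @param path TSV path.
#' @return a data.frame with columns taxon, group, domain.
#' @export
read_taxon_groups <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_taxon_groups(df)
}

#' @rdname read_taxon_groups
#' @param groups a taxon group data.frame.
#' @export
write_taxon_groups <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_taxon_groups <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("taxon", "group", "domain") %in% names(groups)))
  bad <- setdiff(unique(groups$domain), c("Archaea", "Bacteria", "Eukarya"))
  if (length(bad)) stop("unknown domain label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(groups$taxon)) stop("duplicate taxon in group map")
  groups
}

group_taxa <- function(groups, label, field = "group") {
  groups$taxon[groups[[field]] == label]
}
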