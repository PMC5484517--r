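# Residue similarity matrices (published NCBI BLOSUM integer scores).

BLOSUM30_SCORES <- matrix(c(
   4,-1, 0, 0,-3, 1, 0, 0,-2, 0,-1, 0, 1,-2,-1, 1, 1,-5,-4, 1,
  -1, 8,-2,-1,-2, 3,-1,-2,-1,-3,-2, 1, 0,-1,-1,-1,-3, 0, 0,-1,
   0,-2, 8, 1,-1,-1,-1, 0,-1, 0,-2, 0, 0,-1,-3, 0, 1,-7,-4,-2,
   0,-1, 1, 9,-3,-1, 1,-1,-2,-4,-1, 0,-3,-5,-1, 0,-1,-4,-1,-2,
  -3,-2,-1,-3,17,-2, 1,-4,-5,-2, 0,-3,-2,-3,-3,-2,-2,-2,-6,-2,
   1, 3,-1,-1,-2, 8, 2,-2, 0,-2,-2, 0,-1,-3, 0,-1, 0,-1,-1,-3,
   0,-1,-1, 1, 1, 2, 6,-2, 0,-3,-1, 2,-1,-4, 1, 0,-2,-1,-2,-3,
   0,-2, 0,-1,-4,-2,-2, 8,-3,-1,-2,-1,-2,-3,-1, 0,-2, 1,-3,-3,
  -2,-1,-1,-2,-5, 0, 0,-3,14,-2,-1,-2, 2,-3, 1,-1,-2,-5, 0,-3,
   0,-3, 0,-4,-2,-2,-3,-1,-2, 6, 2,-2, 1, 0,-3,-1, 0,-3,-1, 4,
  -1,-2,-2,-1, 0,-2,-1,-2,-1, 2, 4,-2, 2, 2,-3,-2, 0,-2, 3, 1,
   0, 1, 0, 0,-3, 0, 2,-1,-2,-2,-2, 4, 2,-1, 1, 0,-1,-2,-1,-2,
   1, 0, 0,-3,-2,-1,-1,-2, 2, 1, 2, 2, 6,-2,-4,-2, 0,-3,-1, 0,
  -2,-1,-1,-5,-3,-3,-4,-3,-3, 0, 2,-1,-2,10,-4,-1,-2, 1, 3, 1,
  -1,-1,-3,-1,-3, 0, 1,-1, 1,-3,-3, 1,-4,-4,11,-1, 0,-3,-2,-4,
   1,-1, 0, 0,-2,-1, 0, 0,-1,-1,-2, 0,-2,-1,-1, 4, 2,-3,-2,-1,
   1,-3, 1,-1,-2, 0,-2,-2,-2, 0, 0,-1, 0,-2, 0, 2, 5,-5,-1, 1,
  -5, 0,-7,-4,-2,-1,-1, 1,-5,-3,-2,-2,-3, 1,-3,-3,-5,20, 5,-3,
  -4, 0,-4,-1,-6,-1,-2,-3, 0,-1, 3,-1,-1, 3,-2,-2,-1, 5, 9, 1,
   1,-1,-2,-2,-2,-3,-3,-3,-3, 4, 1,-2, 0, 1,-4,-1, 1,-3, 1, 5),
  nrow = 20, byrow = TRUE)

BLOSUM62_SCORES <- matrix(c(
   4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
  -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
  -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
  -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
   0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
  -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
  -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
   0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
  -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
  -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
  -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
  -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
  -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
  -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
  -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
   1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
   0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
  -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
  -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
   0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4),
  nrow = 20, byrow = TRUE)

#' Fetch a residue similarity matrix by name
#'
#' @param name `"BLOSUM30"` or `"BLOSUM62"`, or a user-supplied 20x20
#'   symmetric integer matrix with positive diagonal (rows/cols in the
#'   standard ARNDCQEGHILKMFPSTWYV order).
#' @return a `similarity_matrix`: the score matrix with dimnames set and a
#'   `name` attribute.
#' @export
similarity_matrix <- function(name = "BLOSUM30") {
  if (is.matrix(name)) {
    m <- name
    nm <- attr(name, "name") %||% "custom"
  } else {
    m <- switch(toupper(name),
                BLOSUM30 = BLOSUM30_SCORES,
                BLOSUM62 = BLOSUM62_SCORES,
                stop("unknown similarity matrix: ", name))
    nm <- toupper(name)
  }
  stopifnot(nrow(m) == 20L, ncol(m) == 20L)
  if (!isTRUE(all.equal(m, t(m)))) stop("similarity matrix must be symmetric")
  if (any(diag(m) <= 0)) stop("similarity matrix diagonal must be positive")
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  structure(m, name = nm, class = c("similarity_matrix", class(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
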