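#' The 20 canonical amino acids, alphabetically ordered
#'
#' One-letter codes in the fixed order used everywhere in pepanchor
#' (one-hot encodings, position weight matrices, motif matrices).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Anchor positions of the class II MHC 9-mer core, in P-notation (P1..P9).
# The side chains at P1, P4, P6, P9 bury into the groove pockets; all other
# positions are held fixed by the optimizer.

#' Anchor and non-anchor positions of the 9-mer core
#'
#' Positions are reported in the field's P-notation, P1..P9, which for a
#' 9-mer core coincides with 1-based string indexing. [p_to_offset()]
#' converts P-notation to 0-based sequence offsets.
#'
#' @return Integer vector of positions.
#' @export
anchor_positions <- function() c(1L, 4L, 6L, 9L)

#' @rdname anchor_positions
#' @export
nonanchor_positions <- function() c(2L, 3L, 5L, 7L, 8L)

#' Convert between P-notation and 0-based offsets
#'
#' @param p Integer vector of P-notation positions (P1..P9 given as 1..9).
#' @param offset Integer vector of 0-based offsets.
#' @return The converted positions.
#' @export
p_to_offset <- function(p) {
  p <- as.integer(p)
  stopifnot(all(p >= 1L), all(p <= 9L))
  p - 1L
}

#' @rdname p_to_offset
#' @export
offset_to_p <- function(offset) {
  offset <- as.integer(offset)
  stopifnot(all(offset >= 0L), all(offset <= 8L))
  offset + 1L
}

#' Validate 9-mer core peptides
#'
#' A valid core is exactly 9 residues long and uses only the 20 canonical
#' one-letter amino-acid codes.
#'
#' @param x Character vector of candidate peptides.
#' @return `is_peptide9`: logical vector. `assert_peptide9`: `x`,
#'   invisibly, or an error describing the first offender.
#' @export
is_peptide9 <- function(x) {
  !is.na(x) & nchar(x) == 9L & grepl("^[ACDEFGHIKLMNPQRSTVWY]{9}$", x)
}

#' @rdname is_peptide9
#' @export
assert_peptide9 <- function(x) {
  ok <- is_peptide9(x)
  if (!all(ok)) {
    bad <- x[!ok][1L]
    stop("not a valid 9-mer core peptide: '", bad,
         "' (need exactly 9 canonical residues)", call. = FALSE)
  }
  invisible(x)
}

# n x 9 character matrix of residues; peptides must already be valid.
peptide_matrix <- function(peptides) {
  m <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
              ncol = 9L, byrow = TRUE)
  colnames(m) <- paste0("P", 1:9)
  m
}

# residue -> 1..20 index into AA_ALPHABET; NA for non-canonical
aa_index <- function(res) match(res, AA_ALPHABET)

# Evaluate a function with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
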