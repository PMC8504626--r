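#' Read a proteome FASTA file
#'
#' Sequences are uppercased. Records containing residues outside the 20
#' canonical one-letter codes are retained but flagged (`canonical = FALSE`);
#' downstream 9-mer scanning skips windows that overlap such residues.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `sequence`, `canonical`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("FASTA file contains an empty sequence: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  data.frame(
    id = ids,
    sequence = unname(seqs),
    canonical = grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs),
    stringsAsFactors = FALSE
  )
}

#' Scan a protein sequence for candidate 9-mer cores
#'
#' Returns every overlapping window of length 9 consisting solely of
#' canonical residues, with 0-based offsets into the protein. Windows that
#' overlap a non-canonical residue (e.g. `X`) are skipped. Sequences
#' shorter than 9 yield an empty result.
#'
#' @param sequence Protein sequence (character scalar), or a single-row
#'   data.frame as returned by [read_fasta()].
#' @return A data.frame with columns `offset` (0-based) and `peptide`.
#' @export
scan_9mers <- function(sequence) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  empty <- data.frame(offset = integer(), peptide = character(),
                      stringsAsFactors = FALSE)
  if (L < 9L) return(empty)
  starts <- seq_len(L - 8L)
  peps <- substring(sequence, starts, starts + 8L)
  keep <- is_peptide9(peps)
  data.frame(offset = starts[keep] - 1L, peptide = peps[keep],
             stringsAsFactors = FALSE)
}

#' Flank schemes for display constructs
#'
#' The default invariant peptide flanking residues (IPFR) wrap the 9-mer
#' core as `AA` + core + `WEEG`, enforcing a single binding register in the
#' display assay.
#'
#' @param prefix,suffix Invariant flanks.
#' @return A list with elements `prefix`, `suffix`, `width`.
#' @export
flank_scheme <- function(prefix = "AA", suffix = "WEEG") {
  stopifnot(is.character(prefix), is.character(suffix))
  list(prefix = prefix, suffix = suffix,
       width = nchar(prefix) + 9L + nchar(suffix))
}

#' Parse raw display-construct reads against invariant flanks
#'
#' A read is accepted only if it is exactly `prefix + 9 canonical residues
#' + suffix`; everything else is rejected with a reason (`wrong_length`,
#' `flank_mismatch`, `noncanonical_core`). Rejection is a value, not an
#' error, so a full sequencing run can be filtered in one pass.
#'
#' @param raw Character vector of raw construct sequences.
#' @param scheme A [flank_scheme()]; default IPFR.
#' @return A data.frame with columns `raw`, `core` (NA when rejected),
#'   `accepted`, `reason` (NA when accepted).
#' @export
parse_construct <- function(raw, scheme = flank_scheme()) {
  stopifnot(is.character(raw))
  raw <- toupper(raw)
  np <- nchar(scheme$prefix)
  ns <- nchar(scheme$suffix)
  core <- rep(NA_character_, length(raw))
  reason <- rep(NA_character_, length(raw))

  len_ok <- nchar(raw) == scheme$width
  reason[!len_ok] <- "wrong_length"

  pre <- substring(raw, 1L, np)
  suf <- substring(raw, np + 10L, scheme$width)
  flank_ok <- len_ok & pre == scheme$prefix & suf == scheme$suffix
  reason[len_ok & !flank_ok] <- "flank_mismatch"

  cand <- substring(raw, np + 1L, np + 9L)
  core_ok <- flank_ok & is_peptide9(cand)
  reason[flank_ok & !core_ok] <- "noncanonical_core"
  core[core_ok] <- cand[core_ok]

  data.frame(raw = raw, core = core, accepted = core_ok, reason = reason,
             stringsAsFactors = FALSE)
}

#' Round-by-round peptide count tables
#'
#' A `count_table` holds the deep-sequencing read counts of each peptide
#' across selection rounds, plus per-round depth constants used by the RSR
#' Poisson model. Depth defaults to the per-round column totals — the
#' observable proxy for the sequencing constant of each round (rounds whose
#' total is zero fall back to 1 so the constant stays positive).
#'
#' @param peptides Character vector of 9-mer cores (unique).
#' @param counts Non-negative integer matrix, one row per peptide, one
#'   column per round.
#' @param round_labels Integer round indices, strictly increasing; default
#'   `0:(R-1)`.
#' @param depth Optional per-round positive constants; default column sums.
#' @return An object of class `count_table` with fields `peptides`,
#'   `counts`, `round_labels`, `depth`.
#' @export
count_table <- function(peptides, counts, round_labels = NULL, depth = NULL) {
  assert_peptide9(peptides)
  counts <- as.matrix(counts)
  if (nrow(counts) != length(peptides))
    stop("counts must have one row per peptide", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  dup <- peptides[duplicated(peptides)]
  if (length(dup))
    stop("duplicate peptide in count table: ", dup[1L], call. = FALSE)
  R <- ncol(counts)
  if (is.null(round_labels)) round_labels <- 0:(R - 1L)
  round_labels <- as.integer(round_labels)
  if (length(round_labels) != R || any(diff(round_labels) <= 0L))
    stop("round_labels must be strictly increasing, one per column",
         call. = FALSE)
  if (is.null(depth)) depth <- pmax(colSums(counts), 1)
  depth <- as.numeric(depth)
  if (length(depth) != R || any(!is.finite(depth)) || any(depth <= 0))
    stop("depth needs one strictly positive entry per round", call. = FALSE)
  dimnames(counts) <- list(peptides, paste0("round_", round_labels))
  structure(list(peptides = peptides, counts = counts,
                 round_labels = round_labels, depth = depth),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(x$peptides), "peptides x",
      length(x$round_labels), "rounds (",
      paste0("round_", range(x$round_labels), collapse = ".."), ")\n")
  cat("depth:", paste(signif(x$depth, 4), collapse = " "), "\n")
  invisible(x)
}

#' Read / write count tables as TSV
#'
#' The TSV has a header `peptide<TAB>round_0<TAB>...` and one row per
#' peptide. An optional leading comment line `#depth:<TAB>a0<TAB>a1...`
#' carries explicit per-round depth constants; [write_count_table()] always
#' emits it, so write-then-read is lossless including depth.
#'
#' @param path TSV file path.
#' @param table A [count_table()].
#' @return `read_count_table`: a [count_table()]. `write_count_table`:
#'   `path`, invisibly.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  depth <- NULL
  skip <- 0L
  if (startsWith(first, "#depth:")) {
    depth <- as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][-1])
    skip <- 1L
  }
  df <- read.delim(path, skip = skip, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(colnames(df)[1], "peptide"))
    stop("count table must start with a 'peptide' column", call. = FALSE)
  round_cols <- colnames(df)[-1]
  if (!all(grepl("^round_[0-9]+$", round_cols)))
    stop("round columns must be named round_0, round_1, ...", call. = FALSE)
  labels <- as.integer(sub("^round_", "", round_cols))
  cnt <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(cnt)) stop("counts must be numeric", call. = FALSE)
  count_table(df$peptide, cnt, round_labels = labels, depth = depth)
}

#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#depth:", format(table$depth, scientific = FALSE,
                                       trim = TRUE)), collapse = "\t"), con)
  df <- data.frame(peptide = table$peptides, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
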