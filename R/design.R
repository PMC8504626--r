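#' Select seed peptides from proteomes by predicted enrichment
#'
#' Scans every canonical 9-mer of the given proteomes, scores each with
#' the per-allele predictors' predictive means, and keeps peptides whose
#' mean meets the per-allele threshold for every allele (a dual-allele
#' criterion is therefore the intersection of the single-allele ones).
#' "Some affinity" and "high affinity" are threshold choices; defaults of
#' 2 and 4 on the LRP scale mirror the early/late round split of the
#' display assay.
#'
#' @param proteomes A data.frame from [read_fasta()] (or rbind of
#'   several).
#' @param models A predictor or named list of per-allele predictors (the
#'   categorical predictor's mean is the usual affinity surrogate).
#' @param min_mean Numeric vector of per-allele thresholds, recycled over
#'   alleles; `-Inf` passes everything.
#' @param n_max Maximum number of seeds returned.
#' @return A data.frame with columns `peptide`, `record`, `offset`
#'   (0-based position of the first occurrence), one `score_<allele>`
#'   column per allele, ordered by total score (descending) then
#'   sequence. Empty, with a warning, when nothing passes.
#' @export
select_seeds <- function(proteomes, models, min_mean = 2, n_max = Inf) {
  stopifnot(is.data.frame(proteomes), nrow(proteomes) >= 1L)
  models <- as_model_list(models)
  min_mean <- rep_len(min_mean, length(models))
  hits <- do.call(rbind, lapply(seq_len(nrow(proteomes)), function(i) {
    w <- scan_9mers(proteomes$sequence[i])
    if (nrow(w)) w$record <- proteomes$id[i]
    w
  }))
  if (is.null(hits) || nrow(hits) == 0L) {
    warning("no canonical 9-mers in the given proteomes")
    return(data.frame(peptide = character(), record = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  }
  hits <- hits[!duplicated(hits$peptide), c("peptide", "record", "offset")]
  scores <- lapply(models, function(m)
    predict_enrichment(m, hits$peptide)$mean)
  keep <- Reduce(`&`, Map(function(sc, thr) sc >= thr, scores, min_mean))
  out <- hits[keep, , drop = FALSE]
  for (a in names(models)) out[[paste0("score_", a)]] <- scores[[a]][keep]
  if (nrow(out) == 0L) {
    warning("no 9-mer meets the seed-selection thresholds")
    return(out)
  }
  total <- rowSums(as.matrix(out[, paste0("score_", names(models)),
                                 drop = FALSE]))
  out <- out[order(-total, out$peptide, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n_max)
}

#' Flank a 9-mer core with invariant peptide flanking residues (IPFR)
#'
#' The display construct takes the form `AA` + core + `WEEG` (15
#' residues), which holds the core in a single binding register.
#'
#' @param core Character vector of 9-mer cores.
#' @return Character vector of 15-residue constructs.
#' @export
flank_ipfr <- function(core) {
  assert_peptide9(core)
  paste0("AA", core, "WEEG")
}

#' Flank a 9-mer with its wild-type peptide flanking residues (WPFR)
#'
#' WPFR are the three proteome residues on each side of the 9-mer at its
#' source location. 9-mers within 3 residues of either terminus, or whose
#' flanks contain non-canonical residues, are rejected (rejection is a
#' value, not an error). A replacement `core` may be supplied to build the
#' WPFR construct of an anchor-substituted candidate in its seed's
#' context.
#'
#' @param sequence Source protein sequence (or a single-row [read_fasta()]
#'   data.frame).
#' @param offset 0-based offset of the seed 9-mer in the protein.
#' @param core Optional 9-mer to place between the flanks (default: the
#'   9-mer found at `offset`).
#' @return A list with `construct` (15-mer or `NA`), `core`, `reason`
#'   (`NA` when accepted).
#' @export
flank_wpfr <- function(sequence, offset, core = NULL) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L)
  offset <- as.integer(offset)
  L <- nchar(sequence)
  if (is.null(core)) core <- substring(sequence, offset + 1L, offset + 9L)
  rejection <- function(reason) list(construct = NA_character_,
                                     core = core, reason = reason)
  if (offset < 3L) return(rejection("insufficient_upstream_context"))
  if (offset + 12L > L) return(rejection("insufficient_downstream_context"))
  if (!is_peptide9(core)) return(rejection("noncanonical_core"))
  up <- substring(sequence, offset - 2L, offset)
  down <- substring(sequence, offset + 10L, offset + 12L)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]{3}$", up) ||
      !grepl("^[ACDEFGHIKLMNPQRSTVWY]{3}$", down))
    return(rejection("noncanonical_flank"))
  list(construct = paste0(up, core, down), core = core,
       reason = NA_character_)
}

#' Assemble a defined display library
#'
#' Combines seeds, their optimized proposals and random controls, and
#' positive/negative control peptides into a deduplicated list of display
#' constructs with full provenance. Under the IPFR scheme every member is
#' `AA`+core+`WEEG`; under WPFR, cores are placed in their seed's proteome
#' context (seeds whose context is unavailable contribute no WPFR
#' members). Identical constructs arising more than once are collapsed to
#' a single member whose provenance records are merged.
#'
#' @param seeds A data.frame with column `peptide`, plus `record` and
#'   `offset` when WPFR is requested (as from [select_seeds()]).
#' @param proposals A proposal data.frame ([propose()] /
#'   [propose_methods()]).
#' @param controls A random-control data.frame ([random_controls()]).
#' @param positives,negatives Optional character vectors of control
#'   peptides sampled from the training data.
#' @param schemes Subset of `c("ipfr", "wpfr")`.
#' @param proteomes [read_fasta()] data.frame, required for WPFR.
#' @return A list with `members` (data.frame: `construct`, `core`,
#'   `scheme`, `group`, `seed`, `method`, `rank`, `provenance`) and
#'   `manifest` (per-group/per-scheme counts, duplicates collapsed,
#'   WPFR rejections).
#' @export
assemble_library <- function(seeds, proposals = NULL, controls = NULL,
                             positives = NULL, negatives = NULL,
                             schemes = "ipfr", proteomes = NULL) {
  schemes <- match.arg(tolower(schemes), c("ipfr", "wpfr"), several.ok = TRUE)
  stopifnot(is.data.frame(seeds), "peptide" %in% names(seeds))
  rows <- list()
  rejections <- list()
  add <- function(core, scheme, group, seed, method, rank, provenance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      construct = NA_character_, core = core, scheme = scheme,
      group = group, seed = seed, method = method, rank = rank,
      provenance = provenance, stringsAsFactors = FALSE)
  }
  wpfr_context <- function(seed_pep) {
    i <- match(seed_pep, seeds$peptide)
    if (is.na(i) || is.null(seeds$record) || is.null(proteomes))
      return(NULL)
    j <- match(seeds$record[i], proteomes$id)
    if (is.na(j)) return(NULL)
    list(sequence = proteomes$sequence[j], offset = seeds$offset[i])
  }
  emit_group <- function(cores, group, seed_of, method, rank, provenance) {
    for (scheme in schemes) {
      if (scheme == "ipfr") {
        for (i in seq_along(cores))
          add(cores[i], "ipfr", group, seed_of[i], method[i], rank[i],
              provenance[i])
      } else {
        for (i in seq_along(cores)) {
          ctx <- wpfr_context(seed_of[i])
          if (is.null(ctx)) next
          w <- flank_wpfr(ctx$sequence, ctx$offset, core = cores[i])
          if (is.na(w$construct)) {
            rejections[[length(rejections) + 1L]] <<- data.frame(
              core = cores[i], seed = seed_of[i], reason = w$reason,
              stringsAsFactors = FALSE)
            next
          }
          add(cores[i], "wpfr", group, seed_of[i], method[i], rank[i],
              provenance[i])
        }
      }
    }
  }
  emit_group(seeds$peptide, "seed", seeds$peptide,
             rep("seed", nrow(seeds)), rep(NA_integer_, nrow(seeds)),
             paste0("seed:", seeds$peptide))
  if (!is.null(proposals) && nrow(proposals)) {
    method <- paste(proposals$head_type, proposals$objective, sep = "/")
    emit_group(proposals$candidate, "optimized", proposals$seed, method,
               proposals$rank,
               paste0(method, ":", proposals$seed, ">", proposals$candidate))
  }
  if (!is.null(controls) && nrow(controls)) {
    emit_group(controls$candidate, "random_control", controls$seed,
               rep("random", nrow(controls)), controls$rank,
               paste0("random:", controls$seed, ">", controls$candidate))
  }
  for (grp in c("positive_control", "negative_control")) {
    peps <- if (grp == "positive_control") positives else negatives
    if (is.null(peps) || !length(peps)) next
    assert_peptide9(peps)
    # controls come from the training library, which is IPFR by design
    for (p in peps)
      add(p, "ipfr", grp, NA_character_, grp, NA_integer_,
          paste0(grp, ":", p))
  }
  members <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  members$construct <- ifelse(members$scheme == "ipfr",
                              flank_ipfr(members$core),
                              members$construct)
  # WPFR constructs were validated above; rebuild them here
  wp <- which(members$scheme == "wpfr")
  for (i in wp) {
    ctx <- wpfr_context(members$seed[i])
    members$construct[i] <- flank_wpfr(ctx$sequence, ctx$offset,
                                       core = members$core[i])$construct
  }
  dup <- duplicated(members$construct)
  n_collapsed <- sum(dup)
  if (n_collapsed) {
    merged <- tapply(members$provenance, members$construct,
                     paste, collapse = ";")
    members <- members[!dup, , drop = FALSE]
    members$provenance <- unname(merged[members$construct])
  }
  rownames(members) <- NULL
  manifest <- list(
    n_members = nrow(members),
    per_group = as.list(table(members$group)),
    per_scheme = as.list(table(members$scheme)),
    duplicates_collapsed = n_collapsed,
    wpfr_rejections = if (length(rejections))
      do.call(rbind, rejections) else NULL)
  list(members = members, manifest = manifest)
}

#' Sample positive and negative control peptides from training data
#'
#' Positives are drawn from the peptides that performed best in the
#' training selection (highest LRP stratum), negatives from the worst
#' (lowest stratum).
#'
#' @param training A data.frame with columns `peptide` and `lrp`.
#' @param n_pos,n_neg Numbers of controls.
#' @param rng_seed RNG seed.
#' @return List with character vectors `positives` and `negatives`.
#' @export
sample_controls <- function(training, n_pos = 10L, n_neg = 10L,
                            rng_seed = 1L) {
  stopifnot(all(c("peptide", "lrp") %in% names(training)))
  ord <- order(training$lrp, training$peptide, method = "radix")
  lo <- training$peptide[ord]
  hi <- rev(lo)
  with_seed(rng_seed, list(
    positives = sample(head(hi, max(n_pos * 3L, n_pos)), n_pos),
    negatives = sample(head(lo, max(n_neg * 3L, n_neg)), n_neg)))
}
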