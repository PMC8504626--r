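#' Mann-Whitney U comparison of two RSR groups
#'
#' Rank-based two-sample comparison of labelled RSR samples. The exact
#' null distribution is used when the smaller group has at most 8
#' observations and the pooled values are tie-free; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' When every pooled value is identical the test is vacuous and p = 1 is
#' returned (the tie-corrected variance is zero).
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   stated for `group_a`.
#' @return An object of class `pep_groupcomp`: list with `u_statistic`
#'   (U of `group_a`), `p_value`, `n_a`, `n_b`, `method`, `alternative`.
#' @export
mannwhitney <- function(group_a, group_b,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(group_a) || anyNA(group_b))
    stop("groups must not contain NA", call. = FALSE)
  pooled <- c(group_a, group_b)
  ties <- anyDuplicated(pooled) > 0L
  u <- sum(rank(pooled)[seq_along(group_a)]) -
    length(group_a) * (length(group_a) + 1) / 2
  if (length(unique(pooled)) == 1L) {
    p <- 1
    method <- "degenerate (all values tied)"
  } else {
    exact <- min(length(group_a), length(group_b)) <= 8L && !ties
    wt <- suppressWarnings(
      wilcox.test(group_a, group_b, alternative = alternative,
                  exact = exact, correct = TRUE))
    p <- wt$p.value
    method <- if (exact) "exact" else "normal approximation, tie-corrected"
  }
  structure(list(u_statistic = u, p_value = p,
                 n_a = length(group_a), n_b = length(group_b),
                 method = method, alternative = alternative),
            class = "pep_groupcomp")
}

#' @export
print.pep_groupcomp <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d vs %d), %s p = %.4g [%s]\n",
              x$u_statistic, x$n_a, x$n_b, x$alternative, x$p_value,
              x$method))
  invisible(x)
}

#' Optimization success rate of one seed
#'
#' The fraction of a seed's proposals whose measured RSR is strictly
#' higher than the seed's own RSR. Proposals with undefined RSR (absent
#' from the validation assay) count as not-better rather than being
#' dropped.
#'
#' @param seed_rsr The seed's RSR (finite).
#' @param proposal_rsrs RSR values of the proposals (NA = undefined).
#' @return List with `n_proposals`, `n_better`, `n_undefined`, `rate`.
#' @export
success_rate <- function(seed_rsr, proposal_rsrs) {
  if (length(seed_rsr) != 1L || is.na(seed_rsr))
    stop("seed RSR is undefined", call. = FALSE)
  if (!length(proposal_rsrs))
    stop("need at least one proposal", call. = FALSE)
  better <- !is.na(proposal_rsrs) & proposal_rsrs > seed_rsr
  list(n_proposals = length(proposal_rsrs), n_better = sum(better),
       n_undefined = sum(is.na(proposal_rsrs)),
       rate = mean(better))
}

#' Dual-allele optimization success criteria
#'
#' For a seed optimized for two alleles simultaneously, three nested
#' criteria over its proposals: (i) every proposal has a higher RSR than
#' the seed on allele A; (ii) additionally every proposal retains at
#' least `retain_frac` of the seed's RSR on allele B; (iii) every
#' proposal is strictly better than the seed on both alleles. The relaxed
#' variant requires each criterion of at least `relaxed_min` proposals
#' instead of all of them. Retention at exactly `retain_frac` counts as
#' retained; undefined proposal RSRs fail every criterion.
#'
#' @param seed_rsr_a,seed_rsr_b Seed RSR on alleles A and B.
#' @param prop_rsr_a,prop_rsr_b Proposal RSRs on alleles A and B (equal
#'   length).
#' @param retain_frac Retention fraction for criterion (ii).
#' @param relaxed_min Minimum count for the relaxed flags.
#' @return List with logical vectors `strict` and `relaxed`, each named
#'   `better_a` / `better_a_retain_b` / `better_both`, and `n`.
#' @export
dual_success <- function(seed_rsr_a, seed_rsr_b, prop_rsr_a, prop_rsr_b,
                         retain_frac = 0.8, relaxed_min = 8L) {
  if (length(prop_rsr_a) != length(prop_rsr_b))
    stop("per-allele proposal RSRs must have equal length", call. = FALSE)
  if (is.na(seed_rsr_a) || is.na(seed_rsr_b))
    stop("seed RSR is undefined", call. = FALSE)
  ok_a <- !is.na(prop_rsr_a) & prop_rsr_a > seed_rsr_a
  keep_b <- !is.na(prop_rsr_b) & prop_rsr_b >= retain_frac * seed_rsr_b
  ok_b <- !is.na(prop_rsr_b) & prop_rsr_b > seed_rsr_b
  counts <- c(better_a = sum(ok_a),
              better_a_retain_b = sum(ok_a & keep_b),
              better_both = sum(ok_a & ok_b))
  list(strict = counts == length(prop_rsr_a),
       relaxed = counts >= relaxed_min,
       n = length(prop_rsr_a))
}

#' Extract conditional RSR samples by residue context
#'
#' Builds labelled RSR samples for peptides matching each residue
#' condition set, e.g. all peptides, `{P7 = T}`, `{P7 = T, P6 = D}`.
#' Conditions within one set are conjunctive, so adding a condition
#' always selects a subset. The returned samples feed directly into
#' [mannwhitney()].
#'
#' @param peptides Character vector of 9-mer cores.
#' @param rsr Numeric RSR values aligned with `peptides`.
#' @param conditions Named list; each element a named character vector of
#'   `P<pos> = residue` constraints (e.g. `c(P7 = "T", P6 = "D")`), or
#'   `NULL` for the unconditional sample.
#' @return Named list of numeric RSR samples; empty selections warn and
#'   yield length-0 samples.
#' @export
conditional_groups <- function(peptides, rsr, conditions) {
  stopifnot(length(peptides) == length(rsr), is.list(conditions))
  m <- peptide_matrix(peptides)
  out <- lapply(conditions, function(cond) {
    keep <- rep(TRUE, length(peptides))
    for (nm in names(cond)) {
      pos <- as.integer(sub("^P", "", nm))
      stopifnot(pos >= 1L, pos <= 9L)
      keep <- keep & m[, pos] == cond[[nm]]
    }
    rsr[keep]
  })
  empty <- vapply(out, length, integer(1)) == 0L
  if (any(empty))
    warning("empty selection for condition(s): ",
            paste(names(conditions)[empty], collapse = ", "))
  out
}

#' Per-seed candidate overlap between optimization methods
#'
#' For every pair of methods and every shared seed, the number of
#' candidate peptides the two methods both proposed, plus a per-pair
#' count of seeds with zero overlap.
#'
#' @param proposals A proposal data.frame with columns `seed`,
#'   `candidate` and a method identifier column (`method`, or
#'   `head_type`/`objective`, which are combined).
#' @return List with `overlap` (data.frame: `method_a`, `method_b`,
#'   `seed`, `overlap`) and `zero_overlap` (data.frame: `method_a`,
#'   `method_b`, `n_seeds_zero_overlap`).
#' @export
method_overlap <- function(proposals) {
  stopifnot(all(c("seed", "candidate") %in% names(proposals)))
  if (is.null(proposals$method))
    proposals$method <- paste(proposals$head_type, proposals$objective,
                              sep = "/")
  methods <- sort(unique(proposals$method))
  if (length(methods) < 2L)
    stop("need proposals from at least 2 methods", call. = FALSE)
  seed_sets <- lapply(methods, function(m)
    unique(proposals$seed[proposals$method == m]))
  shared <- Reduce(intersect, seed_sets)
  if (!length(shared))
    stop("methods share no seed sequences", call. = FALSE)
  pairs <- combn(methods, 2L)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    ma <- pairs[1L, j]; mb <- pairs[2L, j]
    for (s in shared) {
      ca <- proposals$candidate[proposals$method == ma & proposals$seed == s]
      cb <- proposals$candidate[proposals$method == mb & proposals$seed == s]
      rows[[length(rows) + 1L]] <- data.frame(
        method_a = ma, method_b = mb, seed = s,
        overlap = length(intersect(ca, cb)), stringsAsFactors = FALSE)
    }
  }
  overlap <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  zero <- stats::aggregate(overlap ~ method_a + method_b, data = overlap,
                           FUN = function(v) sum(v == 0L))
  names(zero)[3] <- "n_seeds_zero_overlap"
  list(overlap = overlap, zero_overlap = zero)
}

#' Position-frequency motif matrix of a peptide set
#'
#' Residue frequencies per core position (a 20 x 9 matrix, residues in
#' [AA_ALPHABET] order, columns P1..P9 each summing to 1) — the matrix
#' behind a sequence logo — plus the modal anchor set: the most frequent
#' (P1, P4, P6, P9) residue combination, ties broken lexicographically.
#'
#' @param peptides Non-empty character vector of 9-mer cores.
#' @return List with `matrix` (20 x 9), `anchor_set` (named residues),
#'   `anchor_count`, `anchor_tally` (data.frame of all anchor sets).
#' @export
motif_matrix <- function(peptides) {
  if (!length(peptides)) stop("empty peptide set", call. = FALSE)
  assert_peptide9(peptides)
  m <- peptide_matrix(peptides)
  freq <- vapply(1:9, function(p)
    tabulate(aa_index(m[, p]), nbins = 20L), integer(20L))
  freq <- freq / length(peptides)
  dimnames(freq) <- list(AA_ALPHABET, paste0("P", 1:9))
  anchors <- apply(m[, anchor_positions(), drop = FALSE], 1, paste0,
                   collapse = "")
  tal <- sort(table(anchors), decreasing = TRUE)
  top <- names(tal)[tal == max(tal)]
  modal <- sort(top)[1L]
  tally <- data.frame(anchor_set = names(tal), count = as.integer(tal),
                      stringsAsFactors = FALSE)
  list(matrix = freq,
       anchor_set = setNames(strsplit(modal, "")[[1]],
                             paste0("P", anchor_positions())),
       anchor_count = as.integer(max(tal)),
       anchor_tally = tally)
}
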