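#' Enumerate the complete anchor-substitution landscape of a seed
#'
#' Every peptide obtained by substituting the four anchor positions (P1,
#' P4, P6, P9) with any of the 20 canonical residues, excluding the seed
#' itself: exactly 20^4 - 1 = 159,999 candidates, in deterministic
#' lexicographic order. The five non-anchor positions are untouched —
#' exhaustive enumeration of this small space is what makes anchor
#' optimization tractable without any search heuristic.
#'
#' @param seed A 9-mer core peptide.
#' @return Character vector of 159,999 candidate peptides.
#' @export
enumerate_anchor_variants <- function(seed) {
  assert_peptide9(seed)
  stopifnot(length(seed) == 1L)
  ch <- strsplit(seed, "", fixed = TRUE)[[1]]
  # expand.grid varies its first factor fastest; order P9, P6, P4, P1 so
  # the assembled strings come out in lexicographic order.
  g <- expand.grid(p9 = AA_ALPHABET, p6 = AA_ALPHABET, p4 = AA_ALPHABET,
                   p1 = AA_ALPHABET, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  cand <- paste0(g$p1, ch[2], ch[3], g$p4, ch[5], g$p6, ch[7], ch[8], g$p9)
  cand[cand != seed]
}

#' Acquisition objectives over predictive distributions
#'
#' The point estimate (PE) objective is the predicted enrichment mean; the
#' upper confidence bound (UCB) adds the predictive standard deviation to
#' the mean, rewarding candidates the model is uncertain about.
#'
#' @param dist A `pep_prediction` (or any list with `mean` and `std`).
#' @param objective `"pe"` or `"ucb"`.
#' @return Numeric vector of objective values.
#' @export
acquisition <- function(dist, objective = c("pe", "ucb")) {
  objective <- match.arg(tolower(objective), c("pe", "ucb"))
  stopifnot(!is.null(dist$mean), !is.null(dist$std),
            all(dist$std >= 0))
  if (objective == "pe") dist$mean else dist$mean + dist$std
}

#' Combined multi-allele objective
#'
#' For multi-allele optimization the acquisition objective is computed for
#' each allele individually and the values are added.
#'
#' @param dists List of per-allele `pep_prediction`s (same peptides).
#' @inheritParams acquisition
#' @return Numeric vector of combined objective values.
#' @export
combined_objective <- function(dists, objective = c("pe", "ucb")) {
  if (length(dists) == 0L) stop("need at least one allele", call. = FALSE)
  objective <- match.arg(tolower(objective), c("pe", "ucb"))
  Reduce(`+`, lapply(dists, acquisition, objective = objective))
}

# Normalize the `models` argument: a single predictor or a (possibly
# named) list of per-allele predictors.
as_model_list <- function(models) {
  if (inherits(models, "pep_ensemble") || inherits(models, "pep_oracle"))
    models <- list(models)
  stopifnot(length(models) >= 1L)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- paste0("allele", seq_along(models))
  models
}

model_head_label <- function(models) {
  heads <- unique(vapply(models, function(m) m$head_type, character(1)))
  paste(heads, collapse = "+")
}

# Score every anchor variant of `seed` under each model, in batches.
# Returns list(candidates, per-model list of (mean, std) vectors).
score_variants <- function(seed, models, batch_size = 4096L) {
  cand <- enumerate_anchor_variants(seed)
  n <- length(cand)
  scores <- lapply(models, function(m)
    list(mean = numeric(n), std = numeric(n)))
  starts <- seq(1L, n, by = batch_size)
  for (s0 in starts) {
    idx <- s0:min(s0 + batch_size - 1L, n)
    X <- NULL
    for (j in seq_along(models)) {
      m <- models[[j]]
      if (inherits(m, "pep_ensemble")) {
        if (is.null(X)) X <- encode_batch(cand[idx])
        d <- predict_encoded(m, X)
      } else {
        d <- predict_enrichment(m, cand[idx])
      }
      scores[[j]]$mean[idx] <- d$mean
      scores[[j]]$std[idx] <- d$std
    }
  }
  list(candidates = cand, scores = scores)
}

proposal_frame <- function(seed, cand, objective_value, objective,
                           head_type, alleles) {
  anch <- peptide_matrix(cand)[, anchor_positions(), drop = FALSE]
  data.frame(seed = seed, candidate = cand,
             P1 = anch[, 1], P4 = anch[, 2], P6 = anch[, 3], P9 = anch[, 4],
             objective = objective, objective_value = objective_value,
             head_type = head_type,
             alleles = paste(alleles, collapse = ","),
             rank = seq_along(cand), stringsAsFactors = FALSE)
}

#' Propose optimized anchor substitutions for a seed peptide
#'
#' Scores all 159,999 anchor variants of `seed` under the acquisition
#' objective (summed over alleles when several models are given) and
#' returns the k highest, ties broken by lexicographic candidate order.
#'
#' @param seed A 9-mer core peptide.
#' @param models A predictor ([train_ensemble()] model or
#'   [oracle_predictor()]), or a named list of per-allele predictors.
#' @param objective `"pe"` or `"ucb"`.
#' @param k Number of proposals (default 10).
#' @param batch_size Scoring batch size.
#' @return A data.frame of proposals: `seed`, `candidate`, anchor residues
#'   `P1`/`P4`/`P6`/`P9`, `objective`, `objective_value`, `head_type`,
#'   `alleles`, `rank`.
#' @export
propose <- function(seed, models, objective = c("pe", "ucb"), k = 10L,
                    batch_size = 4096L) {
  objective <- match.arg(tolower(objective), c("pe", "ucb"))
  models <- as_model_list(models)
  if (k < 1L || k > 159999L)
    stop("k must be between 1 and 159999", call. = FALSE)
  sv <- score_variants(seed, models, batch_size)
  obj <- combined_objective(sv$scores, objective)
  ord <- order(-obj, sv$candidates, method = "radix")[seq_len(k)]
  proposal_frame(seed, sv$candidates[ord], obj[ord], objective,
                 model_head_label(models), names(models))
}

#' Run all four method combinations for one seed
#'
#' PE and UCB objectives under the Gaussian-head and categorical-head
#' models: 4 method combinations x top-k, i.e. 40 proposals per seed at
#' the default k = 10. Duplicate candidates proposed by several methods
#' are kept as separate records (overlap between methods is itself an
#' analysis output). Each variant set is scored once per head and reused
#' for both objectives.
#'
#' @param seed A 9-mer core peptide.
#' @param models_by_head Named list `list(gaussian = ..., categorical =
#'   ...)`; each element a predictor or per-allele list of predictors.
#' @param k Proposals per method.
#' @param batch_size Scoring batch size.
#' @return A data.frame of `length(models_by_head) * 2 * k` proposals.
#' @export
propose_methods <- function(seed, models_by_head, k = 10L,
                            batch_size = 4096L) {
  stopifnot(is.list(models_by_head), length(models_by_head) >= 1L,
            !is.null(names(models_by_head)))
  if (k < 1L || k > 159999L)
    stop("k must be between 1 and 159999", call. = FALSE)
  out <- list()
  for (head in names(models_by_head)) {
    models <- as_model_list(models_by_head[[head]])
    sv <- score_variants(seed, models, batch_size)
    for (objective in c("pe", "ucb")) {
      obj <- combined_objective(sv$scores, objective)
      ord <- order(-obj, sv$candidates, method = "radix")[seq_len(k)]
      out[[paste(head, objective)]] <-
        proposal_frame(seed, sv$candidates[ord], obj[ord], objective,
                       head, names(models))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Random anchor-substitution controls
#'
#' Draws m distinct anchor substitutions uniformly from the 159,999
#' variants, without replacement; the matched negative control for
#' [propose()].
#'
#' @param seed A 9-mer core peptide.
#' @param m Number of controls (default 10).
#' @param rng_seed RNG seed; same seed reproduces the same controls.
#' @return A proposal data.frame with `objective = "random"` and
#'   `objective_value = NA`.
#' @export
random_controls <- function(seed, m = 10L, rng_seed = 1L) {
  assert_peptide9(seed)
  if (m < 1L || m > 159999L)
    stop("m must be between 1 and 159999", call. = FALSE)
  ch <- strsplit(seed, "", fixed = TRUE)[[1]]
  seed_idx <- sum((aa_index(ch[anchor_positions()]) - 1L) *
                    c(8000L, 400L, 20L, 1L)) + 1L
  pick <- with_seed(rng_seed, sample.int(159999L, m))
  pick <- pick + (pick >= seed_idx)      # skip the seed's own anchor tuple
  i0 <- pick - 1L
  a1 <- AA_ALPHABET[i0 %/% 8000L + 1L]
  a4 <- AA_ALPHABET[(i0 %/% 400L) %% 20L + 1L]
  a6 <- AA_ALPHABET[(i0 %/% 20L) %% 20L + 1L]
  a9 <- AA_ALPHABET[i0 %% 20L + 1L]
  cand <- paste0(a1, ch[2], ch[3], a4, ch[5], a6, ch[7], ch[8], a9)
  proposal_frame(seed, cand, NA_real_, "random", "none", "none")
}
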