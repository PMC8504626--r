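#' Construct a synthetic affinity landscape
#'
#' The ground-truth affinity of a 9-mer core is additive: a 9 x 20
#' position-weight term per residue plus sparse pairwise couplings between
#' an anchor position and a non-anchor position. The couplings give the
#' landscape the epistasis seen in real selection data, where the residue
#' context outside the anchors changes which anchor residues help: the
#' default landscape contains a sign-flipping pair, `(P6 = D, P7 = T) ->
#' +flip_magnitude` and `(P6 = D, P7 = D) -> -flip_magnitude`, so aspartic
#' acid at anchor P6 helps in a P7-threonine context and hurts in a
#' P7-aspartate context. The raw score maps to a per-round survival
#' probability through a logistic link, `p = plogis(scale * score +
#' offset)`, which is strictly inside (0, 1).
#'
#' @param pwm_sd SD of the i.i.d. normal position-weight terms.
#' @param n_couplings Number of random anchor x non-anchor couplings (in
#'   addition to the fixed sign-flipping pair).
#' @param coupling_sd SD of the random coupling magnitudes.
#' @param flip_magnitude Magnitude of the fixed P6=D x P7=T/D pair.
#' @param scale,offset Logistic link parameters.
#' @param rng_seed RNG seed; the same seed reproduces the same landscape.
#' @return An object of class `pep_landscape`.
#' @export
make_landscape <- function(pwm_sd = 0.5, n_couplings = 20L,
                           coupling_sd = 1.0, flip_magnitude = 2.0,
                           scale = 1.0, offset = -3.0, rng_seed = 1L) {
  with_seed(rng_seed, {
    pwm <- matrix(rnorm(180L, sd = pwm_sd), 9L, 20L,
                  dimnames = list(paste0("P", 1:9), AA_ALPHABET))
    couplings <- data.frame(pos_i = integer(), res_i = character(),
                            pos_j = integer(), res_j = character(),
                            value = numeric(), stringsAsFactors = FALSE)
    if (flip_magnitude != 0) {
      couplings <- data.frame(
        pos_i = c(6L, 6L), res_i = c("D", "D"),
        pos_j = c(7L, 7L), res_j = c("T", "D"),
        value = c(flip_magnitude, -flip_magnitude),
        stringsAsFactors = FALSE)
    }
    if (n_couplings > 0L) {
      rnd <- data.frame(
        pos_i = sample(anchor_positions(), n_couplings, replace = TRUE),
        res_i = sample(AA_ALPHABET, n_couplings, replace = TRUE),
        pos_j = sample(nonanchor_positions(), n_couplings, replace = TRUE),
        res_j = sample(AA_ALPHABET, n_couplings, replace = TRUE),
        value = rnorm(n_couplings, sd = coupling_sd),
        stringsAsFactors = FALSE)
      key <- function(d) paste(d$pos_i, d$res_i, d$pos_j, d$res_j)
      rnd <- rnd[!duplicated(key(rnd)) & !(key(rnd) %in% key(couplings)), ]
      couplings <- rbind(couplings, rnd)
    }
    structure(list(pwm = pwm, couplings = couplings, scale = scale,
                   offset = offset, rng_seed = rng_seed),
              class = "pep_landscape")
  })
}

#' @export
print.pep_landscape <- function(x, ...) {
  cat(sprintf("pep_landscape: 9x20 PWM (sd of terms %.3g), %d couplings, link plogis(%.3g*score %+.3g)\n",
              stats::sd(x$pwm), nrow(x$couplings), x$scale, x$offset))
  invisible(x)
}

#' Score peptides against a synthetic landscape
#'
#' `landscape_score` is the deterministic additive score (PWM terms plus
#' applicable couplings); `survival_prob` maps it through the logistic
#' link to per-round survival probabilities in (0, 1).
#'
#' @param landscape A `pep_landscape`.
#' @param peptides Character vector of 9-mer cores.
#' @return Numeric vector, one value per peptide.
#' @export
landscape_score <- function(landscape, peptides) {
  assert_peptide9(peptides)
  m <- peptide_matrix(peptides)
  idx <- aa_index(m)
  dim(idx) <- dim(m)
  sc <- numeric(length(peptides))
  for (p in 1:9) sc <- sc + landscape$pwm[p, ][idx[, p]]
  cp <- landscape$couplings
  for (i in seq_len(nrow(cp))) {
    hit <- m[, cp$pos_i[i]] == cp$res_i[i] & m[, cp$pos_j[i]] == cp$res_j[i]
    sc[hit] <- sc[hit] + cp$value[i]
  }
  unname(sc)
}

#' @rdname landscape_score
#' @export
survival_prob <- function(landscape, peptides) {
  stats::plogis(landscape$scale * landscape_score(landscape, peptides) +
                  landscape$offset)
}

#' Simulate a multi-round display selection
#'
#' Peptide concentrations follow a geometric progression, `c_{r+1} = c_r *
#' p(peptide)`, starting from a uniform initial library. Each round is
#' sequenced to a fixed expected depth: round-r counts are drawn as
#' `Poisson(depth_r * c_r / sum(c_r))` — the competitive normalization by
#' the total concentration models sequencing a fixed number of reads from
#' whatever population is left.
#'
#' @param peptides Character vector of distinct 9-mer cores.
#' @param landscape A `pep_landscape`.
#' @param R Number of sequenced rounds (labels `0..R-1`), `R >= 2`.
#' @param depth_per_round Expected reads per round (scalar or length R).
#' @param rng_seed RNG seed.
#' @return An object of class `pep_assay`: list with `table` (a
#'   [count_table()]), `truth` (named per-peptide survival probability)
#'   and `config`.
#' @export
simulate_selection <- function(peptides, landscape, R = 4L,
                               depth_per_round = 1e5, rng_seed = 1L) {
  assert_peptide9(peptides)
  if (length(peptides) == 0L) stop("empty peptide list", call. = FALSE)
  if (anyDuplicated(peptides))
    stop("peptides must be distinct", call. = FALSE)
  stopifnot(R >= 2L)
  depth <- rep_len(as.numeric(depth_per_round), R)
  stopifnot(all(depth > 0))
  p <- survival_prob(landscape, peptides)
  n <- length(peptides)
  counts <- matrix(0L, n, R)
  with_seed(rng_seed, {
    conc <- rep(1 / n, n)
    for (r in seq_len(R)) {
      mu <- depth[r] * conc / sum(conc)
      counts[, r] <- rpois(n, mu)
      conc <- conc * p
    }
  })
  tab <- count_table(peptides, counts)
  structure(list(table = tab, truth = setNames(p, peptides),
                 config = list(R = R, depth_per_round = depth,
                               rng_seed = rng_seed)),
            class = "pep_assay")
}

#' Generate a labelled training set from a simulated selection
#'
#' Draws n distinct uniform-random 9-mers, runs them through
#' [simulate_selection()], and labels each with its last round of
#' presence; peptides never observed in any round get label 0.
#'
#' @param landscape A `pep_landscape`.
#' @param n Number of random 9-mers.
#' @param R,depth_per_round Selection parameters (see
#'   [simulate_selection()]).
#' @param rng_seed RNG seed (peptide draw and assay).
#' @return A data.frame with columns `peptide`, `lrp`, `true_p`.
#' @export
make_training_set <- function(landscape, n = 1000L, R = 4L,
                              depth_per_round = 1e5, rng_seed = 1L) {
  stopifnot(n >= 1L)
  peptides <- with_seed(rng_seed, random_peptides(n))
  assay <- simulate_selection(peptides, landscape, R = R,
                              depth_per_round = depth_per_round,
                              rng_seed = rng_seed + 1L)
  lrp <- integer(n)
  for (i in seq_len(n)) {
    cnt <- assay$table$counts[i, ]
    lrp[i] <- if (sum(cnt) < 1) 0L else lrp_label(cnt,
                                                  assay$table$round_labels)
  }
  data.frame(peptide = peptides, lrp = lrp,
             true_p = unname(assay$truth), stringsAsFactors = FALSE)
}

#' Draw distinct uniform-random 9-mer peptides
#'
#' Samples n distinct 9-mers uniformly over the canonical alphabet — the
#' synthetic analogue of a randomized display library. Consumes the
#' current RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param n Number of peptides.
#' @return Character vector of n distinct 9-mers.
#' @export
random_peptides <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    need <- (n - length(out)) + ceiling(n * 0.05) + 1L
    draw <- matrix(sample(AA_ALPHABET, 9L * need, replace = TRUE),
                   ncol = 9L)
    out <- unique(c(out, apply(draw, 1, paste0, collapse = "")))
  }
  out[seq_len(n)]
}
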