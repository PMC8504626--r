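#' Round survival rate (RSR) estimation
#'
#' The selection assay is modelled as a geometric progression of peptide
#' concentration: a peptide entering round r at concentration `c0 * s^r`
#' contributes reads `n_r ~ Poisson(alpha_r * c0 * s^r)`, where `alpha_r`
#' is a per-round constant reflecting how deeply the round's population was
#' sequenced. The common ratio `s` is the (unnormalized) round survival
#' rate: the proportion of the peptide surviving one round of selection,
#' up to a global constant shared by all peptides in a run.
#'
#' The log-likelihood is
#' `sum_r n_r*log(alpha_r*c0*s^r) - alpha_r*c0*s^r`.
#' For fixed `s` the optimal scale is available in closed form,
#' `c0(s) = sum(n_r) / sum(alpha_r*s^r)`, so the fit reduces to a bounded
#' 1-D search over `log s` of the profile log-likelihood.
#'
#' A profile whose reads fall in a single round (including all of them in
#' the first or last round) pushes `s` to a bound; the fit then reports the
#' boundary value with `converged = FALSE`. An all-zero profile has no
#' defined RSR and is an error here (and a flagged row in [rsr_table()]).
#'
#' @param counts Non-negative integer read counts, one per round (>= 2
#'   rounds).
#' @param depth Per-round positive constants `alpha_r`; default all 1.
#' @param rounds Optional round indices r (default `0:(R-1)`); the
#'   geometric exponent. Non-contiguous windows are allowed.
#' @param bounds Positive search interval for `s`.
#' @param tol Relative tolerance of the 1-D search (on `log s`).
#' @return An object of class `rsr_fit`: list with `s`, `c0`, `loglik`,
#'   `converged`.
#' @examples
#' fit_rsr(c(100, 50, 25))            # exactly geometric: s = 0.5
#' fit_rsr(c(100, 100, 100), depth = c(1, 2, 4))  # depth-rescaled: s = 0.5
#' @export
fit_rsr <- function(counts, depth = NULL, rounds = NULL,
                    bounds = c(1e-6, 1e6), tol = 1e-8) {
  prof <- validate_profile(counts, depth, rounds)
  stopifnot(length(bounds) == 2L, all(bounds > 0), bounds[1] < bounds[2])
  ll <- profile_loglik_fn(prof)
  opt <- stats::optimize(ll, interval = log(bounds), maximum = TRUE,
                         tol = tol)
  u <- opt$maximum
  # optimize() never lands exactly on an endpoint; snap near-boundary
  # solutions to the bound and flag them.
  span <- diff(log(bounds))
  at_lo <- (u - log(bounds[1])) < max(1e-4 * span, 10 * tol)
  at_hi <- (log(bounds[2]) - u) < max(1e-4 * span, 10 * tol)
  converged <- !(at_lo || at_hi)
  s <- if (at_lo) bounds[1] else if (at_hi) bounds[2] else exp(u)
  make_rsr_fit(prof, s, converged)
}

#' Exhaustive grid oracle for the RSR fit
#'
#' Evaluates the profile log-likelihood on an explicit grid of `s` values
#' and returns the argmax. Intended as an independent reference for
#' [fit_rsr()] in tests; it shares only the likelihood definition, not the
#' optimizer.
#'
#' @inheritParams fit_rsr
#' @param grid Strictly positive vector of candidate `s` values.
#' @return An `rsr_fit`; `converged` is `FALSE` when the argmax sits on
#'   either end of the grid.
#' @export
rsr_grid_oracle <- function(counts, depth = NULL, rounds = NULL, grid) {
  prof <- validate_profile(counts, depth, rounds)
  stopifnot(length(grid) >= 1L, all(grid > 0))
  ll <- profile_loglik_fn(prof)
  vals <- ll(log(grid))
  i <- which.max(vals)
  converged <- length(grid) > 1L && i > 1L && i < length(grid)
  make_rsr_fit(prof, grid[i], converged)
}

# --- internals -------------------------------------------------------------

validate_profile <- function(counts, depth, rounds) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    stop("RSR needs at least 2 rounds of counts", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("RSR undefined: peptide has zero reads in every round",
         call. = FALSE)
  if (is.null(depth)) depth <- rep(1, length(counts))
  depth <- as.numeric(depth)
  if (length(depth) != length(counts) || any(depth <= 0))
    stop("depth needs one positive entry per round", call. = FALSE)
  if (is.null(rounds)) rounds <- seq_along(counts) - 1
  rounds <- as.numeric(rounds)
  stopifnot(length(rounds) == length(counts), !is.unsorted(rounds,
                                                           strictly = TRUE))
  list(n = counts, alpha = depth, r = rounds)
}

# Profile log-likelihood over u = log(s), vectorized in u:
#   ll(u) = sum(n*log(alpha)) + N*log(N/D(u)) - N + M*u
# with N = sum(n), M = sum(r*n), D(u) = sum(alpha*exp(r*u)).
profile_loglik_fn <- function(prof) {
  N <- sum(prof$n)
  M <- sum(prof$r * prof$n)
  const <- sum(prof$n * log(prof$alpha)) + N * log(N) - N -
    sum(lgamma(prof$n + 1))
  function(u) {
    D <- colSums(exp(outer(prof$r, u)) * prof$alpha)
    const - N * log(D) + M * u
  }
}

make_rsr_fit <- function(prof, s, converged) {
  c0 <- sum(prof$n) / sum(prof$alpha * s^prof$r)
  mu <- prof$alpha * c0 * s^prof$r
  loglik <- sum(prof$n * log(mu) - mu - lgamma(prof$n + 1))
  structure(list(s = s, c0 = c0, loglik = loglik, converged = converged),
            class = "rsr_fit")
}

#' @export
print.rsr_fit <- function(x, ...) {
  cat(sprintf("rsr_fit: s = %.6g, c0 = %.6g, loglik = %.4f, converged = %s\n",
              x$s, x$c0, x$loglik, x$converged))
  invisible(x)
}

#' Last round of presence (LRP)
#'
#' The training label of the enrichment predictor: the largest round index
#' in which the peptide was observed at least once.
#'
#' @param counts Non-negative integer counts per round.
#' @param rounds Round labels (default `0:(R-1)`).
#' @return Integer round label.
#' @export
lrp_label <- function(counts, rounds = NULL) {
  counts <- as.numeric(counts)
  if (is.null(rounds)) rounds <- seq_along(counts) - 1L
  stopifnot(length(rounds) == length(counts))
  seen <- which(counts > 0)
  if (!length(seen))
    stop("LRP undefined: peptide never observed", call. = FALSE)
  as.integer(rounds[max(seen)])
}

#' Fit RSR for every peptide of a count table
#'
#' Applies [fit_rsr()] row-wise. Peptides with zero total reads have no
#' defined RSR and are flagged (`defined = FALSE`, `s = NA`); boundary
#' (non-converged) fits keep their boundary value but carry
#' `converged = FALSE` so downstream rankings can exclude them.
#'
#' @param table A [count_table()].
#' @param ... Passed to [fit_rsr()] (e.g. `bounds`, `tol`).
#' @return A data.frame with columns `peptide`, `s`, `c0`, `loglik`,
#'   `converged`, `defined`, `lrp`.
#' @export
rsr_table <- function(table, ...) {
  stopifnot(inherits(table, "count_table"))
  n <- length(table$peptides)
  out <- data.frame(peptide = table$peptides, s = NA_real_, c0 = NA_real_,
                    loglik = NA_real_, converged = FALSE, defined = FALSE,
                    lrp = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cnt <- table$counts[i, ]
    if (sum(cnt) < 1) next
    fit <- fit_rsr(cnt, depth = table$depth, rounds = table$round_labels,
                   ...)
    out$s[i] <- fit$s
    out$c0[i] <- fit$c0
    out$loglik[i] <- fit$loglik
    out$converged[i] <- fit$converged
    out$defined[i] <- TRUE
    out$lrp[i] <- lrp_label(cnt, table$round_labels)
  }
  out
}
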