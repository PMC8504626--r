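# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default synthetic landscape (epistatic, with the P6=D x P7 sign flip).
test_landscape <- function() memo("landscape", make_landscape())

# Purely additive landscape: per-position argmax is the exact optimum.
additive_landscape <- function() memo(
  "additive", make_landscape(n_couplings = 0L, flip_magnitude = 0))

# Small simulated training set (labels = last round of presence).
tiny_training <- function() memo(
  "training",
  make_training_set(test_landscape(), n = 150L, R = 4L,
                    depth_per_round = 3e4, rng_seed = 11L))

# Small trained ensembles, one per head type.
tiny_model <- function(head) memo(
  paste0("model_", head),
  train_ensemble(tiny_training(),
                 pep_net_config(head_type = head, K = 6L, width = 8L,
                                blocks = 1L, dropout = 0.1, ensemble = 2L,
                                epochs = 30L, seed = 101L)))

# Independent per-peptide scorer for a landscape: explicit double loop,
# sharing no code path with landscape_score().
naive_landscape_score <- function(landscape, peptides) {
  vapply(peptides, function(pep) {
    ch <- strsplit(pep, "")[[1]]
    s <- 0
    for (pos in 1:9) s <- s + landscape$pwm[pos, ch[pos]]
    cp <- landscape$couplings
    if (nrow(cp)) {
      for (i in seq_len(nrow(cp))) {
        if (ch[cp$pos_i[i]] == cp$res_i[i] &&
            ch[cp$pos_j[i]] == cp$res_j[i])
          s <- s + cp$value[i]
      }
    }
    s
  }, numeric(1), USE.NAMES = FALSE)
}

# Iteratively refined grid search for the RSR: repeated calls to the
# exhaustive grid oracle, zooming on the argmax until the grid spacing
# reaches `rel_res` relative resolution.
refined_grid_rsr <- function(counts, depth = NULL, lo = 1e-3, hi = 1e3,
                             rel_res = 1e-9, points = 2001L) {
  repeat {
    grid <- exp(seq(log(lo), log(hi), length.out = points))
    fit <- rsr_grid_oracle(counts, depth, grid = grid)
    spacing <- log(hi / lo) / (points - 1)
    if (spacing <= rel_res) return(fit)
    lo <- fit$s * exp(-2 * spacing)
    hi <- fit$s * exp(2 * spacing)
  }
}
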