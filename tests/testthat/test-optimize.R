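test_that("anchor enumeration covers 20^4 - 1 variants in lexicographic order", {
  seed <- "ADLIYNFEQ"
  v <- enumerate_anchor_variants(seed)
  expect_length(v, 159999L)
  expect_false(seed %in% v)
  expect_false(anyDuplicated(v) > 0L)
  expect_identical(v, sort(v, method = "radix"))
  # every variant preserves the five non-anchor residues
  for (p in nonanchor_positions())
    expect_true(all(substring(v, p, p) == substring(seed, p, p)))
  # and the anchor tuples cover the full product space plus the seed
  anchors <- paste0(substring(v, 1, 1), substring(v, 4, 4),
                    substring(v, 6, 6), substring(v, 9, 9))
  expect_equal(length(unique(anchors)), 159999L)
})

test_that("acquisition objectives follow their definitions", {
  d <- list(mean = 2.0, std = 0.5)
  expect_equal(acquisition(d, "pe"), 2.0)
  expect_equal(acquisition(d, "ucb"), 2.5)
  d0 <- list(mean = 2.0, std = 0)
  expect_equal(acquisition(d0, "ucb"), acquisition(d0, "pe"))
})

test_that("multi-allele objectives add per-allele acquisitions", {
  da <- list(mean = 2, std = 0.25)
  db <- list(mean = 3, std = 0.5)
  expect_equal(combined_objective(list(da, db), "pe"), 5)
  expect_equal(combined_objective(list(da), "pe"), acquisition(da, "pe"))
  expect_gte(combined_objective(list(da, db), "ucb"),
             combined_objective(list(da, db), "pe"))
  expect_error(combined_objective(list(), "pe"), "at least one")
})

test_that("oracle optimization of an additive landscape equals per-position argmax", {
  land <- additive_landscape()
  seed <- "ADLIYNFEQ"
  top <- propose(seed, oracle_predictor(land), "pe", k = 1)
  # independent closed form: substitute each anchor with its PWM argmax
  best <- strsplit(seed, "")[[1]]
  for (p in anchor_positions())
    best[p] <- AA_ALPHABET[which.max(land$pwm[p, ])]
  expect_equal(top$candidate, paste0(best, collapse = ""))
})

test_that("oracle optimization of a coupled landscape matches brute force", {
  land <- test_landscape()
  seed <- "ADLTYNFTQ"   # P7 = T engages the sign-flip coupling
  # independent per-peptide scorer agrees with the vectorized one
  sub <- with_seed(8, sample(enumerate_anchor_variants(seed), 300))
  expect_equal(naive_landscape_score(land, sub), landscape_score(land, sub),
               tolerance = 1e-12)
  k <- 5L
  top <- propose(seed, oracle_predictor(land), "pe", k = k)
  v <- enumerate_anchor_variants(seed)
  sc <- landscape_score(land, v)
  ord <- order(-sc, v, method = "radix")[seq_len(k)]
  expect_equal(top$candidate, v[ord])
  expect_equal(top$objective_value, sc[ord])
  expect_true(all(diff(top$objective_value) <= 0))
  expect_equal(top$rank, 1:k)
})

test_that("proposals preserve non-anchor residues and bookkeeping fields", {
  model <- tiny_model("gaussian")
  seed <- "ADLIYNFEQ"
  top <- propose(seed, model, "ucb", k = 10)
  expect_equal(nrow(top), 10L)
  expect_true(all(top$candidate != seed))
  for (p in nonanchor_positions())
    expect_true(all(substring(top$candidate, p, p) == substring(seed, p, p)))
  expect_equal(top$P1, substring(top$candidate, 1, 1))
  expect_equal(top$P9, substring(top$candidate, 9, 9))
  expect_error(propose(seed, model, "pe", k = 160000), "between 1 and")
})

test_that("full-rank proposal is a permutation of the variant set", {
  land <- test_landscape()
  seed <- "ADLIYNFEQ"
  all_props <- propose(seed, oracle_predictor(land), "pe", k = 159999L)
  expect_identical(sort(all_props$candidate, method = "radix"),
                   enumerate_anchor_variants(seed))
})

test_that("four method combinations produce 40 proposals per seed", {
  models <- list(gaussian = tiny_model("gaussian"),
                 categorical = tiny_model("categorical"))
  props <- propose_methods("ADLIYNFEQ", models, k = 10)
  expect_equal(nrow(props), 40L)
  expect_equal(as.vector(table(props$head_type, props$objective)),
               rep(10L, 4))
  # duplicates across methods are retained as separate records
  expect_true(all(table(props$head_type, props$objective) == 10L))
})

test_that("random controls are distinct anchor substitutions, reproducible by seed", {
  seed <- "ADLIYNFEQ"
  rc <- random_controls(seed, m = 10, rng_seed = 99)
  expect_equal(nrow(rc), 10L)
  expect_false(anyDuplicated(rc$candidate) > 0L)
  expect_false(seed %in% rc$candidate)
  for (p in nonanchor_positions())
    expect_true(all(substring(rc$candidate, p, p) == substring(seed, p, p)))
  expect_identical(random_controls(seed, m = 10, rng_seed = 99)$candidate,
                   rc$candidate)
  expect_false(identical(
    random_controls(seed, m = 10, rng_seed = 100)$candidate, rc$candidate))
  expect_error(random_controls(seed, m = 200000), "between 1 and")
})

test_that("random anchor draws are uniform over residues at each anchor", {
  rc <- random_controls("ADLIYNFEQ", m = 1e5, rng_seed = 12)
  for (col in c("P1", "P4", "P6", "P9")) {
    tab <- table(factor(rc[[col]], levels = AA_ALPHABET))
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    expect_gt(p, 1e-3)
  }
})

test_that("top-k proposals dominate random controls under the same model", {
  land <- test_landscape()
  orc <- oracle_predictor(land)
  seed <- "ADLIYNFEQ"
  top <- propose(seed, orc, "pe", k = 10)
  rc <- random_controls(seed, m = 10, rng_seed = 3)
  ctrl_obj <- acquisition(predict_enrichment(orc, rc$candidate), "pe")
  expect_true(max(top$objective_value) >= max(ctrl_obj))
  expect_true(min(top$objective_value) >= max(ctrl_obj))  # top-10 of 160k
})
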