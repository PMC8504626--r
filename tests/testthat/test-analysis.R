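test_that("Mann-Whitney handles degenerate, extreme and exact cases", {
  cmp <- mannwhitney(1, 1)
  expect_equal(cmp$p_value, 1)
  # fully separated groups: U = 0 for the lower group, exact p = 2/choose(6,3)... 0.1
  cmp2 <- mannwhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp2$u_statistic, 0)
  expect_equal(cmp2$p_value, 0.1)
  expect_match(cmp2$method, "exact")
})

test_that("Mann-Whitney is symmetric and rank-based", {
  a <- c(1.2, 3.4, 0.8, 2.2)
  b <- c(2.5, 4.1, 3.3, 5.0, 1.9)
  expect_equal(mannwhitney(a, b)$p_value, mannwhitney(b, a)$p_value)
  # invariant under any strictly monotone transform of the pooled values
  expect_equal(mannwhitney(exp(a), exp(b))$p_value,
               mannwhitney(a, b)$p_value)
  expect_error(mannwhitney(numeric(0), b), "non-empty")
})

test_that("exact Mann-Whitney p matches full permutation enumeration", {
  with_seed(19, {
    for (rep in 1:5) {
      a <- rnorm(4)
      b <- rnorm(5)
      cmp <- mannwhitney(a, b)
      pooled <- c(a, b)
      ranks <- rank(pooled)
      us <- apply(combn(9, 4), 2, function(ix)
        sum(ranks[ix]) - 4 * 5 / 2)
      u <- cmp$u_statistic
      p_perm <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
      expect_equal(cmp$p_value, p_perm, tolerance = 1e-12)
    }
  })
})

test_that("large tied samples fall back to the corrected normal approximation", {
  a <- rep(c(1, 2, 3), 10)
  b <- rep(c(2, 3, 4), 10)
  cmp <- mannwhitney(a, b)
  expect_match(cmp$method, "normal")
  expect_true(cmp$p_value > 0 && cmp$p_value < 1)
})

test_that("success rate counts strict improvements over the seed", {
  res <- success_rate(2.5, c(2, 3, 4))
  expect_equal(res$rate, 2 / 3)
  expect_equal(success_rate(5, c(1, 2, 3))$rate, 0)
  expect_equal(success_rate(0.5, c(1, 2, 3))$rate, 1)
  # ties are not improvements; undefined proposals count as failures
  expect_equal(success_rate(2, c(2, 2, 3))$rate, 1 / 3)
  res_na <- success_rate(1, c(2, NA, 3))
  expect_equal(res_na$rate, 2 / 3)
  expect_equal(res_na$n_undefined, 1L)
  expect_error(success_rate(NA, c(1, 2)), "undefined")
  # invariant under common rescaling of all RSR values
  expect_equal(success_rate(2.5 * 7, c(2, 3, 4) * 7)$rate, 2 / 3)
})

test_that("dual-allele criteria nest and handle the retention boundary", {
  ok <- dual_success(1, 1, prop_rsr_a = c(2, 3), prop_rsr_b = c(2, 3))
  expect_equal(unname(ok$strict), c(TRUE, TRUE, TRUE))
  # allele-B RSR exactly at 0.8 x seed: retained (>=) but not better
  edge <- dual_success(1, 10, prop_rsr_a = c(2, 3), prop_rsr_b = c(8, 8))
  expect_true(edge$strict[["better_a_retain_b"]])
  expect_false(edge$strict[["better_both"]])
  # 8 of 10 better on A: strict fails, relaxed (>= 8) passes
  pa <- c(rep(2, 8), 0.5, 0.5)
  rel <- dual_success(1, 1, pa, rep(2, 10))
  expect_false(rel$strict[["better_a"]])
  expect_true(rel$relaxed[["better_a"]])
  expect_error(dual_success(1, 1, c(2, 3), c(2, 3, 4)), "equal length")
})

test_that("conditional groups select conjunctive residue contexts", {
  peps <- c("AAAAAADAA", "AAAAADTAA", "AAAAADDAA")
  rsr <- c(1, 2, 3)
  g <- conditional_groups(peps, rsr,
                          list(all = NULL,
                               p7d = c(P7 = "D"),
                               p7d_p6d = c(P7 = "D", P6 = "D")))
  expect_equal(g$all, rsr)
  expect_equal(g$p7d, c(1, 3))
  expect_equal(g$p7d_p6d, 3)           # conjunction selects a subset
  expect_true(all(g$p7d_p6d %in% g$p7d))
  expect_warning(
    conditional_groups(peps, rsr, list(none = c(P1 = "Y"))), "empty")
})

test_that("method overlap counts shared candidates per seed and pair", {
  seeds <- c("ADLIYNFEQ", "CDEFGHIKL")
  mk <- function(method, cands1, cands2) {
    data.frame(seed = rep(seeds, each = 3),
               candidate = c(cands1, cands2), method = method,
               stringsAsFactors = FALSE)
  }
  c1 <- random_controls(seeds[1], 3, rng_seed = 1)$candidate
  c2 <- random_controls(seeds[2], 3, rng_seed = 2)$candidate
  identical_props <- rbind(mk("m1", c1, c2), mk("m2", c1, c2))
  ov <- method_overlap(identical_props)
  expect_true(all(ov$overlap$overlap == 3L))
  expect_equal(ov$zero_overlap$n_seeds_zero_overlap, 0L)
  # disjoint proposals: every seed has zero overlap
  c1b <- random_controls(seeds[1], 3, rng_seed = 3)$candidate
  c2b <- random_controls(seeds[2], 3, rng_seed = 4)$candidate
  disjoint <- rbind(mk("m1", c1, c2), mk("m2", c1b, c2b))
  ov2 <- method_overlap(disjoint)
  expect_equal(ov2$zero_overlap$n_seeds_zero_overlap, 2L)
  # overlap is symmetric in the pair
  swapped <- rbind(mk("m2", c1, c2), mk("m1", c1b, c2b))
  ov3 <- method_overlap(swapped)
  expect_equal(sort(ov3$overlap$overlap), sort(ov2$overlap$overlap))
  expect_error(method_overlap(mk("m1", c1, c2)), "at least 2")
})

test_that("motif matrices are column-normalized with a modal anchor set", {
  mm <- motif_matrix("ADLIYNFEQ")
  expect_equal(dim(mm$matrix), c(20L, 9L))
  expect_equal(unname(colSums(mm$matrix)), rep(1, 9))
  expect_equal(sum(mm$matrix == 1), 9L)       # one-hot per position
  expect_equal(mm$matrix["A", "P1"], 1)
  mm2 <- motif_matrix(c("ADLIYNFEQ", "ADLIYNFEQ", "CDLIYNFEQ"))
  expect_equal(unname(colSums(mm2$matrix)), rep(1, 9))
  # two peptides share anchors (A,I,N,Q); the third differs at P1
  expect_equal(unname(mm2$anchor_set), c("A", "I", "N", "Q"))
  expect_equal(mm2$anchor_count, 2L)
  expect_error(motif_matrix(character(0)), "empty")
})

test_that("conditional contrasts recover the simulated sign flip", {
  land <- test_landscape()
  mk_group <- function(p6, p7, n, seed) {
    with_seed(seed, vapply(seq_len(n), function(i) {
      ch <- sample(AA_ALPHABET, 9, replace = TRUE)
      ch[6] <- p6; ch[7] <- p7
      paste0(ch, collapse = "")
    }, character(1)))
  }
  groups <- list(t_d = mk_group("D", "T", 80, 1),
                 t_x = mk_group("A", "T", 80, 2),
                 d_d = mk_group("D", "D", 80, 3),
                 d_x = mk_group("A", "D", 80, 4))
  peps <- unique(unlist(groups))
  a <- simulate_selection(peps, land, R = 4, depth_per_round = 8e4,
                          rng_seed = 5)
  fits <- rsr_table(a$table)
  rsr <- setNames(fits$s, fits$peptide)
  g <- conditional_groups(fits$peptide[fits$defined],
                          fits$s[fits$defined],
                          list(p7t_p6d = c(P7 = "T", P6 = "D"),
                               p7t = c(P7 = "T", P6 = "A"),
                               p7d_p6d = c(P7 = "D", P6 = "D"),
                               p7d = c(P7 = "D", P6 = "A")))
  # P6=D raises RSR in the P7=T context ...
  up <- mannwhitney(g$p7t_p6d, g$p7t, alternative = "greater")
  expect_lt(up$p_value, 0.05)
  # ... and lowers it in the P7=D context
  down <- mannwhitney(g$p7d_p6d, g$p7d, alternative = "less")
  expect_lt(down$p_value, 0.05)
})
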