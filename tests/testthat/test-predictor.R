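test_that("one-hot encoding is deterministic, row-normalized and injective", {
  m <- encode_peptide("AAAAAAAAA")
  expect_equal(dim(m), c(9L, 20L))
  expect_equal(unname(m[, 1]), rep(1, 9))
  expect_equal(rowSums(m), setNames(rep(1, 9), paste0("P", 1:9)))
  X <- encode_batch(c("ACDEFGHIK", "LMNPQRSTV"))
  expect_equal(dim(X), c(2L, 180L))
  expect_true(all(rowSums(X) == 9))
  # flattening is position-major and matches the single-peptide encoder
  expect_equal(X[1, ], as.vector(t(encode_peptide("ACDEFGHIK"))))
  peps <- with_seed(3, random_peptides(200))
  expect_equal(nrow(unique(encode_batch(peps))), 200L)
})

test_that("analytic gradients match numerical differentiation", {
  for (head in c("gaussian", "categorical")) {
    cfg <- pep_net_config(head_type = head, K = 4L, width = 5L, blocks = 2L,
                          dropout = 0, epochs = 1L, seed = 9L)
    X <- with_seed(1, matrix(rbinom(6 * 180, 1, 0.1), 6, 180))
    y <- with_seed(2, if (head == "gaussian") rnorm(6) else
      sample(0:3, 6, replace = TRUE))
    params <- with_seed(3, pepanchor:::init_params(cfg))
    lg <- pepanchor:::net_loss_grad(params, X, y, cfg)
    flat <- pepanchor:::flatten_params(params)
    gf <- pepanchor:::flatten_params(lg$grad)
    eps <- 1e-5
    for (nm in names(flat)) {
      for (j in seq_len(min(length(flat[[nm]]), 4L))) {
        up <- flat; up[[nm]][j] <- up[[nm]][j] + eps
        dn <- flat; dn[[nm]][j] <- dn[[nm]][j] - eps
        l_up <- pepanchor:::net_loss_grad(
          pepanchor:::unflatten_params(up, params), X, y, cfg)$loss
        l_dn <- pepanchor:::net_loss_grad(
          pepanchor:::unflatten_params(dn, params), X, y, cfg)$loss
        g_num <- (l_up - l_dn) / (2 * eps)
        expect_equal(gf[[nm]][j], g_num, tolerance = 1e-4,
                     label = paste(head, nm, j))
      }
    }
  }
})

test_that("Gaussian ensemble aggregation follows the law of total variance", {
  mm <- mixture_moments(means = cbind(c(1), c(3)), vars = cbind(c(0), c(0)))
  expect_equal(mm$mean, 2)
  expect_equal(mm$var, 1)
  # average member variance adds on top of the disagreement variance
  mm2 <- mixture_moments(means = cbind(1, 3), vars = cbind(0.5, 0.7))
  expect_equal(mm2$var, 1 + 0.6)
})

test_that("categorical heads derive mean/std from averaged probabilities", {
  # zero-weight members produce uniform probabilities over K categories
  cfg <- pep_net_config("categorical", K = 6L, width = 4L, blocks = 0L,
                        ensemble = 2L, dropout = 0)
  zero_member <- function() {
    p <- with_seed(1, pepanchor:::init_params(cfg))
    p$W0[] <- 0; p$b0[] <- 0; p$Wc[] <- 0; p$bc[] <- 0
    p
  }
  model <- structure(list(members = list(zero_member(), zero_member()),
                          head_type = "categorical", K = 6L, config = cfg),
                     class = "pep_ensemble")
  pr <- predict_enrichment(model, c("ADLIYNFEQ", "AAAAAAAAA"))
  expect_equal(unname(pr$probs), matrix(1 / 6, 2, 6))
  expect_equal(pr$mean, rep(mean(0:5), 2))          # 2.5
  expect_equal(pr$std, rep(sqrt(mean((0:5)^2) - 2.5^2), 2))
})

test_that("prediction moments stay consistent with probabilities", {
  model <- tiny_model("categorical")
  pr <- predict_enrichment(model, tiny_training()$peptide[1:25])
  expect_equal(rowSums(pr$probs), rep(1, 25), tolerance = 1e-6)
  k <- 0:(model$K - 1)
  expect_equal(pr$mean, drop(pr$probs %*% k), tolerance = 1e-8)
  expect_equal(pr$std^2, drop(pr$probs %*% k^2) - pr$mean^2,
               tolerance = 1e-8)
  expect_true(all(pr$std >= 0))
})

test_that("a single-member ensemble predicts its member's distribution", {
  cfg <- pep_net_config("gaussian", width = 6L, blocks = 1L, ensemble = 1L,
                        dropout = 0, epochs = 5L, seed = 5L)
  data <- tiny_training()[1:40, ]
  model <- train_ensemble(data, cfg)
  pr <- predict_enrichment(model, data$peptide[1:10])
  fw <- pepanchor:::net_forward(model$members[[1]],
                                encode_batch(data$peptide[1:10]), cfg)
  expect_equal(pr$mean, fw$mean)
  expect_equal(pr$std, sqrt(fw$var))
})

test_that("training is deterministic given config and seed", {
  cfg <- pep_net_config("gaussian", width = 6L, blocks = 1L, ensemble = 2L,
                        epochs = 3L, seed = 33L)
  data <- tiny_training()[1:40, ]
  m1 <- train_ensemble(data, cfg)
  m2 <- train_ensemble(data, cfg)
  p1 <- predict_enrichment(m1, data$peptide)
  p2 <- predict_enrichment(m2, data$peptide)
  expect_identical(p1$mean, p2$mean)
  expect_identical(p1$std, p2$std)
})

test_that("training rejects empty or out-of-range data", {
  expect_error(train_ensemble(data.frame(peptide = character(),
                                         lrp = integer())),
               "training data")
  expect_error(
    train_ensemble(data.frame(peptide = "ADLIYNFEQ", lrp = 7L),
                   pep_net_config("categorical", K = 6L)),
    "0..K-1")
})

test_that("the ensemble learns a separable synthetic landscape", {
  land <- additive_landscape()
  peps <- with_seed(21, random_peptides(300))
  sc <- landscape_score(land, peps)
  # map scores to 0..5 labels by quantile binning
  y <- as.integer(cut(sc, breaks = quantile(sc, 0:6 / 6),
                      include.lowest = TRUE)) - 1L
  cfg <- pep_net_config("gaussian", width = 16L, blocks = 1L, dropout = 0.1,
                        ensemble = 2L, epochs = 60L, seed = 17L)
  model <- train_ensemble(data.frame(peptide = peps, lrp = y), cfg)
  pr <- predict_enrichment(model, peps)
  expect_gte(cor(pr$mean, y, method = "spearman"), 0.8)
})

test_that("the oracle predictor exposes the landscape with zero uncertainty", {
  land <- test_landscape()
  orc <- oracle_predictor(land)
  peps <- with_seed(4, random_peptides(20))
  pr <- predict_enrichment(orc, peps)
  expect_equal(pr$mean, landscape_score(land, peps))
  expect_equal(pr$std, rep(0, 20))
})

test_that("ensembles round-trip through a model directory", {
  model <- tiny_model("gaussian")
  dir <- withr::local_tempdir()
  save_ensemble(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_ensemble(dir)
  peps <- tiny_training()$peptide[1:10]
  expect_equal(predict_enrichment(back, peps)$mean,
               predict_enrichment(model, peps)$mean)
})
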