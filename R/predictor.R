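#' One-hot encode 9-mer core peptides
#'
#' Positions are rows, residues columns, residues ordered as
#' [AA_ALPHABET]. `encode_peptide` returns the 9 x 20 matrix for a single
#' peptide; `encode_batch` returns the flattened n x 180 design matrix
#' (position-major: columns 1..20 are P1, 21..40 are P2, ...).
#'
#' @param peptide A single 9-mer core.
#' @param peptides Character vector of 9-mer cores.
#' @return A 9 x 20 (or n x 180) numeric 0/1 matrix.
#' @export
encode_peptide <- function(peptide) {
  assert_peptide9(peptide)
  stopifnot(length(peptide) == 1L)
  m <- matrix(0, 9L, 20L, dimnames = list(paste0("P", 1:9), AA_ALPHABET))
  idx <- aa_index(strsplit(peptide, "", fixed = TRUE)[[1]])
  m[cbind(1:9, idx)] <- 1
  m
}

#' @rdname encode_peptide
#' @export
encode_batch <- function(peptides) {
  assert_peptide9(peptides)
  n <- length(peptides)
  chars <- unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE)
  idx <- aa_index(chars)                       # length 9n, position-major rows
  pos <- rep(1:9, times = n)
  row <- rep(seq_len(n), each = 9L)
  X <- matrix(0, n, 180L)
  X[cbind(row, (pos - 1L) * 20L + idx)] <- 1
  X
}

#' Configuration of the ensemble enrichment predictor
#'
#' The predictor is an ensemble of small residual multilayer networks over
#' the one-hot encoded core. Two output heads are supported: `gaussian`
#' (predicts a mean and a variance of the enrichment on the LRP scale,
#' trained by Gaussian negative log-likelihood) and `categorical`
#' (predicts a probability vector over the K LRP categories, trained by
#' cross-entropy). Ensemble members differ only in their random
#' initialization and minibatch order (seeds `seed + 1 .. seed + E`).
#'
#' @param head_type `"gaussian"` or `"categorical"`.
#' @param K Number of LRP categories (categorical head); labels are
#'   `0..K-1`.
#' @param width Hidden width of the network.
#' @param blocks Number of residual blocks.
#' @param dropout Dropout rate on residual-branch activations during
#'   training (no test-time dropout unless `mc_dropout`).
#' @param ensemble Number of ensemble members E.
#' @param epochs,batch_size,lr Adam training schedule.
#' @param var_floor Lower bound added to the Gaussian head variance.
#' @param mc_dropout,mc_passes If `TRUE`, prediction pools `mc_passes`
#'   stochastic dropout passes per member into the mixture.
#' @param seed Base RNG seed; fully determines training.
#' @return A list of class `pep_net_config`.
#' @export
pep_net_config <- function(head_type = c("gaussian", "categorical"),
                           K = 6L, width = 64L, blocks = 2L, dropout = 0.2,
                           ensemble = 5L, epochs = 200L, batch_size = 128L,
                           lr = 1e-3, var_floor = 1e-6,
                           mc_dropout = FALSE, mc_passes = 20L, seed = 1L) {
  head_type <- match.arg(head_type)
  stopifnot(K >= 2L, width >= 1L, blocks >= 0L, dropout >= 0, dropout < 1,
            ensemble >= 1L, epochs >= 1L, batch_size >= 1L, lr > 0,
            var_floor >= 0)
  structure(list(head_type = head_type, K = as.integer(K),
                 width = as.integer(width), blocks = as.integer(blocks),
                 dropout = dropout, ensemble = as.integer(ensemble),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 var_floor = var_floor, mc_dropout = mc_dropout,
                 mc_passes = as.integer(mc_passes), seed = as.integer(seed)),
            class = "pep_net_config")
}

# --- network internals -----------------------------------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
relu <- function(x) pmax(x, 0)

init_params <- function(config) {
  h <- config$width
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  p <- list(W0 = he(180L, h), b0 = numeric(h), blocks = list())
  for (i in seq_len(config$blocks))
    p$blocks[[i]] <- list(A = he(h, h), a = numeric(h),
                          B = he(h, h) * 0.1, b = numeric(h))
  if (config$head_type == "gaussian") {
    p$wm <- rnorm(h, sd = sqrt(1 / h)); p$bm <- 0
    p$ws <- rnorm(h, sd = sqrt(1 / h)); p$bs <- 0
  } else {
    p$Wc <- he(h, config$K) * 0.5
    p$bc <- numeric(config$K)
  }
  p
}

# Forward pass. When `train` is TRUE, inverted dropout is applied to the
# residual-branch activations and all intermediates needed for backprop are
# cached.
net_forward <- function(params, X, config, train = FALSE) {
  S0 <- sweep(X %*% params$W0, 2, params$b0, "+")
  H <- relu(S0)
  cache <- if (train) list(S0 = S0, H = list(H), S = list(), M = list())
  for (i in seq_along(params$blocks)) {
    bl <- params$blocks[[i]]
    S <- sweep(H %*% bl$A, 2, bl$a, "+")
    Z <- relu(S)
    if (train && config$dropout > 0) {
      M <- matrix(rbinom(length(Z), 1L, 1 - config$dropout) /
                    (1 - config$dropout), nrow(Z), ncol(Z))
      Z <- Z * M
    } else M <- NULL
    H <- sweep(H + Z %*% bl$B, 2, bl$b, "+")
    if (train) {
      cache$S[[i]] <- S; cache$M[i] <- list(M); cache$H[[i + 1L]] <- H
    }
  }
  out <- list(H = H, cache = cache)
  if (config$head_type == "gaussian") {
    out$mean <- drop(H %*% params$wm) + params$bm
    out$u <- drop(H %*% params$ws) + params$bs
    out$var <- softplus(out$u) + config$var_floor
  } else {
    logits <- sweep(H %*% params$Wc, 2, params$bc, "+")
    logits <- sweep(logits, 1, apply(logits, 1, max))
    e <- exp(logits)
    out$probs <- e / rowSums(e)
  }
  out
}

# Mean loss and gradients for one minibatch.
net_loss_grad <- function(params, X, y, config) {
  fw <- net_forward(params, X, config, train = TRUE)
  n <- nrow(X)
  g <- list()
  if (config$head_type == "gaussian") {
    m <- fw$mean; v <- fw$var
    loss <- mean(0.5 * log(2 * pi * v) + (y - m)^2 / (2 * v))
    dm <- (m - y) / v / n
    dv <- (0.5 / v - (y - m)^2 / (2 * v^2)) / n
    du <- dv * stats::plogis(fw$u)          # d softplus = sigmoid
    g$wm <- drop(crossprod(fw$H, dm)); g$bm <- sum(dm)
    g$ws <- drop(crossprod(fw$H, du)); g$bs <- sum(du)
    dH <- outer(dm, params$wm) + outer(du, params$ws)
  } else {
    P <- fw$probs
    iy <- cbind(seq_len(n), y + 1L)
    loss <- -mean(log(pmax(P[iy], 1e-12)))
    dL <- P / n
    dL[iy] <- dL[iy] - 1 / n
    g$Wc <- crossprod(fw$H, dL)
    g$bc <- colSums(dL)
    dH <- dL %*% t(params$Wc)
  }
  g$blocks <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    bl <- params$blocks[[i]]
    H_in <- fw$cache$H[[i]]
    S <- fw$cache$S[[i]]
    Z <- relu(S)
    if (!is.null(fw$cache$M[[i]])) Z <- Z * fw$cache$M[[i]]
    gb <- list(B = crossprod(Z, dH), b = colSums(dH))
    dZ <- dH %*% t(bl$B)
    if (!is.null(fw$cache$M[[i]])) dZ <- dZ * fw$cache$M[[i]]
    dS <- dZ * (S > 0)
    gb$A <- crossprod(H_in, dS)
    gb$a <- colSums(dS)
    g$blocks[[i]] <- gb
    dH <- dH + dS %*% t(bl$A)
  }
  dS0 <- dH * (fw$cache$S0 > 0)
  g$W0 <- crossprod(X, dS0)
  g$b0 <- colSums(dS0)
  list(loss = loss, grad = g)
}

# Flatten/unflatten parameter trees so Adam can treat them uniformly.
flatten_params <- function(p) {
  out <- list(W0 = p$W0, b0 = p$b0)
  for (i in seq_along(p$blocks))
    for (nm in names(p$blocks[[i]]))
      out[[paste0("blk", i, "_", nm)]] <- p$blocks[[i]][[nm]]
  for (nm in setdiff(names(p), c("W0", "b0", "blocks"))) out[[nm]] <- p[[nm]]
  out
}

unflatten_params <- function(flat, template) {
  p <- template
  p$W0 <- flat$W0; p$b0 <- flat$b0
  for (i in seq_along(p$blocks))
    for (nm in names(p$blocks[[i]]))
      p$blocks[[i]][[nm]] <- flat[[paste0("blk", i, "_", nm)]]
  for (nm in setdiff(names(p), c("W0", "b0", "blocks"))) p[[nm]] <- flat[[nm]]
  p
}

train_member <- function(X, y, config, member_seed) {
  with_seed(member_seed, {
    params <- init_params(config)
    flat <- flatten_params(params)
    m1 <- lapply(flat, function(w) w * 0)
    m2 <- m1
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t <- 0L
    n <- nrow(X)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        lg <- net_loss_grad(params, X[idx, , drop = FALSE], y[idx], config)
        gf <- flatten_params(lg$grad)
        t <- t + 1L
        for (nm in names(flat)) {
          m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * gf[[nm]]
          m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * gf[[nm]]^2
          mhat <- m1[[nm]] / (1 - beta1^t)
          vhat <- m2[[nm]] / (1 - beta2^t)
          flat[[nm]] <- flat[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
        }
        params <- unflatten_params(flat, params)
      }
    }
    params
  })
}

#' Train an ensemble enrichment predictor
#'
#' Each of the E members is trained on the full data (no bootstrap) from a
#' different random initialization and minibatch order. Labels are last
#' rounds of presence: the Gaussian head treats them as a continuous
#' target on the raw 0..K-1 scale; the categorical head as classes.
#'
#' @param data A data.frame with columns `peptide` and `lrp` (or a list
#'   with those elements).
#' @param config A [pep_net_config()].
#' @return An object of class `pep_ensemble`.
#' @export
train_ensemble <- function(data, config = pep_net_config()) {
  stopifnot(inherits(config, "pep_net_config"))
  peptides <- data$peptide
  y <- data$lrp
  if (is.null(peptides) || is.null(y) || length(peptides) == 0L)
    stop("training data must contain peptides and lrp labels", call. = FALSE)
  assert_peptide9(peptides)
  if (any(is.na(y))) stop("NA labels in training data", call. = FALSE)
  if (config$head_type == "categorical") {
    if (any(y != round(y)) || any(y < 0) || any(y > config$K - 1L))
      stop("categorical labels must be integers in 0..K-1", call. = FALSE)
    y <- as.integer(y)
  } else {
    y <- as.numeric(y)
  }
  X <- encode_batch(peptides)
  members <- lapply(seq_len(config$ensemble), function(e)
    train_member(X, y, config, member_seed = config$seed + e))
  structure(list(members = members, head_type = config$head_type,
                 K = config$K, config = config),
            class = "pep_ensemble")
}

#' @export
print.pep_ensemble <- function(x, ...) {
  cat(sprintf("pep_ensemble: %d x %s-head network (width %d, %d residual blocks)\n",
              length(x$members), x$head_type, x$config$width,
              x$config$blocks))
  invisible(x)
}

#' Uniform-mixture moments of Gaussian ensemble members
#'
#' The ensemble predictive distribution is the uniform mixture of the
#' member Gaussians: its mean is the average member mean and its variance
#' follows the law of total variance,
#' `avg(var_e + mean_e^2) - mean^2`.
#'
#' @param means,vars n x E matrices of member means and variances.
#' @return List with vectors `mean` and `var`.
#' @export
mixture_moments <- function(means, vars) {
  means <- as.matrix(means); vars <- as.matrix(vars)
  stopifnot(identical(dim(means), dim(vars)))
  m <- rowMeans(means)
  v <- rowMeans(vars + means^2) - m^2
  list(mean = m, var = pmax(v, 0))
}

#' Predict enrichment distributions for peptides
#'
#' Generic over predictor objects: [pep_ensemble][train_ensemble()] models
#' and [oracle_predictor()] scorers share this interface, so the optimizer
#' can use either. Gaussian ensembles aggregate members as a uniform
#' mixture ([mixture_moments()]); categorical ensembles average member
#' probability vectors and derive mean/std from the averaged probabilities
#' (`mean = sum k*p_k`, `var = sum k^2*p_k - mean^2`).
#'
#' @param model A predictor object.
#' @param peptides Character vector of 9-mer cores.
#' @param ... Unused.
#' @return An object of class `pep_prediction`: list with numeric vectors
#'   `mean` and `std`, plus an n x K matrix `probs` for categorical heads
#'   (`NULL` otherwise).
#' @export
predict_enrichment <- function(model, peptides, ...) {
  UseMethod("predict_enrichment")
}

#' @rdname predict_enrichment
#' @export
predict_enrichment.pep_ensemble <- function(model, peptides, ...) {
  assert_peptide9(peptides)
  X <- encode_batch(peptides)
  predict_encoded(model, X)
}

# Internal: predict from an already-encoded design matrix (the optimizer
# encodes each enumeration batch once and reuses it across members/heads).
predict_encoded <- function(model, X) {
  config <- model$config
  passes <- function(params) {
    if (config$mc_dropout && config$dropout > 0) {
      lapply(seq_len(config$mc_passes), function(i)
        net_forward(params, X, config, train = TRUE))
    } else list(net_forward(params, X, config, train = FALSE))
  }
  fws <- unlist(lapply(model$members, passes), recursive = FALSE)
  if (model$head_type == "gaussian") {
    means <- vapply(fws, `[[`, numeric(nrow(X)), "mean")
    vars <- vapply(fws, `[[`, numeric(nrow(X)), "var")
    if (nrow(X) == 1L) { means <- t(as.matrix(means)); vars <- t(as.matrix(vars)) }
    mm <- mixture_moments(means, vars)
    dist <- list(mean = mm$mean, std = sqrt(mm$var), probs = NULL)
  } else {
    P <- Reduce(`+`, lapply(fws, `[[`, "probs")) / length(fws)
    k <- 0:(model$K - 1L)
    m <- drop(P %*% k)
    v <- drop(P %*% k^2) - m^2
    dist <- list(mean = m, std = sqrt(pmax(v, 0)), probs = P)
  }
  structure(dist, class = "pep_prediction")
}

#' Ground-truth oracle predictor
#'
#' Wraps a [synthetic landscape][make_landscape()] as a zero-uncertainty
#' predictor: the predictive mean is the exact landscape score and the
#' standard deviation is 0. Interchangeable with a trained ensemble in the
#' optimizer; used as the test double that makes optimizer behaviour
#' exactly checkable.
#'
#' @param landscape A `pep_landscape`.
#' @return An object of class `pep_oracle`.
#' @export
oracle_predictor <- function(landscape) {
  stopifnot(inherits(landscape, "pep_landscape"))
  structure(list(landscape = landscape, head_type = "oracle"),
            class = "pep_oracle")
}

#' @rdname predict_enrichment
#' @export
predict_enrichment.pep_oracle <- function(model, peptides, ...) {
  m <- landscape_score(model$landscape, peptides)
  structure(list(mean = m, std = rep(0, length(m)), probs = NULL),
            class = "pep_prediction")
}

# --- model persistence (JSON manifest + RDS weights) -----------------------

#' Save / load an ensemble model directory
#'
#' The directory holds a JSON manifest (head type, E, K, seed,
#' architecture) next to the member weights.
#'
#' @param model A `pep_ensemble`.
#' @param dir Directory path.
#' @return `save_ensemble`: `dir`, invisibly. `load_ensemble`: the model.
#' @export
save_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "pep_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- unclass(model$config)
  manifest$class <- "pep_ensemble"
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model$members, file.path(dir, "members.rds"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(pep_net_config, manifest[setdiff(names(manifest), "class")])
  members <- readRDS(file.path(dir, "members.rds"))
  structure(list(members = members, head_type = cfg$head_type, K = cfg$K,
                 config = cfg),
            class = "pep_ensemble")
}
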