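#' Run the full synthetic optimization-validation experiment
#'
#' The desk-scale analogue of a complete optimization campaign, exercising
#' every pipeline stage end to end on simulated data: (1) simulate a
#' training selection of random 9-mers and label peptides by last round of
#' presence; (2) train Gaussian-head and categorical-head ensembles; (3)
#' for held-out random seed peptides, propose the top-k anchor
#' substitutions under the four method combinations (PE/UCB x two heads)
#' plus matched random anchor controls; (4) simulate a validation
#' selection of the designed library on the same ground-truth landscape;
#' (5) estimate RSR for every library member and compare the optimized
#' group against the random controls (one-sided Mann-Whitney), compute
#' per-seed success rates and the motif matrix of the proposals.
#'
#' @param rng_seed Master seed; all stage seeds derive from it.
#' @param landscape Ground-truth landscape (default [make_landscape()]).
#' @param n_train Training library size.
#' @param R Selection rounds per assay.
#' @param depth_per_round Sequencing depth per round.
#' @param n_seeds Held-out seed peptides to optimize.
#' @param k Proposals per method.
#' @param m_controls Random controls per seed.
#' @param config_overrides Named list overriding [pep_net_config()]
#'   defaults for both heads (e.g. `list(width = 32, epochs = 60)`).
#' @return A list: `training`, `models`, `seeds`, `proposals`,
#'   `controls`, `assay`, `rsr`, `groups` (named RSR samples),
#'   `comparison` (optimized vs random [mannwhitney()]), `success`
#'   (per-seed success-rate data.frame), `motif`.
#' @export
run_validation_experiment <- function(rng_seed = 1L,
                                      landscape = make_landscape(),
                                      n_train = 1000L, R = 4L,
                                      depth_per_round = 1e5,
                                      n_seeds = 20L, k = 10L,
                                      m_controls = 10L,
                                      config_overrides = list()) {
  rng_seed <- as.integer(rng_seed)
  training <- make_training_set(landscape, n = n_train, R = R,
                                depth_per_round = depth_per_round,
                                rng_seed = rng_seed)
  mk_config <- function(head, seed_off) {
    args <- list(head_type = head, K = max(6L, R), width = 32L,
                 blocks = 1L, dropout = 0.2, ensemble = 5L, epochs = 60L,
                 seed = rng_seed * 1000L + seed_off)
    args[names(config_overrides)] <- config_overrides
    args$head_type <- head
    args$seed <- rng_seed * 1000L + seed_off
    do.call(pep_net_config, args)
  }
  models <- list(
    gaussian = train_ensemble(training, mk_config("gaussian", 1L)),
    categorical = train_ensemble(training, mk_config("categorical", 2L)))

  seeds <- with_seed(rng_seed + 17L, {
    pool <- random_peptides(n_seeds * 3L)
    setdiff(pool, training$peptide)[seq_len(n_seeds)]
  })

  proposals <- list()
  controls <- list()
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    proposals[[s]] <- propose_methods(s, models, k = k,
                                      batch_size = 16384L)
    controls[[s]] <- random_controls(s, m = m_controls,
                                     rng_seed = rng_seed * 100L + i)
  }
  proposals <- do.call(rbind, c(proposals, list(make.row.names = FALSE)))
  controls <- do.call(rbind, c(controls, list(make.row.names = FALSE)))

  library_cores <- unique(c(seeds, proposals$candidate,
                            controls$candidate))
  assay <- simulate_selection(library_cores, landscape, R = R,
                              depth_per_round = depth_per_round,
                              rng_seed = rng_seed + 23L)
  fits <- rsr_table(assay$table)
  rsr_of <- setNames(ifelse(fits$defined, fits$s, NA_real_), fits$peptide)

  groups <- list(
    optimized = unname(rsr_of[proposals$candidate]),
    random_control = unname(rsr_of[controls$candidate]),
    seed = unname(rsr_of[seeds]))
  defined <- lapply(groups, function(g) g[!is.na(g)])
  comparison <- mannwhitney(defined$optimized, defined$random_control,
                            alternative = "greater")

  success <- do.call(rbind, lapply(seeds, function(s) {
    srsr <- rsr_of[s]
    if (is.na(srsr)) return(NULL)
    res <- success_rate(srsr, unname(
      rsr_of[proposals$candidate[proposals$seed == s]]))
    data.frame(seed = s, seed_rsr = unname(srsr),
               n_proposals = res$n_proposals, n_better = res$n_better,
               rate = res$rate, stringsAsFactors = FALSE)
  }))

  list(training = training, models = models, seeds = seeds,
       proposals = proposals, controls = controls, assay = assay,
       rsr = fits, groups = groups, comparison = comparison,
       success = success, motif = motif_matrix(proposals$candidate))
}

#' Measure the conditional effect of an anchor residue on RSR
#'
#' Builds matched peptide groups that differ only in whether anchor
#' position P6 carries aspartic acid (D), within two non-anchor contexts
#' (P7 = T and P7 = D), pushes them through one simulated selection, and
#' contrasts the fitted RSR of the `P6 = D` group against its context's
#' baseline with one-sided Mann-Whitney tests. On the default landscape
#' the constructed coupling makes the P6=D effect positive in the P7=T
#' context and negative in the P7=D context.
#'
#' @param landscape Ground-truth landscape.
#' @param n_per_group Peptides per group (4 groups).
#' @param R,depth_per_round Selection parameters.
#' @param rng_seed Master seed.
#' @return A list with `p_up` (P6=D raises RSR given P7=T), `p_down`
#'   (P6=D lowers RSR given P7=D), the median RSR differences
#'   `delta_t`/`delta_d`, and the group samples.
#' @export
run_context_contrast <- function(landscape = make_landscape(),
                                 n_per_group = 200L, R = 4L,
                                 depth_per_round = 1e5, rng_seed = 1L) {
  mk_group <- function(p6, p7, seed_off) {
    with_seed(rng_seed + seed_off, {
      reps <- peptide_matrix(random_peptides(n_per_group))
      reps[, 6] <- p6
      reps[, 7] <- p7
      unique(apply(reps, 1, paste0, collapse = ""))
    })
  }
  groups <- list(p7t_p6d = mk_group("D", "T", 1L),
                 p7t_base = mk_group("A", "T", 2L),
                 p7d_p6d = mk_group("D", "D", 3L),
                 p7d_base = mk_group("A", "D", 4L))
  peps <- unique(unlist(groups))
  assay <- simulate_selection(peps, landscape, R = R,
                              depth_per_round = depth_per_round,
                              rng_seed = rng_seed + 9L)
  fits <- rsr_table(assay$table)
  rsr_of <- setNames(ifelse(fits$defined, fits$s, NA_real_), fits$peptide)
  sample_of <- function(g) {
    v <- unname(rsr_of[g])
    v[!is.na(v)]
  }
  samples <- lapply(groups, sample_of)
  list(
    p_up = mannwhitney(samples$p7t_p6d, samples$p7t_base,
                       alternative = "greater")$p_value,
    p_down = mannwhitney(samples$p7d_p6d, samples$p7d_base,
                         alternative = "less")$p_value,
    delta_t = stats::median(samples$p7t_p6d) -
      stats::median(samples$p7t_base),
    delta_d = stats::median(samples$p7d_p6d) -
      stats::median(samples$p7d_base),
    samples = samples)
}
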