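---
title: "Anchor-residue optimization for class II MHC display: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-residue optimization for class II MHC display: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepanchor)
```

## The problem

Class II MHC molecules present peptides in an open groove: a 9-residue
core binds in an extended, highly conserved conformation, with the side
chains at positions P1, P4, P6 and P9 buried in binding pockets. These
four **anchor residues** dominate binding affinity, while the remaining
positions face the T-cell receptor. Substituting anchors can therefore
strengthen MHC presentation of a therapeutic peptide without changing the
surface that T cells recognize.

Because only four positions vary, the whole substitution space of a seed
peptide — $20^4 - 1 = 159{,}999$ candidates — can be scored exhaustively
against a learned affinity model. No search heuristic is needed, and
exhaustive scoring lets the model express interactions between anchors
and the fixed non-anchor context that simple per-position preference
rules cannot.

pepanchor implements the complete loop: simulate (or ingest) multi-round
display selection data, estimate per-peptide enrichment, train an
uncertainty-aware predictor, score all anchor substitutions under
Bayesian acquisition objectives, design a validation library, and analyse
the outcome.

## Round survival rate (RSR)

The display assay measures enrichment over iterative selection rounds: a
peptide's concentration is multiplied by its per-round survival
probability each round, and each round's population is deep-sequenced.
We model the reads of one peptide as

$$ n_r \sim \mathrm{Poisson}(\alpha_r \, c_0 \, s^r), \qquad r = 0, \dots, R-1 $$

where $s$ is the common ratio of the geometric concentration progression,
$c_0$ the initial-concentration scale, and $\alpha_r$ a per-round
constant reflecting how deeply round $r$'s population was sequenced. The
population constant is not observable, so $s$ is a scalar multiple of the
true survival probability; it is reported unnormalized as the **round
survival rate**. Rankings, ratios and group comparisons — everything the
analysis suite uses — are invariant to that scale.

Maximum likelihood is computed by profiling: for fixed $s$ the optimal
scale is closed-form, $c_0(s) = \sum_r n_r / \sum_r \alpha_r s^r$, which
reduces the fit to a bounded one-dimensional maximization over $\log s$
(`stats::optimize`). Numerical choices:

* **Depth constants** default to the per-round read totals of the count
  table — the observable proxy for the sequencing constant. Multiplying
  all $\alpha_r$ by any constant leaves $\hat s$ unchanged and is
  absorbed by $\hat c_0$ (tested).
* **Zero counts** in sequenced rounds are genuine Poisson observations
  and stay in the likelihood; absence at depth is informative.
* **Boundary profiles.** A peptide observed in a single round cannot
  identify both parameters: the likelihood is monotone in $s$ and the fit
  returns the bound with `converged = FALSE`. All-zero profiles have no
  defined RSR (`rsr_table()` flags them); downstream success-rate logic
  counts such proposals as failures rather than dropping them.
* **Search interval** defaults to $[10^{-6}, 10^6]$ with relative
  tolerance $10^{-8}$ on $\log s$; an exhaustive grid oracle
  (`rsr_grid_oracle()`) backs the optimizer in the test suite.
* **Rounds included:** all rounds present in the table, from the
  unselected round 0; a window can be selected via the `rounds` argument.

The **last round of presence** (LRP) — the largest round index with at
least one read — is the training label of the predictor, on its natural
0..K−1 scale.

## The enrichment predictor

The predictor is an ensemble of small residual networks over the one-hot
encoded core (9 positions x 20 residues, alphabetical residue order).
Two output heads are provided:

* **Gaussian** — predicts mean and variance of the enrichment treated as
  a continuous value; trained with Gaussian negative log-likelihood. The
  predicted variance passes through a softplus with a floor of $10^{-6}$
  for stability.
* **Categorical** — predicts a probability vector over the K LRP
  categories (default K = 6); trained with cross-entropy. Its predictive
  mean and standard deviation are the moments of that distribution, so
  they are always consistent with the probabilities (asserted in tests).

Members differ only by random initialization and minibatch order; each
is trained on the full data with Adam (default learning rate $10^{-3}$,
batch 128) and dropout on the residual branches (default rate 0.2).
Gaussian ensembles aggregate as a uniform mixture — the ensemble mean is
the average member mean and the variance follows the law of total
variance, so disagreement between members adds to the predictive spread.
Categorical ensembles average probability vectors. Test-time dropout is
off by default so that prediction is deterministic; Monte-Carlo dropout
can be enabled in the config, pooling a stated number of stochastic
passes into the same mixture.

The default architecture (width 64, two residual blocks, five members)
is a deliberate desk-scale choice: the optimizer's contract needs only a
predictive mean and standard deviation, and everything about the network
is configurable. Training labels are used on the raw 0..K−1 scale
without standardization. The training target is deliberately the LRP
label rather than the fitted RSR: labels are cheap, integer-valued, and
match how display training data are annotated in practice.

All gradients are implemented analytically and verified against
numerical differentiation in the test suite; training is exactly
reproducible from the config seed.

## Acquisition and optimization

For a candidate with predictive mean $\mu$ and standard deviation
$\sigma$:

* point estimate (PE): $\mu$;
* upper confidence bound (UCB): $\mu + \sigma$.

For multi-allele optimization the objective is computed per allele and
the values are **added**. `propose()` scores all 159,999 variants in
batches (default 4,096) and returns the top k (default 10); ties are
broken by lexicographic candidate order so results are deterministic.
`propose_methods()` runs the four method combinations (PE/UCB x
Gaussian/categorical heads) with one scoring pass per head, yielding 40
proposals per seed; duplicates across methods are retained as separate
records because between-method overlap is itself an analysis output.
`random_controls()` draws matched random anchor substitutions uniformly
without replacement. Anchor positions are fixed at P1/P4/P6/P9 — the
conserved class II register — and deliberately not configurable.

## Library design

Constructs are 15-mers. The **IPFR** scheme wraps the core in invariant
flanks, `AA` + core + `WEEG`, enforcing a single binding register and
matching the randomized training library; `parse_construct()` inverts it
exactly and rejects reads with mismatched flanks, wrong length or
non-canonical cores (rejection is a value with a reason, not an error).
The **WPFR** scheme places a core between the three residues flanking
its seed in the source proteome; seeds within three residues of a
terminus are rejected rather than padded, since wild-type context is
only defined where it exists. Seed selection scans proteome 9-mers and
thresholds the predictive mean; "some" and "high" affinity are
configuration, defaulting to 2 and 4 on the LRP scale (the early/late
round split). Identical constructs arising from different sources are
collapsed with merged provenance — a synthesized library cannot contain
duplicates, but analyses need to know every origin.

## The simulator

`make_landscape()` draws a ground-truth affinity function: i.i.d. normal
position-weight terms (sd 0.5) plus sparse anchor x non-anchor couplings
(20 random pairs, sd 1), and a fixed sign-flipping pair — P6=D is worth
+2 in a P7=T context and −2 in a P7=D context — so that conditional
anchor effects exist by construction and the analysis suite can be shown
to recover them. Raw scores map to survival probabilities through a
logistic link, $p = \mathrm{plogis}(\text{score} - 3)$. The offset of −3
makes the typical random 9-mer survive a round with probability ≈ 0.05
while peptides two standard deviations up survive with probability ≈
0.5: in a real display selection most random peptides are non-binders
that wash out within a couple of rounds, and this choice reproduces that
dynamic (and a spread of LRP labels) at desk scale.

`simulate_selection()` iterates $c_{r+1} = c_r \cdot p$ from a uniform
initial library and draws round-r counts as
$\mathrm{Poisson}(\text{depth}_r \cdot c_r / \sum c_r)$: the competitive
normalization models sequencing a fixed number of reads from whatever
population remains, which is exactly the unidentifiable population
constant that makes RSR unnormalized.

What the simulator deliberately does not model: yeast growth bias, PCR
amplification noise, register shifting in the groove, linker cleavage
efficiency, or sequencing error (flank filtering is assumed upstream).
Passing tests therefore demonstrate correctness of the estimation and
optimization machinery under the stated observation model, not
robustness to every artefact of a wet-lab run.

## Evaluation suite

Group RSR comparisons use the two-sided (or one-sided, where a direction
is pre-specified) Mann–Whitney U test: exact when the smaller group has
at most 8 tie-free observations, otherwise the tie-corrected normal
approximation; fully tied samples return p = 1. The exact branch is
cross-checked against full permutation enumeration in the tests.
Success rates use a strict `>` against the seed RSR ("higher than"), and
the dual-allele retention criterion uses `>=` at the 80% boundary; both
boundary conventions are fixed here for determinism and documented
because ties are otherwise ambiguous. `conditional_groups()`,
`method_overlap()` and `motif_matrix()` (20 x 9 position-frequency
columns plus the modal anchor set) complete the analysis surface.

## The packaged validation experiment

`run_validation_experiment()` runs the whole loop at a fixed desk scale:
a 1,000-peptide training library selected over R = 4 rounds at
$10^5$ reads/round, Gaussian and categorical ensembles of five members
(width 32, one residual block, 60 epochs — a slimmer network than the
constructor default, chosen so the experiment trains and scores
20 x 159,999 candidates in minutes), 20 held-out random seeds with
40 proposals and 10 random controls each, and a simulated validation
selection of the assembled library. The headline outputs are the
one-sided Mann–Whitney comparison of optimized versus random-control
RSR, per-seed success rates, and the proposal motif.
`run_context_contrast()` is the matching conditional analysis: 200
peptides per group in the P7=T / P7=D x P6=D / P6=A design, one shared
selection, and one-sided tests of the P6=D effect within each context.

These sizes are orders of magnitude below a real campaign (real
randomized libraries run to $10^8$ members); they are chosen so the full
loop, not a subsample of it, is exercised end to end.

## Known limitations

* RSR is unnormalized by construction; absolute survival probabilities
  and confidence intervals for $s$ are out of scope.
* The predictor sees only the 9-mer core: flanking effects on binding
  (which real WPFR data exhibit) are invisible to it, so optimization
  quality under WPFR display is expected to degrade.
* Single-observation profiles return boundary fits; at very low depth a
  large fraction of a library can be in this regime.
* The simulator's logistic link is a modelling convenience; any
  monotone link would preserve the rank-based analyses.
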