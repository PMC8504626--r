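Package: pepanchor
Title: Anchor-Residue Optimization of Peptides for Class II MHC Display
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine-learning-guided optimization of the anchor
    residues (P1, P4, P6, P9) of 9-mer peptide cores presented by class II
    MHC molecules. Provides an uncertainty-aware ensemble enrichment
    predictor with Gaussian and categorical output heads, exhaustive scoring
    of all 20^4 - 1 anchor substitutions under point-estimate and
    upper-confidence-bound acquisition objectives (single- or multi-allele),
    yeast-display library design with invariant or wild-type peptide
    flanking residues, maximum-likelihood estimation of per-peptide round
    survival rates (RSR) from round-by-round deep-sequencing counts under a
    Poisson observation model, a synthetic selection-assay simulator with an
    epistatic affinity landscape, and an evaluation suite (group RSR
    comparisons, optimization success rates, dual-allele criteria,
    conditional anchor and non-anchor contrasts, method overlap, and motif
    matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
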