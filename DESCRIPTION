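Package: gradfp
Title: Connectivity Gradient Fingerprinting and Network Dispersion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes vertex-wise connectivity gradients from resting-state
    functional connectivity matrices (row-wise sparsification, cosine affinity,
    principal-component or diffusion-map embedding), aligns them across
    subjects and sessions with iterative orthogonal Procrustes, and quantifies
    individual uniqueness by connectome fingerprinting: winner-take-all
    identification with a permutation null, within/between-subject similarity
    ratios with a repeated-measures ANOVA, per-network identification, and the
    association between a network's gradient-score dispersion and its
    identification accuracy. Includes a multi-subject multi-session synthetic
    connectome generator with known ground truth for validation and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
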