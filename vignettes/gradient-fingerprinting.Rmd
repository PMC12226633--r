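---
title: "Connectivity-gradient fingerprinting: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-gradient fingerprinting: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradfp)
```

## The scientific question

Resting-state functional connectivity can be summarised by *connectivity
gradients*: continuous spatial components obtained by decomposing a
vertex-by-vertex affinity matrix, such that vertices with similar
whole-brain connectivity profiles receive similar scores. Gradients are
strongly shared across people — the principal gradient reliably runs from
default-mode to sensorimotor/visual cortex — yet they also carry a stable
individual signature. `gradfp` quantifies that tension: how well can a
subject be re-identified across scanning sessions from a gradient map
alone, and which functional networks carry the identifying information?

## The measurement model

For each scan, a T × V time-series matrix is reduced to gradients in four
deterministic steps.

**Connectivity.** Entry (i, j) of the connectivity matrix is the Pearson
correlation between vertex time series i and j. Constant vertices make the
correlation undefined; the package errors by default (naming the vertex)
and can drop them on request.

**Sparsification.** Each row independently keeps its `ceiling((1 − s)·V)`
largest entries, `s = 0.9` by default, i.e. the strongest 10% of
connections per vertex. "Strongest" is interpreted as largest signed
correlation (`rank_by = "value"`), so negative edges survive only when a
row has fewer than 10% positive entries; ranking by magnitude is available
as a switch. Ties at the cut-off keep the lowest vertex index — a
deterministic rule where generic sort stability would otherwise decide.
The diagonal participates in the ranking by default (self-correlation 1
always survives); `zero_diagonal = TRUE` excludes it. Neither convention is
canonical in the field; both are exposed and the default documented.

**Affinity.** Cosine similarity between sparsified rows. The result is
symmetric with unit diagonal; an all-zero row (a vertex with no surviving
connections) is a hard error naming the vertex.

**Decomposition.** Two embeddings are provided.

* *PCA* (default): the affinity columns are mean-centred and the rows
  projected onto the top-k right singular vectors; explained variance is
  `σ_c² / Σσ²` over the full spectrum. Scores are equivariant under vertex
  permutation and invariant to a constant offset of the affinity.
* *Diffusion embedding*: negative affinities are clipped to zero (a Markov
  kernel must be non-negative — PCA, by contrast, uses the signed
  affinity), then `W' = D^{−α} W D^{−α}` with `α = 0.5` and the row-
  stochastic operator `P = D'^{−1} W'`. Eigenvectors are computed through
  the symmetric conjugate `D'^{1/2} P D'^{−1/2}`, an exact similarity
  transform, so the spectrum is real by construction. The trivial
  stationary eigenpair is known in closed form (`M √d' = √d'`) and is
  deflated *before* the decomposition; this keeps the non-trivial
  eigenvectors well defined even when block-structured affinities make the
  leading eigenvalue nearly degenerate. Scores are scaled by `λ^t`, or by
  `λ/(1 − λ)` (the multi-scale convention) when `diffusion_time = 0`, and
  normalised to unit degree-weighted RMS.

Component signs are not identified by either decomposition; before
alignment the package uses the convention that each column's
largest-magnitude element is positive. Sign and frame are ultimately fixed
by alignment.

## Alignment

Each scan's gradient set is aligned to a common template by orthogonal
Procrustes: `R = argmin ‖X R − T‖_F` over orthogonal `R` (reflections
allowed, no scaling or translation), solved by SVD of `XᵀT`. The
generalized variant iterates 10 times (default): align every set to the
current target, then replace the target by the mean of the aligned sets.
The first target is always the provided template, so its sign and
component-order conventions propagate to the group frame, and the total
squared fit error is mathematically non-increasing across iterations.
Component order is never permuted by alignment: an individual whose
components come out in a different order is handled only through rotation
mixing, and the per-set fit error is surfaced for diagnosing such cases.
Explained-variance vectors pass through alignment untouched.

## Fingerprinting statistics

For a session pair (reference, target) and one gradient, the similarity
matrix holds Pearson correlations between all subject pairs' score
vectors. Identification is winner-take-all per row; exact ties (a
measure-zero event in floating point) break to the lowest index and are
flagged. Significance comes from permuting subject labels while holding
the argmax predictions fixed: with add-one smoothing,
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`, which can never be zero; the
literal proportion is reported alongside for comparability with the
older convention. "At least as extreme" is implemented as `≥`, the
conservative choice. The default 1000 permutations put the p-value floor
at 1/1001 ≈ 0.001. An exhaustive mode (N ≤ 7) enumerates all N!
permutations; its null mean is exactly 1/N, a property the test suite
checks against an independent enumeration.

The within/between summary averages the similarity diagonal (within
subject) and the off-diagonal (between subjects); each subject's ratio
divides their diagonal entry by the mean of the off-diagonal entries in
their row *and* column — both sessions treated symmetrically. Ratios above
1 mark individual uniqueness. The ratio table (subjects × 3 gradients × 2
intervals) feeds a classical two-factor within-subject ANOVA in which each
effect is tested against its interaction with subject; a mixed-model fit
would give slightly different numbers, and the classical partitioning was
chosen because it has an exact definitional sums-of-squares form that an
independent oracle in the test suite can verify to 1e-8. Post-hoc paired
comparisons between gradients are Bonferroni-adjusted (×3).

Per-network identification simply restricts the similarity computation to
one network's vertices. The heteromodal/unimodal comparison is a paired
Wilcoxon signed-rank on class-mean accuracies, paired across interval
conditions per gradient by default; zero differences are dropped (the
classical rule), and an all-zero comparison is reported degenerate with
p = 1. The pairing scheme is configurable (`pooled` runs one test across
all gradient × interval conditions) because class sizes are unequal and no
single scheme is canonical.

**Dispersion** is the unbiased sample variance of a network's scores on
one gradient — a broad spread means the network extends along the axis
(integration), a tight one means segregation. Per (network, gradient,
interval) the reported dispersion is the mean of per-scan variances over
all subjects and the interval's two sessions; the alternative reading
(variance of the subject-averaged map) is deliberately not the default,
as averaging before taking the variance conflates group structure with
individual spread. The dispersion–accuracy association is a partial
Pearson correlation controlling for network vertex count, computed by
residualising both variables on vertex count and correlating the
residuals; p comes from the t distribution with n − 3 degrees of freedom,
Bonferroni-corrected ×4 by default (two intervals × two parcellation
schemes). Accuracy enters as percent — cosmetically, since correlation is
scale-invariant. The point cloud pools networks × the three analysed
gradients within one interval.

## The synthetic generator

Real test–retest fMRI is large and preprocessing-heavy; the generator
replaces it with data whose ground truth is known, at configurable scale.
Its hierarchy is:

* a **group template**: per network n and component c, vertex scores are
  drawn `centers[n,c] + dispersion[n,c]·N(0,1)`, then columns are
  Gram–Schmidt-orthogonalised and scaled to unit standard deviation. Unit
  *sd* (not unit norm) keeps per-vertex scores on the O(1) scale that the
  subject/session noise parameters assume; per-network ground-truth
  variances are recorded from the raw draw. A component whose residual
  collapses to a constant after orthogonalisation (possible only in
  degenerate zero-dispersion layouts) is left unscaled rather than
  amplified out of round-off noise.
* a **subject effect**: `G_i = template + σ_subject·E_i`, with `E_i`
  standard normal scaled per-vertex by the owning network's
  `signature_strength` — individual uniqueness is a *placed, recoverable*
  design parameter, not an emergent accident.
* a **session effect**: `G_is = G_i + σ_session·E_is`, isotropic.
* **time series**: `X = S G_isᵀ + σ_obs·noise`, with `S` a T × k matrix of
  latent signals, exactly whitened within each scan (empirical mean zero,
  identity covariance). Exact whitening makes a scan's correlation matrix
  a deterministic function of its latent gradients, so noise-free
  configurations collapse to exactly identical connectivity — a property
  the tests rely on. There is no temporal autocorrelation, hemodynamics,
  or motion structure: the analysis depends only on spatial correlation,
  and none of the downstream statistics touch temporal ordering.

The default layout has six networks — four heteromodal (DMN, FPN, DAN,
VAN) with dispersion 0.7 and signature strengths 1.2–1.5, two unimodal
(SMN, VN) with dispersion 0.35 and strength 0.5 — placing the DMN and the
sensorimotor/visual networks at opposite ends of the principal gradient.
The default study conditions are 30 subjects × 3 sessions (day1/day3/day30
labels for short and long retest intervals), V = 1000, T = 300,
σ_subject = 0.5, σ_session = 0.1, σ_obs = 1. With template columns at unit
sd these give within-subject spatial correlations near 0.97 and
between-subject correlations near 0.76 after the full pipeline —
qualitatively the regime reported for real test–retest data (high shared
structure, reliably separable individuals).

What passing tests on this generator do **not** show: robustness to
temporally structured noise, spatial smoothness of real cortical maps,
distance-dependent connectivity artifacts, or preprocessing choices. The
generator validates the *statistical machinery* (does the pipeline recover
planted structure, at planted strength, with calibrated nulls?), not the
neurobiology.

## Replicate experiments and problem sizes

Two designed experiments accompany the default study:

* **Chance-level control** — with `σ_subject = 0` no individual signal
  exists, and pooled identification over 20 replicate datasets must land
  in the exact binomial 95% interval around 1/N. These replicates run at
  V = 200, T = 150: the property is scale-free, and the reduced size keeps
  20 full pipeline runs cheap.
* **Dispersion-linked recovery** — six networks with dispersions spanning
  0.15–0.9 and `signature_strength = dispersion` (proportionality constant
  1), at N = 20, V = 600, T = 150, σ_session = 0.25, with deliberately
  unequal vertex fractions so the vertex-count covariate is informative.
  Because signature scales with dispersion while the session-noise floor
  is absolute, low-dispersion networks sink toward chance and
  high-dispersion networks stay identifiable, giving the
  accuracy–dispersion cloud the dynamic range a correlation needs. The
  package's claim is that the partial correlation recovers this planted
  positive association in ≥ 90% of 50 replicates.

## Numerical choices and degenerate inputs

* Eigenproblems are solved densely (LAPACK symmetric eigensolvers); the
  PCA route goes through the Gram matrix of the centred affinity, whose
  top-k eigenpairs are well separated in practice. Oracle tests pin both
  embeddings to independent dense decompositions at 1e-8.
* ANOVA effects whose sum of squares is below 1e-12 of the total are
  reported as F = 0 rather than as 0/0 round-off noise; a genuine effect
  over zero error variance keeps F = ∞.
* A similarity matrix entry is undefined if a score vector is constant
  within the mask; this is an error naming the subject, not an NA.
* An all-equal affinity graph has an empty non-trivial spectrum; the
  gradient set is returned flagged `degenerate` with constant scores.
* The pipeline tolerates a degenerate dispersion–accuracy point cloud
  (e.g. every network at ceiling accuracy) by reporting the association as
  undefined rather than failing the run.

## Reproducibility

Every stochastic stage draws its seed from the single configuration seed
through named substreams (`simulation`, `template`, `permutation <pair>
<gradient>`, ...), so stages are independently reproducible and a rerun
with the same configuration is byte-identical, a property the test suite
asserts on the emitted files.

## Known limitations

* Component-order instability across individuals is handled only by
  rotation mixing during alignment; a subject whose second and third
  components swap is diagnosable via `fit_error` but not automatically
  re-ordered.
* The Wilcoxon pairing over two interval conditions has almost no power at
  the default settings; it is reported for completeness and becomes
  meaningful with more conditions or the pooled scheme.
* The generator's noise is white in time and space; estimation noise in
  real data is spatially structured, which typically *helps*
  identification less than white noise does.
* Only dense computation is implemented; V beyond ~5000 would want sparse
  or iterative eigensolvers.
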