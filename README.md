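# gradfp — connectivity-gradient fingerprinting

`gradfp` asks a simple question of resting-state functional connectivity
data: **how individually unique are a person's connectivity gradients, and
where in the cortex does that uniqueness live?**

Connectivity gradients are continuous spatial axes obtained by decomposing a
vertex-by-vertex affinity matrix: vertices with similar whole-brain
connectivity profiles receive similar scores, so each gradient orders the
cortex along one organizing principle (the principal gradient runs from
default-mode to sensorimotor/visual cortex). The package implements the full
analysis chain used in test–retest gradient studies:

1. **Gradients** — per scan: Pearson connectivity matrix → row-wise
   sparsification keeping the top `1 − s` fraction of connections per vertex
   (default `s = 0.9`) → cosine affinity → decomposition by PCA (default) or
   diffusion-map embedding (anisotropic normalisation `D^{−α} W D^{−α}`,
   `α = 0.5`, eigenvectors of the Markov operator).
2. **Alignment** — iterative orthogonal Procrustes to a common template:
   `R = argmin_{RᵀR=I} ‖X R − T‖_F`, solved by SVD, refined for 10
   iterations against the group mean.
3. **Fingerprinting** — for each session pair and gradient, the N × N matrix
   of spatial Pearson correlations between subjects' score vectors;
   winner-take-all identification (accuracy = fraction of correct
   self-matches); a permutation null over subject labels with add-one
   p-values `p = (1 + #{null ≥ obs}) / (n_perm + 1)`; within/between
   similarity ratios and their two-factor repeated-measures ANOVA
   (gradient × time interval, subject as the error stratum).
4. **Networks** — identification restricted to each network's vertices;
   heteromodal vs unimodal accuracy comparison (Wilcoxon signed-rank);
   network dispersion (sample variance of gradient scores) and its partial
   correlation with identification accuracy, controlling for vertex count.
5. **Synthetic data** — a generator producing multi-subject, multi-session
   scans whose latent gradients are a group template plus per-network-scaled
   subject signatures and session noise, with ground truth exposed, so every
   claim the pipeline makes can be tested as parameter recovery.

## Worked example

```r
library(gradfp)

# a 30-subject, 3-session synthetic study (V = 1000 vertices, T = 300)
dataset <- simulate_dataset(synth_config(seed = 1))
config  <- analysis_config(seed = 1)
result  <- run_pipeline(config, dataset)

fp <- result$fingerprints$short.G1   # gradient 1, day1 - day3 pair
fp$identification
#> <identification_result> accuracy 30/30 = 1.000, p = 0.000999
round(c(within = fp$ratios$within, between = fp$ratios$between), 3)
#>  within between
#>   0.989   0.768

result$network_records[result$network_records$gradient_index == 1 &
                       result$network_records$interval == "short",
                       c("network", "class", "accuracy", "dispersion")]
#>   network       class accuracy dispersion
#> 1     DMN heteromodal        1  2.6410935
#> 2     FPN heteromodal        1  2.2705277
#> 3     DAN heteromodal        1  2.7727010
#> 4     VAN heteromodal        1  3.0646450
#> 5     SMN    unimodal        1  0.6655421
#> 6      VN    unimodal        1  0.5349399
```

Every subject is re-identified across sessions from their principal-gradient
map alone (accuracy 1.0, permutation p = 1/1001); within-subject spatial
correlation (0.989) clearly exceeds between-subject correlation (0.768), the
signature of individual uniqueness on top of a strongly shared group
gradient. Heteromodal networks spread far more broadly along the gradient
(dispersion 2.3–3.1) than unimodal ones (0.5–0.7). At these generous
default noise settings every network identifies perfectly; the
dispersion–accuracy association is studied with the harder
dispersion-linked generator design (see
`dispersion_linked_specs()` and the methods vignette), where networks near
the session-noise floor lose identifiability and the partial correlation
controlling for vertex count recovers the planted positive association
(mean partial r ≈ 0.77 over 50 replicates).

A command-line front end over the same functions lives at
`inst/cli/gradfp.R`:

```sh
Rscript inst/cli/gradfp.R simulate --subjects 30 --out-dir data --seed 1
Rscript inst/cli/gradfp.R report --data-dir data --out-dir results --seed 1
```

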