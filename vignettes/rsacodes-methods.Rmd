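---
title: "Methods: representational similarity codes, from behavior to brain maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity codes, from behavior to brain maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsacodes)
```

## The scientific problem

An object concept such as *hairdryer* has visual features (elongated, angular,
similar in shape to a gun) and abstract conceptual features (used to style
hair, found in salons, similar in function to a comb). Representational
similarity analysis (RSA) asks where in the ventral visual stream the
pairwise similarity structure of object-evoked multi-voxel fMRI patterns is
predicted by behavior-derived models of visual similarity, conceptual
similarity, or both — the last being the signature of an *integrative* object
code. `rsacodes` implements that full analysis chain, together with a
synthetic-data generator that produces every input with known ground truth so
each stage can be validated end to end.

## Behavior-based models

**Visual RDM.** Raters judge every unordered pair of the $n$ concepts on a
5-point Likert scale (1 = very dissimilar, 5 = very similar). Raters who rate
any identical-pair catch trial below 4 ("somewhat similar") are excluded
(`filter_raters()`): a rater who does not call an object at least somewhat
similar to itself is not doing the task. Pair means are min–max normalized to
$[0,1]$ over the $n(n-1)/2$ pairs and the RDM cell is $1 -$ normalized mean.
Min–max is our reading of "normalized"; it is the only common normalization
that puts the mean rating on the $[0,1]$ scale on which published
pair-level values are quoted.

**Conceptual RDM.** Feature-generation norms list, per concept, the features
produced and how many of the 20 producers listed each one. Entries produced
by fewer than 4 of 20 are unreliable and dropped; features describing visual
form or color (e.g. *is round*, *is red*) are removed so the model carries
abstract conceptual content only. The RDM cell is $1 - \cos(x_i, x_j)$ on
production-count vectors — counts, not binary indicators, so consensus
features weigh more.

**Embedding RDM.** $1 - \cos$ on fixed-length word vectors (word2vec-style,
300 dimensions). Training embeddings is out of scope; vectors are inputs.

## First- and second-level RSA

First-level brain RDMs use the correlation distance $1 - r$ between
object-evoked t-patterns within an ROI, with no additional pattern
normalization (no "cocktail" mean removal): the measure is plain Pearson
across voxels. Within-object analysis correlates the *same* object's patterns
across the two task contexts; its mean over objects indexes task-invariance
of the object code.

Second-level comparison uses Kendall's $\tau_a = (C - D) / \binom{m}{2}$,
the tie-aware rank correlation recommended when model RDMs predict many tied
dissimilarities. Model-to-model inference uses a stimulus-label randomization
test: object labels of one RDM are permuted (rows and columns together),
$\tau_a$ recomputed, and the one-sided upper-tail p computed with the +1
correction, $p = (1 + \#\{\tau_{null} \ge \tau_{obs}\})/(1 + N)$, so $p > 0$
always. Group inference across subjects uses the one-sided Wilcoxon
signed-rank test on per-subject $\tau_a$ (subjects as a random factor), with
Bonferroni correction over the 4 ROI × 2 model × 2 context family
(critical $\alpha = 0.05/16 = 0.003125$). For parametric interaction tests
the chain $\tau \to r = \sin(\tfrac{\pi}{2}\tau) \to z = \operatorname{atanh}(r)$
is applied, and the 2×2 repeated-measures interaction F is computed as the
squared paired t of the per-subject difference of differences, an exact
identity for this design.

Numerical choices worth noting:

* **Wilcoxon**: zeros are dropped (classic handling; the alternative Pratt
  treatment is not used). For $n \le 25$ the exact null of $W^+$ is built by
  generating-function convolution over doubled (possibly tied) ranks; beyond
  that, a normal approximation with tie and continuity correction.
* **RDM vectorization**: the lower triangle excluding the diagonal, in a
  fixed column-major pair order shared by every comparison.
* **Degenerate inputs**: constant lower triangles make $\tau$ undefined and
  error out; $|r| = 1$ would make Fisher-z infinite and errors out, except in
  the searchlight where $|r|$ is clamped at $1 - 10^{-6}$ (the ceiling occurs
  only in noise-free synthetic data and a bounded map is preferable there).

## Searchlight mapping and group inference

Each searchlight is the $k = 100$ nearest mask voxels to a center voxel
(Euclidean distance in world mm; the original surface-based geodesic
neighborhoods require a cortical mesh, which is out of scope — $k$ is
preserved). Per center: local correlation-distance RDM → $\tau_a$ against the
behavior model → $\sin$ transform → Fisher-z, mapped to the center voxel.

Group analysis z-scores each subject map within the mask ("standardized" is
unspecified in the source analysis; z-scoring is chosen over mean-centering
so subjects contribute on a common scale), then computes a one-sample t per
voxel, converted to z. Threshold-free cluster enhancement integrates
$e_h^E h^H\,dh$ over thresholds with the canonical defaults $E = 0.5$,
$H = 2$, $dh = \max/100$, 26-connectivity. Familywise error is controlled by
a two-stage Monte-Carlo max-statistic null: 100 null maps per subject by
permuting object labels of the local RDMs before model comparison
(implemented by applying the inverse permutation to the model RDM, which
leaves $\tau_a$ unchanged), then 10,000 group assemblies sampling one null
map per subject with replacement, each passed through the group statistic and
TFCE; the corrected p at a voxel compares its observed TFCE against the
distribution of null maxima. Inference is one-sided (positive model fit), and
each model × context map is corrected independently.

Cluster reports give extent, peak statistic with world-mm coordinates, and
the unweighted center of mass; voxel overlap is the logical AND of
thresholded maps, reported the same way without a peak statistic.

## The synthetic world

The generator states a world at the scale of the study it emulates: 40
object concepts, 16 subjects, 8 runs per task context, 15 raters per pair,
20 feature producers, and a 12×12×12 voxel grid with four well-separated
cubic regions implementing the four coding regimes (visual/task-dependent,
conceptual/task-dependent, conceptual/task-invariant, integrative).

* **Model RDMs** come from a chained-pair design: object $2i-1$ is visually
  similar to $2i$, while conceptually the chain is shifted by one, so visual
  partners are conceptually distinct and vice versa. Partner dissimilarities
  are drawn in $[0.05, 0.2]$ and the background in $[0.4, 1.0]$; draws repeat
  until $|\tau_a(V, C)| < 0.02$. The wide background range is deliberate: it
  gives the 780 pairs enough rank spacing that behavioral readouts can
  recover the order.
* **Patterns.** For a region with context weights $(w_v, w_c)$ the object
  covariance is $w_v(1-V) + w_c(1-C) + (1-w_v-w_c)I$, made positive
  semi-definite by a spectral shift $(S + \lambda I)/(1+\lambda)$. The shift
  is used instead of eigenvalue clipping because clipping perturbs
  off-diagonal values non-uniformly and destroys the rank order the analysis
  is supposed to recover (measured ceiling $\tau \approx 0.8$ under
  clipping); the shift rescales all off-diagonals by one factor and keeps the
  ceiling at $\tau \to 1$. Visual and conceptual components are drawn once
  per subject and shared across contexts, so regions loading the same
  component in both contexts show high within-object cross-context
  similarity; the residual component is context-specific. Per-run Gaussian
  noise has sd 1 relative to unit pattern variance (run averages over 8 runs
  then carry noise sd $1/\sqrt 8$) — chosen once as a regime where
  per-subject model fits are modest but consistent, which is what carries the
  real effects.
* **Ratings.** The latent rating is $1 + 4(1 - V_{ij})$; each rater applies a
  deterministic criterion offset spanning one scale step before rounding.
  This models heterogeneous category boundaries across raters and acts as a
  dither: the across-rater mean becomes a fine-grained monotone readout of
  the latent similarity, so the noise-free round trip recovers the model
  order ($\tau_a > 0.95$) despite the 5-point scale. Optional Gaussian rater
  noise and a configurable fraction of catch-failing raters sit on top.
* **Norms.** Pairwise similarity targets are scaled to fit each concept's
  feature-mass budget and realized as shared features with integer counts in
  4..20 (greedy sum-of-squares decomposition), plus unique filler features
  equalizing norms. Absolute cosines are therefore compressed (as in real
  feature norms) but the pair rank order matches the conceptual model.
  Tagged visual-form/color decoys and sub-threshold features exercise the
  filtering rules.
* **Embeddings.** A factor of the PSD-projected Gram
  $(1-\text{leak})(1-C) + \text{leak}(1-V)$, row-normalized and randomly
  rotated into 300 dimensions. `leak` emulates corpus embeddings capturing
  visual semantics.
* **BOLD.** Design-matrix forward model with the double-gamma HRF (peak 6 s,
  undershoot 16 s, ratio 1/6), white Gaussian noise, optional linear drift.
  Ordinary least squares replaces prewhitened GLS throughout: with white
  synthetic noise, prewhitening is exactly a no-op, and the RSA consumes only
  the resulting t-patterns.

What a green test does **not** establish: the generator has no physiological
or temporally autocorrelated noise, no spatial smoothness beyond the
searchlight's own averaging, no subject-level anatomical variability, and
cubic regions instead of cortical geometry. Green therefore means the
*statistical machinery* is correct and calibrated (e.g. FWE at the nominal
0.05 under the global null), not that the pipeline is robust to every
real-fMRI artifact.

## Known limitations and open choices

* Geodesic (surface) searchlights are not implemented; volumetric k-NN with
  $k = 100$ stands in.
* The source analysis reports SEs for model-to-model $\tau$ values by an
  unstated method; this package reports the permutation-null sd instead,
  clearly labeled (`null_sd`).
* NIfTI input/output is unavailable in the target R stack; volumes are
  carried as arrays with an affine and serialized as a plain-text voxel
  table + JSON header (`write_volume_tsv()`).
* Whether similarity files store similarity or dissimilarity is auto-detected
  from the diagonal at load time (`read_rdm_csv()`), overridable by flag.

## A worked ROI example

```{r example}
cfg <- synthetic_config(n_objects = 16, n_subjects = 8,
                        grid_dims = c(8, 8, 6),
                        regions = default_regimes(c(8, 8, 6), 3), seed = 7)
mods <- make_model_rdms(16, seed = 7)
sim <- simulate_patterns(mods$V, mods$C, cfg)
rdms <- lapply(names(sim$patterns), function(s)
  pattern_rdm(roi_patterns(sim, s, "visual", "prc_like")))
group_model_fit(rdms, mods$V, m = 16)
group_model_fit(rdms, mods$C, m = 16)
```

Both models fit the integrative region in the visual task context — the
qualitative signature the full acceptance suite verifies across all four
regimes, both contexts, and the within-object analysis.
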