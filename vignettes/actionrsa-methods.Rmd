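---
title: "Models and methods behind actionrsa"
author: "actionrsa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind actionrsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actionrsa)
```

actionrsa implements a behavioral-to-neural representational similarity
analysis (RSA) of observed actions together with a synthetic-data module
that can generate every input the pipeline consumes. This vignette is the
package's account of the underlying models, the parameters that matter,
the numerical choices, and the limits of what the validation suite shows.

## The representational dissimilarity matrix

Everything in the package flows through one data type: the RDM, a square
symmetric non-negative matrix with zero diagonal whose entry $d_{ij}$
quantifies how dissimilar conditions $i$ and $j$ are in some space —
on-screen arrangement distance, rating differences, image features, or
neural activation patterns. Invariants (symmetry within $10^{-8}$
relative tolerance, non-negativity, zero diagonal) are enforced at
construction; near-symmetric input is symmetrized as $(M + M^\top)/2$,
anything worse is rejected rather than silently repaired.

Two conventions are applied uniformly because nothing downstream is
meaningful without them:

* **Max-normalization.** Behavioral and model RDMs are divided by their
  largest entry, so the maximal dissimilarity is 1. This removes the
  arbitrary scale of screens, Likert ranges, and feature spaces while
  preserving the order of entries.
* **Upper-triangle vectorization.** All RDM comparisons (correlation,
  regression) operate on the $n(n-1)/2$ upper-triangle entries only. The
  structural zero diagonal is never included; including it would inflate
  every correlation with a shared constant.

For rank-based model comparison we use Kendall's $\tau_a$ — the
concordant-minus-discordant count divided by the *total* pair count
$P(P-1)/2$, with no tie correction. $\tau_a$ is the conservative choice
when model RDMs predict tied dissimilarities (the one-vs-two-people model
has only two distinct values); a tie-corrected $\tau_b$ would reward such
models for their ties.

## Multi-arrangement behavior and its aggregation

In the multi-arrangement task, trial 1 shows all items on a circular
arena; every later trial shows an adaptively chosen subset of at least 3.
Per trial, distances are divided by the trial's maximum pair distance
(subsets occupy arbitrary screen area; only relative distances carry
information). Aggregation then averages each pair over its co-occurring
trials and max-normalizes.

Two aggregation modes exist because per-trial max-scaling has a known
small bias: different subsets have different maximal pairs, so pairs
measured mostly in small subsets are averaged on a slightly different
scale than pairs measured in trial 1. With a noiseless simulated
arranger this caps recovery around $r \approx 0.96$. The
`iterative_rescale` mode removes the bias by alternately rescaling each
trial to the current estimate with the least-squares factor
$s_t = \langle d_t, \hat d \rangle / \lVert d_t \rVert^2$ and
re-averaging — the simple fixed point of evidence-weighted dissimilarity
estimation — and recovers a noiseless 2-D arranger's RDM essentially
exactly. The default remains `per_trial_max`: it is simpler, unbiased in
the large-trial limit, and the difference is far below the behavioral
noise floor of real observers.

The adaptive subset rule is deliberately a transparent simplification of
full evidence-optimal item selection: evidence per pair accumulates as
`n_items / subset_size` per co-occurrence (smaller subsets are drawn
larger on screen and measured more precisely), and the next subset seeds
with the weakest pair and greedily adds items covering the largest
evidence deficit, all ties broken by item order so sessions are
reproducible. Simulations in the test suite verify the property that
matters: minimum pair evidence grows monotonically, and adaptive sessions
beat the trivial alternative of re-showing everything.

The simulated arranger places items at the 2-D metric-MDS embedding of the
noise-perturbed true sub-RDM, rescaled to the arena. Its noise default
(`noise_sd = 0.45` on the normalized-RDM scale) was calibrated once so a
20-subject, 28-item cohort reproduces the leave-one-subject-out
reliability regime reported for real semantic multi-arrangement data
(mean LOSO $r \approx 0.6$, individual range roughly 0.45–0.8); it was
not revisited afterwards. LOSO significance uses a permutation null —
shuffling item labels of the held-out subject's RDM — because RDM entries
are not independent, so an analytic null for correlations would be
anticonservative; p-values get Benjamini–Hochberg correction across
subjects.

## Model RDMs

Rating-derived models (sociality, transitivity, observer distance) use
per-subject $|s_i - s_j|$ differences, max-normalized, then averaged
across subjects and renormalized. Averaging normalized per-subject RDMs
(rather than normalizing the average) keeps every subject equally
weighted regardless of how much of the scale they used. The 3-level
distance scale is ordinal and is differenced like any other rating. The
one-vs-two-people model is the binary mismatch matrix, equivalently
$|a-b|$ on 0/1 codes.

The low-level visual control model is the C1 layer of the HMAX hierarchy:
zero-mean, unit-norm Gabor filters (4 orientations, 2 scale bands with
sizes 7/9 and 11/13 pixels) are applied to the grayscale image, responses
are rectified by absolute value, the two scales in a band are combined by
a pointwise max, and local $8\times 8$ / $10\times 10$ neighborhoods are
max-pooled with 50% overlap. Per action, exemplar C1 vectors are averaged
and the model RDM is $1 - r_{\text{Pearson}}$ between action vectors
(squared Euclidean available as an option). The parameterization is a
reduced desk-scale version of the standard C1 table, adequate for images
around $128 \times 96$; tests rely only on C1's structural properties —
exact invariance to additive intensity shifts (zero-mean filters),
orientation selectivity on gratings, and graceful tolerance to small
translations (measured at roughly 4% relative change per pixel of shift;
multi-pixel shifts degrade smoothly rather than staying within any sharp
bound).

Collinearity of a model set is summarized by per-model variance inflation
factors $1/(1-R_i^2)$ from regressing each model's pair vector on all
others; perfectly collinear sets report infinite VIF rather than erroring,
and are rejected only where they would actually break an analysis (the
searchlight regression).

## Searchlights and the two RSA variants

The toy cortical surface is an icosphere — an icosahedron subdivided $s$
times and reprojected to the unit sphere, giving $10\cdot 4^s + 2$
vertices — the simplest closed connected 2-manifold with near-uniform
vertex density. Regions are painted as compact edge-connected patches
(grown by annexing the unassigned neighbor nearest the seed), which keeps
their boundary short; straggly random-growth patches were tried and
rejected because boundary searchlights dominated the recovered maps.

A searchlight is the $k$ vertices nearest a center by breadth-first
edge-hop distance, ties within the last ring broken by Euclidean distance
then vertex index, so construction is deterministic and matches a
geodesic-ring oracle exactly. The canonical 100-feature definition is
honored on meshes large enough to support it; the simulation studies use
proportionally smaller searchlights on their smaller meshes.

**Standard RSA** averages betas across runs, computes the squared
Euclidean RDM of the searchlight patterns, max-normalizes it, and Pearson-
correlates it with the model RDM. Pearson is the default (the maps are
Fisher-transformed and t-tested downstream, which presumes an
approximately continuous, variance-stabilizable statistic); the
correlation method is a parameter, not a hard-wired choice.

**Multiple-regression RSA** first z-scores each vertex across conditions
within run (removing univariate amplitude differences), averages across
runs, z-scores each condition's pattern across searchlight members
(removing pattern-norm differences), computes the squared Euclidean RDM,
and regresses its pair vector on all model vectors by OLS. An intercept is
always included: max-normalized distance vectors have strictly positive
mean, and omitting the intercept would bias every coefficient. Predictors
are *not* z-scored by default, so coefficients live on the normalized-RDM
scale and are comparable across searchlights; a `standardize` flag exists.
Both z-scoring steps and the final max-normalization are individually
toggleable — the exactness oracles below require them off, and a user
replicating a correlation-only analysis may want different combinations.

The linchpin of the whole regression design is the additivity of squared
Euclidean distances over disjoint feature blocks:
$d^2(x, y) = \sum_b d^2(x_b, y_b)$. The synthetic-data module exploits it
in reverse: `plant_brain_patterns()` builds, for each model with weight
$w_k$, an exact Euclidean embedding of $w_k D_k$ (Torgerson
double-centering of the target, eigendecomposition, coordinates
$V\Lambda^{1/2}$; the construction errors if the target is not
embeddable), places the blocks on disjoint vertices, and then spreads them
over the whole region with a random orthonormal rotation, which preserves
every pairwise distance exactly. A noiseless planted region therefore has
squared-Euclidean RDM *identically equal* to $\sum_k w_k D_k$, and the
searchlight regression over the full region recovers the planted weights
to machine precision — the end-to-end oracle for the stack. One subtlety
follows from the rotation: sub-searchlights inside a region see a random
partial projection of the geometry (correlation near, but not exactly, 1),
which is also the realistic situation; exactness claims are always
evaluated over the full region via `roi_searchlight()`.

## Group inference

Per-subject correlation maps are Fisher-transformed ($z = \operatorname{atanh} r$,
clamped at $|r| < 1 - 10^{-12}$ so noiseless maps stay finite) and tested
against zero with one-tailed one-sample t-tests per vertex. Cluster-based
Monte-Carlo permutation correction then: thresholds the t-map at the
one-tailed $p_0 = 0.001$ quantile of $t_{n-1}$; forms edge-connected
clusters; scores each by its mass (sum of t, the max-sum statistic);
builds the null by randomly sign-flipping each subject's map and recording
the maximum cluster mass per iteration (5000 by default, reducible); and
computes corrected $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$
— the add-one rule, so p is never zero and identical-flip iterations are
counted conservatively via $\ge$. Corrected p is converted to a one-tailed
normal z; clusters with $z > 1.65$ are significant and the z-map is
nonzero only at their member vertices (per-vertex display of a
cluster-level decision; a flag could threshold at peaks instead, but the
per-vertex convention matches how such maps are normally rendered).
Sign-flipping is the standard exact permutation scheme for one-sample
symmetric nulls; the null computation is vectorized (one sign matrix
multiplication per batch) so 500–5000 iterations are cheap even in R.

Zero-variance vertices (all subjects identical) are guarded: they receive
a large finite t with the correct sign instead of `Inf`, so degenerate
synthetic data cannot crash the inference. Vertices with any missing
subject value are masked and excluded.

## Characterization

Classical MDS is the Torgerson double-centering of squared
dissimilarities; coordinates are returned for the positive-eigenvalue
subspace and the negative-eigenvalue mass is reported rather than hidden
(RDMs from noisy or rank-transformed data are not exactly Euclidean). PCA
runs on item coordinates — in the pipeline, the MDS coordinates of the
group RDM, which for Euclidean arrangement data coincide with the
arrangement geometry itself and generalize cleanly to rating-derived
RDMs. K-means uses Lloyd's algorithm with k-means++ seeding, 100 restarts
per candidate K (best inertia kept), and mean silhouette width selects K
over the default range 2–10; singleton clusters take silhouette 0 by
convention. Hierarchical clustering defaults to average linkage — the
conventional choice for correlation-like dissimilarities — and exports
Newick via `ape`.

The peak-ROI analysis extracts the searchlight-sized neighborhood of the
argmax vertex of a group map (ties to the lowest index, logged by
construction), computes per-subject neural RDMs with the standard-RSA
recipe, correlates them with every model by Kendall $\tau_a$, t-tests the
correlations one-tailed with BH-FDR, and characterizes the group-mean
neural RDM by rank-rescaling to 0–100 (average ranks for ties) for
display, classical MDS, and a dendrogram.

## The synthetic-data generator as study design

The generator's defaults *are* the emulated study conditions, chosen once:

* **Design**: 12 runs, 28 actions × 12 exemplars (2 actors × 2 scenes ×
  3 viewpoints), 56 experimental trials + 18 null events + 7 catch trials
  per run, 1 s stimulus + 3 s fixation, TR 2.5 s, 142 volumes per run.
  Each session half presents every action × exemplar combination exactly
  once (336 trials); each action appears 24 times over the session. Catch
  trials repeat the previous action with a different exemplar and are
  sampled without replacement within 4-run blocks. Null events are
  interleaved at unconstrained random positions (spacing constraints are
  exposed nowhere because the emulated design did not state any). The
  stated catch-trial *fraction* of the emulated design is internally
  inconsistent with its own counts; the generator fixes 7 per run and
  reports realized fractions.
* **Semantic ground truth**: 28 items in 6 near-balanced clusters in a 2-D
  latent space, cluster centers rejection-sampled to a minimum separation
  of 7 within-cluster standard deviations. Near-balance and a guaranteed
  separation make the planted K real: with freely random centers and
  sizes, "6 planted clusters" frequently contained chance-merged or
  singleton clusters, i.e. no ground truth to recover. Recovery of K
  degrades monotonically as separation shrinks (a trend test covers
  separations 1.5–7); at separation 7, silhouette-guided k-means selects
  K = 6 in ≥ 98% of replicates.
* **fMRI noise**: i.i.d. Gaussian on betas, sd 0.15 for the recovery
  study — calibrated so single-subject searchlight maps correlate with
  the true model around $r = 0.25$ (the realistic 0.1–0.3 regime), then
  frozen. Time-series simulation uses boxcars convolved with a canonical
  double-gamma HRF (gamma shapes 6 and 16, unit rate, undershoot ratio
  1/6) sampled at the TR, plus AR(1) noise with coefficient 0.3 — values
  chosen as the standard parameterization, not fitted to anything.
* **Images**: each action is a Gabor-like parametric texture family
  (orientation, frequency, position, envelope); exemplars are jittered
  instances. Luminance equalization shifts images additively (iterating
  against clipping) to a common mean of 115.8 intensity units and reports
  the achieved means and clipped fractions.

What these simulations do **not** emulate — and therefore what passing
tests do not establish about real data — includes: spatially correlated
and physiological fMRI noise, inter-subject anatomical misalignment,
motion, hemodynamic nonlinearity, behavioral idiosyncrasies beyond
Gaussian placement noise, and any semantic content in the images. The
validation logic is deliberately inverted from an applied study: the
pipeline is checked against *known* planted structure (exact mixture
recovery, spatial Dice ≥ 0.8 with zero false positives, family-wise error
within the binomial envelope of the nominal 0.05, cluster-count
recovery), which certifies the machinery, not any empirical claim.

## Problem sizes and reproducibility

The shipped studies run at desk scale, chosen as the smallest sizes at
which each claim is statistically meaningful: recovery on a 162-vertex
mesh with a 50-vertex region, 5-feature searchlights, 20 subjects, 1000
permutations, 20 replicates; error-rate calibration on a 42-vertex mesh,
200 null cohorts, 500 permutations; cluster-count recovery over 50
replicates. The 100-feature searchlight definition is exercised on a
642-vertex mesh. Every stochastic function takes an explicit seed, derives
independent per-stage streams from it, and restores the caller's RNG
state; `run_pipeline()` is bit-reproducible for a fixed config, and the
pipeline manifest records the config, seeds, and artifact list of a run.
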