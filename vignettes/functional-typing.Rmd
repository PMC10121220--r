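---
title: "Functional cell typing from collicular calcium imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional cell typing from collicular calcium imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfunctype)
```

## The problem

Neurons in the superficial layers of the mouse superior colliculus (SC)
respond to a battery of visual stimuli — moving bars, expanding and
receding discs, a luminance "chirp", color flashes and flashed discs of
different sizes — with diverse, repeatable temporal signatures. The aim
of this package is to turn those per-neuron, trial-by-time calcium
responses into a discrete taxonomy of functional cell types, to ask
whether the types are anatomically organized (patches, depth gradients),
and to ask how the collicular representation relates to the retinal one.

The pipeline is: delta-F/F preprocessing and reliability gating →
per-neuron selectivity indices → a 54-dimensional sparse-PCA feature
matrix → Gaussian-mixture clustering with BIC model selection and
subsampling stability analysis → spatial point-pattern statistics →
linear decomposition of type responses onto a retinal ganglion cell
(RGC) response bank. A synthetic-data generator emulates the statistical
structure of such recordings so that every stage can be validated
without access to raw recordings.

## Preprocessing

Raw somatic fluorescence is corrected for out-of-focus neuropil
contamination as `F_true = F_raw − r·F_neuropil` with `r = 0.7` by
default, detrended by subtracting the 8th-percentile value in a 15 s
sliding window (truncated, not reflected, at the trace edges), and
converted to delta-F/F against the mean grey-screen fluorescence.
A neuron's response reliability for one stimulus is scored by

SNR = Var over time of the repeat-averaged response / time-average of the across-repeat variance,

computed on the time × repeat trial matrix. Neurons whose best
per-stimulus SNR does not exceed 0.35 are excluded. A constant matrix
gives 0/0; we flag it undefined and let it fail the gate. The gate is
applied to detrended delta-F/F traces.

## Selectivity indices

Most indices share the two-sided contrast `(a − b)/(a + b)` of two
non-negative peak responses, so we rectify component peaks at zero
before forming the ratio; this pins every such index inside [−1, 1].
The response to motion (RtM) is deliberately signed — it is the
moving-bar response with the largest absolute value, negative for
motion-suppressed neurons — as are the two post-modulation readouts
(RaFM, RaAM), which measure the response at the sample nearest 1.6 s
after the end of the frequency / amplitude modulation minus the mean
over the grey segment preceding that modulation. Direction and
orientation selectivity are the normalized response-weighted vector
sums of the twelve-direction tuning curve at the first and second
angular harmonic. The preferred direction is the direction of the
largest response *magnitude* (signed): for motion-suppressed neurons
the rectified peaks are all near zero and their argmax is pure noise,
whereas the deepest suppression direction is well defined. Peak-extraction windows are derived from the protocol
segment schedule (e.g. the low-frequency component of the FSI is the
peak in the first 3 s of the frequency modulation, the high-frequency
component the peak in its last 2 s); the habituation index compares
single-trial peaks of the first and tenth expanding-disc repeats; ties
in the best stimulation size go to the smallest size.

Receptive fields are fit with the seven-parameter rotated 2-D Gaussian
(amplitude, two axis SDs, rotation, center, offset) by
Levenberg–Marquardt least squares from two moment-based starts. We use
the raw LM interface rather than a nonlinear-regression wrapper because
circular fields make the rotation parameter unidentifiable — the
Jacobian is singular at the optimum, which is harmless to LM but fatal
to wrappers that post-process the fit. RF size is the area at a tenth
of maximum, `π·2·ln10·B·C`; fits with `R² < 0.5` are flagged invalid
and excluded from RF-based statistics. On- and Off-polarity maps can be
fit separately; the fit with the higher `R²` is reported.

## Feature construction

For clustering we use the responses to the moving bar (preferred
direction only), the looming pair, the chirp, the color flash and the
size series. Repeat-mean traces are lightly smoothed (3-frame moving
average, configurable) so the normalizing range is estimated stably.
Bar and looming responses are aligned on their extremum by circular
shift (removing receptive-field-position timing differences); in the
default `auto` mode the trough is used only when it clearly dominates
the peak (|min| > 1.5 |max|) — without that margin the alignment of
weak or suppressed responses flips between peak and trough from noise
alone, splitting one response type into two artificial shape modes.
Every response is then normalized to [0, 1] per neuron and stimulus. Each
block is reduced by sparse PCA — 6/6/20/8/10 components — and the 50
weights are concatenated with HI, DSI, OSI and MSI, then each of the 54
columns is z-scored. Missing index values (e.g. DSI of a neuron with no
rectified bar response) are imputed with the column mean before
z-scoring.

Our sparse PCA extracts components one at a time by thresholded power
iteration: power steps toward the leading right singular vector of the
deflated residual alternate with hard thresholding that keeps the
largest-magnitude half of the entries (the sparsity fraction is
configurable), followed by projection deflation; weights are the joint
least-squares solution given the components. This yields unit-norm,
near-orthonormal, sparse component rows, deterministic output, and a
reconstruction error that is non-increasing in the number of
components. The data blocks are not column-centered before
factorization, so `D ≈ XF` holds for the responses themselves.

## Clustering and model selection

The feature matrix is fit with a K-component Gaussian mixture by EM.
Covariances are full by default, with a ridge of 1e-6 on the diagonal
(diagonal covariance is available in the configuration). Each restart
is seeded kmeans++-style and refined by Lloyd iterations to
convergence before EM begins — full-covariance EM in 54 dimensions is
sensitive to its starting partition, and Lloyd steps are cheap. Each
random restart runs a capped number of EM iterations (default 15); the
best restart by log-likelihood (equivalently BIC, since K is fixed) is
then run to convergence at a relative log-likelihood tolerance of 1e-4
or 500 iterations. The default of 20 restarts is a desk-scale setting;
published analyses of this kind use up to 1000, and the count is a
plain configuration entry. K is selected by minimizing
`BIC = −2 lnL + k ln n` over K = 2..50 (also configurable), with
`k` counting weights (K−1), means (K·d) and covariance parameters.
The pipeline's model-selection scan uses diagonal covariances by
default and the full-covariance model remains available per fit; the
next paragraph explains why.

A note on what BIC can and cannot resolve in this regime. With full
covariances in d = 54, one component costs ~1540 parameters, i.e. a BIC
penalty of roughly `1540·ln n`. Merging two clusters that differ only
in their means inflates the merged covariance along a single
eigendirection, so the likelihood cost of the merge grows only
logarithmically with the separation — for any realistic separation it
never beats the penalty at n of a few thousand. BIC therefore resolves
the cluster number only when clusters also differ in covariance
*shape*, so that a merged component must inflate its determinant across
many dimensions at once. Functional types do differ that way: each type
expresses its own response motifs strongly and variably, so its
within-type variance concentrates on its own feature dimensions. Both
synthetic generators encode this structure explicitly (see below).
Well-separated but homoscedastic isotropic mixtures are exactly the
case where BIC under-selects, and no tuning of the EM changes that.

A diagonal-covariance mixture inverts the trade-off: it cannot absorb
a mean separation into a rotated covariance, so merging two clusters
inflates the variance of *every* dimension in which they differ, and
its per-component penalty is ~14x smaller (2d + 1 versus ~d²/2
parameters). On the pipeline's feature matrices, full-covariance BIC
under-selects severely while diagonal-covariance BIC tracks the
generative type count closely, at the cost of a modest tendency to
over-split types whose within-type variation is correlated across
features (the diagonal model can only represent such elongation by
extra components). The pipeline therefore scans K with diagonal
covariances by default, and the subsampling-stability stage is the
corrective for the residual over-splits: subclusters of one true type
are exactly the clusters with low Jaccard stability and high mutual
co-association, so the merge rule removes them, and the pipeline's
final type count is the merged count, not the raw BIC argmin.

Full covariance also needs enough neurons per cluster: below about
d + 1 = 55 members the within-cluster scatter is rank-deficient and
only the ridge keeps components proper. The desk-scale simulations are
sized so that the expected cluster occupancy stays well above that
(n = 3000 for 24 types).

## Stability analysis

With the selected K, the dataset is subsampled to 90% (1000 times in
the published setting; the desk default is in the configuration) and
refit. Each full-data cluster is scored by the mean, over subsamples,
of its best-match Jaccard similarity |∩|/|∪| with the subset clusters,
with neurons absent from a subset excluded from both sets. As printed
in its source, the similarity formula has union and intersection
inverted, which would contradict its own "below 0.5 is unstable" rule;
we implement the standard Jaccard coefficient. Clusters with JSC < 0.5
are merged into the cluster with which they share the highest
between-cluster co-association rate if that rate exceeds 35%, else
retained and flagged unstable. Unstable clusters are processed in
order of increasing JSC and rates are not recomputed after a merge.
The co-association matrix counts, for each pair of neurons, the
fraction of runs containing both in which they share a cluster; its
cluster-wise average is the between-cluster rate. The type dendrogram
applies Ward's minimum-variance linkage to the Euclidean distances
between cluster means; its first split defines Group 1 / Group 2.

## Anatomical statistics

Sessions with more than 5 neurons in the field of view enter the
spatial analyses; the region of interest is the convex hull of all ROI
positions. The density recovery profile (DRP) of a type histograms, in
10 µm annuli out to 300 µm (defaults), the same-type neighbor counts
around each reference cell and divides by the mean annulus area clipped
to the hull. We compute the clipped areas in closed form (edge-by-edge
decomposition of the disc-polygon intersection into triangle and
circular-sector parts, in compiled code) rather than by Monte-Carlo
sampling — exact, deterministic, and fast enough to run hundreds of
profiles in tests. The density ratio compares mean density within half
an RF diameter to the 0.5–1 diameter annulus, with the RF diameter
taken as the equivalent-circle diameter `2·√(RFS/π)` of the type's mean
valid RF size and 1 mm of SC corresponding to 88 degrees. The
cross-type density D(i, j) normalizes observed neighbor counts within
50 µm by the count expected under uniformity; we use the per-disc
expectation summed over reference cells (not the union of discs), since
neighbor counts accumulate with multiplicity — with a union normalizer
D would exceed 1 under uniformity instead of calibrating to 1. The
normalized distance between two types divides the centroid distance by
the mean of the two mean within-type pairwise distances; separation is
tested by shuffling labels within the pooled pair (bootstrap p = the
fraction of shuffles reaching the observed normalized distance),
qualifying sessions need at least 10 neurons of both types, and a pair
is separated when every qualifying session has p ≤ 0.01 (the stricter
of the two thresholds stated in the source material; 0.05 is available
via configuration). Depth composition uses bins 0–100, 100–200,
200–350 µm and a chi-square independence test without continuity
correction.

## Retina comparison

Each type's mean chirp+color response is approximated as an
unconstrained linear combination of the RGC bank rows by least squares;
the prediction error is the normalized residual `‖Xa − y‖²/‖y‖²`.
Response vectors are scaled to unit norm before fitting (recorded in
the output); the error is invariant to positive rescaling of the
response either way. Per RGC type, a Welch two-sample t-test compares
its weights across Group-1 versus Group-2 SC types. Representation
dimensionality is compared by PCA explained-variance curves (rows =
types), with row-resampling bootstrap SDs.

## The synthetic generators

`make_archetypes()` builds a bank of functional types, and
`simulate_dataset()` renders a population from it. Design choices worth
knowing about:

* **Event-kernel templates.** Every stimulus-evoked response is a
  scaled copy of a single calcium impulse kernel — an exponential decay
  (reference time constant 0.6 s, GCaMP6f-like) truncated at 1.25 s,
  placed exactly on the 4.8 Hz frame grid. The truncation is shorter
  than every gap between peak-measurement windows, so event responses
  never leak into one another's windows, and a window peak equals its
  event amplitude exactly. Designed peak-ratio indices (HI, LSI, MSI,
  CSI, FSI, SSI, BGI) are therefore recovered from noise-free templates
  to machine precision, which is what the index-correctness tests
  assert. The cost of this controllability is realism: templates are
  pulse trains, not graded waveforms, and the chirp modulation epochs
  are represented by onset/offset bursts rather than oscillations.
* **Transient-only flashes.** Responses decay to zero within the flash
  segment, so PFSI is 1 for every archetype. Sustained flash responses
  are a real-data feature the generator does not emulate; passing tests
  say nothing about PFSI-based discrimination.
* **Distinct types by stratified draws.** The selectivity parameters
  (CSI, FSI, BGI, LSI, HI, preferred size/direction, decay constant,
  response latency) are drawn Latin-hypercube style, one stratum per
  type: a taxonomy presumes distinct types, and i.i.d. draws can
  produce near-duplicates no classifier could separate. Per-type decay
  constants (0.45–0.95 s) and event latencies (0–0.55 s) give each type
  a temporal signature that survives the [0, 1] normalization.
* **Within-type heterogeneity.** Each neuron multiplies its archetype's
  event amplitudes by independent log-normal factors (`amp_jitter`,
  default 0.06 — small against the stratified between-type gaps) and
  one overall gain. This concentrates within-type variance in the
  feature dimensions the type expresses — the covariance-shape
  structure that makes BIC informative (see above). Amplitude jitter
  also spreads each type's measured indices around its target, as in
  real populations.
* **Noise calibration.** Additive i.i.d. Gaussian noise per frame and
  repeat, with the SD chosen per neuron and stimulus as
  `√(Var_t(template)/snr_target)`, so the measured reliability SNR
  matches the target in expectation (plus the ~1/N_repeats bias of the
  estimator). Zero noise reproduces the templates bit-exactly.
* **Anatomy.** One Gaussian patch center per (type, session) in a
  600 × 600 µm field, patch SD 200 µm — the middle of the observed
  150–250 µm patch scale; depths 0–350 µm with Group-1 types biased
  shallow. Genotype labels follow the 490/337/1085/720/485/297
  WT/Vglut2/Vgat/Tac1/Rorb/Ntsr1 mix; population sizes are
  configurable.
* **RGC bank.** 32 smooth random curves (Gaussian bumps plus
  low-frequency sinusoids) on the chirp+color time base, unit-norm and
  verified full-rank — a stand-in with the algebraic properties the
  decomposition needs, not a model of real RGC responses.

`simulate_feature_mixture()` generates labeled Gaussian mixtures
directly in the 54-dimensional feature space for clustering validation:
standard-normal means and tight cluster-specific diagonal covariances,
each cluster with its own sparse set of high-variance dimensions
(defaults: 12 active dimensions at SD 0.5 against SD 0.02), and an
optional coincident isotropic pair that forces a K-component fit to
split one cloud — the canonical unstable-cluster case for the
stability tests.

## Problem sizes and numerical choices

The test-suite simulations use n = 2000 observations for the
model-selection study (20 runs, target K cycling through 4/8/12,
scanning K ± 2 at 20 restarts), n = 3000 neurons from 24 archetypes at
SNR 2 for the end-to-end study (scan 2–40 at 10 restarts), 100
subsamples for stability, 100 homogeneous-Poisson realizations of 500
points for the DRP calibration, and 500 label-exchange runs for the
separation-test false-positive rate. These sizes were chosen so each
study estimates its quantity with useful precision while the whole
suite stays comfortably runnable on a laptop.

Degenerate inputs are handled by flags rather than errors wherever a
real dataset could produce them: 0/0 SNR, all-zero tuning curves,
constant traces, empty types in spatial matrices, sessions without
qualifying type pairs, non-converging or sub-threshold RF fits. Hard
errors are reserved for contract violations (mismatched lengths,
impossible component counts, non-positive baselines).

## Known limitations

* The generator emulates stimulus-locked responses only: no eye or
  locomotion signals, no photon-level noise model, no receptive-field
  position scatter (stimuli are rendered as if centered on every RF,
  so the 3×3 stimulus-location array of the experimental protocol and
  the nearest-location selection are not emulated).
* Real chirp responses contain oscillation-locked structure the
  pulse-train templates lack; sparse-PCA components learned from
  synthetic data are not interpretable as real response motifs.
* The RGC bank is synthetic; reproducing the real retina-to-colliculus
  weight structure requires the published RGC mean responses as an
  external input (`fit_rgc_weights_all` accepts any bank matrix).
* The merge rule is applied once, without recomputing stability scores
  after merging, matching its published description.
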