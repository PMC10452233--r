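---
title: "Methods: source-space power-envelope connectivity and network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-space power-envelope connectivity and network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`pecnet` implements a complete task-EEG functional-network analysis chain:

1. **Synthetic cohort generation** with planted, known envelope couplings
   and group effects (no public task-EEG cohort accompanies the method, so
   ground truth must be manufactured);
2. **Preprocessing**: zero-phase band filtering, downsampling to 256 Hz,
   common-average referencing, epoching on [-100, 500] ms with [-100, 0] ms
   baseline correction;
3. **Source estimation** by the weighted minimum-norm estimate (wMNE) with
   free orientations, collapsed to one scalar series per dipole;
4. **Orthogonalized power-envelope connectivity (PEC)** between all node
   pairs, aggregated to a region-of-interest (ROI) matrix whose row-major
   upper triangle is the per-subject feature vector (2278 features for the
   68-region Desikan–Killiany parcellation);
5. **Binary graph topology**: proportional thresholding (top 10% of
   weights) and five metrics — clustering coefficient CC, characteristic
   path length L, small-worldness σ, global efficiency and local
   efficiency — referenced against 100 degree-preserving, connected random
   networks;
6. **Group statistics**: Shapiro–Wilk/Levene gating, Kruskal–Wallis with
   Bonferroni-corrected pairwise rank post hocs for scalar metrics,
   edge-wise one-way ANOVA with Bonferroni correction over all edges for
   the PEC features, and a lobe-level (68 → 7 region) count of significant
   edges;
7. **Classification**: leave-one-subject-out cross-validation (LOOCV) with
   in-fold feature ranking (Corr, Fisher score, ReliefF, LARS path order),
   an accuracy curve over feature counts, argmax selection of the optimal
   feature count K, occurrence-rate feature ranking, and the full 4 × 4
   grid against logistic regression, AdaBoost, a decision tree and a
   random forest.

# The connectivity estimator

For band-limited analytic signals $X(t)$, $Y(t)$ (Hilbert transform via
FFT with mirror padding), the component of $Y$ orthogonal to $X$ at each
sample is

$$Y_{\perp X}(t) = \mathrm{Im}\!\left( Y(t)\, \frac{X(t)^*}{|X(t)|} \right),$$

which removes any zero-phase-lag (volume-conducted) share of $Y$. Power
envelopes are the squared magnitudes; after local smoothing they are
log-transformed, pooled across epochs, and one Pearson correlation is taken
per direction:

$$\mathrm{PEC}(a,b) = \tfrac12\left[\,r\big(\log P_{b\perp a},\ \log P_a\big)
                     + r\big(\log P_{a\perp b},\ \log P_b\big)\right].$$

Eq. (1)'s orthogonalization is asymmetric in $(X, Y)$; averaging the two
directed correlations is the standard symmetrization and is what makes the
"unique pairwise feature" count of a symmetric matrix meaningful.

## Envelope smoothing: order and cutoff

Two numerical decisions matter a great deal and are worth recording.

**Smoothing happens in the power domain, before the log.** For independent
carriers, the orthogonalized power is $|Y|^2 \sin^2\!\Delta\phi$ with
$\Delta\phi$ the fast phase difference. Left untreated, the
$\log\sin^2\!\Delta\phi$ term contributes variance $\pi^2/3$ per direction
(four times $\pi^2/12$, the variance of $\log|\sin U|$ for uniform $U$),
which attenuates a planted envelope correlation by roughly
$1/\sqrt{1 + 0.82} \approx 0.74$ — far outside any useful tolerance.
Averaging the *power* locally (zero-phase Gaussian filter; the kernel is
positive, so smoothed power remains positive) converts
$\sin^2\!\Delta\phi$ into a nearly constant local factor, and the log of
the smoothed power recovers planted couplings essentially unbiased.
Smoothing after the log instead leaves the heavy lower tail of
$\log|\sin|$ in place and measurably attenuates recovery (~0.73 at a
planted 0.8 in our calibration runs, versus ~0.78 with power-domain
smoothing).

**The default cutoff is half the band width.** The $\sin^2$ noise
decorrelates on the time scale of the band width $B$; physiological power
envelopes are far slower (the generator produces envelopes band-limited to
a tenth of the carrier centre frequency). A cutoff of $B/2$ averages
enough fast noise to make recovery accurate, while cutting it further
(stronger smoothing) increases a subtle leakage bias described next.
`env_lowpass` is exposed on every connectivity function.

## Leakage: what orthogonalization can and cannot remove

An exact zero-lag copy ($Y = cX$, real $c$) has an identically zero
orthogonal component. The degenerate constant envelope is reported as PEC
= 0 — the method's defined answer for pure volume conduction — while the
un-orthogonalized envelope correlation of the same pair is 1. (`NA` is
reserved for genuinely degenerate inputs, e.g. a constant reference
envelope.)

At finite sensor noise the cancellation is imperfect in a specific,
instructive way. For two sensors $Y_i = S + N_i$ seeing one source, the
orthogonalized power works out to approximately
$(n_{1\perp}\,|S|/|Y_1| + n_{2\perp})^2$: the *reference's own noise*
rotates the reference phase and is imprinted on the orthogonalized
component in proportion to the local signal strength. Its expectation is
$v\,(1 + |S|^2/|Y_1|^2)$, a factor that swings between $v$ (envelope dips)
and $2v$ (strong signal) and therefore correlates positively with the
shared envelope. Per-sample orthogonalization cannot remove this: one
sample cannot distinguish the source's phase from the reference's noisy
phase. With σ = 1 log-normal envelopes this residual is roughly
0.05–0.12 in the mean over seeds at sensor SNR 3–10, decreasing with SNR —
small compared to the un-orthogonalized correlation (> 0.9) but not zero.
The test suite asserts the mean-level bound and the exact-duplicate case;
an optional `ref_guard` argument (exclude the lowest reference-envelope
samples, which are the ill-conditioned ones for the division by $|X|$)
trades part of this bias against a mild range-restriction attenuation of
genuine couplings, and is off by default.

## Epoch handling

The analytic signal and envelope smoothing are computed per epoch (with
mirror padding trimmed afterwards), envelope samples are pooled across
epochs, and a single Pearson correlation is computed per direction.
Per-epoch correlations on ~155-sample epochs are far too unstable;
pooling is the documented choice where the upstream description is silent.
The filter chain runs on the continuous record *before* epoching, so
filter transients never sit inside an epoch.

# The synthetic cohort

Each ROI carries $x(t) = e^{\,\varepsilon(t)}\,c(t)$:

- $\varepsilon(t)$ — a smooth standard-normal process (Gaussian low-pass
  filtered white noise, cutoff = carrier-band centre / 10, restandardized),
  so the *log*-envelope is exactly Gaussian — matching the log transform
  the connectivity stage applies. Planted couplings are correlations
  between ROI log-envelopes; the generator whitens the latent processes
  empirically and then colors them with the Cholesky factor of the target
  correlation matrix, so the realized sample correlation equals the
  requested ρ (well within the ±0.02 bookkeeping tolerance).
- $c(t)$ — a constant-modulus, random-phase carrier: band-passed white
  noise whose analytic phase is kept and whose modulus is normalized away.
  Raw band-noise carriers would add their own chi-squared envelope
  fluctuations (variance ≈ 0.41 on the log scale), attenuating every
  planted correlation by a known factor and making the generator's ground
  truth unrecoverable by construction; the constant-modulus carrier keeps
  the planted log-normal envelope as *the* envelope. The price is mild
  FM-like spectral sidebands outside the nominal band (the spectrum
  concentration test allows for them). Carrier phases are independent
  across ROIs, so any zero-lag correlation downstream comes from lead-field
  mixing alone.

Each ROI feeds `dipoles_per_roi` dipoles (default 3) that share the ROI
signal plus small private band-limited noise (10% RMS), exercising the
vertex-pair averaging of the ROI aggregation. The synthetic lead field
gives each dipole an orthonormal random 3-column triad (smoothed over the
sensor index so neighboring sensors see similar gains) scaled by a
log-normal depth-like gain, and a fixed random orientation used when
projecting scalar sources to sensors. Sensor noise is white Gaussian,
scaled to a total signal-to-noise power ratio `snr`. Group effects
multiply the planted ρ of selected edges per group; per-subject seeds
derive deterministically from the master seed, so a cohort regenerates
identically from `(config, seed)`.

What the generator does *not* emulate: ocular/muscle artifacts (the manual
ICA step has no synthetic counterpart; an amplitude-threshold epoch
rejection stands in for visual inspection), realistic head geometry and
volume-conductor physics (lead fields are random smooth gains, not BEM
solutions), 1/f broadband background, and non-stationarity across the
session. Passing tests therefore demonstrate the *machinery* — leakage
suppression, coupling recovery, metric correctness, statistical
calibration, no-leakage cross-validation — not performance on real
patient EEG.

# Source estimation

The inverse operator is
$K = R L^\top (L R L^\top + \lambda I)^{-1}$ with $R$ the diagonal
depth-weighting matrix (per dipole, $1/\sum \lVert\text{column}\rVert^2$
over its three orientation columns) and
$\lambda = \delta\, \mathrm{tr}(L R L^\top)/n_{\text{sensors}}$, which
makes the published $\delta = 1/100$ dimensionless (an SNR-style scaling
of the regularizer to the per-sensor model covariance). The noise
covariance is identity (no empty-room recording exists in a task
protocol). Depth weights are capped at ten times the smallest weight:
unbounded inverse-norm weights over-compensate weak dipoles, and in
recovery simulations the amplified noise at a low-gain dipole can
out-power the truly active one; the cap is the conventional remedy.

The free-orientation estimate is collapsed to a scalar per dipole by the
Euclidean norm over the three components — the literal published order.
The norm rectifies the series (non-negative, frequency-doubled), which is
acceptable here because the envelope stage only consumes magnitudes; an
SVD-based dominant-orientation collapse (`collapse = "svd"`), which
preserves oscillatory sign structure, is provided as a clearly marked
alternative.

# Graph topology

Proportional thresholding keeps the $K = \lceil 0.10 \cdot N(N{-}1)/2
\rceil$ largest upper-triangle weights (228 edges for 68 nodes), with ties
broken deterministically by row-major index. Conventions for sparse
graphs: nodes of degree < 2 contribute 0 to CC and local efficiency
(their denominators vanish); L averages reachable ordered pairs only and
reports the unreachable fraction; global efficiency treats unreachable
pairs as zero efficiency. When thresholding disconnects the graph, σ is
computed on the largest connected component (the degree-preserving null
requires connectedness) and the unreachable fraction flags the situation.
The random ensemble uses Maslov–Sneppen double-edge swaps (10·|E|
attempts, rejecting self-loops/multi-edges) with up to 100 restarts until
connected. Shortest paths come from breadth-first distances; the test
suite checks every metric against an independent hand-coded BFS/triangle
oracle on hundreds of exhaustively checkable small graphs.

# Group statistics

The Shapiro–Wilk (per group) and Levene (mean-centred, the classical
form) screens gate parametric versus non-parametric branches. Scalar
comparisons use Kruskal–Wallis with tie correction; the post hoc is
pairwise Wilcoxon rank-sum with p-values multiplied by the number of group
pairs and capped at 1 (a Dunn-style choice — the upstream description
names only "Bonferroni"). Edge-wise comparisons use a vectorized one-way
F-test per edge (verified against `aov` column by column) with
`p_corrected = min(1, p · n_edges)` within the band — the narrowest family
consistent with per-band reporting. Edges with zero within-group variance
but distinct means are flagged degenerate and reported significant. The
68 → 7 grouping ships as `dk_roi_table()`: the 34 Desikan–Killiany parcels
per hemisphere assigned to frontal, temporal, parietal, occipital, PCC,
ACC and insula.

# Classification

Feature rankings are deterministic: Corr (absolute Pearson correlation
with the label), Fisher score with population variances, ReliefF (k = 10
nearest hits/misses on range-scaled Manhattan distances, every training
subject used — no sampling, hence no seed sensitivity), and LARS (order of
entry into the lasso regularization path computed by `glmnet`, which
coincides with least-angle entry order in practice; never-entering
features append by |corr|). Zero-variance features always rank last.

Classifier hyperparameters (unstated upstream, recorded here): ridge
logistic regression at penalty 1/n; AdaBoost.M1 with 50 depth-1 `rpart`
stumps (implemented in-package — no boosting package is a dependency);
an unpruned decision tree (`cp = 0`, `minsplit = 2`); a 100-tree random
forest. Per-fold classifier seeds derive from the run seed, so a
`cv_result` reproduces bit for bit.

The LOOCV loop ranks features on the training subjects only — corrupting
a held-out subject's features provably never changes that fold's ranking
(asserted by a mutation test). The default feature-count grid is dense
1..50 then log-spaced to F; passing `feature_grid = 1:F` reproduces the
literal exhaustive loop. The optimal K is the argmax of the mean accuracy
curve with smallest-K tie-break; the final feature set is the K features
most frequent among the folds' top-K selections, ties broken by better
mean training rank, then index. SEM is the population standard error of
the per-fold 0/1 accuracies, $\sqrt{p(1-p)/N}$.

One property of the published framework deserves a caution: K is selected
from the same accuracy curve that the held-out subjects produced, which
biases the accuracy *at K* optimistically under the null (label
permutations on pure-noise features center near 0.55–0.60 rather than
0.50 for small grids). The framework is implemented as published; the
permutation-null test therefore checks that chance level lies inside the
permutation distribution of the accuracy at K rather than asserting its
mean equals 0.5. A nested (inner-loop) selection mode was considered and
deliberately not added: it would no longer be the published procedure, and
the bias is documented instead.

# Problem sizes and determinism

The test and acceptance runs use desk-scale sizes chosen to make every
property measurable in minutes: coupled-pair recovery at 60 s × 256 Hz
with up to 100 replicates; leakage over 50 seeds; graph oracles over 500
random graphs of ≤ 7 nodes; σ self-consistency over 20 Erdős–Rényi graphs
(N = 50) and a 68-node Watts–Strogatz lattice, each against 100-network
nulls; statistical calibration over 200 null cohorts of 200 edges
(n = 40/group) and a planted-effect cohort with the full 2278 edges; the
classification grid on 20 subjects. The demonstration workflow under
`analysis/` runs a 3 × 6-subject cohort with 12 ROIs end to end. All
stages accept explicit seeds, snapshot and restore the caller's RNG
state, and regenerate byte-identical outputs from `(config, seed)`.

# Known limitations

- The common-source leakage floor described above (~0.1 at low SNR) is a
  property of per-sample orthogonalization, not of this implementation;
  windowed regression-based orthogonalization would reduce it but is a
  different estimator.
- ROI aggregation averages vertex-pair PECs; with few dipoles per ROI and
  source-space leakage from the inverse, the null-edge baseline at ROI
  level is positive, which compresses group contrasts in small cohorts
  (visible in the `analysis/` demonstration, where edge-wise Bonferroni
  tests at n = 6/group find nothing although classification succeeds).
- The wMNE assumes identity noise covariance; no dSPM/sLORETA variants
  are provided.
- Binary metrics only; no weighted-graph variants, nodal exports,
  modularity or rich-club analyses.
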