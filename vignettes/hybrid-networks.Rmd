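---
title: "Hybrid high-order FC networks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid high-order FC networks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyfcnet)
```

## The three network levels

Resting-state functional connectivity (FC) is usually summarised as the
Pearson correlation between two regions' BOLD time series. hyfcnet builds
three nested descriptions of a subject's connectome from an ROI-averaged
time-series matrix $X \in \mathbb{R}^{L \times R}$ whose columns have been
centred and scaled to unit Euclidean norm:

* **Low-order network** $C = X^\top X$ — the ordinary $R \times R$
  correlation matrix (`fc_low()`).
* **High-order network** $H = \tilde C^\top \tilde C$ — the "correlation of
  correlations": entry $(i, j)$ is the Pearson correlation between the
  $i$-th and $j$-th *columns* of $C$, i.e. between two whole-brain
  connectivity profiles (`fc_high()`; $\tilde C$ is the column-standardized
  $C$).
* **Associated high-order network** $A = \tilde C^\top \tilde H$ — the
  inter-level coupling between each low-order profile and each high-order
  profile (`fc_assoc()`). The raw product is asymmetric and is symmetrized
  as $(A + A^\top)/2$ by default.

Two conventions deserve a note because the matrix algebra forces them.
First, the profile columns $c_i$ and $h_i$ include their diagonal
self-entries: the products $C^\top C$ and $C^\top H$ literally operate on
full columns, and excluding the diagonal would break the stated identities.
Second, $H$ is re-standardized column-wise before entering $A$, so every
entry of $A$ is a genuine Pearson correlation in $[-1, 1]$ rather than an
unnormalized inner product; algebraically $A \ne \tilde C^\top (\tilde
C^\top \tilde C)$. No Fisher r-to-z transform is applied anywhere.

Degenerate windows (a constant ROI signal) raise classed errors naming the
ROI and window instead of propagating NaN — silent NaN would poison the
downstream FFT and graph features.

## Dynamics: sliding windows and spectral networks

A scan of $P$ volumes is segmented into $K = \lfloor (P - L)/S \rfloor + 1$
overlapping windows of $L$ volumes stepped by $S$
(`sliding_windows()`), and the three networks are computed per window. The
package default is $L = 70$, $S = 1$: at a repetition time of 3 s this is a
210-s window, long enough to exceed the 100-s wavelength of a 0.01 Hz
high-pass cutoff, and it yields $K = 61$ windows from the 130 usable
volumes of a 140-volume scan. The static network is the limiting case
$L = P$ (`build_networks(x, spec = NULL)`).

Window-wise features have no temporal correspondence across subjects, so
each edge's length-$K$ fluctuation series $g_{ij} = [C^1_{ij}, \dots,
C^K_{ij}]$ is moved to the frequency domain: `power_spectrum()` takes the
squared magnitude of its DFT at the one-sided bins $q = 0..\lfloor K/2
\rfloor$, giving $Q = \lfloor K/2 \rfloor + 1$ time-invariant networks
$Z^1..Z^Q$ per type (`spectral_stack()`). Choices made here, all
config-exposed:

* *Raw DFT power*, no taper, no detrending, no $1/K$ normalization — the
  simplest reading of "FFT into power spectra". `demean = TRUE` removes the
  series mean first; `magnitude = TRUE` switches $|\cdot|^2$ to $|\cdot|$.
* *The DC bin is retained.* It carries the mean (static-like) FC level, and
  discriminative information in slow FC fluctuation concentrates at low
  frequencies; there is no principled exclusion rule. For odd $K$ (61)
  there is no exact Nyquist bin and $Q = 31$.
* Bin $q$ sits at $(q-1)/(K \cdot S \cdot TR)$ Hz, bounded by the Nyquist
  $1/(2 S \cdot TR)$ of the window-sliding process.
* Only upper-triangle edges are transformed; symmetry fills the rest
  bit-identically.

## Graph features and their reduction

Each spectral network is summarised per node by the weighted local
clustering coefficient
$$f_i = \frac{2 \sum_{j \in \Omega_i} Z_{ij}^{1/3}}{v_i (v_i - 1)},
\qquad \Omega_i = \{ j \ne i : Z_{ij} > 0 \},$$
implemented exactly as printed (`wlcc()`): the sum runs over the direct
neighbors, with no requirement that the neighbors form closed triangles
(the triangle-based Onnela form is a different statistic; the as-printed
form is what this pipeline uses). Any strictly positive weight counts as an
edge — no sparsification threshold. Isolated or single-neighbor nodes
($v_i \le 1$) score 0, which only arises for pathological inputs since
spectral weights are generically positive. The per-node values of all $Q$
networks concatenate frequency-major into a $Q \times R$ feature vector
(`wlcc_features()`). WLCC is cube-root homogeneous — scaling all weights by
$s$ scales every feature by $s^{1/3}$ — a property the tests exploit. For
the static pathway there is no spectrum; the coefficient is taken on the
static network after an absolute-value edge transform (correlations can be
negative; `static_features()`).

With $N$ subjects the $N \times QR$ feature matrix of each network type is
reduced in two supervised-safe stages (`fit_selection()`): feature-wise
standardization and PCA to the at-most-$N{-}1$ components with nonzero
eigenvalue (relative cutoff $10^{-10}$), then a classical LASSO — an
L1-penalized least-squares regression of the $\pm 1$ labels on the
component scores (glmnet, coordinate-descent tolerance $10^{-7}$) —
keeping the components with nonzero coefficients. Standardization before
PCA is on by default because WLCC magnitudes differ strongly across
frequency bins (the DC bin dwarfs the rest). The penalty grid is the usual
20-point log-spaced path from $\lambda_{\max}$ (the smallest penalty
selecting nothing) down to $10^{-3}\lambda_{\max}$. If the chosen penalty
selects nothing, the fit falls back to the smallest path value selecting at
least one component, with a loud message. All statistics (means, scales,
loadings, selected set) are estimated on training subjects only and applied
frozen to test subjects (`apply_selection()`).

## Multi-kernel SVM and nested LOOCV

Each network type's selected features are scaled per subject to unit
Euclidean norm — a normalization that uses no training statistics and is
therefore leakage-safe — and turned into a linear Gram matrix
(`linear_gram()`). The three kernels are fused as
$\tau_1 K_L + \tau_2 K_H + \tau_3 K_A$ with $(\tau_1, \tau_2, \tau_3)$ on
the probability simplex (`composite_kernel()`), searched on a 0.1-step grid
of 66 points (`weight_grid()`), fine enough to resolve interior optima
such as (0.3, 0.5, 0.2). Classification uses a soft-margin SVM with $C = 1$. The solver is
libsvm (via e1071); `svm_fit_predict()` accepts a precomputed kernel and
factorizes it exactly through an eigendecomposition into virtual feature
vectors whose linear kernel reproduces the input, so the solution is the
standard precomputed-kernel dual. Tests cross-check the decision values
against an independent precomputed-kernel implementation (kernlab).

`nested_loocv()` implements the evaluation protocol: every subject is held
out once; an inner leave-one-out loop on the remaining $N - 1$ picks the
hyperparameters, which are then refitted on all $N - 1$ to score the
held-out subject. Two design choices the protocol leaves open:

* *Two-stage search.* The LASSO penalty is chosen per network type by that
  type's single-kernel inner accuracy first, and the kernel weights are
  searched afterwards at the chosen penalties. A joint grid is
  combinatorially heavy and adds nothing at these cohort sizes; the search
  order is config-overridable in the sense that any `tau_grid` can be
  supplied directly.
* *Deterministic ties.* Inner accuracy ties resolve toward the larger
  low-order weight (then larger second weight), and toward the smaller
  penalty. The whole procedure is deterministic given the data — repeated
  runs are bit-identical, which the leakage tests rely on.

Aggregate metrics are accuracy, sensitivity ($TP/(TP{+}FN)$), specificity
($TN/(TN{+}FP)$) and the rank-statistic AUC with ties counting one half
(`classification_metrics()`). Group separability maps use the squared
point-biserial correlation with the population (divide-by-$n$) standard
deviation, which makes $r^2$ exactly the squared Pearson correlation with
0/1 labels (`pointwise_r2()`, `edge_separability()`,
`spectrum_separability()`); zero-variance edges are reported as missing,
not zero.

## What the synthetic cohorts emulate

`simulate_cohort()` generates two-group cohorts from a latent-factor model:
ROIs are partitioned into modules, and every ROI in module $m$ follows
$$x_i(t) = \sqrt{\rho(t)}\, u_m(t) + \sqrt{1 - \rho(t)}\, e_i(t)
 + \sigma\, \eta_i(t),$$
so the within-module signal coupling equals
$\rho(t) = \rho_0 + a \sin(2\pi f t + \phi)$, clipped to $[0, 0.95]$, with
a group-specific amplitude $a$ and frequency $f$ and a uniform random phase
per subject. The defaults mirror a typical small rs-fMRI case-control study at desk
size: 15 subjects per group, 30 ROIs, 130 volumes at TR = 3 s, observation
noise $\sigma = 0.3$, baseline coupling 0.3, and two modules — at a coarse
30-ROI parcellation, two large intrinsic systems is a reasonable idealized
topology, and it matters for detectability: with many small modules most of
a node's neighbors carry no planted signal and the clustering coefficient
dilutes the effect. The default modulation frequency $1/183$ Hz is the
fundamental of the default 61-window edge-series spectrum.

Two presets define the study conditions. The **null** preset (amplitudes
0) plants no group difference and is used to verify that nested LOOCV is
calibrated at chance. The **strong** preset gives cases amplitude 0.9 and
controls 0: coupling then cycles deeply between collapse and saturation.
This amplitude was chosen at design time so the planted effect survives
the two low-pass bottlenecks between generator and classifier — the 210-s
window acts as a moving-average filter that attenuates a bin-1 sinusoid to
roughly 12% of its amplitude, and the cube root in the WLCC compresses
power ratios — while the asymmetric clipping of a deep modulation also
lifts the mean coupling, planting a correlated static-like difference, as
a strong dynamic effect plausibly would.

What the generator does *not* emulate: hemodynamic convolution, scanner
drift, motion artifacts, inter-subject parcellation mismatch, or
heterogeneous effect topographies. Passing the simulation suites therefore
demonstrates that the machinery recovers the kind of time-varying
covariance structure it targets, not that any particular clinical accuracy
would be attained on real data — accuracies on real patient cohorts depend
on data the package does not ship and cannot be reproduced from
simulation.

## Problem sizes and runtime choices

The test and acceptance suites run the full protocol at the study's window
arithmetic ($P = 130$, $L = 70$, $S = 1$, $K = 61$, $Q = 31$, $R = 30$,
$N = 30$). The null-calibration suite averages 20 independent null cohorts
and uses a coarser hyperparameter grid (kernel-weight step 0.5, 8-point
penalty path down to $10^{-2}\lambda_{\max}$): chance-level calibration is
a property of the protocol, not of the grid resolution, so the smaller grid
is a pure runtime choice. The strong-effect and fusion comparisons run the
full default grid. Property tests (oracle equivalence, permutation
equivariance, Parseval, leakage mutation) run at small $R$ where exhaustive
or brute-force oracles are feasible.

## Known limitations

* The LASSO operates in PCA-component space, so its sparsity does not map
  back to sparse sets of raw WLCC features; selected-component loadings are
  exported for inspection instead.
* With $D \gg N$, a discriminative direction carried by a *single* raw
  feature is dense in component space and the pipeline may not isolate it;
  effects spread over many correlated features (the realistic case) load
  on leading components and are found reliably.
* Associated-network symmetrization discards the asymmetric half of the
  inter-level interaction; the raw matrix is available via
  `symmetrize = FALSE`.
* The inner-loop objective is accuracy; with small $N$ its granularity is
  coarse and ties are common (hence the deterministic tie-break rules).
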