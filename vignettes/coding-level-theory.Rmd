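---
title: "Coding levels, kernels and generalization in expansion-layer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding levels, kernels and generalization in expansion-layer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulearn)
```

## The model

Cerebellum-like circuits share an architecture in which a small input layer
(mossy fibers, or olfactory projection neurons in the insect mushroom body)
fans out onto a vastly larger expansion layer (granule cells, Kenyon cells)
that is read out by a single downstream neuron (a Purkinje cell, a mushroom
body output neuron). `granulearn` models this as

\[ h = \phi(J^{\mathrm{eff}} x - \theta), \qquad
   J^{\mathrm{eff}} = J A, \qquad \phi(u) = \max(u, 0)^p , \]

where \(x \in \mathbb{R}^D\) is a point in a low-dimensional *task
subspace*, \(A\) (N x D) embeds the task variables into input-layer
activity, \(J\) (M x N) is the input-to-expansion connectivity, and the
shared threshold \(\theta\) sets the **coding level** \(f\): the average
fraction of expansion-layer units with strictly positive activity. A linear
readout \(\hat f(x) = w \cdot h(x)\) (plus `sign` for categorization) is
trained on \(P\) examples and judged on held-out inputs, by error rate for
categorical targets and by relative mean squared error
\(\mathbb{E}[(f - \hat f)^2] / \mathbb{E}[f^2]\) for continuous ones.

The package asks one central question: **which coding level minimizes the
generalization error, and how does the answer depend on the task?**

## Task families

All data are synthetic; each generator is seeded and bit-reproducible.

* **Random categorization** (`sample_random_categorization`): \(P\)
  patterns with i.i.d. \(\mathcal N(0, 1/D)\) coordinates and random
  \(\pm 1\) labels. Generalization is probed with one noisy copy of each
  training pattern, \(\hat x = \sqrt{1-\epsilon^2}\,x + \epsilon\,\eta\),
  so the train/test overlap is \(\sqrt{1-\epsilon^2}\). Defaults follow
  the flagship conditions \(D = 50\), \(\epsilon = 0.1\).
* **Gaussian-process targets** (`sample_gp_task`): inputs uniform on the
  unit sphere \(S^{D-1}\); the target is one joint draw from a GP with
  squared-exponential covariance
  \(C(x, x') = \exp(-\lVert x-x'\rVert^2 / 2\gamma^2)\). The length scale
  \(\gamma\) dials task smoothness continuously, from nearly random
  (\(\gamma = 0.25\)) to nearly linear (\(\gamma = 2\)); the joint draw
  over train and test points uses a Cholesky factorization with a
  diagonal jitter starting at \(10^{-10}\) and escalating tenfold at most
  three times.
* **Two-joint arm** (`sample_arm_task`): the forward-model task. Inputs
  are unit-normalized 6-vectors (two joint angles around an operating
  point of \(\pi/4\), two angular velocities, two torques, with scales
  0.1, 0.1 and 1); the two-dimensional target is the Cartesian hand
  displacement after integrating the planar two-segment dynamics
  \(M(\vartheta)\ddot\vartheta + C(\vartheta, \dot\vartheta)\dot\vartheta
  = u\) for \(\delta = 0.2\) s. We use the Lagrangian-consistent symmetric
  inertia matrix (the lower-arm center of mass enters every coupling
  term), a fixed-step RK4 integrator with \(dt = 1\) ms (verified by
  step-halving and by energy conservation in the frictionless limit), and
  constant torques over the horizon. Test states are fresh draws, matching
  the other continuous tasks.
* **VOR adaptation** (`sample_vor_task`): head velocity \(v \in [-1, 1]\)
  drives 24 exponential mossy fiber tuning curves
  \(n_j(v) = g_j e^{v r_j} + b_j\) (gains on 6 points in [0.1, 1],
  direction preferences \(\pm 1\), baselines 0 or 1); targets are the 25
  piecewise-linear Purkinje cell tuning curves from all slope pairs on a
  5-point grid over \([-2, 2]\) with value 0.1 at the breakpoint \(-0.2\).
  These tasks bypass the embedding (`input_mode = "direct_input_layer"`).
  The split samples 100 velocities and trains on a random 30 of them; the
  generator exposes both counts because only the pair (100, 30) is fixed
  by convention, not derivable.

## Networks and coding-level control

`expansion_network` supports dense Gaussian weights (the analytically
tractable case; when `N` is omitted the effective weights are drawn
directly as an M x D Gaussian matrix, which is exactly equivalent and
independent of N), sparse excitatory connectivity with in-degree \(K\)
(weights all 1, or half-normal for the heterogeneous variant) with
optional global feedforward inhibition that subtracts the grand-mean
excitatory weight, and two embeddings: random orthonormal columns
(distributed) or disjoint 0/1 blocks (clustered, one task variable per
block of input neurons).

The threshold is calibrated empirically: \(\theta\) is the pooled
\((1-f)\) quantile of preactivations over calibration patterns
(`calibrate_threshold`), which works identically for every connectivity
kind; for dense Gaussian weights and unit-norm inputs it converges to the
analytic value \(\Phi^{-1}(1-f)\), which the tests use as an oracle. The
measured coding level on held-out patterns is required to sit within 0.01
of the request. For clustered embeddings a per-pattern winner-take-all
rule (`winner_take_all`) fixes the active count at \(\lceil fM \rceil\)
exactly, with ties at the cutoff broken toward the lowest neuron index (a
unit tied exactly with the cutoff is kept as a member but carries zero
activity, since activities are measured relative to the cutoff).

## Kernel theory

In the wide-network limit the learning problem is kernel regression with
the dot-product kernel

\[ K(\rho) = \mathbb{E}\,[(u-\theta)_+^p (v-\theta)_+^p], \qquad
   (u, v) \sim \mathcal N\!\left(0, \begin{pmatrix} 1 & \rho \\
   \rho & 1 \end{pmatrix}\right). \]

`analytic_kernel` evaluates the defining expectation directly: the inner
conditional expectation has a closed form in truncated-normal moments for
integer \(p\), and the remaining one-dimensional integral is evaluated by
adaptive quadrature to near machine precision. We deliberately do not
reproduce any closed-form special-case expression beyond the zero-threshold
arc-cosine formula, which serves as a test oracle together with a
\(10^7\)-sample Monte-Carlo check: the expectation *is* the definition.

Under the uniform measure on \(S^{D-1}\) the eigenfunctions of any
dot-product kernel are spherical harmonics, and the Funk–Hecke theorem
reduces each eigenvalue to a one-dimensional integral of \(K(t)\) against
the degree-\(k\) ultraspherical polynomial under the overlap density
\((1-t^2)^{(D-3)/2}\). `kernel_eigenvalues` evaluates these with
Gauss–Legendre nodes (Chebyshev–Gauss for \(D = 2\), where the density is
singular at the endpoints), doubling the node count until all eigenvalues
are stable to \(10^{-10}\), and clipping quadrature noise at zero.
Eigenvalues are stated **per mode** in the orthonormal-harmonic
convention, so \(\sum_k N(D,k)\,\lambda_k = K(1)\); the trace identity is
required to hold to 1% and fixes the default degree cutoffs (60 for
\(D = 3\), 25 for \(D = 6\)). The GP target spectrum uses the same
machinery, since on the sphere the squared-exponential covariance is
itself a dot-product kernel, \(C(t) = e^{-(1-t)/\gamma^2}\); the expected
squared coefficient of each mode of a GP draw equals the covariance
eigenvalue. `project_target_power` estimates the same decomposition
empirically from samples through the addition theorem, which is how
arbitrary targets (e.g. categorization labels) are analyzed.

Two spectral facts drive everything else: lowering \(f\) suppresses the
normalized kernel at small overlaps (pattern separation), and raising
\(f\) increases the relative weight of low-frequency eigenvalues. Sparse
codes are therefore biased toward high-frequency targets, dense codes
toward low-frequency ones.

## Predicting generalization error

`predict_generalization_error` turns the two spectra into an analytic
error estimate of the spectral-bias form
\(\mathrm{Error} = C_1 \sum_\alpha \big(c_\alpha / (C_2 +
\lambda_\alpha)\big)^2\) (normalized by total target power). The
mode-independent constants are realized through the standard
self-consistent scale \(\kappa\) of kernel-regression theory:

\[ \kappa = \lambda_{\mathrm{ridge}} + \kappa \sum_\alpha
   \frac{\lambda_\alpha}{P\lambda_\alpha + \kappa}, \qquad
   \gamma_v = \sum_\alpha \frac{P\lambda_\alpha^2}
   {(P\lambda_\alpha + \kappa)^2}, \qquad
   C_2 = \kappa / P, \qquad C_1 = \frac{C_2^2}{1 - \gamma_v}. \]

Sums run over modes (degeneracy-weighted over degrees); \(\kappa\) is
found by bracketed root finding on \([0,\ \mathrm{ridge} + \mathrm{tr}\,K]\),
ridgeless requests are stabilized with a jitter of \(10^{-9} K(1)\)
(tested to move predictions by less than 1%), and \(\gamma_v \ge 1\) is
reported as a divergence rather than silently clipped. The prediction is
invariant to a joint rescaling of the spectrum and ridge, is monotone in
\(P\), and assigns less error to better-represented modes.

**Validity regime.** The self-consistent constants are a random-matrix
asymptotic. The test suite validates the implementation itself against an
equal-eigenvalue closed form and against Gaussian-feature simulations, and
validates the full pipeline against wide-network simulations in the
sample-limited regime (short length scales, small \(P\)), where predicted
and simulated errors agree to within tens of percent or better. When the
predicted error becomes very small (long length scales or large \(P\) at
\(D = 3\), where the error is carried by barely-learnable high-frequency
tail modes), the approximation systematically *underestimates* the
simulated error by severalfold; the acceptance suite measures this
honestly rather than restricting attention to the favorable regime. Users
should treat predictions below roughly \(10^{-1}\) relative error as
qualitative.

## Readouts

Four fitting procedures are provided. `fit_least_squares` returns the
minimum-norm solution in Gram form (algebraically identical to the
pseudo-inverse, tested against it). `fit_ridge` minimizes
\(\sum_\mu \lVert y_\mu - w \cdot h_\mu \rVert^2 + M\alpha\lVert w
\rVert^2\); the \(M\) scaling keeps \(\alpha\) comparable across widths.
`fit_online_cf` implements the climbing fiber delta rule
\(\Delta w = \eta\, c\, h(x)\) with the error signal
\(c = y - w \cdot h\), per-epoch shuffling, zero initialization (the
natural convention for an unwritten synapse), and a divergence guard;
with defaults \(\eta = 0.7/M\) it converges to the minimum-norm
interpolator on realizable problems.

`fit_nonnegative` models the sign constraint of granule cell-to-Purkinje
cell synapses: \(\min_{w \ge 0, b} \sum_\mu (y_\mu - w \cdot h_\mu -
b)^2\), with categorization targets mapped to \(\{0, 1\}\) and continuous
targets to their absolute values. Because no quadratic-programming
backend fits this problem size here, the solver is built in: active-set
nonnegative least squares (Lawson–Hanson, with the bias as a permanently
passive column), which terminates finitely with exact KKT conditions. One
genuine design decision hides in this operation: in the wide regime
(\(M \gg P\)) the constrained least-squares optimum is an entire
polytope, and "the" weight distribution is a convention. A vertex
solution has support at most \(P\), giving a silent-synapse fraction of
\(1 - P/M\) for *every* task. We instead return the **minimum-norm
nonnegative interpolator** (computed from the \(P\)-dimensional dual by
semi-smooth Newton), which is the unique canonical point, produces the
delta-at-zero-plus-continuous-bulk weight histogram characteristic of
capacity-maximizing readouts with roughly half the synapses silent, and
makes the silent fraction task-dependent (higher for random
categorization at its native \(D = 50\) than for smooth GP targets),
as the tests verify.

## Experiment drivers and replication

`run_coding_level_sweep`, `run_architecture_sweep` and
`run_theory_comparison` wire the modules together under a nested config
(task / network / sweep / replication / readout). Within a replicate the
task and network are fixed and the threshold is re-calibrated at each
grid point, so error-versus-\(f\) curves are paired; every (row,
replicate, stage) seed derives from the base seed by a counter scheme
(`derive_seed`), making any single cell independently reproducible. Rows
carry mean, standard error over seeds and the measured coding level;
results serialize to CSV with a config hash and the seed table. Failed
cells are logged and skipped; a sweep aborts if more than half its cells
fail. `find_optimal_coding_level` reports the argmin with ties broken
toward sparser codes, flags boundary optima, and returns an interval
rather than a point when the curve is flat relative to its pooled
standard error. The default coding-level grid has 14 points on
\((0, 0.5]\), denser near zero where categorization optima live;
\(f \le 0.5\) reflects the empirical rarity of denser codes, and the
eigenvalue symmetry between \(f\) and \(1-f\) (verified for all degrees
\(\ge 2\)) means little is lost.

Presets (`experiment_preset`) encode the standard conditions: the
flagship categorization setting (M = 10,000, D = 50, P = 1,000,
\(\epsilon = 0.1\)), GP tasks at M = 200,000 with dense, sparse
(N = 7,000, K = 4) and clustered variants, the mushroom-body model
(M = 10,000, N = 50, K = 7), the arm forward model (M = 20,000), the VOR
battery (M = 20,000, N = K = 24 with dense Gaussian weights onto the
tuning curves), and the two architecture sweeps (in-degree at fixed
synapse count S = MK = 10,000 with N = 100; expansion ratio at N = 700),
both at \(f = 0.3\), D = 3, P = 200. Where a multi-curve figure's length
scales are needed the default grid is \(\gamma \in \{0.25, 0.5, 1, 2\}\)
with \(\gamma = 1\) as the single-curve default. One preset deviates from
the printed table: the clustered embedding needs \(D \mid N\), so the
clustered comparison uses N = 6,999 instead of 7,000. Every preset takes
a `scale` argument dividing M and the seed count for quick runs.

## What the tests do and do not show

The suite runs entirely on synthetic data, at sizes chosen for a
single-CPU run: the sparse-optimum checks use M = 2,500 (categorization)
and M = 10,000 (mushroom body) with 10 seeds; the length-scale ordering
uses M = 20,000 with 10 seeds; theory-versus-simulation uses M = 100,000
with 15 seeds per cell; the sparse/dense/clustered comparison uses
M = 20,000 with 6 seeds; kernel and spectral checks run at their printed
scales. The properties verified — sparse optima for random
categorization, denser optima for smoother targets, equivalence of
realistic sparse connectivity with the Gaussian theory, failure of
clustered input representations, near-task-independence of optimal
anatomical parameters, high silent-synapse fractions — are statements
about this model class under its stated input distributions. The
generators do not emulate temporal dynamics, spiking variability,
heterogeneous thresholds or inhibition, correlated or non-uniform input
statistics, or out-of-distribution probes, so passing tests support the
theory's internal consistency and its qualitative trends, not
quantitative claims about biological tissue.

## Known limitations

* The error predictor degrades in the fluctuation-dominated small-error
  regime (see *Validity regime* above); its constants are asymptotic, and
  no finite-width or finite-sample correction is implemented.
* The analytic theory requires unit-norm inputs under the uniform sphere
  measure; the simulation side has no such restriction, which is why the
  categorization and arm tasks are handled by simulation and empirical
  decomposition rather than closed-form spectra.
* The online rule has no weight decay or clipping; nothing constrains it
  on inconsistent problems beyond the divergence guard.
* Winner-take-all ties at the cutoff produce a kept unit with zero
  activity; the measured coding level can then fall below
  \(\lceil fM \rceil / M\) on adversarial inputs (measure-zero for
  continuous preactivations).
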