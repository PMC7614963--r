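---
title: "Self-supervised k-space reconstruction: model, weights, and oracles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised k-space reconstruction: model, weights, and oracles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmri)
```

## The problem and the measurement model

Accelerated MRI acquires a random subset of k-space, the Fourier
representation of the image, across several receiver coils. Writing the
fully sampled multi-coil data as $y_0$, the scanner delivers
$y = M_\Omega y_0$, where $M_\Omega$ is a diagonal 0/1 mask with
per-location sampling probability $p_j > 0$. Supervised reconstruction
networks regress $y \mapsto y_0$, but fully sampled references are often
unavailable. This package implements training schemes that use *only* the
sub-sampled $y$:

* a second random mask $M_\Lambda$ with density $\tilde p_j < 1$ is applied
  during training, $\tilde y = M_\Lambda M_\Omega y_0$, and the network is
  trained to map $\tilde y \mapsto y$ with a weighted squared error;
* the acquired set is thereby partitioned into an input set
  $B = \Omega \cap \Lambda$ and a loss set $A = \Omega \setminus \Lambda$.

The central object is the diagonal correction matrix built from the two
densities,
$$
k_j = \frac{1 - p_j}{1 - \tilde p_j\, p_j},
\qquad
(1-k_j)^{-1} = \frac{1 - \tilde p_j p_j}{p_j (1 - \tilde p_j)}
             = \frac{P(j \notin \Lambda \cap \Omega)}{P(j \in \Omega \setminus \Lambda)} .
$$

Two exact statements drive everything (`verify_claim1()`,
`verify_claim2()` check them by brute-force enumeration on discrete
ensembles):

1. **De-biasing identity.** $\mathbb E[Y_0\mid\tilde Y] =
   (1-K)^{-1}(\mathbb E[Y\mid\tilde Y] - K\tilde Y)$. A network trained with
   a full-rank loss weighting converges to $\mathbb E[Y\mid\tilde Y]$, so
   the fully sampled data can be estimated at inference by applying
   $(1-K)^{-1}$ — the *unweighted Noisier2Noise* route
   (`n2n_correct_plain()`, `n2n_correct_dc()`).
2. **Partitioned-loss minimizer.** With the rank-deficient weighting
   $W = (1-M_\Lambda)M_\Omega$ (the SSDU masking), the minimizer already
   equals $\mathbb E[Y_0\mid\tilde Y]$ at every location not sampled in
   $\tilde y$ — no correction needed at inference (`ssdu_estimate()`).

Because the trained network only approximates the ideal minimizer, its
statistical error is amplified by $(1-K)^{-1}$ wherever sampling is sparse.
The *K-weighted* SSDU loss multiplies the masked residual by
$(1-K)^{-1/2}$, which exactly cancels that amplification for a squared
loss; `method_spec()` exposes all variants (`unweighted_n2n`, `ssdu_2d`,
`ssdu_1d`, `kweighted_ssdu_1d`, `supervised`).

A loss-decomposition identity (`loss_decomposition()`) explains the
difference between the routes: for any network output consistent with its
input data, the identity-weighted loss splits exactly into the SSDU term
plus a term supported off the acquired set. That second term is what
shrinks unacquired k-space and makes the $(1-K)^{-1}$ correction necessary;
under the SSDU weighting it is identically zero.

## Sampling distributions and their parameters

`build_column_density(width, accel, order = 8, center_cols = 10,
cap_epsilon = NULL)` builds the 1D (column-wise) variable density used for
acquisition: a fully sampled central block of 10 phase-encode columns and a
polynomial profile $(1-|d|)^8$ outside it, scaled by bisection (with
clipping at the cap) so the expected acceleration $N/\sum_j p_j$ matches
`accel` within 0.5%. The defaults — order 8, 10 central columns, cap
$\epsilon = 10^{-3}$ for partitioning densities — are the standard
configuration for this family of experiments. The signed distance $d$ is
normalized by (half-width + 1) so the density is strictly positive
everywhere, which the correction matrix requires. `build_bernoulli_density`
is the radially symmetric 2D analogue with a 10×10 central region; its
`low_freq_high_prob = FALSE` mode emulates partitioners whose density
*grows* with radius.

Choices made where the recipe is open:

* the polynomial profile is $(1-|d|)^{\text{order}}$ in normalized distance
  (only "polynomial, order 8" is fixed by convention); the order is a
  parameter;
* the cap $1-\epsilon$ is applied to the whole partitioning density, not
  only the center — a conservative superset that changes nothing where the
  density is already below it;
* the partitioning density defaults to the same family and order as the
  acquisition density (same *type*, different acceleration), the
  configuration that both theory and practice favor;
* masks live on the 2D grid and broadcast across coils (physical Cartesian
  sampling is coil-independent); 0-based center conventions are left-biased
  for even grids.

## Training protocol

`train()` follows the standard protocol for this method family: the
acquisition mask of each slice is drawn once and frozen (a prospectively
sub-sampled scan cannot re-acquire), while the partitioning mask is redrawn
*once per epoch* per slice from a seeded stream
(`derive_seed(master, epoch, slice)`), which makes runs bit-reproducible
and exposes the network to many partitions of the same data. The optimizer
is Adam at a fixed learning rate $10^{-3}$ for 50 epochs, batch size one
slice; losses are summed over k-space and coils within a slice. Batch size
and initialization are not pinned down by convention, so they are package
choices: batch 1 keeps the step count equal to the slice count, and the
refinement kernels start at zero so the untrained estimator is the
data-consistency projection. A `train(..., init_params = )` warm start
allows staged schedules; the fixed-rate default matches the reference
protocol.

Self-supervised paths never read the reference: `make_dataset()` gates
$y_0$ behind `get_reference()`, which errors when the dataset is built with
`reference_access = FALSE`. The test suite trains on a locked dataset to
prove the path is clean.

## The compact estimator

Reproducing a full variational network is out of scope; the package
provides `compact_unrolled_estimator()`, a small physics-guided network
with the same skeleton: unrolled blocks alternating (a) coil combination
after an inverse FFT, (b) a learned complex convolution applied residually
in the image domain, and (c) a soft data-consistency step in k-space with a
learnable step size ("soft" meaning the pull toward the measured samples
has a trainable weight rather than being a hard overwrite; the hard version
is available as `dc_wrap()`). Its gradients are computed analytically by
adjoint passes and are verified against finite differences in the tests.
Coil sensitivities come from the simulator rather than an estimation
module: sensitivity estimation is deliberately decoupled, which published
ablations justify (masking the sensitivity input changes test error by
under a percent).

The estimator is linear in the data for fixed parameters. That is enough
for the framework's contracts and for the desk-scale study below, but it
bounds the achievable image quality — no nonlinear prior means no
suppression of residual incoherent aliasing beyond what the learned
convolution provides.

`diagonal_estimator()` (per-location complex gain and offset) exists for
the enumeration oracles: on a discrete ensemble whose posterior mean
depends only on whether a coordinate was observed, it can represent
$\mathbb E[Y\mid\tilde Y]$ exactly, so gradient training can be checked
against the enumerated conditional expectation (the convolutional
estimator, being translation-equivariant, cannot represent that map, which
is why the convergence oracle uses the diagonal one).

## What the synthetic generator emulates — and what it does not

`make_phantom()` produces complex images with smooth magnitude (random
ellipses, lightly blurred) and smooth low-order polynomial phase;
`make_coils()` produces smooth complex sensitivities normalized to unit
sum-of-squares; `forward_kspace()` applies a centered *unitary* FFT, fixed
package-wide so that Parseval holds and k-space NMSE equals coil-image
NMSE. The generated data reproduce the features the method relies on —
energy concentrated at low frequencies (the tests assert ≥ 90% of spectral
energy in the central half-band), multi-coil redundancy, smooth phase — but
not measurement noise (simulation is noise-free by design; the theory here
ignores noise), anatomical zero-padding, motion, or realistic contrast.
Passing tests therefore demonstrate the *mechanics* (identities, contracts,
method ordering), not clinical image quality.

## Desk-scale study conditions

The end-to-end check trains three methods under identical budgets on a
seeded synthetic dataset: 64×64 grid, 4 coils, acquisition at $R_\Omega=4$
(1D column-wise, order 8, 10 central columns), partitioning at
$R_\Lambda=2$ (same type, cap $10^{-3}$), 100 training slices, 15 test
slices, 50 epochs. These sizes are the package's chosen desk scale: large
enough that the self-supervised estimators see a representative spread of
masks, small enough to run attended. The assertions are directional —
K-weighted 1D-partitioned SSDU must reach test NMSE within a factor 1.5 of
the supervised ceiling, and unweighted Noisier2Noise must not beat it —
with the exact numbers recomputed and logged by
`scripts/acceptance.R`.

One behaviour deserves emphasis. With an order-8 polynomial density on a
64-wide grid, edge columns have sampling probability near $10^{-10}$, so
$(1-k_j)^{-1}$ reaches the configurable clip (default $10^6$, with a
warning). Unweighted Noisier2Noise multiplies its network output by that
weight at inference and its k-space NMSE explodes — the error-amplification
failure mode that motivates the K-weighting, in its starkest form. On
scanner data the same columns sit inside anatomical zero-padding and are
removed by a support mask (`apply_support()`); the synthetic study keeps
them to show the mechanism honestly. The SSDU variants, which need no
correction, are unaffected.

A robustness sweep over $R_\Lambda \in \{1.2, 1.6, 2, 4, 6\}$ is a
one-liner over `train()` (loop `build_column_density(64, accel = RL,
cap_epsilon = 1e-3)` into the `lambda_dist` argument); it is not part of
the default test run because five additional training runs would dominate
the suite's runtime.

## Numerical choices and degenerate inputs

* Correction weights are computed in double precision from *analytic*
  densities, never from single mask draws; for procedural samplers with no
  closed form, `estimate_density()` (1000 draws by default in practice)
  feeds `compute_K()`.
* `compute_K()` rejects $p_j = 0$ or $\tilde p_j = 1$ naming the offending
  locations, and clips $(1-k)^{-1}$ at `max_weight` with a warning.
* Acceleration scaling stops when $N/\sum p$ is within 0.5% of target;
  a request below the fully sampled center's budget errors as infeasible.
* The discrete oracle alphabets exclude zero so that a zero in $\tilde y$
  identifies "unsampled" unambiguously; deviations are reported absolutely
  on $O(1)$ alphabets with a $10^{-10}$ pass level, far from both float
  noise and any logic error.
* Loss decomposition enforces its input-consistency precondition at
  relative $10^{-8}$ before splitting.

## Limitations

Non-Cartesian and equidistant/regular sampling are out of scope, as are
measurement-noise-aware variants, multi-mask partitioning with a fixed
number of partitions per slice, and single-instance (zero-shot) training.
The estimator is a compact stand-in with a few hundred parameters; absolute
NMSE values at desk scale are far below (better than) what full-scale
experiments on scanner data report, and only the *relative* ordering of the
methods is meaningful here.
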