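---
title: "Models and methods behind sptkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sptkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptkinetics)
```

sptkinetics analyzes live-cell single-molecule tracking data of
chromatin-associated proteins — HP1-family proteins and their binding
partners in fission yeast are the motivating system — and turns localization
tables into biophysical quantities: the number of mobility states, per-state
diffusion coefficients and occupancies, continuous-time binding/unbinding
rate constants, photobleaching-corrected residence times, and per-state
spatial clustering statistics. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical choices made where
the design was genuinely open.

## The generative model for trajectories

A tracked molecule carries a hidden mobility state $k \in \{1,\dots,K\}$
that evolves between consecutive camera frames according to a per-frame
transition matrix $T$. Conditional on the state, each coordinate of the
displacement over one frame interval $\Delta t$ is Gaussian:

$$\Delta x,\ \Delta y \sim \mathcal{N}(0,\ 2 D_k \Delta t),$$

so the two-dimensional per-step mean squared displacement is
$4 D_k \Delta t$. Observed positions add independent localization noise
$\mathcal{N}(0, \sigma_{loc}^2)$ per coordinate, contributing
$4\sigma_{loc}^2$ to the per-step MSD. Motion is confined to a circular
nucleus; track lengths are geometric, reflecting a constant per-frame
photobleaching probability.

Simulator parameters (`sim_config()`), all in micrometres and seconds:

* `dt_frame = 0.04` — the 40 ms frame interval of the imaging experiments
  the model describes.
* `D` — per-state diffusion coefficients; chromatin-bound states sit near
  0.005–0.01 µm²/s, freely diffusing states near 0.2–0.5 µm²/s.
* `R_nuc = 1.0` — nucleus radius. The clustering analysis approximates the
  fission-yeast nucleus as a circle of roughly this size; the value is
  exposed as configuration rather than hard-coded.
* `sigma_loc = 0.02` — localization precision typical of single-molecule
  experiments on this camera format.
* `p_bleach = 0.05` — per-frame bleaching, giving mean track lengths of a
  few tens of frames.

Three design choices deserve comment. **Confinement** is enforced by
rejection-resampling of steps that would cross the nuclear boundary, which
preserves the Gaussian step distribution in the interior (a reflecting or
absorbing boundary would distort it differently). **Localization noise**
that would place an observed point outside the nucleus is redrawn, because
experimental localizations outside the nucleus mask are never analyzed.
**Initial states** are drawn from the stationary distribution of $T$,
matching the equilibrium assumption the rate-constant inference makes.

What the simulator deliberately does not emulate: raw camera frames and
spot detection, anisotropic or time-varying diffusion, gap frames and
tracking errors, non-circular nuclei, and 3-D motion. Passing recovery
tests on simulated data therefore demonstrates the estimators' correctness
under the stated model, not robustness to detection artifacts.

## Bayesian inference of mobility states

`infer_states()` fits a fixed-$K$ hidden Markov model to single-frame
displacements by Gibbs sampling. The emission variance per coordinate for
state $k$ is $s_k^2 = 2 D_k \Delta t + 2\sigma_{loc}^2$; the sampler
alternates

1. per-step state labels by forward-filtering backward-sampling, run
   vectorized across all tracks simultaneously;
2. per-state variances from the conjugate inverse-gamma update;
3. transition-matrix rows from Dirichlet–multinomial updates.

Reported quantities are posterior means with posterior standard deviations:
$D_k = \max(0, (s_k^2/2 - \sigma_{loc}^2)/\Delta t)$, weight fractions
$\pi_k$ defined as the fraction of steps assigned to state $k$ (compared in
diagnostics against the stationary distribution of $T$), and the per-frame
transition matrix. States are relabeled by ascending variance every sweep,
which makes label order deterministic and repeated runs with one seed
bit-identical.

The number of states is chosen by `select_K()`, which fits each candidate
$K$ and minimizes a BIC computed from the marginal step likelihood at the
posterior-mean parameters, with ties (and near-ties) resolved toward the
smaller $K$. With well-separated states (ratio ≳ 3 in $D$) and around
$10^4$ steps this selects the generating $K$ reliably; states with nearly
identical variances trigger a merge warning and the criterion prefers the
smaller model.

Priors are weakly informative: Dirichlet(1) rows, and an inverse-gamma
variance prior whose mean matches the overall mean squared displacement.
Defaults are 600 sweeps with 150 discarded; a split-chain potential scale
reduction factor above 1.1 on any state variance attaches a convergence
warning rather than failing silently.

Two known approximations. First, consecutive displacements of one molecule
share localization noise and are therefore slightly anti-correlated
($-\sigma_{loc}^2$ per coordinate); the model treats steps as independent
given their states, as the per-step mobility-state framework assumes. The
marginal step variance is unaffected, so posterior means remain accurate at
realistic noise levels, but posterior spreads are mildly optimistic.
Second, confinement truncates steps near the nuclear boundary, depressing
apparent $D$ by a few percent for fast states in a 1 µm nucleus. Parameter
recovery is therefore validated on unconfined simulations (the estimator
under its own model), and the confinement bias is treated as a property of
confined data, not of the estimator.

## From per-frame transitions to rate constants

The per-frame transition matrix mixes all transitions that happen within
40 ms. `infer_rate_constants()` converts it into continuous-time rate
constants $k_{ij}$ (s⁻¹) with a Bayesian Synthetic Likelihood (BSL)
Metropolis sampler:

* **Forward simulation.** The frame is divided into `n_fine = 100` steps of
  $\delta t = 4\times10^{-4}$ s. $M$ molecules are partitioned across
  states by the equilibrium proportions; each fine step moves molecules out
  of state $i$ by sequential binomial draws with per-destination
  probability $k_{ij}\,\delta t$. The summary statistic is the per-frame
  transition count matrix (frame-start state by frame-end state).
* **Synthetic likelihood.** `n_sim = 2000` simulated summaries define a
  multivariate Gaussian (covariance regularized by
  $10^{-6}\,\mathrm{tr}(\Sigma)/d$ on the diagonal); the likelihood of the
  observed matrix — scaled to $M$ molecules — is its Gaussian log-density.
* **Proposals.** One of three multiplicative moves, chosen uniformly: one
  random rate times $e^{0.02 T}$, every rate times $e^{0.02 T/N^2}$, or a
  random pair of opposing rates ($k_{ij}, k_{ji}$) times $e^{0.01 T}$, with
  $T$ Student-t(10) and $N$ the state count.
* **Prior and acceptance.** The improper Jeffreys scale prior
  $P(k) \propto 1/k$ is flat in $\log k$; because the multiplicative
  t-moves are symmetric in log-space, the Metropolis acceptance reduces to
  the likelihood ratio — equivalent to carrying the explicit proposal
  Jacobian in rate space.

Because the $M$ molecules are independent, the sequential-binomial fine
stepping of a population is distributed exactly as one multinomial draw per
start state from the 100th power of the one-fine-step transition matrix.
The likelihood evaluator uses this collapsed form, which is why a full
$5\times10^4$-proposal chain runs in tens of seconds in pure R;
`simulate_transition_summary()` keeps the literal fine-step loop, and the
test suite checks the two agree in mean and covariance. Note the collapse
is an algebraic identity, not an approximation.

The chain is initialized at the matrix logarithm of the observed transition
matrix (off-diagonal entries clamped below at $10^{-3}$ s⁻¹), runs
$5\times10^4$ proposals by default with 20% burn-in and thinning of 10, and
reports posterior means with 95% highest-density intervals. For two-state
systems the matrix logarithm provides an exact oracle, and posterior means
agree with it to well under 5% at the default settings. An acceptance rate
below 1% attaches a convergence warning. Proposals that push any fine-step
exit probability to 1 or beyond are invalid under the discretization and
are rejected outright. `M` defaults to $10^4$ molecules per simulation, a
value on the scale of the observed step counts.

For the published two-state example — per-40-ms transition probabilities of
0.8% (slow to fast) and 21% (fast to slow) — the matrix-logarithm rates are
0.226 and 5.92 s⁻¹, and the BSL posterior mean for the dissociation (slow
to fast) rate lands at ≈ 0.22–0.23 s⁻¹, consistent with the reported value
of 0.236 s⁻¹ once the two-significant-figure rounding of the inputs is
taken into account.

## Photobleaching-corrected residence times

Time-lapse imaging keeps the integration time $\tau_{int}$ (0.2 s) constant
while inserting variable dark delays, so the total period per frame is
$\tau_{TL} = \tau_{int} + \tau_{delay}$. A molecule detected in $n$
consecutive frames has measured residence time
$\tau_{measured} = (n-1)\tau_{TL}$. Fitting the residence times at one
interval to a single exponential gives an apparent rate confounding
dissociation and photobleaching; because bleaching acts only during
integration,

$$k_{app}\,\tau_{TL} = k_{diss}\,\tau_{TL} + k_{bleaching}\,\tau_{int},$$

so a weighted linear regression of $k_{app}\tau_{TL}$ on $\tau_{TL}$
separates the two: the slope is $k_{diss}$ and the intercept over
$\tau_{int}$ is $k_{bleaching}$. The regression uses the known per-point
variances propagated from the exponential fits ($(X'WX)^{-1}$ with
$W = 1/\sigma^2$), so the reported uncertainties reflect those fit errors
directly. The mean chromatin-bound dwell time is $1/k_{diss}$ — e.g. a rate
of 0.26 s⁻¹ corresponds to 3.85 s.

Three fitting modes are provided. The default continuous-exponential MLE
($k_{app} = 1/\overline{\tau}$ over molecules with a measurable dwell)
matches the probability-density-fit reading of the experimental procedure
but ignores that frame counts are discrete: on data whose dwells are exact
multiples of $\tau_{TL}$, it estimates $(1 - e^{-k\tau_{TL}})/\tau_{TL}$
rather than $k$, an effect that matters once $k\,\tau_{TL}$ is not small.
The `"geometric"` MLE models the frame counts exactly and is what the
simulation-recovery tests use; `"histogram"` reproduces a least-squares fit
to the log survival curve, which is also unbiased for discrete data. Dwell
runs are detected from trajectories (`detect_stationary_dwells()`) as
maximal runs staying within `r_stat` of the run's first localization, with
no gap closing; `r_stat` defaults to $3\sigma_{loc}$, which keeps a truly
stationary molecule inside the disc with high probability while breaking
runs at displacements beyond the noise scale.

## Spatial clustering per mobility state

Ripley's K on a circular window, with the strict-inequality convention

$$K(r) = \lambda^{-1} \sum_i \sum_{j \ne i} \frac{I(r_{ij} < r)}{n},$$

uses the isotropic edge correction: each pair is weighted by the inverse of
the fraction of the circle of radius $r_{ij}$, centered on point $i$, that
lies inside the nucleus circle. (Many packages use $\le$; the strict
inequality is deliberate and only matters for exactly repeated distances.)
$H(r) = \sqrt{K(r)/\pi} - r$ is zero under complete spatial randomness,
positive for clustering. Per-cell curves are averaged with weights equal to
each cell's localization density, and the default grid spans 40 radii from
0.025 to 1 µm.

Raw $H$ of tracking data is inflated by trajectory autocorrelation —
consecutive steps of one molecule are nearby by construction. The
normalization simulates `n_reps` control datasets matched to the data in
ROI, track count, track-length distribution and empirical step-length
distribution, but with uniform starting positions and isotropic directions
(`resample_matched_trajectories()`), and reports
$H_{norm}(r) = H_{data}(r) - \overline{H_{sim}}(r)$ together with the
2.5%/97.5% simulation envelope, so users can re-derive alternative
normalizations from the same output. Requirements and edge cases: at least
10 steps for a stable empirical step distribution, states with fewer than
10 points are skipped with a warning, and radii beyond the window diameter
are flagged rather than dropped.

`render_heatmap()` adapts the reconstructed single-molecule density map to
localization data: each localization contributes a unit-integral Gaussian
(width `psf_sigma_um`) on a `pixel_um` grid and the image is globally
normalized to a maximum of 1. Rendering from localizations rather than raw
camera pixels is an explicit adaptation — raw frames are outside this
package's scope.

## Orchestration, determinism and problem sizes

`run_pipeline()` chains the stages, writes CSV/JSON outputs plus a manifest
carrying the configuration hash and per-stage seeds, and aborts with a
stage-tagged error while retaining partial outputs. Every stage derives its
seed deterministically from the root seed and the stage label, so a rerun
with the same configuration and seed reproduces all numeric outputs
byte-for-byte. R's Mersenne-Twister generator drives all randomness.

The validation suite works at desk scale, chosen so each check is decisive
yet quick: $10^4$–$10^5$ steps for MSD, occupancy and state-recovery
checks; $10^4$ molecules per delay for dwell-time recovery; chains of
$2.5\times10^4$ proposals with 2000 simulations per likelihood for the rate
sampler (posterior means then sit within ~1% of the two-state oracle);
500-point patterns over 100 seeds for the edge-correction calibration.

## Known limitations

* Per-step independence ignores the localization-noise anti-correlation of
  consecutive steps; posterior uncertainties for $D$ are slightly
  optimistic.
* Confinement biases apparent $D$ low near the boundary; estimates from
  strongly confined fast states should be read as effective coefficients.
* The continuous-exponential dwell MLE inherits a discreteness bias at
  large $k\,\tau_{TL}$; use the geometric variant when frame counts are
  short.
* Circular nuclei only; real nuclear masks are approximated by circles, as
  in the clustering analysis the package follows.
* Model selection uses BIC on the marginal step likelihood, not the
  nonparametric posterior over $K$ that hierarchical Dirichlet-process
  analyses provide; with heavily overlapping states it will prefer merged
  models.
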