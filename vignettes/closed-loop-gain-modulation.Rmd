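---
title: "Closed-loop gain modulation: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop gain modulation: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopgain)
```

This vignette is the package's own account of the science it implements:
the models, the estimators, the tunable parameters that matter, and the
places where the design was genuinely open and a choice had to be made.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The minimal feedback model

A moving animal receives sensory input caused by its own actions
(reafference) in addition to externally generated input (exafference).
The minimal model treats collective neural activity $B(t)$ as a leaky
integrator driven by endogenous white noise and, in the closed-loop
condition, by an idealized linear, instantaneous reafferent feedback of
strength $w$:

$$\dot B_o = -B_o/\tau + I(t) + \xi_o, \qquad
  \dot B_c = -B_c/\tau + w B_c + I(t) + \xi_c.$$

In the replay condition the realized feedback input $wB_c(t)$ of a
closed-loop run is recorded and played back as exafferent input to an
identical system with fresh noise:
$\dot B_r = -B_r/\tau + wB_c(t) + \xi_r$. The closed forms implemented by
`analytic_summary()` are

$$\mathrm{Peak}_o = \sigma^2\tau/2,\quad
  \mathrm{Peak}_c = \frac{\mathrm{Peak}_o}{1-w\tau},\quad
  \mathrm{Peak}_r = \mathrm{Peak}_c +
     \mathrm{Peak}_o\frac{2w\tau}{w\tau-2},$$

with gains $\mathrm{Gain}_o=\tau$, $\mathrm{Gain}_c=\tau/(1-w\tau)$ and
effective time constant $\tau_{\mathrm{eff}}=\tau/(1-w\tau)$. For
suppressive feedback ($w<0$) the ordering
$\mathrm{Peak}_c < \mathrm{Peak}_o < \mathrm{Peak}_r$ holds: the brain
receives *identical* total input in the closed-loop and replay
conditions, yet fluctuates more in replay because the input is no longer
real-time feedback.

Numerical choices. The Euler map uses noise increments
$\sigma\sqrt{dt}\,\xi$, making $\sigma^2$ the instantaneous-variance
parameter of the continuous model; all closed-form checks use this
convention. The simulators are first-order linear recursions evaluated
with `stats::filter`, so a $10^6$-step run costs a fraction of a second.
Replay stores the realized feedback term rather than re-deriving it from
the trace, avoiding a one-step discretization mismatch. Variance
estimates discard a burn-in of $10\,\tau_{\mathrm{eff}}$ and carry a
batch-means standard error (30 batches), the scale against which the
stochastic acceptance checks are written.

## 2. The cortex–vibrissa network

The whisker-system model couples $2N=200$ linear rate neurons ($N$
excitatory, $N$ inhibitory) to a single two-segment whisker:

$$\dot x_i = -x_i + \textstyle\sum_j w_{ij}x_j - a_i
             - w_{x\theta}\,\theta_p + \xi_i + I, \qquad
  \dot a_i = -0.07\,a_i + 0.008\,x_i.$$

Connectivity is sparse ($p=0.1$) and excitation-dominated: excitatory
columns carry $b_0(J + g)$ masks with $J = 1/(pN)$, inhibitory columns
$-b_0 g$ masks, where $g$ is normalized so that the random part of the
spectrum is a disc of radius $b_0 g_0$ ($g_0 = 0.05$), independent of $N$
and $p$. Because the whole matrix is proportional to $b_0$, the
calibration of the leading eigenvalue to $0.975$ is a single exact
rescaling (`calibrate_b0()`), verified by re-solving the eigenproblem.
Slightly below instability, recurrent excitation amplifies a coherent
population mode whose interplay with the slow adaptation current produces
the quiet-state oscillation; whisker feedback reaches every neuron
through the protraction angle, and the excitatory population mean drives
the whisker's base-spring equilibrium.

**Two clocks and one calibration constant.** The printed rate constants
of the cortical equations, combined literally with a 0.5 ms step, do not
place the quiet-state spectral peak at the stated ~1 Hz, and a whisking
oscillator damped at $0.98$ per *network* time unit cannot show a 10 Hz
spectral peak at all — the two subsystems cannot share a clock and both
match their stated observables. The package therefore integrates the
cortical equations and the whisker drive on a "network" clock whose
scale, `time_unit_scale` (seconds per network time unit), is a single
calibration constant, while the whisking oscillator runs on the wall
clock with its frequency given directly in Hz. The default
`time_unit_scale = 0.0126` s was fixed once by locating the quiet-state
spectral peak of the seed-averaged population spectrum (in cycles per
network unit) and mapping it to 1 Hz. The implied biophysical constants
are reassuring: a membrane/rate relaxation of ~13 ms and an adaptation
time constant of ~180 ms, both in the physiological range for cortical
neurons, and the linearized mode analysis then predicts the observed
peak. The oscillator pair $(u, v)$ has damping $0.98\,\mathrm{s}^{-1}$
and frequency 10 Hz (quality factor ~32); its linear rotation–decay part
is advanced exactly each step because forward Euler is only marginally
stable for a high-Q oscillator at 0.5 ms.

**Whisker mechanics.** The whisker is two massless unit-length segments:
energy $E = k_1(\theta_p-\theta_{eq})^2 + (k_2/2)\theta_h^2$ (the
asymmetric weighting is deliberate and affects constrained solutions),
minimized subject to the wall constraint
$\sin\theta_p + \sin(\theta_p-\theta_h) \le 1$. Off the wall the minimum
is $(\theta_{eq}, 0)$ exactly; on the wall the constraint is active and
the minimizer is found by golden-section search along the contact
manifold (tested against a dense two-dimensional grid search). The
stiffness ratio $k_2/k_1$ spans flexible (0.1) to stiff (10) whiskers: a
stiff whisker's protraction angle is clamped toward the wall angle
during contact, interrupting the feedback the cortex receives; a
flexible whisker keeps $\theta_p$ near $\theta_{eq}$ while the tip
bends.

**Free parameters that the model definition leaves open.**

* Oscillator noise `cpg_sigma` (0.8 per $\sqrt{s}$): sets the whisking
  amplitude; the default gives a ~25° s.d. protraction excursion,
  comparable to free whisking.
* `whisk_setpoint` (25°): rodents whisk about a protracted set point;
  with the wall one section-length above the whisker, whisking about
  this set point produces repeated sustained contacts rather than rare
  grazes. In wall-free conditions the set point only shifts the mean
  angle of a linear system and is immaterial.
* The feedback weight $w_{x\theta} = 0.002$ multiplies the protraction
  angle *in degrees*: at the model's whisking amplitudes this makes the
  sensory feedback comparable to the printed stimulus amplitude
  $I = 0.035$, whereas radians would render the loop entirely
  negligible.
* Neural noise is unit variance per printed Euler step, re-expressed as
  an instantaneous amplitude so that the process is step-size invariant.

**Paired comparisons.** The simulator draws its oscillator noise
variates on every step whether or not the oscillator is active, so two
runs with the same seed share one noise stream across behavioural
conditions. Condition contrasts (open vs closed vs touch, stiffness
sweeps) are therefore paired, which is what makes modest effects
resolvable in 50-s runs: the loop gain of the implemented whisker
pathway at the slow peak is of order 0.1, so closed-loop suppression of
low-frequency power is a 5–10% effect, far below the run-to-run
variability of an unpaired spectral estimate.

**Correlation metric.** Inter-neuron correlations that probe the
coherent slow fluctuations are computed after averaging each trace over
one whisk cycle (a boxcar of width $1/f_{whisk}$, which has a spectral
zero exactly at the whisking frequency). Without this, the common 10-Hz
locking that whisking adds masks the decorrelation of the slow mode that
the condition comparison is about.

**Discriminability.** Sensory events are scored by the Chernoff distance
$\Psi = -\min_{0<\lambda<1}\log\int p_1^\lambda p_0^{1-\lambda}$ between
the joint membrane distribution of a small neuron subset (default 3)
with and without the event, evaluated with the closed-form Gaussian
expression and a bounded scalar optimization over $\lambda$
($[10^{-3}, 1-10^{-3}]$, tolerance $10^{-8}$). The closed form was
derived by completing the square and verified against numeric
quadrature; note that the covariance mixture takes the weights
*opposite* to the density powers
($C_\lambda = \lambda C_0 + (1-\lambda)C_1$ for
$\int p_1^\lambda p_0^{1-\lambda}$). Covariances carry a relative ridge
of $10^{-8}\,\mathrm{tr}(C)/d$. Ensembles are event-aligned trials; the
package's scaled-down defaults (50 trials) replace the hundreds of
independent network instantiations a large study would use, and the
summary index defaults to the window mean of $\Psi(t)$ (the window
maximum is also reported, since either convention is defensible).

## 3. Closed-loop filter estimation

For paired closed-loop/replay recordings $(B_c, E_c, B_r, E_r)$ sampled
at ~2.5 Hz the pipeline assumes, per cell,

$$B_c = F E_c + R_{Bc}, \quad E_c = G B_c, \qquad
  B_r = F E_c + R_{Br}, \quad E_r = G B_r$$

in the frequency domain, with noise-free environment. Fitting happens in
the replay condition, where there is no loop: `fit_afferent()` regresses
$B_r$ on Laguerre-basis convolutions of $E_c$, `compute_residual()`
forms $R_{Br}$, and `fit_efferent()` regresses $E_r$ on the residual.
The round-trip feedback filter is $H = F\,G$. From
$B_c = (1-H)^{-1}R_{Bc}$ and $B_r = HB_c + R_{Br}$, with equal residual
spectra, the closed/replay power ratio is $1/(|H|^2 + |1-H|^2)$;
truncating the geometric series $(1-H)^{-1} = 1 + H + H^2 + \dots$ after
one cycle gives the single-cycle control $1/(|H|^2 + |1+H|^{-2})$. The
naive (loop-ignoring) closed-loop filter is predicted as
$F + (G/(1-H))^{*}\,|R_{Br}|^2/|E_c|^2$ and acquires an acausal lobe
because brain and environment interact mutually in the closed loop.

Estimator choices, in order of consequence:

* **Basis and order selection.** Causal filters use discrete Laguerre
  functions (pole grid $\{0.6, 0.8, 0.9\}$), acausal ones Hermite
  functions (width grid $\{1, 2, 4\}$ s, orthonormalized on the lag
  grid); order 0–15 and scale are selected jointly by
  $AIC = n\log(RSS/n) + 2k$. Order 0 — the empty model — is a first-class
  candidate, so an input that does not drive the output yields an
  exactly zero kernel rather than fitted noise. When a truncated basis
  becomes numerically collinear the order range is capped at the
  well-conditioned leading block.
* **Kernel support.** All session fits default to 6 s of lags (15
  samples at 2.5 Hz), the scale on which the sensorimotor kernels live;
  longer supports only add variance.
* **Block demeaning.** Visual-gain blocks alternate every 30 s and shift
  mean activity levels; every fit and spectrum operates on per-block
  demeaned series (`block_demean`, idempotent).
* **Spectra.** Band-power ratios use Welch segments of half the series
  length (frequency resolution first); the spectra entering the naive
  prediction use short 32-sample segments (variance first, since the
  prediction divides two spectral estimates).
* **Weighted band means.** An observed ratio of band powers equals the
  denominator-spectrum-weighted mean of the pointwise ratio, so
  predictions are compared to data with replay-spectrum weights; the
  unweighted mean overstates suppression whenever $H$ rotates across the
  band.
* **Log-space comparison.** Band-power *ratios* are biased upward in
  short sessions (a Jensen effect of the noisy denominator); log
  band-power differences are nearly unbiased because numerator and
  denominator share their estimator bias, so population tests operate on
  log ratios.
* **Error ratio within the naive basis.** The prediction error ratio
  $R_{prediction}/R_{naive}$ compares, by default, projections onto the
  basis functions the naive fit was allowed to use: the naive estimate
  is AIC-regularized and cannot express arbitrarily sharp structure, so
  raw-grid mean square errors would penalize the prediction for detail
  the reference estimate could never show. The raw comparison remains
  available (`project = FALSE`).
* **Single-cycle variant.** The one-cycle ratio substitutes $B_1$ for
  $B_c$ in both the numerator and the replay drive
  ($1/(|H|^2+|1+H|^{-2})$); the variant that substitutes only in the
  numerator is implemented as `"numerator"`. The behavioural feedback
  filter defaults to regressing $E_c$ on $E_r$, with the opposite
  direction available.

## 4. The synthetic session generator

`session_config()`/`make_ground_truth()`/`simulate_session()` generate
paired sessions with known ground truth: 30 cells, 180 s per condition
at 2.5 Hz, 30-s gain blocks (factors 1.2/0.8). Per-cell afferent kernels
are net-negative alpha functions ($\tau_F = 0.6$ s, mean net area
$-0.65$), efferent kernels of the feedback minority (10% of cells, as in
the strongly loop-coupled population the analysis highlights) are
net-positive ($\tau_G = 0.5$ s, mean net area 0.3), log-normal amplitude
spread 0.3; the round-trip kernel is net negative and peaks near 1 s.
The loop closes with a one-sample delay (the efferent kernels have no
zero-lag tap), and configurations are rejected unless
$\max_\omega|H_{tot}| < 1$ and $|1-H_{tot}|$ stays above a margin.

Two features deserve justification:

* **Unrecorded-population drive.** Swimming is driven by the whole
  brain; the handful of recorded cells contribute only part of it. The
  environment therefore receives an additional white neural drive of
  unit amplitude inside the loop (fresh realization in replay). This is
  what makes the session identifiable at all: without it the environment
  is a low-pass function of the recorded cells' noise, the environment
  spectrum vanishes at high frequency, and the naive filter develops
  unbounded high-frequency structure. It is white because swim power is
  a broadband bout process. A corollary of the loop algebra is worth
  recording: in a session whose environment is driven purely by
  recorded-cell noise, the per-cell afferent signal-to-noise ratio is
  bounded by $1/\sqrt{n_{fb}}$ regardless of kernel amplitudes — large
  per-cell stimulus SNR and a purely self-generated environment are
  mutually exclusive. The defaults give an afferent SNR well below one,
  which is also why the pipeline's population statements are
  sign-test-shaped rather than per-cell-exact.
* **Gain on the afferent path.** The visual gain multiplies the mapping
  from swim power to stimulus, which in the reduced two-variable model
  sits inside the afferent filter; applying the block factors to $F$ in
  *both* conditions (the replay stimulus embeds the gain schedule it was
  recorded under) keeps the filters condition-invariant, which is the
  assumption the estimation relies on. Gain-dependent baselines are
  added to the environment so that block demeaning has real work to do.

What passing tests on these sessions do and do not show: the generator
is linear with Gaussian noise and a white environment drive, so it
validates the estimators under the model's own assumptions (plus
delay, gain blocks, population crosstalk, and optional AR(1) noise and
calcium smoothing as stress modes). It does not emulate calcium-indicator
nonlinearity, bout discreteness, or nonstationary behavioural state, and
agreement on synthetic sessions is not evidence about any real dataset.

## 5. Problem sizes and tolerances used by the test suite

Deliberately scaled-down study conditions keep the default suite fast:
network condition runs are 50 s (versus 200 s conditions in a full
study) with 20 seeded repeats and paired noise streams; discriminability
uses 50 trials per condition; session-level population statements pool
10–20 sessions of 30 cells. Stochastic checks are written against
3-standard-error bands (batch means for variances, across-seed spreads
for ratios) or paired sign tests at the 5% level; exact identities
(e.g. $H = FG$ on the grid, kernel = basis × coefficients, block means
after demeaning) are asserted to machine-level tolerances; derived
closed forms are checked against independent brute-force oracles
(spectral integrals, quadrature, grid searches) at $10^{-4}$ or better.

## 6. Known limitations

* The time-unit calibration fixes the quiet-state peak near 1 Hz by
  construction; only the CPG-locked peaks and the orderings across
  conditions are genuine predictions of the implementation.
* The per-cell closed-loop formulas are exact only when one cell
  dominates the loop; with population crosstalk they remain
  directionally correct (and the tests treat them accordingly), but
  per-cell magnitudes are biased by the $(1-H_{cell})$ versus
  $(1-H_{tot})$ mismatch.
* Rate dynamics only: no spiking, no thalamic pathway, no separate
  retraction-driving population; the whisker is massless and
  frictionless with a single overhead wall.
* The Chernoff machinery assumes Gaussian response distributions, which
  is exact for the linear network but an approximation anywhere else.
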