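---
title: "Synergy extrapolation in an EMG-driven musculoskeletal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synergy extrapolation in an EMG-driven musculoskeletal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synx)
```

## The problem

EMG-driven musculoskeletal models predict joint moments from measured muscle
excitations, but some functionally important muscles — deep hip muscles such
as the iliopsoas foremost — are hard or invasive to record. Synergy
extrapolation (SynX) predicts such an *unmeasured* muscle's excitation from
the low-dimensional synergy structure of the *measured* channels: gait
excitations are well approximated by a handful of time-varying synergy
excitations mixed through time-invariant weights, so the missing channel is
modelled as another mixture of the same synergies, and its unknown weights
are identified by requiring the full EMG-driven model to reproduce
inverse-dynamics joint moments.

This package implements the complete chain — EMG processing, per-trial
synergy analysis, the rigid-tendon Hill-type forward model, simplified
moment-tracking calibration, the SynX estimator itself, the
2 algorithms × 5 normalizations × 8 synergy-number methodological sweep, and
the evaluation metrics — together with a seeded virtual-subject generator so
that every stage can be validated against ground truth without experimental
data.

## Models and procedures

### EMG processing

Raw EMG is conditioned per channel with fourth-order zero-phase Butterworth
filters (a second-order filter applied forward-backward): high-pass at 40 Hz,
demeaning, full-wave rectification, low-pass at $3.5/t_f$ Hz, where $t_f$ is
the gait-cycle period in seconds, so envelope smoothness scales with cadence.
Filter ringing can push the smoothed envelope marginally negative; values are
clamped at zero because excitations feed non-negativity-constrained
factorization and a muscle model defined on $[0,1]$.

Each trial is cubic-spline resampled to 101 frames spanning heel strike to
heel strike plus $n_{pad} = \mathrm{round}(10/t_f)$ preceding frames
(round half up), roughly 100 ms of history that the electromechanical delay
consumes. Five magnitude normalizations are supported (`MaxOver`, `MaxPer`,
`VarOver`, `VarPer`, `MagPer`); "Over" constants are shared across the trial
set the caller supplies (typically one leg's trials), "Per" constants are
trial-specific. Whether the schemes operate on the plain envelopes or on
signals first normalized to their across-trial maximum is genuinely open;
the default applies them to the envelopes directly, and
`process_emg(renormalize_from = "maxover")` provides the other ordering.

### Synergy analysis

Per trial, the padded excitation matrix $E$ (frames × measured channels) is
factorized as $E \approx W H$ (NMF) or $E \approx W H + \mathbf{1}\mu'$
(PCA). PCA is computed analytically; the sign indeterminacy is fixed by
making each component's largest-magnitude loading positive. NMF uses
alternating least squares with non-negativity by clamping, run from 10
seeded random initializations with the smallest Frobenius error kept —
matching the conventional ALS-with-replicates recipe. The least-squares
subproblems use a minimal-norm SVD pseudoinverse, which keeps the updates
defined when a factor loses rank (routine once the synergy count reaches the
effective rank of the data); replicates whose factors collapse to zero are
restarted. Convergence is declared at a relative objective change below
$10^{-6}$ or 1000 iterations. Reconstruction quality is summarized by
pooled, uncentered variance accounted for,
$\mathrm{VAF} = 100\,(1 - \lVert E - \hat E\rVert_F^2 / \lVert E\rVert_F^2)$.

### Musculotendon model

Each muscle produces a moment about each spanned joint

$$M = r \, F_o^M \left[ a\, f_l(\tilde l^M) f_v(\tilde v^M) +
  f_p(\tilde l^M) \right] \cos\alpha ,$$

with a rigid tendon: the fiber length along the tendon is
$\ell = l^{MT} - l_s^T$, constant-thickness pennation gives
$l^M = \sqrt{\ell^2 + (l_o^M \sin\alpha_o)^2}$ and
$\cos\alpha = \ell / l^M$. Fiber velocity follows by the chain rule from the
joint velocities through the geometry and is normalized by a maximum
contraction velocity of $v_{max} = 10\, l_o^M/\mathrm{s}$.

The normalized curves are standard phenomenological forms, chosen and
documented here because no canonical closed forms exist for them:
a Gaussian active force-length $f_l = \exp(-(\tilde l - 1)^2/\gamma)$ with
$\gamma = 0.45$; a Hill hyperbola force-velocity normalized to $f_v(0)=1$,
$f_v(-1)=0$ (shape constant $a_f = 0.25$) with a $C^1$ eccentric branch
saturating at 1.4; and an exponential passive curve, zero at or below
optimal length and scaled so $f_p(1 + \varepsilon_0) = 1$ with stiffness
$k_p = 4$, $\varepsilon_0 = 0.6$. All are overridable through
`muscle_curves()`, and the tests target these documented forms.

Activation dynamics transform excitation $e$ into activation in two stages:

$$\frac{du}{dt} = (c_1 e(t-d) + c_2)\,(e(t-d) - u), \qquad
  a = (1 - c_3)\,u + c_3 \left[ g_1 g_2 (u + g_3)^{g_4} + g_5 + 1 \right],$$

with $c_1 = 1/\tau_{act} - 1/\tau_{dact}$, $c_2 = 1/\tau_{dact}$,
$\tau_{dact} = 4\tau_{act}$, electromechanical delay $d \le 100$ ms, and a
nonlinearity constant $c_3 \in [0,1]$. The constants
$g_1..g_5$ are conventionally fitted to isometric-contraction data that are
not available here, so the defaults construct
a concave power law mapping $[0,1]$ onto $[0,1]$ with $a(0)=0$, $a(1)=1$
(the classic "A-shape"); endpoint and monotonicity checks run at
construction and reject user-supplied constants that break them. The
bracketed term is implemented literally as written, with the
endpoint-normalization constraint absorbing the ambiguity in how the
trailing "+1" associates.

The ODE is integrated with an explicit midpoint (RK2) scheme at the frame
rate, sub-stepped so the per-step rate-time product stays below 0.05 — the
guard doubles as a stability margin and keeps the global error against the
analytic exponential solution below $10^{-4}$ at 1 ms steps. Fractional-
frame delays are realized by cubic interpolation on the padded grid, with
constant extension before the first sample.

### Geometry surrogate

Musculotendon lengths are least-squares polynomials in the joint angles the
muscle spans, and moment arms are the *analytic* negative partial
derivatives of that polynomial, so the tendon-excursion identity
$r_j = -\partial l^{MT}/\partial q_j$ holds by construction (verified by
finite differences in the tests). Velocity enters only through
differentiation of the fitted length — angle-velocity cross terms in the
surrogate are deliberately omitted as a documented simplification. Each
surrogate records its fitted angle domain and rejects evaluation far outside
it.

### Calibration

The tracking objective pools squared moment errors over frames, DOFs and
trials: $J = \sum_{trials}\sum_{frames}\sum_{i=1}^{N}
(M_i^{mod} - M_i^{exp})^2$ (the per-joint sum is the conventional form; the
frame/trial pooling convention is fixed here). Calibration minimizes $J$
over a chosen per-muscle design — electromechanical delay, activation time
constant, nonlinearity constant, EMG scale factor, and ±15% multiplicative
adjustments of optimal fiber length and tendon slack length — under box
bounds ($d \in [0, 0.1]$ s, $\tau_{act} \in [0.01, 0.05]$ s,
$c_3 \in [0,1]$, EMG scale $\in [0.05, 1]$), using L-BFGS-B on a
bound-normalized scale starting from the template's current values.  The
elaborate staged protocols and penalty terms used in full subject-specific
calibrations are replaced by one optional quadratic regularizer toward the initial values
(weight $10^{-4}$ on the normalized scale by default) plus an optional
`stages` argument that optimizes parameter subsets in sequence.  When the
design leaves the geometry untouched, moment-arm and Hill-curve terms and
the moments of non-calibrated muscles are precomputed once per trial, so an
objective evaluation only reruns activation dynamics for calibrated muscles.

### The SynX estimator

With the calibrated model fixed, the unmeasured excitation is
$e_x = W H_x$ (NMF) or $e_x = W H_x + \mu_x$ (PCA), and $(H_x, \mu_x)$
minimize the same tracking objective. Three numerical choices matter:

* **Constraints.** $e_x(t) \in [0,1]$ at every frame is linear in the
  weights. It is enforced by an exterior quadratic-penalty loop around the
  bound-constrained quasi-Newton solve; the penalty weight starts at the
  scale of $\sum (M^{exp})^2$ and grows tenfold until the unclamped
  reconstruction violates the box by less than $10^{-5}$. A log-barrier was
  rejected because NMF synergy excitations can be exactly zero between
  bursts, leaving no strict interior. The model always consumes the clamped
  series, and both clamped and raw series are reported.
* **Bounds.** $H_x \ge 0$ for NMF (the weights of a non-negative mixture);
  unbounded for PCA in principle, with a wide stabilizing box of
  $\pm 10 \max|H_m|$ that the diagnostics flag if it ever binds.
* **Starts.** $H_x$ initializes uniformly in $[0,1]^p$ and $\mu_x$ at the
  mean of the measured channel means; `n_starts` seeded starts (default 5,
  2 in sweeps) guard against the non-convexity that NMF-space weights can
  induce, and every start's final objective is logged. Multi-start is cheap insurance for the NMF case even though the PCA-space
  objective is usually benign.

Weights are trial-specific: each trial is solved independently, with no
cross-trial coupling. An identifiability probe perturbs each weight and
flags the solution when the moments do not respond (e.g. a muscle with zero
moment arms), rather than reporting spurious precision.

Because only the unmeasured muscle's contribution changes during
optimization, the measured muscles' moments are computed once and the
per-evaluation cost is one activation-dynamics integration per unmeasured
compartment — this is what makes the 80-combination sweep practical.

### Evaluation

Reconstructions are scored on the 101-frame cycle grid (padding excluded):
Pearson $r$ for shape, RMSE for magnitude, per-DOF MAE for moment accuracy,
and pooled VAF for factorization quality. Correlations are banded as weak
($r < 0.35$), moderate ($0.35 \le r \le 0.67$), strong
($0.67 < r < 0.9$) and very strong ($r \ge 0.9$); the conventional bands gap
at their edges, so both boundary points are assigned to "moderate" here,
while $r = 0.9$ is explicitly very strong. Best-synergy-number histograms
count, per trial, the $p$ maximizing $r$ or minimizing RMSE, ties going to
the smallest $p$. `mean_curve_r()` provides the separate average-curve
comparison.

## The virtual subject

`make_virtual_subject()` draws, deterministically from one seed, a
ground-truth system shaped like the study design it stands in for: 16 EMG
channels driving 16 muscles (configurable up to shared-channel layouts) over
5 DOFs (hip flexion/extension and ab/adduction, knee flexion/extension,
ankle plantar/dorsiflexion and in/eversion), two walking speeds with cycle
periods of 1.25 s and 1.0 s, and $p_{true} = 5$ synergies — the regime the
method is expected to do best in. Synergy excitations are periodic Gaussian
bumps in percent gait cycle with seeded centers and widths; channel weights
are sparse non-negative mixtures scaled so each channel peaks between 0.3
and 0.8. Joint angles are two-harmonic Fourier series with
physiological-order amplitudes; geometry is exact quadratic polynomials (so
the surrogate fit recovers it to machine precision); Hill and activation
parameters are drawn inside the calibration bounds.

`generate_trials()` adds trial-to-trial variability (±15% synergy amplitude,
±2% cycle timing jitter), runs the ground-truth forward model for the
moment targets, and applies multiplicative Gaussian envelope noise and
additive moment noise scaled by each DOF's moment SD. The default noisy
condition is 10% excitation noise and 5% moment noise. A carrier mode
synthesizes raw EMG as 40–450 Hz band-limited noise amplitude-modulated by
the true envelope, purely to exercise the filtering chain.

What the generator does *not* emulate: measurement cross-talk,
non-stationary noise, within-trial synergy-weight drift, soft-tissue
artifact, model-form error between the "experimental" moments and the
muscle model (moments are generated by the same model family that SynX
inverts), and pathological asymmetries. Passing tests therefore demonstrate
internal consistency and recoverability under the stated noise, not
performance on real data.

## Problem sizes and runtimes

The test suite and the acceptance script use: 10 trials (5 per speed) for
recovery and calibration checks, 2 random starts per solve inside sweeps,
the full 80-combination grid on one trial for bookkeeping and constraint
invariants, and the 2 × 5 grid at $p \in \{5, 6\}$ plus a $p = 3..10$
profile on 10 noisy trials for the noisy-regime checks. These sizes were
chosen so each stage still exercises the full design while a complete run
stays in the minutes range on one core.

## Known limitations

* One unmeasured channel at a time; simultaneous calibration of model
  parameters and synergy weights is out of scope by design.
* Synergy analysis happens once, before weight optimization — it is not
  re-run inside the loop when normalization constants change.
* The simplified calibration omits the additional constraints and penalty
  terms of full subject-specific protocols; geometry coefficients are taken
  as given.
* Elastic tendon behaviour, anatomical wrapping geometry, and
  angle-velocity coupling in the surrogate are not modelled.
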