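---
title: "Models and methods behind probswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind probswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

probswitch implements, end to end, the analysis stack for a mouse
two-port probabilistic switching task with fiber-photometry recordings:
task simulation, trial-history behavioral statistics, a recursive
logistic-regression model of choice, lock-in style demodulation of
frequency-modulated photometry, and a time-shifted kernel ridge GLM
linking behavioral events to the neural signal. This vignette explains
the models, their assumptions, the tunable parameters, and the numerical
choices made where the method leaves room.

## The task

A trial starts with a center-port poke (CE, center entry; CX, exit),
followed by a left or right side poke (SE, side entry) within 8 s, a
first lick at the spout (FL), and withdrawal (SX, side exit). One side
port pays reward with high probability `p_high`, the other with
`p_low`; these are *per-port* probabilities (90/10 means 0.9 and 0.1)
and rewards are drawn independently per choice -- there is no baiting of
the unchosen port. After 50 rewards have been earned in a block the
probabilities swap sides with no cue; the animal must infer the reversal
from its outcome history. The simulator (`simulate_session()`) enforces
a 1 s minimum inter-trial interval and draws within-trial latencies from
log-normal distributions whose defaults (center dwell 0.25 s, side
approach 0.5 s, first lick 0.3 s, consumption 1.2 s on rewarded trials,
quick exit 0.2 s otherwise) put rewarded trials at 2-3 s total and make
unrewarded side-port occupancy visibly shorter than rewarded -- the
qualitative timing structure of the real task. Latency draws are capped
at 6 s so the 8 s side-poke deadline can never be violated; aborted
trials are out of scope.

A subtlety worth knowing: the trial immediately *before* a block
transition is strongly biased toward the high port, because the
transition is triggered by the 50th reward and rewards are much more
likely on high-port choices. Transition-aligned curves from any agent --
even one that ignores outcomes entirely -- therefore show structure at
negative offsets. This is a property of the task, not a bug.

## Behavioral statistics

`p_high_port_curve()` and `p_switch_curve()` align per-trial indicators
to block transitions (offset 0 = first trial under the flipped
probabilities), average within mouse first and then across mice, as is
standard for repeated-measures behavioral data. The recovery of p(high
port) is summarized by `fit_tau()`, a least-squares fit of

$$p(t) = A - B e^{-t/\tau}, \qquad t = 1 \ldots 20$$

over the first 20 post-transition trials, with `A`, `B`, `tau` free and
initialized from the series endpoints. A flat series makes `tau`
unidentifiable; the fit flags this (`degenerate = TRUE`) instead of
returning an arbitrary number.

`conditional_switch()` conditions p(switch) on the previous `depth`
trials (default 2), encoding histories as words over `{A, a, B, b}`:
A/a = same side as the reference (most recent) trial, B/b = opposite
side; upper case = rewarded. This alphabet is a documented convention of
the package; other analyses may label histories differently. The
frequency-weighted mean of the conditional rates reproduces the overall
p(switch) exactly (law of total probability), which is enforced by
tests on every input.

`criteria_check()` applies the four expert-performance criteria over
exactly five consecutive sessions (mean p(high port) >= 0.80, var <
0.003; mean p(switch) <= 0.15, var < 0.001; mean p(left) in [0.45,
0.55], var < 0.005; >= 200 trials per session). Mean thresholds are
inclusive and variance thresholds strict; the variance is the
population variance over the five sessions (population chosen over the
sample variance and documented here, since either reading of
"variance" is defensible).

## The RFLR choice model

The recursively formulated logistic regression predicts the next choice
from a perseveration term and an exponentially decaying evidence trace:

$$\phi_{t+1} = c_t r_t + e^{-1/\tau}\,\phi_t, \qquad
  \psi_{t+1} = \alpha c_t + \beta \phi_{t+1}, \qquad
  P(\text{left}) = \sigma(\psi_{t+1})$$

with choices coded c = +1 (left) / -1 (right) and rewards r in {0, 1}.
`alpha` is the tendency to repeat the last choice regardless of outcome,
`beta` weights the reward evidence, and `tau` (trials) sets how many
past trials the evidence integrates over. `phi` starts at 0 at each
session start and the first trial, having no prediction, is excluded
from the likelihood. Predicted probabilities are clamped at 1e-12 from
the boundaries.

`fit_rflr()` maximizes the likelihood by stochastic gradient descent
with analytic gradients, one session per mini-batch, `tau` parameterized
as `log(tau)` to stay positive, and a `1/sqrt(epoch)` learning-rate
decay (base rate 0.05, 200 epochs). Plain SGD converges very slowly
along the narrow valley where `beta` and `tau` trade off against each
other (a larger decay constant can mimic a larger evidence weight over
short horizons); classical momentum (coefficient 0.9, exposed, set 0 to
disable) fixes this, reaching the same optimum as a full-batch BFGS
solve of the identical objective -- which is exactly what the test suite
checks. Parameter recovery on simulated agents (20 sessions x 1000
trials at alpha = 1, beta = 2, tau = 1.4) comes back within 10% on all
three parameters.

`psychometric()` bins teacher-forced log-odds into 13 equal-count
(quantile) bins -- bin placement is otherwise unspecified, and quantile
bins keep per-bin counts balanced -- and fits
`p = 1/(1 + exp(-(psi - m)/s))` by least squares; smaller `s` means a
steeper curve. `compare_psychometrics()` is the extra sum-of-squares
F-test of one-shared-curve versus separate curves. The logistic fitter
self-starts from a logit-scale linear regression and falls back to
direct Nelder-Mead minimization of the same sum of squares when the
Levenberg-Marquardt gradient check rejects degenerate (e.g. exactly
fitting) inputs.

## Photometry demodulation

Two LEDs are amplitude modulated at 167 Hz (signal) and 223 Hz
(control); one detector stream at 2000 samples/s carries both.
`demodulate()` recovers a channel's slow envelope by short-time spectral
power: Hamming-windowed frames of 216 samples advancing by 108 (frame
period 54 ms), direct complex-exponential projection at nine 1
Hz-spaced frequencies spanning an 8 Hz band around the carrier (direct
evaluation, because the native resolution 2000/216 Hz is not 1 Hz), and
the band-mean power as the demodulated value. Band power is
proportional to the squared modulation amplitude -- a x2 amplitude step
becomes a x4 power step -- and the two carriers separate with cross-talk
well under 2% because their 56 Hz spacing dwarfs the 8 Hz band.

Each frame is assigned the time `k * 54 ms`, the energy centroid of its
Hamming window; this keeps event-to-frame alignment unbiased, which
matters for kernel estimation. The 500 ms window "immediately following
an event" used by `window_mean()` therefore averages exactly 9 frames.

Detrending is a rolling z-score: per-sample `(x - mu_w)/sigma_w` over a
centered 1-minute window, truncated at the edges (centered/truncated is
the package's choice; a trailing-window variant is not provided, and
the behavior is exposed only through the window width).
The z-score appears at two places, and the distinction matters:

* **On the raw modulated trace** (`detrend_raw = TRUE`): here `sigma_w`
  is dominated by the carrier modulation itself, so the operation
  removes photobleaching essentially without touching the signal. The
  analysis paths that feed the GLM (`recovery_report()`,
  `run_pipeline()`) use this.
* **On the demodulated power** (`zscore = TRUE`, the default): this
  yields the z-scored fluorescence series used for peri-event averages.
  Its `sigma_w` contains the signal's own variance, so window-to-window
  differences in event density modulate the local gain slightly. On
  noise-free synthetic input this signal-dependence is the dominant
  residual; with realistic noise it is minor. It is a property of the
  method, not of the implementation.

Because the final z-score removes scale, the whole chain is invariant to
a global gain on the raw samples (tested to 1e-6). One caveat is
documented rather than hidden: a perfectly constant-envelope channel
demodulates to a flat series whose only variation is deterministic
spectral-leakage ripple (relative SD about 3e-4); the z-score then
normalizes that ripple to order one. "No signal" should therefore be
judged before the z-score, or via event-locked averages, never by the
raw magnitude of the z-scored trace.

## The kernel GLM

`build_predictors()` lays ten binary event series on the frame grid:
CE, CX, SE, SX each split into ipsi/contra relative to the recorded
hemisphere, plus Rew and Unrew. `build_design()` expands each series
into 41 lagged copies (shifts of -20..+20 frames, 54 ms each), giving
410 columns; only frames from 20 frames before CE to 20 after SX are
modeled (the margin equals the shift span so every in-window event has
full kernel support), the inter-trial interval is excluded, and frames
shared by consecutive trial windows are duplicated into both trials'
groups so grouped cross-validation never splits an event from its
flanks. `fit_ridge()` solves

$$J(\beta) = \lVert y - X\beta \rVert_2^2 + \alpha \lVert \beta \rVert_2^2$$

in closed form via the normal equations, with the intercept included
and unpenalized and `alpha = 1` by default. Neither the response (it is
already z-scored) nor the predictors are standardized: the penalty is
interpreted on that raw scale. `cross_validate()` is a grouped shuffle
split by trial (10 folds, 80/20), and `omission_analysis()` refits the
ten model variants (Full, -Rew, -Direction, -Direction&Rew, -CE/CX,
-CE, -CX, -SE/SX, -SE, -SX) under a shared 5-fold scheme; variants are
expressed as column maps on the full design's crossproducts, so every
variant sees identical folds at almost no extra cost. `-Direction`
collapses each ipsi/contra pair into one timing-preserving series,
leaving (4 + 2) x 41 = 246 columns.

One identifiability point drove a design choice. If Rew/Unrew are
placed at the side-entry frame, then `SE_ipsi + SE_contra = Rew +
Unrew` holds row-wise in the design -- an exact linear dependency under
which the generating kernels of that quartet cannot be recovered (ridge
returns one representative of an equivalence class). The outcome is
physically revealed at the first lick, so the default places Rew/Unrew
at the FL frame (`outcome_at = "FL"`); the side-entry placement remains
available with the degeneracy documented. Note that events of a trial
remain strongly correlated (SE is followed by FL a few frames later),
so small-amplitude kernels are intrinsically the hardest to recover.

## The synthetic generator and what passing tests mean

`truth_spec()` fixes every generator parameter: the RFLR agent (alpha
1, beta 2, tau 1.4), the 90/10 task at 500 trials/session, the latency
distributions above, per-event response kernels, AR(1) frame noise
(coefficient 0.8, SD 0.5 z-units -- approximating the slow
autocorrelation of calcium indicators), an exponential bleaching drift
(30% depth, 20 min time constant) applied before modulation to exercise
the detrending path, and the 167/223 Hz carriers. Kernels are
difference-of-exponentials transients (100 ms rise, 400 ms decay,
support within the 41-lag window): a large positive transient after
ipsilateral center entry (1.5 z), a negative transient after rewarded
outcomes (-1.5 z), a positive one after unrewarded outcomes (+1.2 z),
and smaller positive responses (0.4-0.6 z) for the remaining events.
The small amplitudes are set at 0.5 z and not lower because, under the
fixed AR(1) noise, the per-event error of a 41-lag kernel estimate at
the default cohort size makes weaker kernels unresolvable at the 0.95
correlation level the recovery contract asks for; 0.5 z is within the
range of the smaller peri-event responses such recordings show.

The fluorescence envelope is rendered as a piecewise-linear
interpolation through frame-center values before modulation, so the
Hamming-windowed band power tracks the frame series faithfully; the
residual imperfection is the 108 ms window mixing adjacent frames,
which caps the *full-chain* noise-free kernel recovery near correlation
0.998-0.999 (the estimator-level noise-free recovery, with the response
built directly from the kernels on the frame grid, is exact to
numerical precision). Round-trip tests distinguish these two levels
deliberately.

What the generator does *not* emulate: biophysical indicator dynamics
(nonlinear calcium binding, saturation), motion artifacts, hemodynamic
or autofluorescence contamination, session-to-session expression
changes, and any behavioral non-stationarity (satiety, disengagement).
Passing recovery tests therefore demonstrates that the pipeline is
correct and well-conditioned for signals of this class, not that real
recordings satisfy its assumptions.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use, as the package's
standard desk-scale conditions: 20 sessions x 1000 trials for RFLR
recovery; a 6-mouse cohort with one rendered photometry session each
(about 240k design rows) for kernel recovery and cross-validation;
two-tone 40 s recordings for demodulation checks; and 1000 Monte-Carlo
replicates for the noisy tau-recovery check. These sizes keep every
stage within a few tens of seconds on one core while leaving the
statistical margins comfortable.

## Known limitations

* The demod-domain rolling z-score has signal-dependent local gain (see
  above); kernel estimates inherit a small systematic distortion from
  it that more data does not remove. Using the raw-domain detrend for
  GLM responses minimizes this.
* `fit_tau()` fits the across-mice mean curve; per-mouse tau values on
  few transitions can be unstable and are intentionally not returned by
  default.
* The simulator never emits aborted or timed-out trials, and the CSV
  schema has no representation for them.
* Elastic-net regularization is not implemented; ridge and OLS are.
  The solver slot in `fit_ridge()` is closed-form only.
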