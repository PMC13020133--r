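---
title: "Joint analysis of motion perception and smooth pursuit under direction biases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint analysis of motion perception and smooth pursuit under direction biases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdkpursuit)
library(dplyr)
```

## The scientific problem

When people track and judge the direction of a noisy moving stimulus, both
their perceptual reports and their smooth-pursuit eye movements combine
the current sensory evidence with expectations: short-term trial history,
an experimentally induced over-representation of one direction, and
long-standing "in-built" preferences for cardinal (horizontal/vertical)
directions.  The canonical paradigm presents random-dot kinematograms
(RDKs) whose global direction is one of 16 values spaced 22.5&deg; apart, at
signal coherences of 5%, 15% and 40%, across sessions in which either all
directions are equally likely or one "frequent" direction carries about
60% of the trials (rightward 0&deg;, or oblique up-left &minus;135&deg;).
Participants track the dots with their gaze and then draw the perceived
direction; eye position is recorded at 500 Hz.

The interesting phenomena live in the details of the measurement chain:

* **Perception.** The signed angular error `delta = stimulus - report`
  is computed on the circle (so the difference between 350&deg; and 10&deg; is
  20&deg;).  A report within the half-open &plusmn;11.25&deg; bin around the
  stimulus is *correct*; within the same bin around the opposite
  direction it is an *opposite* error; anything else is a *general*
  error.  Error trials are summarised by normalised 16-bin direction
  choice histograms, per-trial cardinal (+1/4 vs &minus;1/12) and hemifield
  (&plusmn;1/7, boundary bins 0) bias scores, and compared across sessions
  with a per-bin permutation test.
* **Pursuit.**  Gaze position is low-pass filtered (second-order
  Butterworth, 30 Hz, zero-phase), differentiated to velocity, and
  saccades are masked by a speed threshold.  Three phases are read out:
  anticipation (mean velocity in &minus;50 to 100 ms around stimulus onset,
  valid when its amplitude is 0.25&ndash;2.5 &deg;/s), open-loop acceleration
  (mean projected velocity in 200&ndash;220 ms minus 100&ndash;120 ms, divided by
  0.1 s), and steady state (mean projected velocity in 400&ndash;600 ms),
  where projection means
  `vproj = vx * cos(theta) + vy * sin(theta)` onto the stimulus
  direction `theta`.

Human data for this paradigm are not publicly deposited, so the package
ships a *synthetic observer*: a generative model that reproduces the
statistical structure the analysis assumes, making every stage testable
by parameter recovery.

## The synthetic observer

`observer_params()` collects the generative parameters.  Perceptual
reports are drawn from a mixture

* with probability `lapse_rate` (default 0.02): uniform on the circle;
* otherwise, with probability `w_sensory[coherence]`: a von Mises
  centred on the true direction with concentration `kappa[coherence]`;
* otherwise a *guess* from a cardinal von Mises mixture (components at
  0&deg;, &plusmn;90&deg;, 180&deg;, shared concentration `kappa_cardinal`) whose
  density is multiplied by
  `1 - a * vM(theta; frequent, kappa_avoid) / max(vM)` — a smooth dip of
  depth `a = avoidance_strength` at the session's frequent direction.

The defaults (`w_sensory = 0.30/0.80/0.95`, `kappa = 8/25/60` across the
5/15/40% coherences) were chosen once so that simulated accuracy rises
from roughly one-fifth to roughly four-fifths across the three coherence
levels, the operating range a practitioner would recognise for this
task; the cardinal weights favour rightward and horizontal directions,
and the default avoidance strength 0.6 produces a clear dip at the
frequent direction in error-trial histograms.  These are plausibility
choices, not fits to any dataset.

Eye velocity is the sum of

* an **anticipatory ramp** toward a direction drawn (von Mises, spread
  `anticipation_spread` = 40&deg;) around the expected direction — the
  frequent direction in biased sessions, a per-subject idiosyncratic
  direction otherwise.  The ramp starts at gap onset, plateaus at
  `anticipation_gain` (0.8 &deg;/s) before stimulus onset, and fades out
  after pursuit latency;
* a **visually driven component** along the stimulus direction, zero
  until `pursuit_latency_ms` (100 ms), then rising smoothly to
  `pursuit_gain[coherence] * 10` &deg;/s over `pursuit_rise_ms` (300 ms), so
  the plateau is reached exactly at the 400-ms steady-state window;
* white Gaussian velocity noise (`velocity_noise_sd` = 0.5 &deg;/s per
  channel) and **saccades** injected as raised-cosine velocity pulses
  (Poisson events, default 2 per second, 150 &deg;/s peak, 30 ms), whose
  ground-truth intervals are returned for testing the detector.

All transitions use a quintic smoothstep, which is twice continuously
differentiable.  This is a deliberate design choice: the measurement
chain low-pass filters position at 30 Hz with a zero-phase filter, and a
velocity profile with a slope discontinuity (e.g. a pure exponential
rise switched on at latency) leaves a filter transient of a few tenths
of a &deg;/s right inside the 100&ndash;120 ms acceleration window.  With C2
transitions the filter passes the deterministic profile essentially
unchanged (errors around 10^-4 relative), so noise-free recovery of the
generator parameters through the *full* chain is meaningful; it is also
closer to the smoothly accelerating velocity profiles actually measured
in pursuit.  Position is the trapezoid integral of velocity, so the
integral-consistency invariant holds to numerical precision.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- analysis_config(
  n_subjects = 8,
  designs = list(
    make_session_design("unbiased", n_trials = 120),
    make_session_design("biased", frequent_direction = 0, n_trials = 120),
    make_session_design("biased", frequent_direction = -135, n_trials = 120)
  ),
  n_perm = 2000, seed = 1
)
run <- run_pipeline(cfg)
tidy(run$results$choice_tests$biased_0)
autoplot(run$results$choice_tests$biased_0)
```

The full-size study conditions are the defaults of `analysis_config()`:
21 subjects, 480 unbiased and 474 biased trials per session, 10000
permutations.  The examples above, and the package's tests, run the same
code on smaller problem sizes (a few subjects, tens to hundreds of
trials, 200&ndash;2000 permutations), which the package treats as its standard
worked-example scale; all statistical behaviour checked by the test
suite is scale-free or tested at the scale stated in each test.

## Numerical and statistical design choices

**Angles.**  Everything lives on the half-open interval (&minus;180&deg;, 180&deg;]
with 0&deg; = rightward and positive angles clockwise/downward.  All 16
direction bins are half-open `[c - 11.25, c + 11.25)`, which makes the
three-way correct/opposite/general classification an exact partition —
closed bins would double-count boundary reports.  The hemifield score
assigns 0 to the boundary bins 0&deg; and 180&deg; and &plusmn;1/7 to the seven
strictly-signed bins per hemifield, the only assignment consistent with
defining hemifields by the sign of the angle.

**Filtering.**  The low-pass is applied forward and backward (zero
phase): a causal filter would delay the velocity trace by several
milliseconds and shift every window-based latency estimate.  The trace
is padded by odd reflection before filtering, so constant and linear
trends pass without edge transients.  Velocity uses central differences,
exact for locally quadratic position.

**Saccade masking.**  The speed threshold defaults to 30 &deg;/s with 10 ms
of padding on each side — conventional for 10 &deg;/s pursuit; both are
config parameters.  Masked samples become `NA` and window means simply
ignore them; a window with less than 50% unmasked coverage yields a
missing metric and flags the trial.  When the detector is scored against
the generator's ground truth, "pursuit samples" are samples more than
22 ms away from any true saccade interval: the 10-ms padding plus filter
smear deliberately masks a small neighbourhood around each event, and
counting that neighbourhood as false alarms would penalise the detector
for doing what it is configured to do.

**Permutation test.**  The observed statistic is the mean over subjects
of the per-bin histogram difference (test minus baseline session); the
null permutes session labels within each subject, preserving each
subject's per-session trial counts, with a subject-level flip exposed as
an option.  The p-value uses the add-one estimator and is **two-sided by
default** (tail of |difference|).  A one-sided p taken in the direction
of the observed difference — the way per-bin difference displays are
often read — is exposed as `alternative = "directional"`, but it cannot
be the default: choosing the tail after seeing the sign doubles the
type-I rate to 2&alpha;, and the package's own calibration tests require the
per-bin rejection rate at &alpha; = 0.01 to sit at the nominal level.  No
multiple-testing correction is applied across the 16 bins by default
(matching the per-bin display convention); Bonferroni is available.

**Watson&ndash;Williams.**  The classical corrected F is implemented directly
(no circular-statistics dependency exists in the package's stack):
per-group resultant lengths, pooled within-group resultant, Fisher's
A1-inverse for the concentration, correction factor `1 + 3/(8 kappa)`.
A warning is raised when the pooled resultant length drops below 0.45,
where the test is known to misbehave.  The test suite cross-checks the
implementation against an independent transcription of the textbook
formulas and verifies the nominal 5% size by simulation.

**Correlating angles.**  A Pearson correlation between two angular
series is not well defined; the package wraps both series and re-centres
both on the circular mean of the first, which places the cut point of
the circle opposite the bulk of the data.  This is documented as the
package's choice and is reliable only when the joint distribution is
concentrated — at low coherence the reported correlations should be read
with that caveat.

**Determinism.**  Every random stage derives a child seed from the
master seed (per subject, per trial, per analysis), so a single trial
can be regenerated in isolation and the whole pipeline is bit-for-bit
reproducible; the permutation and simulation seeds are echoed in the run
report.

## What the generator does and does not emulate

The synthetic observer reproduces the *statistical contracts* the
analysis relies on: direction probabilities of the session designs,
coherence-dependent report precision, cardinal clustering and avoidance
of the frequent direction in guesses, anticipatory velocity oriented
toward the expected direction, coherence-dependent pursuit gain,
velocity noise and saccades with known ground truth.  It does not
emulate pursuit latency variability across subjects, catch-up saccade
dynamics coupled to position error, blinks, drift in fixation, or any
dependence of perceptual reports on the eye movement actually produced.
Passing tests therefore demonstrate that the measurement chain recovers
known generative structure — not that the generator is a faithful model
of human observers.

## Known limitations

* The GLMM/LMM wrappers are contract-level: they expose signs and
  p-values of fixed effects and surface convergence complaints, but
  model selection, random-slope structures and Bayes factors are out of
  scope.
* The serial-dependence Watson&ndash;Williams test assumes reasonably
  concentrated per-subject mean errors; with very few trials per bin the
  low-concentration warning should be taken seriously.
* The per-trial re-centring rule for angle/report correlations breaks
  down when the two series are diffusely or multimodally distributed.
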