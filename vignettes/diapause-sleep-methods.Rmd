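---
title: "Methods: circadian activity, deep sleep and shade preference analysis with flysleepr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian activity, deep sleep and shade preference analysis with flysleepr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysleepr)
library(data.table)
```

## Scope

`flysleepr` quantifies *Drosophila* behavior from two kinds of recordings:
Trikinetics-style Drosophila Activity Monitor (DAM) files, in which an
infrared beam across the middle of each tube counts crossings per time
bin, and single-fly video-tracking trajectories from a 44 mm x 6 mm
arena whose long axis is split into two lighting zones (shaded vs.
bright, or red vs. blue) by a filter at a configurable boundary.  On top
of these it implements the analyses used to characterize how
diapause-inducing cool temperatures (10 C) reshape circadian activity,
deepen sleep, and abolish the warm-temperature preference for resting in
the shade: day-folded activity profiles and peak phase, the morning
activity index, day/night activity totals, five-minute-rule sleep
scoring, vibration/blue-light arousal thresholds as a function of prior
immobility, responder proportions, post-stimulus speed kinetics, sleep
latency, zone preference indices, and the aligned-rank-transform (ART)
factorial ANOVA conventions of this literature.

Because raw recordings from the original study design are not shipped,
the package includes a first-class synthetic fly generator.  Its role is
to provide ground-truth data *with known generative parameters* so that
every estimator in the package can be validated by parameter recovery;
it is not a fitted model of real flies.

## Time conventions

All analyses run on zeitgeber time (ZT): ZT 0 is lights-on and the
photoperiod `xL:yD` puts lights-off at ZT `x`.  DAM timestamps are
mapped to ZT using the configured lights-on clock time; the first record
maps into `[0, 1440)` minutes and ZT accumulates monotonically from
there, so multi-day recordings fold by `zt_min %% 1440`.  All intervals
are half-open `[start, end)`.  Trajectories are assumed to start at
ZT 0 (the simulator guarantees this); an offset argument
(`start_zt_min`) covers recordings that start elsewhere.  Arena
coordinates are millimeters with the origin at the shaded-end wall and x
along the tube.

## Sleep scoring

A minute `[m, m+1)` is immobile when the fly never strays more than
`move_threshold_mm` (default 3 mm, roughly one body length — the same
displacement used to score stimulus responses) from its position at the
start of the minute.  For DAM data a bin is immobile when its count is
zero.  Sleep is any maximal run of at least five consecutive immobile
minutes; untracked minutes break runs rather than join them, which is
the conservative choice when tracking drops out.  Raising the movement
threshold can only add immobile minutes, so total scored sleep is
monotone in the threshold — a property the test suite checks, together
with exact agreement with an independent brute-force run scanner on
random immobility strings.

## Arousal trials

A stimulus train (default: five 3-s vibration pulses of increasing
drive level delivered back-to-back, every 2 h; or five 3-s blue-light
pulses with 10-s gaps) defines one potential trial per fly.  The fly
enters the trial if it was immobile for at least `min_immobility_s`
(default 5 s, the shortest reporting bin) at train onset.  Immobility is
anchored at the fly's position on the last frame before onset and
scanned backwards; the scan is capped at 4 h, beyond the deepest
reporting bin (> 120 min), and durations at the cap are treated as
right-censored.  The response window of pulse *k* runs to the onset of
pulse *k+1* (the last window extends one pulse length plus one
interpulse gap), and a response is a displacement of at least 3 mm from
the pre-stimulus position inside a window.  The arousal threshold of a
trial is the intensity of the first responding pulse.

Two reporting conventions exist for non-responding trials, and
published threshold-vs-immobility averages do not always state which is
used, so `threshold_vs_immobility()` exposes both: censor at the
maximum delivered intensity (default; keeps deep-sleep trials in the
average as a lower bound) or drop.  Intensities default to an identity
drive-level calibration (levels 1..5 map to g values 1..5 in arbitrary
units); a measured accelerometer calibration can be loaded from CSV.

Sleep latency is clocked from the first response frame to the rest
onset of the next scored sleep bout.  The five-minute rule places bout
starts on a minute grid, which would add a ~0.5-min quantization bias —
material when cold-regime latencies are ~2 min.  Since trajectories
carry frame resolution, the package refines the endpoint by scanning
backwards from the bout start while the fly stays within the movement
threshold of its bout position, recovering the actual settling frame.
With DAM-only data the endpoint falls back to the bout-start minute.
When a fly resumes rest almost instantly, the measured latency floors
near zero plus one frame, not at five minutes: the bout *certifies* the
rest but its start backdates to the beginning of the immobile run.

## Preference indices

Every preference index is the standard difference-over-sum place
preference: `PI = (t_A - t_B) / (t_A + t_B)` over frames (occupancy
PI) or bout minutes (sleep PI), bounded in `[-1, 1]` with 0 =
indifference and positive values meaning preference for zone A (shade
or red by convention).  The exact formula behind published shade/sleep
PIs is described in supplementary material we do not reproduce; the
difference-over-sum form is adopted because reported values span
`[-1, 1]` with 0 as indifference.  A frame exactly on the zone boundary
belongs to zone A; a bout's zone is the zone of its median position
(robust to boundary jitter).  Swapping the zone labels negates every
index, and the bout-based sleep PI equals a per-frame (sleep AND zone)
computation exactly when bouts do not straddle the boundary — both are
tested.  Note that the PI of a window is a ratio of sums, not the mean
of sub-window PIs, unless denominators are proportional; the test suite
keeps a counterexample.

The day is partitioned, when needed, as early day `[ZT 0, 6)`, late day
`[6, 12)`, early night `[12, 18)`, late night `[18, 24)`.

## Activity profiling

`daily_profile()` folds each fly's complete days onto the 24-h axis,
averages within fly and then across flies (mean ± SEM), with optional
circular centered moving-average smoothing and peak normalization.
Peak phase is smoothed argmax — not curve fitting — matching how peak
times are read descriptively from such profiles; ties break toward the
earliest ZT, and the conventional evening-peak search window is ZT 2 to
lights-off + 2 h.  A 30-min smoothing window is the default used in the
package's own analyses; the smoothing behind published peak times is
not stated, so it is a configurable convention here.

The morning activity index is the proportion of daytime activity in
`[ZT 0, 6)`.  The literature also contains a `[ZT 0, 5)` variant of the
window; the package defaults to ZT 0-6 and makes the window an
argument.

## The synthetic fly

The generator is a discrete-time (default 1 Hz) two-state model built
from the classical two-process framing: a circadian wake drive `C(t)`,
a sum of circular Gaussian bumps on the 24-h ZT axis, and a sleep
homeostat `H` in `[0, 1]` that rises at `homeostat_rise_per_h` while
awake and decays exponentially at `homeostat_decay_per_h` while
resting.  An awake fly enters rest with per-minute hazard
`plogis(b0 + bH*H - bC*C)` (converted to the frame step as
`1-(1-p)^(dt/60)`); a resting fly wakes spontaneously at
`trans_r2w_per_min`.  On entering rest the fly settles at a uniform
point in the shaded zone with probability `plogis(A - kappa*H)` —
light aversion traded off against sleep pressure — and otherwise in the
bright zone; rest positions carry 0.1 mm Gaussian micro-jitter (real
micro-movements during rest are not quantified anywhere we can cite;
this stand-in simply exercises the immobility threshold).  Awake flies
random-walk with reflecting walls.

Stimuli interrogate a resting fly at each pulse onset: it responds when
a logistic draw with midpoint `theta(d)` (the arousal threshold at its
current immobility `d`, interpolated linearly in log immobility between
`threshold_nodes`) and slope `response_prob_slope` succeeds.  A steep
finite slope (10 per g) rather than a hard threshold avoids
zero-variance estimators; `Inf` is accepted and gives the hard rule.  A
responding fly moves ballistically with speed decaying from
`post_startle_peak_mm_s` with constant `post_startle_decay_min`, then
walks until an exponentially distributed re-sleep latency
(`resleep_latency_mean_min`) elapses.

A deliberately small design choice: there is no discrete "deep sleep"
state.  Depth emerges entirely from `theta(d)` and the homeostat, which
is the smallest mechanism that reproduces threshold-vs-immobility
curves of the observed shapes.

### Regime defaults

The two built-in regimes encode the qualitative study conditions; node
values are package defaults chosen once for shape and recoverability,
and are **not** fitted to any real recording:

* **warm25** — bumps at ZT 0.7 and ZT 14.5 (crepuscular, evening peak
  ~1.5 h before lights-off under 16L:8D, midday siesta between);
  threshold nodes (5 s, 0.35), (5 min, 0.35), (10 min, 3.5),
  (75 min, 3.8), (120 min, 2.6) — low before 5 min, an exactly 10-fold
  rise by 5-10 min, peak at 60-90 min, decline after; re-sleep latency
  mean 25 min (the scale of reported late-night latencies); strong
  shade logit (A = 4.5, kappa = 1.5), so nearly all daytime sleep is
  shaded.
* **cold10** — a single bump at ZT 9.5 (mid-to-late-day activity peak);
  high rest pressure (b0 = 1.5) with a low spontaneous wake rate;
  threshold nodes (5 s, 0.7), (15 s, 1.2), (20 s, 5.0), (1 min, 5.2),
  (2.5 h, 5.4) — easily roused only within the first 15 s of rest, with
  the threshold rising steeply immediately beyond 15 s so it exceeds
  the warm peak within 0.25-1 min and plateaus above the strongest
  delivered pulse (only a few percent of deep-sleep trials respond, at
  the strongest pulse); re-sleep latency mean 2 min; an indifferent
  shade logit (A = 0.05, kappa = 0.3), noting that `H` sits near zero
  in a mostly-sleeping fly.

Wake step SDs (2.8 mm warm, 2.0 mm cold per 1-s frame) are set high
enough that a *walking* fly almost never stays within the 3-mm
immobility radius for the 5-s eligibility window; when it briefly does,
it leaves the radius within the first pulse window, so such "pauses"
enter the threshold analysis at the response floor rather than at an
arbitrary later pulse.  Startled flies run along the tube axis (a
random transverse heading in a 6-mm-wide arena would often fail to
clear the 3-mm response criterion before bouncing off a wall), with
peak speeds (3.5 / 3.0 mm/s) above the wake step SD so a generative
response crosses the criterion inside its own 3-s pulse window at 1 Hz
frames.

Because immobility keeps accruing during a 15-s train and the cold
threshold curve rises several-fold between 15 and 20 s, validation
against ground truth evaluates the generative threshold at the
immobility the fly had reached at the deciding pulse (the responding
pulse, or the last delivered pulse for censored non-responders); for
every bin whose immobility dwarfs the train length the two references
coincide.  Measured latencies also carry a small positive bias: when
the first post-startle rest is interrupted before five minutes, the
scored bout — and hence the latency endpoint — defers to the next
qualifying rest.

The simulator consumes a fixed set of random draws per frame (one
transition uniform, three settle uniforms, two movement normals), so
runs with matched seeds stay aligned when a single parameter changes;
this makes couplings such as "raising `bH` never decreases total rest"
testable pathwise.  Stimulus-event draws are consumed only when a pulse
fires, so exact alignment is guaranteed only for undisturbed runs.

### What the generator does and does not emulate

It reproduces, by construction: crepuscular bimodality with a siesta at
25 C vs. a single mid/late-day peak at 10 C; immobility-dependent
arousal thresholds with the two regime shapes; short cold re-sleep
latency; shade-biased warm resting that dissipates in the cold; and
DAM counts consistent with the trajectory via beam emulation.  It does
not emulate: tracking noise and dropouts (tests inject those
separately), temperature ramps, inter-fly heterogeneity in parameters,
grooming/feeding micro-behavior, or any pharmacological or genetic
manipulation.  Passing recovery tests therefore demonstrates estimator
correctness on data with known truth — not that real flies obey this
model.

## Statistics layer

`art_anova()` implements the aligned-rank transform for a two-way
layout: for each effect the response is aligned by removing the cell
mean and adding back that effect's own estimate computed from
unweighted cell means, ranked with average ranks, and passed to a
standard type-III factorial ANOVA on the ranks (sum-to-zero contrasts,
via `car::Anova`); only the aligned effect's row is kept.  A fully tied
alignment (e.g., identical responses) is reported as F = 0, p = 1
rather than 0/0.  Post-hoc contrasts run on the aligned ranks with
pooled-variance t statistics and either Bonferroni or Tukey-Kramer
adjustment.  Repeated measures within a fly should be collapsed to
per-fly summaries before testing, matching the per-fly n reporting
convention and avoiding pseudo-replication; the package deliberately
fits no mixed models.  `rank_sum()` enumerates the exact permutation
distribution of the rank sum for pooled n of at most 20 (correct under
ties because ranks are averaged first) and otherwise uses the normal
approximation with tie and continuity corrections.

Null calibration is a standing test: over 1,000 two-way null
simulations the per-effect type-I error at alpha = 0.05 must stay
within [0.03, 0.07].

## Problem sizes used in the validation suite

The test and acceptance analyses use cohorts of 60 flies x 4 days (1 Hz
frames) per temperature regime for threshold and latency recovery, 20
flies x 3 days for preference indices, and 12 flies x 2 days for
activity signatures; these sizes give estimator standard errors
comfortably inside the stated recovery tolerances (one intensity step
per immobility bin; 20% of the generative latency mean) while keeping a
full run on one CPU in minutes.  Scoring equivalence uses 1,000 random
immobility strings; beam emulation is checked against a brute-force
crossing counter on 100 random walks.

## Known limitations

* The simulator's wake/rest architecture is exponential-ish by
  construction; real fly bout-length distributions are heavier tailed.
* Arousal eligibility at very short immobility (5-15 s) is dominated by
  pause-like events; with DAM data (1-min bins) this bin is not
  measurable at all.
* The ART implementation targets two-way layouts, the largest design
  used in this family of analyses.
* Latency refinement to frame resolution assumes trajectories; DAM-only
  latencies keep the minute-grid floor.
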