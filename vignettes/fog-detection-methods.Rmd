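---
title: "Detecting freezing of gait from binary plantar-pressure insoles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting freezing of gait from binary plantar-pressure insoles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfog)
```

## The measurement model

Each insole carries six pressure-sensing units (PSUs), membrane switches
with a fixed switching pressure: the output is 1 whenever the applied
plantar pressure reaches or exceeds the threshold, and 0 otherwise
(`binarize()`, inclusive comparison). S1 sits under the heel with the
highest threshold (50 kPa by default, because heel strike carries the
largest impact), S2/S3/S6 under the metatarsal heads (27.5 kPa, the
mid-range of the 20--35 kPa hardware variants) and S4/S5 capture
inversion/eversion loading (20 kPa). Both insoles sample at 32 Hz, so one
sample spans $\Delta t = 1/32$ s; time is represented purely as
`sample_index / sampling_rate`, with no wall clocks.

The *combined signal* of a foot is the per-sample OR of its six bits
(`combine_signal()`). While it is 1 the foot is loaded somewhere (single
support / stance); while it is 0 the foot is airborne (swing). Its
0\,\to\,1 transitions are foot strikes (FS) and its 1\,\to\,0 transitions
foot offs (FO) (`detect_events()`). Double support is the conjunction of
the two feet's combined signals. `segment_phases()` turns maximal runs
into half-open episodes $[a\Delta t, (b{+}1)\Delta t)$; episodes touching
a recording boundary are flagged *truncated*, because their observed
duration is a biased underestimate, and are excluded from every duration
statistic. `running_durations()` provides the equivalent streaming view:
accumulators that grow by $\Delta t$ while their phase condition holds and
reset to zero the sample it fails; the peak an accumulator attains inside
an episode equals that episode's duration.

## The FoG decision

Freezing of gait manifests as complete akinesia or trembling in place
(both feet remain loaded: abnormally long double support) or as small
shuffling steps (abnormally short swings). Gait varies strongly between
wearers and with medication state, so all decisions are made *relative to
a per-user calibration*: a short FoG-free walk with straight lines and
turns from which `calibrate()` takes the arithmetic mean of non-truncated
double-support durations ($\bar T_{DS}$) and of pooled left+right
non-truncated swing durations ($\bar T_{SW}$). Calibration requires at
least 8 episodes of each kind per foot by default; fewer raise an error
naming the deficient phase rather than producing a fragile baseline.

With dimensionless multipliers $k_{DS}, k_{SW} > 1$:

* a double-support episode raises the long-double-support index when its
  duration $\ge k_{DS}\,\bar T_{DS}$;
* a swing is *short* when its duration $\le \bar T_{SW}/k_{SW}$
  (equivalently its reciprocal peak $\ge k_{SW}/\bar T_{SW}$), and the
  short-swing index fires at the $m_{SW}$-th consecutive short swing of
  the *same* foot ($m_{SW} = 2$ by default; the left and right shuffling
  events are bookkept separately, so runs are per-foot, and only a
  non-short swing of the same foot resets the counter).

The per-sample decision is the disjunction of the two indices. All
comparisons are inclusive ($\ge$), and the same comparison is used during
training and deployment. The reference defaults $k_{DS} = 4.7$ and
$k_{SW} = 4.5$ are the values obtained on the original clinical training
data and ship in `detection_thresholds()`; they are starting points, not
universal constants — per-user training (below) is preferred.

`detect_fog_offline()` turns the indices into events: one LDDS event per
flagged double-support episode, one SSW event per maximal run of at least
$m_{SW}$ consecutive short swings (interval from the first short swing's
start to the last one's end). Detections separated by less than
`merge_gap` (0.5 s, below one gait cycle, so fragments of one clinical
freeze are not double-counted) merge into a single event keeping the
earliest onset and that detection's kind.

### Online detection and its equivalence to the offline path

`onset_detector()` / `detector_step()` implement the same decision as a
streaming automaton: the LDDS onset fires at the first sample where the
running double-support accumulator reaches $k_{DS}\bar T_{DS}$ — exactly
$\lceil k_{DS}\bar T_{DS}/\Delta t\rceil\,\Delta t$ after the double
support began, measured at the end of the crossing sample — and the SSW
onset fires at the foot strike ending the $m_{SW}$-th consecutive short
swing. The two paths are required to announce *identical* event sets on
every input, which pins down several conventions:

* onset times use an end-of-sample convention (an accumulator value is
  known once its sample has completed);
* a truncated double-support episode that has already crossed the
  threshold is detected by both paths (the online detector cannot know the
  recording is about to end, and truncation only underestimates the
  duration, so the crossing is certain); truncated swings are ignored by
  both paths;
* the merge rule is evaluated in detection order: a new detection joins
  the current merged event if an earlier member is still running (or may
  still extend — a fired short-swing run remains open until the same
  foot completes, or provably exceeds, a non-short swing) or if its
  interval starts within `merge_gap` of the latest completed member.

This equivalence is asserted property-style on randomized streams in the
test suite.

## Threshold training

`build_instances()` reduces a labelled recording to scored instances: each
non-truncated double-support episode with ratio
$T_{DS}/\bar T_{DS}$, and each maximal same-foot swing run with ratio
$\bar T_{SW}/\min(T_{SW})$ (its largest reciprocal swing peak). Labels are
*kind-matched* — double-support instances against LDDS truth intervals,
swing runs of foot $f$ against SSW$_f$ truth — because the two indices
respond to different FoG manifestations and are trained independently; a
flat any-overlap label would poison the double-support class with the
normal-length double supports that occur *inside* a shuffling episode.
Swing runs are delimited by label changes: without a delimiter each foot
would contribute exactly one run per recording. A normal-labelled run is
then scored by its most extreme (shortest) swing, which is precisely the
"largest normal value" boundary the fuzzy zone needs.

The *fuzzy zone* is the ratio interval between the largest normal-gait
value and the smallest FoG value (`compute_fuzzy_zone()`, stored sorted).
`train_thresholds()` evaluates every candidate $k$ on a 0.1-step grid
spanning the zone (0.1 matches the precision of the published defaults),
classifying FoG iff ratio $\ge k$, and returns the grid point maximising
sensitivity + specificity. Sensitivity is non-increasing and specificity
non-decreasing in $k$ by construction, and this is asserted during
training. Ties — in particular the fully separable case where the whole
interior scores 2 — resolve to the midpoint of the maximal-scoring
contiguous grid interval, rounding to the lower grid point on an exact
half, which places the decision boundary centrally between the classes
rather than hugging either.

## Evaluation conventions

`evaluate_events()` matches predictions to truth greedily one-to-one in
time order; a pair matches when the prediction interval overlaps the truth
interval expanded by `tol` = 0.5 s on each side (annotation jitter between
video and sensor clocks). TP/FN count truth episodes, FP counts unmatched
predictions. Event detection has no natural negative *event*, so the
negative class is episode-level: TN counts normal-labelled instances not
flagged at the thresholds in use. This is a declared convention — the
original supplementary definitions are not available — and it makes
accuracy an episode-level quantity dominated by the (many) normal
episodes. `detection_accounting()` reports the event-count view: correct
= matched/predicted, over = its complement (they sum to 100% exactly),
under = unmatched truth/total truth. `latency_stats()` summarises
onset-minus-truth-start per event kind.

## The streaming transport model and cueing

The insoles transmit in fixed packets of 8 samples (`packetize()`); a
packet is delivered at the capture time of its last sample plus an
optional transmission delay, so a sample's availability delay spans
$[0, (p{-}1)/F_s]$ within a packet and `packet_period()` $= p/F_s$ (0.25 s
at the defaults) is the response-time variation packetization induces.
`stream_detect()` replays packets in delivery order into the online
automaton; packetization may delay *decisions* (`decision_time`) but never
changes them, and a trailing partial packet is flushed at stream end so
finite recordings lose nothing. The default transmission delay is 0:
radio latency is hardware-specific and out of scope, so reported
latencies isolate the algorithmic plus packetization components.

`cueing_step()` is the intervention controller: cueing activates at the
first FoG flag and deactivates only after the wearer's usual gait has been
maintained for 30 s *in a continuum* — any FoG flag during the countdown
clears it. `wear_life()` converts a PSU's compression-cycle fatigue
rating into expected wearing life (months of 30.44 days).

## What the synthetic generator emulates — and what it does not

No clinical recordings are distributed, so `simulate_recording()`
generates labelled bilateral pressure traces with the statistical
structure the detector consumes:

* **Clean gait**: alternating stance/swing per foot with a double-support
  overlap at each step. Per-step double-support and swing durations are
  Gaussian around `ds_mean` = 0.15 s and `swing_mean` = 0.45 s with an 8%
  coefficient of variation, rounded to whole samples; stance is emergent
  (about $ds + \text{contralateral swing} + ds \approx 0.75$ s — the
  configured `stance_mean` of 0.65 s is documentation of scale, the
  generator honours the two durations that drive the calibration
  baselines, as the three are mutually overdetermined). Turns are
  represented temporally: 10% of double supports are widened 1.5-fold.
* **Pressure waveforms**: within each contact the heel loads first (a
  raised sinusoidal bump peaking at 120 kPa over the first 60% of the
  contact, never below 70 kPa while active) and the forefoot afterwards
  (80 kPa peak over the last 60%, never below 45 kPa), so every contact
  sample clears at least one PSU threshold and the binarized stance equals
  the scheduled stance to the sample. The amplitudes are synthetic
  conveniences chosen to clear the thresholds with margin, not measured
  values.
* **Episodes**: starts follow a Poisson process at `fog_rate` = 2/min;
  durations are i.i.d. from a log-normal law ($\sigma = 0.8$) truncated by
  rejection — not clipping, so the law has no atoms at the bounds — to
  0.4--31.8 s, with the location parameter solved numerically
  (`calibrate_episode_location()`, bisection to $10^{-3}$ s) so the
  truncated mean is 2.4 s, the published cohort statistics. The log-normal
  family itself is a modelling choice; the clinical distribution's shape is
  unknown. Manifestations are multinomial: 40% akinesia (both feet held
  loaded), 20% trembling (both feet loaded while one forefoot oscillates
  about its threshold at 4--8 Hz — no foot clears the ground, so it
  presents as long double support, and the truth label is LDDS), 40%
  shuffling (one foot takes 0.05--0.12 s swings with 0.2 s stances while
  the other stays loaded; episodes start and end on a swing so even a
  0.4 s episode contains the two short swings the detector needs).
* **Placement rules**: episodes snap to the next double-support instant;
  the first 30 s (plus a 1.5 s snapping buffer) are kept episode-free so
  calibration has a guaranteed FoG-free window, inter-episode gaps are at
  least 2 s, and nothing is injected into the last 5 s. All randomness
  flows from the single seed; equal configurations are bit-identical.

By construction, injected freezes and clean gait are well separated
(double supports of at least 0.4 s against a 0.15 s baseline; swings of at
most 0.12 s against 0.45 s), so trained thresholds reach sensitivity +
specificity = 2 on clean synthetic cohorts. Real pathological gait is far
less tidy: festination, near-threshold loading, sensor-skin migration,
dropped packets and annotation ambiguity all blur the classes. Passing the
synthetic suite therefore demonstrates the *machinery* — segmentation,
calibration, training, the offline/online equivalence, the latency
accounting — not clinical performance; the published clinical accuracy
figures were obtained on undeposited data and cannot be reproduced here.

## Numerical choices

Run/episode arithmetic is integer (sample counts); thresholds convert once
per run via $\lceil k_{DS}\bar T_{DS}/\Delta t - 10^{-9}\rceil$ and
$\lfloor (\bar T_{SW}/k_{SW})/\Delta t + 10^{-9}\rfloor$, the guards
absorbing float noise so decimal-valued baselines behave as exact
arithmetic. Times are multiples of $1/32$ and hence exact in binary
floating point. Ratio-grid classification uses a $10^{-12}$ guard for the
same reason. Degenerate inputs fail loudly: empty streams, misaligned
feet, single-class training sets, non-positive parameters and time
regressions all raise typed errors rather than guessing.

## Problem sizes

The packaged checks run a deliberately desk-scaled protocol: 20 synthetic
recordings of 180 s (seeds 1--20), per-recording calibration on the clean
30 s window, thresholds trained on recordings 1--10 and evaluated on
11--20, offline and through the 8-sample packetizer; the episode-duration
law is checked with 1,500 draws; the segmentation/accumulator equivalence
runs on 1,000 randomized streams. `scripts/acceptance.R` re-runs the same
protocol from scratch for any seed.

## Known limitations

* Temporal information only: no stride length, speed or spatial metrics
  (the hardware has no distance sensing).
* No FoG *prediction* before onset, and no medication-state modelling.
* The episode-level negative class makes specificity and accuracy depend
  on how finely normal gait is segmented into instances.
* The per-user calibration assumes the calibration walk is FoG-free; a
  contaminated baseline inflates $\bar T_{DS}$ and silently raises the
  detection bound.
* Bluetooth transport, audio/laser cue delivery and battery modelling are
  out of scope; `transmission_delay` is a single constant, not a radio
  model.
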