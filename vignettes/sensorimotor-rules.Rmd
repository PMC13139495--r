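---
title: "Modelling sensorimotor rules of fly courtship song"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sensorimotor rules of fly courtship song}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songrules)
```

## The problem

During courtship a *Drosophila* male patterns his song — trains of brief
pulses, sustained sine oscillation, or silence — moment by moment, using
feedback cues from the partner: how far away she is, how she moves, where
she sits in his visual field. `songrules` implements a pipeline for asking
*which rules* map those cues to song: kinematic featurization of two-fly
pose tracks, a hidden-state input-driven emission model (HMM-GLM) of song
patterning, behavioural-map segmentation of the joint dynamics, and
signal-level song statistics. A synthetic-data generator with full ground
truth makes every stage testable without any recordings.

## Feedback features

`compute_features()` turns two-fly pose tracks (six body parts per fly)
into ten per-frame features at 30 Hz: signed forward velocity along the
head–abdomen axis (`cFV`, `pFV`; mm/s, courter/partner), lateral and
rotational speeds as magnitudes (`cLS`, `pLS`; `cRS`, `pRS`), the
thorax–thorax distance `dis` (mm), the relative angles `ctheta` (the
courter's position in the partner's frame) and `ptheta` (the partner's
direction in the courter's frame; both in [0°, 180°]), and the body-angle
difference `phi`. Angles are held in degrees at interfaces and radians
internally, and headings are unwrapped before differencing so a 360°
wrap never masquerades as a rotation burst. Downsampling (e.g. 100 to
30 Hz) low-pass filters before decimating to avoid aliasing. Missing
keypoints are linearly interpolated up to 0.2 s; longer gaps flag frames
invalid, and those frames are excluded from the interaction masks.

An interaction requires the pair to be within 8 mm with the partner inside
±60° of the courter's heading. When both flies qualify simultaneously the
previously assigned courter is retained; at a first mutual encounter the
fly facing its partner more directly is chosen, with ties to fly 0 (the
rule in the source analysis fixes only the persistence, so the
initialization is our choice). Head/tail quadrant occupancies are smoothed
with a 0.5 s rule — bouts shorter than 0.5 s are dropped and same-quadrant
bouts separated by less than 0.5 s merge — before computing
P(quadrant | interaction). Tail-to-head transition events require at
least 2 s in the tail quadrant followed by at least 2 s in the head
quadrant; a gap tolerance (default 0.5 s) covers the frames consumed by
the partner's turn itself.

## The HMM-GLM

At each 30 Hz frame the male emits one of `M = 3` modes
(pulse, sine, silence). A hidden state `z_t` in `1..K` indexes a
*sensorimotor rule*: a multinomial GLM from the cue history to mode
probabilities,

P(y_t = i | x_t, z_t = k) = exp(w_ki · x_t) / Σ_j exp(w_kj · x_t),

with the silence filter pinned to zero for identifiability. The cue
history spans 4 s (N = 120 lags); each feature's lagged history is
projected onto D = 10 raised-cosine basis functions whose peaks are
log-spaced so recent lags are resolved finely and delayed ones coarsely
(the source defines the basis family but not D; 10 is the package default
and configurable). The projected vector is z-scored — statistics estimated
on training trials and frozen for held-out data — and a bias 1 appended,
so each state's filter bank has M × (10·D + 1) coefficients. Rows at a
trial start lack full histories; missing lags are imputed with the
training feature means, equivalent to zero-padding in z-scored space.
Hidden-state dynamics are a fixed sticky transition matrix α and initial
distribution π; transitions do not depend on the inputs.

Inference uses scaled forward–backward recursions; the per-step scaling
constants are one-step predictive probabilities, so subsets of time
points (e.g. only pulse-to-sine switches) can be scored exactly. Fitting
is EM: π and α update in closed form from the state and pairwise
marginals; each state's filters are a γ-weighted L2-penalized multinomial
regression solved by L-BFGS, warm-started from the previous iterate. The
penalty is `l2` per training sample (default 1e-3) on all non-bias,
non-silence coefficients. The penalized objective is non-decreasing each
iteration (a filter update that fails to improve its expected objective is
discarded), and the fit stops at a relative change below 1e-6 or 200
iterations. Restarts draw small random slopes and scatter the per-state
biases around the empirical log-odds (sd 1.5): starting all states at the
same biases traps EM in a symmetric optimum where the states never
differentiate, which the bias spread reliably breaks.

Model quality is reported as the held-out normalized log-likelihood in
bits per sample relative to a chance model that predicts each mode with
its empirical frequency on the same evaluation frames; the chance model
therefore scores exactly 0 bits against itself. Because the chance model
is refit to each evaluation set's own base rates, a covariate-blind model
carrying training base rates can legitimately score below zero when state
dwell times are long relative to the trial. Both raw and normalized
likelihoods are exposed.

Downstream analyses built on the fitted model: Viterbi decoding (ties to
the lower state index); mapping the three states to the `whatever`
(silence-dominant), `chasing` (pulse-biased) and `close` (sine-biased)
rules, with an error rather than a guess when the emission profiles admit
no strict ordering; permutation feature importance (shuffling one raw
feature across time before lag expansion and reporting the
log-likelihood reduction); a counterfactual sweep of `ctheta` or `ptheta`
over 0–180° in 1° steps (181 grid points, inclusive) with `phi` coupled
as 180° minus the swept angle — frames with incomplete histories are
excluded from its aggregation since their counterfactual history is
undefined; a 2-D embedding of the per-frame filtered cues (the "decision
space"); and state inference on unseen trials with frozen parameters and
training z-score statistics.

## Behavioural maps

The social map featurizes each frame as the concatenated 15-sample
history of all ten features (150 dimensions), embeds a temporally uniform
10% subsample with UMAP (seeded, single-threaded for reproducibility),
transforms the remaining frames into the fitted space, estimates a kernel
density on a grid (normal-reference bandwidth; default 256×256, with a
light Gaussian smoothing), and segments it with a watershed transform so
each density mode becomes one region. Cells below the 1% density quantile
are background, modes shallower than 5% of the peak merge into their
neighbours, and watershed basins that capture no data points are folded
into the background — they are artefacts of the far-field density tail.
The wavelet map replaces the lag features with Morlet power at 25
dyadically spaced frequencies (1–25 Hz) of 24 egocentrically aligned pose
channels (both flies' six keypoints × two coordinates, translated to the
thorax, rotated to the heading, scaled by fly length — the channel
composition is configurable because the source states the dimension but
not the composition), giving 600 features per frame. Mode counts on real
data are not reproducible targets: nonlinear embeddings are seed- and
hyperparameter-dependent, so the tests assert structure (separation of
scripted scenarios, reproducibility under a fixed seed, region
connectivity), not particular counts.

## Song statistics

Pulse waveforms are 35 ms snippets at 10 kHz. The carrier is the dominant
spectral frequency below 1 kHz ("central frequency" is read as the
spectral peak, not the centroid). The envelope is the analytic-signal
magnitude smoothed with a Gaussian kernel whose *standard deviation* is
1.5 ms (truncated at ±4σ) and normalized to unit peak — normalization
makes the 0.08 noise and 0.5 width thresholds scale-free, which the
source leaves implicit; the width is the total time above half peak.
Pulses whose max-minus-mean envelope falls below 0.08 are flagged noisy;
envelopes crossing 0.5 into more than one region are flagged multi-peak;
both are excluded from width summaries. Inter-pulse intervals above
100 ms are bout breaks and dropped. Sine carriers take the modal
dominant frequency over 256-sample segments. Bouts are maximal song runs
interleaved by less than 100 ms of silence; the bout order is one plus
the number of within-bout mode transitions. Pulse-type clustering embeds
normalized waveforms (unit peak, fixed polarity) in 2-D and finds the two
dominant clusters by the same kernel-density + watershed segmentation
used for the maps, labelling the shorter-envelope cluster `P_fast` and
assigning the remainder with a support-vector classifier trained on the
two clusters.

## The synthetic generator

The generator fixes the study conditions for every test. Features are
discretized Ornstein–Uhlenbeck processes at 30 Hz with stationary moments
and timescales chosen as typical of courting flies (forward velocities of
a few mm/s with ~0.5 s persistence, distances of ~5 ± 3 mm with ~1 s
persistence, rotational speeds of tens of deg/s); magnitude features take
absolute values, relative angles fold into [0°, 180°] and `phi` wraps to
±180°. The ground-truth model has K = 3 states — silence-, pulse- and
sine-biased, mirroring the whatever/chasing/close structure — with a
sticky transition matrix (diagonal 0.97) and filters loading on distance
and lateral speed, the leading cues in the source analysis. Scripted pose
scenarios provide kinematic ground truth: in `male_turns` the partner
executes a rapid 180° reversal that converts a tail interaction into a
head interaction at a known time; in `female_slows` the partner's speed
drops during scripted song epochs while the courter extends a wing.
Synthetic audio renders pulses as 250 Hz carriers under Gaussian
envelopes of 4 ms full width at half maximum at a 36 ms inter-pulse
interval, sine song as a 150 Hz tone, plus a playback stimulus with ten
increasing amplitude steps.

What the generator does *not* emulate: pose-estimation noise structure
(occlusions, identity swaps), the heavy-tailed and context-dependent
statistics of real fly locomotion, agonistic song, and any closed-loop
coupling from the song back to the partner's behaviour. Passing tests
therefore demonstrate correctness of the computations and recoverability
under the stated conditions, not biological conclusions about real flies.

## Numerical choices and scales

Forward–backward uses per-step scaling rather than log-space recursions;
posterior identities (each γ row sums to one, pairwise marginals sum to
γ) hold to 1e-12 and all quantities match exhaustive path enumeration to
1e-8 on small instances. The EM inner optimizer runs at most 30 L-BFGS
iterations per state per iteration — warm starts make longer inner runs
unnecessary — and monotonicity is guarded explicitly. Model files are
JSON with 17 significant digits, which round-trips IEEE doubles exactly.

Test and acceptance problem sizes are desk-scale choices: parameter
recovery uses one trial of 50,000 frames (about 28 synthetic minutes);
the model-comparison experiment trains on 30,000 and holds out 10,000
frames. The latter size matters: with strongly autocorrelated OU inputs
the effective sample count is roughly the frame count divided by the
correlation time in frames, and below ~10,000 frames a 600-coefficient
filter bank overfits badly enough that the intercept-only hidden Markov
baseline can win held out. The workflow under `analysis/` uses six
18,000-frame trials with two held out, which keeps the full fit clearly
ahead of both baselines.

## Known limitations

Transitions are input-independent by design (the source model shares
this); the rule labelling assumes exactly three states; UMAP embeddings
are reproducible only under a fixed seed and thread count; audio I/O is
in-memory vectors plus plain-text serialization rather than WAV
containers; and the pipeline's statistical summaries delegate group
comparisons (Mann–Whitney, Wilcoxon) to standard routines on the exported
tables rather than wrapping them.
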