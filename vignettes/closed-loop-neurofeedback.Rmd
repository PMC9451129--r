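---
title: "Simulating closed-loop narrative neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop narrative neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(storynf)
```

## The paradigm

A listener hears an ambiguous story that admits two mutually exclusive
readings: the *cheating* interpretation (Joanie really is in bed with Lee)
and the *paranoid* one (her husband Arthur is deluded). During each of 4
story-listening runs there are 7 predefined analysis windows ("stations",
3–16.5 s long at a 1.5 s TR). Just before each station the participant
declares at a probe which interpretive lens they will adopt; during the
station, brain activity is decoded into p(c), the probability of the
cheating interpretation; afterwards a monetary score is displayed.
Participants are randomly and double-blindly assigned to a target group,
and the score rewards decoded activity that deviates from the average
interpretation trajectory *in the assigned direction*. The package
simulates this entire loop, replacing the scanner and the human with
generative models, so that every formula and statistic of the procedure
can be executed and tested at desk scale.

## Pattern model

Neural data are abstracted to feature vectors (default 100 dimensions,
standing in for ROI voxels after functional alignment; the analysis depends
only on pattern geometry). Two templates, one per interpretation, differ by
`separation` (default 2) along a random unit discriminant `direction`. A
station pattern is

```
midpoint + (bias_st + snr * theta) * (separation / 2) * direction + N(0, I)
```

* `theta` ∈ [−1, 1] is the agent's latent interpretation (+1 cheating).
* `bias_st` ∈ [−1, 1] is the stimulus-driven lean of the narrative at that
  station; the defaults span [−0.6, 0.6] across the 7 stations, emulating
  the observation that many stations are strongly biased toward one
  interpretation regardless of the listener. This is what makes the pilot
  normalization consequential.
* `snr` scales the interpretation signal against the unit-SD isotropic
  noise and is the knob for per-participant decodability.

With `separation = 2`, `snr = 1` the instructed training classes are
separated by d′ ≈ 2 along one axis of a 100-dimensional unit-noise space:
decoders trained on 80 patterns per station are good but imperfect, which
is the realistic regime for multivoxel classification of narrative
interpretation.

## Decoders and pilot normalization

Each station gets its own L2-penalized logistic regression (inverse
regularization `C = 1`, fitted with glmnet at `lambda = 1/(C n)` without
standardization, convergence threshold 1e-12; the objective is convex so
the fit is solver-independent). The decoded p(c) is
`logistic(w · pattern + b)`, so p(c) + p(paranoid) = 1 holds exactly.

Free-interpretation pilot agents (theta drawn uniformly per participant,
pooled over both conditions) provide per-station reference distributions:
μ_st and σ_st of p(c). The population-SD convention is used because the
pilot is treated as a fixed reference, not a sample whose uncertainty is
propagated; `sd_mode = "sample"` is available. A station with σ_st = 0
(e.g. from all-zero decoder weights) raises an error rather than silently
producing constant scores, because degenerate pilot data invalidate the
whole feedback scheme.

The feedback score is `score_c = (p(c) − μ_st)/(3 σ_st) + 0.5` clipped to
[0, 1]; the 3σ scaling maps typical z-scores into [−0.5, 0.5]. Group
alignment flips the score for the paranoid group (`1 − score_c`), and
rewards are `score_final` where it exceeds 0.5, else 0 — an exact tie at
0.5 earns nothing. Note the zero-information fairness property: a
participant pinned at the pilot mean earns nothing in either group.
Payout maps each of the 28 station rewards to an equal share of the $20
bonus cap; the per-station dollar amount is not otherwise constrained, so
the uniform cap/28 scaling is the simplest rule that respects the cap.

## Timing

All timeline arithmetic is in TR units: the analyzed window is the
on-screen station window shifted by 3 TRs (4.5 s of hemodynamic lag), and
feedback appears 1 further TR later — 4 TRs (6 s) after station end. The
probe display sequence is described with two lead times that do not
reconcile exactly (a 4 s lead before the station vs. a 2 s gap after the
probe response); both are exposed in `timing_config()` and neither affects
the scores, only logged onsets.

## The participant agent

No participant model is given by the paradigm itself, so the agent is a
deliberate, minimal invention, with every parameter surfaced:

* **Probe policy**: P(cheating) = logistic(theta / temperature),
  temperature 0.5 by default — saturated agents still explore occasionally.
* **Lens commitment**: during a station the momentary interpretation is
  `clamp(theta + 0.5 * sign(probe choice))`. Participants are instructed to
  *adopt* the declared lens for the upcoming station, so the declared
  choice must leave a trace in the momentary neural state. This term is
  also what makes the loop learnable: without it, reward depends only on
  the slow latent state, is not contingent on the probed lens, and the
  dynamics acquire two symmetric absorbing states, so agents end on the
  assigned side only at chance and no learning-rate effect exists. With
  it, choosing the assigned lens is differentially rewarded, and at high
  decodability essentially all agents converge to the assigned side.
* **Update**: theta ← clamp(theta + learning_rate × reward × sign(choice)),
  applied at feedback onset (after the 4-TR delay), so rewarded lenses are
  reinforced; zero reward leaves the agent unchanged.

Per-participant heterogeneity in `run_experiment()` — snr uniform on
[0.2, 1.5], learning rate on [0.05, 0.4] — emulates the wide spread of
decoding accuracy seen across real participants and is what generates the
headline relationship: decoding accuracy correlates positively with
group-aligned ("correct") interpretation scores. The package's acceptance
suite checks this as a direction (sign test over 20 replicate cohorts of
20 agents), not as a magnitude: the real effect size depends on the real
cohort, which is not packaged.

Yoked-control mode replaces each delivered reward by a same-group donor's
reward for the same station, matched on probe choice; when the donor chose
the other lens at that station the donor's reward is delivered anyway and
the event flagged `yoked_fallback`, keeping sessions complete and
auditable. The participant's own decoded stream is still logged.

## Questionnaire model

Comprehension answers (27 single-choice items against a fixed key) are
correct with probability 0.9 independent of interpretation — real
participants essentially all understood the story, and free-text grading
is out of scope. Interpretation items are Bernoulli in the latent state,
P(cheating-consistent) = (1 + theta)/2, coded ±1; one of the 12 items is
excluded from scoring (mirroring the question whose answer was given away
before the experiment), so the interpretation score is the mean of 11
codes. Empathy ratings discretize 3 ± 1.5·theta (Arthur +, Lee −,
Joanie −1.0·theta, "the girl" neutral) with SD-0.5 jitter onto the 1–5
scale; the Arthur − Lee difference, sign-aligned by group, is the
"correct empathy" score.

## Statistics

Group comparisons use the pooled-variance Student t test (df = n₁+n₂−2,
hence t(18) for 10 vs 10), one-tailed where a direction is predicted;
correlations are Pearson with the t-transform p value; multiple
comparisons across the 7 stations of a run use Bonferroni with family 7,
and run-wise tests family 4. The median split by decoding accuracy is
performed within each assigned group with a deterministic
(accuracy, participant id) tie-break, yielding 5 + 5 "best" and "worst"
participants in the standard cohort; odd group sizes are an error rather
than an arbitrary allocation. Decoding accuracy is undefined for a
participant who never declared one of the lenses; such participants are
flagged NA (never silently dropped), and `run_experiment()` then skips the
split-based analyses with a warning instead of aborting the cohort.
Aggregate tables average within participant first, then report mean ± sem
across participants with per-cell n (sem is NA for a single participant).

## Determinism and problem sizes

Every stage seed derives arithmetically from one master seed (all derived
seeds stay below 2³¹); each session additionally splits its seed into
named pattern/probe/questionnaire substreams realized as pre-seeded draw
blocks, so logs are reproducible bit-for-bit and a stored config digest
accompanies every serialized output. The test suite runs cohorts of 8–20
agents with 30–100 features, 200 signal-free participants for the
null-centering check and 20 replicate cohorts for the correlation
direction — sizes chosen so the full loop is exercised many times over
while each property remains a sharp statistical test (3-SE bands against
Monte-Carlo, binomial and closed-form oracles).

## Limitations

The generator emulates pattern geometry, not BOLD physics: no temporal
autocorrelation, drift, motion, or alignment error, and one pattern per
station rather than TR-wise averaging. Passing tests therefore validate
the procedure's logic and statistics — not that real cortical patterns are
decodable at any particular accuracy. The agent is a stand-in whose
parameters cannot be estimated from the paradigm; conclusions about human
learning dynamics are out of scope. Comprehension scoring assumes a
single-choice format with a fixture key.
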