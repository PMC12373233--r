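---
title: "Models and methods behind throwpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind throwpredict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(throwpredict)
```

`throwpredict` analyses experiments in which athletes verbally predict the
outcome of their own throws under sensory occlusion. This vignette documents
the generative model behind the synthetic cohorts, the operational
definitions used by the kinematic and acoustic detectors, the statistics, and
the numerical choices made where the design was genuinely open.

## The decision model

A participant's verbal prediction is modelled as an equal-variance
signal-detection decision. On each prediction trial the internal evidence is

$$ e \sim N(+d'/2, 1) \text{ after an actual hit}, \qquad
   e \sim N(-d'/2, 1) \text{ after an actual miss}, $$

and the participant verbalizes "hit" iff $e > c$. This symmetric
parametrization makes the criterion $c$ the direct bias parameter and
reproduces the standard estimators exactly: the hit rate is
$\Phi(d'/2 - c)$, the false-alarm rate $\Phi(-d'/2 - c)$, so
$z(HR) - z(FA) = d'$ and $-(z(HR) + z(FA))/2 = c$. The test suite verifies
both identities empirically (binomial error at $n = 10^5$ trials).

Chance-corrected accuracy is computed on the percent scale. The formula for
`%Acc_Pred` is a ratio of percentages and therefore yields a fraction; since
its worked examples and cohort summaries are conventionally given in percent
(20%, 10%), the package multiplies by 100. The chance rate uses the margins
of the same valid-trial table as the percent correct, keeping the two
quantities internally consistent.

Extreme rates: the log-linear correction (+0.5 per cell, +1 per row total) is
applied for the SDT quantile transforms only, and is the default. The
accuracy formulas need no quantile transform and always use raw proportions.
With `correction = "none"` an extreme rate raises an error rather than
returning an infinity.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the analysis assumes:
19 participants, 500 throws each, conditions alternating with trial 1 a
feedback trial (an arbitrary convention, fixed for reproducibility), verbal
predictions only on prediction trials. Actual outcomes are Bernoulli at the
participant's hit rate on every trial. Defaults are the published cohort
presets (`hit_rate = 0.634`, `d_prime = 0.36`, `criterion_c = -0.32`) and the
published exclusion fractions (0.82% invalid trials; additional speech
extraction failures bringing the speech-stage exclusions to about 3.4% of
prediction trials).

Bias–performance coupling. Better shooters tend to answer "hit" more
liberally. When hit rates vary across participants, the realised criterion is
$c_i = c_0 - \beta\,(hr_i - \overline{hr})$ with $\beta$ =
`bias_performance_coupling` (default 1.2). Centring at the cohort mean keeps
$c_0$ the cohort-mean criterion whatever the performance level — so parameter
recovery stays unbiased — while any positive $\beta$ yields the negative
correlation between criterion and hit rate.

Speech ground truth. Verbal latency is
`latency_base_s` (0.8 s) plus `latency_hit_shift_s` (−0.1 s) for verbalized
hits plus Gaussian trial noise (SD 0.15 s, floored at 0.15 s);
amplitude is `amplitude_base` times `amplitude_hit_gain` (1.25) for
verbalized hits times log-normal trial noise (SD 0.25 log units).
Between-participant offsets (latency SD 0.08 s; amplitude SD 0.2 log units)
are included because the median normalization is supposed to remove them.
The magnitudes of the hit shift and gain are free parameters — only their
signs are constrained by the phenomenon being modelled — and the chosen
values produce per-participant effects large enough to be detected reliably
at the study's sample size, without being trivially large at the trial level
(the trial noise SDs exceed the shifts).

Determinism. All randomness flows from one integer seed; each participant's
stream is derived by an arithmetic sub-seed, so identical seed + config gives
byte-identical output and adding participants never perturbs existing ones.

At cohort scale the generator emits the per-trial latency/amplitude ground
truth directly as "measured" features; synthesising thousands of waveforms is
deliberately not the default (`synthesize_audio = TRUE` runs the full WAV
chain on small cohorts). The waveform-to-feature path is validated separately
on `simulate_speech_clip()` output. What the generator does *not* emulate:
real articulation variability (formant structure, coarticulation), room
acoustics, marker occlusion patterns, fatigue or learning trends, and any
trial-to-trial dependence. Passing tests therefore demonstrate that the
pipeline recovers what the model puts in — not that real recordings are this
clean.

## Kinematic release detection

The ball centre is the midpoint of the two pole markers. Release (distance
criterion) is the first frame whose fingertip–centre distance exceeds the
previous frame's by strictly more than 3 mm, with ties broken toward later
frames. A candidate is confirmed only if the ball speed exceeds 5 m/s and
more than 0.5 s has elapsed since ball contact. Operational definitions the
criterion itself leaves open:

- *Ball speed* is the norm of the central-difference velocity of the centre
  (one-sided at stream ends); no estimator is prescribed by the criterion, so
  the package uses the lowest-bias two-point stencil.
- *Contact onset* is the first frame of the longest run with distance ≤
  `min_dist_m` + 5 mm preceding the candidate (ties toward the later run).
- Streams with flagged or missing frames inside
  [contact onset − 0.5 s, candidate + 5 frames] are rejected outright,
  mirroring the exclusion of trials with detached markers.

The anticipatory criterion is the mean ball height, over ten warm-up throws,
at the frame nearest 40 ms before the distance-detected release; at 240 Hz,
40 ms is 9.6 frames and the nearest-frame rule reads release − 10. For the
anticipatory detector the speed confirmation is evaluated over a short
forward window (default 25 frames) after the height crossing rather than at
the crossing itself: the whole point of the anticipatory trigger is to fire
~40 ms *before* release, when the ball is still accelerating and necessarily
slower than 5 m/s; release is confirmed immediately afterwards. The timing of
the confirmation is not otherwise prescribed, so this forward-window reading
is the package's choice.

The synthetic throw places the hand–ball separation between frames
`release_frame − 1` and `release_frame`, so the first supra-threshold distance
step (≈ `release_speed / fs` ≈ 23 mm per frame) lands exactly on the nominal
release frame, and uses a quartic upswing speed profile so ball speed crosses
5 m/s only within about 3 frames of release and height rises monotonically
through the calibration window.

## Speech feature extraction

The chain is: 2nd-order Butterworth band-pass 500–4000 Hz → subtract mean →
absolute value → 25 ms moving average (window rounded to an odd sample
count; shrinking windows at the edges). The envelope maximum (first sample on
ties) is the response amplitude; the last sample before the maximum strictly
below 5% of it is the onset.

Moving-average alignment. The band-pass filter is applied forward-only
(causal) by default, with zero-phase filtering as an option. The moving
average is likewise trailing (causal) by default. A centred window leaks
burst energy half a window (12.5 ms) ahead of the true onset, which biases
the 5%-of-maximum rule roughly 9–11 ms early — about twice the 5 ms recovery
tolerance the package holds itself to — whereas the trailing window's bias is
only +1 to +4 ms. `ma_align = "center"` remains available.

Validity. A clip is "no response" when the envelope maximum does not exceed
5× the median envelope of the first 100 ms (an operationalization of
"could not be detected properly"); it is "onset undetectable" when no sample
before the maximum falls below the 5% threshold. Normalization divides by the
participant's median over valid trials (making relative latency and amplitude
dimensionless with median 1); subtraction is the noted alternative, but the
ratio form is scale-free and robust to microphone gain, which is the stated
purpose of the normalization. Participants with fewer than two valid trials
are flagged and excluded from speech analyses.

## Statistics

t statistics, correlations and the within-subject ANOVA are delegated to
base R (`t.test`, `cor.test`, `aov` with an `Error(id/(A*B))` stratum); the
test suite checks every statistic against direct formula evaluation and a
full sums-of-squares decomposition to 1e-10 relative error. Effect sizes:
η² = t²/(t² + df) for t-tests (the standard convertible definition; none is
prescribed), η² = r² for correlations, and partial η² =
SS_effect/(SS_effect + SS_error) per ANOVA effect. Participants missing any
ANOVA cell are dropped listwise.

"Uninformed priors" for the Bayes factors are operationalized as the common
defaults of the standard analysis software: a Cauchy prior with scale 0.707
on the standardized effect for t statistics (JZS), and a stretched-beta prior
of width 1 (uniform on (−1, 1)) on the population correlation. Both are
computed by numerical integration — the JZS factor integrates the
noncentral-t likelihood against the prior (`integrate`, relative tolerance
1e-9, failures raised as errors, never silently approximated), the
correlation factor integrates the exact sampling density of r, whose Gauss
hypergeometric term is summed to machine precision. One-tailed factors
truncate the prior to the tested direction (prior truncation, not posterior
restriction). A perfect sample correlation is reported as the BF10 → ∞
limit. Evidence categories use the conventional 3/10/30/100 boundaries,
applied to BF10 or its reciprocal with the favoured hypothesis reported.

## Blocks, exclusions, degenerate inputs

Blockwise accuracy splits each participant's valid prediction trials in
temporal order into `n_blocks` blocks of `round(n / n_blocks)` trials with
the remainder absorbed by the last block (249 trials → 50, 50, 50, 50, 49); a
block with an empty actual-outcome row is flagged undefined rather than
erroring. A chance level of exactly 100% (degenerate margins) makes the
accuracy undefined and is flagged. The exclusion audit records every dropped
trial with a machine-readable reason (`invalid_flag`, `no_answer`,
`changed_answer`, `speech_extraction_failed`), and the pipeline guarantees
input trials = analysed trials + audited behavioural exclusions. A
participant with no usable speech stays in the behavioural analyses and is
dropped from the speech analyses only.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen so each property is decided by
its own sampling error: parameter recovery over 200 replicate cohorts of
19 × 500 trials; null calibration on 1000 zero-sensitivity participants plus
600 replicate cohorts for the type-I rate; the accuracy–sensitivity coupling
on a 100-participant cohort with d′ ~ U(0, 1.5), c ~ U(−0.8, 0.2); speech
recovery on 100 clips at 16 kHz (the 100 kHz laboratory rate is a config
knob, not needed to exercise a 500–4000 Hz band); release detection on
100 synthetic throws; and the effect-direction check over 100 seeds at
n = 18. Exhaustive table enumeration covers all 2×2 tables with total ≤ 20.

## Known limitations

- The generator's speech model is an amplitude/latency abstraction; it
  cannot validate robustness to real-world acoustics.
- The release detectors assume uniformly sampled, gap-free streams; gaps must
  be flagged upstream (flagged trials are refused, not repaired).
- The correlation Bayes factor assumes bivariate normality, inherited from
  the exact sampling density of r.
- Provided-mode ingestion expects the package's own CSV/WAV layouts;
  proprietary capture formats are out of scope.
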