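---
title: "Models and methods: decoding anticipation and learning task assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: decoding anticipation and learning task assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(takeoverlearn)
```

## The problem

When a human and a robot share a task made of discrete subtasks, the human
may silently prefer to do some subtasks themselves. Anticipation of an
upcoming takeover (human about to act instead of the robot, or vice versa)
leaves a measurable trace in the EEG: a positive fronto-central deflection
roughly 500 ms after the onset of the robot's movement in the trial *before*
the switch. `takeoverlearn` provides both halves of the resulting
machine-learning problem:

1. **Decoding**: can single trials of such anticipatory activity be
   classified above chance? (Windowed ERP features, shrinkage-regularized
   LDA, class-balanced repeated cross-validation, binomial chance level.)
2. **Learning**: can a robot, given only a noisy decoded anticipation signal,
   learn which subtasks the human wants to keep? (A bandit-style value
   memory with per-trial standardization and a softmax policy, evaluated in
   simulation.)

Because no public recordings exist for this paradigm, the decoding half is
exercised on a synthetic epoch generator whose defaults emulate a realistic
session; the learning half is purely a simulation model whose decoder
quality is set to empirically measured accuracies.

## Synthetic ERP epochs

`generate_epochs()` draws trials of `channels x samples` data on the grid
`t_k = t_start + k/srate * 1000` ms, keeping every sample with
`t_k <= t_end` (so the default −200..1200 ms window at 512 Hz has 717
samples). Each trial is:

* **1/f background noise**, white noise shaped in the frequency domain by
  `1/sqrt(f)` and rescaled to `noise_scale` µV SD per channel (default 8 µV,
  a typical residual single-trial amplitude after band-pass filtering).
  Channels are independent; real EEG has strong spatial correlation, which
  is deliberately omitted — see *Limitations*.
* an optional **10 Hz oscillation** (default 2 µV) with uniform random
  phase per trial and channel, giving the spectrum a realistic alpha bump;
* for trials of the conditions in `effect_classes` (default `RH_pre`, the
  anticipated human takeover from the robot), a **Gaussian-in-time positive
  deflection** with peak `effect_amplitude` (default 3 µV), latency 500 ms
  and SD 60 ms on a fixed fronto-central channel set. A Gaussian bump is
  the simplest smooth unimodal shape consistent with the reported scalp
  topography; no generative form is prescribed by ERP theory.

Default trial counts are 530 `RR_pre` versus 212 `RH_pre`, the mean
per-session counts of the robot-continuation versus human-takeover
conditions; the imbalance is part of the study conditions, not an artifact.
(Splitting a session into its two collaboration scenarios would halve these
counts to roughly 265 + 106 = 371 trials per decoding problem — consistent
with the reported average sample-size-adjusted chance level of 54.3%, which
`chance_level(371)` reproduces to within 0.2 points.)

The default montage has 27 scalp channels. The recording montage this
emulates lists 30 electrode labels of which three are EOG leads and two are
mastoid references; removing those leaves 25, yet the decoder operates on 27
scalp channels. We complete the montage with CP1 and CP2, the two sites
present in the standard 32-channel extension of this cap but absent from
the printed list, restoring the documented 27-channel / 405-feature layout.

## Feature extraction

Per trial and channel the series is baseline-normalized by subtracting its
mean over 0–800 ms, then averaged within 15 windows: four contiguous 50 ms
windows over 400–600 ms (fine coverage of the component) and eleven 100 ms
windows hopping by 50 ms over 0–600 ms (coarse coverage of the whole ERP).
These hop/width choices are the unique schemes producing four windows in
400–600 ms and eleven in 0–600 ms. Windows are half-open `[start, end)` on
the sample grid; ties at window edges therefore belong to the later window,
and no sample at or after 600 ms enters any window (inter-trial intervals
can be as short as 600 ms, so later samples could leak the next trial).
The baseline, by contrast, intentionally runs to 800 ms; corrupting
600–800 ms shifts all 15 features of a channel by one common constant,
which the discriminant largely absorbs.

## The rLDA decoder

For two classes with feature means `mu1`, `mu2` and class covariances
`S1`, `S2` (unbiased `1/(N-1)` normalization), the shrinkage-regularized
discriminant uses `S~j = (1 - lambda) Sj + lambda I` and solves

```
(S~1 + S~2) w = mu1 - mu2,    b = -w'(mu1 + mu2)/2
```

A trial is assigned to class 1 when the decision value `w'x + b` is `>= 0`
(ties to class 1, a fixed documented rule). `lambda = 0.9` throughout: for
405-dimensional ERP features and a few hundred trials, heavy shrinkage
towards the identity is the robust operating point, and it is deliberately
not optimized per dataset. The midpoint bias is the standard LDA boundary;
a `sum` convention (`b = -w'(mu1 + mu2)`, no ½) is available for strict
comparability with a variant formulation but places the boundary away from
the class midpoint and is not recommended.

`cross_validate()` implements the within-session scheme: 10 random folds
(permutation, contiguous split, remainder spread one per fold), calibration
on 9 folds after `balance_classes()` oversamples the minority class with
replacement up to the majority count (no trial is discarded; the test fold
stays imbalanced), all repeated 10 times. TNR and TPR are the per-class
correct rates of class 1 and class 2; ACC the overall percent correct;
all averaged over the 100 fits.

**A bias worth knowing about.** With heavily imbalanced classes and no true
effect, this scheme classifies *above* 50% overall: the minority-class mean
is estimated from fewer unique trials, its larger estimation noise pushes
the midpoint boundary towards the minority side, and predictions drift
toward the majority class (we observe ≈56% overall accuracy at 530/212
null trials, with the minority recall correspondingly depressed). This is a
property of balanced-training/imbalanced-testing LDA pipelines in general,
not a bug; per-class rates (TNR/TPR) expose it immediately. Null-calibration
checks in this package therefore use balanced trial counts, and reported
accuracies at imbalanced counts should always be read next to the per-class
rates and the binomial chance level.

`chance_level(n, alpha)` is the inverse binomial test: the smallest
`100 k/n` with `P(Binomial(n, 1/2) >= k) <= alpha`, defaulting to
`alpha = 0.05`.

## The simulated decoder and the learner

The joint task has `n` subtasks, `m` of them silently claimed by the human;
episodes are `o = 10` i.i.d. uniform subtask demands (sampling with
replacement — visit counts per subtask are binomial, not exact). The
simulated anticipation decoder draws `eps ~ U(0,100)` and compares it with
the context rate chosen by the true consecutive-actor pair — TNR_HH,
TPR_HR, TNR_RR, TPR_RH — returning the true next actor when `eps <= rate`
and the opposite one otherwise (the boundary is measure-zero for a
continuous draw; the inclusive comparison is documented for countable
generators). The empirical operating point, measured during intermittent
collaboration, is TNR_HH = 51.5, TPR_HR = 51.4, TNR_RR = 57.9,
TPR_RH = 56.1 percent — only the robot-continue/human-takeover contrast is
meaningfully above chance, which is exactly the regime that makes learning
from the signal interesting.

Per trial the learner:

1. observes the decoded anticipation `a^` for the demanded subtask `s`,
2. credits `q(s, a^) <- q(s, a^) + alpha * R` (`alpha = 0.05`, `R = 1`),
3. standardizes the whole memory, `q <- (q - mean(q)) / SD(q)` over all
   `2n` entries (population SD; any consistent SD convention only rescales
   `q` and is absorbed by the temperature),
4. reports the softmax policy `p(a|s) = exp(q(s,a)/tau) / sum_a exp(q(s,a)/tau)`
   at `tau = 0.1`, and its **choice accuracy**: the mean policy mass on the
   truly responsible agent across all `n` subtasks.

Choice accuracy is probability-weighted because the uniform initial policy
then starts curves exactly at 0.5; an argmax-fraction variant is available
via `choice_accuracy(..., argmax = TRUE)` for sensitivity analysis. The
very first trial of a repetition has no predecessor context, so it is
recorded at the uniform policy without an update; afterwards the running
previous actor carries across episode boundaries, treating the
collaboration as one long trial sequence. The update targets the subtask
demanded at the *anticipated* trial, the only reading consistent with the
decoded signal being the anticipated responsibility for the next action.

The per-trial standardization is what makes the dynamics interesting: it
pins the spread of `q` at 1, so each `0.05` increment is also an implicit
leak of everyone else's values. The memory behaves like a mean-reverting
(AR-like) process rather than a diverging counter — preferences saturate,
old preferences decay as new evidence accumulates, and with `tau = 0.1`
the policy is near-binary for any clearly separated pair while staying
exactly 0.5 for untouched subtasks.

## Simulations

`run_sim()` averages `n_repetitions = 100` independent repetitions (fresh
memory, assignment and sequences each), with per-repetition seeds drawn
from the master seed so the averaged curve is exactly reproducible. The
full baseline (100 x 200 episodes x 10 trials) runs in roughly ten seconds
on one CPU. Bundled designs:

* **baseline** (`sim_spec()` defaults): n = 4, m = 2, empirical rates. The
  averaged curve first crosses 70% around episode 25–40 and 80% around
  episode 70–120 (seed-to-seed spread of the crossing episode is wide
  because the curve is shallow there), settling near 0.86 over episodes
  100–200.
* **decoder-quality sweep**: all four rates set to 50, 60, 70 or 80 versus
  the empirical point. Curves order strictly by decoder quality from
  episode ~20 on; the 50% arm is flat at 0.5 (a chance decoder's updates
  are action-symmetric, so no preference can accumulate in expectation).
* **hidden re-assignment** (`reassignment_every = 40`): the human redraws
  their `m` subtasks every 40 episodes; the learner is not told and its
  memory is never reset, so entrenched values must be overwritten. Accuracy
  drops at each boundary and recovers within the segment. Re-learning
  segments plateau below the fresh-start first segment (≈0.60 vs ≈0.73 at
  empirical rates): overwriting a saturated preference takes longer than
  forming one from indifference, and 40 episodes are not enough to finish.
  Later segments are mutually stable, so accuracy does not keep degrading.
* **scalability suite** (`run_scalability_suite()`): n = 4/6/10 balanced
  plus the imbalanced n = 10, m = 2. Learning slows with n (fewer visits
  per subtask per episode: episodes-to-70% roughly 27/35/49/27 at the
  empirical point). The imbalanced arm learns *faster and higher* than
  balanced n = 10: robot-owned subtasks carry the two above-chance context
  rates (TNR_RR, TPR_RH), and with m = 2 eight of ten subtasks enjoy them.

## Numerical choices

* Softmax uses row-max subtraction; policies are finite for any finite `q`.
* `standardize_memory()` returns an all-equal memory unchanged (SD = 0
  guard); after any single update the SD is already positive.
* `sign(0)` ties in the decoder go to class 1; tie rules are fixed, not
  random.
* Fold assignment re-draws (with a log-free retry) in the degenerate case
  of a calibration set missing a class — unreachable at the default sizes.
* All generators take integer seeds and restore the caller's RNG state.

## Limitations

* The noise model is spatially white; real EEG's volume-conducted
  correlation structure makes the decoding problem *harder* than the
  synthetic default at matched SNR, so synthetic accuracies should be read
  as pipeline calibration, not as predicted real-data performance.
* No artifacts (blinks, EMG), no non-stationarity, no preprocessing chain:
  the generator produces already-clean epochs.
* The learner model is a bandit-style accumulator — no discounting,
  eligibility traces or exploration; the robot's decoded signal never
  influences which subtask comes next.
* Wall-clock claims about collaboration time depend on an assumed 2 s trial
  duration and are not modelled here.
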