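---
title: "Adaptive PSI temporal order judgments: models, simulator and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive PSI temporal order judgments: models, simulator and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tojpsi)
```

## The scientific problem

In a crossmodal temporal order judgment (TOJ) task, two brief visual
targets appear left and right of fixation with a signed stimulus onset
asynchrony (SOA), shortly after a nociceptive cue on one hand (or both
hands). The observer reports which target appeared first (or, in half of
the blocks, second). Under *prior entry*, attended stimuli are perceived
earlier than unattended ones, so a lateral cue shifts the point of
subjective simultaneity (PSS): the stimulus on the uncued side must lead
by several milliseconds to be perceived as simultaneous with the cued-side
stimulus. The package implements the full computational pipeline of such a
study: the psychometric model, the adaptive Bayesian procedure that places
trials, the factorial designs of two experiments, a generative simulator
of cohorts of observers, and the within-subject statistical battery.

## The psychometric model

Responses are modeled with a two-parameter logistic,

$$f(x) = \frac{1}{1 + e^{-\beta (x - \alpha)}},$$

where $x$ is the SOA in ms (negative = left target first) and $f(x)$ the
probability that the right target is judged first. $\alpha$ (ms) is the
PSS; $\beta$ (1/ms) is the slope, inversely related to judgment noise —
the just noticeable difference is $\mathrm{JND} = \ln 3/\beta$, and the
derivative of the curve at the PSS is $\beta/4$. The reported "slope" is
the raw $\beta$ of this parameterization. An optional symmetric lapse rate
$\lambda$ extends the model to
$\psi(x) = \lambda + (1 - 2\lambda)f(x)$ so that simulated observers can
make stimulus-independent errors; *fitting* always keeps $\lambda = 0$, so
estimates remain on the two-parameter logistic and any true lapses are a
documented source of misspecification quantified by the recovery studies.

## The adaptive PSI engine

Each 20-trial series is run with the PSI procedure: a posterior is
maintained over a discrete $(\alpha, \beta)$ grid, and each trial's SOA is
the candidate minimizing the expected posterior entropy
$E[H](x) = \sum_{r \in \{0,1\}} p(r \mid x)\, H(\mathrm{posterior} \mid x, r)$,
after which the posterior is updated by Bayes' rule with the observed
Bernoulli outcome. Estimates are posterior means: $\hat\alpha$ on the
natural scale and $\hat\beta$ through the mean of $\log\beta$, because
slopes are scale parameters and average poorly in natural units.

Numerical choices:

* **Grid**: $\alpha$ uniform from $-200$ to $200$ ms in 41 steps (the span
  of the most extreme SOAs used), $\beta$ log-spaced from 0.005 to 0.5
  1/ms in 25 steps, uniform priors on $\alpha$ and on $\log\beta$. The
  grids are configurable and recorded in every session log header.
* **Tie-breaking**: expected entropies can tie (exactly so in mirror-
  symmetric states). Candidates are walked in the order (smallest $|SOA|$
  first, negative before positive) and a later candidate must improve the
  expected entropy by more than $10^{-12}$ nats to displace the incumbent.
  This makes stimulus selection fully deterministic given the state.
* **Complement probabilities** $p(r = 0)$ are computed from the mirrored
  logistic rather than as $1 - p$, so extreme slope-by-SOA cells never
  round to exactly 0 and batch log-likelihoods stay finite.
* **Stopping**: fixed 20 trials per series; no early stopping.
* **Degenerate states**: a point-mass posterior makes every candidate's
  expected entropy zero; the engine warns and returns the tie-break
  default.

The trial loop (select, respond, update) also exists as compiled code for
the large simulation studies; the test suite checks it against the
step-by-step R implementation, and checks the R implementation against
brute-force enumeration oracles on small grids.

How precise can 40 trials be? The single-trial Fisher information for
$\alpha$ is at most $\beta^2/4$, so with $\beta = 0.05$ the best possible
standard error after 40 trials is $\sqrt{4/(40\beta^2)} \approx 6.3$ ms.
The engine's measured median absolute error over 40-trial series
($\approx 5.8$ ms, well within the pre-set 9 ms bound used by the
acceptance suite) is therefore close to the information-theoretic floor;
milli-second-scale group effects become detectable only by averaging over
cue sides, modalities and participants, which is exactly what the designs
do.

## The two designs

* **Experiment 1**: 10 SOAs ($\pm$200, $\pm$90, $\pm$55, $\pm$30, $\pm$10
  ms), cue conditions unilateral-left, unilateral-right and bilateral;
  four blocks crossing target position (near/far from the trunk) with
  response modality ("which first"/"which second"); one independent
  20-trial PSI series per cue condition per block, randomly interleaved:
  240 trials.
* **Experiment 2**: 20 SOAs (adding $\pm$145, $\pm$75, $\pm$60, $\pm$45,
  $\pm$15, $\pm$5 and dropping nothing), unilateral cues only, eight
  blocks crossing position, hand congruency (hands beside the judged pair
  or the other pair) and modality: 320 trials.

Each (block $\times$ cue condition) series drives its own fresh engine
state; states are not shared across the two modality blocks of the same
condition. Timing fields (500 ms fixation lead, 200 ms cue-to-target
interval, 2000 ms inter-trial) are carried as metadata only — the
simulator is not a real-time engine.

## The generative observer model

A simulated participant holds one true shift per condition cell. With the
response model above ($\psi$ = probability of "right first"), attention
drawn to the **left** hand means the left target is perceived earlier, so
the right target must lead for subjective simultaneity: the generative PSS
is $+s$ for a left cue, $-s$ for a right cue and 0 for bilateral cues.
The analysis-side combination $(\mathrm{PSS}_L - \mathrm{PSS}_R)/2$ then
recovers $+s$, a positive number meaning prioritization of the cued side.
"Which second" blocks complement the report label and nothing else — any
modality-specific bias is deliberately out of scope, which is also why the
analysis pools the two modalities before fitting.

The cohort layer draws each participant's cell shifts from an
equicorrelated multivariate Gaussian and slopes from a truncated
log-normal; trials are i.i.d. given the condition (no fatigue or drift —
a known limitation of the simulator relative to real sessions, along with
the absence of modality-specific biases and of slope differences between
cue conditions).

### Calibration of the default cohorts

The default cohorts reproduce the reported group-level conditions:
17 participants with near/far unilateral cell means 10.95 and 5.34 ms for
the first design; 23 participants with congruent/incongruent means 10.94
and 7.85 ms for the second. Three further choices were calibrated once,
before any acceptance check was run, and not revisited:

* **Observer slope and lapse** (`beta_mean = 0.1` 1/ms, log-SD 0.2,
  `lapse = 0.01`). Reported cell SDs describe *estimated* PSS values and
  therefore bound estimation noise from above: at 40 trials per cell,
  shallower defaults (e.g. $\beta = 0.04$) produce estimation variance
  alone exceeding the reported total variance of 53 ms², which is
  impossible. At the chosen defaults the simulator's measured
  estimation-noise variance for a combined unilateral cell is about
  19 ms², comfortably inside the reported totals.
* **Generative between-participant SDs** are the reported SDs deconvolved
  by that noise: $\sqrt{\mathrm{SD}^2_{\mathrm{reported}} - 19}$.
* **Between-cell correlation 0.9.** The reported within-subject
  near-vs-far contrast ($F(1,16) = 16.66$ on a 5.61 ms mean difference)
  implies a difference SD of only $\approx 5.7$ ms, i.e. a between-cell
  covariance of $\approx 31$ ms² — at the upper edge of what the
  deconvolved cell SDs allow. The shared correlation is therefore capped
  at 0.9, realized as a common participant-level susceptibility component
  plus cell-specific deviations.

A null cohort keeps this whole between-participant structure and zeroes
the cell means; it is the generative null for type-I-error calibration.

## The analysis battery

Per participant, condition cell and cue condition, the two response
modality blocks are pooled (2 × 20 = 40 trials, "which second" reports
complemented into implied first judgments) and the model refitted in one
batch over the same parameter grid — the product of Bernoulli likelihoods,
hence identical to sequential updating and order-independent. Pooling
then refitting was chosen over averaging the two per-block estimates
because 20 trials per fit leaves substantial small-sample noise; the
alternative remains available (`refit = "average"`). Left- and right-cue
PSS values combine as $(\mathrm{PSS}_L - \mathrm{PSS}_R)/2$; unilateral
slopes are averaged arithmetically (the combination rule for location
parameters mirrors the published procedure; for the two slopes of one
cell the plain average is used). Bilateral cells stay in the left/right
frame.

Statistics follow the published battery: two-sided one-sample t tests of
each cell's PSS against zero with Cohen's $d = t/\sqrt{n}$; a 2 × 2
fully-within ANOVA (cue condition × position, or position × congruency)
computed from sums of squares with each effect tested against its own
effect-by-participant interaction, partial
$\eta^2_p = F \cdot df_1/(F \cdot df_1 + df_2)$, and contrasts implemented
as 1-df within-participant F tests (squared paired t) of one factor at
each level of the other. With two-level factors sphericity is trivially
satisfied, so the Greenhouse-Geisser $\epsilon$ is reported as 1 and the
correction is vacuous. No multiple-testing correction is applied and raw
two-sided p values are reported. Figure-style intervals use the plain
Cousineau within-subject normalization (value − participant mean + grand
mean); the Morey factor $\sqrt{J/(J-1)}$ is available as an option but is
not the default.

```{r example, eval = FALSE}
cfg <- exp1_config()
logs <- simulate_cohort(reference_cohort(cfg, seed = 7), cfg)
res <- run_toj_analysis(logs)
print(res)
```

## What the validation studies show (and do not show)

The test suite and `scripts/acceptance.R` recompute, from scratch:

* every published Cohen's d and partial eta squared from its printed test
  statistic (exact identities);
* the factorial arithmetic of both designs;
* exact agreement of stimulus selection with brute-force expected-entropy
  enumeration and of sequential updating with batch Bayes on small grids;
* PSS recovery for on-grid lapse-free observers (median absolute error
  below the pre-set 9 ms bound at 40 trials; RMSE decreasing over
  20/80/320-trial budgets);
* a 5% type-I error rate for the combined unilateral PSS over 400
  simulated null cohorts (17 participants each);
* sign recovery of the near > far gradient and of the cue-by-position
  interaction in over 90% of 200 cohorts at the first design's trial
  budget.

Problem sizes (100-400 replicates, cohorts of 17) are the package's
standard study sizes for these Monte-Carlo checks. Because the simulator
generates i.i.d. logistic observers, passing these checks demonstrates
internal consistency and statistical calibration of the pipeline — not
that real observers are logistic, lapse-free or drift-free. Group-level
human results can only be emulated at the reported means, not reproduced.

## Known limitations

* The engine fits a lapse-free logistic; true lapses bias slope estimates
  downward and inflate PSS noise (quantified by the recovery studies).
* Whether the original adaptive procedure marginalized over a lapse
  dimension, and its grid ranges and priors, are not recoverable from the
  published record; the defaults here are declared, not inferred.
* Engine state deliberately resets per block; persisting states across the
  two modality blocks of a condition is a plausible alternative reading of
  the original procedure and would halve estimation noise per cell.
* JND-based group analyses, Bayesian group models and automated outlier
  exclusion are out of scope.
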