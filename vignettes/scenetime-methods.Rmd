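---
title: "Methods: sensitivity, ceiling normalization and causal-direction analysis for rapid scene categorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensitivity, ceiling normalization and causal-direction analysis for rapid scene categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenetime)
```

## The scientific problem

Humans categorize real-world scenes after glimpses of a few tens of
milliseconds. Two category systems are of interest: the *semantic* identity
of a scene (beach, residential, road, farm, car-park, nature) and its
*spatial structure* (open, closed-off, navigable, cluttered). A
long-standing "space-centered" account holds that spatial layout is
recovered first, from global image statistics, and that scene semantics are
then inferred from layout. `scenetime` implements the analysis machinery
needed to interrogate that account with backward-masked, time-limited
categorization data:

1. **m-AFC sensitivity** (`pc_mafc()`, `dprime_mafc()`, `dprime_series()`):
   a task-size-independent d′ so that a 6-alternative and a 4-alternative
   task can be compared on one scale.
2. **Ceiling performance** (`loocv_ceiling()`): how well an observer *can*
   do on each task, estimated from a separate pool given unlimited viewing
   time.
3. **Agreement-based normalization** (`bin_by_agreement()`,
   `shared_bin_weights()`, `normalized_dprime()`, `bootstrap_equalize()`):
   the two tasks differ in how much unlimited-time observers agree about the
   "correct" label; normalization removes this confound before comparing
   time-courses.
4. **Conditional-probability causal models** (`conditional_probability_table()`,
   `model_predictions()`): for each trial, predict the category in one
   system from the categories reported in the other, through an empirical
   conditional prior.
5. **Decision-variable correlation** (`dvc()`, `pairwise_human_dvc()`,
   `loocv_human_dvc()`, `model_human_dvc()`): trial-by-trial agreement
   between two responders that factors out overall performance, used to ask
   *which* causal direction better explains human responses.

Because the package must be fully testable without the human dataset, it
ships a first-class synthetic-observer simulator (`build_joint_model()`,
`sample_image_set()`, `simulate_unlimited_pool()`, `enumerate_design()`,
`simulate_timed_experiment()`, orchestrated by `run_pipeline()`) that
reproduces the study's design and the statistical structure the analyses
assume.

## The m-AFC observer model

Sensitivity is defined through the unbiased max-rule observer: on a trial
with m categories the target category carries Gaussian evidence with mean d′
and unit variance, the m − 1 alternatives carry standard normal evidence,
and the observer reports the maximum. Proportion correct is

$$p_c(d', m) = \int \phi(t - d')\, \Phi(t)^{m-1}\, dt,$$

which equals 1/m at d′ = 0 and is strictly increasing in d′. `pc_mafc()`
evaluates the integral by 61-node Gauss–Hermite quadrature (after the
substitution t = d′ + √2 u); this agrees with adaptive quadrature to below
1e−11 over d′ ∈ [−2, 4], m ≤ 8, and with a 10⁷-draw Monte-Carlo simulation
of the max rule within Monte-Carlo error (both are asserted in the test
suite). `dprime_mafc()` inverts the forward model with a bracketing
root-finder (residual < 1e−9; round-trips close to 1e−6). Negative d′ is
returned for below-chance accuracy.

**Extreme proportions.** A perfect score has infinite d′. The
`"half_trial"` correction clamps accuracy to [1/(2n), 1 − 1/(2n)] before
inversion — 10/10 correct becomes 0.95 — and leaves non-extreme proportions
untouched. It is applied everywhere a d′ is computed from counts, so ceiling
estimates and timed estimates are treated identically.

**Aggregation.** d′ is computed per observer per condition cell and then
averaged; reported uncertainty is the standard error *over observers* (for
model predictions, which have no observers, the SE is a bootstrap over
images). Pooling trials before inversion is deliberately avoided so that
unequal trial counts across observers cannot reweight the average.

## Ground truth, agreement, and the LOOCV ceiling

Ground-truth labels come from a time-unlimited pool of N observers (N = 20
per task by default): each image's label is the modal vote, and
*inter-observer agreement* is the fraction of votes for the mode, which
lives on the grid {1/N, …, 1}. Modal ties are broken lexicographically by
default (deterministic and seed-free; `seeded_random` and `flag` policies
are available) and are always flagged.

The ceiling for a task is estimated by leave-one-out cross-validation over
the unlimited pool: each observer in turn is scored against the modal labels
of the other N − 1 observers, accuracies are converted to d′, and the N
values are summarized by mean ± SE. The ceiling is below the
perfect-agreement bound exactly to the extent that observers disagree given
unlimited time, which is what makes it the right reference for timed
performance.

## Normalizing away ceiling differences

The semantic task produces more very-high-agreement images than the spatial
task, so raw d′ comparisons between tasks are confounded by ceiling. The
normalization computes d′ separately within each agreement bin, then
averages per-bin d′ with a single weight vector shared by both tasks — the
average of the two tasks' agreement-histogram proportions, renormalized over
jointly occupied bins. Policy details, all config-exposed:

* **Bin edges.** One bin per attainable agreement value k/N, merged upward
  until every bin holds at least `min_images` images (default 20) in every
  task. This respects the discrete support of the agreement statistic while
  keeping per-bin d′ estimable.
* **Empty observer × condition × bin cells** are skipped and the weights
  renormalized for that cell; the skip count is recorded on the result.
* **Bootstrap equalization** (`bootstrap_equalize()`) resamples an equal
  number of *images* per bin with replacement (preserving each image's
  one-presentation-per-color structure) and recomputes the normalized d′
  with uniform weights, as a robustness companion to the analytic weighting.

A caution established while validating this module: per-bin d′ inherits a
small-sample bias from the nonlinear inversion (approaching a tenth of a d′
unit at ~15 trials per bin and high accuracy). When two tasks populate bins
unevenly, this bias
does not cancel between them. Recovery experiments therefore need bins with
tens of trials per observer-condition cell; the packaged recovery check uses
2,832 images for exactly this reason.

## Causal models and decision-variable correlation

The empirical conditional prior p(y | x) between the two category systems
is estimated from the unlimited pools. Because different observer pools
labelled the two systems, there is no vote-to-vote correspondence; per image
the two label multisets are paired by their outer product, each pair
weighted 1/(n_pred · n_tgt) so every image contributes weight one
(`pairing = "modal"` pairs only the modal labels). Smoothing is off by
default (`alpha = 0`, the pure empirical conditionals); a predictor category
never observed then has an unusable row, and predicting from it is an error
rather than a silent guess.

A causal model predicts, for each image and presentation time, the category
in the target system by summing the stored conditional over the predictor
labels reported by the n observers of the predictor pool and taking the
argmax (with n = 1 this is the mode of the conditional row). Scores are
invariant to observer order, and duplicating the pool rescales all scores
without changing the argmax.

Model quality is assessed not by d′ alone — two responders can match in
accuracy while erring on different images — but by decision-variable
correlation: responses are converted to binary correct/incorrect against the
modal ground truth, the phi coefficient is computed independently within
each ground-truth category, and the retained per-category values are
averaged unweighted. Categories with fewer than `min_trials` aligned trials
(default 5) or zero variance in either vector are skipped with a logged
reason, never imputed as zero. Two human-human references bracket the model:
the mean DVC over all observer pairs, and the LOOCV DVC of each observer
against the N − 1 others' modal responses (mode denoising makes the LOOCV
reference the higher of the two). Cohen's kappa and plug-in mutual
information are provided as alternative agreement/performance metrics.

The factoring-out of overall performance by DVC is a first-order property,
not an identity: the phi coefficient of two binary variables with a fixed
underlying evidence correlation still drifts with the marginals. Over
moderate sensitivity contrasts — the operating range of a masked
categorization experiment — the drift is on the order of a hundredth of a
correlation unit, while doubling d′ compresses phi noticeably. The packaged
invariance check therefore contrasts d′ = 1 and 1.5 at the default shared
noise weight.

## The synthetic study

The simulator emulates the study conditions end to end: 708 outdoor scenes,
6 semantic × 4 spatial categories, 20 unlimited-viewing observers per task,
35 semantic / 30 spatial timed observers, and a within-subject
2 (color) × 4 (duration: 13.3, 26.7, 53.3, 106.7 ms) × 3 (viewing: mono,
stereo, reverse-stereo) design in which every image appears once per color
condition — 1,416 trials in 24 color-pure blocks of 59 over two sessions,
with the duration × viewing assignment balanced (59 images per cell per
color) and drawn independently per color condition.

Generative structure, and the reasons behind each choice:

* **Category coupling.** A joint model draws each image's root-system label
  from a marginal and its dependent-system label from a conditional row that
  mixes a uniform row with a concentrated row (mixture weight =
  `coupling_strength`); the causal `direction` chooses which system is the
  root. This is the minimal family that spans independence to deterministic
  coupling with one interpretable knob.
* **Sensitivity growth.** d′(t) = (d_asym + boosts) · (1 − exp(−t/τ)) — the
  simplest monotone, asymptoting form; defaults d_asym = 2.2, τ = 40 ms put
  the four durations on the rising limb with d′ ranging from ≈ 0.5 to ≈ 2.
  Color adds 0.15 and either stereo condition adds 0.10 in d′ units — small
  cue advantages of the size the timed tasks are sensitive to. Lapses
  (uniform guesses) occur at rate 0.02.
* **Image difficulty and ambiguity.** Each image carries per-task ambiguity
  a ∈ [0, 1]: an unlimited-viewing vote is uniform with probability a, else
  the generative label, so agreement declines smoothly from 1 toward the
  uniform-vote mode statistic. Defaults Beta(1.5, 6) (semantic) and
  Beta(2.5, 4.5) (spatial) produce negatively skewed agreement
  distributions with higher semantic agreement, qualitatively matching the
  two tasks. Timed evidence then *targets the pool's modal label* and is
  *scaled by realized agreement* (rescaled above chance; the pipeline
  attaches both after computing ground truth). Driving timed difficulty by
  the realized consensus rather than the latent ambiguity makes
  "same agreement ⇒ same timed behaviour" true by construction — without
  it, two tasks with different ambiguity priors would differ systematically
  *within* a matched agreement bin (the posterior of ambiguity given the
  bin depends on the prior), and the normalization control would be testing
  the simulator's priors instead of the analysis.
* **Shared evidence noise.** Trial evidence mixes an image-presentation-level
  Gaussian component common to all observers (variance share
  `shared_noise_weight`, default 0.3) with observer-private noise. The
  shared component is what gives human-human DVC its positive value; setting
  it to zero drives pairwise DVC to zero. Streams are named, so two
  simulated pools given the same `shared_noise_seed` share image-level noise
  — and two simulated *tasks* can be put on common random numbers for paired
  comparisons.
* **Routed responses.** In the task on the *dependent* system, a fraction
  `route_weight` (default 0.5) of responses is produced by perceiving the
  root category (same evidence machinery and shared-noise stream as the root
  task's own pool) and mapping it through the coupling row's mode. This
  implements, generatively, the hypothesis under test — observers inferring
  one system from the other — and makes direction recovery falsifiable: the
  matching-direction conditional model attains a higher model-human DVC than
  the mismatching one, and both collapse to ≈ 0 under an independent joint
  model.
* **Viewing-condition report.** The 2D/3D/3D-reversed report is a separate
  low-sensitivity 3-AFC channel (asymptote 0.8 d′, τ = 60 ms), so
  category discrimination dominates viewing-condition discrimination as in
  the timed tasks.
* **Determinism.** All randomness flows from one top-level seed through
  named child streams (images, pools, trials, per-observer responses,
  shared noise), so any stage can be re-run independently and a config +
  seed reproduces every table bit for bit.

What the simulator does *not* emulate: pixels, masks, GIST statistics,
stereo rendering, observer-specific response biases, non-uniform confusion
structure (incorrect unlimited-viewing votes are uniform over alternatives),
and learning or fatigue across sessions. Passing tests therefore show that
the *analysis machinery* behaves as claimed under the assumed statistical
structure — not that real scene perception has that structure.

## Problem sizes and numerical choices

The test suite and acceptance checks run at these sizes, chosen so each
check's sampling error is small against the effect it measures: design and
agreement checks at the canonical 708 images / 20 voters; quadrature checks
against 10⁷-draw Monte-Carlo oracles; DVC null and invariance checks on
10,000-trial aligned pairs (20 seeds per sensitivity level); the
normalization recovery on 2,832 images × 30 observers × 10 seeds (see the
bias note above); direction recovery and ceiling ordering on the full
default pipeline (708 images, 35/30 observers) over 10 seeds per direction.
Argmax ties anywhere (modal votes, model predictions) default to the
lexicographically first label so that reruns are identical; random
tie-breaking is available behind a seed. Quadrature nodes (61) and the
root-finder bracket ([−8, 10], auto-extended) are fixed constants; both are
far inside their accuracy plateaus.

## Known limitations

* The conditional prior treats votes as exchangeable across observers
  (outer-product pairing); if real observers have correlated idiosyncrasies
  across tasks, the empirical conditionals would differ.
* The DVC's performance invariance is approximate (see above); comparisons
  across large d′ gaps should lean on the human-human references computed at
  matched conditions rather than on absolute DVC values.
* Ceiling estimates inherit the modal-label instability of low-agreement
  images; with N = 20 voters the agreement grid is coarse (0.05 steps), and
  bins below ~20 images per task are merged away.
* `run_pipeline()` uses one shared trial list for both task pools. If real
  assignments differed across pools, model-human DVC would have to be
  computed on the intersection of aligned trials instead.
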