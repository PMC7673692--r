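---
title: "Satiety-weighted preference models for spike counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satiety-weighted preference models for spike counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpref)
```

## The scientific problem

In a session where a thirsty animal earns sucrose or water, the relative
value of the two rewards is not fixed: as thirst is quenched, choices shift
from water toward sucrose. `vpref` analyzes single-unit recordings from such
sessions. It asks, for each neuron, whether reward-evoked spiking tracks
this internally driven preference shift, and if so, whether the neuron's
activity is better explained by *overall satiety* (everything declines as
the animal drinks), by *relative preference* (sucrose responses rise as
water responses fall), or by a weighted mixture of both.

The package is organized around the classic R modelling idiom: `fit_mle()`
is the fitting function, returning an `scm_fit` object with `print`,
`coef`, `logLik`, `predict`, `residuals` and `simulate` methods;
`compare_models()` wraps the per-neuron model comparison. Everything else —
session I/O, the synthetic generator, behavioral curves, PSTHs, the GLM
classifier, the behavioral readout, the pipeline driver — supports that
core.

## Data model

A *session* is an ordered table of completed trials (contiguous 1-based
trial numbers; forced and choice trials interleaved), per-neuron spike-time
vectors, and lick times, all in seconds on one session clock. Two tasks are
supported: *specific cues*, where distinct auditory cues announce forced
sucrose, forced water, or choice trials (30/30/40%), and *uncertain
outcome*, where 60% of trials carry a single forced cue whose reward
(sucrose or water, 50/50) is revealed only at delivery. Reward follows the
response by 2 s.

Analysis windows are fixed: cue activity is counted 0–0.75 s after cue
onset, reward activity 0.75–1.95 s after delivery. Both intervals are
half-open `[start, end)` so a spike on a shared boundary is never counted
twice. Reward-window analyses include only forced trials on which the
animal was in the reward port at delivery; trial number serves as the proxy
for elapsed time throughout, because the preference shift unfolds over
trials, not wall-clock seconds.

## The spike-count model family

For a neuron's reward-window count $s(t)$ on trial $t$ of a session with
$t_{end}$ trials:

* **unmodulated** — $s(t) \sim \mathrm{Pois}(\bar{s})$, with $\bar{s}$ the
  mean count. Its MLE is closed-form; no optimization is run.
* **satiety** — $\mathrm{Sat}(t) = 1 - t/t_{end}$;
  $s(t) \sim \mathrm{Pois}(e^{a\,\mathrm{Sat}(t)+b})$. A linear proxy for
  uniformly declining motivation.
* **preference** — a logistic $L(t) = 1/(1+e^{-k(t-t_0)})$ with steepness
  $k$ (per trial) and midpoint $t_0$ (trials), evaluated over all trials
  $1..t_{end}$, min–max normalized to $[0,1]$ over that range, and
  inverted ($1-{\cdot}$) on water trials;
  $s(t) \sim \mathrm{Pois}(e^{a\,\mathrm{Pref}(t)+b})$.
* **mixed** — $\mathrm{SWP}(t) = w\,\mathrm{Pref}(t) + (1-w)\mathrm{Sat}(t)$,
  $w \in [0,1]$; the satiety-weighted preference.
* **licks** — the per-trial total lick count, min–max normalized over the
  included trials, replaces the covariate; an alternative explanation in
  which firing merely follows consummatory behavior.

The gain $a$ is constrained positive everywhere it appears, encoding the
prior that these neurons track value positively; with that constraint the
direction of modulation is carried entirely by the covariate.

Two normalization conventions deserve note, because the definitions leave
them open:

* The preference covariate is normalized over the *full* session range
  $1..t_{end}$, not just the included trials, so sucrose and water trials
  share one curve and the covariate is a property of the session, not of
  the trial subset.
* The logistic is built on the sucrose convention (increasing) and then
  inverted for water trials *after* normalization. With min–max
  normalization over the session the reverse order (invert, then
  normalize) coincides only when the logistic spans symmetric values, so
  the implemented order is a convention, stated here rather than asserted
  as canonical.

## Fitting and model selection

`fit_mle()` minimizes the exact negative Poisson log-likelihood with
`optim(method = "L-BFGS-B")` under bounds $a \in (0, 10]$, $k \in
[10^{-3}, 5]$, $t_0 \in [1, t_{end}]$, $w \in [0, 1]$, $b$ unbounded, from
20 random starting points ($a \sim U(0.01, 5)$, $b \sim U(\ln 0.1,
\ln(\max s + 1))$, $k \sim U(0.01, 1)$, $t_0 \sim U(1, t_{end})$,
$w \sim U(0, 1)$). The objective's gradient is supplied analytically —
including the derivative of the min–max-normalized logistic with respect
to $k$ and $t_0$ — which makes a 20-start mixed fit on a 150-trial session
take a fraction of a second. Any fit ending on a parameter bound is
flagged (`at_bound`); the outer bounds are wide enough to be inactive at
the optima recovered in the parameter-recovery tests. Internally the
log-rate is clamped at ±50 to keep the objective finite for extreme
offsets; reported likelihoods are recomputed exactly at the optimum.

Model comparison uses cross-validated likelihood: 50 repetitions of fitting
to a random 80% of included trials and scoring the held-out 20%. Two
numerical choices matter here:

* The held-out score is the *mean per-trial log-likelihood* (averaging the
  log, not the raw likelihood), which is numerically stable and invariant
  to test-set size.
* All candidate models for one neuron are scored on the **same** 50
  partitions. Pairing the splits removes split-to-split noise from the
  between-model differences; with independent splits, selection between a
  true model and a nested extension (satiety vs. mixed) degrades toward a
  coin flip, because the genuine CV gap is far smaller than the variance
  contributed by drawing different partitions.
* Training-set fits are warm-started from the full-data MLE. Because of
  this, the inner cross-validation optimizations need only one additional
  random start (`cv_n_starts = 1` is what the packaged analyses use),
  while full-data fits always use the 20 random starts.

Ties in cross-validated likelihood (rare, but exact ties occur for
degenerate data) resolve toward the model with fewer free parameters.

## From neurons to behavior

The behavioral reference is a logistic $L(t)$ fitted by nonlinear least
squares (`minpack.lm::nlsLM`) to the raw 0/1 choice sequence — not to the
smoothed preference curve — giving $\hat{k}_{beh}$, $\hat{t}_{0,beh}$ and
asymptotic standard errors. Sessions whose choices are all identical are
flagged non-identifiable rather than fitted.

Each neuron's mixed-model $(k, t_0)$ defines its own preference curve over
$1..t_{end}$; its $t_0$ is the neural indifference point. Agreement with
behavior is quantified by the Spearman correlation between the two curves
at unit trial spacing and by $|\Delta t_0|$. One consequence of the
$k > 0$ constraint is worth flagging: every fitted neural curve is
non-decreasing, as is the behavioral curve whenever the session shifts
toward sucrose, so the rank correlation concentrates near $+1$ and the
discriminating signal lives mostly in near-flat curves (fitted $k$ tiny)
and in the indifference-point error. The group contrasts (outcome × time
neurons vs. the rest, two-sided Wilcoxon rank-sum) separate cleanly in the
end-to-end tests despite this compression.

The complementary trial-level correlations use Spearman's $\rho$
throughout: reward-window counts vs. preference on forced trials of each
outcome (water trials against $1 - p(t)$), and cue-window counts vs.
log-latency across all trials.

## The GLM classifier

Forced-trial window counts are regressed on outcome (water = 0,
sucrose = 1), trial number (untransformed), and their product with a
log-link Poisson GLM (`stats::glm`, IRLS, tolerance $10^{-8}$, Wald
p-values). A neuron is *outcome × time* when the interaction is significant
at $P < 0.05$ (per neuron, uncorrected) *and* positive — the time slope for
sucrose exceeds that for water. Under the null this one-directional rule
classifies 2.5% of neurons, which the calibration test verifies (together
with uniformity of the interaction p-values). Fit quality is summarized by
the deviance pseudo-$R^2$, $1 - D/D_0$, labelled as such because several
pseudo-$R^2$ definitions exist for Poisson models. Cue-window
classification does not require port occupancy (the inclusion rule is
stated only for reward activity); in the uncertain-outcome task the cue
carries no outcome information and cue-window classification serves as a
negative control.

## The synthetic generator

`simulate_session()` produces complete sessions with known ground truth:
an i.i.d. trial schedule at the task frequencies, 20–45 s inter-trial
intervals, reward 2 s after the response; choices drawn from the same
logistic family the analysis fits ($P(\text{sucrose at } t) =
1/(1+e^{-k_{true}(t-t_{0,true})})$), which makes behavioral parameter
recovery well-posed by construction; log-normal press latencies, optionally
coupled to the preference drive to exercise the latency-correlation
analysis; licking as a post-reward Poisson burst whose water rate declines
linearly with trial number (default slope −0.03 licks/s per trial from a
6 licks/s base) while sucrose licking stays constant; and spike trains in
which each included trial's analysis-window count is drawn
$\mathrm{Pois}(\lambda(t))$ with $\lambda$ computed by the *same*
`model_rate()` the fitter optimizes (generator/fitter consistency is a
tested invariant), embedded in a homogeneous 4.8 Hz background — the median
baseline rate of the recorded population the conditions emulate. An
"unmodulated" synthetic neuron keeps exactly its background rate inside the
window.

Default study conditions: 150-trial uncertain-outcome sessions (the
recorded sessions spanned 126–175 trials), 60/40 forced/choice,
$k_{true} = 0.15$, $t_{0,true} = t_{end}/2$, 30 neurons of which 70% are
mixed-model encoders with $(a, b, w) = (1.5, 0.5, 0.7)$ sharing the
behavioral $(k, t_0)$. These are deliberately *session-like*, not
data-matched: the generator emulates the trial structure, the preference
shift, declining water licking, and window-level count statistics, but not
within-trial firing dynamics, spike-history structure, correlated noise
across neurons, or behavioral lapses. Passing tests therefore demonstrate
that the estimators recover known structure under realistic sizes and
noise — not that the recorded data satisfy the models.

## Display conventions

PSTHs use 10-ms bins, smoothed per trial with a causal half-normal kernel
(σ = 3 bins), averaged, smoothed again (σ = 8 bins), and z-scored against
the per-trial mean rates in the 10 s preceding each cue (sample SD,
neurons with zero baseline SD are excluded with an explicit error). The
causal kernel uses only current and past bins and is renormalized to unit
mass over the available lags, so constants map to themselves and smoothed
activity never precedes its cause; mass conservation is exact only for
features at least one kernel length from the trace start. Lick PSTHs skip
z-scoring and use a single σ = 25 smoothing pass. The nominal bin width is
read as 0.01 s; a 0.01-*ms* bin would make the σ = 3–25 bin kernels span
microseconds, inconsistent with their purpose.

## Degenerate inputs and tie-breaks

* Preference covariate with a numerically flat logistic (range `< 1e-12`):
  defined as constant 0.5 rather than 0/0.
* `neg_loglik` returns `Inf` (not an error) when a zero rate meets a
  positive count, so optimizers can recover.
* Nearest-choice-trial assignment resolves equidistant neighbors to the
  earlier trial; the Gaussian choice kernel is renormalized at sequence
  edges so constant choice sequences map to themselves exactly.
* Quarter boundaries for $t_{end} \not\equiv 0 \pmod 4$: the first
  $t_{end} \bmod 4$ quarters take the extra trial.
* Constant lick covariates raise a degenerate-covariate error; constant
  curves yield `NA` correlations rather than fabricated values.

## Problem sizes used by the shipped analyses

The test-suite and acceptance analyses run at: 50 replicate neurons for
mixed-parameter recovery (150 trials; 25 replicates each at 100 and 400
trials for the shrinkage check); 50 neurons per generating family for the
selection confusion matrix and 25 for the licks alternative; 500 null
neurons for classifier calibration; 100 replicate sessions for behavioral
recovery; and one 150-trial, 30-neuron session for the end-to-end
pattern. The oracle-equivalence check compares `fit_mle` against a dense
grid search on 50 instances of 30 trials.

## Known limitations

* Counts are modeled as conditionally Poisson; overdispersion
  (negative-binomial noise) and spike-history effects are out of scope.
* The preference weight $w$ is constant within a session.
* The $k > 0$ constraint compresses the curve-agreement statistic (see
  above); indifference-point error is the sharper readout.
* The behavioral standard errors are asymptotic (from the nonlinear
  least-squares fit), not resampled.
* The session format takes port occupancy at delivery as a given boolean
  per trial; inferring it from photobeam signals is upstream of this
  package.
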