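---
title: "Methods: crow-search feature selection, sparse autoencoders and equilibrium-optimizer tuning"
author: "crowsae authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crow-search feature selection, sparse autoencoders and equilibrium-optimizer tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowsae)
```

This vignette is the package's own account of what it computes and why:
the models and search procedures, the parameters that matter, the places
where the design was genuinely open and the choice we made, and what the
synthetic benchmarks do and do not demonstrate.

## The problem

Postpartum hemorrhage (PPH) risk screening is a strongly imbalanced
binary classification task over a wide panel of routinely collected
obstetric variables: cohorts of order 10^4 deliveries, of order 10^2
candidate features, with roughly one positive in ten records. Most
features carry no signal, so the pipeline couples three stages: a wrapper
feature-subset search, a representation-learning classifier, and a
metaheuristic tuner for the classifier's hyperparameters. Each stage is an
independent, seeded, testable function; `pph_pipeline()` composes them with
a strict train/test discipline (no held-out record reaches selection or
tuning).

## Oppositional binary crow search

The selector keeps a flock of `n_crows` continuous positions in
`[0,1]^p`. A position becomes a feature mask by strict thresholding at
0.5 (a coordinate exactly at the threshold excludes the feature, so
"include" always requires positive evidence). The mask is scored by the
wrapper cost

$$\mathrm{cost}(S) \;=\; \bigl(1 - C(S)\bigr) \;+\; W\,\frac{|S|}{p},$$

with $C(S)$ the stratified cross-validated accuracy of a cheap reference
classifier on the masked features and $W \in [0,1]$ the parsimony weight.
Lower is better. The default evaluator is a single nearest neighbour on
standardized features with 5-fold CV: parameterless, fast, and a
reasonable proxy for "does this subset carry class signal". It is
pluggable (`evaluator` argument), so the full autoencoder classifier can
stand in at small scale.

Per iteration, each crow picks a uniformly random flock member `j` and
pursues its memorized best position:

$$x_i \leftarrow \mathrm{clamp}_{[0,1]}\!\bigl(x_i + \tau\, fl\,(M_j - x_i)\bigr),
\qquad \tau \sim U(0,1),$$

unless an awareness draw $\theta < AP$ fires, in which case the crow
restarts at a uniform random position. Opposition-based learning enters
through the flight length: each pursuit evaluates the candidate under both
`fl` and its reflection $\overline{fl} = fl_{\min} + fl_{\max} - fl$ and
keeps the cheaper of the two. Memories update greedily, so the best-cost
history is non-increasing by construction.

Open choices and how we resolved them:

* **Ownership of `fl`.** Neither a global constant nor a per-crow state is
  forced by the update rule; we draw `fl ~ U(fl_min, fl_max)` fresh per
  crow per move. Combined with the opposition step this probes one short
  and one long step each move, which is the practical point of reflecting
  the flight length.
* **Cost direction.** The size-penalty term is $W\,|S|/p$, so that
  accuracy dominates and parsimony breaks ties; with $W = 0.01$ a
  one-feature change moves the cost by $6.7\times10^{-5}$ at $p = 149$,
  below the $1/n$ quantization of CV accuracy. A literal alternative form
  $C + W(1 - p/|S|)$ is available behind `as_printed = TRUE` for
  comparison; its size term rewards arbitrarily small subsets without
  bound, which is why it is not the default.
* **Degenerate masks.** An all-zero candidate is assigned cost `Inf`
  inside the loop and never sent to the evaluator.
* **Caching.** Mask costs are memoized (the evaluator is deterministic
  given its seed), so revisited subsets are free; `n_evaluations` counts
  distinct masks scored.

Defaults (`n_crows = 25`, `AP = 0.3`, `fl` in `[0.1, 1.8]`,
`max_iter = 100`) are the method's reference operating point. At this
budget, on a 600-record, 149-feature cohort with 15 planted informative
columns (1.5 SD class shift, cohort prevalence), the selected mask's
overlap with the planted set is significant at the 0.01 level under the
one-sided hypergeometric test for every seed we probed. At sharply
reduced budgets (10 crows, 25 iterations) the overlap still exceeds its
chance expectation but single runs are only sometimes significant at
0.01 — worth knowing before shrinking budgets in applications.

## Sparse stacked autoencoder classifier

Each layer is a sigmoid autoencoder
$h = \sigma(Wx + b)$, $\hat x = \sigma(W'h + b')$, trained on

$$E \;=\; \frac{1}{N}\sum_{i=1}^{N}\tfrac12\lVert \hat x_i - x_i\rVert^2
\;+\; \frac{\lambda}{2}\bigl(\lVert W\rVert_F^2 + \lVert W'\rVert_F^2\bigr)
\;+\; \beta\, \mathrm{KL}(\hat\rho \,\Vert\, \rho),$$

where $\hat\rho_j$ is the batch-mean activation of hidden unit $j$ and

$$\mathrm{KL}(\hat\rho \,\Vert\, \rho) = \sum_j \rho\ln\frac{\rho}{\hat\rho_j}
+ (1-\rho)\ln\frac{1-\rho}{1-\hat\rho_j}.$$

Layers stack greedily — layer $\ell+1$ pretrains on layer $\ell$'s code —
and a softmax head on the last code is fine-tuned with all encoders on the
multinomial cross-entropy (computed through a log-sum-exp). Decoders are
frozen after pretraining: fine-tuning treats the feed-forward classifier
path as one model, and the reconstruction parameters play no role in it
(this is configurable in principle but not exposed, as nothing in the
package needs it).

Numerical and design choices:

* **Logs are natural** throughout.
* **Input scaling.** Features are min–max scaled to `[0,1]` inside
  `sae()` (sigmoid reconstruction targets must be bounded); the scaling is
  stored on the model and applied by `predict()`.
* **Initialization.** Weights are symmetric-uniform with half-width
  $\sqrt{6/(\text{fan}_{in}+\text{fan}_{out})}$ (overridable via
  `init_scale`); biases start at zero.
* **$\hat\rho$ is a batch estimate.** The sparsity term uses the current
  mini-batch's mean activations (the standard stochastic surrogate for the
  full-data definition); full-batch training (`batch_size = Inf`) recovers
  the exact form. Batch means that reach 0 or 1 exactly are clipped to
  `[1e-6, 1 - 1e-6]` with a warning; `kl_sparsity()` itself refuses
  boundary values rather than clipping silently.
* **Optimizer.** Plain mini-batch gradient descent — the learning rate,
  epochs and batch size are exactly the quantities the tuner searches —
  with one deterministic safeguard: if the full-data loss after an epoch
  rises by more than 1% relative, the epoch is reverted and the step size
  halved ("bold driver" damping). Without it, a fixed step that is
  slightly too large can oscillate and walk the softmax head into a
  degenerate always-one-class region; with it, training is monotone up to
  the 1% tolerance while small mini-batch fluctuations are left alone.
* **Gradients.** All backpropagation is hand-derived and the test suite
  checks every parameter block of both objectives against central finite
  differences at 1e-5 relative tolerance — this is the module's master
  oracle.
* **Ties.** Hard predictions are the argmax with ties toward the lower
  class index, so an untrained (zero) head predicts class 0 everywhere,
  deterministically.

Two runs with the same `sae_control(seed = )` produce bit-identical
models; no function perturbs the caller's RNG state.

## Equilibrium-optimizer tuning

`eo_optim()` minimizes a black-box objective over a box. Particles
("concentrations") relax toward an equilibrium pool — the four best
solutions so far plus their elementwise mean, one of the five drawn
uniformly per particle per iteration:

$$C \leftarrow C_{eq} + (C - C_{eq})\odot F + \frac{G}{\lambda V}\odot(1 - F),$$

with per-particle turnover $\lambda \sim U(0,1)^d$,
$F = a_1\,\mathrm{sign}(r - 0.5)\,(e^{-\lambda t} - 1)$, and a
generation-rate term $G = GCP\,(C_{eq} - \lambda\odot C)\odot F$ where
$GCP = 0.5\,r_1$ with probability $1 - GP$ and 0 otherwise (one draw per
particle, shared across dimensions). The time parameter
$t = (1 - \mathrm{Iter}/\mathrm{Max})^{a_2\,\mathrm{Iter}/\mathrm{Max}}$
decays from 1 to 0, shifting exploration to exploitation; $a_1 = 2$,
$a_2 = 1$, $GP = 0.5$, $V = 1$. Decisions worth recording: the
generation-rate switch compares $r_2$ against $GP$ (a literal always-on
switch is recovered by `GP = 0`); a product variant of $t$ is available as
`as_printed = TRUE` on `eo_time_param()` but pins $t$ to zero at both
ends of the run and is not used; $\mathrm{sign}(0) = 0$, so an exact
$r = 0.5$ draw moves nothing in that dimension; updates are clamped to
the box; the pool updates greedily, making the best-cost history
non-increasing.

`tune_sae()` applies this to hyperparameter selection. The search box
(`sae_space()`) spans learning rate, weight decay and sparsity weight on
log10 scales, the sparsity target linearly, and layer widths with
rounding; the objective (`sae_cv_fitness()`) is
$1 - \mathrm{CA}_{validation}$, the mean held-out fraction-correct over
stratified k-fold CV (10 folds at reference scale; the desk-scale profile
uses 3). A fold whose training fails scores worst-case fitness 1 with a
warning, so one pathological configuration cannot abort a search. Tuning
hyperparameters — rather than having the optimizer set the network's
weights directly — is the only reading consistent with a CV-accuracy
objective; a direct-weight mode would be computationally implausible at
the target scale and is deliberately not provided.

## Synthetic cohorts: what they emulate and what they don't

`synth_pph()` plants the minimal structure under which wrapper-selection
recovery is measurable: labels Bernoulli(prevalence) (or exact-count), a
chosen number of informative columns whose positive-class mean is shifted
by `effect_size` standard deviations, and pure-noise remaining columns.
Defaults reproduce the target cohort's shape — 11,000 records, 149
features, prevalence 1042/11000 ≈ 9.47%, 15 informative columns — and
`effect_size = 1.5`, a shift large enough that a planted column is
individually detectable at moderate n, which is the regime in which
feature-selection benchmarks are informative at all.

Real obstetric data differ in every inconvenient way: correlated and
mixed-type features, nonlinear and interaction effects, missingness,
label noise, drifting prevalence. Passing the package's benchmarks
therefore demonstrates that the machinery is implemented correctly and
can recover simple planted structure — not that it will attain any
particular accuracy on a hospital cohort.

Two scale notes, chosen once as the package's own test conditions. Test
and example datasets use a few hundred records with prevalence 0.30
rather than the cohort's 9.5%: at n = 600 a 9.5% minority (~57 cases)
makes "held-out accuracy above the base rate" nearly uninformative, while
at 30% it is a real bar. And the shipped smoke profile (flock of 4, 3
selector iterations, 2-particle tuning, 60 fine-tune epochs) exists so the
full pipeline runs end-to-end in seconds; the reference profile
(`crow_select` defaults, 10-fold CV tuning) is the method's actual
operating point.

## Repeated runs and reporting

`pph_pipeline()` repeats split → select → tune → train → evaluate with
per-run seeds derived as `master_seed + run`, re-running feature selection
each run by default (`reselect_features = FALSE` reuses the first mask).
Metrics are the six confusion-matrix summaries — precision, recall,
accuracy, harmonic-mean F-score, Matthews correlation, error rate — plus
the ROC area by trapezoidal threshold sweep; ratios with zero denominators
report 0 with a `degenerate` flag rather than aborting a run, which
matters at strong imbalance. The aggregate row is the plain arithmetic
mean of per-run metrics at full precision (display rounds to 4 decimals).
A failed run is recorded as a machine-readable error entry and excluded
from the aggregate; the JSON report carries per-run metrics, selected
features, tuned hyperparameters and seeds.

## Known limitations

* The selector's continuous-position dialect refines subsets slowly near
  an optimum; exact recovery of a planted subset needs either an easy
  cost landscape or the reference budget (see the recovery note above).
* The classifier is a plain sigmoid network trained by gradient descent;
  no momentum, early stopping or class re-weighting. Under strong
  imbalance its argmax decisions can be conservative even when the
  ranking (AUC) is good; users who need calibrated decisions at 9.5%
  prevalence should threshold the probability output themselves.
* `sae_cv_fitness()` is expensive (k trainings per evaluation); tuning
  budgets in examples are intentionally tiny, and the tuner's benefit at
  those budgets is modest.
* The metrics module is strictly binary; no multi-class or calibration
  support.
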