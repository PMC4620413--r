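---
title: "Methods: quantum-inspired fruit fly optimization for SVM tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantum-inspired fruit fly optimization for SVM tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qfoa)
```

## The problem

Small, imbalanced medical-imaging cohorts — a few dozen diseased cases
against a larger pool of normals — are the setting where an RBF-kernel
soft-margin SVM is attractive and where its two hyperparameters, the
penalty factor $C$ and the kernel width $\gamma$, dominate performance.
Ordinary accuracy-driven tuning is a poor guide here: a classifier that
calls everything "normal" scores high accuracy while missing every
patient. `qfoa` tunes $(C, \gamma)$ by minimizing a cost-sensitive
cross-validation objective,

$$
\mathrm{Fitness}(C, \gamma)
  = \frac{1}{K} \sum_{k=1}^{K}
    \bigl[\, w \cdot \mathrm{FNR}_k + (1 - w)\cdot \mathrm{FPR}_k \,\bigr],
$$

the $K$-fold mean of a weighted sum of the missed-diagnosis rate (FNR)
and the misdiagnosis rate (FPR). With the default $w = 0.9$ a missed
patient costs nine times a false alarm, which matches clinical
priorities: a false positive triggers follow-up examination, a false
negative delays treatment.

## The optimizer

The search engine is a fruit fly swarm with a quantum-inspired encoding.
Each candidate is a *phase position*: two angle vectors
$(\theta^x_1,\dots,\theta^x_n)$ and $(\theta^y_1,\dots,\theta^y_n)$, one
angle pair per optimized dimension ($n = 2$ for SVM tuning). A position
decodes to **two** solutions at once,

$$
s^{\cos}_j = \tfrac{1}{2}\bigl(\cos^2\theta^x_j + \cos^2\theta^y_j\bigr),
\qquad
s^{\sin}_j = \tfrac{1}{2}\bigl(\sin^2\theta^x_j + \sin^2\theta^y_j\bigr),
$$

so a swarm of $M$ flies effectively covers a doubled search space. The
squared amplitude distance lies in $[0, 2]$; dividing by its maximum 2
is the one affine normalization that both lands the value in $[0, 1]$
(convenient for zooming into parameter ranges) and makes the two
solutions exactly complementary, $s^{\cos}_j + s^{\sin}_j = 1$ — the
quantum identity $\cos^2 + \sin^2 = 1$ carried through the decoding.
Both decoded solutions are evaluated every iteration and the fly is
scored by the better of its two smells; this realizes the doubled
search space literally rather than leaving the second solution unused.

Each iteration:

1. every fly is re-drawn around the swarm axes by adding an independent
   Uniform$(-V, V)$ draw to every angle (default $V = 1$ radian), with
   wrap-around into $[-\pi, \pi]$ so the phase interpretation stays
   valid;
2. flies are decoded and scored;
3. with probability $P_m$ a fly undergoes a *quantum NOT-gate* mutation:
   one of its $2n$ angles is replaced by $\pi/2 - \theta$, which swaps
   that coordinate's cosine and sine amplitudes. The gate is an
   involution, so mutation never loses information;
4. a mutated fly that improves is always kept; a worsening mutation is
   kept with the annealed Boltzmann probability
   $P = \bigl[1 + e^{\,l\,(F_{\text{new}} - F_{\text{old}})}\bigr]^{-1}$,
   which is at most $1/2$ and decays with both the size of the worsening
   and the iteration count $l$ — early exploration, late exploitation;
5. the swarm axes move to the best fly whenever the population minimum
   improves on the incumbent.

The decoded solution is zoomed into SVM parameters by
$C = C_m \cdot s_1$, $\gamma = g_m \cdot s_2$. The zoom multiples are
*prior knowledge about the data*: they define the parameter ranges the
search covers and should be set from what is known about the feature
scales (see below).

The classic fruit fly optimizer (`foa_optimize`) is included as a
baseline: real-valued axes, per-dimension perturbation, decoding through
$S = 1/\sqrt{X^2 + Y^2}$, greedy axis relocation, no mutation. An
exhaustive lattice search (`method = "grid"` in `tune_svm`) serves as a
deterministic reference.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `population_size` (M) | 20 | flies per iteration; typical swarm size for this algorithm family |
| `max_iterations` | 100 | fixed iteration budget; termination is deliberately a fixed budget, no early stopping, for reproducibility |
| `mutation_prob` (P~m~) | 0.2 | NOT-gate mutation rate; enough diversity without destroying convergence |
| `perturb_range` (V) | 1 rad | half-width of the uniform angle perturbation |
| `k_folds` (K) | 5 | cross-validation folds; every fold keeps both classes by stratification |
| `fnr_weight` (w) | 0.9 | cost ratio of missed diagnosis to false alarm |
| `c_multiple` (C~m~) | 1 | upper end of the C search range |
| `gamma_multiple` (g~m~) | 2000 | upper end of the gamma search range |

The zoom defaults (1 and 2000) describe a search over $C \in (0, 1]$,
$\gamma \in (0, 2000]$ — ranges appropriate for feature sets whose
pairwise distances are small. For the package's own synthetic cohort,
whose features are standardized to unit variance (typical squared
distances of order $2 \times \mathrm{dims}$), $\gamma$ above about 1
collapses the RBF kernel to the identity and the SVM to a majority-class
rule; the worked examples and tests therefore use the prior-knowledge
zoom $(C_m, g_m) = (10, 1)$ for that cohort. This is the intended use of
the zoom multiples, not a special case: choose them from the scale of
*your* data.

## Numerical and design choices

- **Stratified folds, frozen per run.** FNR is undefined on a fold with
  no positives, so folds are stratified (each class shuffled separately
  under the fold seed and dealt round-robin). The assignment is fixed
  across all candidate evaluations of one optimization run, which makes
  candidate comparisons like-for-like and the recomputation identity
  exact: the reported best fitness equals `evaluate_candidate` re-run at
  the best parameters with the stored fold seed, bit for bit.
- **Standardization inside the folds.** Features are centred and scaled
  using statistics of the training folds only, so no information leaks
  from a held-out fold into training.
- **Boundary clamping.** $s = 0$ decodes to $C = 0$ or $\gamma = 0$,
  both outside the SVM contract; zoomed parameters are clamped below at
  $10^{-6}$ times their multiple.
- **Degenerate metrics.** Precision with no predicted positives is
  reported as `NA`; F1 with `tp = 0` is defined as 0 so repeated-run
  harnesses never crash on a degenerate classifier. A fold or test split
  missing a whole class raises an error naming the empty class.
- **Acceptance rule.** The Boltzmann acceptance is implemented as the
  logistic form above: worse moves accepted with probability $\le 1/2$,
  annealed by iteration, and strict improvements accepted with
  probability 1. The rule is isolated in `acceptance_probability` so an
  alternative annealing schedule can be swapped in.
- **RNG discipline.** One seed per run drives initialization,
  perturbation, mutation and acceptance draws in a documented fixed
  order (perturbations fly-by-fly, then per fly: mutation coin,
  coordinate draw, acceptance draw), so equal seeds give bitwise equal
  trajectories. Repeated-run harnesses use consecutive seeds from a base
  seed.
- **Summary convention.** Repeated-run spread is reported as the sample
  standard deviation (denominator $n - 1$); a single run reports 0.

## The synthetic cohort

No public data accompany the problem this package grew out of, so
`generate_feature_dataset` emulates the relevant structure: 33 positive
and 81 negative samples split 17/41 for training and 16/40 for testing,
features drawn from class-conditional Gaussians with identity
covariance, negatives at the origin and positives displaced by
`separation` along the fixed unit vector $(1,\dots,1)/\sqrt{d}$.
`separation` is the single difficulty knob, in units of the
within-class standard deviation: 0 makes the classes identical in
distribution, 6 (the default) makes them cleanly separable, and tuned
test accuracy rises monotonically in between.

What passing tests on this cohort do show: the optimizer finds
parameter regions with perfect cross-validated and held-out
classification when such regions exist, respects the fitness scale when
they do not, and the whole pipeline is deterministic. What they do not
show: behaviour under correlated features, label noise, non-Gaussian
class shapes, or distribution shift between train and test — real CT
feature tables have all of these.

The texture front-end (`generate_texture_images`,
`extract_gray_fractal_features`) is an explicitly toy stand-in for a
real image feature pipeline: smooth low-frequency fields versus rough
pixel noise, summarized by mean intensity, intensity spread, histogram
entropy and the box-counting fractal dimension of the median-threshold
binarization. Median thresholding is parameter-free and scale-robust;
box counting uses dyadic box sizes with a least-squares fit of
$\log N(\varepsilon)$ against $\log(1/\varepsilon)$ and recovers the
analytic dimensions of a filled square ($\approx 2$) and a line
($\approx 1$). The estimator is validated on those fixtures, not
claimed to match any particular clinical feature definition.

## Problem sizes used in the shipped checks

The package's tests and the acceptance script run the tuner at
scaled-down budgets chosen as sufficient for their tasks: the
parameter-recovery check uses $M = 20$ with 25 iterations (the
separable cohort is found well before the default 100-iteration
budget), the fitness-scale check at zero separation uses $M = 10$ with
10 iterations, and the toy-objective oracle comparisons use the full
default configuration. The fitness-scale check uses the symmetric
weight $w = 0.5$, under which any label-independent classifier has
expected fitness exactly $0.5$; under asymmetric weights the expected
value of a degenerate majority-class rule is $w$, not $0.5$, so the
symmetric weight is the one at which the scale of the objective can be
confirmed against theory.

## Known limitations

- The fitness surface over $(C, \gamma)$ is piecewise constant on small
  cohorts (finitely many distinct CV confusion counts), so many
  parameter settings tie at the optimum; reported best parameters are
  one member of the optimal plateau, seed-dependent.
- With $w$ close to 1 the objective ignores false alarms almost
  entirely; on hard data the tuned classifier may buy FNR = 0 with a
  substantial FPR. That is the intended trade, but worth remembering.
- The optimizer is a metaheuristic: no convergence guarantee exists
  beyond the monotone best-so-far trajectory, and the shipped
  oracle-equivalence checks are statistical (9 of 10 seeds), not
  universal laws.
- Binary classification only; multi-class problems and kernels other
  than the RBF are out of scope.
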