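---
title: "Optimized weighted deep-feature fusion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimized weighted deep-feature fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jellyfuse)
```

## The problem

Transfer-learning pipelines for skin-lesion classification extract fixed
feature vectors from dermoscopy images with several pre-trained CNN
backbones (a VGG16-like extractor yielding 512 features, and two 1024-wide
extractors in the configuration this package mirrors). The blocks are
complementary, and the simplest ensemble — concatenating them into one
2560-column matrix (the *combined feature set*, CFS) — ignores that some
extractors, and some individual features, carry more class signal than
others.

`jellyfuse` implements the weighted-fusion family built on that
observation:

* **CFS** — plain concatenation, the baseline.
* **AWFS** — *adaptive weighted feature set*: one scalar weight per block,
  set from each block's standalone validation accuracy.
* **MOWFS** — *model-based optimized weighted feature set*: the block
  weights $(w_1, w_2, w_3) \in [0,1]^3$ are decision variables of a
  metaheuristic that minimizes a classifier-based cost.
* **FOWFS** — *feature-based optimized weighted feature set*: one weight
  per fused column ($\sum_b d_b$ variables, 2560 at the default widths),
  optimized the same way.

After optimization, entries with weight $> 0.5$ (strictly) form the
*highest-ranked feature set* used for final classification; for MOWFS the
rule acts at block granularity, which is why published ranked
dimensionalities at that level are block sums such as $512 + 1024$.

## The jellyfish search optimizer

The workhorse optimizer is an artificial jellyfish search (AJS), a swarm
method with three motion modes, applied to each member $i$ at iteration
$t$:

1. **Ocean current** (global drift): with a single uniform draw $u$,
   $$\vec{c} = x^{*} - \varphi\, u\, \bar{x}, \qquad
     x_i \leftarrow x_i + u'\,\vec{c},$$
   where $x^{*}$ is the incumbent best, $\bar{x}$ the swarm mean, and
   $\varphi > 0$ the distribution coefficient.
2. **Passive swarm motion** (local jitter):
   $x_i \leftarrow x_i + \omega\, u_d\,(\text{ub}_d - \text{lb}_d)$ with an
   independent draw per dimension and motion coefficient $\omega$.
3. **Active swarm motion** (pairwise): against a random partner $j \ne i$,
   move toward $j$ if $f(x_i) \ge f(x_j)$ and away otherwise, by a random
   fraction of the separation vector.

A *time-control* draw
$f_{TC} = \lvert (1 - t/T)\,(2u - 1)\rvert \in [0, 1)$ selects the mode:
ocean current when $f_{TC} \ge c_0$ (default $c_0 = 0.5$), otherwise
passive motion with probability $f_{TC}$ and active motion with the
complement. The envelope decays linearly in $t$, so the swarm drifts
globally early and refines locally late; at $t = T$ the drift branch is
unreachable. Out-of-box coordinates re-enter from the *opposite* bound
(`wrap_bounds()`), repeatedly if needed.

Real-coded GA (roulette-wheel selection on inverted cost, arithmetic
crossover 0.8, per-gene Gaussian mutation 0.1 with $\sigma = 0.1 \times$
span, elitism 1) and canonical global-best PSO (inertia 1 damped by 0.99
per iteration, $c_1 = 1.5$, $c_2 = 2.0$, velocities clamped to the box
span) serve as baselines under the same budget.

### Design choices in the optimizer

Several details are under-determined in the published descriptions of this
family; the package fixes them as follows and treats them as its own
contract:

* **Budget.** Population 10, 50 iterations, for every optimizer. All
  configurable.
* **$\varphi = 3$, $\omega = 0.1$** — the values used in the original
  jellyfish-search publication; neither is dictated by the fusion method
  itself.
* **Time-control range.** The raw product $(1 - t/T)(2u - 1)$ spans
  $(-1, 1)$; the absolute value is taken so the stated $(0,1)$ range and
  the $f_{TC} \ge c_0$ branch both make sense.
* **Greedy per-member acceptance.** A candidate replaces a member's
  location only when its cost is not worse; the wrapper loop's
  per-iteration "keep the minimum-cost weights" step is read at member
  level. This tightens convergence by roughly an order of magnitude on the
  3-D sphere benchmark versus unconditional updates and is what makes
  per-feature weight resolution possible at a 500-evaluation budget.
* **Draw granularity.** Ocean current uses one scalar draw (mirroring its
  scalar random coefficient); passive motion draws per dimension to keep
  exploration isotropic.
* **Ties** in active motion move toward the partner ($\ge$ branch).
* **Initialization** is uniform over the box; one seeded RNG stream per
  run makes results bit-reproducible.

## The wrapper cost

MOWFS/FOWFS minimize `mse_cost()`: weight the fused training matrix, split
it into an inner stratified 70/30 train/validation partition, fit the
chosen classifier, and return the mean squared error between one-hot labels
and predicted class-probability vectors on the validation fold. The inner
split is fixed by a seed and shared by every candidate, so the objective is
deterministic; cost evaluations run inside an isolated RNG scope
(`withr::with_seed`) and do not perturb the optimizer's stream. The final
stratified 80/20 test split is taken *before* any weight learning and never
enters the cost.

Two practical points matter more than they might appear:

* **Classifier choice.** Decision trees and Gaussian naive Bayes are
  invariant to per-feature positive rescaling, so they cannot feel fusion
  weights at all; an MLP simply re-absorbs the scaling into its first
  layer. The SVM (fitted with `scale = FALSE`, precisely so the weights
  reach the kernel) is the classifier that gives the wrapper a usable
  gradient, and is the default for the optimized strategies.
* **Probability smoothness.** Platt calibration refits an internal
  cross-validated sigmoid per candidate, which makes the cost landscape
  rugged under small weight perturbations. The wrapper cost therefore uses
  a softmax over one-vs-rest aggregated pairwise SVM decision values —
  smooth and deterministic — while the evaluation harness keeps standard
  calibrated probabilities for metrics and AUC.

AWFS's published description says only that weights are chosen
"adaptively" after a uniform initialization; the package uses the simplest
data-driven rule — each block's standalone validation accuracy divided by
the best block's accuracy, so weights lie in $(0, 1]$ — and makes no claim
that this matches the original authors' mechanism.

## Evaluation harness

`train_eval()` reports accuracy, macro-averaged precision, sensitivity and
F1 (the averaging mode is a package choice; unweighted macro is standard
when minority lesion classes matter), and macro one-vs-rest AUC via pROC.
`rank_methods()` ranks methods within each dataset (rank $k$ = best, ties
averaged — the convention under which larger rank sums mean better
methods), and `friedman_statistic()` computes
$$FM = \frac{12}{N\,k\,(k+1)} \sum_j R_j^2 \;-\; 3\,N\,(k+1)$$
from the rank sums. `paper_rounding = TRUE` truncates the leading
coefficient to three decimals before multiplying, replicating a
hand-computed presentation of the statistic
($0.083 \times 1922 - 144 = 15.526$ for $R = (32, 27, 13)$, $N = 12$,
$k = 3$); the full-precision value for the same table is $16.1667$. The
statistic is invariant to reversing the rank direction, which the test
suite exploits to cross-check against `stats::friedman.test`.

`delta_report()` recomputes improvement-over-CFS figures, in percentage
points, from packaged CSV copies of the published validation-accuracy
tables, and checks them against the narrative claims quoted alongside those
tables. Several narrative figures are arithmetically inconsistent with
their own table cells; the report flags these (`consistent = FALSE`)
rather than forcing agreement.

```{r deltas}
rep <- delta_report()
subset(rep$table, classifier == "SVM" & strategy == "FOWFS-AJS",
       select = c(dataset, delta_fused_pp, delta_ranked_pp, dim_ranked))
table(rep$claims$consistent)
```

## The synthetic generator

Real dermoscopy deep features are out of scope; `generate_dataset()`
produces multi-view tables with the same *shape* and a known ground truth.
Labels follow a configurable class-proportion vector (default: one
dominant class at 65%, mimicking lesion-class skew without copying any
dataset's exact frequencies). Each block's informative columns receive
per-class means drawn from
$N\!\left(0,\; \text{effect}^2 / (2\,n_{\text{info}})\right)$, so the
expected squared distance between class-mean vectors *per block* equals
$\text{effect}^2$: the effect size is the block-level class separation in
noise-sd units, independent of how many columns carry it. All other
columns are standard normal.

The block-level normalization is deliberate. If every informative column
individually carried the full separation, a 20-column block at effect 2.5
would separate classes at $\approx 11\sigma$ — every classifier saturates,
the wrapper cost is flat in the weights, and weight optimization would be
unfalsifiable. Under the block-level reading the two-block probe
(`make_two_block_probe()`: 300 samples, 20 informative + 20 noise columns,
effect 2.5 vs 0) gives the informative block a standalone accuracy near
0.9, a validation MSE around 0.1, and a cost that responds measurably to
each weight — the regime in which parameter recovery is a meaningful test.

What the generator does *not* emulate: the covariance structure of real
CNN features (correlated, non-Gaussian, layer-normalized), label noise,
or class-dependent feature scale. Passing recovery tests show the wrapper
machinery works; they do not certify performance on real dermoscopy data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the optimizer benchmarks
at 20 seeds (1-D quadratic against a $10^{-4}$-step grid oracle; 3-D
sphere) and the recovery studies at 10 seeds on the 40-column probe —
sizes chosen so the full pipeline, including ~500 SVM fits per wrapper
run, completes comfortably on a single CPU while leaving the success
criteria statistically crisp. Degenerate inputs are handled explicitly: an
empty ranked selection is a classed error (`degenerate_selection_error`)
that `run_experiment()` converts into a full-set fallback with a warning;
an all-equal GA fitness degrades roulette selection to uniform; a
non-finite objective value aborts optimization with a diagnostic rather
than corrupting the incumbent.

## Known limitations

* The optimized strategies inherit wrapper feature selection's cost: every
  candidate evaluation is a classifier fit. At the published 2560-feature
  scale with an SVM cost this is hours, not seconds; the package is
  routinely exercised at reduced widths.
* At a 500-evaluation budget in a 2560-dimensional box, per-feature
  weights move little from initialization; FOWFS's selection at that scale
  is closer to randomized screening than to a converged optimum. The probe
  studies use 40 dimensions for exactly this reason — and even there the
  selection's enrichment for truly informative columns is modest and
  varies with the random seed, while the block-level (MOWFS) weight
  ordering is recovered essentially always. Per-feature selection should
  be read as a noisy ranking, not a certainty.
* AWFS's adaptation rule and the MOWFS block-level ranking rule are
  package interpretations of under-specified descriptions (see above).
* The image-extractor module is a thin adapter contract; no pre-trained
  backbone ships with the package.
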