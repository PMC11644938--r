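---
title: "Band selection through discrete relaxation: model and methods"
author: "bsdr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band selection through discrete relaxation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsdr)
```

## The problem

Hyperspectral instruments measure reflectance in hundreds to thousands
of narrow spectral bands. For most downstream tasks — crop
classification from imaging spectrometry, soil organic carbon
estimation from laboratory spectra — only a handful of bands carry the
discriminative signal, and the rest are highly collinear with their
neighbors. *Band selection* chooses a small subset of the original
bands (preserving their physical interpretation, unlike projection
methods such as PCA), which reduces data volume and often improves the
accuracy of models that struggle with thousands of correlated inputs.

Choosing the best $t$ of $L$ bands is a combinatorial subset-selection
problem, NP-hard in general. This package implements a gradient-based
approach that exploits the *quasi-continuity* of hyperspectral data:
adjacent bands are so strongly correlated that reflectance "between"
two bands, obtained by linear interpolation, is physically meaningful.
That property turns the discrete search over index subsets into a
smooth optimization over continuous index positions.

## The model

Each of the $t$ requested band indices is represented by an
unconstrained learnable scalar $c_p$. Its sigmoid image
$r_p = \sigma(c_p) \in (0,1)$ is a *normalized band index*: position 0
is the first band, position 1 the last. Two maps connect the relaxed
index to the data:

* **Denormalization.** $d(q) = \lfloor q \, (L-1) \rfloor + 1$ maps a
  normalized index onto the 1-based integer band range, monotonically
  and onto $\{1,\dots,L\}$ (`denormalizeIndex()`).
* **Interpolation.** For sample $i$ with reflectance vector $v_i$,
  $$B_i(q) = v_i[d(q)] + \big(v_i[d(q)+1] - v_i[d(q)]\big)\,
  \big(q(L-1) - \lfloor q(L-1)\rfloor\big),$$
  the piecewise-linear interpolant through the band grid
  (`interpolateReflectance()`). It is exact at grid points, continuous
  on $[0,1]$, and differentiable between grid points with slope
  $(v_i[d(q)+1]-v_i[d(q)])(L-1)$ — the quantity that carries the loss
  gradient into the band parameters. At $q = 1$ the second index would
  leave the array; because the fractional factor is then exactly zero
  we clamp that access to $v_i[L]$, which preserves the formula's value
  while making evaluation total.

The $t$ interpolated values $B_i(r_1),\dots,B_i(r_t)$ feed a small
*inference network*: two hidden layers of 128 and 64 units with Leaky
ReLU activations (negative slope 0.01 by default) and a linear output
head with $K$ units ($K$ = number of classes, or 1 for regression).
Training minimizes mean squared error (regression) or mean
cross-entropy on the raw scores (classification) **jointly** over the
band parameters and the network weights:

$$\arg\min_{\theta,\,c}\; \frac{1}{N}\sum_{i=1}^N
\Big(y_i - f_\theta\big([B_i(\sigma(c_1)),\dots,B_i(\sigma(c_t))]\big)\Big)^2 .$$

After training, each index is snapped to the nearest integer band,
$\mathrm{round}(r_p (L-1)) + 1$, duplicates are removed and the result
sorted (`extractBands()`). Several relaxed indices can converge to the
same band, so the final set size $t' \le t$.

The learnable-parameter count is
$t + (128t + 128) + (128 \cdot 64 + 64) + (64K + K) = 129t + 8384 + 65K$
(`countParameters()`), independent of $L$ — the property that makes the
approach data-efficient compared with attention-based selectors whose
parameter counts scale with the full spectral dimension. At $t = 5$
this gives 9354, 10069 and 9094 parameters for 5-class, 16-class and
single-output heads respectively, and every unit increase of $t$ adds
exactly 129 parameters.

## Training procedure and tunable parameters

`bsdrTrain()` performs full-batch training: one gradient update per
epoch computed on the entire training split. With so few parameters
this is affordable and gives low-variance gradients. Defaults, each
exposed in `bsdrConfig()`:

| parameter | default | meaning |
|---|---|---|
| `targetSize` | — | t, number of relaxed indices (1 ≤ t < L) |
| `epochs` | 500 | full-batch updates; no early stopping |
| `learningRate` | 0.001 | step size; the selection is sensitive to it — too large overshoots along the spectral axis, too small fails to move the indices before training ends |
| `hiddenSizes` | 128, 64 | inference-network widths |
| `negativeSlope` | 0.01 | Leaky ReLU slope for negative inputs |
| `optimizer` | `"adam"` | `"sgd"` gives plain full-batch gradient descent |
| `seed` | 1 | seeds the network weight initialization only |

Design choices where the procedure was genuinely open:

* **Optimizer.** The update rule is described here only as
  gradient-descent-family; we default to Adam ($\beta_1 = 0.9$,
  $\beta_2 = 0.999$) because plain gradient descent at learning rate
  0.001 for 500 epochs moves the band parameters too little to traverse
  the spectral axis; plain SGD remains available via the config.
* **Index initialization.** "Linearly spaced across the spectral
  dimension" is realized as $r_p = p/(t+1)$: strictly interior (so the
  inverse sigmoid is finite), symmetric, and strictly increasing — the
  property that lets a plain vector emulate a *set* of distinct
  indices. It uses no randomness; the seed affects only the network
  weights, which are drawn uniformly from $\pm 1/\sqrt{\text{fan-in}}$.
* **Integer preview rule.** The per-epoch trace and the final
  extraction both use nearest-integer rounding of the continuous
  position $r(L-1)$ (ties rounding up via $\lfloor x + 0.5\rfloor$,
  rather than round-half-to-even). The floor map $d(\cdot)$ is used
  only as the interpolation bracket; using it for reporting would bias
  selected indices downward by half a band on average.
* **No input scaling.** Reflectance is fed raw, in $[0,1]$; no
  standardization is applied anywhere in the pipeline.
* **Divergence.** A non-finite training loss aborts with an error
  naming the epoch rather than returning a silently broken model.

`bsdrTrain()` records, after every epoch, the current integer band
preview, the training loss, and validation metrics (overall accuracy
and Cohen's kappa, or R² and RMSE) on the held-out validation split —
useful for watching indices drift toward informative regions.

## Evaluation protocol

Selected bands are scored by an independent, non-deep-learning model so
that the bands, not the selector's own network, are what is evaluated.
`makeSplitPlan()` reproduces the protocol per fold: 90% of samples
train the selector (a random tenth of that held out for validation);
the remaining 10% is halved into an SVM training and an SVM test split.
Across the ten folds the evaluation blocks partition the dataset
exactly (largest-remainder sizing keeps fold sizes within one sample).
For classification, fold assignment and the halving are stratified by
class — with 5%-sized SVM splits an unstratified draw can easily lose a
rare class entirely; stratification is therefore the default whenever
labels are available, and the plan construction is deterministic given
$(n, \text{fold}, \text{seed})$.

`evaluateBandsSVM()` trains an RBF-kernel SVM (`e1071`/libsvm) on the
selected columns with the protocol's grid-searched hyperparameters —
$C = 10^5$ for classification, $C = 100$ for regression, $\gamma = 1$,
no scaling — and reports overall accuracy and Cohen's kappa
($\kappa = (p_o - p_e)/(1 - p_e)$, always $\le$ OA when chance
agreement $p_e < 1$) or R² and RMSE. Multiclass problems use libsvm's
native one-vs-one decomposition, the long-standing default of the SVM
implementations this protocol is built on. `crossValidate()` sweeps
folds and target sizes, attaches a per-fold all-bands baseline, and
`summarizeCrossValidation()` reports mean ± sample standard deviation
(n − 1 denominator) per cell.

`bruteForceSubsetSearch()` is the exhaustive oracle: it scores every
$t$-subset with the same SVM harness (guarded to
$\binom{L}{t} \le 10^5$) and is used in tests to show the
gradient-based search lands within a few percent of the true optimum on
instances small enough to enumerate.

## The synthetic generator

Real benchmark datasets are large external downloads; the package
instead ships a generator (`generateSpectra()`) that emulates the one
structural property the algorithm exploits — quasi-continuity — plus a
known ground truth to recover:

* Spectra are sums of random-amplitude Gaussian bumps (about
  $L/2s$ bumps of width $s$ = `smoothness` bands, amplitudes
  $\mathcal{N}(0,1)$) over a random linear baseline, min–max rescaled
  to $[0,1]$ over the whole matrix. At the default smoothness of 5
  bands, adjacent-band correlation exceeds 0.9, comparable to real
  reflectance spectra.
* The regression target is a fixed random linear combination
  (coefficients of magnitude 0.5–1.5, random sign) of reflectance at
  the planted bands, standardized to zero mean and unit variance, plus
  $\mathcal{N}(0, \text{noiseSd}^2)$ noise. Standardization makes
  `noiseSd` read directly as a fraction of the signal spread and keeps
  the target scale stable across band counts and smoothness settings
  (it also keeps the target well clear of the SVR harness's
  $\varepsilon$-insensitive tube, whose default width of 0.1 would
  otherwise swallow a small-amplitude latent). Classification
  quantile-bins that latent score into K classes balanced to within
  one sample, which keeps class boundaries tied to the planted bands
  and makes band recovery well-posed.
* Defaults: three planted bands at 20%, 50% and 80% of the spectral
  range (40/100/160 at $L = 200$ — far enough apart that recovery is
  unambiguous at smoothness 5) and noise standard deviation 0.05, i.e.
  5% of the unit signal spread.

`missingBandScenario()` deletes a contiguous band block and reindexes,
mimicking datasets with excluded water-absorption regions; because the
interpolant then treats two spectrally distant bands as adjacent, band
recovery degrades — the package reproduces this documented failure mode
rather than hiding it.

What the generator does **not** emulate: radiative-transfer physics,
sensor noise signatures, spatial structure, class imbalance, and
nonlinear target links. Passing recovery tests therefore demonstrates
that the optimizer finds planted informative bands under the
quasi-continuity premise, not that it ranks bands correctly on any
particular real sensor's data.

## Problem sizes used in the test suite

The package's property tests run at deliberately modest sizes chosen to
exercise each claim: parameter recovery uses $N = 2000$, $L = 200$,
$t = 3$ over ten seeds with full 500-epoch training; the near-optimality
check uses $L = 10$, $t = 2$ ($\binom{10}{2} = 45$ subsets, exhaustively
enumerable); metric fuzzing uses 1000 random confusion matrices. These
sizes make the whole suite run in minutes on a single CPU while keeping
every training run at the full default epoch count.

## Numerical notes and limitations

* Normalized indices live strictly inside $(0,1)$ (sigmoid image), so
  the boundary bands 1 and $L$ are reachable only in the limit; in
  practice rounding makes them reachable from $r < 0.5/(L-1)$ upward.
  Training asserts interiority after every update.
* Grid-point evaluation is exact up to a few ulps of drift in
  $q(L-1)$; tests allow $10^{-9}$.
* The search is local: indices converge to optima near their linearly
  spaced starting positions, a sensitivity inherited from the
  gradient-based formulation. Multiple seeds (restarts) are the
  practical mitigation; the CLI accepts a seed for exactly this reason.
* Duplicate convergence (t' < t) is legitimate output, not an error;
  consumers should read `tPrime()` rather than assuming `targetSize`
  bands.
* Gapped spectra violate the adjacency premise; see
  `missingBandScenario()`.
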