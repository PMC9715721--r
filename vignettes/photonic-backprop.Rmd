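---
title: "Stochastic photonic backpropagation: model, update rules, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic photonic backpropagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

photonbp implements a family of biologically motivated learning rules for a
three-layer logistic network, in which the backward teaching signal is
imagined to be carried by ultraweak photons: only a random fraction of
synapses receives an update on any trial, each update may be quantised to a
single bit (a fixed step up or down), and a fraction of synapses may receive
uncorrelated random one-bit kicks. This vignette is the package's own
account of the model, its parameters, the numerical and design choices made
where the printed equations leave gaps, and — importantly — what the test
suite does and does not establish about these rules.

## The network

The network is input → hidden → output with logistic units
$\sigma(x) = 1/(1+e^{-x})$ in the hidden and output layers:

$$a^h = \sigma(W^{hi}\,[x; 1]), \qquad a^o = \sigma(W^{oh}\, a^h).$$

The hidden layer has a bias, stored as the final column of $W^{hi}$ acting
on a constant input of 1, so it is trained and masked exactly like any other
hidden-layer weight; the output layer has no bias. Layer sizes are
unrestricted (`init_network(n_input, n_hidden, n_output)`); weights start
uniform on $(-r, r)$ with $r = \sqrt{6/(\text{fan}_{in}+\text{fan}_{out})}$,
which keeps logistic units out of saturation initially.

## Teaching signals and the gradient convention

The error signals are the standard logistic-output deltas:

$$\delta^o = a^o - y, \qquad
  \delta^h_k = \Big(\sum_l \delta^o_l\, W^{oh}_{lk}\Big)\, a^h_k (1 - a^h_k),$$

and the per-trial weight increments are the outer products
$\delta^o (a^h)^\top$ and $\delta^h ([x;1])^\top$.

One point deserves care. These deltas are often presented as the gradient of
the squared error $\tfrac12\lVert a^o - y\rVert^2$, but they are not: the
true squared-error gradient carries an extra output-slope factor
$a^o(1-a^o)$ at the output layer. The pair above is instead the *exact*
gradient of the Bernoulli cross-entropy
$-\sum_l [\, y_l \log a^o_l + (1-y_l)\log(1-a^o_l)\,]$, for which the output
slope cancels — precisely the equations as printed, including the hidden
layer's slope factor. The package therefore ships both losses:
`squared_error_loss()` as the conventional reporting metric and
`cross_entropy_loss()` as the objective the updates actually descend. The
gradient oracle in the tests (central finite differences, relative tolerance
$10^{-5}$) checks against the cross-entropy, and a second test pins the
documented relationship $\nabla_{SE} = \nabla_{CE} \cdot a^o(1-a^o)$ on
single-output networks. Note that the one-bit rules below are unaffected by
the choice of convention: the omitted factor is strictly positive, so every
sign is identical either way.

## The four update modes

All modes are online: one example, one update. With learning rate
$\varepsilon$ and masking proportion $q$:

* **full** — classic online backpropagation; every weight moves by
  $-\varepsilon g$.
* **stochastic** — per trial, a fresh uniformly random subset of
  $\mathrm{round}(q\,n)$ weights per layer (independently for the two
  layers, bias column included) receives the gradient update; the rest are
  untouched. $q = 1$ reproduces **full** bit-for-bit, which the suite checks
  over a 1000-trial run. The masked update is unbiased: its per-weight mean
  is $q$ times the full update, checked by Monte-Carlo at 10,000 draws.
* **binary** — the masked weights move by exactly
  $-\varepsilon\,\mathrm{Sgn}(g)$ with the three-valued sign
  ($\mathrm{Sgn}(0)=0$); each backward "photon" carries one bit.
* **binary_noisy** — the binary update is applied first; then an
  independently drawn subset of $\mathrm{round}(n_p\,n)$ weights per layer
  receives $-\varepsilon\eta$ with $\eta$ uniform on $\{-1,+1\}$,
  independent across weights and trials. Weights selected by both draws
  receive both increments (the composition is additive; the equations do not
  say, and addition is the natural reading of "first updated ... then").

Parameters and defaults:

| parameter | meaning | range | typical |
|---|---|---|---|
| `learning_rate` ($\varepsilon$) | step size per update | $\ge 0$ | 0.01–0.1 |
| `q` | fraction of weights updated per trial | $[0,1]$ | 0.01–1 |
| `noise_p` ($n_p$) | fraction of weights receiving a noise kick | $[0,1]$ | $\le q$ |
| `seed` | run RNG seed | integer | — |

Randomness contract: one seeded stream per run. `train_online()` draws the
whole example order first (a fresh shuffle per epoch), then per trial the
signal mask and, in `binary_noisy`, the noise draw, in that fixed order.
Degenerate mask sizes 0 and $n$ do not consume the stream, so a $q=1$
stochastic run stays aligned with a full run and `noise_p = 0` reduces
`binary_noisy` to `binary` exactly. Sweeps derive repetition seeds as
`master_seed + 1000003*(cell-1) + 97*(rep-1)` (mod $2^{31}-1$), so every
number in a sweep is reproducible from the master seed.

## Training protocol

`trial_error()` is 0 when the output and one-hot target agree on their
argmax, 1 otherwise. (The printed per-trial error formula, taken literally,
returns 1 on a perfect match; the surrounding prose is unambiguous that it
indicates a mismatch, so the prose wins. Exact real-valued equality of a
logistic output with a 0/1 target cannot occur, hence the argmax reading.)
The convergence diagnostic is the moving average of the last 100 trial
errors (fewer while fewer exist); validation error is recorded every 500
trials by default; test error is the misclassification rate on held-out
data, computed without weight updates.

## Synthetic data

Two generators make the whole system testable with no downloads; both are
fully determined by their spec (kind, sizes, noise, seed).

* **Gaussian blobs** — class centers drawn uniformly on the unit sphere in
  `n_features` dimensions; points are center plus isotropic
  $\mathcal N(0, \sigma^2)$ noise, mapped to $[0,1]$ by the fixed affine map
  $(x+1)/2$ with clipping. The map is data-independent and preserves
  separation measured in noise standard deviations; `center_sep_sigmas`
  re-derives $\sigma$ from the minimum pairwise center distance so "centers
  $4\sigma$ apart" is a statable world. At $4\sigma$ the task has an
  irreducible error floor of roughly $\Phi(-2) \approx 2.3\%$ per adjacent
  class pair — it is a sanity task, not a trivially separable one.
* **Digit glyphs** — fixed 8×8 bitmaps of the digits 0–9 (repository-owned
  constants, resampled for other sizes), shifted by a uniform random ±1
  pixel in each direction, plus per-pixel Gaussian noise, clipped to
  $[0,1]$, flattened row-major. This emulates the *structure* of a
  handwritten-digit task (10 classes, overlapping pixel patterns, nuisance
  translation) at desk scale. It does not emulate stroke variability,
  class imbalance, or 28×28 resolution; a green learning test here says the
  rule can learn a small noisy image classification task, not that it
  reproduces any particular published error figure. Because strokes are thin,
  a 1-pixel shift nearly de-correlates an image from its unshifted template;
  the independent nearest-neighbour oracle in the tests therefore matches
  against all nine 1-pixel shifts of each template.

An IDX reader/writer (`read_idx()`, `write_idx()`, `load_digit_dataset()`)
handles the big-endian ubyte container used by the classic digit benchmarks,
so user-supplied full-scale data drops in via
`photonbp train --data idx:<images>,<labels>`.

## Numerical choices

* `logistic()` is computed branch-wise, so no overflow for any double input.
* `forward()` clamps activations into $[10^{-12}, 1-10^{-12}]$: the backward
  slope $a(1-a)$ must never see an exact 0/1 produced by double-precision
  saturation. (We verified that *allowing* saturation — where
  $\mathrm{Sgn}(\delta) = \mathrm{Sgn}(0) = 0$ could in principle freeze
  drifting weights — does not change any conclusion below.)
* Mask sizes round half away from zero and are clamped to $[0, n]$.
* Ties in argmax are broken by the first maximum, identically in training
  and evaluation.
* `learning_rate = 0` is permitted: a frozen run is the cheapest way to test
  that the loop itself changes nothing it should not.

## What the tests establish — and a candid negative result

The suite verifies the contracts above exactly (gradient oracle, $q=1$
degeneracy, masking unbiasedness, the one-bit step set
$\{-\varepsilon, 0, +\varepsilon\}$, determinism, serialization round-trips)
and demonstrates learning for the full and stochastic modes: full
backpropagation drives both synthetic tasks to their error floor, and
stochastic masking learns at $q$ as small as 0.01 ($\approx 40$ of 4160
weights per trial) given a correspondingly larger step size.

The one-bit rule is different, and the package does not paper over it. With
logistic outputs every activation is positive, so
$\mathrm{Sgn}(\delta^o_l a^h_k) = \mathrm{Sgn}(\delta^o_l)$: the sign update
of an output weight depends only on whether its row is the target row. For
$C$ balanced classes each output weight then receives an expected increment
of $-\varepsilon q\,(C-2)/C$ per trial — for $C = 10$ an unbounded downward
drift that saturates the output layer, carries no per-synapse information,
and (once the rows are near-uniform) also erases the per-unit structure of
the hidden teaching signal $\sum_l \delta^o_l W^{oh}_{lk}$. Consequently the
one-bit mode does not learn the 10-class glyph task at any setting we
tried, and the corresponding acceptance checks are deliberately left
failing rather than weakened. At $C = 2$ the drift term vanishes and the
rule does learn — but the output layer still performs an undirected
$\pm\varepsilon$ random walk, so converged runs are metastable: they can
reach zero error and later diffuse back toward chance. The noise-robustness
experiment is therefore run on the 2-class task, where a working baseline
makes the comparison meaningful; its monotonicity holds within sampling
error, while sustained convergence is exactly as fragile as the analysis
predicts.

## Known limitations

* Pure R, single-threaded: fine for desk-scale experiments (tens of
  thousands of trials on networks with a few thousand weights run in
  seconds); a 784-500-10 run over $6\times 10^4$ trials takes minutes.
* No mini-batching, momentum, schedules, regularization, softmax, or deeper
  architectures — deliberately out of scope.
* The glyph generator is a structural stand-in, not a substitute for real
  handwritten digits; conclusions about absolute error levels do not
  transfer.
* The one-bit analysis above means results obtained with `binary` /
  `binary_noisy` on tasks with more than two balanced classes should be
  interpreted as properties of the printed rule, not as a bug in need of
  fixing here.
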