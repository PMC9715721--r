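# photonbp

Training neural networks when the backward channel is made of photons:
**photonbp** implements a three-layer logistic network trained online with a
family of biologically motivated, degraded variants of backpropagation in
which the teaching signal is imagined to be carried by ultraweak (bio)photon
emission. It is aimed at computational-neuroscience users who want a small,
fully deterministic, dependency-light testbed for stochastic and one-bit
learning rules.

## The model

Forward pass (logistic units, hidden bias folded into the weight matrix, no
output bias):

    a_h = sigma(W_hi [x; 1]),    a_o = sigma(W_oh a_h),    sigma(x) = 1/(1+exp(-x))

Teaching signals (the standard logistic-output deltas):

    delta_o = a_o - y
    delta_h[k] = (sum_l delta_o[l] W_oh[l,k]) * a_h[k](1 - a_h[k])

Four online update modes, with learning rate `eps`, masking proportion `q`
and noise proportion `n_p`:

| mode | per-trial update |
|---|---|
| `full` | every weight: `w <- w - eps * g` (classic online backprop) |
| `stochastic` | a fresh random `round(q*n)` subset per layer gets the gradient update; `q = 1` is bit-identical to `full` |
| `binary` | masked weights move by exactly `-eps * Sgn(g)`, `Sgn(0) = 0` — one bit per weight |
| `binary_noisy` | `binary`, then an independent `round(n_p*n)` subset gets `-eps * eta`, `eta` uniform on `{-1,+1}` |

Per-trial classification error is argmax agreement with the one-hot target;
the convergence diagnostic is the 100-trial moving average; validation is
evaluated every 500 trials. Everything — initialisation, data order, masks,
noise — derives from one seeded RNG stream per run, so every number is
reproducible.

Data: seeded synthetic generators (Gaussian class blobs; noisy shifted 8x8
digit glyphs) make all tests self-contained, and an IDX (idx3-ubyte /
idx1-ubyte) reader accepts user-supplied full-scale digit data.

See `vignettes/photonic-backprop.Rmd` for the full methods account —
including the gradient convention (the printed deltas are the exact gradient
of the Bernoulli cross-entropy, not of the squared error) and a candid
analysis of when the one-bit rule can and cannot learn.

## Worked example

```r
library(photonbp)

spec <- synthetic_task_spec("glyphs", n_classes = 10, n_examples = 4000,
                            glyph_size = 8, noise_sd = 0.1, seed = 42)
task <- make_task(generate_dataset(spec), n_validation = 400, n_test = 400,
                  seed = 42)

set.seed(42)
net0   <- init_network(n_input = 64, n_hidden = 64, n_output = 10)
config <- update_config("stochastic", learning_rate = 0.1, q = 0.1)
sched  <- training_schedule(n_trials = 10000, validation_every = 500)

fit <- train_online(net0, task$train, config, sched,
                    val_data = task$validation)
print(fit$log)
cat(sprintf("final moving-average training error: %.3f\n",
            final_error_rate(fit$log)))
cat(sprintf("held-out test error: %.3f\n",
            evaluate_misclassification(fit$params, task$test)))
```

Output:

```
<training_log: 10000 trials, final error rate 0.100, 20 validation points>
final moving-average training error: 0.100
held-out test error: 0.098
```

Reading: with only 10% of weights updated per trial (q = 0.1), the masked
gradient rule drives the 10-class glyph task from chance (0.9) to a 10%
error rate within 10,000 trials; training and held-out error agree, so the
network is learning the task rather than memorising the stream.

## Command line

```sh
inst/scripts/photonbp train --mode binary --q 0.1 --epsilon 0.1 \
    --hidden 64 --trials 20000 --seed 1 --data glyphs --out run1
inst/scripts/photonbp sweep --config sweep.json --out sweep1
inst/scripts/photonbp gen-data --data blobs --n 1000 --out blobs.csv
inst/scripts/photonbp eval --network run1/network.json --data glyphs --seed 1
```

`--data idx:<images>,<labels>` trains on user-supplied IDX digit files
(e.g. the classic 784-500-10 configuration at `--q 0.1 --epsilon 0.01
--trials 60000`); nothing is downloaded by the package.

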