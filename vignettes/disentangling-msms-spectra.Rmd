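---
title: "Disentangling tandem mass spectra with variational autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling tandem mass spectra with variational autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`msvae` learns low-dimensional latent representations of tandem (MS/MS) mass
spectra with variational autoencoders and audits them against known factors
of generation — collision energy, instrument type, compound mass, ionization
mode and the like. This vignette is the package's account of the model, its
conventions and tunable parameters, what the synthetic-data generator does
and does not emulate, and the design choices made where the design was
genuinely open.

## The spectrum representation

An MS/MS spectrum is a list of peaks on the continuous m/z axis. Binning the
axis discards mass resolution, so the package instead uses a sparse vector of
interleaved (m/z, intensity) pairs. The pipeline, in order:

1. reject peaks whose relative intensity (percent of the base peak) is below
   `min_intensity`;
2. reject peaks above `max_mz`;
3. keep the `max_num_peaks` = *N* most intense peaks (ties broken by lower
   m/z, for determinism — the ordering of equal-intensity peaks is otherwise
   arbitrary);
4. rescale intensities into `[min_intensity, 100]` (dynamic range
   expansion); a single-peak spectrum is not rescaled, and a degenerate
   all-equal spectrum maps to 100. With `rescale_intensity = FALSE` the base
   peak is simply normalized to 100, and the `min_intensity` threshold is
   applied on that base-peak-normalized scale;
5. interleave (m/z / `mz_reference`, intensity / 100) pairs in descending
   intensity order and pad with (0, 0) pairs to length 2*N*.

Two conventions are worth calling out because nothing forces them:

* **m/z is scaled by a fixed `mz_reference`** (default `max_mz`), not by a
  per-spectrum or per-dataset maximum. A fixed denominator makes decoding
  well defined and stable across datasets.
* **Padding is the pair (0, 0).** A true peak cannot have scaled m/z of 0
  (m/z is strictly positive), so padding is unambiguous, and `devectorize()`
  treats any pair with zero m/z or sub-threshold intensity as padding. This
  is also how decoder outputs are re-interpreted as spectra: hallucinated
  sub-threshold pairs are dropped rather than displayed.

Defaults (`max_num_peaks = 50`, `min_intensity = 0.1`, `max_mz = 2500`,
`rescale_intensity = TRUE`) mirror the most common operating point for
library-scale data; the tests and examples in this package use smaller *N*
(10–20) because synthetic spectra are narrower.

## Models and objectives

Encoders and decoders are stacks of fully connected layers, each followed by
batch normalization and a ReLU, with two exceptions: the encoder output layer
is purely affine (it parameterizes the posterior mean and log-variance), and
the decoder output layer is affine + sigmoid with no normalization, so every
reconstructed cell lies in (0, 1). Predictor heads use the same hidden-block
recipe with an affine output. A zero-hidden-layer model degenerates to a
single affine map.

The BetaVAE loss is

$$\mathcal{L} = \lVert x - \hat{x} \rVert^2 \;+\; \beta \,
\mathrm{KL}\!\left(q(z \mid x)\,\Vert\, \mathcal{N}(0, I)\right),$$

with the reconstruction term the **per-sample sum of squared cell errors,
averaged over the batch**, and the KL term in closed form for the
diagonal-Gaussian posterior, summed over latent dimensions and averaged over
the batch. The summed reconstruction convention is deliberate: it makes
`beta = 1` exactly the negative evidence lower bound under a unit-variance
Gaussian likelihood, and it keeps the effective KL weight independent of the
vector length 2*N*. (With a per-cell *mean* instead, the same `beta` would be
2*N* times stronger; at the `beta` values explored here, 0.01–2, that regime
collapses the posterior onto the prior and the model degenerates to
reproducing the dataset mean — detectable with the baseline metric below.)

JointVAE adds categorical latent blocks. Discrete codes are sampled with the
Gumbel-softmax relaxation (temperature default 0.67) during training and
one-hot argmax at evaluation; each block's KL is measured against the uniform
categorical prior. Both KL channels are driven toward capacity targets that
ramp linearly from 0 to `cont_max_capacity` / `disc_max_capacity` over
`capacity_steps` training steps:

$$\mathcal{L} = \lVert x - \hat{x}\rVert^2
 + \gamma_c \left| \mathrm{KL}_c - C_c(t) \right|
 + \gamma_d \left| \mathrm{KL}_d - C_d(t) \right|.$$

Training uses Adam at `learning_rate` (default 1e-3; the examples here use
3e-3, which converges in the small epoch budgets used throughout) with an
optional weighted random sampler that draws each example with probability
proportional to its inverse class frequency, so batches hold a similar number
of instances of each class even at 9:1 imbalance. All randomness —
initialization, sampler order, reparameterization noise, Gumbel draws — flows
from the single seed in `train_config()`, so histories are bit-reproducible.
Gradients are hand-derived (including the batch-norm and Gumbel-softmax
paths) and pinned by a finite-difference test at tolerance 1e-4.

Joint training of a factor predictor adds the head objective (cross-entropy
or squared error) to the VAE loss; the head consumes the posterior mean
concatenated with the remaining (non-target) factor columns, and its
gradient flows into the encoder through the mean path. Predictor inputs are
z-scored on the training split: factor columns live on instrument scales
(hundreds of Da) that would otherwise swamp binary codes.

## Reconstruction evaluation

Four per-pair metrics are available: cosine similarity, Euclidean distance,
mean per-cell relative change, and mean per-cell symmetric percentage
difference (the latter two stabilized with ε = 1e-8; the field uses these
names without fixed formulas, so the standard per-cell definitions are
adopted). A zero-norm vector has cosine similarity 0 by convention, so
padding-only vectors never crash evaluation.

The *average-reconstruction baseline* scores every sample against the
element-wise mean sample. It is not a model metric: it is the floor any
useful autoencoder must beat, because a model that has collapsed to decoding
the dataset mean scores exactly at it.

The *ranked similarity score* compares a reconstruction against a database,
sorts by the chosen metric (descending for cosine, ascending for distances,
ties broken by database order) and reports the 0-based position of the true
spectrum, summarized by mean, SD, minimum and quartiles. Ranks are 0-based so
a perfect self-match reports 0.

## Disentanglement metrics

Three supervised scores are implemented, each in [0, 1]:

* **BetaVAE metric** — repeatedly fix one factor, draw a batch of sample
  pairs agreeing on it, average the absolute latent differences, and train a
  multinomial linear classifier to predict which factor was fixed; the score
  is held-out accuracy (protocol defaults: 500 points, pair batch 64, 80/20
  split).
* **FactorVAE metric** — normalize each latent dimension by its empirical SD
  over a reference sample, prune dimensions whose SD falls below
  `collapse_threshold` (default 0.05) times the median (a collapsed
  dimension would otherwise always win), then per vote fix a factor and let
  the dimension with the smallest batch variance vote for it; the score is
  the accuracy of the per-dimension majority-vote table.
* **MIG** — discretize each latent dimension into 20 equal-width bins
  (an estimation detail the metric's definition leaves open), compute
  empirical mutual information with each factor, and average the
  entropy-normalized gap between the top two dimensions per factor.

These metrics answer "is there *a* disentangled structure", not "*which*
latent encodes *which* factor". That question is the job of the two-step
analysis.

## The two-step correlation analysis

Step 1 operates on narrow partitions: the dataset is first restricted to
analysis ranges per factor (continuous factors to `[low, high)`, categorical
factors to an allowed label set), then grouped so that within a partition
exactly one factor varies while every other factor is pinned to a single bin
(continuous bins are half-open `[low, low + step)` with step default 5) or
label. Within each partition of at least `min_size` (default 10) members,
the Pearson correlation between the varying factor and every latent
coordinate is computed. Pinning the other factors controls for their
influence on the correlation.

Step 2 aggregates the partition-level coefficients into distributions per
factor × latent pair. A factor correlates with a latent variable *better on
average* when the distribution mean is further from 0, and *consistently*
when its SD is small — both are reported, and a mean near 0 with a large SD
(sign cancellation across partitions) is surfaced rather than hidden.
Undefined cells (zero-variance partitions) are excluded from the summaries,
not zero-imputed; they are treated as 0 only inside the assignment step so
the assignment stays total.

Factors are assigned to latent variables greedily on the **absolute** mean
coefficient, removing each matched row and column (ties broken by lower
latent index, then factor name order). Absolute-value matching is the
convention consistent with negative coefficients winning a column in the
worked examples shipped in the tests. The assignment is `distinct` when it
is injective *and* each factor's matched |mean r| strictly exceeds its
runner-up across the other latent variables — the operational form of "each
factor correlates with exactly one latent variable". Correlations use
posterior means, never samples, so the analysis is deterministic given a
trained model.

An ordinary least-squares utility regresses disentanglement scores on
one-hot-expanded hyperparameter subsets (optionally with full interactions)
and reports R² per subset, for asking how much of a score's variance
hyperparameters explain.

## The synthetic-data generator

The generator exists so that every stage — including disentanglement
recovery — is testable without downloading spectral libraries. Each compound
template has an exact mass (uniform over `mass_range`), 10–40 fragment
channels at random fractions of the exact mass, and gamma-distributed
channel propensities. Factor effects are applied in separable steps, so the
factors are independent by construction (the assumption disentanglement
machinery makes of true generative factors):

* **Collision energy**: channel weights are a softmax of log-propensities
  shifted by `-energy_slope · CE · (fragment mass / exact mass)`, and the
  number of open channels grows with CE — so low energy yields a few
  higher-mass peaks and high energy more, lower-mass peaks. Setting
  `energy_slope = 0` switches the mass response off (the null used in
  tests).
* **Instrument type**: a fixed multiplicative gain signature over a 25-Da
  grid, drawn once per instrument from a log-normal with SD
  `instrument_distortion_sd` — a learnable, clusterable stand-in for
  analyzer/detector differences.
* **Ionization mode**: all m/z shift by ±1.00728 Da (the proton-adduct
  convention) and the precursor m/z moves to mass ± proton; total intensity
  is unaffected, so a factor-blind summary cannot see the mode.
* **Noise**: multiplicative log-normal intensity noise with SD `noise_sd`
  (default 0.1).

Two designs are provided. `hmdb_like` is perfectly balanced: exactly 6
spectra per compound, two ionization modes crossed with collision energies
{10, 20, 40}, a single instrument type. `mona_like` is unbalanced:
`spectra_per_compound` random factor combinations per compound, instruments
drawn with configurable imbalance weights, collision energies drawn from the
configured levels (the analyses here use 10–50 in steps of 10 so the
partition binning at step 5 is exercised). Everything is a deterministic
function of the configuration seed.

What the generator does **not** emulate: real fragmentation chemistry
(bond-breaking rules, neutral losses), isotope patterns, adduct diversity
beyond the proton pair, retention time, and the heavy-tailed peak-count
distributions of real libraries. Passing tests on synthetic data therefore
demonstrate that the machinery recovers structure that is present by
construction; they do not demonstrate that real MS/MS libraries are
disentanglable at any particular fidelity.

## Numerical choices and degenerate inputs

* Collision-energy strings with units or ranges ("35%", "20–40 eV") are kept
  verbatim in `collision_energy_raw` alongside a best-effort numeric parse
  (first numeric token); no silent unit conversion is attempted.
* Missing numeric factors stay `NA`, are counted, and are dropped row-wise
  only by analyses that need them — never imputed.
* Categorical codes default to first-appearance order but accept explicit
  code maps, because Pearson correlation on label codes depends on the
  coding and published code maps must be reproducible.
* Zero-norm cosine is 0; zero-variance correlation cells are flagged
  undefined; a factor with zero entropy is excluded from MIG with a flag;
  all-collapsed representations raise an error rather than voting.
* Slerp falls back to linear interpolation below an angle of 1e-6 and
  refuses zero vectors. Traversal ranges default to ±3 in latent units
  (roughly ±3 posterior SDs under the standard-normal prior) and are
  configurable.
* PCA projections fix signs by making the largest-magnitude loading of each
  component positive, so projections are deterministic.
* Batch normalization uses biased batch variance in training and running
  statistics at evaluation; the posterior-mean path through a trained model
  is therefore deterministic.

## Problem sizes

The test suite and the acceptance script run at desk scale by choice: 1000
random spectra for the preprocessing oracle, 200 synthetic compounds (1200
spectra, 40-cell vectors) for the end-to-end run with 5 seeds and 20 epochs,
40 compounds for the 15-model beta-trend sweep, and 300–500 protocol points
for the metric sanity checks. These sizes keep every property crisp (the
stochastic criteria are trend-level, with seeds fixed) while completing in
minutes on one CPU.

## Known limitations

* The encoder/decoder family is deliberately small and fully connected; no
  convolutional or attention architectures are provided.
* The two-step analysis requires knowing candidate factors and their
  reasonable ranges; it audits a hypothesis, it does not discover factors.
* Pearson correlation on integer-coded categorical factors is kept for
  fidelity with how such audits are practiced, with a rank-correlation mode
  available as a robustness check (`cross_correlate_factors(method =
  "spearman")`); codings should be chosen deliberately.
* JointVAE capacity targets and gammas interact strongly; the defaults are
  starting points, not tuned recommendations.
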