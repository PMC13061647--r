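---
title: "Dual-manifold closed-loop evolution: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-manifold closed-loop evolution: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic world does and does not emulate, and the choices we made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The experimental logic

One closed-loop *evolution* treats a neuron's firing rate as a black-box
objective over a generator's latent space: a population of latent vectors
is rendered to images, each image is presented and scored by the evoked
rate, and a rank-based evolutionary optimizer (CMA-ES) proposes the next
population. A *paired* session runs two such threads against the same
neuron — one in a flexible texture-like space, one in a constrained
object-centric space — with the two threads' images and a fixed set of
reference images randomly interleaved within every block, so recording
state affects both threads equally. Alignment between the neuron's tuning
and each parametrization is then read out three ways: whether the climb
succeeds at all, where it starts and ends, and how fast it converges.

Everything downstream (PSTH dynamics, tuning landscapes along
pullback-metric eigen-axes, spatial attribution) consumes the session
record produced by this loop.

## 2. The synthetic world

The package ships no recorded data and no pretrained networks; both
generators and the neuron are explicit synthetic stand-ins chosen so that
every analysis has a closed-form or brute-force oracle.

**Texture generator** (`make_texture_generator`): a strictly linear map
over a seeded dictionary of localized, oriented band-pass (Gabor-like)
elements with random RGB color directions, plus a mid-gray offset, clipped
to `[0, 1]` after synthesis. Element centers are stratified over the image
so local patterns can be placed anywhere. Defaults: 64 x 64 x 3 images,
256 elements (tests often use 16–128 for speed; the contrast with the
object space needs only `latent_dim` asymmetry). The pre-clipping map is
exactly linear (`gen$render_preclip`), which gives analytic oracles for
the pullback Hessian and the line search.

**Object generator** (`make_object_generator`): a smooth parametric scene
— background gradient plus one superellipse blob with two internal parts —
whose latent splits into a `class` sub-block (shape exponent, aspect, hue,
part layout, saturation; via a fixed seeded linear map followed by `tanh`
squashing) and a `noise` sub-block (position, scale, rotation). Zero noise
centers the object. The latent-to-parameter map is exposed
(`gen$param_map`) so identity/pose factorization and morphing are testable
against the analytic map. Defaults: 16 + 16 dimensions.

What this world emulates: the flexibility-versus-prior contrast (a linear
dictionary can match arbitrary local patterns; the blob scene can only
move within its parametric family), the class/noise partition, and
deterministic continuous rendering. What it does not: photorealism,
learned image statistics, perceptual metrics, or the sheer dimensionality
of real GAN latent spaces. A green test therefore certifies the analysis
machinery, not any biological claim.

**Neuron model** (`neuron_model`): Gaussian tuning in the RMS-pixel
distance between the image patch at the neuron's locus and a preferred
template, with separate early and late temporal kernels (Gaussian bumps,
zero before stimulus onset). Each kernel may carry its own template *and
its own tuning width*, emulating coarse-to-fine response dynamics and
late-emerging preferences. The combined kernel is normalized at
construction so a fully preferred image peaks exactly at `peak_rate`.
Spiking is inhomogeneous Poisson at 1 ms resolution over `[-50, 400)` ms
(onset at 0, half-open intervals throughout), deterministic given a seed.
The recorded system gives no generative model of responses; all of this
structure is the package's stand-in.

## 3. The optimizer

`cma_init`/`cma_ask`/`cma_tell` implement standard rank-mu CMA-ES
(weighted recombination, cumulative step-size adaptation, rank-one plus
rank-mu covariance update), maximizing scores. Because the update is
rank-based it is invariant to affine positive transformations of the
scores — the property that makes firing rates in arbitrary units a valid
objective. Candidates with non-finite scores (failed renders) are excluded
from recombination and counted. `project_to_subspace` restricts the search
to an orthonormal basis (Gram deviation tolerance `1e-8`), expanding
candidates before rendering; with the identity basis it reproduces the
unrestricted run bit-for-bit. The test suite cross-checks trajectories
against an independently transcribed reference implementation under a
shared sampling convention.

Initial step sizes are per-space: 3.0 for the texture space and 0.09 for
the object space (both exposed in `evolution_config`). The per-space step
calibration *is* the central methodological manipulation this pipeline
inherits; treating them as configuration rather than constants keeps that
explicit.

## 4. Session parameters

| parameter | default | units | why |
|---|---|---|---|
| `blocks` | 40 | generations | typical session length; 4–60 accepted (the success test needs 4) |
| `popsize` | 30 | images/thread/block | middle of the 25–40 range used in vivo |
| `trials_per_image` | 1 | presentations | rapid serial presentation shows each image once |
| `n_ref` | 10 | images | fixed references, drawn 5 + 5 from the two priors once per session |
| `window` | `[50, 200)` | ms | scoring window for the mean firing rate |
| `sigma_texture` / `sigma_object` | 3.0 / 0.09 | latent units | per-space step calibration |
| `stim_ms` / `isi_ms` | 100 / 150 | ms | presentation timing; metadata only, trials are simulated independently |

One master seed per session derives a private stream per component
(`derive_seed`), so equal seeds give byte-identical sessions while any
component can be re-run in isolation.

## 5. Alignment metrics: choices made

**Success test.** "Activity in two consecutive blocks exceeds the first
two blocks" leaves the candidate pairs open; we use pairs `(b, b+1)` for
`b >= 3` (disjoint from the baseline), select the pair with the highest
pooled mean, and run a two-sided Welch t-test with an explicit direction
check. The max-over-pairs selection inflates the null rate above the
nominal level; the suite calibrates the implementation against an
independently coded brute-force oracle rather than against the nominal
alpha.

**Convergence time.** Two published phrasings coexist ("80% of the
session-wise maximum" vs "80% of the maximum activation increase"); both
are implemented, and the *increase* form is the default because it is
invariant to affine rescaling of the scores. The trajectory is smoothed by
Gaussian-process regression (squared-exponential kernel plus white noise,
hyperparameters by marginal-likelihood maximization via Nelder–Mead, a
small jitter on the diagonal) with a centered moving-average fallback when
the optimization or factorization degenerates; `smoother = "none"` exposes
the raw rule for oracle comparisons.

**First-generation comparisons.** The z-score baseline is unspecified in
the source material; `session_zscore` standardizes over *all* image
responses in the session (both threads plus references) and records the
constants on the object.

**Confidence intervals.** The published interval method is unspecified;
the package reports Wilson intervals for binomial fractions and
Jeffreys-style beta intervals for the shape fractions, and labels them as
such.

## 6. PSTHs and temporal analyses

PSTHs discretize spike times into 1 ms bins and convolve with a Gaussian
density (sigma = 2 ms) that is truncated and *renormalized per source bin*
at the window edges, so each spike contributes exactly unit mass — the
conservation invariant the tests assert. Temporal attribution fixes the
best block by the `[50, 200)` ms mean and normalizes the difference PSTH
by its summed 0–200 ms difference; a zero denominator is flagged rather
than propagated. Time-binned trajectories normalize by the session maximum
over threads, blocks and bins inside `(50, 200)` ms; paired t-tests across
sessions are Benjamini–Hochberg corrected across blocks within each time
bin at FDR 0.05. PSTH distances integrate over time in seconds after
normalization by the neuron's maximum block-average rate
(`session_max_rate`), and satisfy `d_psth >= |d_act|` with equality iff
the difference never changes sign.

## 7. Tuning landscapes

**Metric choices.** The pullback Hessian uses the summed squared pixel
distance, for which a linear generator gives `H = 2 A'A` exactly; the line
search uses the Euclidean (root-sum-square) pixel distance, which is
monotone in the step size and gives the closed form
`alpha = d / ||A v||`. A single metric cannot satisfy both closed forms
(the Hessian of a non-squared norm is singular at zero), hence the split;
any metric obeying the contract (symmetric, zero at identity) can be
plugged into either, including the package's perceptual patch metric.
Note the scale this implies: a pixel-L2 distance of 0.40 over a 64 x 64 x 3
image is an RMS change of only 0.0036, so neurons probed along these axes
must have tuning widths at that scale to show structure — the probe
neurons in the tests and README do.

**Finite differences.** The Hessian uses central differences with step
`h` (recommended `0.01 x` the space's initial sigma); a Richardson
step-halving check on up to ten random diagonal entries warns when `h` is
too coarse. Non-finite entries raise an error naming the coordinate pair.

**Line search.** Bracket by doubling from the tolerance up to
`|alpha| <= 1e3`, then bisect to `|D - d_target| <= 1e-3`. A coarse
ten-point scan over the bracketed range must be monotone within 5% of the
running maximum; genuine folds raise a diagnostic error and the affected
axis is dropped (and logged) by `build_axis_stimuli`.

**Classification rule.** The published analysis names three fits but not
how they combine. Operationalization: require a significant one-way ANOVA
(default `p < 0.01`) across the nine distance levels; then *bell* needs a
Gaussian fit with interior peak (`|mu| < 0.4`), Gaussian R-squared
exceeding the linear R-squared by at least 0.05, and a unimodal GP mean;
*ramp* needs a significant linear slope (`p < 0.05`) and a monotone GP
mean; anything else significant is *other*. Monotonicity and unimodality
are judged with a slack of 2% of the GP curve's range so smoothing ripple
at the noise floor cannot flip a call. Zero-variance responses short-
circuit to *nonsignificant* with fits skipped. The Gaussian fit itself is
a grid-plus-Nelder-Mead least-squares with the amplitude constrained
non-negative — robust at six trials per level where `nls` routinely fails.

**Axis selection.** The in-vivo procedure chose 10–20 axes "adaptively",
without specifying how; the package deterministically takes the top
eigenvalue axes per subspace (default 10).

## 8. Spatial attribution

The pretrained convolutional extractor is replaced by a fixed seeded bank
of oriented color filters applied to mean-centered local patches (default
16 px patches, stride 4, 16 channels, absolute-value rectification; a
64 px image gives the familiar 13 x 13 grid). Any object with the same
contract can be plugged in. Per-location ordinary least squares with
intercept yields adjusted R-squared masks; with `n <= channels + 1` a
ridge fallback (penalty `1e-3 x` the mean diagonal of `X'X`) is used and
flagged. Weight vectors average over the largest 8-connected region
strictly above the 80th-percentile threshold, with row-major discovery
order breaking size ties deterministically.

Two identifiability caveats the simulations exposed, worth knowing before
interpreting encoding models on real data:

* *rectified features* — absolute-value channels all track local contrast
  energy, so the channel weights of a factorized readout are not
  identifiable from them; `feature_bank(rectify = "none")` provides signed
  features for encoding-model work;
* *stimulus ensemble rank* — patches of images from a `d`-dimensional
  generator vary in at most `d` directions, so readouts are identified
  only up to the stimulus subspace; the planted-readout recovery test uses
  white-noise stimuli, and the low-dimensional bundled generators are kept
  out of that loop deliberately.

`feature_exemplar` screens cells by response correlation (restricting the
spatial support — overlapping patches make an unrestricted spatial factor
unidentifiable), initializes a rank-1 factorized readout from the screened
correlation structure, refines it by alternating least squares, and then
maximizes the model's prediction over the generator latent with CMA-ES.
When the training latents are supplied, the returned exemplar is
guaranteed to predict at least as high as every training image.

The concentration score convolves a similarity heatmap with normalized
uniform filters (default sides 1, 2, 3, 5, 8 grid units — the published
range is unspecified beyond "a range of filter sizes") and averages the
per-size maxima; closed forms for uniform and delta maps are exact and
tested.

## 9. The parameter-recovery world

The acceptance suite includes a planted-peak recovery experiment: a neuron
Gaussian-tuned around a known texture-space latent `z*`, recovered to
within `0.1 ||z*||` by the paired evolution in at least 7 of 10 seeds.
Diagnosing this world fixed three choices, made once:

* at one presentation per image, the score is an integer spike count in a
  150 ms window (resolution 6.7 spikes/s); quantization alone floors the
  recoverable distance near 1.4 latent units and Poisson noise near 2–3,
  regardless of the planted norm. The recovery experiment therefore uses
  six presentations per image — the same repetition count the tuning
  measurements use — while the session default stays one;
* the driver is multi-unit-like (peak 250 spikes/s; single-unit drivers at
  ~100 spikes/s leave the noise floor above the criterion), with broad
  early tuning (width 0.09 RMS, visible from the search's starting
  distance) and sharp late tuning (0.02 RMS, supplying gradient near the
  peak) — the coarse-to-fine structure real dynamics motivate;
* 16 dictionary elements, planted norm 12 (= 4 x the initial step), and
  60 blocks, the long end of the session-length range.

## 10. Sessions, serialization, CLI

Sessions round-trip through plain text: JSON for configuration, generator
recipes and the neuron; CSV (17-significant-digit formatting, so doubles
survive exactly) for latents, scores, traces and spike trains; a manifest
with MD5 checksums over every file. Images are never stored — generators
are deterministic, so stimuli re-render exactly from stored latents; PNG
export exists for inspection. Loading verifies every checksum first and
names the offending file on mismatch or absence; missing schema fields
raise explicit errors. The CLI binds the stages together
(`evomanifold_cli`), validates its JSON config, and lists the registered
generator plugins when given an unknown name.

## 11. Known limitations

* The generators are caricatures: no learned statistics, no perceptual
  metric, latent dimensionalities orders of magnitude below the real
  models. Conclusions about *biological* alignment cannot be drawn from
  this package alone.
* The pixel metrics are not perceptual; distance-matched stimuli are
  matched in pixel space, and the `0.40 ... -0.40` targets inherit the
  pixel scale (see section 7).
* Single-trial scoring is noisy by construction; analyses that need
  precision (tuning curves, parameter recovery) must use repeated
  presentations, as their in-vivo counterparts did.
* The GP regression is a smoother, not an uncertainty model: only its
  posterior mean is consumed.
* Win rates and success tests assume independent sessions; the package
  does not model the site-resampling correlations present in chronic
  recordings.
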