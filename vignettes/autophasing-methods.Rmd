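---
title: "Automated phase correction of 1D NMR spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated phase correction of 1D NMR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A phase-sensitive 1D NMR spectrum is only fully quantitative in pure
absorption mode.  After Fourier transformation of the complex FID the
spectrum generally carries two phase errors: a frequency-independent
zeroth-order error (PH0) and a first-order error (PH1) that varies linearly
with frequency and stems from the effective delay between excitation and the
first sampled point.  `nmrphaser` corrects both automatically, in two tiers:
a classical entropy-minimization grid search that brings residual errors
below about 10 degrees, and a pair of neural sign-of-error classifiers that
drive the residuals to sub-degree level through an iterative correction loop.

## Conventions

All phase arithmetic follows three fixed conventions, chosen once and used
everywhere:

* **Axis direction.** Index 1 of a `spectrum1d` is the *left* (downfield,
  high-frequency) end of the displayed spectrum.
* **Phase ramp.** Applying a `phase_pair` (PH0, PH1) multiplies point $k$
  (0-based) by $\exp\!\big(i\,\tfrac{\pi}{180}(\mathrm{PH0} +
  \mathrm{PH1}\,k/(N-1))\big)$.  The denominator $N-1$ makes the endpoints
  exact: the left end receives exactly PH0 and the right end exactly
  PH0 + PH1, which matches the endpoint parametrization used by the score
  surfaces.  (A ramp of $k/N$ differs by a single grid step; the endpoint
  form is the one we standardize on.)
* **Sign.** Phase factors multiply as $e^{+i\varphi}$; *correcting* an error
  $\varphi$ therefore means applying $-\varphi$.  A single internal constant
  controls this choice, since the literature uses both conventions.

PH1 is quoted throughout as the *total* phase change across the spectrum, so
it is directly comparable between spectra of different lengths.  PH0 is
displayed wrapped to $(-180, 180]$; internally values are kept unwrapped so
composition of corrections is exact.

## FID processing

`process_fid()` implements the standard pipeline: exponential apodization
($e^{-\pi\,\mathrm{lb}\,t}$, default 0.3 Hz), halving of the first FID point
(suppressing the constant offset of a truncated FID), zero filling to a
power of two (FFT efficiency; also the natural lengths for the synthetic
training spectra), complex FFT with the output reordered to the axis
convention above, and digital-filter compensation.  The spectrometer's
digital filter delays the FID by the group delay $g$ (in dwell periods),
which appears as a linear phase ramp of roughly $360 g$ degrees across the
spectrum; `group_delay_correct()` applies the standard first-order
compensation of $-360 g$ degrees.  Any small residual constant phase is
absorbed by the subsequent PH0 correction, which is exactly the job of the
rest of the package.

## Synthetic training data

Real biofluid peak lists with ground-truth phases are not available at build
time, so the generator is first-class, seeded, and fully synthetic:

* `fixture_peaklists()` emulates dense metabolomics-like $^1$H spectra
  (synthetic stand-ins, labelled as such): $\geq 100$ peaks per list,
  organized into singlet/doublet/triplet clusters with small splittings,
  with at least 40% of peaks packed into a central region spanning 15% of
  the axis — mimicking the crowded carbohydrate region of urine or serum
  spectra — and peak heights spanning over two orders of magnitude.
* `synthesize_spectrum()` builds each spectrum in the time domain: each
  Voigt peak contributes a damped complex oscillation (exponential damping
  for the Lorentzian fraction, Gaussian damping for the Gaussian fraction),
  and one FFT produces matched absorption/dispersion parts.  This guarantees
  that a phase error distorts the lineshape exactly the way it does in
  measured data, which is the signal the classifiers must learn.
* `augment_peaklist()` diversifies each list: the axis is split into 8 equal
  segments whose contents are shuffled; a random fraction (uniform in
  [0, 0.3]) of peaks is removed; survivors are displaced by up to 2000
  points; widths are resampled in [3, 30] points (FWHH) and heights
  log-uniformly over two decades; the axis is mirrored with probability 0.5
  (solvent-relative asymmetry of real spectra); and each peak sprouts a
  partially overlapping shoulder with probability 0.15 (offset 0.2–0.8 FWHH,
  height 20–80% of the parent), so the networks cannot rely on peak symmetry
  alone.  Segment count, removal rate and shoulder statistics are package
  defaults recorded in `synth_config()`; they are plausible choices, not
  measured constants.
* Each sample receives a smooth baseline — a shape-preserving piecewise
  cubic Hermite interpolant through alternating-sign control points with
  exactly five interior extrema, rescaled to exactly 0.6% of the tallest
  peak — and complex Gaussian noise with a per-sample standard deviation
  drawn log-uniformly from $[10^{-4}, 5\times10^{-3}]$ of the tallest peak
  (the noise level itself is a package default; published training setups
  state only that noise is added).  The baseline prevents the classifiers
  from keying on negative intensity or global smoothness alone.
* About 30% of samples additionally contain 1–3 broad background peaks
  (FWHH up to 500 points by default; the cap is configurable down to 300,
  as both values are plausible for macromolecular backgrounds), emulating
  protein background in biofluid spectra.

Labels are the *sign* of the injected error: for the PH0 task, $|\mathrm{PH0}|
\sim U[0.5^\circ, 5^\circ]$ with PH1 = 0; for the PH1 task, $|\mathrm{PH1}|
\sim U[1^\circ, 10^\circ]$ accompanied by a PH0 of equal magnitude and
independent random sign (so the PH1 network cannot solve its task by looking
at one end of the spectrum only); the `zero` class carries no error.  A
coarser pretraining regime uses $|\mathrm{PH0}| \in [5^\circ, 10^\circ]$ and
$|\mathrm{PH1}| \in [5^\circ, 20^\circ]$.  Phases are injected before the
baseline is added (the baseline is a post-detection artifact and should not
rotate with the signal).  All randomness descends from one master seed via
per-sample substreams, so manifests are byte-reproducible, and a
manifest-only mode draws the identical per-sample plans without
materializing spectra.

What the generator does *not* emulate: quantum-mechanical J-coupling
(multiplets are geometric, not simulated), solvent-suppression artifacts,
ridge noise, and field-dependent lineshape distortions.  Passing tests
therefore demonstrate correct behaviour on idealized dense spectra, not
performance claims on any particular real instrument or sample.

## The entropy objective

The coarse phaser minimizes the first-derivative Shannon entropy with a
quadratic negativity penalty:

$$H = -\sum_k h_k \ln h_k + w \sum_{R_k < 0} (R_k / R_{\max})^2, \qquad
h_k = \frac{|\Delta R_k|}{\sum_j |\Delta R_j|},$$

over first differences $\Delta R$ of the real part.  A well-phased
absorption spectrum concentrates its derivative at sharp peaks (low entropy)
and has no negative intensity; the penalty (weight $w = 1000$ by default)
also resolves the 180-degree ambiguity of a purely derivative-based
objective.  The exact functional used by other implementations is generally
unpublished; this ACME-style form is a package choice, configurable, and
validated by its behaviour (residuals below 10 degrees per component on
dense synthetic spectra).  The objective is invariant under uniform
rescaling of the spectrum.  `grid_search()` evaluates it on the full
$-180..180^\circ \times -180..180^\circ$ grid in 10-degree increments (both
endpoints included; $\pm 180$ are equivalent phases and the tie-break
toward smallest $|\mathrm{PH0}|$, then $|\mathrm{PH1}|$, keeps the result
deterministic).  For spectra longer than 16384 points the objective is
evaluated on a stride-4 decimated copy for speed; correctness tests run
undecimated.

## The classifiers

Two independent networks, ANN-ph0 and ANN-ph1, receive the same uncorrected
spectrum and each output probabilities over {negative, zero, positive} — the
sign of the remaining error of their component.  The architecture combines:

1. a strided 1D convolutional front end (strides 4, 2, 2, 2; kernels 9, 5,
   5, 5; channels 2 → 16 → 32 → 64 → 64) that extracts local lineshape
   features (the characteristic "dip and recover" signature of a small phase
   error) and reduces the sequence length by a factor of 32;
2. a transformer encoder (4 layers, 4 heads, embedding 64, pre-LN, MLP
   multiplier 2) whose attention uses a *relative* position bias: one
   learned scalar per signed log-spaced distance bucket (32 buckets per
   direction, 65 scalars per head), exact for small offsets and log-binned
   up to the maximum token distance.  The bias depends only on $i - j$, so
   the features are invariant to where a peak sits while still encoding
   order and distance — appropriate because absolute position carries no
   information about phase;
3. global average pooling over tokens, which makes the network accept any
   input length up to the maximum field of view of 131,072 complex points
   (4,096 tokens), followed by a small fully connected head.

Input channels are the real and imaginary parts, each normalized by
$\max_k |R_k|$ (scale invariance by construction; a real-only variant is
configurable for ablation) and then passed through an amplitude compression
$x \mapsto \mathrm{asinh}(c\,x)/\mathrm{asinh}(c)$ with $c = 100$ by
default.  The compression is the numerical analogue of the few-hundred-fold
vertical zoom a spectroscopist uses to see a sub-degree phase error: the
diagnostic dip-and-tail signature lives at the percent amplitude scale and
would otherwise be nearly invisible next to the tallest peaks.  The
published account of the tandem-network approach does not state the
internal dimensions or the input encoding; the configuration above is this
package's scaled-down default (about 170k trainable parameters), and no
attempt is made to match any particular parameter count.

**Training.** Adam (learning rate $10^{-4}$, decoupled weight decay
$10^{-5}$), mini-batches of 4, categorical cross-entropy, 400 epochs — these
full-scale defaults follow the standard recipe for this architecture.
Several additions are part of this package's recipe, all standard practice
for small transformers: global gradient-norm clipping at 1.0 (without it,
training intermittently collapses to the uniform predictor after an early
destabilizing step), dropout 0.1 on the attention output and MLP hidden
layer (at a few hundred training spectra the network otherwise memorizes
each sample's noise realization — fine-stage training accuracy approaches
1 while held-out accuracy stalls), an optional cosine learning-rate decay,
best-epoch selection on the validation set, and the two-stage curriculum:
the model first learns the easier coarse-error (pretraining) data, then
fine-tunes on the subtle fine-error data.  Forward and backward passes are
implemented natively (RcppArmadillo), with a pure-R reference
implementation of the identical computation kept for cross-checking, and
finite differences as the independent gradient oracle in the test suite.

**Scaled problem sizes.** The package's tests and examples train at desk
scale: 4,096-point spectra, 600 training / 150 validation samples per task
and stage, 15 pretraining + 30 fine-tuning epochs, learning rate $10^{-3}$
with cosine decay.  The larger learning rate at this scale compensates for
the roughly 50-fold smaller number of optimizer steps relative to the
full-scale recipe; recipe choices were fixed in pilot runs evaluated on
their own held-out draws.  Classification accuracy is always reported on a
fresh test split never used for training or epoch selection — best-epoch
selection makes the selection set's own accuracy an optimistic estimate.
Note that a 4,096-point spectrum carries 32-fold fewer data points per
phase error than the 131,072-point spectra of a full-scale training set,
and 600 training spectra are 30-fold fewer than a full-scale database, so
desk-scale accuracies are a conservative floor for the method, not an
estimate of full-scale performance; the test suite computes and asserts the
actual numbers.  Full-scale training (18,000 samples of up to 131,072
points, 400 epochs) uses the same code path with the default configuration.

## The correction loop

`deep_phase()` composes the stages:

1. **Coarse:** entropy grid search, applied once.
2. **ANN loop:** both classifiers are queried on the current spectrum; each
   component whose predicted sign is not `zero` receives a correction of the
   current step size (default 2 degrees) opposing the predicted sign, both
   components simultaneously.  A component's step is halved whenever its
   predicted sign flips, and an oscillation guard halves both steps when the
   same sign/step pattern recurs three times.  The loop exits when both
   networks predict `zero` (or after `max_iterations`).  The published
   workflow states only that corrections are applied iteratively "until both
   networks predict no further error"; the step policy (size, halving rule,
   simultaneous application) is this package's design, recorded in
   `phaser_options()`.
3. **Refinement:** finite-difference ascent on the sum of the two
   zero-class probabilities over (PH0, PH1), with central differences
   (probe 0.5 degrees), normalized gradient steps, and step halving when no
   improving move exists, terminating when the step drops below 0.3 degrees.
   Accepted refinement moves never decrease the score sum by construction.

The result records the composed total correction, the fully phased spectrum,
a per-iteration trace (every applied correction plus both classifiers'
probabilities) whose sum reproduces the total exactly, a convergence flag
(final step below threshold *and* both classifiers voting `zero`), and the
final step size.  A spectrum with fewer than about 15 detected peaks
(`count_peaks()`: local maxima above 5 times a robust noise estimate) is
outside the method's reliable domain and triggers a warning rather than an
error.  Only PH0 and PH1 are modelled; spectra with higher-order phase
errors cannot be fully corrected by design.

## Numerical and design notes

* Tie-breaks: the grid search resolves exact objective ties toward the
  origin, then by grid order; `which.max` resolves (measure-zero) probability
  ties toward the more negative class, deterministically.
* Degenerate inputs: all-zero real parts are rejected by preprocessing
  (degenerate-input error) and return entropy 0 with a warning in the
  objective; empty peak lists synthesize to all-zero spectra.
* Checkpoints and dataset containers are JSON-manifest + little-endian
  float64 pairs, so any language can read them; loading validates tensor
  shapes against the embedded configuration, and the phasing pipeline
  refuses model pairs with incompatible input configurations.
* Test and acceptance problem sizes (50 spectra of 4,096–32,768 points for
  the entropy benchmark; 100 end-to-end recoveries at 4,096 points; the
  scaled training run above) are the package's chosen desk-scale study
  conditions; the generator's scientific constants (error ranges, widths,
  baseline, broad-peak rate) are never reduced.

## Known limitations

The classifiers are valid only within their training domain: peak widths of
roughly 3–30 points (plus broad backgrounds), errors within the fine ranges
after coarse correction, at least ~15 peaks.  The entropy stage assumes the
true correction lies within one grid cell of a global entropy minimum, which
very sparse or heavily baseline-distorted spectra can violate; on spectra
whose errors are already small, its 10-degree grid can even select a distant
spurious minimum, which is why the neural stage records every visited state
and reverts to the best-scoring one.

Two desk-scale limitations deserve emphasis.  First, the zero-versus-small
decision boundary: confusion matrices show that sign confusions
(negative vs positive) are rare and errors concentrate on the `zero`
boundary, where sub-degree PH0 and few-degree PH1 errors approach the
information limit of a 4,096-point noisy spectrum.  Second, the (PH0, PH1)
compensation ridge: because peaks cluster near the spectrum center, a
zeroth-order error accompanied by a first-order error of about twice the
magnitude and opposite sign leaves the crowded center almost perfectly
phased, and only sparse edge peaks betray the error.  The summed zero-class
score surface is correspondingly elongated along this ridge, which bounds
how precisely the refinement can pin PH1 at desk scale.  Both effects
shrink as spectrum length, peak count and training-set size grow toward the
full-scale configuration.

Baseline *correction* is out of scope: the `--baseline none` CLI hook is a
deliberate no-op pass-through, and any residual baseline should be handled
downstream after phasing.
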