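---
title: "Post-acquisition shimming: model, training procedure, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-acquisition shimming: model, training procedure, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Even a well-shimmed NMR magnet leaves residual field inhomogeneity over the
sample volume. Spins at different positions precess at slightly different
frequencies, so every line in the spectrum is smeared by the *distribution*
of frequency offsets across the sample. To a good approximation this smearing
is position-independent in frequency: the observed spectrum is the ideal
spectrum convolved with one machine- and shim-state-specific kernel, the
**response function**. Classical reference deconvolution inverts this
convolution using a single user-chosen reference peak and is notoriously
sensitive to that choice.

This package takes the learning route instead:

1. **Calibrate.** Acquire (here: simulate) many spectra of a narrow singlet
   under systematically mis-set low-order axial shims (Z1, Z2) plus one
   best-shimmed reference.
2. **Extract.** Recover one response function per calibration spectrum by
   least-squares deconvolution against the reference
   ([`extract_response()`]).
3. **Train.** Generate endless synthetic "clean" spectra of
   Lorentzian-Gaussian multiplets, convolve each with a randomly drawn
   library kernel, add noise, and train a convolutional autoencoder with
   attention pooling to undo the distortion ([`train_model()`]).
4. **Correct.** Resample any spectrum from the same machine to the training
   frequency step, scale its tallest peak to 16, run the network, and undo
   the scaling and resampling ([`correct()`]).

The key assumption inherited from reference deconvolution is that *the whole
spectrum is distorted by the same kernel*. The network's attention mechanism
exists precisely because different spectral regions carry very different
amounts of information about that shared kernel: narrow singlets expose it,
broad or overlapped multiplets mask it.

## Network architecture

The encoder applies `depth = 4` stride-1 1-D convolutions (kernel 7, 64
channels) interleaved with three ReLUs, so each of the `L` input positions is
summarized from its 25-point neighborhood (`depth * (kernel - 1) + 1`). A
single trainable query vector of 64 values scores every latent column; the
softmax of the scores gives attention weights, and the weighted average of
latent columns is one 64-dimensional global feature vector. That vector is
broadcast-concatenated onto every latent column (128 channels) and decoded by
a mirrored stack of four transposed convolutions back to one output channel.
The output is linear - corrected spectra may legitimately contain small
negative baseline excursions, so no output activation is applied. End to end,
one output point depends on 49 input points plus the global features.

An auxiliary decoder (linear 64 -> `aux_hidden`, ReLU, linear ->
`n_response`) reads the global vector and predicts the response function
itself. It is a training-time device: forcing the pooled features to encode
the kernel is what makes the attention useful. After training it is kept only
for diagnostics.

Parameter bookkeeping under the defaults: encoder 86,720; decoder 115,329;
attention 64 - together 202,113 for the inference network, which is the count
we compare against the published total of 202,176 (within 0.04%). The exact
published figure cannot be decomposed once any two-layer auxiliary decoder is
included (its smallest possible size already exceeds the 63-parameter gap),
so we read it as describing the network retained for inference and treat the
auxiliary width (default 64) as a free choice. `count_parameters()` reports
every component separately so nothing is hidden.

Numerical conventions worth stating once: all convolutions and transposed
convolutions use zero padding of `(kernel - 1)/2` so length is always
preserved; all response kernels act *centered*, i.e. index `(N - 1)/2`
(0-based) corresponds to zero frequency shift; attention scores are plain dot
products with the query - no bias, no temperature - which is exactly what
makes the attention block 64 parameters. Initialization is fan-in-scaled
uniform under a caller-supplied seed, with He scaling (`sqrt(6/fan_in)`
bounds) on the ReLU-fed layers and `sqrt(3/fan_in)` on linear-output layers,
biases at zero: with eight stacked convolutions, anything weaker attenuates
activation variance several-fold per layer and visibly slows the first
thousand optimizer steps.

## Resolution planning

Let `W` (Hz) be the width of the broadest response expected from the machine
and `FWHM_min`/`FWHM_max` the natural linewidth range of interest (0.4 and 4
Hz are serviceable for small molecules in solution). The frequency step `Δf`
must satisfy

* `FWHM_min > 1 · Δf` - the narrowest undistorted singlet spans more than one
  point, else it carries no shape information;
* `W + FWHM_max < 100 · Δf` - the broadest distorted peak stays under 100
  points, roughly twice the autoencoder receptive field.

The kernel length is the smallest odd `N` with `N · Δf >= W`.
`response_length()` enforces this formula strictly; an explicit odd
`n_override` reproduces externally chosen lengths (e.g. 61 points at
`Δf = 0.3406` Hz and `W ≈ 21` Hz, where the formula itself yields 63 - the
quoted `W` values are rounded, so the formula stays authoritative and the
override stays explicit).

## The calibration simulator

Real calibration data comes from scripted acquisitions; the simulator
replaces the spectrometer so the entire pipeline is buildable and testable.
It models the axial field offset at normalized column position
`z ∈ [-1, 1]` with the first two Legendre profiles,

    delta(z) = kappa1 * z1 * z + kappa2 * z2 * (3 z^2 - 1) / 2,

the idealized shapes of the Z1/Z2 shim coils. The response function of a
setting is the distribution of `delta(z)` under uniform `z` - computed by
deterministic midpoint quadrature with 2e5 samples, histogrammed at `Δf/8`,
smoothed by the discretized natural Lorentzian of the calibration singlet,
and box-averaged onto the `N`-point grid (edge fine-bins split evenly between
neighboring coarse bins, which keeps the mirror symmetry
`response(z1, z2) = reverse(response(-z1, z2))` exact). If more than 0.1% of
the mass falls outside the `N`-point window the simulator refuses, mirroring
the user's duty to choose `W` generously.

Default couplings (`kappa1 = 0.08`, `kappa2 = 0.035` Hz per shim unit) put
the corners of a ±80-unit grid at a ~13 Hz response span, inside a 21 Hz
window at `Δf = 0.34` Hz. The default natural half-width, 0.016 Hz, is what a
~20 s transverse relaxation time implies - the defining property of a good
calibration sample, whose line contributes essentially nothing to the
observed width. There is no published shim-unit-to-Hz mapping; these are
simulator knobs, not measured constants, and the tests treat them as such.

What the simulator deliberately does **not** model: off-axis (X/Y) shim
profiles, sample-volume and susceptibility effects, phase errors, baseline
drift, and apodization. Passing tests on simulated data therefore demonstrate
the correctness of the machinery (deconvolution, training, correction
plumbing), not performance on any particular real spectrometer.

## Response extraction

With the reference `best` and a distorted calibration spectrum `d` on the
same grid, the kernel solves `argmin_r ||A r - d||^2 + λ ||r||^2`, where
column `t` of `A` is `best` shifted by `t - (N-1)/2` bins, rows restricted to
a fit window. The window defaults to: centered on the maximum of `d`, wide
enough to contain every point of `best` above 0.1% of its maximum, plus
`N`-point margins on both sides. The solver is dense QR; `λ` is specified
relative to the largest diagonal of the normal matrix, defaults to 0, and a
rank-deficient system triggers one automatic retry at `1e-8` with a warning.
No sign or unit-area constraint is imposed - measured kernels are asymmetric
and somewhat irregular, and constraining them would bias the fit. The
relative RMS fit residual is recorded on every kernel, and kernels whose
endpoints exceed 5% of their maximum raise a window-too-narrow warning.

## Synthetic training spectra

Clean spectra are sums of 2-5 multiplets. Each line is the equal-width
Lorentzian-Gaussian mixture

    f(w) = (1 - g) H w0^2 / (w0^2 + (w - w_c)^2) + g H exp(-(w - w_c)^2 / (2 s^2)),

with `w0 = s * sqrt(2 ln 2)` tying both components to one FWHM. A multiplet
of multiplicity `m` has `m` equidistant components spaced by `j1` with
binomial weights `C(m-1, k) / 2^(m-1)`; with probability 0.5 a second
coupling `j2` splits every component into a half-weight doublet. Parameter
ranges: centers ±279.02 Hz (clipped to 90% of the grid half-span on narrow
grids), couplings 0-15 Hz, per-multiplet widths 1-2 Hz scaled by a
spectrum-wide factor 0.2-1 (component half-widths 0.2-2 Hz), intensities 1-3,
height factors 0.5-4 (multiplet) and 0.5-2 (spectrum), Gaussian fraction
0-1, noise SD uniform on [0, 0.02].

Two of these choices are interpretations rather than transcriptions. First,
harvesting multiplicities and intensities from a molecule database is
replaced by direct sampling - multiplicity weights (0.30, 0.30, 0.20, 0.10,
0.05, 0.03, 0.02) favor the low multiplicities that dominate small-molecule
spectra, and intensities are uniform on [1, 3]. Second, the second coupling
is applied as a probability-0.5 tensor doublet split: a single equidistant
m-plet uses only one spacing, and only a product of two couplings explains
component weights below 1/64 (such as 1/256) in the source ranges. Training
spectra are *not* per-spectrum normalized; the inference-time target height
16 sits inside the generated height range by construction.

## Training

The loss for a batch of `K` examples is

    L = (1/K) * ( |S_trg - S_out|^2 + |R_trg - R_out|^2 + |S_inp - S_out * R_out|^2 )

with `*` the centered same-mode convolution. Each `|·|^2` is the *mean* of
squared element differences over its vector: the published notation does not
fix mean-vs-sum, and per-element means make the loss (and hence the learning
rate) independent of the training length, so the same hyperparameters
transfer between the 2048-point full-scale setting and shorter smoke runs.
The three terms are the reconstruction loss, the distortion loss (the
auxiliary decoder must recover the kernel actually applied), and a
consistency loss that re-distorts the output and compares against the noisy
input - a mild regularizer that anchors the output to the observed data.

Training is online: every batch is freshly generated and never reused, which
removes overfitting as a failure mode. The optimizer is Adam with moments
(0.9, 0.999) and epsilon 1e-8; no dropout or weight decay. Gradients are
clipped to a global norm of 5 before the moment updates - a fresh model's
first few batches produce gradients orders of magnitude above steady state
(and strongly seed-dependent), and because the second moment's 0.999 decay
remembers them for about a thousand batches, an unclipped spike can throttle
most of a short run. The full-scale
schedule ramps batch size up and learning rate down - 1.6 M spectra at
(64, 1e-3), 25.6 M at (512, 1e-3), 12.8 M at (512, 5e-4), 40 M spectra in
total. Gradients are computed by an analytic backward pass (verified against
finite differences in the test suite) and can run in single precision, the
standard choice for stochastic gradient training; parameters and optimizer
state stay in double.

### The desk-scale smoke preset

`smoke_preset()` is a miniature of the full study sized for a few minutes on
one CPU core: a 16 × 16 shim grid spanning ±37.5 simulator units (256
kernels, response spans up to ~6 Hz), 256-point spectra, a 12 Hz / 37-point
response window, a 32-channel model (the architecture shape - kernel 7,
depth 4, attention pooling - is unchanged; only the width shrinks), and one
phase of 50,048 spectra (782 batches of 64) at learning rate 1e-3. The width
and spectrum length were sized once against the GEMM throughput of a single
CPU core so that a full smoke run takes minutes, and are not tuned
afterwards. What a successful smoke run demonstrates is that the pipeline
end-to-end - generator, convolution, loss, gradients, optimizer - learns to
invert genuine distortions; it does not reach full-scale reconstruction
quality, which needs the 40 M-spectrum schedule and the full-width model.

## Correction-time behavior and degenerate inputs

`correct()` preserves the caller's grid exactly: the model runs at its
training step and the result is interpolated back. Resampling uses a natural
cubic spline with flat extrapolation at the edges - smooth lineshapes
interpolate cleanly and, unlike FFT resampling, truncated spectra produce no
ringing. Inputs whose resampled length falls below 64 points are rejected
loudly rather than padded silently. Spectra with no positive peak cannot be
height-normalized and are rejected. A peak-height dynamic range beyond 1:220
(the nominal coverage of the training heights) triggers a warning suggesting
solvent-peak removal; nothing is removed automatically. Attention weights are
exposed per point and summarized per user-supplied frequency region by
`attention_report()`; there is no automatic multiplet segmentation.

## Known limitations

* The distortion-as-convolution assumption fails for very large
  inhomogeneities; when multiplet maxima merge, no post-acquisition method
  recovers them reliably.
* Kernels wider than the calibration library's widest are extrapolation;
  quality degrades.
* The simulator's two-coefficient field model spans a much smaller distortion
  family than a real shim stack; models trained on it are demonstrations,
  not drop-in spectrometer models.
* Phasing, baseline correction and apodization are upstream preprocessing;
  the package assumes properly phased, unapodized frequency-domain input.
* Time-domain back-transformation of corrected spectra is out of scope here;
  outputs stay in the frequency domain.
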