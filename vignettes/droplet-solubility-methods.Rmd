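---
title: "Methods: droplet-microfluidic solubility mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet-microfluidic solubility mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dropsol` analyses droplet-microfluidic PEG-precipitation screens: each
water-in-oil droplet is a sample of composition space, labelled mixed or
aggregated from its fluorescence images, and the *relative solubility* of
the protein is read off a classifier's phase boundary. This vignette is
the package's account of the underlying models, the tunable parameters,
and the design decisions taken where the procedure was genuinely open.

## The generative model

The simulator (`phase_truth()`, `sample_compositions()`,
`assign_labels()`, `render_frames()`) encodes the assumptions the
analysis relies on:

* **Composition by linear dilution.** A droplet is a convex combination
  of inlet stock solutions; the volume fraction of each barcoded inlet
  follows a stratified ramp (an evenly spaced grid over the configured
  fraction range, permuted independently per inlet), mirroring flow-rate
  programming with constant total flow. Fractions sum to one by
  construction; species concentrations are fractions times stocks.
* **A boundary linear in composition.**
  `boundary = c0 + b_protein * protein + sum_a s_a * additive_a`, in
  w/v % precipitant. Positive additive slope = solubilising additive
  (w/v % PEG gained per mM), the convention used for reporting excipient
  slopes. An optional per-additive breakpoint switches to a second slope
  beyond a given concentration, emulating the salting-in/salting-out
  behaviour of NaCl. Linearity is the ideal-solution assumption the
  screens themselves rest on.
* **Logistic label noise.** A droplet aggregates with probability
  `plogis((PEG - boundary)/noise_width)`. The measured probability
  gradient has finite width but no stated noise law; the logistic is the
  canonical monotone choice, and `noise_width` (w/v % PEG, default 0.5)
  sets the transition scale.
* **Affine imaging.** Interior intensity in channel *k* is
  `illumination * gain_k * conc_k + dark + N(0, noise_sd)`; aggregated
  droplets additionally carry 2–6 small bright blobs in the protein
  channel at `spec_contrast` (default 3) times the local signal — only
  the protein is covalently labelled, so specs appear nowhere else. The
  camera noise law and magnitude are not constrained by the assay
  description; Gaussian read noise (default sd 3 counts on a dark level
  of 100) is configuration-exposed.
* **Geometry.** Non-overlapping disks, radius uniform in 10–14 px on a
  512 x 512 frame, about 100 droplets per frame. Real emulsion packing,
  droplet formation physics and photobleaching are not modelled.

Because every rendered droplet carries its true composition and label in
a truth table, the pipeline's recall, composition error, call accuracy
and boundary recovery can all be scored exactly — that is what the test
suite does. Passing those tests shows the *analysis* is correct under
the stated generative assumptions; it cannot certify performance on real
micrographs with debris, focus drift, spectral cross-talk or non-disk
droplets, none of which the generator emulates.

## Detection and statistics per droplet

Detection thresholds each channel with Otsu's method and unions the
masks; a channel whose threshold fails to clear its own background
(threshold below median + 2 mad, or more than 40 % of pixels above it)
carries no signal and is skipped, so a dye-free channel cannot flood the
mask with noise. Relative thresholding makes detection invariant to
constant intensity offsets. Connected components are filtered by
equivalent radius (`r_min`–`r_max`, default 6–20 px) and circularity
`4 * pi * area / perimeter^2` (default floor 0.8, perimeter measured
along the object contour), which removes fused droplet pairs; records
touching the frame border are dropped with per-reason counts. Interior
statistics use pixels within 0.9 x radius of the fitted centre,
excluding the oil rim.

Composition inference uses the **median** interior intensity rather than
the mean. This matters: aggregate specs inflate the protein-channel
mean, so a mean-based estimate leaks the class label into the inferred
protein concentration, and a classifier given that axis will happily
separate the classes on it instead of on composition. The median is
unbiased as long as specs cover a minority of interior pixels. Records
keep mean, median and sd per channel.

## Calibration

Three image sets, ten frames each by default, mirror the three
corrections a fluorescence readout needs: the **dark** level is the
per-channel median of empty frames; the **flat field** is the smoothed
(Gaussian, sigma = 5 % of the frame side — enough to suppress droplet
residue while preserving the illumination shape), dark-subtracted,
max-normalised mean of homogeneous-dye frames, applied per pixel at the
droplet centre; the **endpoint gain** of each channel is the corrected
interior intensity of droplets containing only that inlet's solution,
divided by the tracer stock — a zero-intercept linear intensity model,
the standard dilute-dye assumption. Inlet fractions follow by dividing
corrected intensities by gain x stock; the unbarcoded buffer inlet takes
the remainder. Negative fractions are clipped and flagged; droplets
whose barcoded fractions exceed 1 by more than 0.05 are flagged
inconsistent and excluded rather than repaired.

## Aggregate calling

The inhomogeneity score is `max(CV, w * spot_fraction)` over
dark-corrected protein-channel interior pixels, with `CV = sd/mean` and
`spot_fraction` the share of pixels above `mean + k * sd` (defaults
k = 3, w = 10). Both components are scale-free, so the score is
invariant to absolute brightness. Droplets with mean corrected signal
below `min_signal` (default 5 counts) are flagged low-signal, scored 0,
and excluded from calling.

The mixed/aggregated threshold is chosen once per experiment: Otsu's
criterion on `log(1 + score)` proposes a split, and the threshold is
placed at the kernel-density minimum between the two cluster medians.
The refinement is deliberate — the aggregated score cluster is broad and
the Otsu split alone sits inside its lower tail, miscalling borderline
aggregates and biasing the boundary upward by a systematic ~0.7 w/v %
in simulation. When no density valley exists (a dip-test-style check:
density at the split must be below 0.7 x the density at both cluster
medians), the score distribution is treated as unimodal and a configured
fallback threshold is used. A score exactly at the threshold is called
mixed, conservative toward solubility.

## Phase boundary, probability and uncertainty

The classifier is a soft-margin SVM (e1071/libsvm) on standardised
features, linear kernel by default, `(x . y + 1)^2` for the curved
option, regularisation C = 1 in standardised space,
inverse-prevalence class weights (screens near a boundary edge are
imbalanced). The aggregation probability is a sigmoid (Platt)
calibration fitted by logistic regression of the training labels on the
decision values — fitted once on the training set, deterministic under a
seed, and making the phase boundary exactly the p = 0.5 contour. Kernel
choice, when left open, is decided by held-out log-likelihood with a
margin (`compare_kernels()`): poly2 must beat linear by 2 log-units on
the held-out split.

Two numerical points. First, features whose relative spread is below 5 %
are treated as held fixed and removed from the fit: a flow-fixed axis
(protein in a one-dimensional titration) re-enters the model as a pure
measurement-noise dimension, and any residual correlation between that
noise and the label tilts the boundary; in simulation this produced a
~2 w/v % read-off error before the gate was introduced. Second, the
relative solubility is the p = 0.5 crossing along the precipitant axis,
found by bisection to 0.01 w/v % inside the training range; when p never
crosses 0.5 the screen is reported as censored ("boundary not
bracketed", above or below the sampled range) rather than extrapolated —
the behaviour a screen at very high solubility (e.g. an extreme pH)
requires.

The boundary's standard deviation — its visual "thickness" — is
operationalised as the standard deviation of the crossing over B = 200
bootstrap resamples of the droplets, each refitted with identical
hyperparameters, under a fixed seed. Bootstrap resamples that lose a
class or fail to bracket are dropped from the spread.

## Formulation analytics

Per-additive slopes are weighted least squares of per-level solubility
reads against concentration, weights 1/sd^2 (unweighted if any sd is
missing or nonpositive). The reads-per-level design — one phase model
per additive concentration — was chosen over fitting the slope to a 2-D
boundary contour; it matches how replicate screens are actually
composed, and gives each point an honest uncertainty. The two-regime
option fits a continuous two-segment line with the breakpoint chosen by
grid search over interior concentration levels, accepted only when the
residual sum of squares improves enough to pay a one-parameter penalty
(`n log(RSS/n) + 2k`); with levels every 100 mM this localises a 350 mM
kink to within one level spacing.

The two-excipient combination slope is `-(w_x / w_y)` from the
linear-kernel boundary normal in raw mM units: −1 means equally
effective per mM, below −1 the x-axis compound is more efficient. A
boundary parallel to an axis (|w| ratio below `axis_tol`) is reported
symbolically as infinite rather than as a large number. AUC comparison
integrates solubility-minus-baseline over the shared concentration range
(trapezoid rule); for linear effects the AUC ratio equals the slope
ratio, and AUCs of additively acting excipients add. Condition ranking
uses pairwise z = delta / sqrt(sd1^2 + sd2^2) with |z| >= 2 flagged;
censored conditions rank above (or below) all measured ones with no
z-scores.

## Problem sizes and reproducibility

Defaults follow the study conditions: ~100 droplets per 512 x 512
frame, ten calibration frames per condition, 2000–4000 droplets per
boundary estimate, B = 200 bootstrap resamples (B = 25–50 in tests,
where only coverage, not the last digit of the sd, is at stake), 600–800
droplets per concentration level in the additive screens. All
randomness — composition sampling, labelling, rendering, bootstrap — is
driven by explicit seeds, and a run with the same configuration and seed
reproduces its CSV/JSON outputs byte for byte.

## Known limitations

* Spectral cross-talk, FRET and photobleaching are neither simulated nor
  corrected; the calibration assumes one dye per channel.
* The inhomogeneity statistic targets bright specs; weak diffuse
  precipitation that raises variance without distinct spots may sit near
  the threshold.
* The mixed/insoluble dichotomy is operational, not thermodynamic: the
  method cannot distinguish oligomers, amorphous precipitate and
  fibrils.
* Boundary and slopes assume the linear-dilution and linear-boundary
  models; strongly non-ideal excipient interactions would need the poly2
  kernel and would make the single-number combination slope an
  approximation of a curved trade-off.
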