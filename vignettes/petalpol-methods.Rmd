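---
title: "Methods: imaging polarimetry and choice-learning models in petalpol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging polarimetry and choice-learning models in petalpol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalpol)
```

petalpol bundles the two computational halves of a
flower-polarization learning study: an imaging-polarimetry pipeline that
turns rotating-analyzer photograph stacks into per-pixel polarization
maps, and a behavioural toolkit that models whether foragers learn to
discriminate polarization-patterned targets. This vignette documents the
models, the conventions, the tunable parameters, and the design choices
made where the methods literature leaves them open.

## 1. Rotating-analyzer polarimetry

### Forward model

Light from a scene point with total radiance $R$ (linear camera counts),
degree of linear polarization $d \in [0,1]$ and angle of polarization
$\phi$ passes an ideal linear analyzer at orientation $\theta$ with
transmitted intensity

$$I(\theta) = \tfrac12 R\,\bigl(1 + d \cos 2(\theta - \phi)\bigr) + \text{dark}.$$

The factor $\tfrac12$ is the transmission of an ideal polarizer for
unpolarized light. Writing $S_0 = R$, $S_1 = R d\cos 2\phi$,
$S_2 = R d \sin 2\phi$ puts this in Stokes form
$I(\theta) = \tfrac12(S_0 + S_1\cos 2\theta + S_2 \sin 2\theta)$. The
synthetic renderer (`render_stack()`) evaluates exactly this model, so
the noiseless pipeline identity — render, ingest, estimate, map, and
recover the ground truth to $10^{-6}$ — is a meaningful test, not a
tautology: estimation runs through the same code path used for real
stacks and knows nothing of the scene description.

Only *linear* polarization is modelled. A rotating linear analyzer
cannot measure $S_3$, so "degree of polarization" throughout the package
means degree of linear polarization (DoLP); circular components, rare in
floral reflections, would be absorbed into the unpolarized part.

### Estimator

`estimate_stokes()` fits the three Stokes parameters per pixel by
ordinary least squares of the $N$ measured intensities on the design
matrix with rows $\tfrac12(1, \cos 2\theta_k, \sin 2\theta_k)$. The
design depends only on the angle list, so one QR factorization is shared
by every pixel and the whole image is a single matrix solve. At least
three angles distinct modulo $180^\circ$ are required (the design must
have rank 3); the default acquisition uses seven frames at
$0, 20, \dots, 120^\circ$ plus one dark frame, mirroring the acquisition
protocol the pipeline is built for. Whether those seven angles spanned
$0$–$120^\circ$ or some other range in the original acquisition is not
recorded; the default assumes $0$–$120^\circ$ and is configurable. For
angle sets containing $\{0, 60, 120\}^\circ$ the least-squares solution
coincides with the classical three-point closed form, which the test
suite uses as an independent oracle ($10^{-9}$ relative agreement on
noiseless data).

The per-pixel RMS residual of the sinusoid fit is returned as a
diagnostic; it is exactly zero for data following the forward model.

### Maps, conventions, thresholds

`compute_maps()` derives

* AoP $\phi = \tfrac12\,\mathrm{atan2}(S_2, S_1)$, reported in degrees in
  $[0, 180)$, measured counterclockwise from the image x-axis. The
  reference axis is a package convention (no standard exists for
  flower-frame imaging); all AoP arithmetic is axial (period
  $180^\circ$).
* DoLP $d = \sqrt{S_1^2+S_2^2}/S_0$, clipped to $[0,1]$ (noise can push
  the raw ratio above 1).

A pixel's AoP is numerically meaningless when there is little polarized
signal, so the validity mask excludes pixels with $d <$ `dolp_min`
(default 0.05) or $S_0 \le$ `s0_min` (default 0; around $5\times$ the
dark-noise SD is a sensible field setting), as well as pixels that were
saturated in any raw frame or translated in from outside the field of
view during registration. Degenerate pixels are flagged, never
NaN-propagated. The published percentage-polarization images may have
been thresholded or smoothed in ways that are not recorded; these
defaults are this package's own choice.

Ring summaries (`ring_summary()`) average AoP with the axial circular
mean — angles doubled, vector-averaged, halved — and report the
inter-ring difference as an axial distance in $[0^\circ, 90^\circ]$,
with an exact $90^\circ$ tie reported as $90^\circ$. False-colour
rendering (`false_color()`) maps AoP onto a cyclic hue wheel (0 and
$180^\circ$ share a hue) with brightness optionally weighted by DoLP, so
unpolarized regions fade to black.

### Ingest: Bayer channels, dark frames, registration

Raw mosaic frames are handled without interpolation: `split_bayer()`
pulls the four colour-filter sub-grids apart into half-resolution
channels (an exact bijection, tested by round trip), and one channel —
default G1, configurable, since the original choice of channel is not
recorded — proceeds to polarimetry. All processing is in linear counts;
no gamma anywhere. `dark_subtract()` removes the lens-cap frame, clamps
at zero and marks full-scale (saturated) pixels invalid; a stack without
a dark frame is only processed on explicit request.

Registration (`register_stack()`) is translation-only: tripod-mounted
acquisition leaves no appreciable rotation or scale change. Shifts are
estimated by FFT cross-correlation of mean-subtracted *gradient
magnitude* images (cyclic centred differences). Correlating edge
strength rather than raw intensity matters here: as the analyzer
rotates, the two polarizer rings of a contrast target swap brightness,
and raw-intensity phase correlation can lock onto a peak one pixel off
(or worse, on an anti-correlated feature); region boundaries, in
contrast, persist in every frame. On noiseless synthetic stacks the
estimator recovers every integer jitter up to $\pm 10$ px exactly.
Subpixel refinement is deliberately not attempted — whole-pixel accuracy
suffices at the default scene scale. All-constant frames (correlation
undefined) are flagged and left unshifted.

### The synthetic scene

`scene_pattern()` describes a bull's-eye target: a polarizing inner disc
(24 mm outer diameter) and a polarizing outer annulus (38 mm outer
diameter) on an unpolarized background, at a default scale of 10 px/mm
(radii 120 and 190 px in a 420×420 image) — the scale is arbitrary and
configurable. The type invariant keeps the regions strictly nested, so
the default geometry leaves a 1 px unpolarized gap between the rings
where the physical filters abut. "Contrast" targets set the ring AoPs
$90^\circ$ apart (axially); "plain" targets set them equal.
`dfic_condition()` supplies the neutral-density intensity factors
($10^{-0.3}$ and $10^{-0.9}$) for the four intensity-contrast target
conditions. Default radiances (40000 counts for rings, 8000 for
background, dark level 100, 16-bit range) put the signal in a realistic
mid-scale regime.

Noise is optional and off by default: Gaussian read noise, Poisson shot
noise with a counts-per-photoelectron gain, and per-frame integer
translation jitter. All randomness flows from one explicit seed per
call and the caller's RNG state is restored. What the generator does
**not** emulate: lens vignetting and defocus, polarizer diattenuation
and spectral non-ideality, demosaicing artefacts, UV response, and
fractional-pixel drift. Tests passing on synthetic stacks therefore
validate the estimator and bookkeeping, not the radiometric fidelity of
any particular camera.

Frames are kept as floating-point counts clipped to the sensor range;
quantization to 16-bit integers happens at TIFF export. This is what
makes the $10^{-6}$ end-to-end identity achievable in memory while disk
round trips are accurate to half a count.

## 2. The learning model

### Specification

For bee $i$ at trial $t$ of $T$ (the protocol records $T = 100$ choices
per bee, at least nine bees per treatment),

$$\mathrm{logit}\,P(y_{it}=1) = x_{it}'\beta + b_i + s_i\,\tilde t,
\qquad b_i \sim N(0,\sigma_b^2),\quad s_i \sim N(0,\sigma_s^2),$$

with experience scaled as $\tilde t = (t-1)/(T-1) \in [0,1]$ for
numerical conditioning (the covariate coding of the original analysis is
unrecorded; on this coding $\beta_1$ reads directly as the log-odds gain
over a full session). The random effects are independent ("uncorrelated
random intercept + slope"), capturing between-subject differences in
both *ability* and *rate of acquisition*; a random-intercept-only
structure is available via `random = "intercept"`. Fixed-effect
structures: `null` (intercept only — random effects retained),
`experience`, `experience_condition`, and `experience_x_condition`. The
main-effects spec exists because it is the reduced model of the
interaction test.

### Estimation

Subjects are independent, so the marginal likelihood factorizes into a
1- or 2-dimensional integral per bee. Each integral is approximated by
Laplace's method at the per-bee posterior mode, found by damped Newton
iterations in compiled code; the outer optimization over
$(\beta, \log\sigma_b, \log\sigma_s)$ uses `L-BFGS-B` with
$\log\sigma \in [\log 10^{-3}, \log 20]$ and ordinary-logistic starting
values. With 100 trials per bee the Laplace approximation is accurate —
the test suite confirms agreement with an independent mixed-model
implementation (lme4's Laplace fit) to two decimals in deviance and
coefficients, and adaptive quadrature would be a natural extension, not
a correction. At the lower $\sigma$ bound the model collapses to
ordinary logistic regression, which is exactly the behaviour verified in
the degenerate-variance tests against an IRLS oracle. Fits are
deterministic given data and starting values; non-convergence is
reported by warning and flagged on the object, never silently accepted.

Deviance is $-2\times$ the maximized approximate log-likelihood, and
$\mathrm{AIC} = \text{deviance} + 2\,(\text{fixed effects} +
\text{variance components})$ — variance components count as parameters,
the common mixed-model convention. This convention is stated explicitly
because published AIC values from other software cannot be regenerated
without the underlying data; only *differences* of deviances and AICs
between nested fits are meaningful anchors, and those obey
$\Delta\mathrm{AIC} = \Delta\text{deviance} - 2\,\Delta\mathrm{df}$
identically.

### Inference

`compare_nested()` (and `chisq_lrt()` for working directly from
reported statistics) tests the removed term by referring the deviance
change to $\chi^2_{\Delta\mathrm{df}}$. `experience_test()` is the
primary learning test (experience model vs null);
`interaction_test()` asks whether a task-irrelevant intensity-contrast
overlay alters the learning rate (interaction model vs main-effects
model). Simulation at the study scale (9 bees × 100 trials) shows the
experience test holds its nominal 5% size under a no-learning null and
exceeds 80% power when learning reaches ~75% end-of-session accuracy —
the problem sizes used in the test suite (500 null and 200 learning
replicates, 120-replicate uniformity checks for the interaction test)
were chosen to give Monte-Carlo standard errors comfortably below the
margins being asserted.

One accuracy note: a $\chi^2$ p-value recomputed from a deviance change
that was *printed* rounded to 3 significant figures is itself only
reproducible to about $2\times 10^{-4}$, which is the tolerance the
corresponding tests use.

### Simulator defaults as study conditions

`simulate_choices()` defaults describe the learnable-task scenario:
$\beta_0 = 0$ (chance-level first choice), $\beta_1 =
\mathrm{logit}(0.75) \approx 1.10$ (mean end-of-session accuracy 75%,
the level real learners approach), $\sigma_b = \sigma_s = 0.5$ (moderate
heterogeneity: individual end-of-session accuracies spanning roughly
0.6–0.87), $T = 100$ trials, 9 bees. The no-learning scenario used for
size calibration sets $\beta_1 = 0$ and $\sigma_s = 0$ — if nothing is
learned there is no between-bee variation in learning rate to model —
and is fitted with the random-intercept structure for the same reason.

For intensity-contrast sessions the simulator attaches a condition label
to each trial. The label of the *chosen* flower is drawn uniformly from
the levels: with four flowers of every condition present in each
Latin-square arrangement and correctness independent of the intensity
overlay, uniformity is the exact marginal of the rearrangement schedule,
so nothing is lost by not simulating the spatial walk. Non-null
interaction scenarios are built by per-condition slope offsets
(`condition_beta`).

### Learning curves

`learning_curve()` pools choices across bees within consecutive trial
bins and reports the proportion correct with a Wilson score 95%
interval. Wilson was chosen for its near-nominal coverage without the
conservatism of the exact (Clopper–Pearson) interval; at $n = 100$ per
bin the two differ by under 0.02, which the tests verify. Pooling
happens at the bin level (counts summed across bees, one interval on the
pooled counts); per-bee curves can be had by subsetting the table first.

## 3. The constrained Latin-square rearrangement

Between foraging bouts the sixteen targets (four per condition) are
rearranged under three constraints: no target in its previous place, no
place holding the same condition as before, and the conditions again
forming a 4×4 Latin square. `shuffle_layout()` draws random order-4
Latin squares (row-wise rejection construction) until one is discordant
with the previous layout — different condition at every cell — which
enforces the second and third constraints directly; physical targets of
each condition are then assigned to that condition's new cells by a
random permutation, and the first constraint follows automatically
(a target's new cell holds its condition; its old cell no longer does).
A discordant Latin square always exists at order 4, so rejection cannot
stall, and acceptance is frequent enough (roughly one in four draws)
that performance is a non-issue. The test suite validates 1,000 chained
shuffles against an independent brute-force constraint checker.

## 4. Numerical and degenerate-input policy

* Rank-deficient analyzer sets, odd-dimension mosaics, missing dark
  frames, single-bee tables, negative variances and non-Latin grids are
  rejected with errors, not repaired silently.
* Degenerate pixels (zero signal, unpolarized, saturated) are flagged in
  validity masks and excluded from summaries; no NaN propagates.
* DoLP is clipped to $[0,1]$; AoP arithmetic is axial everywhere; the
  inter-ring difference at an exact tie reports $90^\circ$.
* All stochastic functions take an explicit seed and restore the
  caller's RNG state; fixed seed implies bit-identical output.

## 5. Known limitations

* The polarimetry model assumes an ideal analyzer (no diattenuation
  correction) and a linear sensor; it starts from linear single-channel
  or mosaic arrays, not camera RAW containers.
* Registration is whole-pixel translation only — adequate for
  tripod-mounted stacks, insufficient for handheld or rotating subjects.
* The Laplace approximation is a large-cluster approximation; with very
  few trials per subject a quadrature-based fit would be preferable.
* Published headline statistics from the original bee experiments derive
  from unreleased data; this package reproduces their *arithmetic*
  (deviance/AIC/χ² relationships) and their *design* (sample sizes,
  trial counts, randomization constraints), and validates its estimators
  on synthetic data with known truth.
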