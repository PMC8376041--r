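---
title: "Quantifying AP morphogen gradients: models, methods and design choices"
author: "GradQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AP morphogen gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GradQuant)
```

## The scientific problem

In the first hours of *Drosophila* development the anterior determinant is
laid down as a maternally deposited *bicoid* (*bcd*) mRNA cap at the
anterior pole, from which the Bicoid protein morphogen gradient is
translated. How far the mRNA itself spreads, how its distribution shifts
between the cortical layers, and how these change from the pre-blastoderm
cleavage cycles through the syncytial blastoderm to cellularization (cc14)
are all read out from confocal images of fixed embryos, stained for *bcd*
mRNA or for Staufen (Stau), the RNA-transport protein that accompanies it.

GradQuant implements the quantitative pipeline for such data: intensity
profiles are extracted along the anterior-posterior (AP) axis at two
cortical depths (apical, above the nuclear layer; basal, below it), each
profile is decomposed into a small sum of exponentials, and the fitted
parameters drive developmental staging, stage-prototype curves, cumulative
mass summaries, and comparisons against the classical protein-gradient
length constant. Two-dimensional structure in the same images is assessed
with 2D and shaped-2D singular spectrum analysis (SSA).

## The profile model

A profile is modelled over a stated window of percent egg length (%EL,
0 = anterior pole) as

$$I(x) \;=\; \sum_{i} C_0^{(i)} e^{\alpha_i x} \;(+\,B),$$

with one component plus flat background (`1expB`, the classical protein
parameterization), two components (`2exp`, the default for mRNA), or three
(`3exp`, whose third component is constrained to rise posteriorly,
$\alpha_3 \in (0, 0.2]$ per %EL, as seen for some Stau profiles). The
exponential base $\lambda = e^{\alpha}$ per %EL is the natural scale for
comparing steepness: $\lambda$ near 1 is a shallow gradient. Decaying
rates are bounded to $\alpha \in [-1, 0)$ per %EL; x enters as raw %EL
(not window-shifted), so $C_0$ always refers to the extrapolated x = 0
amplitude and $\lambda$ is comparable across fit windows.

After fitting, components are put in canonical order: the **anterior**
component is the decaying component with the largest contribution
$C_0 e^{\alpha\,\mathrm{lo}}$ at the window start (near-ties, within 1e-9
relative, go to the steeper rate); the remaining decaying component is
**shallow**; a rising component always ranks third. Default windows are
(10, 90) %EL for *bcd* and (10, 80) %EL for Stau, both configurable.

### Why multi-start bounded least squares

Sums of exponentials are notoriously ill-conditioned: the objective has
long curved valleys and the shallow component is barely identified when
its rate approaches zero. The fitter therefore (i) seeds from a log-linear
regression plus a log-spaced grid of rate pairs, solving amplitudes
linearly at each start, (ii) embeds the best lower-order model as an extra
boundary start — which also guarantees the SSE nesting
$SSE_{3exp} \le SSE_{2exp} \le SSE_{1expB}$ at the returned optima — and
(iii) refines each start with bounded Levenberg-Marquardt using the
analytic Jacobian (`minpack.lm`), keeping the best of all restarts
(default 8).

One numerical choice deserves emphasis: intensities are normalized to
their window maximum and quantized to seven significant digits before
optimization. Microscope data carry at most 16 bits of intensity
precision, so nothing is lost; in exchange the optimizer sees bit-identical
inputs when both layers are rescaled by a common factor, which makes the
staging features below *exactly* invariant to the arbitrary intensity
scale of an acquisition rather than approximately so. Fitted amplitudes
are mapped back to the data scale afterwards.

### Identifiability limits

The anterior rate is only as identifiable as the window lets it be. For a
steep pre-blastoderm-like regime ($\alpha_1 = -0.2$, length constant
5 %EL) the anterior component has decayed to ~13% of $C_0$ by the window
start at 10 %EL, and even maximum-likelihood fits on 2%-noise data show a
median $\lambda_1$ error of about 0.02 — an intrinsic limit, not an
optimizer defect (we verified the fitted SSE beats the truth's SSE in
every replicate). The parameter-recovery benchmarks in the test suite and
acceptance script therefore use the syncytial-blastoderm-like regime
$C = (200, 20)$, $\alpha = (-0.1, -0.01)$, representative of cc10-13 where
most embryos of such datasets lie; there the median errors are
$|\Delta\lambda_1| \approx 0.007$ and $|\Delta \ln C_1| \approx 0.07$ at
additive noise of 2% of the anterior amplitude.

## Staging features and classification

Four quantities summarise an embryo's apical/basal fit pair:

* $\lambda_1^{ap}$, $\lambda_1^{ba}$ — anterior exponential bases;
* $C^{ab} = \ln(C_1^{ap} / C_1^{ba})$ — which layer is brighter, on a log
  scale;
* the shallow ratio $(C_2^{ap}\alpha_2^{ap})/(C_2^{ba}\alpha_2^{ba})$,
  kept as a plain ratio (its sign is positive when both shallow rates are
  negative).

The stage signature is: cleavage embryos have the smallest
$\lambda_1^{ap}$ (sharp, localized anterior cap) and $C^{ab} > 0$;
syncytial-blastoderm embryos have larger $\lambda_1^{ap}$ (posterior
spreading) and flip to $C^{ab} < 0$; at cellularization $C^{ab}$ flips
back strongly positive while $\lambda$ stays high. Classification uses
standard LDA (`MASS::lda`) with empirical priors; rows lacking a shallow
component are excluded, never imputed, and counted. Should the pooled
covariance be singular, a ridge-regularized Gaussian discriminant takes
over (logged). Prediction ties are broken by the fixed label order
cleavage < syncytial < cc14.

Because the original study's per-class accuracies were estimated on an
unpublished dataset and the estimation scheme is unstated, evaluation here
reports leave-one-out by default with resubstitution also available
(resubstitution is systematically optimistic, which the test suite
verifies as a trend). Significance of group differences uses label-
permutation tests (add-one corrected), which need no distributional
assumptions at these sample sizes; the omnibus statistic is the sum over
features of the between-group sum of squares standardized by pooled
within-group variance.

## The synthetic cohort generator

No public counterpart of the study's confocal dataset exists, so the
package ships a generator whose defaults encode the stage regimes above as
distributions: per-layer two-exponential means for the three main stages
and the nine age sub-groups (CleavageEarly ... cc14late), with
between-embryo lognormal spread on amplitudes (sdlog 0.15) and Gaussian
relative spread on rates (8%), values chosen once as a realistic
between-embryo variability for this kind of FISH data. The sub-group
means interpolate the stage regimes smoothly, with $\lambda_1^{ap}$
increasing monotonically from CleavageEarly through cc13 and the
apical:basal flip placed within early cc14 (the Early1 to Early2
transition). Noise is additive Gaussian by default (sd 2 a.u. against
anterior amplitudes of 60-240 a.u.), with optional multiplicative
lognormal and baseline terms; the numeric preset means are generator
configuration, not measured values.

What passing tests on these cohorts shows — and does not show: they
verify that the estimators recover known parameters under the assumed
noise and variability structure, that the staging signal encoded in the
presets is recoverable, and that every algebraic identity holds. They do
not certify performance on real images, whose noise is neither Gaussian
nor stationary and whose segmentation is harder than a threshold.

### Synthetic images

`embryoScene()` / `renderEmbryoImage()` draw a sagittal section: an
axis-aligned ellipse with an apical cortical band (to 14 px depth) and a
basal band (14-28 px), each carrying its layer's gradient, plus optional
nuclei blobs at the nuclear-layer depth, sinusoidal cytoplasmic texture
and noise. Band intensities are a function of AP-chord %EL — the same
coordinate the extractor projects onto — rather than of arc length along
the cortex; this makes the analytic disc-average oracle exact and keeps
apical and basal profiles in one coordinate system, while dorsal/ventral
parameter asymmetry remains available for pole-through profiles. With an
integer ellipse center and semi-axes the rendered mask's AP chord is
exactly center ± a, so extraction and ground truth share the coordinate
to machine precision. The rendered image decomposes exactly (bit-for-bit)
into trend + texture + noise components, stored alongside.

## Profile extraction

Extraction follows the ROI-chain construction: the embryo boundary is
eroded inward by the layer depth (level set of the Euclidean distance
transform), the offset contour is ordered from the anterior pole
posteriorly (or ventral-pole-dorsal for full contours), ROI centers are
placed at uniform arc-length spacing, and each sample is the mean
intensity over the disc intersected with the mask. Pixel convention:
centers at integer (row, col), membership by center distance ≤ radius.
An ROI with no mask pixel yields `NA` — downstream fits skip missing
samples, never impute them. Positions are the AP-chord projection in %EL
for apical/basal chains (arc-length fraction for custom contours). The
actual depths, radius and spacing used in the original study are
unpublished; the defaults here (depths 8 and 20 px, radius 4 px, spacing
5 px at a ~220 px embryo) are package configuration.

## 2D and shaped 2D SSA

For images, the package embeds every $L_x \times L_y$ sliding window as a
column of a Hankel-block-Hankel trajectory matrix, takes its SVD, and
reconstructs grouped eigentriples by diagonal averaging (each pixel
averages the corresponding entries over all windows covering it). The
default grouping follows the cortical-signal convention: F1 (first
eigentriple) is the smooth trend, F2-F4 the mid-frequency
inhomogeneities, and the remainder noise; a w-correlation matrix is
available to justify other groupings. The *shaped* variant admits an
arbitrary mask: only window placements fully inside the mask enter the
matrix, and pixels covered by no placement are reported `NA`, never
zero-filled. On a full-rectangle mask the shaped variant reduces exactly
to the plain one.

Numerical choices: the SVD is taken directly on the trajectory matrix
(not its Gram matrix), so trailing singular values are accurate to
machine epsilon relative to $\sigma_1$ — the rank-1 property of separable
exponential images holds to ~1e-15 — and reconstruction is done by exact
accumulation rather than FFT convolution, so full-rank reconstruction
reproduces the input to ~1e-14 relative. The default window is a quarter
of the region extent per axis (the study's windows are unpublished);
windows much larger than the trend's curvature scale start mixing texture
into F1.

## Cumulative summaries and the length constant

Prototypical stage profiles average fitted parameters component-wise
(on $(C_0, \alpha)$ directly — averaging $\lambda$ or $\log C$ instead is
defensible but changes little at the observed spreads, and plain means
are the stated construction). Background handling follows the flat
hypothesis: the intensity at a posterior anchor (default 95 %EL) is
subtracted everywhere, negatives are clipped to zero with the clipped
fraction reported. The cumulative curve is the trapezoid-integrated,
total-normalized intensity mass; for a pure exponential sampled on a
uniform grid the trapezoid rule scales numerator and denominator by the
same factor, so the computed ECDF matches the closed form to machine
precision, not merely to quadrature error. Curves are compared against
the closed-form ECDF of the reference gradient (length constant
$-1/\alpha$ = 20 %EL, the standard protein value) by sup-norm distance.

## Degenerate inputs and edge rules

* All-zero or too-short windows are rejected before fitting (the
  log-linear initialization is undefined).
* A flat background can masquerade as a shallow exponential; the `2exp`
  optimum may sit at the $\alpha_2 \to 0^-$ boundary, which is exactly
  why `1expB` is retained as a diagnostic.
* Model selection prefers `2exp` unless the three-exponential fit
  converges, its third component rises with non-negligible amplitude,
  and it cuts the SSE by more than a configurable relative threshold
  (default 0.1).
* Offset depths that erode the mask away, window placements that fit
  nowhere in a shaped mask, and ellipses exceeding the image frame are
  all rejected with informative errors.

## Problem sizes used in validation

The shipped validation uses cohorts of 20 embryos per stage (60 per
classification experiment), 100-replicate parameter-recovery batches,
and 128 x 128 px images with 32 x 32 SSA windows — sizes at which every
algebraic identity can be checked exactly and the statistical checks have
comfortable margins, while a full run stays within a couple of minutes.

## Known limitations

* The stage-preset means are plausible regime encodings, not measured
  values; absolute accuracies on synthetic cohorts say nothing about the
  absolute accuracies attainable on real embryos.
* Segmentation is a threshold plus largest component — adequate for
  rendered scenes, not for debris-laden or touching embryos.
* Steep pre-blastoderm gradients fit over (10, 90) %EL carry an
  irreducible $\lambda_1$ uncertainty (see identifiability above); window
  choice matters more than optimizer effort there.
* Shaped-SSA component images are defined only where windows fit; thin
  masks (relative to the window) can leave large uncovered margins.
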