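# GradQuant

Quantification of anterior-posterior (AP) morphogen gradients in early
*Drosophila* embryos: *bicoid* (*bcd*) mRNA and Staufen (Stau) protein
intensity profiles from sagittal confocal sections, their multi-exponential
decomposition, discriminant-based developmental staging, and 2D singular
spectrum analysis of the underlying images.

## Who this is for

Groups quantifying maternal gradient dynamics from fluorescence images of
pre-cellularization embryos — or validating such pipelines — who need:

* reproducible extraction of apical and basal AP intensity profiles via
  chains of circular ROIs along offset cortical contours;
* robust decomposition of each profile into one (+ background), two, or
  three exponential components over a stated %EL window;
* staging of embryos into cleavage (cc 1–9), syncytial blastoderm
  (cc 10–13) and cellularization (cc14) from the fitted parameters;
* trend/texture/noise separation of the raw images by 2D and shaped-2D
  SSA (Hankel-block-Hankel embedding, SVD, diagonal averaging);
* a seeded synthetic-embryo generator with exact ground truth for
  end-to-end validation.

## The model

A profile over window (lo, hi) %EL is fit as

    I(x) = sum_i C0_i * exp(alpha_i * x)  (+ B),

x in %EL from the anterior pole, by bounded multi-start nonlinear least
squares. The exponential base `lambda = exp(alpha)` per %EL measures
steepness (near 1 = shallow); `-1/alpha` is the length constant. Components
are canonically ordered anterior / shallow / rising. Each embryo's
apical+basal fit pair yields the four staging features
`lambda1_apical`, `lambda1_basal`, `Cab = ln(C1_apical/C1_basal)` and the
shallow-component ratio, which feed a linear discriminant classifier;
`Cab` and the shallow ratio are exactly invariant to the arbitrary
intensity scale of an acquisition.

## Worked example

Generate a three-stage synthetic cohort, fit every profile, inspect the
stage regimes, and classify:

```r
library(GradQuant)
rec   <- generateCohort(c("cleavage", "syncytial", "cc14"),
                        nPerPreset = 12, seed = 99)
feats <- cohortFeatures(rec, restarts = 6)
aggregate(cbind(lambda1Apical, cab) ~ stage, feats,
          function(v) round(mean(v), 3))
#>       stage lambda1Apical    cab
#> 1      cc14         0.930  0.837
#> 2  cleavage         0.838  0.753
#> 3 syncytial         0.913 -0.568

evaluateClassifier(feats, feats$stage, scheme = "loo", nPerm = 199, seed = 5)
#> ConfusionMatrix (loo), n = 36, accuracy = 0.972, permutation p = 0.005
#>             cleavage syncytial cc14
#>   cleavage        12         0    0
#>   syncytial        0        11    1
#>   cc14             0         0   12
```

The feature table reads directly as biology: cleavage embryos have the
steepest apical anterior exponential (smallest `lambda1Apical`, the
compact mRNA cap) and apical brighter than basal (`cab > 0`); syncytial
embryos have spread posteriorly (`lambda1` up) and flipped basal-bright
(`cab < 0`); at cellularization the apical layer flips back on top with
`lambda1` staying high. Leave-one-out staging recovers the labels for 35
of 36 embryos, far above the 1/3 chance level (permutation p = 0.005).

A single fit, and its anterior length constant in %EL:

```r
fit <- fitProfile(rec[[1]]@apical, "2exp", window = c(10, 90))
fit
#> MultiExpFit [2exp] on window (10, 90) %EL: SSE = 188.7, n = 81
#>   anterior C0 =   117.453  alpha = -0.15215  lambda = 0.85886
#>   shallow  C0 =    12.316  alpha = -0.00710  lambda = 0.99292
lengthConstant(fit)[1]
#> [1] 6.572569
```

Cumulative curves compare a measured gradient with the classical 20 %EL
reference; for a pure exponential the two agree to machine precision:

```r
x <- seq(0, 100, 1)
curve <- cumulativeDistribution(AxisProfile(x, 100 * exp(-x / 20)))
compareToReference(curve, 20)$maxDeviation
#> [1] 2.220446e-16
```

Images: `embryoScene()` + `renderEmbryoImage()` draw a sagittal section
with exact ground truth; `embryoMask()`, `offsetContour()`,
`buildRoiChain()` and `extractProfile()` take an image back to profiles;
`ssa2d()` / `shapedSsa2d()` / `splitSignalNoise()` separate trend,
mid-frequency structure and noise.

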