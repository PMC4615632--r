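---
title: "Quantifying and classifying throat colour morphs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying throat colour morphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dragonmorph)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic-data tests do and do not show
about real measurements.

## The problem

Tawny dragon lizards (*Ctenophorus decresii*) carry four discrete throat
colour morphs — orange, yellow, grey and an orange centre surrounded by
yellow. Deciding whether such morphs are objective phenotypic classes, and
tracking how colour develops under hormonal manipulation, requires replacing
human colour judgement with instrument-based measures: spectra scored
through a model of the *lizard's* eye, photographs reduced to calibrated
colour-layer proportions, and multivariate statistics on the resulting
variables.

## Receptor-noise-limited contrast

Colour discriminability is modelled as limited by noise in the receptor
channels. For receptor class $i$ with spectral sensitivity $S_i(\lambda)$,
the quantum catch of a surface with reflectance $R(\lambda)$ under
irradiance $I(\lambda)$ is

$$q_i = \sum_{\lambda=300}^{700} R(\lambda)\, I(\lambda)\, S_i(\lambda)\,
\Delta\lambda .$$

Two stimuli $A, B$ differ in channel $i$ by $\Delta f_i = \ln(q_i^A/q_i^B)$.
With Weber-fraction noise $\omega_i$ per channel, the chromatic distance in
just-noticeable differences (JND) is the standard quadratic form that
reduces, for a dichromat, to $|\Delta f_1-\Delta f_2| /
\sqrt{\omega_1^2+\omega_2^2}$; the package implements the general
$n$-receptor form (`chromaticContrast()`), and the luminance distance as
$\Delta L = |\Delta f_{ach}| / \omega_{ach}$ (`achromaticContrast()`). One
JND is the discrimination threshold.

Parameters of the default viewer (`tawnyDragonVisualSystem()`):

| parameter | value | meaning |
|---|---|---|
| λmax (UVS, SWS, MWS, LWS) | 365, 440, 493, 571 nm | receptor peak sensitivities |
| abundance η | 1 : 1 : 3.5 : 6 | relative receptor frequencies |
| ω_LWS | 0.05 | reference Weber fraction |
| derived ω | $\omega_i=\omega_{LWS}\sqrt{\eta_{LWS}/\eta_i}$ | noise falls with channel redundancy |
| background | flat 30 % reflectance | neutral viewing background |
| grid | 1 nm, 300–700 nm | the lizard visual range |

Design choices where the underlying description is silent, made once and
documented here:

- **Sensitivity shape.** Only λmax values are reported for this visual
  system; receptor sensitivities are reconstructed with the vitamin-A1
  pigment absorbance template (Govardovskii-type α plus β band,
  `pigmentTemplate()`), peak-normalized. This is standard practice in
  lizard visual modelling.
- **Illuminant.** "Full sunlight" is represented by the CIE D65 relative
  spectral power distribution converted to quantal units
  (`d65Illuminant()`): a public, reproducible daylight reference. Chromatic
  JND is invariant to illuminant *scale* (log ratios cancel), so only the
  spectral shape matters, and any irradiance spectrum can be supplied.
- **No ocular-media correction and no von Kries adaptation.** Neither can
  be parameterized from the available description; a multiplicative
  adaptation term cancels in log catch ratios of two stimuli under one
  illuminant, so omitting von Kries scaling does not change any JND output.
- **Achromatic channel.** The luminance receptor is not named in the source
  analysis; the package uses the LWS catch with ω = 0.05 — the receptor
  whose noise anchors the model. A double-cone mechanism, if preferred, can
  be approximated by supplying a custom `visualSystem()`.
- **Integration.** Rectangle-rule summation at 1 nm (Δλ = 1), matching
  spectrometer resolution; trapezoid differences are far below every
  tolerance used in the tests.

## Calibrated image segmentation

Cameras apply a nonlinear transfer curve; lighting varies between
photographs. The pipeline therefore (i) fits, per channel, a power law
`reflectance = a · response^γ` to six grey-ramp squares of known reflectance
(log–log least squares, isotonic fallback for non-monotone inputs;
`fitLinearization()`), (ii) maps every pixel through the fitted curve
(`applyCalibration()`), (iii) rescales channels so the in-frame 30 % grey
standard reads exactly 0.30 (`equalizeToStandard()`), and (iv) classifies
throat pixels (`segmentThroat()`).

The per-pixel scores operate on luminance-normalized coordinates
$(r,g,b) = (R,G,B)/(R{+}G{+}B)$, which makes the segmentation exactly
invariant to uniform intensity rescaling:

- red when $r - g \ge 0.20$,
- otherwise yellow when $\min(r,g) - b \ge 0.15$,
- otherwise grey (the remainder class; proportions sum to 1).

The thresholds 0.20 (red) and 0.15 (yellow) are the published segmentation
settings; the conservative red threshold is what keeps orange distinct from
yellow, and red is deliberately tested first for the same reason. The exact
per-pixel score formulas of the original MATLAB scripts are not printed
anywhere, so `redness = r − g` and `yellowness = min(r,g) − b` are this
package's documented reconstruction; both the scores' thresholds and the
score functions sit behind one function boundary and can be swapped.

Numerical conventions: images are H×W×3 arrays in [0, 1] (calibrated values
clipped at 1.5 to allow specular highlights), row-major with origin top-left;
masks must match image dimensions exactly; pixels with zero channel sum have
no chromatic signal and are counted grey.

## Morph classification

`canonicalDiscriminant()` performs canonical discriminant analysis of the
seven colour variables (proportion red/yellow/grey; chromatic and achromatic
contrast of throat and bib): eigen-decomposition of $W^{-1}B$ (within- and
between-group scatter), giving min(p, g−1) = 3 canonical axes for four
morphs, per-axis shares of discriminable variance, Wilks'
$\Lambda = \prod_i (1+\lambda_i)^{-1} = \det W / \det(W{+}B)$ and Rao's F
approximation (df1 = p(g−1) = 21; df2 is reported fractional, not rounded).
`crossValidateLOO()` refits the discriminant n times, holding out one row
each time — deterministic, no randomness.

Open choices, decided as follows: **equal priors** across the four morphs
(the era-typical default of the software families used for such analyses;
proportional priors are one argument away); a **linear** rule with pooled
covariance, consistent with the canonical framing (no quadratic
discriminant); **no feature scaling**, since the analysis is affine-invariant
(verified by a property test); exact score ties broken by the fixed morph
order orange, yellow, grey, orange+yellow. Which week represents each
female's "peak colour expression" is an input (a `peak` column in the
measurement table), not recomputed.

## Hormone and time-course statistics

**Testosterone.** The repeat-sampling design (18 females sampled
pre-implant, 11 at week 1, 15 at week 4 — 44 records) is analysed as the
female-blocked additive model `testosterone ~ female + timepoint`
(`anovaTime()`), whose error df, $44 - 1 - 17 - 2 = 24$, is the only reading
consistent with the reported df pair (2, 24) despite the "one-way ANOVA"
label; the reconstruction is deliberate and documented. Pairwise timepoint
contrasts use least-squares means with Tukey–Kramer adjustment on df 24
(`pairwiseAdjusted()`), consistent with the reported adjusted p values.

**Morph frequencies.** `freemanHaltonExact()` enumerates every r×c table
with the observed margins and sums the multivariate hypergeometric
probabilities of tables no more probable than the observed one; probability
ties within 1e-12 count as "as extreme". Totals above 200 route to a seeded
Monte-Carlo mode over margin-conditional tables. On 2×2 tables the procedure
coincides with the classic two-sided Fisher test (a property verified
against `stats::fisher.test` on random tables).

**FDR.** `fdrBH()` validates and applies the Benjamini–Hochberg step-up
rule via `stats::p.adjust`.

**Colour development.** `fitTimecourse()` fits, by REML
(`lme4`), fixed effects week, week², morph, morph×week and morph×week² with
a random female intercept; morph uses sum-to-zero contrasts so each term's
Wald F is a marginal (type III) test. Denominator df is the residual
(containment-style) df $N - \mathrm{rank}(X)$ — the software defaults behind
the original tables are unknown, so exact denominator-df machinery
(Kenward–Roger, Satterthwaite) is deliberately out of scope.
`perMorphTrend()` is the within-morph follow-up (week and week² only) used
when the quadratic interaction is significant. Degenerate inputs — zero
residual variance — are refused with an explicit error rather than reported
as infinite F.

## What the synthetic generators emulate

The generators encode the study conditions so that every stage is testable
offline:

- `genReflectance()`: 1-nm spectra, 300–700 nm; orange as a sigmoidal
  long-pass (midpoint 580 nm), yellow as a long-pass (midpoint 500 nm),
  grey/cream flat; ultraviolet reflectance suppressed below the visible
  plateau; multiplicative lognormal noise. The shapes are parametric
  idealizations, not digitized curves.
- `genThroatImage()`: throat pixel counts follow the requested proportions
  exactly (largest-remainder apportionment); the scene embeds a six-step
  grey ramp and a 30 % grey standard, then applies `response =
  linear^(1/γ)` (default γ = 2.2, a typical camera transfer curve) and
  additive sensor noise (default sd 0.01).
- `genFeatureTable()`: multivariate-normal colour variables at the study's
  morph counts 10/7/7/11, morph-typical means, shared diagonal covariance
  (sd 0.08 on proportions, 1.5 JND on contrasts).
- `genHormonePanel()`: lognormal concentrations (positive, right-skewed)
  with a per-female random intercept, arithmetic means anchored at the
  reported 55.95 / 262.16 / 134.02 ng/mL, and exactly 7 week-1 and 3 week-4
  records removed so the design reproduces n = 18/11/15.
- `genTimecourse()`: quadratic mean trajectories per morph over weeks 1–6,
  10, 12 — rising curvature of proportion red for orange and orange+yellow,
  flat for yellow and grey — plus random female intercepts; effect sizes
  chosen so that the qualitative result pattern holds with high power at
  study-scale n.

What passing tests therefore show: the algebra and algorithms are correct
(closed forms, determinant identities, round trips, enumeration oracles),
and the pipeline recovers known truth under the stated noise models. What
they cannot show: behaviour under real-world complications absent from the
generators — spatially structured lighting, chromatic aberration, throat
curvature and shadow, spectrometer probe geometry, or within-female
correlation beyond a constant intercept (the true longitudinal correlation
structure of colour variables is unreported; the random-intercept default is
an assumption).

## Problem sizes and numerical tolerances

The test suite runs its simulation studies at 100 replicates for image
recovery (noise sd 0.01, tolerance 0.02 absolute on proportions), 200
replicates for mixed-model coefficient recovery (within 2 SE) and null
behaviour, and 50 random tables for the exact-test oracle — sizes chosen to
keep the whole suite under a minute while leaving the pass criteria
comfortably away from their simulation noise. Closed-form checks use
tolerances 1e-9 to 1e-12; the near-singular scatter guard in the
discriminant uses `rcond < 1e-12`; zero-variance guards use relative 1e-12.

## Known limitations

- The package deliberately models no colour space beyond the receptor-noise
  model (no tetrahedral colour space, hue or saturation metrics) and no UV
  photography: the throat colours in question have minimal UV reflectance.
- RAW camera decoding is out of scope; inputs are demosaiced rasters.
- Masks (throat, bib, grey standard) are inputs, not detected.
- Male morph counts for the sex-frequency comparison come from prior work
  and are not bundled; `runPipeline()` takes them as configuration, and the
  worked examples use a synthetic male sample, clearly labelled as such.
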