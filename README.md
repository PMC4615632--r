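# dragonmorph

Objective quantification and classification of throat colour morphs in the
tawny dragon lizard (*Ctenophorus decresii*) and similar polymorphic agamids,
for researchers studying colour polymorphism, its hormonal control and its
visual ecology.

Males of *C. decresii* express four discrete throat morphs — orange, yellow,
grey and orange+yellow — and females can be induced to express them under
experimental testosterone elevation. Confirming that such morphs are *objective*
classes, rather than observer labels, takes three quantitative ingredients,
all implemented here:

1. **Receptor-noise-limited colour contrast.** For a viewer with receptor
   classes *i* (peak sensitivities λmax = 365, 440, 493, 571 nm; relative
   abundances η = 1 : 1 : 3.5 : 6), the quantum catch of a stimulus is
   *qᵢ = Σ_λ R(λ) I(λ) Sᵢ(λ) Δλ*. Discriminability of two stimuli A, B in
   just-noticeable differences (JND) follows from the log catch ratios
   Δfᵢ = ln(qᵢᴬ/qᵢᴮ) weighted by Weber-fraction channel noise
   ωᵢ = ω_ref √(η_ref/ηᵢ), anchored at ω_LWS = 0.05. Throat and bib spectra
   are scored as chromatic (ΔS) and achromatic (ΔL = |Δf_LWS|/ω_LWS) contrast
   against a neutral 30 % grey background.
2. **Calibrated image segmentation.** Photographs are linearized against a
   six-step grey ramp (per-channel power law fitted in log–log space),
   equalized to an in-frame 30 % grey standard, and each throat pixel is
   classified from its luminance-normalized coordinates
   (r, g, b) = (R, G, B)/(R+G+B): red if r − g ≥ 0.20, else yellow if
   min(r, g) − b ≥ 0.15, else grey.
3. **Statistics.** Canonical discriminant analysis of the seven colour
   variables (three layer proportions, throat and bib chromatic/achromatic
   contrast) with Wilks' Λ = det(W)/det(W+B), Rao's F approximation and
   leave-one-out cross-validation; a female-blocked ANOVA of plasma
   testosterone with Tukey-adjusted contrasts; an exact r×c morph-frequency
   test; Benjamini–Hochberg FDR; and quadratic mixed-effects colour
   trajectories (week, week², morph and their interactions, random female
   intercept).

A seeded synthetic-data module (`genReflectance`, `genThroatImage`,
`genFeatureTable`, `genHormonePanel`, `genTimecourse`) emulates the study
conditions — four morph classes, low-UV reflectance spectra, a nonlinear
camera response, a ~5-fold testosterone surge at week 1 that partially
declines by week 4, and morph-specific quadratic colour trajectories — so
every stage can be exercised without any external data.

## Worked example

```r
library(dragonmorph)

# conspicuousness of an orange throat spectrum to the conspecific eye
s <- genReflectance("orange", seed = 42)
contrastVsBackground(s)
#> ContrastResult: chromatic 25.166 JND, achromatic 7.206 JND

# morph classification on a synthetic 35-female feature table
tab <- genFeatureTable(seed = 42)
canonicalDiscriminant(tab)
#> Canonical discriminant analysis: 4 groups, 7 features
#>   Wilks' lambda = 0.0018, F(21, 72.34) = 27.47, p = 2.29e-26
#>   % variance per canonical axis: 79.6 / 20.1 / 0.3
crossValidateLOO(tab)
#> Leave-one-out cross-validation (n = 35): overall 100.0% correct

# testosterone time course at the experiment's sampling design
anovaTime(genHormonePanel(seed = 42))
#> Testosterone time course: F(2, 24) = 26.70, p = 7.89e-07 (44 records, 18 females)
#>   timepoint   mean    SE
#> 1       pre  58.63 17.42
#> 2     week1 279.27 24.77
#> 3     week4 152.45 20.34
```

The orange spectrum sits ~25 JND from the grey background in colour — far
beyond the 1-JND discrimination threshold — while a grey throat is near 1 JND.
The four morph groups are strongly separated (small Wilks' Λ, 3 canonical
axes, df1 = 21), and the hormone design (44 records, 18 females, 3
timepoints) yields the blocked error df of 24.

`runPipeline(list(simulate = TRUE, seed = 1, outDir = "out"))` runs every
stage end to end and writes `results.json` and an echoed `config.json`.

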