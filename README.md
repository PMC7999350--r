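# phcDepth

Depth-resolved quantification of phenolic-compound (PhC) fluorescence in
leaf cross-section micrographs.

## What it is for

Leaf cross-sections stained with Naturstoff reagent A and excited with UV
light show three fluorescence colors: red chlorophyll autofluorescence
(mesophyll only), blue cell-wall/vascular autofluorescence, and yellow
flavonoid fluorescence. For researchers asking *where across the leaf
depth* phenolics accumulate — and how variety, CO2 and light regime move
that localization — `phcDepth` turns an RGB micrograph of a half-lamina
(midrib at one edge, margin at the other, adaxial side up) into five
mesophyll layer means and a full inferential analysis:

1. **Spectral separation** — hue-window segmentation in HSV: a pixel's
   brightness V = max(R,G,B)/255 is kept where hue ∈ [30°, 90°]
   (yellow), saturation ≥ 0.2 and V ≥ 0.04; red ([330°, 360°] ∪ [0°, 30°])
   and blue ([190°, 270°]) channels likewise.
2. **Leaf geometry** — the mesophyll span of each image column is its
   longest chlorophyll-positive run (the epidermis has no chlorophyll);
   columns whose span is > 15% blue are vascular and excluded, with ±3
   columns of dilation.
3. **Systematic uniform random sampling** — five vertical transects at
   stride s = W/5 with one shared offset u ~ U(0, s), giving every usable
   column equal inclusion probability (unbiased by design).
4. **Depth binning** — transect pixel i (of L) joins layer
   floor(5(i − ½)/L): AD, UM, MM, LM, AB from the adaxial to the abaxial
   boundary; unweighted averaging over 5 transects × 3 sections gives one
   profile per biological replicate.
5. **Statistics** — four-way fixed-effects ANOVA
   (Var × CO2 × Light × Loc), Fisher's LSD letters at α = 0.05, and a
   surface-dominant / lower-mesophyll-dominant / flat pattern call.

A synthetic-micrograph generator with analytic ground-truth gradients
g(d) = s·[b + A_ad e^(−d/λ) + A_ab e^(−(1−d)/λ) + B e^(−(d−0.7)²/2w²)]
(d = relative depth) and a piecewise-linear diurnal light model validate
the whole pipeline by parameter recovery.

## Worked example

```r
library(phcDepth)

t0  <- treatmentLabel("BARKE", "LC", "HL")    # variety, CO2, light
sec <- renderSection(t0, seed = 42)           # synthetic section, known truth
prof <- profileSection(sec@image, seed = 42)  # the full image pipeline
prof
#> SectionProfile over 5 transects | BARKE LC HL rep 1 sec 1
#>     AD     UM     MM     LM     AB
#> 0.2638 0.1687 0.1400 0.1515 0.2033

round(depthMeans(layerTruth(sectionTruth(sec))), 4)
#>     AD     UM     MM     LM     AB
#> 0.5261 0.3164 0.2699 0.2907 0.4219

classifyPattern(prof)
#> [1] "SURFACE_DOMINANT"
cor(depthMeans(prof), depthMeans(layerTruth(sectionTruth(sec))))
#> [1] 0.9939437
```

The recovered profile tracks the analytic layer truth (r = 0.994) with
the expected uniform factor ≈ ½ from the generator's chlorophyll/PhC row
interleave (see the methods vignette): a high-light leaf peaks in the
adaxial layer, dips mid-leaf, and rises again abaxially. The diurnal
model reproduces the cultivation light integrals exactly:

```r
dailyIntegral(lightRegime("HL")$par)
#> [1] 54      # mol m-2 day-1; LL gives 14.4
```

Batch interface (also exposed by `inst/scripts/phcdepth.R` as a
`simulate | profile | analyze` command line):

```r
man  <- runSimulate("images", nReplicates = 6, seed = 1)   # 216 TIFFs + truth
prof <- runProfile(man, "profiles", seed = 1)              # tidy layer CSVs
res  <- runAnalyze("profiles/replicates.csv", "analysis")  # ANOVA + LSD + patterns
```

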