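# echorestore

Restoration of echocardiographic (ultrasound) images by sample-block
matching, and the accompanying biomarker cutoff statistics for studies of
patent ductus arteriosus (PDA) in preterm infants.

Echocardiography is the reference standard for detecting a patent arterial
duct, but the images are degraded by multiplicative speckle, and clinically
acquired frames often contain regions (dropout, shadowing, annotation burn-in)
that must be repaired before quantitative reading.  `echorestore` provides
the two image-processing stages and the downstream statistics in one
package:

1. **Multi-scale edge-preserving smoothing.**  A Gaussian pyramid
   {G<sub>l</sub>} of the image *I* fixes, at every scale and position, a
   reference coefficient *g*.  The input is remapped point-wise through

   r(i) = i − m<sub>f</sub> (i − g) exp(−(i − g)² / 2σ<sub>r</sub>²),

   which pulls intensities within ≈ σ<sub>r</sub> of *g* (speckle, fine
   texture) toward *g* while leaving genuine contours (|i − g| ≫
   σ<sub>r</sub>) untouched.  The level-*l* Laplacian coefficient of each
   remapped image is collected into an output pyramid {L<sub>l</sub>},
   which is collapsed via G<sub>l</sub> = L<sub>l</sub> + u(G<sub>l+1</sub>).
   The contour threshold can adapt per pixel: σ<sub>ra</sub> =
   σ<sub>0</sub> V̄/(V̄ + V) is inversely related to the local variance
   V of the image, so flat regions are smoothed hard and busy regions
   gently.  The difference T = I − S between the input and the smoothed
   image S is the texture component; S is the structure component.

2. **Structure-guided exemplar inpainting.**  Masked regions are repaired
   by greedy block matching: front pixels are ranked by priority
   P(p) = C(p)·D(p), where C is patch confidence and the data term
   D = |∇<sup>⊥</sup>S·n| is the isophote strength of the *structure*
   component across the fill front, so restoration proceeds along the main
   anatomical contours first.  The best source block minimises the
   masked sum of squared differences (point-wise product with the
   known-pixel indicator) over all fully-known blocks.

3. **Biomarker statistics.**  Wilcoxon rank-sum comparison (normal
   approximation without continuity correction, exact enumeration at small
   n), chi-square/Fisher 2×2 tests, bivariate correlation, and ROC analysis
   with the Youden index J = sensitivity + specificity − 1 selecting the
   best cutoff — the pipeline used to evaluate serum NT-proBNP (pg/mL) as
   an early predictor of symptomatic PDA against echocardiographic indices
   (duct diameter, LA/AO ratio).

Because no imaging or patient data are deposited with such studies, the
package ships generators for both: speckled phantoms with known ground
truth (`make_phantom()`), and two-group lognormal biomarker cohorts with a
Gaussian-copula dependence structure calibrated to published group moments
and rank correlations (`generate_cohort()`).

## Worked example

```r
library(echorestore)

# a speckled two-tone phantom with a hole straddling the boundary
ph <- make_phantom(phantom_spec(
  size = c(64, 64), scene = "step", tones = c(0.25, 0.75),
  speckle_shape = 25, seed = 7,
  hole = list(type = "rect", row = 28, col = 28, height = 10, width = 10)))
damaged <- ph$image
damaged[ph$mask] <- 0

# edge-preserving smoothing + structure/texture split
cfg <- filter_config(n_levels = 3, base_sigma = 0.15, base_mf = 1, adaptive = TRUE)
dc <- decompose(damaged, cfg)
sd(dc$texture)
#> texture sd: 0.0197 (speckle captured by the residual)

# structure-guided block-matching repair
repaired <- inpaint_image(damaged, ph$mask, k = 4, cfg = cfg)
mean(abs(repaired[ph$mask] - ph$truth[ph$mask]))
#> mean abs error inside the hole: 0.0716

# synthetic biomarker cohort at the study's group sizes (aPDA 56 / PDA 13)
cohort <- generate_cohort(cohort_spec(seed = 1))
pda <- as.integer(cohort$group == "PDA")
wilcoxon_rank_sum(cohort$ntprobnp_d3[pda == 0], cohort$ntprobnp_d3[pda == 1])
#> day-3 rank-sum Z = -4.895 (p = 9.8e-07)
roc_analysis(cohort$ntprobnp_d3, pda)
#> <ROC: AUC 0.938; cutoff 1.701e+04 (sens 92.3%, spec 87.5%)>
cor(cohort$ntprobnp_d3, cohort$duct_diameter, method = "spearman")
#> day-3 NT-proBNP ~ duct diameter: r_s = 0.818
```

The texture standard deviation shows how much speckle the decomposition
moved out of the structure image; the hole error is measured against the
known clean scene; and the cohort statistics illustrate the full biomarker
pipeline — a strongly negative Z (aPDA ranks far below PDA), a high AUC
with its Youden-optimal cutoff in pg/mL, and a strong positive rank
correlation between the day-3 biomarker and duct diameter, as built into
the generator's calibration.

A command-line front end with `filter | decompose | inpaint | phantom |
stats` subcommands is installed at `inst/cli/echorestore`.

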