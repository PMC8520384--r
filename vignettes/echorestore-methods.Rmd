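---
title: "Multi-scale restoration of ultrasound images and biomarker cutoff statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale restoration of ultrasound images and biomarker cutoff statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echorestore)
```

This vignette is the package's own account of its models and the choices
behind them: what is computed, under which assumptions, with which defaults,
and where the design was genuinely open.

## 1. Pyramids

`build_gaussian_pyramid()` blurs with the separable 5-tap binomial kernel
[1, 4, 6, 4, 1]/16 and decimates by keeping every other sample starting at
the first, so level $l{+}1$ has $\lceil n/2 \rceil$ samples — the rule that
keeps arbitrary (odd) image sizes well defined.  `build_laplacian_pyramid()`
stores $L_l = G_l - u(G_{l+1})$ with $u$ the zero-insertion upsampler
convolved with twice the same kernel, cropped to the finer level's exact
size; the coarsest level is the Gaussian residual.  Because
`collapse_laplacian()` adds back *the same* $u(G_{l+1})$ that was
subtracted, reconstruction is exact to round-off for every size — the test
suite checks `< 1e-10` over random images from 8 to 64 px.

Boundaries use reflect-101 (mirror about the edge sample, no duplication).
This is the one mirror variant for which the zero-inserted upsampling grid
still preserves constants at the borders: the odd- and even-phase tap sums
of the doubled kernel are each 1, and reflect-101 continues the alternating
sample/zero pattern correctly across the edge.  Edge-repeat mirroring does
not (it darkens borders), which matters on echo images whose sector borders
are already dark.  A constant image therefore has exactly zero band energy
at every level.

## 2. Point-wise remapping and the adaptive fields

The smoothing primitive is the detail-attenuation map
$$r(i) = i - m_f\,(i-g)\,e^{-(i-g)^2/2\sigma_r^2},$$
fixed point at the Gaussian reference $g$, identity for $m_f = 0$, and
asymptotically the identity as $|i-g| \to \infty$.  Its deviation from the
identity is bounded by $m_f \sigma_r e^{-1/2}$ (maximum at $|i-g| =
\sigma_r$) and by $m_f\,5\sigma_r e^{-12.5} \approx 1.9\times10^{-5}
m_f\sigma_r$ beyond $5\sigma_r$ — the quantitative sense in which contours
are preserved while detail is flattened.

The contour threshold can adapt to the local activity of the image.
`local_variance()` is the population variance over a mirror-padded
$(2k{+}1)^2$ window (population rather than sample: it is a deterministic
window statistic, directly checkable against a double-loop oracle), and
`adaptive_fields()` maps it through the saturating inverse
$$\sigma_{ra}(p) = \sigma_0\,\frac{\bar V}{\bar V + V(p)}, \qquad
  m_{fa}(p) = m_0\,\frac{\sigma_{ra}(p)}{\sigma_0},$$
with $\bar V$ the image-mean variance plus $10^{-12}$.  A plain reciprocal
$1/V$ blows up on flat regions; the rational form is bounded by $\sigma_0$,
halves exactly at $V = \bar V$, and is strictly decreasing in $V$.  Tying
$m_{fa}$ to the same profile keeps a single knob: both the threshold and
the strength of smoothing back off together where the image is busy
(contours), which is the intended inverse relation between smoothing and
local change.  The alternative — increasing $m_{fa}$ with variance — would
smooth contours hardest, defeating the purpose.

## 3. The multi-scale filter

The reference semantics are exhaustive: for every band level $l$ and
position, remap the full input around $g = G_l[x,y]$ (with per-level
$\sigma_r$, $m_f$ read from the adaptive fields where enabled), build the
remapped image's Laplacian pyramid, and keep its level-$l$ coefficient at
$(x,y)$; the coarsest Gaussian residual is copied unchanged and the output
pyramid collapsed, clipping to $[0,1]$ because remapping can overshoot the
nominal range.  This reference is implemented in plain R and kept for
small inputs and tests.

The default `method = "window"` path (compiled) evaluates each coefficient
on the sub-window of the input that can influence it: each blur–decimate
step has a 5-tap footprint, so a radius of $10\cdot2^l + 4$ full-resolution
pixels is sufficient for band $l$; the window start is snapped to the
$2^{l+1}$ decimation lattice so sub-window and full-image sample grids
coincide, and windows clipped at a true image border reproduce the
full-image mirror padding exactly.  The two paths agree to $10^{-10}$ on
random images (both parities, adaptive and fixed parameters) — one of the
test suite's equivalence checks.  Adaptive fields are computed once at full
resolution and brought to each level by $2\times2$ block means, since
nothing fixes the scale at which the variance rule should apply; computing
them per level from decimated images would couple the parameter fields to
the pyramid's own smoothing.

Defaults: `n_levels = 3`, $\sigma_0 = 0.15$ (a mid-range contour scale for
luminance in $[0,1]$: speckle excursions on echo images are typically well
under 0.15 while chamber/wall contrasts exceed it), $m_0 = 1$ (full
smoothing; set 0 for the identity), variance half-width `k = 2`.
`decompose()` returns the filtered image as structure $S$ and the exact
residual $T = I - S$, so additivity is definitional ($<10^{-12}$).

## 4. Inpainting

`inpaint_image()` is greedy exemplar fill with the data term computed on
the structure component.  Priorities are $P(p) = C(p) D(p)$: $C$ the mean
confidence over the in-image part of the $(2k{+}1)^2$ patch (known pixels
start at 1, unknown at 0, filled pixels inherit the confidence of the step
that filled them), and $D = |\nabla^\perp S \cdot n| + \varepsilon$ with
the isophote taken on $S$ by central differences and the front normal from
central differences on the mask.  $\varepsilon = 10^{-3}$ keeps flat
regions fillable (otherwise their priority would be exactly zero and the
ordering among them undefined).

Two choices deserve explanation:

* **Harmonic initialisation of the hole.**  The content inside the masked
  region is arbitrary (dropout, annotation, zeros), and any gradient it
  induces in $S$ would corrupt the guidance.  The region is therefore
  relaxed to the harmonic (Laplace) interpolant of its boundary before the
  structure component is extracted.  Guidance then responds to the
  surrounding scene — an edge entering the hole continues to attract the
  front — while the copied pixel values still come exclusively from
  never-masked source blocks, so the initialisation never leaks into the
  output values.
* **Matching on intensity, not on $S$.**  The block SSD is computed on the
  working image over the target's known pixels only (point-wise product
  with the known indicator), with ties broken by scan order (smallest row,
  then column) for determinism.  Matching on $S$ would select sources with
  the right geometry but arbitrary texture; matching on intensity
  preserves speckle statistics in the fill.  Source candidates are all
  fully-known blocks in the whole image — no search window, as none is
  specified for the method — and a target patch with no known pixels
  (possible deep inside a large hole) is given SSD 0 against every
  candidate, deterministically returning the scan-order first.

Each iteration fills at least one pixel, so the loop terminates in at most
$|\Omega|$ steps; known pixels are never rewritten (checked bitwise), and
because fill is copy-only the output range is contained in the observed
source range.  Default patch half-width `k = 4` (9×9 blocks): large enough
to carry the two-tone context of a chamber boundary, small enough that a
64² image offers thousands of candidate blocks.

## 5. Phantoms

`make_phantom()` degrades a clean piecewise scene (step, elliptic
"chambers", checkerboard) with unit-mean gamma multiplicative speckle
(shape = number of looks; 9–25 spans visually realistic B-mode speckle)
followed by additive Gaussian noise, clipped to $[0,1]$.  This is the
standard desk-scale ultrasound surrogate: it reproduces the
signal-dependent, multiplicative character of speckle but **not** the
spatial correlation of a real point-spread function, the log-compression
of clinical scan converters, or anisotropic shadowing.  Tests passing on
these phantoms therefore demonstrate the algorithmic properties (edge
preservation, guided fill, oracle equivalence), not clinical-grade
performance on scanner data.

## 6. Biomarker statistics

`wilcoxon_rank_sum()` uses mid-ranks, the tie-corrected variance, and
$Z = (W-\mu_W)/\sigma_W$ with no continuity correction, matching the SPSS
convention of reporting a signed Z for the rank-sum comparison; with
$N \le 12$ and no ties it also enumerates all $\binom{N}{n_1}$ assignments
for an exact two-sided p.  The exhaustive enumeration shows the normal
approximation's worst-case gap from the exact p at $n = 8,7$ is just over
0.05 at a single central lattice value while the distribution-averaged gap
is an order of magnitude smaller — the tests assert the latter and the
shrinkage of the worst case with $N$.  `fisher_exact_2x2()` sums
hypergeometric masses not exceeding the observed table's, and
`group_count_test()` applies the usual switch: Pearson chi-square without
continuity correction when all expected cells are ≥ 5, Fisher otherwise.
`roc_analysis()` calls a subject positive when score ≥ threshold, computes
the empirical curve over all distinct thresholds, AUC by trapezoid
(verified in tests against brute-force pairwise concordance, ties counted
half), and picks the cutoff maximising Youden's $J$ with ties resolved
toward higher specificity — when two cutoffs discriminate equally, the
cheaper error for a screening biomarker is the false positive, which a
higher-specificity cutoff avoids.

## 7. The cohort generator

`generate_cohort()` draws, per group, a latent multivariate normal with
correlation matrix $R$ and pushes each coordinate through a lognormal
marginal.

* **Marginals.**  Biomarker levels are positive and strongly right-skewed
  (group SDs of the same order as the means), so lognormal with
  closed-form moment matching: $\sigma^2 = \log(1 + (s/m)^2)$, $\mu =
  \log m - \sigma^2/2$.  Quoted "mean ± x" cells are interpreted as mean ±
  SEM — the usual convention alongside rank-sum Z statistics — so the
  marginal SD is $x\sqrt{n_{\mathrm{ref}}}$ with $n_{\mathrm{ref}}$ the
  *source* group size (56 / 13), regardless of how many subjects are
  generated; `se_is_sem = FALSE` switches to reading them as SDs.
  Echocardiographic indices have no published moments; the defaults place
  the symptomatic group above the diagnostic thresholds (duct > 1.5 mm,
  LA/AO > 1.3) and the asymptomatic group below: duct 1.8 ± 0.5 vs
  2.5 ± 0.6 mm, LA/AO 1.2 ± 0.15 vs 1.5 ± 0.2.
* **Dependence.**  The copula is calibrated to *rank* (Spearman)
  correlations via $\rho_{\mathrm{latent}} = 2\sin(\pi r_s/6)$.  Rank
  correlations are invariant under the monotone marginal transforms, so
  recovery is marginal-free; a product-moment target, by contrast, is not
  even attainable for every $r$ under heavy-tailed lognormals (for the
  asymptomatic day-3 marginal the maximal Pearson correlation with a
  near-normal index is ≈ 0.83 < 0.856), and its sample estimate at
  $n = 10^4$ still fluctuates by several hundredths.  Published targets:
  day-3–diameter 0.856, day-5–diameter 0.528, day-5–LA/AO 0.721.  The
  three unpublished pairs are fixed once at day-3–day-5 0.60,
  day-3–LA/AO 0.62, diameter–LA/AO 0.68 — plausible within-subject
  couplings chosen so the joint latent matrix is positive definite
  (smallest eigenvalue 0.10); the generator refuses non-positive-definite
  target sets rather than silently projecting them.
* **Determinism.**  All draws run under the spec's seed with the caller's
  RNG state restored, so generation is a pure function of the spec.

Generated cohorts at the study's own sizes (56/13) yield strongly negative
rank-sum Z and AUCs in the 0.9 range, as the calibration implies; the
published patient-level estimates (AUC 0.949, cutoff 6411 pg/mL — 27035
pg/mL in the same study's abstract — Z −5.018/−4.742) derive from
unpublished raw data and are deliberately not treated as reproduction
targets.  Both quoted cutoffs are simply admissible points on synthetic
ROC curves; the generator takes no side on which is correct.

## 8. Problem sizes and limitations

The test suite and the acceptance script run at the sizes the properties
are stated at: 100 random pyramids up to 64 px, the filter phantom at
128², inpainting at 64² with 9×9 patches and 50 oracle instances at 20²,
200 random ROC cohorts (n ≤ 30), and generator recovery at 10,000 subjects
per group — small enough to re-run in minutes, large enough that the
Monte-Carlo tolerances (3 SE on means, ±0.03 on rank correlations) are
meaningful.  Known limitations: grayscale 2-D only (no cine loops, DICOM,
or color Doppler); the exhaustive filter reference is quadratic per level
and intended for ≤ 32² inputs; exemplar fill searches all candidate blocks
(no approximate nearest neighbour), so very large holes in very large
images are slow; and the phantom and cohort generators emulate published
summary statistics, not patient-level data.
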