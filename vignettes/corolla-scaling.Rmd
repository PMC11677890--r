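---
title: "Measuring petals and modelling corolla-area scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring petals and modelling corolla-area scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalmetry)
library(dplyr)
```

## The problem

Petal area is the natural measure of petal size, and the summed petal
area of a flower — the corolla area — is a proxy for flower size, which
matters for pollinator attraction and reproductive investment. Planimetric
measurement (scanning every petal and counting pixels) is accurate but
destructive and slow. Allometric shortcut models estimate area from two
ruler measurements instead:

* **Montgomery equation (ME)**, per petal: $A = k\,L W$, where $L$ is the
  petal length, $W$ the maximum width perpendicular to the length axis,
  and $k$ a dimensionless proportionality coefficient ($\pi/4$ for an
  ellipse, $1$ for a rectangle; leaves typically fall between $1/2$ and
  $\pi/4$).
* **Montgomery–Koyama–Smith equation (MKSE)**, per flower:
  $A_T = k_{KS}\, L_{KS} W_{KS}$, where $A_T$ is the total petal area of
  the flower, $L_{KS}$ the *sum* of its petals' widths and $W_{KS}$ the
  *maximum* petal length. The naming follows the foliage-per-shoot
  analogy: petals laid side by side form a strip of length $\sum W$ and
  depth $\max L$.
* **Power-law equation (PLE)**: $A_T = \beta\,(L_{KS} W_{KS})^{\alpha}$,
  which relaxes the MKSE's isometry; $\alpha = 1$ recovers the MKSE
  structure, so the PLE nests the MKSE.

This package implements the full chain: silhouette image → boundary
polygon → $(A, L, W)$ → per-flower $(A_T, L_{KS}, W_{KS})$ → fitted and
compared models, plus a synthetic generator so the chain can be validated
end-to-end with known ground truth.

## Fitting and model choice

All models are fitted by ordinary least squares after natural-log
transformation, which stabilises the multiplicative error variance of
area measurements. For the ME and MKSE the slope is fixed at 1, so the
single parameter is the intercept, estimated as the mean log ratio:
$\hat a = \overline{\ln A - \ln LW}$ and $\hat k = e^{\hat a}$ (no
bias-corrected back-transform is applied; the coefficient is interpreted
on the natural scale as the geometric-mean area ratio). Goodness of fit
is the log-scale RMSE with divisor $n$ (not $n - p$), matching the ML
variance; AIC is $2p - 2\log\mathcal L$ with
$\log\mathcal L = -\tfrac n2(\ln 2\pi + \ln(\mathrm{rss}/n) + 1)$ and
$p$ = regression parameters + 1 for the error variance (so $p = 2$ for
ME/MKSE, $p = 3$ for PLE). No small-sample correction (AICc) is applied.

Because the PLE nests the MKSE, its RMSE can never be larger; the extra
parameter is accepted only when the percent error
$\mathrm{PE} = (\mathrm{RMSE}_{MKSE} - \mathrm{RMSE}_{PLE}) /
\mathrm{RMSE}_{MKSE} \times 100\%$ exceeds 5%. A tie at the threshold
goes to the simpler model. The decision trace also records both AICs and
whether the PLE slope's 95% CI contains 1, which reads directly as
"isometric scaling is (not) tenable".

Confidence intervals are nonparametric case-resampling bootstrap
percentile intervals (default $B = 3000$ replicates, seed mandatory).
Case resampling with percentile bounds was chosen as the least
assumption-laden scheme: residual resampling would presume the fixed-x
design is meaningful, which it is not for field-collected flowers. On
zero-noise data the interval collapses to the point estimate.

```{r fits}
sim <- generate_dataset(seed = 42)
petals_ob <- filter(sim$petals, species == "obovate")
fit_montgomery(petals_ob, bootstrap = 500, seed = 1)

flowers_no <- filter(sim$flowers, species == "notched")
mkse <- fit_total_area_model(flowers_no, "MKSE")
ple <- fit_total_area_model(flowers_no, "PLE", bootstrap = 500, seed = 1)
select_model(mkse, ple)
```

## Measurement conventions

`trace_boundaries()` labels 8-connected foreground components
(8-connectivity avoids splitting thin petal tips), drops components below
100 px (a scanner-noise filter, configurable), and contours each
component's 0/1 grid at level 0.5 by marching squares, giving sub-pixel
vertices at the midpoints between foreground and background pixel
centres. Only the outer contour is kept — petal silhouettes are simply
connected, so interior holes are treated as scanning artefacts.
Coordinates become physical units via $2.54/\mathrm{dpi}$ cm per pixel,
with y increasing upward. Components touching the image border are
returned but flagged, since their outlines may be clipped.

`measure_petal()` needs a length-axis convention. The default
(`axis_spec("principal")`) takes the major principal axis of the
outline's second area moments; `axis_spec("landmarks", base, apex)` is
available when the symmetry axis is known. On near-symmetric shapes the
two agree; the principal axis requires no landmarks, which is why it is
the default. $L$ is the outline's extent projected on the axis and $W$
the maximum perpendicular caliper extent (not the width at mid-length —
the two conventions cannot be distinguished from published summary
statistics, so the geometrically simpler one was chosen and is stated
here). Because $L$ and $W$ are orthogonal extents of the same outline,
$A \le L W$ holds for every petal, so per-petal Montgomery ratios lie in
$(0, 1]$, and after aggregation $A_T \le L_{KS} W_{KS}$ per flower. For
an apex-notched petal the axis runs through the notch and no correction
is applied; the measured envelope then understates the lobes' outline,
which is precisely the mechanism that pushes notched species toward
larger fitted $k$.

Degenerate cases: polygons with fewer than 3 distinct vertices or zero
signed area are rejected at construction; isotropic second moments (e.g.
a square) trigger a warning and a fall back to the longest-diameter
axis; coincident landmarks are an error.

## What the generator emulates — and what it does not

`generate_dataset()` draws two species-like populations whose *structure*
mirrors a two-species flower collection:

* **obovate** preset: 60 flowers, 11–12 narrow obovate petals each
  (≈ 690 petals), half-width profile $f(t) = t^{p_1}(1-t)^{p_2}$ with
  $p_1 = 1.4 > p_2 = 0.8$ (widest towards the apex), mean $W/L = 0.55$,
  no notch, log-area noise $\sigma = 0.037$.
* **notched** preset: 63 flowers, exactly 5 broad rounded petals each
  (315 petals), $p_1 = p_2 = 0.9$, mean $W/L = 0.90$, apex notch of
  depth $0.05\,L$, $\sigma = 0.047$, and a size–shape drift of $-0.1$
  so the corolla-level exponent is $\alpha = 0.9$ (large flowers have
  proportionally less petal area), exercising the regime where the PLE
  beats the MKSE.

Flower sizes are lognormal (sdlog 0.12/0.10) while petals within a
flower vary only a little (sdlog 0.04) — flowers differ in size far more
than their own petals do. Petal count totals, flower counts, petal-scan
noise magnitudes and the 600 dpi default raster resolution are chosen to
match the sampling scale typical of this kind of field study; the shape
parameters and $W/L$ targets are illustrative, not measurements of any
real species. The generator does **not** attempt real trait
distributions, petal overlap, curvature out of plane, or scanning
artefacts (JPEG noise, shadows), so green tests certify the computational
chain, not the field protocol.

Each petal's noise-free area is computed from its constructed outline,
so the true per-species $k$ is the shape-determined ratio $A/(LW)$ of
the outline family (exact for this family, since area is bilinear in
$L$ and $W$). With $\sigma = 0$ the fits recover it to $10^{-6}$. For
parameter-recovery and bootstrap-coverage simulations, where the
corolla-level estimand must be known in closed form,
`simulate_flower_summaries()` imposes the MKSE exactly at flower level.

One honest subtlety: even with drift 0, the estimated corolla exponent
sits slightly below 1, because $W_{KS}$ is a maximum statistic — flowers
whose longest petal fluctuates high get a high $L_{KS}W_{KS}$ without a
matching $A_T$. This attenuation is intrinsic to the KS construction
under within-flower heterogeneity, and is visible in real datasets too;
it is one reason the PLE can win on species whose petal number or shape
varies more.

## Numerical choices

* Natural logarithms throughout; correlation and the PLE exponent are
  base-invariant, and $\hat k$ is recovered by `exp()` of the intercept.
* The apex notch is built by truncating the half-width profile at
  $t = 1 - d$ (rescaled so the lobe tips still reach $x = L$) and
  cutting an inward wedge to $(L(1-d), 0)$; the axis extent stays
  exactly $L$ while the wedge's area is removed.
* Rasterization marks pixels whose centres fall inside the polygon
  (even-odd scanline rule). The rasterize → trace → measure loop closes
  within 1% at 600 dpi for petal-like shapes with tip exponents near 1;
  strongly cuspy tips ($p \gg 1$) lose sub-pixel-wide tip length and
  need higher dpi. The error decreases monotonically with dpi.
* Tukey HSD uses the studentized-range distribution on the one-way
  layout (Tukey–Kramer for unequal group sizes), on raw trait scales.
  Compact letters are assigned greedily in descending-mean order.
  Petals are treated as independent observations even though petals of
  one flower are correlated — a deliberate simplification, flagged as a
  caveat, matching how such trait panels are usually reported.

## Problem sizes used in validation

The test-suite simulations use the study-scale defaults above (60 + 63
flowers, ≈ 1000 petals), 200-replicate recovery runs at $n = 60$ flowers
and $\sigma = 0.03$, 1000–3000 bootstrap replicates, 50-outline raster
round-trips at 600 dpi, and a $10^6$-point Monte-Carlo area oracle —
sizes at which every estimate under test is stable to well inside the
asserted tolerances.

## Known limitations

* No grayscale thresholding or artefact cleanup: inputs must already be
  binary silhouettes.
* Width is the maximum caliper width; studies that measured width at a
  fixed station along the axis will differ for asymmetric shapes.
* The HSD panel ignores flower-level clustering of petals; a
  mixed-effects extension is out of scope.
* No reduced-major-axis fitting and no heteroscedasticity-robust errors;
  the OLS-on-logs convention is standard for these models.
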