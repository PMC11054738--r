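---
title: "Hue-spectrum fingerprinting with PQS compression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hue-spectrum fingerprinting with PQS compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huePQS)
```

This vignette is the package's own account of the science it
implements: the measurement models, the tunable parameters and their
defaults, what the synthetic study generator does and does not emulate,
and the numerical and design choices made where more than one
reasonable option existed.

## 1. The measurement models

### Hue spectrum

A fruit photographed on a white background is converted to HSV (hexcone
model; hue in degrees, saturation scaled 0–100%). Every pixel of the
segmented fruit region contributes its *saturation* to the 1° bin
containing its hue, so the spectrum weights colors by their vividness
rather than counting them. This is what makes the fingerprint robust on
a white stage: gray background and specular glare have saturation near
zero and are doubly suppressed — first by the saturation threshold,
then by the weighting itself.

Binning is circular (bin 359 is adjacent to bin 0), so red mass
spanning the 0°/360° wrap is handled without splitting the red peak.
Spectra are used unsmoothed. Two normalizations are carried:
`raw_sum` (bin masses; their total equals the total ROI saturation
exactly, which the tests exploit as a conservation law) and
`per_pixel` (mean saturation per ROI pixel), the default for any
between-frame comparison because it removes the confound between fruit
size and spectral amplitude.

### PQS gravity point

The spectrum is read as a polar curve $r(\theta)$ and compressed to the
area centroid of the enclosed region, summed per sector of width
$\Delta\theta$:

$$A = \tfrac12 \sum_i r_i^2 \Delta\theta, \qquad
X = \frac{1}{3A}\sum_i r_i^3 \cos\theta_i \Delta\theta, \qquad
Y = \frac{1}{3A}\sum_i r_i^3 \sin\theta_i \Delta\theta .$$

These sums are the *exact* centroid of the piecewise-constant polar
region, which gives three independent analytic anchors used by the
tests: a constant spectrum maps to the origin; a half-disk maps to
$(4r/(3\pi), 0)$; a single 1° sector maps to
$(2r/3)(\cos\theta_c, \sin\theta_c)$ exactly. A Monte-Carlo centroid
(`gravityPoint()` vs `gravityPointMC()`) provides an
implementation-independent cross-check: both describe the same region,
so the closed form must sit within sampling error of the rejection
estimate.

Because the radius enters cubically in the numerator and quadratically
in the denominator, the gravity point is homogeneous of degree one in
the spectrum ($k\,r \mapsto k\,(X,Y)$) and strongly dominated by the
tallest, narrowest peak. Two consequences matter for interpretation:
the `per_pixel` scaling must be used before PQS (otherwise fruit area
masquerades as color), and a vivid narrow peak at small hue can carry a
*larger* Y than a dull broad peak at large hue even though
$\sin\theta$ is smaller — which is exactly how ripening, which both
reddens and vivifies the surface, can move the gravity point outward in
both coordinates at once.

An optional `hueRange` arc restricts the sums, implementing the
trimming of indifferent hue segments; the default is the full circle.

### Reference instrument indices

* **DA-index** $I_{AD} = A_{670} - A_{720}$: the absorbance difference
  between the chlorophyll-a peak and a reference wavelength, a proxy
  for photosynthetically active chlorophyll. It decays toward zero as
  ripening progresses and cannot go below zero in tissue, though the
  pure instrument difference can; readings outside the nominal 0–5
  instrument range are flagged, never clamped, so the index stays an
  exact difference (and antisymmetric in its arguments).
* **Acoustic firmness** $S = f^2 m^{2/3}$ from the resonance frequency
  $f$ (Hz) and mass $m$ (g) of an impacted fruit. With $f$ in Hz the
  raw product sits near $10^5$–$10^6$ for plausible tomato resonances,
  while practitioners report single digits in $g^{2/3}s^{-2}$; an
  instrument scale factor (default $10^{-6}$, equivalent to quoting $f$
  in kHz) maps the formula onto the conventional reporting band without
  altering it. The scale is configurable.

## 2. The statistical layer

* **Factorial ANOVA.** Fixed-effects linear model over maturity group,
  treatment and storage day with all pairwise interactions and no
  three-way term (the shipped design; 2–3 factors and explicit
  interaction lists are supported). Sums of squares are Type III with
  sum-to-zero contrasts — the SPSS default, hence the routing most
  comparable with published group tables. Each term's SS is computed
  directly as the residual-SS increase from dropping the term's
  columns from the full model, which stays well defined for degenerate
  inputs: a constant response reports $F = 0$, a perfect noise-free
  fit reports $F = \infty$ with $p = 0$. Interactions with empty
  design cells abort with the offending cell named — which is why
  treatment models exclude the never-treated fully-ripe control group.
* **Levene routing.** Classic Levene (absolute deviations from the
  group mean; median optional) decides the post hoc route at
  $\alpha = 0.05$: Tukey HSD under homogeneous variances, Games–Howell
  otherwise.
* **Games–Howell.** Welch-type pairwise statistics
  $t = |m_i - m_j| / \sqrt{s_i^2/n_i + s_j^2/n_j}$ with
  Welch–Satterthwaite degrees of freedom, referred to the studentized
  range as $q = t\sqrt2$. The summary-statistics interface (mean, SD,
  n per level) exists so letter displays can be checked directly
  against published group tables. For two groups with equal sample
  variances and sizes Games–Howell and Tukey coincide exactly, a
  reduction the tests verify.
* **Replication level for published summaries.** When a published
  table reports groups of 20 fruits measured at two points each, the
  measurement-level $n = 40$ is the replication that reproduces
  published letter partitions; at fruit-level $n = 20$ adjacent
  advanced groups can merge. The package takes no side — `n` is an
  explicit input — but the worked checks use $n = 40$ and the test
  suite exposes the sensitivity.
* **Compact letters.** Insert-and-absorb: each significant pair splits
  every letter containing both members, subset letters are absorbed.
  Levels connected by $p \ge \alpha$ share a letter; the sharing
  structure is invariant under level relabeling.
* **Correlations.** Pearson and Spearman matrices with two-sided
  p-values; Spearman is carried because the chlorophyll index relates
  to color monotonically but not linearly. Constant features and pairs
  with fewer than 3 complete rows yield `NA` with a warning.

## 3. The synthetic study generator

The generator emulates a six-group, two-arm, two-week storage trial:
maturity groups A–F graded on the CTIFL color scale, a control arm and
a gaseous 1-MCP arm for A–E (F, fully ripe at day 0, is the absolute
control and never treated), 20 fruits per group and arm, sampled on
days 0, 2, 5, 7, 9, 12, 14 (a grid of roughly twice-weekly
measurements; configurable).

**Latent kinetics.** Each fruit carries a ripeness state
$u(t) \in [0,1]$ following a logistic curve with group-specific start
($u_0$ = 0.05, 0.2, 0.4, 0.6, 0.75 for A–E; 0.995 for F, the practical
stand-in for "fully ripe" since a logistic start must be below one) and
rate $k(1 - \rho\,e_g)$ under treatment, with baseline
$k = 0.35$/day, treatment slowing $\rho = 0.9$ and efficacy profile
$e_g$ = (1, 1, 0.6, 0.3, 0.2, 0) for A–F. The profile encodes the
climacteric biology: receptor blockade is most effective before the
ethylene burst, so mature-green and breaker fruit benefit most. Setting
$\rho = 0$ makes the arms identical in law, the null used for
calibration tests.

**Measured quantities.** All derive from $u$ plus noise:

* $a^\* = -15 + 41u$ (green $-15$ to red $+26$), measurement SD 1.6 —
  at these values a noise-free group-A control fruit ends two weeks
  above $+20$ while its treated counterpart stays below zero.
* DA-index $= 1.79\,e^{-6.39u}$, spanning ~1.3 (mature green) down to
  ~0.003 (fully ripe), with additive + proportional noise and a floor
  at zero (chlorophyll cannot be negative).
* Firmness $S$ starts Uniform(5.2, 7.8) at day 0 and decays
  exponentially in storage time toward a floor of 2, at a rate slowed
  by treatment ($\rho_S = 0.8$, same efficacy profile); controls end
  below 3 while treated early-stage fruit stays near 4.
* Between-fruit heterogeneity: $u_0$ jittered on the logit scale
  (SD 0.2), rates jittered log-normally (SD 0.08–0.1).

**Surface color: a two-patch mixture.** The visible surface is modeled
as a dull, hue-broad green patch (105° ± 18°, saturation 25 ± 8) and a
vivid, hue-narrow red patch (12° ± 4°, saturation 88 ± 6) whose
*surface fraction equals* $u$. This mirrors how CTIFL stages are
actually defined (percent of the surface turned red) and it is what
makes the PQS behave like real data: as the red fraction grows the
spectrum's amplitude rises much faster than $\sin\theta$ falls, so both
gravity coordinates increase with ripeness (after a brief dip at the
green end of Y), normalized green falls, normalized red rises, and the
Spearman sign structure among (S, DA, a\*, R_N, G_N, PQS-Y) comes out
with firmness and chlorophyll anti-correlated with the redness
features. These patch parameters were calibrated once against that
qualitative sign structure and the published value ranges, not against
any specific study's test statistics, and are not intended to be
re-tuned.

**Vision features** are computed by drawing a cloud of 1200 surface
pixels per fruit-day from the mixture, quantizing to 8-bit RGB (as a
camera would), and running the package's own spectrum and gravity-point
code — so the generator exercises the measurement pipeline rather than
shortcutting it.

**The renderer** (`renderTomatoImage()`) rasterizes the same surface
model as a disk on a noisy near-white background, optionally with an
illumination cast (to exercise white balancing) and a compact glare
cluster of saturation below 2% (to exercise segmentation). It returns
exact ground truth: the fruit and glare masks and the per-bin
saturation tally of the quantized fruit pixels, computed by its own
inline hexcone arithmetic so the tally-vs-`hueSpectrum()` agreement
test compares two code paths.

**What the generator does not emulate.** Photorealistic shading,
within-fruit spatial color gradients, multi-fruit frames (frames hold
one fruit; multi-fruit images are supported through crop lists),
ethylene biochemistry, spoilage events, camera optics or device color
models ($a^\*$ is driven by the same latent state as hue rather than
converted colorimetrically — published data treat them as strongly
correlated measurements, and a shared monotone latent reproduces that
structure without a device model). Passing tests on synthetic data
therefore demonstrates internal consistency and statistical
calibration, not instrument-level accuracy on real fruit.

## 4. Numerical choices and degenerate inputs

* **Saturation threshold.** Otsu's criterion on the whole-percent
  saturation histogram (101 bins), maximizing between-class variance;
  ties are resolved by averaging the tying thresholds. Otsu is
  parameter-free and ideal for the bimodal dull-background /
  vivid-fruit setting; it is *not* appropriate when the fruit itself is
  strongly bimodal in saturation (a dull green patch plus a vivid red
  patch at intermediate ripeness makes the histogram trimodal and Otsu
  may cut between the fruit modes). A fixed-threshold override is part
  of the pipeline configuration for exactly that case, and the
  end-to-end pipeline example uses it. A constant saturation raster is
  an error advising the fixed threshold; an empty ROI ("no fruit
  found") is an error, not an empty result.
* **Achromatic pixels** get hue 0 and saturation 0; they can never
  pass a positive threshold, so the convention is inert.
* **White balance** maps each channel's white-region median to 240 —
  high enough to be a genuine white reference, low enough that gains
  rarely clip at 255. The automatic white region is saturation ≤ 10%
  and value ≥ 60%; fewer than 100 such pixels, or a zero median, is a
  hard error naming the channel.
* **Hue bins** are 1° (360 bins), the resolution at which peak
  positions are conventionally discussed; `gravityPoint()` also
  accepts any equal-bin vector, which the refinement tests use.
* **Zero-area spectra** have no gravity point and raise an error
  (single-bin spectra are fine — the thin-sector formula applies).
* **Perfect fits and constant responses** in the ANOVA report
  $F = \infty$ and $F = 0$ respectively rather than failing.
* **Readings CSV round trip** serializes doubles with 17 significant
  digits, so write–read–write is bit-exact.
* **Determinism.** Every stochastic component takes a seed;
  `simulateStudy()` regenerated with the same configuration is
  byte-identical, including PNG frames and the JSON/YAML sidecars.

## 5. Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely from generated
data at desk scale, chosen to keep the full suite in a few minutes on
one CPU while leaving the statistical assertions well powered: the
default study (6 groups × ≤2 arms × 20 fruits × 7 days = 1540
fruit-days) for effect detection and the Spearman sign structure (25
seeds); 100 seeds of a two-day variant for treatment-contrast
recovery; 1000 replicates of a 2×2×20 null design for rejection-rate
calibration; 100 rendered frames for segmentation fidelity and the
conservation laws; and 10⁵ Monte-Carlo samples per spectrum for the
gravity-point oracle.

## 6. Known limitations

* Otsu thresholding on strongly two-mode fruit surfaces (above).
* The hue↔a\* link is a shared latent state, not colorimetry; absolute
  agreement between simulated a\* and simulated RGB is not meaningful.
* PQS-Y is not globally monotone in ripeness at the extreme green end
  (the brief dip noted above); rank correlations over a full study are
  dominated by the monotone regime, but single very-green frames
  should be interpreted via PQS-X, which is monotone throughout.
* The statistical layer treats storage day as a fixed factor, matching
  the published analyses it mirrors; no repeated-measures correlation
  structure is modeled.
* Multiple-testing control is applied within each post hoc family
  (studentized-range adjustment), not across response variables.
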