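---
title: "Composition Wheels: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition Wheels: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`domwheel` characterizes dissolved organic matter (DOM) by a suite of
concentration-independent composition metrics and renders them as four-axis
polygon "Composition Wheels". This vignette is the package's account of the
underlying models, the tunable parameters, the numerical choices, and what
the synthetic-data generator does and does not emulate.

```{r setup}
library(domwheel)
```

## Optical metrics

All absorbance work starts from the Naperian absorption coefficient
$a(\lambda) = \ln(10)\,A(\lambda)/L$ (m$^{-1}$), where $A$ is decadal
absorbance and $L$ the cuvette path length in metres (default input data use
a 1 cm cuvette, $L = 0.01$). Negative $A$ (instrument noise near the
detection limit) passes through to negative $a$ and is excluded only where a
downstream computation cannot use it.

**Specific coefficients.** `suva()` is $a(255)/[\mathrm{DOC}]$ in
L mg$^{-1}$ m$^{-1}$, with `sac350()` and `sac420()` its 350 and 420 nm
analogues. Two conventions deserve emphasis:

* The ln(10) factor is **included**. Much of the literature reports decadal
  SUVA$_{254}$ ($A_{254}/L/[\mathrm{DOC}]$); values here are a factor
  $\ln 10 \approx 2.303$ larger, and the evaluation wavelength is 255 nm.
  The natural-water range on this convention is roughly 1–21 L mg$^{-1}$ m$^{-1}$.
* SAC350 is computed from the absorbance **at 350 nm**. Printed metric
  tables in the literature occasionally repeat the 420 nm symbol in the
  350 nm row; we treat the row label as authoritative. All three specific
  coefficients are emitted in L mg$^{-1}$ m$^{-1}$.

**Spectral slopes.** `spectral_slope()` fits
$a(\lambda) = a_{\mathrm{ref}}\,e^{-S(\lambda - \lambda_{\mathrm{ref}})}$
over a window (endpoints inclusive; defaults 275–295 nm and 350–400 nm,
$\lambda_{\mathrm{ref}}$ the lower edge). The default estimator is nonlinear
least squares on the coefficients themselves (Levenberg–Marquardt,
initialized from the log-linear regression of $\ln a$ on $\lambda$); the
log-linear estimate is retained as `method = "log_linear"` because the two
agree to machine precision on noise-free exponentials but weight
heteroscedastic noise differently. Numerical guards:

* points with $a \le 0$ are excluded before fitting (their log is undefined
  and they sit at the noise floor); fewer than 3 usable points returns a
  missing fit with a warning;
* if the optimizer fails to converge (e.g. an exactly flat spectrum makes
  the decay rate unidentifiable), the log-linear estimate is returned with a
  warning rather than an error.

$S$ is reported positive for normally decaying spectra, in nm$^{-1}$;
`slope_ratio()` is $S_{275-295}/S_{350-400}$ and returns missing when the
denominator slope is zero or unfit.

**Interpolation.** Index wavelengths (255, 350, 365, 420, 465, 665 nm) are
read off the measurement grid exactly when present and by linear
interpolation otherwise; compliant 5 nm grids hit every index wavelength
exactly, so interpolation order is immaterial in practice. Querying outside
the measured range is an error, and indices whose wavelengths are not
covered are emitted as missing with a warning. No baseline re-correction is
applied by default: blank correction is assumed done at the instrument.

## Chemistry

DON is total dissolved N minus inorganic species,
$\mathrm{DON} = \mathrm{TDN} - (\mathrm{NO_3} + \mathrm{NO_2} + \mathrm{NH_4})$,
all mg N/L. A negative difference indicates analytical over-subtraction and
is returned as missing — not clipped to zero — so no near-zero denominators
are fabricated for the ratio. The DOC:DON ratio is molar, using atomic
masses 12.011 (C) and 14.007 (N); the source methods do not state the masses
used, and any modern standard-atomic-weight table agrees to the digits that
matter here.

## Ingest and averaging

The four CSV inputs (long-format spectra, chemistry, LC-OCD fractions,
metadata) are validated strictly: duplicated sample ids and non-numeric
cells are hard errors naming the offender, hydrologic settings outside the
closed vocabulary are recoded to `"other"` with a warning, and LC-OCD
fractions must each lie in [0, 100] and sum to at most 100 plus a
2-percentage-point rounding tolerance. Samples present in some files but not
others are retained with explicit missing blocks; nothing is imputed.

Repeated sampling events are collapsed by `average_by_site()` as the
arithmetic mean of each **derived metric** over non-missing events — not by
averaging spectra and re-deriving — matching the site-level averaging used
when such datasets are assembled. Whether the ordination should see
individual samples or site averages is a genuinely open choice; both paths
are exposed (`run_pca()` accepts either table) and the complete-case subset
size is logged so the analyst can see what the PCA actually used.

## PCA screening and axis selection

`run_pca()` standardizes each requested column (so the analysis is on the
correlation structure and invariant to affine rescaling of any metric),
restricts to complete cases, and decomposes by SVD. Component signs are
fixed by making each component's largest-magnitude loading positive —
otherwise loadings are reproducible only up to sign across BLAS builds.
Contributions are $100\,l_{jk}^2/\sum_j l_{jk}^2$; the combined PC1–PC2
statistic weights the two components by their eigenvalues,
$(c_{j1}\lambda_1 + c_{j2}\lambda_2)/(\lambda_1+\lambda_2)$. The exact
contribution statistic used in published ordination-contribution figures is
rarely stated; this is the convention of standard ordination contribution
plots, and the tests verify it against direct recomputation from loadings.

`select_axes()` implements the quasi-independence rule: one metric from each
of four analytical families (absorbance magnitude, absorbance shape,
size-exclusion, stoichiometry). Within a family, metrics below the
contribution threshold (default 2%) are screened out and the best survivor
wins; ties break alphabetically and are logged. The **family constraint
outranks the threshold**: a family whose members all fall below the screen
still contributes its best metric, with a warning. This choice reconciles
two facts about how such axes are selected in practice — stoichiometric
ratios can contribute little ordination variance yet are selected anyway
precisely because they carry information the optical metrics cannot. An
entirely absent family is an error, since the wheel would no longer span
four analytical principles.

## Wheel geometry

Axis bounds are the min and max of each metric over the reference dataset
(`fit_axes()`), or explicit published bounds (`manual_axes()`,
`read_bounds()`). Normalization is $v = (x - \min)/(\max - \min)$, clipped
into $[0,1]$ with a counted warning when a new sample falls outside the
reference range — so wheels from later studies remain drawable against fixed
bounds. Samples missing any axis metric get no wheel and are reported.

The default axis layout places SUVA up-left (135°), S$_{275-295}$ up-right
(45°), HSF down-right (315°) and DOC:DON down-left (225°). Orientation is
scientifically arbitrary; this order is chosen so the photolyzed end member
elongates toward the top-right corner, the orientation in which such figures
are usually read. Wheels generalize to $k \ge 3$ axes at even spacing for
surrogate-axis substitution (e.g. a fluorescence component replacing HSF).

Area uses the shoelace formula on the polygon vertices; for four orthogonal
axes it reduces to $\tfrac12\sum_i v_i v_{i+1}$ (cyclic), giving 2 for an
all-ones wheel. Distances between wheels are Euclidean in normalized axis
space.

**Templates and classification.** End-member templates express qualitative
low/mid/high levels at fixed anchors 0.15/0.5/0.85 — drawing conventions,
not measured values. Classification (`classify_wheels()`) defaults to the
two dominant end members observed in natural datasets, groundwater-sourced
DOM (trapezoid: high SUVA, HSF, DOC:DON; low slope) and photolyzed DOM
(kite: high slope, rest low), labelling samples farther than 0.6 from both
as `"intermediate"`. The other three templates (microbial degradation,
terrestrial leachate, autochthonous production) differ from the dominant
pair on only one or two axes; they are overlays for interpreting shifts, and
using them as classification classes would split the dominant classes on
distinctions the axes cannot support. Two published characterizations of the
groundwater end member disagree on DOC:DON (dataset-wide results say
highest; a figure caption says low); the default template uses **high**
DOC:DON, with `end_member_templates(variant = "caption")` for the
alternative.

`degradation_shift()` returns the expected sign of change per axis —
photolysis: S$_{275-295}$ up, the other three down (all four axes respond);
microbial degradation: SUVA up, DOC:DON down, slope and HSF unchanged. These
are annotations for reading observed shifts, never applied to data.

## Rendering

SVG is the canonical output: coordinates are written at fixed precision with
no timestamps or generated ids, so identical inputs give byte-identical
files — diffable in tests and version control. `render_facets()` draws one
panel per (site, hydrologic setting) pair present, color encoding site and
panel encoding setting, with optional heavier-stroke highlighting of
end-member samples and template outlines overlaid. PNG output rasterizes the
ggplot2 `autoplot()` version and is a convenience, not a deterministic
artifact.

## The synthetic-data generator

`synth_dataset()` emulates a two-end-member study: per-sample target metrics
are drawn from groundwater-like and photolyzed-like clusters, then the raw
inputs are **back-solved** so the pipeline reproduces the targets — the
spectrum is a single exponential whose 275 nm amplitude is set from the
target SUVA and DOC, DON is set from the target DOC:DON, and LC-OCD minor
fractions share out the non-humic remainder (≈5% left unresolved, as real
chromatograms do). Back-solving keeps ground truth exact, which forward
simulation of chemistry would not. Absorbance noise is multiplicative
lognormal (σ = 1% by default), keeping spectra positive and mimicking
relative instrument error.

Cluster locations are fixed study conditions, chosen once to sit toward the
extremes of the ranges reported for natural waters at continental scale
(SUVA 1.1–21 L mg$^{-1}$ m$^{-1}$, slope 0.005–0.032 nm$^{-1}$, DOC:DON
9–124, HSF 14–85%): groundwater-like SUVA 9 ± 1.2, slope 0.008 ± 0.0015
nm$^{-1}$, HSF 72 ± 5%, DOC:DON 90 ± 12; photolyzed-like 2.5 ± 0.6,
0.028 ± 0.002, 25 ± 5, 15 ± 3. Draws are truncated to the published ranges.

What the generator does **not** emulate: non-exponential spectral shoulders
(iron interference, scattering), correlated noise across wavelengths,
seasonal drift, the continuum of intermediate compositions real surface
waters show, or any mechanistic photochemistry. Passing tests therefore
demonstrate that the pipeline recovers what the model family can express —
not that real DOM obeys a single exponential, and not that real datasets
separate this cleanly into two clusters.

With σ = 1% noise, a single-point index like SUVA carries ≈1% relative
standard deviation and the 5-point 275–295 nm window gives
$\mathrm{se}(S) \approx \sigma/\sqrt{\sum(\lambda-\bar\lambda)^2} \approx
6\times10^{-4}$ nm$^{-1}$; round-trip tests assert unbiasedness and
5-standard-error per-sample bounds rather than tolerances tighter than the
information content of the window.

## Problem sizes and determinism

The test-suite simulations use 10–50 samples per cluster, 200-replicate
noise studies for slope bias, and 1,000 random wheels for the geometry
closed form — sizes at which every Monte-Carlo margin in the assertions is
several standard errors wide while the whole suite runs in well under a
minute. All stochastic fixtures take explicit seeds; `synth_dataset()`
refuses to run without one. The acceptance script
(`scripts/acceptance.R --seed N --out f.json`) derives every random draw
from its `--seed`.

## Known limitations

* Iron-rich samples inflate absorbance-derived metrics; the package neither
  detects nor corrects this (published practice is to exclude such sites).
* Fluorescence indices (HIX, PARAFAC components) are supported only as
  pre-computed surrogate columns substituted onto wheel axes, never computed.
* The min–max normalization ties wheel shape to the reference dataset;
  comparing studies requires sharing bounds files (`write_bounds()`), and a
  single extreme sample stretches the axis for everyone.
* Classification is nearest-template in normalized space with a fixed
  cutoff; it has no probabilistic calibration, and the qualitative template
  anchors (0.15/0.5/0.85) are conventions.
* Degradation annotations are directions only; rates and extents of
  photolytic or microbial processing are outside scope.
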