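---
title: "Methods: plumage color spaces, complementary colors and phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plumage color spaces, complementary colors and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumacolor)
```

This vignette is the package's own account of its methods: the models, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, the numerical choices, and known
limitations.

## From reflectance to cone catches

A plumage patch enters the pipeline as a two-column spectrum (wavelength
in nm, reflectance as a proportion; percent input is detected when values
exceed 1.5 and divided by 100). Spectra are linearly resampled onto the
canonical grid, 300–700 nm at 1 nm — the avian-visible range used by the
tetrachromatic visual models. Up to 5 nm of missing coverage at either
edge is filled by holding the nearest measured value; larger gaps are an
error, because silent extrapolation at the UV end would bias the u-cone
catch. Resampling is idempotent and integration error of the 1 nm
trapezoid rule on these smooth curves is far below the 1e-4 tolerance the
tests enforce against a 0.1 nm oracle.

Cone sensitivities come from the Govardovskii A1 pigment template (alpha
plus beta band, unit-peak normalized). Defaults are averaged avian
systems: UVS peaks at 372/456/544/609 nm, VS at 418/478/542/607 nm, and
the double cone (luminance channel) at 563 nm, a blue-tit-like curve. No
oil-droplet or ocular-media filtering is applied; users with measured
sensitivities can supply a tabulated curve instead, which takes precedence
over the nomogram. Because the von Kries correction divides each cone's
catch by its illuminant catch, any per-curve scaling cancels, so
unit-peak normalization is a convention, not an assumption.

The illuminant defaults to idealized uniform white. Under it the von
Kries-corrected catch of a flat spectrum is exactly its reflectance level,
which gives luminance a direct interpretation: a 34%-reflectance white
belly scores 0.34.

Black patches (mean reflectance below 0.02, configurable) are flagged and
excluded from all chromatic computation. The receptor-noise transform
takes logarithms of catches, so zero-reflectance patches would be
singular there; placing them at the achromatic origin would instead
fabricate a chromatic datum. They therefore carry luminance only, and
their color score is missing, never zero. The 0.02 threshold is a design
choice: zero-reflectance treatment of black plumage is standard, but no
published cutoff exists, so it is exposed as a parameter.

## Tetrahedral space and color volume

Relative catches (u, s, m, l summing to 1) map into Goldsmith's
tetrahedral space by the fixed linear rule with the achromatic point at
the origin and pure-cone stimuli at vertices of circumradius 0.75. The
occupied color volume of a group is the volume of the 3-D convex hull of
its points, computed by an in-package incremental (beneath-beyond) hull;
it is validated against the closed-form volume of the vertex tetrahedron
(0.21650635) and an external qhull computation frozen into the tests.
Clouds that are coplanar within a 1e-10 volume tolerance report zero
volume with a degeneracy flag rather than an error, since near-linear
patch clouds are common in small groups.

Percent occupancy is reported against a reference volume. The default
reference is the full tetrahedron; studies that express occupancy against
the published total volume of avian plumage colors should set
`reference_volume` to that value (it is not hard-coded here because the
published scalar is not part of this package's sources). The volume report
records which reference was used, and percentages under the two
conventions are not comparable.

## Receptor-noise XYZ space and the color score

Discriminability between two patches is the tetrachromatic
Vorobyev–Osorio distance ΔS in just noticeable differences, a quadratic
form in log-catch contrasts weighted by Weber fractions. The default
Weber fractions follow the common derivation from relative cone densities
u:s:m:l = 1:2:2:4 with noise 0.1 in the most abundant cone, giving
(0.2, 0.141, 0.141, 0.1) — "Leiothrix-like" values; they are a single
configuration shared by every stage that needs them.

`xyz_from_catches()` realizes ΔS as a Euclidean distance: a sequential
noise-weighted orthogonalization maps the four log catches onto three
axes. Any rotation of such axes is equally valid, so the orientation is
frozen and documented: X is the l-vs-m opponent contrast, Y brings in s,
and Z carries the u contrast with positive sign (more u-catch, larger Z).
Every axis annihilates the uniform direction, which yields two structural
properties the tests enforce to 1e-8: intensity invariance (scaling a
spectrum, or all catches, moves nothing) and an achromatic image exactly
at the origin. The explicit `achromatic_origin()` step is therefore an
identity under this transform; it exists so that the convention is
visible and preserved if a differently-centred transform is substituted.

The one-dimensional color score is the spherical elevation
Φ = atan2(Z, √(X²+Y²)) ∈ [−π/2, +π/2]. Φ keeps the information Euclidean
distance discards — which side of the achromatic point a color lies on —
so complementary colors get opposite signs. The azimuth θ is computed and
stored but unused downstream; PCA on the XYZ coordinates (covariance, not
correlation, since the axes share JND units) quantifies how much variation
the major axis explains, and the reported azimuthal variance fraction
makes the "variation is mostly elevational" assumption checkable per
dataset. PC1 loadings are sign-fixed (non-negative Z weight) purely for
reproducibility; loading signs are orientation-dependent and carry no
biological meaning here.

## Aggregation and the complementary-color test

Species × region score matrices average patch → specimen → species, in
that order, so heavily sampled specimens cannot dominate a species mean.
Comparative analyses use male plumage by default (`sex_filter =
"male_only"`); per-taxon extreme scores pool sexes by default, since a
dimorphic species' extremes may sit in different sexes. Extremes are
taken over patch-level scores, not region means: a single saturated patch
legitimately carries a taxon's maximum.

The complementary-color test asks whether taxa hold colors on both sides
of the achromatic point: two-sided one-sample t-tests of per-taxon maxima
and minima against zero, a paired t-test of maxima against minima, and
the fraction of taxa with max > 0 > min. Degenerate inputs (zero variance
across taxa) report an infinite t with an exact-tie flag instead of
failing. No multiple-testing correction is applied across clades; the
tests are reported per clade. Histogram bins are aligned at zero so the
sign structure is visible at any bin width (default 0.2 rad,
presentational only).

## Phylogenetic signal

Pagel's λ scales the off-diagonal of the Brownian-motion covariance C
(shared path lengths). The estimator profiles the GLS mean and rate out
of the Gaussian likelihood and maximizes over λ ∈ [0, λ_max], where
λ_max = max(diag C)/max(offdiag C) keeps the scaled covariance
positive-definite (slightly above 1 on ultrametric trees). For
ultrametric trees the eigenvectors of the λ-transformed covariance do not
depend on λ, so one eigendecomposition serves the whole optimization and
all randomizations; non-ultrametric trees fall back to a Cholesky path.
Boundary optima are checked explicitly because λ̂ frequently sits at 0 or
λ_max. Significance is the proportion of tip-label permutations whose
re-estimated λ̂ reaches the observed value, with 1000 randomizations by
default, and a likelihood-ratio test against λ = 0 is reported as a
cross-check since permutation and LR conventions differ across
implementations. Star phylogenies are flagged unidentifiable (λ does not
enter the likelihood), zero-length branches are perturbed by 1e-8 with a
warning, and zero-variance traits are flagged rather than fitted.

Mantel correlations (Pearson, one-tailed greater, 999 permutations by
default, via vegan's permutation machinery) relate the matrix of absolute
differences in region mean scores to the patristic distance matrix. Within
`signal_table()`, the λ randomizations and the Mantel permutations each
use one shared sub-seed across rows, so identical trait columns produce
identical rows.

## The synthetic-data generator

`simulate_clade()` emulates the study design the pipeline targets: a
clade of ~15–30 species (default 20) by seven body regions, one male
specimen per species (optionally a duller female), and a complementary
pair of spectral classes — a carotenoid-like long-pass sigmoid (inflection
605 nm, width 25 nm, plateau 0.65) and a structural short-wavelength
Gaussian (peak 460 nm, sd 40 nm, plateau 0.5). Under the `redistributed`
model each species splits its regions between the two classes (at least
one region each), which is the planted ground truth for "complementary
colors present"; under `one_sided` all regions carry the long-wave class,
emulating clades clustered on one side of the achromatic point. Species
identity enters as a Brownian shift of the template peak wavelength
(sd 8 nm across a unit-depth Yule tree) so spectra are phylogenetically
structured, while class-to-region assignment is random and therefore
carries no signal — a deliberate contrast the signal tables should (and
do) recover. Measurement noise is multiplicative Gaussian (sd 0.05,
clipped to [0,1]), keeping spectra physical and intraspecific variation
below interspecific variation. No within-patch variance structure is
modelled, because no estimate of it exists in this context; the noise
scale is a free parameter chosen once.

What passing tests on synthetic clades do **not** show: the templates are
phenomenological, with no pigment chemistry, iridescence, oil-droplet
filtering or realistic covariance between hue and brightness, and the
planted two-class structure is cleaner than real plumage. Recovery on
synthetic data validates the computation, not the biology of any real
clade.

All randomness flows from explicit seeds; per-operation sub-streams are
derived deterministically from one master seed, and seeded operations
restore the caller's RNG state. Reruns of `run_all()` with the same
configuration are byte-identical, which the tests check on the emitted
CSVs.

## Problem sizes used in the checks

The test suite and acceptance script use problem sizes chosen to make
Monte-Carlo error small relative to each tolerance while keeping runs
quick: 100 random spectra against the 0.1 nm integration oracle, clouds of
10,000 points for PCA recovery (closed-form fraction matched within 2%),
2,000 simulated datasets for t-test calibration at n_taxa = 27, 50 (tests)
or 25 (script) replicates of 64-tip Yule trees for λ recovery with 199
randomizations, and 500 replicates for Mantel null calibration.

## Known limitations

- Averaged UVS/VS systems do not model any particular species' vision;
  they make clades comparable, not perceptions exact.
- Luminance is the raw double-cone catch; no achromatic JND model is
  implemented.
- The RNL transform's orientation (hence loading signs and the sign of Φ)
  is a frozen convention; only sign *contrasts* between patches are
  interpretable.
- Pagel's λ here assumes a single Gaussian trait per region;
  Ornstein–Uhlenbeck and rate-shift models are out of scope.
- Subspecies handling is by choice of the taxon column; no name
  reconciliation beyond exact matching against tree tip labels.
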