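---
title: "Buffer-based accessibility of lung cancer screening providers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Buffer-based accessibility of lung cancer screening providers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsaccess)
```

## The problem

Low-dose computed tomography (LDCT) is the recommended screening modality for
lung cancer in older adults, and has been Medicare-reimbursable since 2015.
Uptake is low, and one candidate explanation is geographic: the providers who
bill LDCT screening services are not located where the people most likely to
need screening — heavy smokers — live. `lcsaccess` implements a small-area
accessibility analysis that quantifies this mismatch. It takes a provider
utilization table (one row per provider × procedure code, with coordinates), a
census-tract/county tessellation, tract- and county-level Medicare population
denominators, and a county smoking-prevalence surface, and produces:

1. a **coverage model**: a fixed-radius Euclidean buffer around each provider,
   with a census tract *served* by a provider when **more than 51%** of the
   tract's area falls inside the 30-mile buffer;
2. **density metrics**: provider counts aggregated to tracts and counties,
   expressed per 1000 beneficiaries;
3. a **bivariate classification**: each county cut into low/medium/high
   tertiles on provider density and on smoking prevalence (breaks at the 34th
   and 67th percentiles), combined into nine classes, with counties lacking
   any service carried as an explicit `no_service` class.

The national inputs this emulates are access-restricted or bulky, so the
package ships a seeded synthetic-geography generator that reproduces their
structural properties and plants recoverable ground truth; all tests and the
acceptance script run against it.

## The coverage model

All geometry is planar. WGS84 inputs are projected with a spherical Albers
equal-area conic (authalic radius, rescaled so 1 planar unit = 1 mile) whose
central latitude and standard parallels are fitted to the layer's bounding box
(parallels at 1/6 and 5/6 of the latitude span). Over a region a few hundred
miles across this keeps area distortion negligible (the projection is exactly
equal-area on the sphere; sphere-vs-ellipsoid area differences are below 0.5%)
and distance distortion within ~0.5%, far inside the margin that could flip a
51% area decision. The projection is configurable; round-trip
projection error is below 1e-6 miles.

Buffers are regular polygons with 64 vertices per quarter circle (256 total)
inscribed in the true circle; their area is within 0.1% of πr². Tract–buffer
intersections use Sutherland–Hodgman clipping of the (arbitrary, simple)
tract polygon against the convex buffer, and areas come from the shoelace
formula, so area fractions are exact up to the circle discretization. Two
exact screens skip most pairs: a tract whose bounding box is at least the
radius away from the provider has fraction 0, and a tract whose vertices all
lie within the buffer polygon's inscribed radius has fraction 1 (any polygon
with all vertices in a convex set lies inside it).

The served rule is a *strict* inequality — a fraction of exactly 0.51 is not
served — reflecting the literal "more than 51%" definition.

### County aggregation

A county's provider count is the **sum of its member tracts' counts**: a
provider serving k tracts of one county contributes k. This multiplies
providers across tracts deliberately; it is the only aggregation consistent
with published county densities exceeding 100–300 providers per 1000
beneficiaries when fewer than two thousand distinct providers exist
nationally. The alternative that counts each provider at most once per county
is available as `distinct_providers = TRUE` and is labelled a deviation in
run reports.

## Density metrics

Density is `per_capita × count / population`, with tract Medicare population
as the tract denominator and county fee-for-service (FFS) population as the
county denominator. Zero-population units have undefined density and are
excluded from distributional summaries (mirroring the exclusion of
zero-beneficiary tracts in the source data); no-service units have density 0,
which **is** included in distribution summaries by default — a county median
of 0.5 with IQR lower bound 0 is only reproducible if structural zeros stay
in the distribution — while maps and bottom-density rankings treat them as
missing instead. Quartiles use linear interpolation between order statistics
(type 7), stated here because the convention materially changes IQRs on
skewed density distributions. (Published served-county IQRs of this design
are internally inconsistent with any single quantile convention; the package
documents its own convention rather than matching any one printed interval.)

## Bivariate classification

Percentiles are **mid-rank**: `100·(#{x < v} + 0.5·#{x = v})/n`. This is
symmetric, stable under ties (all members of a tie share one percentile), and
makes split sizes exactly derivable: n distinct values get percentiles
(i−0.5)/n·100, so 9 distinct values split 3/3/3 under the (34, 67) breaks and
1000 distinct values split 340/330/330 (the breaks define a 34/33/33% split,
so exact thirds are not attainable at large n). An empirical-CDF alternative
(`percentile_method = "ecdf"`) is provided. Levels: low `p < 34`, medium
`34 ≤ p < 67`, high `p ≥ 67`.

No-service counties are excluded from the density percentile pool by default
(`density_pool = "served"`): with nearly half the counties at structural
zero, including them would collapse the low and medium tertiles onto zero and
the map's "low density" class would be meaningless. Whether the original
analysis pooled them is not recoverable; both behaviors are supported and the
default is documented, not asserted as the original. Smoking percentiles are
always computed over all counties with smoking data, including no-service
ones.

## The synthetic geography

The generator emulates, per input:

* **Tessellation** — an `nx × ny` grid of square tracts (default 40×40 of
  10 miles) grouped into `county_block × county_block` counties (default 4,
  giving 100 counties). Interior grid nodes are jittered jointly (default
  ±15% of a side), so tracts are irregular quadrilaterals that still
  partition the region exactly and counties dissolve exactly — areas stay
  analytically checkable while the clipping code sees non-trivial shapes.
* **Populations** — tract Medicare populations are lognormal (median 210,
  sdlog 1.0), with an exact `round(fraction × n)` of tracts forced to zero
  population (default 0.8%, the observed share of zero-beneficiary tracts).
  County FFS population is 70% of the summed tract population, which lands
  the county FFS median near the observed ~3900.
* **Smoking surface** — Gaussian noise at county centroids, smoothed with a
  Gaussian kernel (bandwidth 1.5 county sides), affinely rescaled to mean
  17.5% / SD 3.4% (SD from the observed IQR 15.2–19.8 via IQR/1.349), clipped
  to (0.1, 99.9). Smoothing gives genuine spatial autocorrelation — verified
  in tests by comparing neighbor correlation against the unsmoothed surface.
* **Providers** — counties receive providers with weights
  `exp(strength × clustering × z)` in the standardized smoking surface, so
  `provider_clustering < 0` reproduces the observed misalignment (providers
  concentrated away from high-smoking counties); points are uniform within an
  area-weighted random tract of the county. Service counts are lognormal
  (median 19, sdlog 0.84 — matching mean≈27, SD≈25) truncated below 11, the
  public-use file's suppression floor. The emitted table also contains
  sub-threshold rows (counts 1–10) and decoy procedure-code rows so the
  ingest filter is exercised, plus a per-county planted truth label
  (`high-smoking/low-access` = top smoking tertile with zero assigned
  providers) for recovery tests.

Every sub-generator draws from its own stream derived from the scenario seed,
so adding a generator never perturbs the others, and identical scenarios
produce byte-identical bundles (GeoJSON/CSV writers serialize numerics at
full `%.17g` precision).

What the generator does **not** emulate: real U.S. geography or FIPS codes,
road networks and travel time, multi-site providers, age structure, or the
urban/rural population gradients that drive much of the real spatial pattern.
Passing tests therefore demonstrate correctness of the *method* — geometry,
aggregation, classification, determinism — not calibration of any real-world
quantity.

## Numerical choices and degenerate inputs

* Buffer discretization error (≤0.1% of area) is orders of magnitude below
  the 51% decision margin; the discretized circle is inscribed, so fractions
  are (negligibly) conservative.
* Conflicting coordinates for one provider id are fatal, not averaged — an
  averaged location could silently cross a buffer boundary.
* Zero-area tracts are an error naming the tract; consecutive duplicate
  vertices are repaired with a warning.
* Rank-table ties break by unit id; requesting more rows than exist truncates
  with a warning.
* Empty provider cohorts flow through: all counts zero, 100% of counties
  uncovered, summaries flagged undefined where applicable.
* An all-tie variable puts every unit at the 50th percentile → "medium".

## Problem sizes

The reference scenario used by the acceptance script is 1600 tracts / 100
counties / 60 providers, which the full pipeline traverses in well under a
minute; the test suite uses instances from 4 to 900 tracts. These sizes were
chosen to exercise every code path (edge counties, zero-population tracts,
suppressed and decoy rows, no-service counties) at interactive run times; the
method itself scales linearly in (provider × nearby-tract) pairs thanks to
the bounding-box and inscribed-radius screens.

## Known limitations

* The fixed 30-mile Euclidean radius understates access in rural areas;
  adaptive radii, cumulative-opportunity measures, and network buffers are
  out of scope.
* The equal-area projection is spherical; at continental scale, east–west
  distances can deviate from geodesics by a few tenths of a percent. This
  affects only borderline tracts whose covered fraction sits within that
  sliver of 0.51.
* Only single-ring polygons are supported in the GeoJSON layers (holes and
  multipolygons do not occur in the synthetic tessellation).
* Smoking prevalence enters as a given input surface; its small-area
  estimation is upstream of this package.
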