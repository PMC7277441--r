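# lcsaccess

Spatial accessibility of lung cancer screening (LDCT) providers: a tested,
reusable R pipeline for buffer-based coverage analysis, small-area provider
densities, and bivariate classification against smoking prevalence.

## What it computes, for whom

Health-services researchers studying geographic disparities in cancer
screening need to turn a table of billing providers into area-level access
measures. `lcsaccess` implements the standard fixed-radius catchment design
at census-tract resolution:

* **Coverage**: every provider gets a 30-mile Euclidean buffer in an
  equal-area planar projection (miles). A tract *t* is **served** by provider
  *p* when

  `area(t ∩ B(p, r)) / area(t) > 0.51`  (strict, r = 30 mi),

  computed by exact polygon clipping.
* **Density**: tract provider counts are summed; county counts are the sum
  of member-tract counts. Density is `1000 × count / population`, with tract
  Medicare population and county Medicare fee-for-service (FFS) population as
  denominators. Zero-population units are excluded from summaries;
  no-service units count as zeros in distributions but as *missing* on maps.
* **Bivariate classes**: counties are cut into low / medium / high tertiles
  (mid-rank percentiles, breaks at the 34th and 67th) on density and on
  smoking prevalence, giving the nine classes low-low … high-high, plus an
  explicit `no_service` class.

Provider ingest reproduces the public-use file's semantics: rows are filtered
to the screening procedure code (HCPCS G0297 by default), services are summed
per provider id, and providers below 11 total services are suppressed.

Because the national inputs (provider utilization file, tract/county
shapefiles, enrollment tables, county smoking estimates) are bulky or
access-restricted, the package includes a first-class synthetic-geography
generator — seeded, byte-reproducible, with planted ground truth — that
emulates their structural properties. See the methods vignette
(`vignettes/accessibility-methods.Rmd`) for the design.

## Worked example

```r
library(lcsaccess)

dir <- "run1"
cfg <- run_config(seed = 1, indir = dir)   # 30 mi, 51%, G0297, floor 11, per 1000
run_simulate(cfg)                          # reference scenario: 1600 tracts, 100 counties
run_pipeline(cfg)
```

The stages log their filter waterfall:

```
[simulate] seed=1 nx=40 ny=40 counties=10x10 providers=60
[provider_ingest] rows in=76, matching code G0297=68, providers retained=60 (floor 11)
[coverage_model] providers=60 tracts=1600 served pairs=1502
[density_metrics] tracts excluded (zero population)=13; counties without service=34/100
[bivariate_classify] classified=100 no_service=34
[report_outputs] report written to report.md
```

and `run1/summary.json` then holds the headline numbers, e.g. for this seed:
34% of counties have no LDCT service; county provider density has median 2.54
per 1000 FFS beneficiaries (IQR 0–6.58) over all counties, and median 4.71
among the 66 served counties; county smoking prevalence has median 16.6%
(IQR 14.9–19.7%). Per-county classes are in `bivariate_classes.csv`, the
class-coded geometry in `map_layer.geojson`, ranking tables in
`rank_tables.csv`, and the scatter data in `scatter.csv`. Interpretation: the
generator plants providers preferentially in low-smoking counties
(`provider_clustering = -0.6`), and the class table makes the resulting
mismatch explicit — high-smoking counties are mostly `no_service` or
`low-high`.

A thin CLI with per-stage subcommands is included at
`inst/cli/lcsaccess.R`:

```sh
Rscript inst/cli/lcsaccess.R all --seed 1 --indir run1
```

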