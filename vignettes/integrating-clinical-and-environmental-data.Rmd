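---
title: "Integrating clinical records with environmental exposures: methods and design"
author: "clinexpo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating clinical records with environmental exposures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinexpo)
```

## The problem

Electronic health records carry essentially no information about the physical
environment a patient lives in, while environmental surfaces — gridded
pollutant estimates, road networks, census socio-environmental tables — carry
no individual-level health outcomes. Studying individual-level questions such
as *do patients breathing more fine particulate matter exacerbate more often?*
requires joining the two worlds on the only keys they share: the residence
geocode and the time stamp. That join is awkward because every source speaks a
different spatiotemporal dialect: patient addresses are point coordinates,
census attributes attach to polygons, pollutant estimates attach to grid cells
at hourly, daily, or annual resolution, and road exposure is a distance to a
line.

`clinexpo` implements this integration as a configurable pipeline of small
transformation steps, each reading and writing files, chained by a declared
dependency graph. The end product is an *integrated feature table*: one
de-identified, binned row per patient per study year, safe to expose to an
open query service, supporting cohort selection and 2×2 association tests.

## Pipeline model

A workflow is a YAML document listing step instances. Each step carries a
`name`, an optional `dependsOn` list, an optional `skip` flag, and a `step`
block naming a plugin `function` and its `arguments` (which include input and
output paths, so one step's output feeds the next). Execution order is a
topological sort of the dependency graph; ties are broken by declaration
order so a configuration always runs the same way. Each run produces an
execution report partitioning the steps into succeeded, skipped, and failed.

Two skip semantics matter:

* `skip: true` marks a step as already done — its outputs are assumed present
  from a prior run and its *downstream* steps still execute. This is what
  makes partial re-execution cheap: re-running a pipeline with completed
  steps skipped is byte-identical to a full run.
* A *failed* step, by contrast, blocks its descendants, which are reported as
  skipped with reason `upstream_failure`. Siblings not downstream of the
  failure still run, maximizing partial progress. The report's distinct
  failed/skipped categories imply the two situations must be told apart; the
  specific continue-siblings policy is this package's choice.

Execution is sequential. The step contract — every step's effect is fully
described by its declared inputs and outputs — means any topological-order
execution, serial or parallel, yields identical results, so serial execution
is an implementation detail rather than a semantic restriction.

Environmental sources are typically one file per calendar year, so a template
step with a `{{year}}` placeholder can be expanded with `expand_years()` into
one concrete step per year instead of hand-writing near-identical YAML.

## From FHIR resources to clinical features

`consolidate()` groups a stream of FHIR R4 JSON resources (Patient,
Encounter, Condition, MedicationRequest) into one bundle per patient, keyed
by the subject reference. Resources referencing no known patient are counted
and set aside rather than silently dropped, so a conservation check (input
encounters = attached encounters + orphans) always holds. The residence
geocode is read from the standard address geolocation extension; when a
patient has several addresses, the one whose validity period covers the study
year wins, and among those the latest period start. This multi-address rule
is our own; patients with no geocoded address are flagged and kept — they
drop out only of exposure columns, not of the cohort.

`to_vector()` turns a bundle into the per-year clinical feature row: age at
January 1, sex, race, ethnicity (source codes remapped to display labels via
a configurable map), a count of emergency/inpatient encounters in the
calendar year carrying a respiratory diagnosis code, and 0/1 flags per
configured medication and condition code set. Three deliberate choices:

* Visits are counted per *encounter*, not per diagnosis, so "two or more
  annual ED or inpatient visits" — the operational definition of an asthma
  exacerbation used throughout — is a count of visits.
* The year is a half-open calendar interval `[Jan 1, next Jan 1)`.
* Code sets are configuration, not code. The shipped defaults (a handful of
  ICD-10 J-code prefixes, the string `"prednisone"`) are illustrative
  placeholders for a study's curated sets, which are never published inside a
  software package.

## Exposure attachment

Pollutant grids arrive as long CSV (cell, timestamp, pollutant, value) at
hourly, daily, or annual native resolution. Aggregation is resolution-aware
and idempotent: hourly series are first reduced to daily means, daily means
to an annual mean-of-daily-means (`avg_daily`) and max-of-daily-means
(`max_daily`); data already at daily resolution skip the first stage, and
annual values pass through as both statistics.

Two numeric policies, both configurable:

* **75% completeness.** A day with fewer than 18 of 24 hourly values present
  reports no daily statistic — the standard completeness convention in
  air-quality summaries — and missingness propagates rather than biasing the
  annual mean toward well-measured hours.
* **Nearest cell, 1.5× coverage radius.** A geocode is assigned the grid cell
  with the nearest center by great-circle (haversine) distance, with no
  interpolation; nearest-neighbor is the simplest defensible mapping and is
  exactly what the test oracles check. Points farther than 1.5 grid spacings
  from every center are out of coverage and yield missing exposures. Ties go
  to the lexicographically smallest cell id, for determinism.

## Spatial joins

**Nearest road.** The distance from a geocode to a road is the minimum
point-to-polyline distance: the perpendicular foot where it falls inside an
edge, otherwise the nearest vertex. Distances are computed in meters in a
local equirectangular projection centered at the query point rather than with
full geodesics: at the sub-10-km scales relevant to road-exposure studies the
discrepancy is well under 0.5% (the tests bound it against both a dense
great-circle sampling oracle and `geosphere`'s geodesic point-to-line
distance), and the planar formulation is simple enough to verify by hand.
Two road sources — census-geometry-style and traffic-monitoring-style — run
through the same geometric core and differ only in the attribute columns
carried into the feature table (road class vs. annual average daily traffic).
Ties go to the smallest segment id.

**Census units.** Polygon containment uses the even-odd (ray casting) rule.
Boundary points are assigned to the containing unit earliest in unit-id
order — an arbitrary but deterministic rule for a measure-zero case. The
matched unit id keys a join against the socio-environmental attribute table;
version 2 of that table additionally carries an urban/rural `ur` field. The
unit granularity (block, block group) is treated as opaque: any polygon
partition with a keyed attribute table works.

## Binning and de-identification

Continuous exposures are quantile-binned: edges at empirical quantiles with
linear interpolation (`stats::quantile` type 7, the same interpolation rule
as the pandas `qcut` convention this mirrors), intervals right-closed, and
labels printed as ranges. The first bin includes the minimum and is labelled
`"[a, b]"` so the label states exactly what the bin contains. Heavily tied
data can collapse duplicate edges; the result is fewer bins and a warning,
never an error. The default of 5 bins for continuous exposures is a
conventional quintile split; the end-to-end study uses 2 bins because its
query is a low/high dichotomy. Every binned variable's method and edges are
recorded in a YAML manifest next to the table, so range labels stay
interpretable downstream.

De-identification implements the Safe-Harbor-style subset relevant to a
tabular schema: identifier and geocode columns are dropped, date columns
truncate to year, and ages over 89 collapse to a top category `"90+"`. Two
safety properties are enforced and tested: the operation is idempotent, and a
deny-pattern scan (id-like, coordinate-like, birth/address-like column names)
refuses to emit a table whose policy missed a column. Rows are sorted by all
columns before writing, which both makes output byte-reproducible and
prevents source row order from aiding re-identification. Small-cell
suppression (censoring bins with few patients) is *not* applied; a deployment
exposing tables publicly should consider it.

## Cohort queries

The query layer reproduces the consuming service's 2×2 interrogation style:
conjunctive cohort filters (`=`, `<`, `>=`, with binned range labels ordered
by their parsed lower edge), a feature dichotomized at a level or cutpoint,
an outcome dichotomized at a threshold, Pearson's chi-square **without
continuity correction** on the resulting table, and cells formatted as
`"N (p%)"` column percentages. The no-correction choice is not stylistic: on
the published prednisone-by-exacerbation panels it reproduces the printed
statistics (46.4781, 54.8241) to all four printed decimals, which a
Yates-corrected statistic does not. Statistics are rounded half-up to 4
decimals and percentages to 2, matching the published formatting. Degenerate
tables (a zero marginal) raise an error rather than returning `NaN`.

## The synthetic study

Because the validating clinical dataset is protected health information, the
package ships deterministic generators for every input family, with one
master seed and fixed per-generator offsets (adding a generator never
perturbs another's stream). `fixture_spec()` defines the study conditions:

* 2,000 patients placed uniformly over a 1°×1° area, one study year;
* a planted effect: patients in the western half both breathe more PM2.5
  (daily cell means around 14 vs 7 µg/m³, about the contrast between a
  polluted and a clean US urban year, daily noise SD 2) and exacerbate with
  probability 0.4 vs a 0.1 baseline — a deliberately strong signal so a
  single year of 2,000 patients detects it essentially always;
* prednisone orders at probability 0.17 given exacerbation vs 0.10 without,
  the order of magnitude seen in asthma cohorts;
* a 4×4 pollutant grid and census partition, lattice roads, and an ACS-style
  table with an urban/rural field.

The full pipeline on these conditions, dichotomizing binned annual-average
PM2.5 against the two-or-more-visits outcome, is validated two ways: with
the effect on, the association chi-square must exceed the df = 1 critical
value 3.841 in at least 19 of 20 seeds; with the effect off (high-region
probability set to baseline) it must do so in at most 4 of 20 — the upper
99.7% binomial bound on a nominal 5% type-I rate at that sample of seeds.
These sizes (2,000 patients, 20 seeds per arm, 365 daily values per cell)
are the package's validation conditions throughout the tests and the
acceptance script.

What the generator does *not* emulate: realistic ICD coding noise, pollutant
transport physics or temporal autocorrelation, address changes within a year,
and spatial confounding (in real data the exposed region differs in more
than exposure). Passing tests therefore demonstrate that the machinery —
parsing, joining, aggregating, binning, de-identifying, testing — is correct,
not that any epidemiological estimate from real data would be unbiased.

## Known limitations

* FHIR coverage is the minimal resource set the feature extractor needs
  (Patient, Encounter, Condition, MedicationRequest/Statement), read from
  NDJSON; no server interaction or terminology expansion.
* Geometry I/O is GeoJSON; binary shapefiles should be converted upstream.
* The planar nearest-road distance degrades beyond a few tens of kilometers;
  grids and road networks are assumed regional, not continental.
* Chi-square queries are 2×2 only, mirroring the validating analyses; r×c
  tables, multivariable models, and multiple-testing control are out of
  scope.
* No small-cell suppression before table export (see above).
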