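---
title: "Methods: intermunicipal patient-journey networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intermunicipal patient-journey networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sihnet)
```

## The model

A hospitalization record carries a municipality of residence (origin), a
municipality of occurrence (destination), a competence year and month, and a
procedure code. After restricting to one procedure group, each year's records
define a directed weighted graph G = (V, A): vertices are municipalities
active that year, an arc O → D carries the number of journeys from O to D as
its weight, and self-journeys (origin = destination) are excluded — the
object of study is the *intermunicipal* network. One record is one
hospitalization authorization, not one unique patient; repeat admissions are
journeys and are counted as such.

For a focal municipality the package reports, per year: the in- and
out-degree (distinct counterpart municipalities on incoming / outgoing arcs),
the incoming and outgoing flow (summed arc weights), and the flow-weighted
mean arc length per direction,

$$\bar D \;=\; \frac{\sum_{a=1}^{k} D_a F_a}{\sum_{a=1}^{k} F_a},$$

where the sum runs over the focal municipality's arcs in that direction,
\(D_a\) is the straight-line distance in km and \(F_a\) the arc weight. When
the degree \(k\) is zero the statistic is undefined and is reported as `NA` —
deliberately never 0, which would be a real (and wrong) distance. In CSV
output `NA` is written as the literal string `NA`; distances are kept at full
precision internally and rounded to 2 decimals only when written.

Assumptions worth stating: the origin field is the *recorded* municipality of
residence (registration errors are known to exist in admission systems and
are not modelled); distances are straight lines, a lower bound on road
distance; and a record belongs to its competence year, with no admission-date
reconstruction across year boundaries.

## Distances and coordinates

Municipality positions are city points in decimal degrees (WGS84/SIRGAS2000,
which agree at sub-meter level). Two straight-line distances are offered:

* **`utm`** (default): both points are expressed in UTM and the planar
  Euclidean norm is divided by 1000. If the registry supplies an
  easting/northing/zone triple for both points in the same zone it is used
  directly; otherwise both points are projected with the package's
  transverse-Mercator forward projection (scale 0.9996, false easting
  500 000 m, false northing 10 000 000 m in the south) **forced into the zone
  of the first point**. A state like Bahia spans zones 23S/24S, and a planar
  Euclidean distance is only meaningful within a single frame; forcing the
  first argument's zone makes the choice deterministic and symmetric in
  practice (the distance changes by well under 0.1% if the other zone is
  chosen). The projection series is validated against a published worked
  example to the example's printed precision (0.1 m).
* **`great_circle`**: haversine on the mean sphere, R = 6371.0088 km;
  zone-free and adequate whenever sub-percent accuracy suffices.

The two methods agree closely but not arbitrarily well: the mean sphere
radius exceeds the WGS84 meridional curvature radius (≈ 6337–6341 km at
9–18°S) by about 0.5%, while UTM tracks the ellipsoid at scale ≈ 0.9996. For
near-meridional pairs the relative gap can therefore reach ≈ 0.6%, while
east–west-dominant pairs stay well under 0.5%. The test suite asserts exactly
these analytic bounds; treat `utm` as the reference method, as mean arc
lengths in kilometers are conventionally computed on UTM coordinates.

Municipality codes are normalized to their 6-digit form (a 7th check digit,
common in registries, is truncated) so that record files and registries join
reliably. Records with out-of-range months or years, malformed codes, or
empty procedure codes are diverted to a rejection report rather than silently
dropped; accepted + rejected always equals the row count.

## The synthetic generator

Real admission extracts cannot be redistributed, so the package ships a
generator whose output exercises every pipeline stage. It is a standard
spatial-interaction (gravity) model: for year t, origin O and provider D ≠ O,
the journey count is Poisson with mean

$$\lambda_{OD} = \theta \cdot \mathrm{pop}_O \cdot \mathrm{cap}_D \cdot e^{-d_{OD}/\delta},$$

with \(d_{OD}\) the great-circle distance and \(\delta\) = `decay_km`. The
defaults describe a Bahia-like world and are fixed once: 50 municipalities
uniform in a state-sized box (lat −18.3…−8.5, lon −46.6…−37.3), log-normal
populations (median 20 000, sd(log) = 1 — a right-skewed municipal size
distribution), the 5 largest municipalities as providers (regionalized
high-complexity care concentrates in hubs), years 2008–2020,
`decay_km = 250` (state-scale journeys are common but long ones rarer), and
\(\theta\) calibrated analytically so the expected total record count is
10⁴. Macroregion labels are assigned by spatial quadrant.

Randomness is keyed per `(seed, year, origin, destination)`: each pair draws
from its own private stream, so runs are reproducible record-for-record and
*adding* municipalities or years never changes an existing pair's draws (a
property the test suite checks directly). The global RNG state of the caller
is left untouched.

What the generator does **not** emulate: seasonality (months are uniform),
case-mix and demographics, capacity constraints or waiting lists, recording
errors in the origin field, year-over-year trend in provider capacity, and
intra-municipal admissions (every generated record is intermunicipal). A
green pipeline test therefore establishes that counting, distance weighting,
`NA` handling and exports are correct — not that the gravity model is a good
epidemiological description of any real state.

## Numerical and design choices

* **Self-loops** are dropped from networks by default but retained by
  `count_by_provider()`, whose provider totals deliberately include residents
  treated at home.
* **Out-of-registry codes** (e.g. out-of-state residents) are excluded from
  networks with a warning and an `unresolved` report; the analysis scope is
  the registry's territory.
* **Macroregion percentages** are computed on distinct municipalities (the
  degree), not on flow weights, and printed to 1 decimal. Counterparts
  without a label fall into an explicit `"unknown"` bucket.
* **Eq.-1 evaluation** is a plain weighted mean; the suite checks it against
  an independent naive loop on 1000 random networks to 10⁻⁹ relative, and
  checks the min/max-arc bounds and invariance under weight rescaling.
* **Degenerate inputs**: an empty year yields an empty matrix/network (not an
  error); a focal municipality absent from a network has all-zero degrees and
  flows and `NA` mean lengths; duplicate years in a time series are an error;
  a gap year inside a requested range produces the all-zero/`NA` row.
* **Ties and ordering**: generated records and exported tables are sorted on
  (year, origin, destination) so identical seeds give byte-identical files.
* **GEXF** is the primary visualization export (node attributes `lat`, `lon`,
  `macroregion`; directed edges with integer weights and a `distance_km`
  attribute); GraphML via igraph is the alternative. Round trips are exact
  for weights and directions.

## Limitations

Straight-line distances understate real travel; competence-year attribution
can shift a December admission's journey into the next file year; the
indices are local to a focal municipality — topological analyses of the full
state network (centrality, communities) are out of scope; and the shipped
8-municipality Bahia registry is a convenience extract of published city-point
coordinates for examples and distance checks, not a full state registry.
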