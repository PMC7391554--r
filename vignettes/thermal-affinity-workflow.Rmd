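---
title: "Occupancy-derived thermal affinities: models, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy-derived thermal affinities: models, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaffin)
```

## The scientific problem

Experimentally derived upper thermal limits (CTmax, LT50, and related
metrics) exist for only a few hundred marine species, because the
experiments are slow, expensive, and sometimes ethically fraught. Occurrence
records, by contrast, exist for over a hundred thousand marine species in
open repositories, each record placed in space (latitude, longitude), often
in time (month, year), and often at a sampling depth. If the environmental
temperatures at the places a species has been recorded — its *realised*
thermal niche, summarised as a "thermal affinity" — track its physiological
limits, then affinity can stand in for experiment at scale.

This package implements that workflow end to end: quality-control of
occurrence records, matching each record to gridded sea-temperature
products, reduction to per-species affinity summaries, aggregation of
experimental limits, and the statistical layer relating the two. A seeded
synthetic-ocean generator stands in for the external data services, so the
entire chain is testable offline against known ground truth.

## The matching model

Two complementary temperature products are supported.

**The climatology** is a pair of co-registered 2-D rasters of long-term
mean sea surface temperature (SST) and sea bottom temperature (SBT).
Matching is a plain cell lookup by latitude and longitude: cells are
half-open intervals `[edge_i, edge_{i+1})` in both axes, with the
northernmost/easternmost boundary edge closed so the grid's own boundary is
covered. A record on a masked (land) cell is an exclusion — there is no
nearest-wet-cell fallback, because a coarse cell that is mostly land
genuinely carries no usable temperature, and silently borrowing a
neighbour's water would bias affinities warm or cold depending on
coastline orientation.

**The depth-resolved series** is a 4-D field (month-year, depth band,
latitude, longitude) on the World Ocean Atlas standard depth bands to
2,000 m: 10 m bands to 50 m, 25 m bands to 200 m, 50 m bands to 300 m,
100 m bands to 1,500 m, and 250 m bands to 2,000 m — 27 bands. Bands, like
cells, are half-open with a single closure at 2,000 m. Matching is an
exact lookup by cell, month-year, and band; no temporal or vertical
interpolation is performed, because the record's date is itself only
month-resolved and the product's bands are the native resolution of its
source profiles. Three values are extracted per record: SST (surface
band), SBT (the cell's deepest wet band, which is the temperature at
2,000 m where the column reaches the scheme floor), and temperature at the
record's sampling depth. A record dated outside the product's coverage, or
with no parseable month/year, is excluded from this product only; it
remains eligible for the climatology, so the two products legitimately
summarise different record subsets per species.

### Record-level normalisation

Depth in occurrence aggregators is inconsistently signed and frequently
missing. Both negative and missing depths are set to 0 m (sea surface).
This deliberately does *not* absolute-value negative depths even where a
sign convention is the likely cause, because a negative value can equally
flag an intertidal record or a missing value; an `assume_sign_error`
override exists but is off by default. Longitudes outside [-180, 180) are
wrapped by modular arithmetic (the standard marine convention); latitudes
outside [-90, 90] cannot be wrapped and are rejected with a logged reason.
Dates are parsed from ISO full dates, year-month, or bare year; a bare
year leaves the month missing, which makes the record ineligible for
month-matched lookup without discarding it. Every rejected row carries
exactly one reason code, and `rows in = records out + rejected` is an
invariant checked on every run.

### The "best" temperature rule

Which layer best represents the water a species experiences depends on its
functional group: SST for birds, mammals, and pelagic and reef-associated
fish; SBT for benthos, macroalgae, and demersal and benthopelagic fish.
Sparse habitat categories are merged before this rule is applied
(bathydemersal into demersal; pelagic-neritic and pelagic-oceanic into
pelagic). Nekton have no conventional rule; as water-column animals they
default to SST here, with a configuration override — this is a declared
choice, not an inference.

## Thermal affinity

Per species and per temperature measure, the affinity summary is the mean,
minimum, maximum, median, standard deviation, median absolute deviation,
and 5th and 95th quantiles of the matched temperatures, plus the total and
matched record counts. Numerical conventions, declared for
reproducibility: quantiles use linear interpolation between order
statistics (type 7, the default of most statistical environments), the MAD
is scaled by 1.4826 for normal consistency, and the SD uses the sample
(n - 1) denominator. With one matched record the SD is reported missing
rather than zero; with none, only the counts are reported.

## Experimental limits

Thermal-limit compilations report heterogeneous metrics. Where a species
carries both LT0 and LT100 (algal studies), the LT100 records are kept as
the upper limit and LT0 dropped; a lone LT0 is retained. A species with
several estimates gets a mean weighted by the inverse of each estimate's
reported standard deviation — `sum(v/sd) / sum(1/sd)` — so more precise
estimates count for more. This is 1/SD weighting as reported in the
field's compilations, not the inverse-variance (1/SD²) weighting of
meta-analysis; the package implements the former deliberately and notes
the distinction here. Two policy questions are left configurable because
no convention settles them: a species with a *mixture* of reported and
missing SDs falls back to the unweighted mean by default (the alternative
imputes the median reported SD), and an SD of exactly 0 — infinite
weight — is treated as missing with a warning. Targeted corrections to
individual records (transcription errors found on checking original
sources) are applied through a generic, logged edit mechanism rather than
hard-coded species names.

## The statistical layer

Upper thermal limit is modelled as a second-order polynomial in mean
thermal affinity, `tmax = a + b·x + c·x²`, by ordinary least squares in
three nested forms: pooled, additive group intercepts, and a full
group-by-polynomial interaction (per-group curves sharing one residual
variance; independent per-group refits are available by subsetting).
Forms are compared by the extra-sum-of-squares F-test, and R² is computed
from sums of squares directly (the ratio reported by `summary.lm` is
meaningless for a near-constant response).

Coefficients are reported on the **raw basis** — the parameterisation in
which the curve's vertex `-b/(2c)` is a temperature — rather than on an
orthogonalised basis. At ocean-temperature scales (|x| ≲ 30 °C, quadratic
term ≲ 900) the raw design's conditioning is benign (condition numbers
around 1e5, far from double precision's limits), which test suites verify
against an independent normal-equations solve to 1e-8; an orthogonalised
intermediate basis would therefore add a transformation step without
improving the estimates. Confidence intervals are 95% t-based Wald
intervals. The vertex is reported only when `c < 0` (an interior maximum
exists) and is flagged as extrapolated when it lies outside the observed
affinity range.

**Safety margins.** A species' thermal safety margin is `tmax − mean
affinity`, an exact identity preserved bit-for-bit in the output. Species
are binned by affinity as cold (≤ 10 °C), moderate (> 10 and ≤ 20 °C), or
warm (> 20 °C); both boundary closures are applied exactly as printed,
everywhere they are used. Data-poor groups (birds, mammals, nekton) are
excluded from margin tables by default, configurably. Empty group × bin
cells are absent from the table, not zero.

## The synthetic ocean

The generator emulates the *structure* of the real data services, with
known ground truth:

- **Temperature fields.** SST at a cell is
  `sst_equator + sst_gradient·|lat|` plus a fixed per-cell anomaly
  (default 28 °C at the equator, −0.35 °C per degree, anomaly SD 0.5 °C).
  Temperature declines by `depth_decay` (default 1 °C) per band down to
  the cell's randomly drawn deepest wet band, so SBT ≤ SST by
  construction. The monthly product adds a seasonal cosine (default
  amplitude 4 °C, peaking in August in the north and February in the
  south) and a per-year interannual anomaly, so temperature is
  non-increasing down every water column in every month by construction.
- **Land** is laid down as contiguous random blocks (default 30% cover),
  not salt-and-pepper noise, so that the coarse-cell "mostly land"
  matching failure mode of real products actually occurs.
- **Occurrences** are placed on wet cells with probability proportional
  to a Gaussian kernel in temperature around the species' preferred
  temperature, evaluated on the best measure for the species' group, so
  each species' ground-truth affinity is well defined. Records are placed
  intact first and corrupted second (depth blanked at 40%, sign-flipped
  at 2%, date blanked at 5%, year pushed out of coverage at 1% by
  default), keeping the spatial truth available to oracle tests. Sampling
  depths are uniform within the cell's wet column, so
  deeper-than-the-cell exclusions do not arise under the defaults; that
  exclusion path is exercised by targeted tests with hand-built records.
- **Thermal limits** are drawn from
  `a + b·x + c·x² + Normal(0, noise_sd)` on the species' true preferred
  temperature `x`, 1–3 estimates per species, half carrying a reported SD.

Default species preferences are uniform on 4–24 °C with a 1.5 °C niche
breadth — comfortably inside the synthetic ocean's available temperature
range, so the occupancy-derived mean is an essentially unbiased estimate
of the preference. This matters for what the validation can claim: with
preferences near the edge of the available range the kernel truncates and
the estimate attenuates, which is a real phenomenon (range-edge species
in a real ocean suffer the same censoring) but would conflate generator
artefacts with pipeline defects.

**What passing tests do and do not show.** The synthetic ocean has
latitudinally smooth, seasonally sinusoidal temperatures, unbiased
spatial sampling within the thermal kernel, and defects injected
independently at fixed rates. Real occurrence data are taxonomically and
spatially biased, spatially autocorrelated within surveys, and their
defects cluster by data provider. Passing the recovery tests therefore
demonstrates that the *pipeline machinery* is correct — matching is
exact, accounting conserves records, the estimator recovers generating
parameters when its assumptions hold — not that affinity estimates from
real repositories are unbiased.

## Problem sizes and validation design

The validation suite runs at sizes chosen to make each check sharp and the
whole suite quick to iterate: oracle equivalence on a 10×10-cell,
27-band, 24-month world with 1,000 random records (including deliberate
out-of-grid, dateless, and below-floor cases); end-to-end parameter
recovery on 100 replicates of a 50×50-cell world with 200 species × 200
records, generating coefficients (15, 1.2, −0.02) and unit residual noise,
requiring each pooled raw-basis coefficient inside ±3 SE in ≥95% of
replicates and the mean estimated vertex within 2 °C of the generating
optimum at 30 °C; and type-I error calibration of the
interaction-vs-additive F-test on 500 null datasets of 150 species,
requiring rejection at the 0.05 level within 5% ± 2 points. Recovery uses
the climatology "best" measure, where the generator's ground-truth
affinity is defined; the depth-resolved measures are validated by the
oracle-equivalence and accounting checks instead.

## Degenerate inputs and tie-breaks

- A depth of exactly 2,000 m maps to the deepest band (single closed
  edge); deeper records return no band, and during matching surface and
  bottom temperatures are still extracted.
- A record exactly on an interior cell edge belongs to the lower
  (half-open) cell; on the grid's north/east boundary, to the last cell.
- A niche SD of 0 (or kernel underflow far from any available
  temperature) degenerates to placement on the temperature-closest wet
  cell(s).
- An all-land world refuses to place occurrences rather than looping.
- Affinity bins at exactly 10 °C and 20 °C go to cold and moderate
  respectively, per the declared closures.

## File formats

Occurrences, thermal limits, affinities, margins and reports are plain
CSV with documented headers. The two gridded products are serialised as
self-describing JSON documents carrying cell edges, coverage metadata and
full-precision values (missing values as `null`); the loaders validate
the format tag, the dimension bookkeeping, and the depth coordinate
against the standard band scheme, and never fill missing values. The
format round-trips exactly and is diffable text, which keeps fixtures
transparent and version-controllable.

## Known limitations

- No horizontal interpolation or nearest-neighbour fallback: species
  whose records hug coarse coastlines lose more records than
  open-water species, as with the real products.
- Microhabitat effects are invisible: supra-littoral and intertidal
  species experience air temperatures that no sea-temperature product
  captures, and their affinities will look implausibly cold.
- Metric heterogeneity in thermal limits (CTmax vs LT50 vs LT100) is
  recorded but not modelled.
- The generator's bathymetry is a random per-cell deepest band, not a
  physical sea floor; biased-sampling scenarios beyond independent defect
  injection are an extension point, not a feature.

## A worked example

```{r example, eval = FALSE}
w <- make_world(world_config(n_lat = 20, n_lon = 20, seed = 1))
p <- species_params(n_species = 50, seed = 2)
occ <- sample_occurrences(w, p, seed = 3)
lim <- make_thermal_limits(occ$truth, seed = 4)

qc <- qc_occurrences(occ$occurrences)
m <- match_climatology(qc$records, w$climatology)
m <- match_depth_series(m, w$depth_series)
m <- assign_best_temperature(m, occ$truth)
match_report(m)

aff <- summarize_affinity(m)
limits <- aggregate_tmax(select_upper_limit(lim))
d <- merge(limits, aff[aff$measure == "best_clim", c("species_id", "mean")])
names(d)[names(d) == "mean"] <- "affinity"
fit <- fit_polynomial_model(d, form = "pooled")
fit
vertex(fit)
```
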