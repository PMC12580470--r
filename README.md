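# dielshift

Camera-trap analysis of **temporal displacement**: how much a mammal
community shifts its daily activity — toward the night, away from trails —
under combined pressure from hunting and outdoor recreation.

The package targets the paired-deployment survey design used in European
protected areas: cameras at locations on hiking trails, each paired with
an off-trail camera 100 m away in the forest, running for about a year
across seasons with very different hunting intensity. From the raw
trigger streams it computes:

1. **Independent events** — triggers of the same class at the same camera
   are collapsed when separated by less than a class-specific interval
   (8 s for people passing in groups, 5 min for wildlife), chained
   record-to-record.
2. **Hunting-effort strata** — each study month is classed by its share
   of all successful hunting events: `< 5%` low, `5–10%` medium, `> 10%`
   high; the two high windows spanning the turn of the year are pooled.
3. **Relative abundance index (RAI)** and **trail index** — RAI is
   independent events per 100 trap-days; the trail index is

   ```
   TI = ln( (RAI_trail + 1) / (RAI_forest + 1) )
   ```

   positive when a species is recorded relatively more on trails.
   Uncertainty comes from a nonparametric bootstrap over camera
   *locations* (each resampled location brings its trail and forest
   camera together), with percentile CIs and zero-overlap significance
   for trail-vs-forest and cross-stratum contrasts.
4. **Activity curves** — clock time is converted to sunrise/sunset-
   anchored solar time (sunrise at π/2, sunset at 3π/2, via a built-in
   NOAA-style solar ephemeris), events are split into a 24-cell grid of
   effort × placement × recreation intensity (median split of trail
   recreation RAI) × hunting-zone membership, and each cell with ≥ 10
   events gets a von Mises kernel density with bootstrap envelopes.
5. **Nocturnality model** — events are classed day/night by nautical
   twilight (sun 12° below the horizon) and the per-camera night
   proportion is modelled with a beta-binomial regression (logit link,
   mean–precision parameterization, fitted by maximum likelihood) with
   three-way interactions between hunting effort, camera placement, and
   each of distance-to-hunting-zone, recreation RAI and visibility.

A synthetic-data generator (`sim_config()`, `write_synthetic_study()`)
emulates the full study design — 61 paired locations, seasonal hunting
calendar, diurnal recreation with trigger bursts, species event streams
with a known circadian ground truth — so the entire pipeline runs and is
testable without any field data.

## Worked example

The package ships the published pooled RAI estimates of the study system
(five species × three effort strata) for desk-scale checks:

```r
library(dielshift)
ref <- reference_rai_estimates()
r <- ref[ref$species == "red_deer" & ref$effort == "high", ]
c(r$rai_trail, r$rai_forest)
#> [1] 5.55 7.03
round(trail_index(r$rai_trail, r$rai_forest), 2)
#> [1] -0.2
```

Red deer under high hunting effort were recorded somewhat more in the
forest than on trails (TI = −0.20). A full synthetic run:

```r
cfg <- sim_config(n_location_pairs = 10, seed = 99,
                  species_params = default_species_params()["red_deer"],
                  recreation_mean_rate = 3)
paths <- write_synthetic_study(cfg, "study")
rc <- run_config(paths$detections, paths$deployments, paths$hunting,
                 output_dir = "out", species = "red_deer",
                 bootstrap_reps = 200, seed = 1)
res <- run_pipeline(rc, stages = "abundance")
res$abundance_table
#>  stratum rai_trail rai_forest trail_index trail_index_lo trail_index_hi
#>     high      6.78       5.63        0.16          -0.03           0.37
#>   medium      6.44       6.26        0.02          -0.17           0.19
#>      low      6.79       7.65       -0.10          -0.46           0.21
```

Each row pools the 10 trail and 10 forest cameras in one effort stratum:
events per 100 trap-days per placement, the trail index, and its
percentile bootstrap CI over locations. A CI excluding zero would flag a
significant trail/forest difference. `run_pipeline()` with the default
stages also writes the activity-curve grids and the beta-binomial
nocturnality coefficient tables, plus a JSON manifest recording the seed
and all dropped rows/subsets.

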