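# habistack

Flyway-scale habitat analysis from presence-only records, as a tested R
pipeline: per-species presence-background maximum-entropy suitability
models, predictor screening, natural-breaks binarization and stacking into
richness hotspots, group-level climate-driver importance via
gradient-boosted trees, a use-availability land-use preference index,
moving-window landscape diversity, and protected-area gap analysis.

It is written for spatial ecologists who need the whole chain —
occurrences + environmental rasters in, reliability-screened suitability
maps, driver rankings and a regional gap report out — reproducible under a
single seed, and testable end-to-end against a synthetic landscape
generator with known ground truth.

## The models in brief

**Suitability.** For each species, a maximum-entropy distribution over the
background sample, `q(x) = exp(λ·f(x)) / Z`, fitted by minimizing the
L1-penalized negative presence log-likelihood

```
-(1/m) Σ_presences λ·f(x) + log Z + Σ_j β_j |λ_j|
```

with linear/quadratic/hinge features min-max scaled on the background.
Maps are reported on the logistic scale `P = q·e^H / (1 + q·e^H)` (H the
entropy of the fitted background distribution). Per species, 10 replicates
of a 75/25 subsample evaluation give mean AUC and its coefficient of
variation; species with AUC ≤ 0.90 or CV ≥ 0.15 are excluded from all
stacked products.

**Screening.** Zero-contribution variables are dropped, then among pairs
with Pearson |r| ≥ 0.8 at the occupied cells, the lower-contribution
member is removed iteratively.

**Hotspots.** Binary species maps (top class of an exact Fisher–Jenks
3-class split) are summed to richness, reclassified into
non-suitable / low / high; the high class is "suitable habitat".

**Drivers by group.** Boosted trees (binary logistic, inverse-frequency
class weights, 70/30 split, fivefold stratified CV for hyperparameters)
rank climate variables by normalized Gain importance, fold mean ± sd.

**Preference and exposure.** `RF = (occupied suitable area / suitable
area) × 10⁴` per land-cover class; Shannon diversity and evenness in a
900-m moving window; quantile summaries of a disturbance layer over each
group's habitat; per-region suitable/reserve/overlap areas with both
coverage ratios.

## Worked example

```r
library(habistack)

cfg <- landscape_config(nrows = 64, ncols = 64, n_env_layers = 4, seed = 42)
bundle <- simulate_bundle(cfg, n_species_per_group = 2, n_presences = 200)

out <- run_pipeline(bundle$stack, bundle$occurrences,
                    bundle$reserves, bundle$regions,
                    pipeline_config(out_dir = "run42", seed = 42,
                                    n_background = 2000, n_replicates = 5))

read.csv("run42/evaluation.csv")
#>           species auc_mean   auc_sd       cv excluded
#> 1    sp_waders_01   0.9220 0.006921 0.007506    FALSE
#> 2    sp_waders_02   0.9128 0.025731 0.028189    FALSE
#> 3 sp_waterfowl_01   0.9035 0.039520 0.043740    FALSE
#> 4 sp_waterfowl_02   0.9026 0.045785 0.050724    FALSE
#> 5     sp_gulls_01   0.9113 0.041899 0.045977    FALSE
#> 6     sp_gulls_02   0.9057 0.034024 0.037567    FALSE

out$gaps[, c("region", "suitable_area", "reserve_area", "overlap_area",
             "coverage_pct_reserve", "coverage_pct_suitable")]
#>   region suitable_area reserve_area overlap_area coverage_pct_reserve coverage_pct_suitable
#> 1      1       0.00215     0.000909      0.00018                 19.8                  8.37
#> 2      2       0.00000     0.000666      0.00000                  0.0                    NA
#> 3      3       0.00000     0.000090      0.00000                  0.0                    NA
#> 4      4       0.00000     0.001638      0.00000                  0.0                    NA
```

Every species clears the reliability rule (mean AUC > 0.90, CV < 0.15) on
this synthetic landscape; the suitable habitat concentrates in one Voronoi
region, which is 8.4% covered by reserves (areas in 10^4 km^2; ratios are
percent). The `NA`s mark regions with no suitable habitat — a ratio with a
zero denominator is reported missing, never zero.

`evaluation.csv` lists the replicate AUC mean, its spread and the
exclusion flag per species; `importance.csv` the per-group Gain rankings
(means summing to 1); `preference.csv` the RF index per land class;
`gap_report.csv` the per-region areas and the two coverage percentages
(overlap/reserve — the convention of published regional protection tables —
and overlap/suitable). All CSVs are byte-identical across reruns with the
same seed.

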