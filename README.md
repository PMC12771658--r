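# divebudget

Behavior classification, time-activity budgets and energy expenditure from
tri-axial accelerometry on wintering diving ducks.

## The problem

Time-activity budgets for waterbirds are traditionally built from diurnal
shore-based instantaneous scan samples. Scans miss the night, miss birds
beyond ~200 m of shore, and are taken when temperatures are warmest — so
daily energy expenditure (DEE) extrapolated from them can be biased low.
GPS/GSM transmitters with tri-axial accelerometers (ACC) record short
acceleration bursts around the clock (here: 5 s at 10 Hz every 10 min,
with hourly GPS fixes), and a classifier trained on behavior-labelled
bursts turns them into full 24-h budgets.

`divebudget` implements that pipeline end to end for the four-class
ethogram *feeding* (diving + swimming), *flying*, *preening*, *resting*
(loafing + sleeping):

1. **Censoring** — daily displacement from hourly GPS via great-circle
   distances; mean-shift change-points (binary segmentation, reported when
   the standardized mean difference ≥ 0.5) mark the post-surgery
   hyper-movement phase, which is censored along with birds surviving
   ≤ 14 days.
2. **Features** — each burst is trimmed to its middle 3 s, decomposed into
   static (centered running mean) and dynamic components, and summarised
   into a 94-feature battery (per-axis statistics, inverse coefficient of
   variation `mean/SD`, ODBA `mean(|dx|+|dy|+|dz|)`, VeDBA
   `mean(√(dx²+dy²+dz²))`, Euler posture angles, axis correlations), then
   thinned with a greedy |r| > 0.9 correlation filter.
3. **Classification** — gradient-boosted decision trees (500 trees, depth
   3, η = 0.1); features are ranked by ensemble gain and the top 3 are
   refit into the final model, evaluated by confusion matrix and
   per-class F1.
4. **Budgets** — NOAA solar geometry assigns each burst to
   `[sunrise, sunset)` (diurnal) or its complement; bird-days with < 95 %
   of expected bursts are dropped; proportions are aggregated per period,
   per bird, or pooled. Scan records get both summary conventions
   (per-scan mean and pooled counts).
5. **Energetics** — hourly energy expenditure
   `HEE = RMR · Σᵢ aᵢ tᵢ + C_T` with RMR = 15.89 kJ/bird/h, multipliers
   a_feeding = 1.85, a_preening = 1.66, a_resting = 1.05, and
   a_flight = 3.6 · 52.6 · M^0.74 / RMR (= 9.2 at M = 0.70 kg);
   thermoregulation `C_T = 0.1392 · max(0, 14.4 − T) · 20.1` kJ/h.
   DEE is the 24-h sum, or mean HEE × 24 / × daylight hours for the
   scan-style extrapolations.
6. **Contrasts** — Wilcoxon rank-sum (r = |Z|/√N), binomial GLM/GLMM with
   per-bird random intercept, and Welch t-tests with Cohen's d.

A synthetic world generator produces every input table (labelled ACC
bursts, GPS tracks with post-release displacement decay, winter weather,
truth schedules, shore-truncated scans) with known ground truth, so the
whole pipeline is testable at desk scale.

## Worked example

```r
library(divebudget)

report <- run_pipeline(world_config(n_birds = 5, n_days = 16, seed = 11),
                       n_train = 100, quiet = TRUE)
report$model$features
#> [1] "x_sd"   "x_mean" "y_mean"
round(unlist(report$energy), 1)
#>           hee_diurnal         hee_nocturnal               hee_24h
#>                  48.8                  63.3                  57.2
#>         acc_dee_sum24              scan_hee scan_dee_extrapolated
#>                1373.9                  50.3                1208.3
#>     scan_dee_daylight        daylight_hours
#>                 492.5                   9.8
report$flags
#> $nocturnal_hee_gt_diurnal
#> [1] TRUE
#> $acc_dee_gt_scan_dee
#> [1] TRUE
```

Reading the output: the classifier picked three posture/intensity
features; nocturnal mean HEE (63.3 kJ/bird/h) exceeds diurnal (48.8)
because nights are colder and carry more flight, and the full 24-h ACC
DEE (1374 kJ/bird/day) exceeds the value obtained by extrapolating
diurnal scan samples to 24 h (1208) — the scan method misses exactly the
expensive nocturnal hours. `report$stats` holds the corresponding
rank-sum, GLMM and t-test results.

Single pieces are available directly, e.g.

```r
budget_from_counts(rbind(
  diurnal   = c(feeding = 32715, flying = 2607, preening = 50003, resting = 1456),
  nocturnal = c(feeding = 22838, flying = 4063, preening = 74232, resting = 3272)))
#> Time-activity budget
#>      scope n_total n_feeding p_feeding n_flying p_flying n_preening p_preening n_resting p_resting
#>    diurnal   86781     32715     0.377     2607   0.0300      50003      0.576      1456    0.0168
#>  nocturnal  104405     22838     0.219     4063   0.0389      74232      0.711      3272    0.0313
#>      total  191186     55553     0.291     6670   0.0349     124235      0.650      4728    0.0247
```

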