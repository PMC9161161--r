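# greenkeeper

Decision support for precision nitrogen (N) management on sand-based
creeping-bentgrass putting greens.

Putting greens are the most intensively fertilized turf on a golf course,
yet almost no soil test guides their N program: managers fertilize on
experience, which tends toward over-application. On a sand root zone the N
cycle simplifies — fertilizer in, clippings out, losses negligible — so the
right dose can be tied to how much the grass actually grows. `greenkeeper`
implements four dosing strategies around that idea, plus a seeded virtual
putting green on which they can be run, audited and compared end to end:

1. **Growth-potential (GP) dosing** — the temperature-only growth index

   `GP(T) = exp(−0.5·((T − T₀)/var)²)`, `T₀ = 20 °C`, `var = 5.5`

   scales a capped replacement dose: `dose = mean(GP) × Gmax × c_N × Δt × 10`
   with maximum daily growth `Gmax = 3.2 g m⁻² d⁻¹`, tissue N concentration
   `c_N = 0.039`, and `Δt = 14 d`, giving a 17.47 ≈ 17.5 kg ha⁻¹ biweekly cap.
2. **Experience schedule** — 10 kg ha⁻¹ every other week, ~150 kg ha⁻¹ per
   30-week season.
3. **NDRE threshold** — withhold N when the mean normalized-difference
   red-edge index of the last 14 days exceeds 0.28 (the virtual-reference
   reading of turf at minimally acceptable quality 6); otherwise 10 kg ha⁻¹.
4. **Regression-forest (ML-RF) dosing** — an in-package random forest
   predicts the next two weeks' clipping yield from weather, ET, soil
   moisture, traffic, NDRE, recent N and root zone; the dose replaces the
   predicted clipping N inside the target band 17.5–22.5 g m⁻²/2 wk
   (quality 6–7), pushes toward the band median (20) below it, and is zero
   above it.

Budgets close the loop: uptake = clippings × 3.9% × 10 (kg ha⁻¹), and
`NUE = (uptake − control uptake) / N applied × 100`.

## Worked example

A two-year virtual trial (calibration year + evaluation year) on two root
zones differing in organic matter, all four strategies plus an unfertilized
control, two replicate plots:

```r
library(greenkeeper)
report <- run_trial(trial_config(master_seed = 42, replicates = 2))
print(report)
```

```
Virtual N trial (master seed 42): 20 plots
   zone   strategy cum_n_applied cum_clipping  nue mean_quality mean_ndre
1     A    control           0.0         83.6   NA         2.59     0.243
2     B    control           0.0        105.1   NA         3.00     0.250
3     A experience         150.0        416.5 86.6         7.95     0.310
4     B experience         150.0        424.6 83.1         8.03     0.311
5     A         gp         223.8        473.2 67.9         8.40     0.316
6     B         gp         223.8        477.0 64.8         8.42     0.316
7     A       mlrf          83.6        281.2 92.2         6.12     0.290
8     B       mlrf          79.0        288.6 90.6         6.25     0.291
9     A       ndre          75.0        267.7 95.9         5.86     0.287
10    B       ndre          60.0        255.9 98.0         5.67     0.285
```

Reading it: the GP model, running near its temperature optimum, applies the
most N (223.8 kg ha⁻¹ in the evaluation season) and produces the lushest
turf but the lowest N use efficiency; the experience schedule applies its
fixed 150; the forest-guided plan (~80 kg) and the NDRE rule (60–75 kg) cut
N by roughly two thirds while holding quality near the acceptable 6 mark —
and only those two strategies respond to the root-zone difference (note
their A ≠ B totals, while GP and experience dose both zones identically).
`report$ratio_stats` shows the forest's biweekly predictions centered near
the observed yields (median ratio ≈ 0.9) while the GP model over-forecasts
growth (median ≈ 1.2 here; larger whenever the green cannot realize its
temperature potential). `percent_reduction(223.8, 75)` → 66 (% less N than
GP). `export_report(report, "out/")` writes `report.csv`,
`fertilization_log.csv` and `report.json` (seeds included; re-runs are
byte-identical).

Single components are plain functions: `growth_potential(20)` → 1,
`gp_dose(weather_14d)` → 17.47 kg ha⁻¹ at full potential, `ndre_dose()`,
`mlrf_dose(20)` → 7.8 kg ha⁻¹, `n_budget(184.2, 80, 64.9)$nue` → 58.2.

## Command line

```sh
exec/greenkeeper gp-dose --weather weather.csv --interval 14
exec/greenkeeper ndre-dose --history ndre.csv --date 2021-06-14 --threshold 0.28
exec/greenkeeper mlrf-train --obs obs.csv --weather weather.csv --model m.rds
exec/greenkeeper mlrf-recommend --model m.rds --features next14.csv
exec/greenkeeper evaluate --obs obs.csv --fert fert.csv --control control.csv
exec/greenkeeper run --config trial.yaml --out outdir
```

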