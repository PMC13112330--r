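# benthochange

Change detection for benthic foundation species — cold-water corals
(Cnidaria) and sponges (Porifera) — between repeat georeferenced
photomosaic surveys of fixed monitoring sites. The package is aimed at
benthic ecologists running long-term monitoring programs on seamounts and
other deep-sea habitats intersecting an oxygen minimum zone (OMZ), where a
baseline mosaic (T0) and a revisit 3–5 years later (T1) must be turned
into defensible statements about population loss and health decline.

## What it computes

Given per-timepoint annotation tables (one row per individual: identity,
projected x/y in metres, and four ordinal condition metric scores at T1):

* **Individual matching** — greedy nearest-neighbour assignment within an
  OTU under a distance cap (default 0.5 m ≈ georeferencing RMSE + margin),
  resolving every individual to *survived*, *lost* or *recruit*, after
  clipping the baseline to the survey overlap polygon.
* **Oxygen zones** — per-site mean dissolved oxygen, classified into the
  regional OMZ zones ([O₂] > 1, 1–0.5, < 0.5 mL/L) with boundaries
  assigned upward, and zone stability between surveys (raw concentrations
  from different instruments are never differenced).
* **Condition score** — for each metric, scores are frequency-weighted by
  cumulative occurrence, `w(s) = (n₁ + … + n_s)/n_total`, then severity
  scaled by `s/S_max`; negative metrics (tissue loss, biofouling,
  orientation change) flip sign, and the summed score is clamped to
  [−1, 1]. The maximum observed level of every metric carries weight 1.
* **Δ abundance** — per-OTU percent change `100·(A₁ − A₀)/A₀` within any
  factor (site, phylum, zone, seamount), pooling counts before the ratio;
  plus fate tallies with the identities `n_t0 = survivors + lost`,
  `n_t1 = survivors + recruits`.
* **Test battery** — paired Wilcoxon signed-rank tests (one-sided
  "greater", Bonferroni family of two) that are *exact under ties and
  zeros* via a shift-algorithm enumeration for n ≤ 30; exact two-sample
  rank-sum tests; tie-corrected Kruskal–Wallis; Dunn's post hoc with Holm
  (or Bonferroni) adjustment.
* **Synthetic surveys** — a generator with per-site survival, recruitment,
  metric-score distributions, positional jitter and partial revisit
  coverage, emitting ground truth, plus `seamount_study_config()`, a
  12-site configuration whose expected totals mirror the published
  Northeast Pacific monitoring aggregates (844 individuals, expected gross
  losses 143 + 32, expected recruitment 12).

## Worked example

```r
library(benthochange)

bundle <- generate_study(seamount_study_config(), seed = 42)
report <- run_pipeline(bundle, tolerance = 0.5)
report
#> Repeat-survey change report
#>   sites: 12, individuals T0: 531, T1: 427
#>   survivors: 357, lost: 174, recruits: 70 (net -104)
#>   tests run: 10 (see $stats)
```

The analyzed baseline (531) is smaller than the generated 844 because the
five partial-coverage sites are clipped to their revisit windows before
matching. Losses (174) and recruits (70) are *observed* fates: with
realistic 0.25 m jitter some survivors near the matching tolerance are
scored as a loss plus a recruit, exactly as in real mosaic pairs.

```r
summarize_headline(report)
#> # A tibble: 1 × 7
#>   n_sites sites_abundance_decline sites_condition_decline net_loss ...
#> 1      12                      11                      10      104
classify_zone(monitoring_sites()$o2_t0_ml_l)
#>  [1] LOW  LOW  LOW  LOW  LOW  LOW  LOW  LOW  MID  HIGH LOW  LOW

signed_rank_test(c(3, 5, 7), alternative = "greater")
#> Wilcoxon signed-rank test (exact)
#> V = 6, n = 3, alternative = greater, p = 0.125
```

`report$stats` is a tidy table (one row per test); individual results have
`tidy()`/`glance()` methods, and `plot_abundance_change()` /
`plot_condition()` give summary figures. A thin command-line wrapper with
`simulate`, `run` and `report` subcommands ships in
`inst/cli/benthochange-cli.R`.

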