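# baskettrend

Trend analysis of grocery purchase prices, expenditure shares and
nutrient density across ordinal income-adequacy groups.

## What problem this solves

Loyalty-card transaction data make it possible to ask how a
household's *perceived income adequacy* (PIA) — a five-level ordinal
self-assessment of how well disposable money covers needs — relates to
what the household actually buys: the price paid per kilogram and per
megajoule within each food group, the share of total energy (E%) and
expenditure (EX%) allocated to each group, and the nutrient density of
the basket (Nutrient Rich Food Index, NRFI). `baskettrend` packages
that analysis for epidemiologists and nutrition researchers as a
tested, reproducible pipeline:

* **Cohort filters** — loyalty ≥ 41%, annual purchases ≥ 100 €, a
  substantive PIA answer (levels 1–5).
* **Basket aggregation** — per participant × food group sums of
  expenditure (€), volume (kg) and energy (MJ); derived prices
  €/kg = expenditure/volume and €/MJ = expenditure/energy; E% and EX%
  shares; volume-weighted NRFI.
* **Trend inference** — the two-sided Jonckheere–Terpstra test
  U = Σ_{ℓ<ℓ'} Σ_{a∈ℓ, b∈ℓ'} k(x_a, x_b) with the tie kernel
  (k = 1 if x_a < x_b, 0.5 on ties), unweighted (tie-corrected
  asymptotic null, exact enumeration for n ≤ 9) and
  inverse-probability weighted for confounding by education and sex
  (multinomial propensity model; seeded within-stratum permutation
  null), with Benjamini–Hochberg FDR control at 5% and a
  median-variance effect size per group.
* **Synthetic data** — a generator that emulates the statistical
  structure of such cohorts (confounded ordinal PIA, per-group
  multiplicative price gradients, shifting volume shares, lognormal
  prices), so every stage is verifiable against known ground truth
  without proprietary retailer data.

Because real loyalty-card datasets of this kind are proprietary, the
package's claims are property-based: known gradients are recovered,
null configurations stay null, and the tests hold their nominal size.

## Worked example

```r
library(baskettrend)

cfg <- sim_config(n_participants = 1000, seed = 2018)
res <- run_pipeline(cfg, out_dir = "out", n_perm = 2000)

str(res$manifest$counts)
#> List of 5
#>  $ participants_in: int 1000
#>  $ included       : int 805
#>  $ exclusions     :List of 3
#>   ..$ expenditure_below_min: int 24
#>   ..$ loyalty_below_min    : int 124
#>   ..$ pia_not_stated       : int 47
#>  $ transactions   : int 626970
#>  $ major_groups   : int 17

subset(res$trends, outcome == "price_per_kg" &
       group %in% c("Fish and seafood", "Potatoes"))[,
  c("group", "z", "z_w", "p_w", "p_bh", "significant", "effect_size_pct")]
#> # A tibble: 2 x 7
#>   group                 z    z_w      p_w     p_bh significant effect_size_pct
#> 1 Fish and seafood 18.2   12.9   0.000500 0.000531 TRUE             0.347
#> 2 Potatoes          0.429  0.949 0.347    0.347    FALSE            0.00000779
```

1,000 simulated cardholders are generated; 805 pass the inclusion
filters (124 below the 41% loyalty threshold, 24 under 100 € of
annual purchases, 47 declined the PIA question). The default
configuration injects a 5%-per-level price gradient everywhere except
potatoes, and the results recover exactly that: the €/kg trend for
fish is strongly positive (weighted z = 12.9, BH-adjusted p ≈ 0.0005)
while potatoes shows no significant trend. `z` is the unweighted
asymptotic statistic, `z_w`/`p_w` the education/sex-weighted
permutation version, and `effect_size_pct` the share of overall
median variability lying within the group across PIA levels.

The same objects expose the median matrices
(`res$medians$price_per_kg`), price correlations
(`res$correlations`), and the Figure-style bivariate trajectories
(`res$trajectories$energy$series` gives each group's path span and
direction from PIA 1 to 5). `out/` contains the full CSV set plus a
`manifest.json` sufficient to re-run the pipeline bit-identically.

A thin CLI wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/baskettrend.R", package="baskettrend"))')" \
  simulate --config cfg.yaml --out data_dir --seed 7
```

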