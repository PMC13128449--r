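# regrow

Resistance, return rates and recovery times of biodiversity along forest
chronosequences.

## What it is for

When agricultural land in the tropics is abandoned, how quickly do the
abundance, diversity and species composition of its communities return to an
old-growth forest state? `regrow` answers this with a space-for-time
(chronosequence) design: plots under active use (cacao or pasture), secondary
forest plots of known age since abandonment, and undisturbed old-growth
reference plots. It is aimed at community ecologists analysing
species-by-plot abundance matrices for one or many taxa.

The package decomposes resilience into two components per land-use legacy:

- **Resistance** — how much of an ecological attribute ψ survives active
  land use, relative to the old-growth reference:

  `Resistance = exp(−|ln(ψ₀ / ψ_Ref)|)`

  where ψ₀ and ψ_Ref are the central values (median by default) of the
  attribute over active and old-growth plots. The measure lives in
  [0, 100] % and penalises levels above the reference as well as below
  (a ratio of 0.7 scores 70 %, a ratio of 1.3 scores 77 %).

- **Return rate** λ (per year) — the rate constant of the
  negative-exponential approach to the reference after abandonment,
  estimated by least squares with ψ₀ and ψ_Ref held fixed:

  `ψ(t) = ψ₀ + (ψ_Ref − ψ₀)(1 − e^{−λt})`

From these it derives the **recovery time** to within ±10 % of the
reference,

  `T_rec = −ln(0.1 ψ_Ref / |ψ_Ref − ψ₀|) / λ`

and the **relative recovery after 30 years** (the resistance formula applied
to the modelled ψ(30)). Communities with resistance > 90 % count as
instantaneously recovered (T = 0, no rate); fitted times beyond 300 years
are either zeroed (when active and old-growth spreads overlap — an artefact
of data spread) or classified as *arrested recovery*.

Ecological attributes supported: total abundance; alpha Hill diversity of
orders 0, 1, 2; and compositional similarity to the old-growth reference via
Bray–Curtis, the beta-Hill overlap transforms (Sørensen / Horn /
Morisita–Horn for q = 0, 1, 2), or Jaccard for presence/absence
(literature) data. Uncertainty comes from a leave-one-plot-out jackknife;
cross-taxon analyses (random-forest predictor importance, Spearman, paired
signed-rank, Kruskal–Wallis with FDR control) compare the components across
taxa. A seeded synthetic chronosequence generator with known ground truth
underpins the test suite and provides ready-made example data.

## Worked example

```r
library(regrow)

d <- generate_study_shaped_dataset(seed = 42)   # 62 plots, 4 taxa
sm <- summarize_resilience(d$abundances$canopy_taxon, d$plots,
                           "bray_curtis_sim")
sm[, c("legacy", "resistance_pct", "return_rate",
       "recovery_time_years", "relative_recovery_pct", "classification")]
#>    legacy resistance_pct return_rate recovery_time_years
#> 1   cacao           44.6      0.0551                31.0
#> 2 pasture           48.5      0.0481                34.1
#>   relative_recovery_pct classification
#> 1                  89.4          normal
#> 2                  87.8          normal
```

About 45 % of the compositional similarity to old growth survives active
use; the fitted return rate of ~0.055 / year implies roughly 31 years until
the cacao-legacy community is within 10 % of the reference, and the modelled
trajectory has regained ~89 % of the reference similarity at year 30. The
taxon was generated with λ = 0.05 and a compositional resistance target of
0.4, so the pipeline recovers its ground truth.

The fit itself is a first-class object:

```r
series <- metric_series(d$abundances$canopy_taxon, d$plots, "bray_curtis_sim")
fit <- fit_recovery(series, legacy = "cacao")
fit
#> Negative-exponential recovery fit (bray_curtis_sim, cacao legacy)
#>   lambda    = 0.055147 per year (SE 0.00405, p = 3.4e-12, significant)
#>   psi0      = 0.29018   psi_ref = 0.65075  (median)
#>   R-squared = 0.939 on 23 plots
tidy(fit)     # broom-style coefficient table
autoplot(fit) # points + fitted trajectory
```

Jackknife intervals and the full multi-taxon artifact set (summary TSV,
pairwise similarities, CIs, comparative statistics, JSON run manifest):

```r
ens <- jackknife_resilience(d$abundances$canopy_taxon, d$plots,
                            "bray_curtis_sim", "cacao")
ci_from_ensemble(ens)

run_pipeline(d$plots, d$abundances, out_dir = "out",
             metrics = c("abundance", "hill_q1", "bray_curtis_sim"))
```

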