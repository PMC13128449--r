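---
title: "Decomposing biodiversity resilience along a chronosequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing biodiversity resilience along a chronosequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrow)
```

## The model

`regrow` treats recovery after agricultural abandonment as a single-regime
return to an old-growth reference state. For an ecological attribute ψ
(total abundance, a Hill diversity, or compositional similarity to the
reference), the trajectory over time since abandonment `t` is

$$\psi(t) = \psi_0 + (\psi_{Ref} - \psi_0)\,(1 - e^{-\lambda t}),$$

so the distance to the reference shrinks at the constant **return rate**
λ (per year). **Resistance**, the fraction of the attribute surviving
active land use, is the negative exponential of the absolute log-ratio of
the active level to the reference,

$$\mathrm{Resistance} = \exp(-|\ln(\psi_0/\psi_{Ref})|) \in [0, 1],$$

which deliberately penalises attribute levels *above* the reference as
well as below: an active community at 130 % of the old-growth level is
still a disturbance effect and scores 0.77, not 1. The **recovery time**
is the solution of the trajectory for ψ(t) = 0.9 ψ_Ref (recovery from
below) or 1.1 ψ_Ref (from above), a ±10 % tolerance band that absorbs
natural variation among old-growth plots:

$$T_{rec} = \frac{-\ln\!\big(0.1\,\psi_{Ref} / |\psi_{Ref} - \psi_0|\big)}{\lambda}.$$

The same log-ratio transform applied to the modelled ψ(30) gives the
**relative recovery after 30 years**, a horizon chosen to be meaningful
for restoration planning while staying inside the age range a
chronosequence of up to ~40 years supports.

Underlying assumptions worth keeping in mind: plots of different ages are
exchangeable realisations of one successional trajectory (the
space-for-time substitution); recovery is monotone with a single
asymptote — no alternative stable states, no overshoot dynamics; and the
active-plot level is a valid estimate of the starting condition of the
recovering plots.

## The metric layer

Per-plot attributes are total abundance and alpha Hill numbers
(`q` = 0, 1, 2: richness, exponential Shannon entropy, inverse Simpson).
Compositional similarity of a plot to the reference is the mean of its
pairwise similarities to every old-growth plot. The reference value
ψ_Ref for similarity is built the same way *within* the old-growth set:
each old-growth plot's mean similarity to the others is computed, and the
median of those means is the asymptote — full recovery means being as
similar to old growth as old-growth plots are to each other.

Pairwise similarity options:

* **Bray–Curtis** (the default compositional metric), computed on
  within-plot relative abundances via `vegan::vegdist` and flipped to a
  similarity.
* **Beta-Hill overlap** of order `q`: the pair's gamma Hill diversity over
  its alpha Hill diversity (two assemblages, equal weights; alpha computed
  from the joint assemblage with each within-plot relative abundance
  halved), transformed from the [1, 2] beta range to a [0, 1] overlap.
  These transforms reduce exactly to Sørensen (`q` = 0), Horn (`q` = 1, via
  the Shannon-beta limit) and Morisita–Horn (`q` = 2), and the test suite
  pins the partitioning convention by checking those equivalences against
  independently coded textbook formulas on random communities.
* **Jaccard** on presence/absence, for literature datasets without
  abundances.

Centering rule: ψ₀ and ψ_Ref are medians (robust to outliers) unless the
old-growth median is exactly 0, in which case both switch to means —
recovery towards a reference of 0 is not biologically meaningful. The
±10 % tolerance of the recovery-time formula uses whichever center
ψ_Ref was computed with. Species with zero total abundance are dropped
before any metric; plots with zero totals are dropped from series that
cannot define their metric, with a logged reason.

## Fitting choices

Only λ is free in the trajectory fit; ψ₀ and ψ_Ref are fixed at the data
centers. Fitting them freely would decouple resistance (defined from the
same centers) from the curve and let the asymptote drift away from the
old-growth level; a `free_psi0` switch exists for sensitivity work and
profiles ψ₀ out linearly at each candidate λ. Active plots enter at
`t` = 0 alongside the secondary plots of the same legacy, and the two
legacies (cacao, pasture) are always fitted separately.

Numerics: λ is constrained to [0, 10] per year; the sum of squared errors
is scanned on a logarithmic bracketing grid (121 points down to 10⁻⁴) and
polished by Brent minimisation at tolerance 10⁻¹²; a solution is accepted
only if it beats the λ = 0 boundary. The objective has a single relevant
basin in practice, and the unit tests verify agreement with a dense
10⁻⁴-step grid search on noisy series. The standard error is the
one-parameter Gauss–Newton (asymptotic) form
`sqrt(SSE/(n−1) / Σ J_i²)` with `J_i = (ψ_Ref − ψ₀) t_i e^{−λ t_i}`, and
significance of λ is a two-sided Wald test at α = 0.05. R² is
`1 − SSE/SST` over the fitted points; a degenerate flat series returns
λ = 0, flagged non-significant.

Rule order for the summary: resistance > 90 % ⇒ the community is treated
as undisturbed or instantaneously recolonised — recovery time 0, no
return rate estimated (the relative recovery at the horizon then equals
the resistance). Otherwise the draft recovery time above 300 years is
resolved against the data spread: if the mean ± SD intervals (sample SD,
n − 1) of active and old-growth plot values overlap, the huge time is an
artefact of spread and is zeroed; if they are disjoint the community is
**arrested** and the value is kept, reported as “>300”. The cap and the
30-year horizon are configurable (`cap_years`, `t_eval`). A gap
|ψ_Ref − ψ₀| inside the tolerance band with resistance still ≤ 90 %
(possible only under the mean rule) yields T = 0 with a warning.

## Uncertainty

Errors are leave-one-plot-out jackknife, not bootstrap: with ~20–40 plots
per legacy, resampling with replacement discards too much information per
replicate. Each replicate deletes one plot eligible for the legacy —
its active and secondary plots plus *all* old-growth plots, which both
legacies share — and reruns the entire computation, including the
similarity-to-reference values and ψ_Ref itself. Intervals are percentile
intervals (2.5th–97.5th, linear interpolation between order statistics —
`quantile` type 7; the convention is stated because none is standard)
over the replicate statistics; trajectory envelopes are pointwise
percentiles over the replicate curves. Replicates where the
instant-recovery rule fires contribute no rate; rate intervals are taken
over defined replicates only, with the count reported. Arrested
replicates propagate an infinite upper recovery-time bound, rendered
“>cap”.

A known limitation, verified on synthetic data: leave-one-out replicates
deviate from the full-data estimate by O(1/n), so the percentile band is
systematically **narrower** than a sampling-distribution confidence
interval, and its coverage of a generating parameter is well below the
nominal 95 % (the suite's sanity check asserts only a loose floor). The
band is best read as a deletion-sensitivity diagnostic. The
replicate-equals-independent-rerun property, by contrast, is exact and
tested exactly.

## The synthetic chronosequence

The generator exists so every stage is testable against known ground
truth. Its defaults mirror the targeted field design: 6 active plots per
legacy, 17/16 secondary plots (cacao/pasture legacies) with integer ages
drawn uniformly on 1–38 years, 17 old-growth plots — 62 in total.

Community construction: an old-growth expected composition `p_OG` is
drawn from a lognormal rank-abundance model (meanlog 0, sdlog 1 — a
typical evenness for species-rich tropical samples; 100 species by
default). The disturbed composition is
`r·p_OG ⊕ (1−r)·p_spec` with a disjoint pool of 40
disturbance-specialist species, so the expected Bray–Curtis similarity of
the disturbed to the old-growth composition equals the target resistance
`r` exactly. A plot of age `t` samples counts multinomially (500
individuals — a realistic per-plot sampling depth at which sampling noise
is visible but not dominant) from a Dirichlet-perturbed mixture
`(1−w)p_D + w·p_OG` (concentration 200, giving the plot-to-plot
heterogeneity that makes old-growth plots only ~60 % similar to each
other, much as replicate field plots are).

Because Dirichlet heterogeneity and finite depth attenuate *measured*
similarities nonlinearly in the mixture weight, feeding the raw weight
`w = 1 − e^{−λt}` into the sampler would bend the expected similarity
trajectory away from the negative exponential and bias the recovered λ
upward. The generator therefore calibrates: it estimates the
weight-to-expected-similarity map by Monte Carlo (21-point grid, 40
sampled plot pairs per point, seeded) and inverts it so the expected
measured similarity itself follows the trajectory at exactly the
configured rate. Bray–Curtis is the calibration target, matching its role
as the headline compositional metric; the Hill-beta similarities are
measured on the same communities but not calibrated.

What the generator does *not* emulate: spatial autocorrelation and
landscape context, differences in sampling effort between plots,
detection error, species interactions or dispersal limitation, and any
mechanism behind arrested recovery beyond setting λ = 0. Passing the
parameter-recovery tests therefore shows the pipeline is correct and
well-calibrated under its own assumptions — not that those assumptions
hold for any particular field system.

Problem sizes in the test suite are the package's own balance of power
against runtime: the parameter-recovery experiment uses 50 seeds at the
full 62-plot design (median relative error on λ under 15 %, mean measured
resistance within 10 percentage points of target); the jackknife
coverage sanity check uses 30 seeds at a reduced design.

## Cross-taxon statistics

The relative importance of resistance versus return rate for recovery
time across taxa uses random-forest regression (`ranger`, 500 trees,
default split rules, impurity importance, explicit seed — the forest is
the only stochastic component, so determinism demands pinning). Taxa
under the instant-recovery rule carry no rate and are excluded, as are
undefined or infinite recovery times; both counts are reported.
Associations use Spearman's rank correlation with midranks; paired
contrasts use the Wilcoxon signed-rank test (zeros dropped; exact
enumeration when ≤ 10 untied pairs remain, otherwise the normal
approximation with continuity correction); grouped contrasts
(life-history rank, dispersal mode, trophic level) use Kruskal–Wallis
with tie correction. All grouped tests run in one declared family and are
adjusted together by Benjamini–Hochberg FDR. Literature-style datasets
(presence/absence only) run through the identical pipeline restricted to
richness (`hill_q0`) and Jaccard similarity, with explicit skip reasons
for studies missing a stage or a usable (≥ 2 sample) reference.

## Interface notes

Everything user-facing takes a data frame first and returns a tibble;
fits are small S3 objects with `tidy()`, `glance()`, `augment()`,
`predict()` and `autoplot()` methods. `run_pipeline()` composes
validation → metrics → fits → jackknife → comparative statistics and
writes the artifact set (summary TSV shaped like a per-taxon results
table, long pairwise-similarity TSV, CI table, JSON manifest with seed
and versions). Readers auto-detect tab- or comma-delimited text from the
header line; ages are real-valued years and are never rounded; plots and
species are identified by id strings, never by position.

## Known limitations

* A single recovery model: no linear, logistic or multi-asymptote
  alternatives, by design, so that λ and T_rec are comparable across all
  taxa and attributes.
* Recovery times extrapolated beyond the oldest secondary plot (~38
  years) inherit the model's functional form; they are reported with
  intervals but are less reliable than interpolated ones.
* The jackknife band understates sampling uncertainty (see above).
* Coverage-standardised (rarefied/extrapolated) Hill numbers are out of
  scope; all diversities are computed on observed counts.
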