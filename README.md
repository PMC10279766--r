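# isoweb

Stable isotope trophic analysis of benthic food webs.

Deep-sea communities — cold-water coral reefs in particular — are hard to
observe feeding, so their trophic structure is usually inferred from
carbon and nitrogen stable isotopes. δ¹³C records the primary carbon
source of a web; δ¹⁵N increases by a roughly constant trophic enrichment
factor (TEF ≈ 3.4 ‰) at each feeding step, so a consumer's continuous
trophic position relative to an isotopic baseline (here suspended
particulate organic matter, SPOM, at trophic level λ = 1) is

```
TP = λ + (δ¹⁵N − δ¹⁵N_baseline) / TEF
```

`isoweb` implements that workflow end to end for ecologists working with
group-level or sample-level isotope tables:

* δ-value computation from raw isotope ratios, validation, aggregation
  and baseline pooling;
* trophic position estimation with propagated uncertainty
  (`sd(δ¹⁵N)/TEF`) and TEF sensitivity scans;
* trophic guild detection by k-means on the (δ¹³C, δ¹⁵N) plane —
  k-means++ seeding, 100 restarts, exhaustively-verified optimality on
  small sets — with elbow, silhouette and gap-statistic selection of the
  number of guilds and majority voting;
* whole-web metrics: isotopic ranges, inter-guild distances in ‰ and in
  trophic levels, δ¹³C–δ¹⁵N correlation;
* a seeded synthetic food-web generator with ground truth, so every
  stage is testable against known answers (exact recovery at zero
  noise, closed-form TEF-misspecification bias, Monte-Carlo guild
  recovery).

A packaged fixture (`angola_reef_groups()`) carries published
group-level means for an Angolan margin cold-water coral reef community
(29 groups: 6 particulate organic matter pools, 23 consumer taxa).

## Worked example

```r
library(isoweb)
groups <- angola_reef_groups()
res <- run_pipeline(groups, k = 4, seed = 1)
#> input interpreted as group-level summaries (29 groups)
#> baseline: d15N = 4.23 per mil (lambda = 1) from SPOMtrap342, SPOMtrap526, SPOM342, SPOM532
#> trophic positions computed for 23 fauna groups (TEF = 3.4 per mil)
#> k fixed to 4
#> k-means: raw per-mil axes, n_init = 100, WSS = 64.895

res$guilds[, c("cluster", "n", "mean_d13C", "mean_d15N", "mean_tp")]
#>   cluster  n mean_d13C mean_d15N  mean_tp
#> 1       1  6 -21.56667  4.831667       NA
#> 2       2 14 -18.70214 12.855000 3.538235
#> 3       3  4 -13.98500 14.962500 4.158088
#> 4       4  5 -18.71800 20.190000 5.695588
```

Reading the output: the SPOM baseline pools the four suspended-matter
groups to δ¹⁵N = 4.23 ‰. The four guilds, numbered by ascending mean
δ¹⁵N, are (1) the particulate organic matter pools (no trophic
position — they are the baseline side of the web), (2) fourteen
suspension feeders around TP 3.5, sitting ~2.4 trophic levels above the
POM pool — evidence of an unsampled intermediate food source such as
zooplankton, (3) echinoderms plus a eunicid polychaete around TP 4.2
with strongly ¹³C-enriched tissue (predation/detritivory), and (4) five
sponge taxa whose extreme δ¹⁵N puts their nominal TP near 5.7, a known
signature of microbially-mediated nitrogen cycling rather than of
apex predation. `run_pipeline(..., out_dir = "run")` additionally writes
`tp_table.csv`, `clusters.csv`, `cluster_summary.csv`,
`web_metrics.json` and a run manifest; with `k = NULL` it first selects
k by the three-method vote and writes `kselect.csv`.

Simulation-based validation follows the same surface:

```r
sim <- simulate_web(default_web_spec(seed = 7))
recovery_report(sim, seed = 1)
#> Recovery report: 23 taxa
#>   adjusted Rand index: 1
#>   max |TP error|: 0.349
```

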