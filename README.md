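# imgtx

Imaging transcriptomics in R: does the spatial distribution of a gene's
expression across the human brain match the spatial distribution of
task-related brain activation?

The package is for researchers who have (or want to emulate) two very
different resources: a donor expression atlas — a few hundred sampling
sites per postmortem donor, each with MNI coordinates and probe-level
normalized microarray expression — and a coordinate-based meta-analytic
study database, where each published fMRI study carries term labels and a
list of activation foci in MNI millimeters. `imgtx` builds the bridge
between them and quantifies its strength, with a synthetic-data generator
(planted, known effect sizes) so every stage has a ground-truth recovery
test.

## The statistic at its core

For a term *T* with studies *S(T)*, the activation-likelihood map is

> v(x) = #{ s ∈ S(T) : min over foci f of s of ‖f − c(x)‖ ≤ r } / |S(T)|

with c(x) the center of voxel x and r a kernel radius (10 mm default).
For donor d with sites i = 1..n, gene expression g (probe-averaged) and
map values m at the sites, both standardized, the per-donor statistic is
the OLS slope β_d (= Pearson r_d), with a two-tailed p on n − 2 df. The
across-donor inference is an approximate random-effects analysis:

> t = mean(β) / (sd(β) / √D),  df = D − 1

over D donors. Robustness is the inter-donor repetition count — the
number of donors individually significant at α = 0.05 — compared against
a null distribution built by drawing |S(T)| random non-term studies,
rebuilding the map, and recounting, B times; the empirical p is
#{null ≥ observed}/B. Downstream stages: bidirectional stepwise
regression of map values on two genes' standardized expression plus
their interaction (zero-imputed betas, aggregated with the same t-test),
gene-set screening with Benjamini–Hochberg FDR, a gene-by-cognitive-domain
correlation profile, and a sex-adjusted partial correlation between a
16-item sense-of-direction sum score and a circadian-regularity rating.

## Worked example

```r
library(imgtx)

cfg <- simulation_config(seed = 1)           # the default synthetic study
db  <- generate_study_database(cfg)
map <- build_activation_map(select_studies(db, "navigation"),
                            cfg$grid, radius = 10, term = "navigation")
atlases <- generate_expression_atlases(cfg, map)

res <- correlate_gene_map("CRY2", map, atlases)
print(res$table, digits = 3)
#>   donor_id n_sites slope     r        p
#> 1 donor_01     500 0.254 0.254 8.96e-09
#> 2 donor_02     500 0.249 0.249 1.61e-08
#> 3 donor_03     500 0.286 0.286 7.23e-11
#> 4 donor_04     500 0.342 0.342 3.34e-15
#> 5 donor_05     500 0.324 0.324 1.13e-13
#> 6 donor_06     500 0.295 0.295 1.83e-11
res$random_effects
#> random effects over 6 donors: mean slope 0.2916 (SD 0.0372), t(5) = 19.216, p = 7.039e-06

repeatability_test(db, "navigation", "CRY2", atlases, cfg$grid,
                   B = 1000, seed = 2)
#> repeatability null for CRY2: observed 6/6 donors significant (alpha = 0.05)
#>   null counts over B = 1000: mean 0.90, SD 0.91; empirical p = 0 (plain)

behavior_analysis(generate_behavior(cfg))$partial
#> partial correlation (controlling sex): r = 0.114, p = 0.05122 (n = 292, df = 289)
```

Reading it: the generator planted a site-level correlation of ρ = 0.3
between CRY2 expression and the navigation map; probe noise attenuates
the expectation to ≈ 0.29, and all six donors recover slopes near that
value, individually significant. No random non-term study set in 1,000
draws repeated across all six donors (most repeat in none or one, mean
0.90), so the observed 6/6 repetition has empirical p = 0 at B = 1000.
The behavioral table planted a sex-adjusted latent correlation of 0.15;
this seed's sample estimate after Likert coarsening is r = 0.114.

One call runs everything (simulate → map → correlate → null → stepwise →
gene screen → domain profile → behavior) and writes `report.json` plus a
markdown summary:

```r
report <- run_full_study(pipeline_config(seed = 1), out_dir = "results")
```

The methods vignette (`vignettes/imaging-transcriptomics.Rmd`) documents
the model, the generator's design and its limits, and every numerical
choice.

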