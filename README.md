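# mobiscale

Scaling laws and displacement correlations in human mobility, from raw
GPS trajectories.

## What it does, and for whom

`mobiscale` is an R toolkit for researchers in human mobility, movement
ecology and epidemic modelling who work with dense GPS logs (Geolife-style
PLT files) and want the two statistical fingerprints of human travel:

1. **Heavy-tailed scaling laws.** Trips are condensed into *effective
   staying positions* — maximal sub-sequences of track points confined
   within `d_max = 10` m for longer than `t_min = 120` s — and the
   displacement Δr between consecutive staypoint centres, the staying
   time Δt, and the elapsed travel time Δt_e are pooled and log-binned.
   The displacement density is fitted with a two-regime power law

   P(Δr) ∝ Δr^(−β₁) below a break scale, ∝ Δr^(−β₂) above it,

   and by continuous maximum likelihood, α̂ = 1 + n / Σ ln(xᵢ/x_min),
   with a Kolmogorov–Smirnov-optimal lower bound and a semiparametric
   bootstrap confidence probability p (the Clauset–Shalizi–Newman
   recipe).

2. **Serial displacement correlations.** Kendall's tau in pair-sum form,

   τ = 2/(n(n−1)) Σ_{i<j} sgn(xᵢ−xⱼ) sgn(yᵢ−yⱼ),

   applied to consecutive and lagged displacement pairs (pairs never
   cross file boundaries), its power-law lag decay, the lag-1 Pearson
   autocorrelation of log-displacements, and the Hurst exponent from
   detrended fluctuation analysis (DFA): H is the log-log slope of the
   RMS detrended fluctuation F(l) against box size l; H = 0.5 means no
   memory, H > 0.5 long-term persistence.

Five seeded agent-based simulators — Lévy flight, CTRW,
exploration/preferential-return, a SLAW-style fractal-landscape walk and
a hierarchical-traffic-system (HTS) walker — emit series in the same
format, so the same analyses answer which model mechanisms reproduce the
empirical correlation signatures. A synthetic-data module generates GPS
tracks with planted staypoints and displacement series with planted
correlation structure for testing.

## A worked example

```r
library(mobiscale)

# a synthetic cohort standing in for a GPS corpus
co  <- generate_cohort(n_users = 16, n_per_user = 400, seed = 1)
cfg <- mobility_config(min_staypoints = 0, n_bootstrap = 100, seed = 1)
su  <- summarize_users(co$series, config = cfg)
cross_user_correlations(su)
#> # A tibble: 6 × 5
#>   correlation_stat fit_stat          tau n_users ci_halfwidth
#>   <chr>            <chr>           <dbl>   <int>        <dbl>
#> 1 tau1             ks_p           -0.125      16        0.363
#> 2 tau1             R_displacement -0.75       16        0.363
#> 3 r_delta          ks_p           -0.142      16        0.363
#> 4 r_delta          R_displacement -0.767      16        0.363
#> 5 hurst            ks_p            0.108      16        0.363
#> 6 hurst            R_displacement -0.267      16        0.363
```

Each row is a Kendall's tau across the 16 users between a correlation
statistic (consecutive-displacement tau, log-displacement Pearson r, DFA
Hurst H) and a power-law fit-quality statistic (bootstrap p, or the
log-log Pearson R of the binned density, where −1 is a perfect power
law). In this cohort correlation strength and tail cleanliness are
coupled by construction, and the table shows it: `tau1` vs
`R_displacement` = −0.75, i.e. users with stronger serial correlation
have densities closer to a power law (more negative R), well beyond the
±0.363 null band for 16 users. (The bootstrap `p` columns are much
weaker probes here: the KS test assumes independent draws, and the
strongly autocorrelated users deflate their own `p`; see the vignette.)

```r
# the hierarchical-traffic-system walker at its calibrated defaults
hts <- simulate_hts(seed = 1)
lagged_tau(hts, 1)
#> # A tibble: 1 × 4
#>     tau n_pairs   lag ci_halfwidth
#>   <dbl>   <int> <int>        <dbl>
#> 1 0.337    9999     1       0.0131
```

A single HTS run gives a consecutive-displacement tau of ~0.34 (the
10-seed mean at these defaults is ~0.39) — far
outside the null band — with a slow, power-law-like lag decay
(`tau_lag_profile(hts, 15)`), the signature that distinguishes
hierarchy-driven models from Lévy/CTRW (tau ≈ 0) and from EPR (lag-1
only).

On real data, replace the cohort with `run_population("path/to/Data")`
and `run_individual("path/to/Data")`, which apply the 6 h file filter,
extract staypoints, and produce the population report and the per-user
summary table plus the six cross-user correlations.

## Package map

| Module | Purpose |
|---|---|
| `read_plt()`, `read_plt_dir()`, `write_plt()`, `filter_trajectories()`, `write_series()`/`read_series()` | Geolife PLT parsing, 6 h file filter, series files |
| `extract_staypoints()`, `haversine_distance()` | 10 m / 120 s staypoint rule (consecutive or all-pairs variant) |
| `build_series()`, `add_relative_displacement()`, `pool_population()`, `speed_displacement_pattern()` | displacement / staying-time / elapsed-time / speed series |
| `log_bin()`, `fit_two_regime()`, `fit_powerlaw_ks()`, `loglog_pearson()` | distributions and power-law fits |
| `kendall_tau()`, `lagged_tau()`, `tau_lag_profile()`, `fit_tau_decay()`, `tau_ci()`, `log_pearson()`, `scatter_correlation_pattern()` | correlation analysis |
| `dfa()`, `rfgn()` | detrended fluctuation analysis, fractional Gaussian noise |
| `simulate_levy()`, `simulate_ctrw()`, `simulate_epr()`, `simulate_slaw()`, `simulate_hts()` | mobility models |
| `itinerary_plan()`, `generate_trajectory()`, `generate_series()`, `generate_cohort()` | synthetic data with planted ground truth |
| `run_population()`, `run_individual()`, `summarize_users()`, `cross_user_correlations()`, `run_staytime_independence()`, `mobility_config()` | pipelines and configuration |

The methods vignette (`vignettes/mobility-analysis.Rmd`) documents the
model assumptions, parameter choices and limitations.
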