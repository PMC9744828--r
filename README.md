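# sleepcourse

Analysis toolkit for self-reported sleep duration across the adult
life-course in large mobile-game cohorts, and its association with spatial
navigation performance. It is aimed at researchers who want the complete,
tested computational chain behind life-course studies of this kind —
including a seeded synthetic cohort generator with known ground truth, so
every stage is verifiable without access to any participant data.

## What it computes

* **Penalized piecewise-linear change-point detection.** The per-age mean
  sleep curve *x* is segmented by exactly minimizing
  *D<sub>K</sub>* = Σ<sub>j</sub> SSE<sub>j</sub> + βK, where each segment
  carries its own least-squares line and β is a fixed cost per change point
  (default β = 0.02 squared hours). Solved by optimal partitioning (dynamic
  programming) with a brute-force enumeration oracle and a threshold sweep
  for stability.
* **Navigation performance composites.** Trajectory path lengths
  (first attempts only), tutorial normalization, first-principal-component
  scoring, and the negate/offset/z-score composition giving wayfinding (WF)
  and training (TP) performance, mean 0 / SD 1 across the scored cohort.
* **Cohort pipeline.** Inclusion filters (age ≤ 70, 5–10 h sleep,
  ≥ 500 players per country), 3-year-window age curves, Hedges' *g* with
  small-sample correction *J* = 1 − 3/(4n − 9), short/long-sleeper
  proportions, an ML linear mixed model
  `sleep ~ age_c*(gender+education+home_env+commute) + age_c² + (1|country)`
  with country conditional modes, and per-age-group quadratic
  sleep–performance models with delta-method peak CIs.
* **Geographic stage.** Supra-national cluster ANOVA
  (`sleep ~ age + gender + cluster`) with a label-shuffle permutation null
  (country- or participant-level), latitude/GDP country-level regressions,
  and per-subgroup change points (e.g. WEIRD vs non-WEIRD, gender).
* **Synthetic cohort generator.** Three-phase piecewise-linear age trend
  (change points 33/53, slopes −0.025/−0.005/+0.012 h/yr from 7.35 h at 19),
  +0.13 h gender offset, country random intercepts, integer-hour reporting
  with ~1.5% out-of-range responses, filtered marginal SD ≈ 1.07 h, and an
  inverted-U sleep→navigation-skill link peaking at 7 h, concentrated in the
  oldest group — plus checkpoint-based game trajectories sampled every
  500 ms.

## Worked example

```r
library(sleepcourse)

g   <- generate_cohort(cohort_config(n_participants = 200000, seed = 2024))
flt <- apply_inclusion_filters(g$records, filter_config())
str(flt$report)
#> List of 6
#>  $ age             : int 0
#>  $ sleep_low       : int 1491
#>  $ sleep_high      : int 1394
#>  $ country         : int 648
#>  $ kept            : int 196467
#>  $ n_countries_kept: int 61

seg <- optimal_segmentation(per_age_mean_signal(flt$records), beta = 0.02)
print(seg)
#> Penalized piecewise-linear segmentation (beta = 0.02)
#>   change points at positions: 34, 54
#>   (a change point at position a starts the segment [a, ...))
#>   total SSE = 0.0134078, deviation = 0.0534078
```

The detector finds the two life-course breaks (truth: 33 and 53; ±1–2 years
of positional noise is expected at this cohort size — the *number* of phases
and the stability of the set across the 0.005–0.09 penalty sweep are the
robust findings).

```r
hedges_g(list(mean = 7.07, sd = 1.09, n = 349034),   # published women
         list(mean = 6.94, sd = 1.04, n = 381153))   # published men
#> Hedges' g = 0.122, 95% CI [0.118, 0.127] (n1 = 349034, n2 = 381153)

lmm <- fit_sleep_lmm(flt$records)
print(lmm)
#> Linear mixed model of reported sleep (ML, country random intercept)
#>   13 fixed effects, 61 countries; SD(country) = 0.211 h, SD(residual) = 1.048 h
conditional_mode_vs_raw(flt$records, lmm$conditional_modes)$r
#> [1] 0.9998721
```

The gender effect size reproduces the published 0.12; country conditional
modes track raw country means almost perfectly when demographics are
balanced across countries.

```r
sub    <- flt$records[seq_len(12000), ]
traj   <- generate_trajectories(sub, trajectory_config(seed = 2025), g$truth)
scores <- compute_tp_wf(traj)
print(fit_performance_model(scores, sub, seg$changepoints))
#> Quadratic sleep-performance models (OLS, n = 12000 )
#>   WF per-group sleep terms:
#>     young  b1 = +0.356  b2 = -0.0244  peak = 7.27 h [6.67, 7.87]
#>     middle b1 = +0.925  b2 = -0.0656  peak = 7.05 h [6.85, 7.25]
#>     older  b1 = +2.245  b2 = -0.1595  peak = 7.03 h [6.94, 7.13]
#>   TP per-group sleep terms:
#>     young  b1 = +0.022  b2 = -0.0021  peak = 5.40 h [-14.87, 25.68]
#>     middle b1 = +0.010  b2 = -0.0007  peak = 7.08 h [-11.84, 26.00]
#>     older  b1 = +0.092  b2 = -0.0075  peak = 6.15 h [2.44, 9.86]
```

Wayfinding performance shows the inverted-U against reported sleep with its
peak at ≈ 7 h, sharpest in the oldest group (negative quadratic, tight peak
CI); training performance — motor skill only — shows no meaningful sleep
dependence. That is exactly the generator's ground truth.

```r
cmap <- with(country_clusters(), setNames(maddison_cluster, code))
permutation_null(sub, cmap, n_shuffles = 100, seed = 7)  # country-level null
#> Cluster ANOVA permutation test (country-level shuffle)
#>   observed F(6, 11991) = 10.98; null mean F = 10.06; p = 0.3861 (100 shuffles)
```

With no cluster-level signal in the generator (only country-level noise),
the observed F sits inside its permutation null, as it should. Adding
`cluster_shift_sd = 0.3` to the cohort config pushes the observed F beyond
every shuffled value.

## Command line

```sh
Rscript inst/cli/sleepcourse-cli.R changepoint --input curve.csv --beta 0.02 \
    --sweep 0.005:0.09:0.001
Rscript inst/cli/sleepcourse-cli.R geocluster --cohort cohort.csv \
    --countries countries.csv --shuffles 100 --seed 7
```

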