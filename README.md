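# bpgrowth

Growth-curve shape analysis for nestling mass-at-age data with the
five-parameter Bertalanffy-Putter (BP) model

```
m'(t) = p m(t)^a - q m(t)^b,   m(0) = c > 0,   0 <= a < b,
```

whose exponent pair `(a, b)` determines the dimensionless **shape ratio**

```
m_infl / m_max = (a/b)^(1/(b-a)),
```

the mass at the growth curve's inflection point relative to its asymptotic
mass.  Classical three-parameter models pin this ratio to a constant
(logistic growth: exactly 0.5; generalized Bertalanffy: below 1/e = 0.368;
Richards: above 1/e), so they cannot let the data say *where* in its growth
a nestling slows down.  The BP model can, and the ratio turns out to be a
small-sample-stable statistic that can be related to brood and
environmental conditions (urbanisation, light, noise, brood size) even when
the exponents themselves are poorly determined.

The package is aimed at ecologists and biostatisticians analysing repeated
nestling weighings (the canonical design: eight masses at odd days 1-15),
and provides:

* the BP model itself — numerical trajectories, named special cases, shape
  parameters, family ratio bounds (`bp_solve`, `bp_shape`,
  `bp_shape_ratio`, `bp_family_ratio_bounds`);
* per-bird fitting by log-scale least squares (SSLE) over an exponent-pair
  grid, each grid point optimised by simulated annealing with warm starts,
  neighbour repair and automatic boundary extension (`bp_grid_search`,
  `fit_study`), scored by log-scale R-squared and small-sample AICc, with
  ratio-stability summaries over good-fit regions (`good_fit_region`);
* the ratio-vs-environment test battery — Spearman correlation,
  median-split and ratio-class Mann-Whitney tests, sign tests against 1/3,
  a reliability rule, binomial and permutation estimates of spurious
  significance, and one-bird-per-nest resampling (`run_test_battery`,
  `shuffle_null`, `representative_resampling`, `analyze_study`);
* a synthetic study generator with known ground truth for end-to-end
  validation (`simulate_study`, `ratio_recovery_experiment`).

## Worked example

Simulate a small study, fit every bird on a coarse grid, and test the
ratios against the nest indicators:

```r
library(bpgrowth)

sim <- simulate_study(study_design(nests = 6,
                                   strata = c(blue_f = 6, blue_m = 6,
                                              great_f = 0, great_m = 0)),
                      seed = 26)
tab  <- validate_study_table(sim$table)
fits <- fit_study(tab,
                  bp_grid(a_max = 1.2, b_max = 2.6, spacing = 0.2,
                          min_gap = 0.2, max_extensions = 1),
                  bp_anneal_config(iters = 200, restarts = 1, polish = 120),
                  seed = 4)
head(fits[, c("bird_id", "a", "b", "rl2", "ratio")])
#>   bird_id   a   b       rl2     ratio
#> 1    B001 0.0 2.8 0.9974196 0.0000000
#> 2    B002 0.4 2.2 0.9988157 0.3878711
#> 3    B003 1.4 2.2 0.9996066 0.5683707
#> 4    B004 1.4 2.0 0.8709677 0.5518615
#> 5    B005 1.4 2.0 0.9822287 0.5518615
#> 6    B006 1.4 2.6 0.9756231 0.5969834
```

Each row is one bird's best-fit exponent pair, its log-scale R-squared
(`rl2`), and the shape ratio derived from `(a, b)` alone.  A ratio near 0.5
means logistic-like growth; lower means the bird slowed down earlier
relative to its final mass; B001's best fit lies on the `a = 0` line — no
inflection point in its observation window, ratio 0 by convention.  This
demo grid is deliberately coarse (spacing 0.2, `a` capped at 1.2 plus one
boundary extension), which is why B004's fit presses the boundary and stops
at `rl2` 0.87; production fits use finer spacings and a larger extension
budget (see `bp_grid()`).

A single curve's shape parameters:

```r
bp_shape(bp_params(1, 2, c = 0.1, p = 1, q = 1))
#> m_max = 1 g, m_infl = 0.5 g, t_infl = 2.19722 d, ratio = 0.5
```

— the logistic special case: asymptote `p/q = 1`, inflection at half the
asymptote, reached at `t = log(9) = 2.197` days for `c = 0.1`.

The fitting pipeline's recovery of the ratio is checked end to end on
synthetic birds with known truth:

```r
res <- ratio_recovery_experiment(n_birds = 10, seed = 77)
attr(res, "summary")
#> median_abs_err       spearman
#>     0.02445929     0.93939394
```

so on noisy eight-point series the grid search recovers individual shape
ratios to about 0.02-0.03 and preserves their ranking.

A command-line front end chaining `simulate -> fit -> analyze` over the
study-table CSV lives in `inst/scripts/bpgrowth-cli.R`.

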