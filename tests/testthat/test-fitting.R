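test_that("SSLE matches a direct log-residual computation", {
  d <- make_logistic_series()
  pars <- bp_params(1, 2, 1.1, 0.5, 0.5 / 11)
  # data generated exactly from the params
  expect_lt(ssle(pars, d), 1e-8)
  # one observation inflated by factor e: one squared log-residual of 1
  m2 <- d$masses; m2[4] <- m2[4] * exp(1)
  expect_equal(ssle(pars, mass_series(d$times, m2)), 1, tolerance = 1e-4)
  # spreadsheet-style oracle: fixed noisy series against the closed form
  set.seed(9)
  noisy <- d$masses * exp(rnorm(8, 0, 0.1))
  expected <- sum((log(noisy) -
                     log(logistic_closed(d$times, 1.1, 0.5, 0.5 / 11)))^2)
  expect_equal(ssle(pars, mass_series(d$times, noisy)), expected,
               tolerance = 1e-5)
  # degenerate parameters: penalty value, with a warning
  bad <- bp_params(1, 8, 1.1, 5, 1e-12)
  expect_warning(v <- ssle(bad, d), "degenerate")
  expect_identical(v, .Machine$double.xmax)
})

test_that("RL-squared compares the fit against the geometric-mean constant", {
  d <- make_logistic_series(sigma = 0.05, seed = 4)
  logm <- log(d$masses)
  ssle_const <- sum((logm - mean(logm))^2)
  expect_equal(rl_squared(0, d), 1)
  expect_equal(rl_squared(ssle_const, d), 0)
  expect_equal(rl_squared(0.01 * ssle_const, d), 0.99)
  expect_error(rl_squared(1, mass_series(0:5, rep(2, 6))), "identical")
})

test_that("AICc follows the small-sample formula and K conventions", {
  expect_equal(aicc(8, 8, 6), 96)               # 0 + 12 + 84
  expect_equal(aicc(8, 8, 4), 8 + 2 * 4 * 5 / 3)  # 21.333...
  expect_equal(aicc_K("BP"), 6L)
  expect_equal(aicc_K("fixed"), 4L)
  expect_equal(aicc_K("family"), 5L)
  expect_error(aicc(1, 7, 6), "n > K")
  expect_error(aicc(1, 5, 4), "n > K")
})

test_that("fixed-exponent annealing recovers noiseless logistic data", {
  d <- make_logistic_series()
  f <- fit_fixed_exponents(1, 2, d, bp_anneal_config(iters = 800,
                                                     restarts = 2,
                                                     polish = 400), seed = 21)
  expect_lt(f$ssle, 1e-4)
  expect_equal(f$c, 1.1, tolerance = 0.1)
  expect_equal(f$p / f$q, 11, tolerance = 0.5)  # asymptotic mass
  # seeded determinism
  f2 <- fit_fixed_exponents(1, 2, d, bp_anneal_config(iters = 800,
                                                      restarts = 2,
                                                      polish = 400), seed = 21)
  expect_identical(f[c("c", "p", "q", "ssle")], f2[c("c", "p", "q", "ssle")])
})

test_that("near-constant data admit a near-flat Brody fit", {
  d <- mass_series(seq(0, 14, 2), rep(7, 8) * exp(c(-1, 1, -1, 1, -1, 1, -1,
                                                    1) * 1e-3))
  f <- fit_fixed_exponents(0, 1, d, test_config(), seed = 3)
  logm <- log(d$masses)
  ssle_const <- sum((logm - mean(logm))^2)
  expect_lt(f$ssle, ssle_const * 1.05 + 1e-6)
})

test_that("grid search finds the generating exponent pair on clean data", {
  d <- make_logistic_series()
  grid <- bp_grid(a_min = 0.8, a_max = 1.2, b_max = 2.6, spacing = 0.05,
                  min_gap = 0.05, max_extensions = 1)
  fit <- bp_grid_search(d, grid, bp_anneal_config(iters = 1000, restarts = 2,
                                                 polish = 600), seed = 31)
  expect_lte(abs(fit$params$a - 1), 0.05)
  expect_lte(abs(fit$params$b - 2), 0.05)
  expect_lt(abs(fit$shape$ratio - 0.5), 0.02)
  expect_gt(fit$rl2, 0.999)
  # objective consistency: reported SSLE equals SSLE recomputed at the params
  expect_equal(fit$ssle, ssle(fit$params, d), tolerance = 1e-9)
})

test_that("unbounded exponential data yield ratio 0 or a boundary flag", {
  # pure exponential growth (q = 0, a = 1): no inflection in the data
  mu <- 1.1 * exp(0.15 * seq(0, 14, 2))
  d <- mass_series(seq(0, 14, 2), mu)
  grid <- bp_grid(a_min = 0, a_max = 1.2, b_max = 2.4, spacing = 0.1,
                  min_gap = 0.2, max_extensions = 0)
  fit <- bp_grid_search(d, grid, test_config(), seed = 8)
  # the best fit either degenerates towards no inflection within the data
  # range or presses against the grid boundary
  expect_true(fit$boundary_hit ||
                fit$shape$ratio < 0.05 ||
                bp_asymptotic_mass(fit$params) > 2 * max(mu))
})

test_that("finer grids and larger budgets never fit worse", {
  d <- make_logistic_series(sigma = 0.05, seed = 12)
  coarse <- bp_grid(a_min = 0.8, a_max = 1.2, b_max = 2.4, spacing = 0.2,
                    min_gap = 0.2, max_extensions = 0)
  fine <- bp_grid(a_min = 0.8, a_max = 1.2, b_max = 2.4, spacing = 0.1,
                  min_gap = 0.2, max_extensions = 0)
  f_coarse <- bp_grid_search(d, coarse, test_config(), seed = 5)
  f_fine <- bp_grid_search(d, fine, test_config(), seed = 5)
  expect_lte(f_fine$ssle, f_coarse$ssle + 1e-6)
  small <- bp_grid_search(d, coarse, bp_anneal_config(iters = 60, restarts = 1,
                                                      polish = 30), seed = 7)
  big <- bp_grid_search(d, coarse, bp_anneal_config(iters = 600, restarts = 2,
                                                    polish = 300), seed = 7)
  expect_lte(big$ssle, small$ssle + 1e-8)
})

test_that("the good-fit region summarises ratio stability", {
  d <- make_logistic_series(sigma = 0.03, seed = 13)
  grid <- bp_grid(a_min = 0.7, a_max = 1.3, b_max = 2.8, spacing = 0.1,
                  min_gap = 0.1, max_extensions = 0)
  fit <- bp_grid_search(d, grid, test_config(), seed = 14)
  # threshold 0: the whole evaluated grid qualifies
  all_region <- good_fit_region(fit, threshold = -Inf)
  expect_equal(all_region$n_pairs, sum(!is.na(fit$grid$ssle)))
  # threshold at the best RL2: at least the best pair remains
  top <- good_fit_region(fit, threshold = fit$rl2 - 1e-12)
  expect_true(any(abs(top$pairs$a - fit$params$a) < 1e-9 &
                    abs(top$pairs$b - fit$params$b) < 1e-9))
  # excellent-fit region median ratio stays near the generating ratio
  reg <- good_fit_region(fit, threshold = 0.995)
  expect_lt(abs(reg$ratio_median - 0.5), 0.05)
  expect_error(good_fit_region(fit, threshold = 1), "best achievable")
})

test_that("Anderson-Darling checks calibrate under the lognormal null", {
  pars <- bp_params(1, 2, 1.1, 0.5, 0.5 / 11)
  tt <- seq(0, 14, by = 0.5)
  mu <- bp_solve(pars, tt)
  set.seed(15)
  fails <- replicate(150, {
    d <- mass_series(tt, mu * exp(rnorm(length(mu), 0, 0.05)))
    !distribution_checks(d, list(params = pars))$normal_residuals$pass
  })
  expect_lt(mean(fails), 0.10)
  expect_gt(mean(fails), 0.005)
  # a gross outlier breaks lognormality: flat series, one 10x value
  set.seed(16)
  flat <- 10 * exp(rnorm(8, 0, 0.05)); flat[5] <- flat[5] * 10
  chk <- distribution_checks(mass_series(seq(0, 14, 2), flat),
                             bp_params(0, 1, 10, 0.01, 0.001))
  expect_false(chk$lognormal_masses$pass)
  # all-zero residuals are non-applicable
  d0 <- mass_series(tt[1:10], mu[1:10])
  chk0 <- distribution_checks(d0, list(params = pars))
  expect_true(is.na(chk0$normal_residuals$pass))
  expect_true(chk0$low_power)
})

test_that("family-restricted fits sweep one free exponent", {
  d <- make_logistic_series(sigma = 0.03, seed = 51)
  f <- fit_named_family(d, "generalized-logistic", range = c(0.2, 2.5),
                        spacing = 0.1, config = test_config(), seed = 52)
  expect_equal(f$params$b - f$params$a, 1, tolerance = 1e-9)
  expect_lt(abs(f$shape$ratio - 0.5), 0.1)
  expect_equal(f$aicc, aicc(f$ssle, 8, 5))
  r <- fit_named_family(d, "Richards", range = c(1.2, 3.6), spacing = 0.2,
                        config = test_config(), seed = 53)
  expect_equal(r$params$a, 1)
  expect_gt(r$shape$ratio, exp(-1))  # Richards ratios sit above 1/e
  expect_error(fit_named_family(d, "logistic"), "fixed")
  # the full BP grid never fits worse than a nested family on the same data
  grid <- bp_grid(a_min = 0.2, a_max = 1.4, b_max = 2.6, spacing = 0.2,
                  min_gap = 0.2, max_extensions = 0)
  full <- bp_grid_search(d, grid, test_config(), seed = 54)
  expect_gt(full$rl2, 0.99)
})
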