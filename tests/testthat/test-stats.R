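test_that("Spearman test recovers perfect and inverted rankings", {
  x <- c(0.2, 0.35, 0.4, 0.55, 0.6, 0.7)
  expect_equal(spearman_test(x, x)$rho, 1)
  expect_equal(spearman_test(x, -x)$rho, -1)
  expect_error(spearman_test(x, rep(1, 6)), "constant")
  expect_error(spearman_test(x[1:4], x[1:4]), "at least 5")
})

test_that("median split sends ties to the high class and tests the ratio", {
  ratios <- c(0.3, 0.4, 0.5, 0.6)
  ind <- c(1, 2, 2, 3)  # median 2: ties upward -> high class has 3 members
  r <- median_split_test(ratios, ind)
  expect_equal(r$n_high, 3)
  expect_equal(r$n_low, 1)
  expect_equal(r$median_ratio_high, 0.5)
  expect_equal(r$median_ratio_low, 0.3)
  # no location difference when all ratios are equal
  expect_equal(median_split_test(rep(0.5, 8), c(1:8))$p_value, 1)
  expect_error(median_split_test(1:4 / 10, rep(2, 4)), "empty class")
  # a monotone indicator-ratio link is detected at n = 30
  set.seed(41)
  ind <- rnorm(30)
  rat <- plogis(0.8 * ind + rnorm(30, 0, 0.3))
  expect_lt(median_split_test(rat, ind)$p_value, 0.05)
})

test_that("median split p-value is invariant under monotone indicator maps", {
  set.seed(42)
  ratios <- runif(20, 0.2, 0.8)
  ind <- rlnorm(20, 0, 1)
  p1 <- median_split_test(ratios, ind)$p_value
  p2 <- median_split_test(ratios, log(ind))$p_value
  p3 <- median_split_test(ratios, rank(ind))$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("ratio classification puts the threshold bird in the high class", {
  ratios <- c(0.2, 0.5, 0.7, 0.45, 0.8)
  ind <- c(10, 20, 30, 40, 50)
  r <- ratio_class_test(ratios, ind, threshold = 0.5)
  expect_equal(r$n_high, 3)  # 0.5 itself is high-ratio
  expect_equal(r$n_low, 2)
  expect_equal(r$median_indicator_high, 30)
  expect_equal(r$median_indicator_low, 25)
  # identical indicator for all birds: no difference
  expect_equal(ratio_class_test(ratios, rep(3, 5))$p_value, 1)
  expect_error(ratio_class_test(rep(0.9, 5), ind), "empty")
  # invariance under a monotone transform of the ratio + threshold
  p1 <- ratio_class_test(ratios, ind, 0.5)$p_value
  p2 <- ratio_class_test(qlogis(ratios), ind, qlogis(0.5))$p_value
  expect_equal(p1, p2)
})

test_that("sign test against a reference value and its median CI", {
  expect_equal(sign_test_vs_value(seq(0.4, 0.9, length.out = 10), 1 / 3)$p_value,
               2^-10)
  set.seed(43)
  sym <- 1 / 3 + c(-(1:10), 1:10) / 50
  p <- sign_test_vs_value(sym, 1 / 3)$p_value
  expect_gt(p, 0.3); expect_lt(p, 0.8)
  r <- sign_test_vs_value(c(0.2, 0.3, 1 / 3, 0.5, 0.6, 0.7), 1 / 3)
  expect_equal(r$n_used, 5)  # the tie is dropped
  expect_error(sign_test_vs_value(rep(1 / 3, 6), 1 / 3), "tie")
  # CI bounds are order statistics enclosing the median
  x <- sort(runif(25, 0.3, 0.7))
  ci <- sign_test_vs_value(x, 0.5)$ci
  expect_true(ci["lower"] %in% x && ci["upper"] %in% x)
  expect_lte(ci["lower"], median(x)); expect_gte(ci["upper"], median(x))
})

test_that("binomial spurious-count probability matches brute-force pmf sums", {
  for (n in c(5, 13, 15)) for (k in c(0, 1, 3, n, n + 1)) {
    expected <- if (k > n) 0 else sum(dbinom(k:n, n, 0.05))
    expect_equal(spurious_count_pvalue(n, 0.05, k), expected,
                 tolerance = 1e-12)
  }
  expect_equal(spurious_count_pvalue(13, 0.05, 0), 1)
  expect_equal(spurious_count_pvalue(13, 0.05, 14), 0)
})

test_that("shuffle null counts spurious correlations under dependence", {
  set.seed(44)
  n_nests <- 10; n_birds <- 30
  nest_ids <- sprintf("N%02d", rep(1:n_nests, each = 3))
  env <- as.data.frame(matrix(rnorm(n_nests * 13), n_nests,
                              dimnames = list(NULL, paste0("v", 1:13))))
  rownames(env) <- sprintf("N%02d", 1:n_nests)
  ratios <- runif(n_birds, 0.2, 0.8)
  r <- shuffle_null(ratios, nest_ids, env, n_shuffles = 400, seed = 1)
  expect_length(r$counts, 400)
  expect_lte(r$quantile95, 3)
  expect_identical(r$quantile95,
                   unname(quantile(r$counts, 0.95, type = 1)))
  # identical seeds reproduce the null exactly
  r2 <- shuffle_null(ratios, nest_ids, env, n_shuffles = 400, seed = 1)
  expect_identical(r$counts, r2$counts)
  # perfectly duplicated indicators: counts come in blocks of 13
  env13 <- env; for (v in paste0("v", 2:13)) env13[[v]] <- env13$v1
  r13 <- shuffle_null(ratios, nest_ids, env13, n_shuffles = 300, seed = 2)
  expect_true(all(r13$counts %in% c(0L, 13L)))
})

test_that("representative resampling reduces each nest to one bird", {
  env <- data.frame(v1 = c(5, 3, 8, 1, 9, 2), v2 = rnorm(6),
                    row.names = sprintf("N%d", 1:6))
  # nests of size one: the reduced sample is the full sample
  ratios <- c(0.3, 0.45, 0.5, 0.6, 0.7, 0.25)
  nests <- sprintf("N%d", 1:6)
  ids <- sprintf("B%d", 1:6)
  det <- representative_resampling(ratios, nests, ids, env)
  full <- spearman_test(ratios, env$v1)
  expect_equal(det$rho[det$indicator == "v1"], full$rho)
  expect_setequal(attr(det, "bird_ids"), ids)
  # tie in |ratio - nest median| goes to the lower bird id
  ratios2 <- c(0.4, 0.6, 0.3, 0.5, 0.7, 0.45, 0.72, 0.2, 0.55)
  nests2 <- c("N1", "N1", "N2", "N2", "N2", "N3", "N4", "N5", "N6")
  ids2 <- sprintf("B%d", 1:9)
  det2 <- representative_resampling(ratios2, nests2, ids2, env)
  picked <- attr(det2, "bird_ids")
  expect_length(picked, 6)
  expect_true("B1" %in% picked)   # N1: 0.4 and 0.6 equidistant from 0.5
  expect_true("B4" %in% picked)   # N2: 0.5 is the median bird
  # bootstrap draws are reproducible under a fixed seed
  b1 <- representative_resampling(ratios2, nests2, ids2, env,
                                  mode = "bootstrap", B = 5, seed = 9)
  b2 <- representative_resampling(ratios2, nests2, ids2, env,
                                  mode = "bootstrap", B = 5, seed = 9)
  expect_identical(b1, b2)
  expect_true(all(b1$frac_significant >= 0 & b1$frac_significant <= 1))
})

test_that("a true covariate effect survives one-bird-per-nest reduction", {
  set.seed(46)
  n_nests <- 11
  env <- data.frame(light = rlnorm(n_nests, 8, 0.5),
                    row.names = sprintf("N%02d", 1:n_nests))
  nest_ids <- sprintf("N%02d", rep(1:n_nests, times = 3))
  z <- scale(env$light)[rep(1:n_nests, times = 3)]
  ratios <- plogis(qlogis(0.5) - 1.2 * z + rnorm(length(z), 0, 0.25))
  det <- representative_resampling(ratios, nest_ids,
                                   sprintf("B%02d", seq_along(ratios)), env)
  expect_lt(det$rho[det$indicator == "light"], 0)
  expect_lt(det$p_value[det$indicator == "light"], 0.05)
})

test_that("the reliability rule needs three tests, one strong, two strata", {
  row <- function(stratum, rho, pa, pb, pc)
    data.frame(stratum = stratum, indicator = "isa", n = 26, rho = rho,
               p_a = pa, ratio_high = 0.47, ratio_low = 0.53, p_b = pb,
               ind_high = 4, ind_low = 13, p_c = pc)
  # all tests weak: nothing reported
  b <- rbind(row("blue_f", -0.5, 0.5, 0.5, 0.5),
             row("blue_m", -0.5, 0.5, 0.5, 0.5))
  expect_equal(nrow(reliability_verdict(b)), 0)
  # the published pattern: three significant tests, one strong, both sexes
  b <- rbind(row("blue_f", -0.54, 0.004, 0.03, 0.02),
             row("blue_m", -0.48, 0.007, 0.003, 0.011))
  v <- reliability_verdict(b)
  expect_equal(nrow(v), 1)
  expect_true(v$reliable)
  expect_equal(v$direction, -1)
  expect_equal(v$n_strata_pass, 2)
  # significant in a single stratum only: not reliable
  b <- rbind(row("blue_f", -0.54, 0.004, 0.03, 0.02),
             row("blue_m", -0.1, 0.5, 0.6, 0.7))
  v <- reliability_verdict(b)
  expect_false(any(v$reliable))
  # opposite directions in the two strata do not corroborate each other
  b <- rbind(row("blue_f", -0.54, 0.004, 0.03, 0.02),
             row("blue_m", 0.54, 0.004, 0.03, 0.02))
  v <- reliability_verdict(b)
  expect_false(any(v$reliable))
})

test_that("the battery runs per stratum and indicator", {
  set.seed(47)
  n <- 40
  birds <- data.frame(
    stratum = rep(c("blue_f", "blue_m"), each = n / 2),
    ratio = runif(n, 0.2, 0.8),
    isa = rlnorm(n, 1.5, 0.5),
    light = rlnorm(n, 8, 0.4))
  b <- run_test_battery(birds, c("isa", "light"))
  expect_equal(nrow(b), 4)
  expect_true(all(c("rho", "p_a", "p_b", "p_c") %in% names(b)))
  expect_true(all(is.finite(b$p_a)))
})

test_that("Spearman power grows with effect size and sample size", {
  rate <- function(n, beta, reps = 300) {
    mean(replicate(reps, {
      ind <- rnorm(n)
      ratio <- plogis(beta * ind + rnorm(n, 0, 0.5))
      spearman_test(ratio, ind)$p_value <= 0.05
    }))
  }
  set.seed(48)
  r0 <- rate(30, 0)
  r_mid <- rate(30, 0.4)
  r_big <- rate(30, 1.0)
  expect_gte(r_mid, r0 - 0.03)
  expect_gte(r_big, r_mid)
  expect_gt(r_big, 0.8)
  set.seed(49)
  expect_gte(rate(40, 0.6), rate(15, 0.6) - 0.03)
})
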