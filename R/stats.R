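#' Spearman rank-correlation test (test a)
#'
#' Rank correlation between per-bird shape ratios and an indicator, with
#' average ranks for ties and a two-sided p-value (exact for small samples
#' without ties, t-approximation otherwise, as implemented by
#' [stats::cor.test()]).
#'
#' @param ratios,indicator paired numeric vectors, `n >= 5`.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(ratios, indicator) {
  stopifnot(length(ratios) == length(indicator))
  ok <- is.finite(ratios) & is.finite(indicator)
  x <- ratios[ok]; y <- indicator[ok]
  if (length(x) < 5) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman rho undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# Mann-Whitney wrapper following the study's convention: exact distribution
# for combined n <= 20 without ties, otherwise the normal approximation with
# continuity and tie correction.
mann_whitney <- function(x, y) {
  if (length(unique(c(x, y))) == 1) return(1)  # no location difference
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y)) <= 20 && no_ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))$p.value
}

#' Median-split location test on the ratio (test b)
#'
#' Splits a stratum at the median of an environmental indicator — birds with
#' indicator values equal to or above the median form the high class, the
#' rest the low class — and tests for a location difference in the shape
#' ratio between the classes with a two-sided Mann-Whitney test.
#'
#' @param ratios per-bird shape ratios of one stratum.
#' @param indicator paired indicator values.
#' @return List with `median_ratio_high`, `median_ratio_low`, `n_high`,
#'   `n_low`, `p_value`, and `indicator_median` (the split point).
#' @export
median_split_test <- function(ratios, indicator) {
  stopifnot(length(ratios) == length(indicator))
  med <- stats::median(indicator)
  hi <- indicator >= med
  if (!any(hi) || all(hi))
    stop("median split produced an empty class (n_high = ", sum(hi),
         ", n_low = ", sum(!hi), ")")
  list(median_ratio_high = stats::median(ratios[hi]),
       median_ratio_low = stats::median(ratios[!hi]),
       n_high = sum(hi), n_low = sum(!hi),
       p_value = mann_whitney(ratios[hi], ratios[!hi]),
       indicator_median = med)
}

#' Ratio-class location test on the indicator (test c)
#'
#' Classifies birds as high-ratio (fitted shape ratio `>= threshold`, the
#' default 0.5 being the fixed ratio of logistic growth) or low-ratio, and
#' tests for a location difference in the environmental indicator between
#' the classes with a two-sided Mann-Whitney test.
#'
#' @param ratios per-bird shape ratios of one stratum.
#' @param indicator paired indicator values.
#' @param threshold high-ratio cutoff (a bird exactly at the threshold is
#'   high-ratio).
#' @return List with `median_indicator_high`, `median_indicator_low`,
#'   `n_high`, `n_low`, `p_value`.
#' @export
ratio_class_test <- function(ratios, indicator, threshold = 0.5) {
  stopifnot(length(ratios) == length(indicator))
  hi <- ratios >= threshold
  if (!any(hi) || all(hi))
    stop("ratio classification produced an empty class (n_high = ", sum(hi),
         ", n_low = ", sum(!hi), ")")
  list(median_indicator_high = stats::median(indicator[hi]),
       median_indicator_low = stats::median(indicator[!hi]),
       n_high = sum(hi), n_low = sum(!hi),
       p_value = mann_whitney(indicator[hi], indicator[!hi]))
}

#' One-sided sign test against a reference value, with median CI
#'
#' Tests whether values are located above `reference` (one-sided binomial
#' sign test, ties with the reference dropped) and builds an order-statistic
#' confidence interval for the median by inverting one-sided sign tests for
#' each limit.
#'
#' @param x numeric values (e.g. ratios of sigmoidal birds).
#' @param reference reference value (e.g. 1/3).
#' @param conf nominal two-sided confidence level for the median interval.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List with `p_value`, `n_used`, `median`, `ci` (achieved interval),
#'   `ci_achieved_alpha` (the one-sided level actually attained per limit).
#' @export
sign_test_vs_value <- function(x, reference, conf = 0.95,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  d <- x[x != reference]
  if (length(d) == 0) stop("all values tie with the reference")
  n <- length(d)
  k <- sum(d > reference)
  p <- if (alternative == "greater")
    stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  else
    stats::pbinom(n - k - 1, n, 0.5, lower.tail = FALSE)
  # order-statistic CI: largest j with P(X < j) <= (1-conf)/2, X ~ Bin(m, 1/2)
  xs <- sort(x)
  m <- length(xs)
  alpha <- (1 - conf) / 2
  j <- stats::qbinom(alpha, m, 0.5)
  if (stats::pbinom(j - 1, m, 0.5) > alpha) j <- j - 1
  j <- max(j, 1)
  list(p_value = p, n_used = n, median = stats::median(x),
       ci = c(lower = xs[j], upper = xs[m + 1 - j]),
       ci_achieved_alpha = stats::pbinom(j - 1, m, 0.5))
}

#' Binomial estimate of the spurious-significance count
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n_tests, alpha)`:
#' the chance of observing `k` or more false "significant" outcomes among
#' `n_tests` independent tests at level `alpha`.  With 13 indicators and
#' alpha 0.05, three or more spurious hits have probability 0.0245, so at
#' most two per test series are expected by chance.
#'
#' @param n_tests number of tests in the series.
#' @param alpha per-test false-positive rate.
#' @param k threshold count.
#' @return `P(X >= k)`.
#' @export
spurious_count_pvalue <- function(n_tests, alpha, k) {
  stopifnot(alpha > 0, alpha < 1, k >= 0, n_tests >= 1)
  if (k > n_tests) return(0)
  stats::pbinom(k - 1, n_tests, alpha, lower.tail = FALSE)
}

# Vectorised two-sided Spearman p-values via the t-approximation; used inside
# resampling loops where stats::cor.test would dominate the runtime.
spearman_p_approx <- function(rho, n) {
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Permutation null for the count of significant correlations
#'
#' Reshuffles the birds of one stratum at random among the nest sites (the
#' nest characteristics are not altered), reruns the Spearman correlation of
#' ratio against every indicator, and counts the spuriously significant
#' outcomes per shuffle.  The 95% quantile of the counts estimates how many
#' significant correlations to expect by chance when the indicators are
#' mutually correlated (the plain binomial estimate assumes independence).
#' Inside the loop the Spearman p-value uses the t-approximation.
#'
#' @param ratios per-bird shape ratios of one stratum.
#' @param nest_ids per-bird nest identifiers (defines the bird-to-nest
#'   assignment to be permuted).
#' @param indicators data frame or matrix of per-nest indicator columns,
#'   one row per nest, with `rownames` (or a `nest_id` column) identifying
#'   the nest.
#' @param n_shuffles number of random shuffles (the study used 10,000).
#' @param alpha significance level for counting.
#' @param seed optional integer seed.
#' @return List with `quantile95`, `counts` (one per shuffle), `alpha`,
#'   `n_shuffles`.
#' @export
shuffle_null <- function(ratios, nest_ids, indicators, n_shuffles = 10000,
                         alpha = 0.05, seed = NULL) {
  stopifnot(length(ratios) == length(nest_ids), n_shuffles >= 100)
  if (!is.null(seed)) set.seed(seed)
  ind <- as.data.frame(indicators)
  nid_col <- match("nest_id", names(ind))
  nest_key <- if (!is.na(nid_col)) as.character(ind[[nid_col]])
              else rownames(ind)
  if (!is.na(nid_col)) ind <- ind[, -nid_col, drop = FALSE]
  if (length(unique(nest_ids)) < 2) stop("need at least 2 nests")
  rows <- match(as.character(nest_ids), nest_key)
  if (anyNA(rows)) stop("nest_ids not found among indicator rows")
  X <- apply(as.matrix(ind[rows, , drop = FALSE]), 2, rank)
  n <- length(ratios)
  # permuting birds among nests within the stratum == permuting which
  # bird carries which nest's indicator row
  R <- matrix(NA_real_, n, n_shuffles)
  for (s in seq_len(n_shuffles)) R[, s] <- rank(ratios[sample.int(n)])
  rho <- stats::cor(R, X)   # n_shuffles x n_indicators rank correlations
  sig <- spearman_p_approx(rho, n) <= alpha
  counts <- rowSums(sig)
  list(quantile95 = unname(stats::quantile(counts, 0.95, type = 1)),
       counts = counts, alpha = alpha, n_shuffles = n_shuffles)
}

#' Representative-bird resampling (nest-size bias check)
#'
#' Reduces a stratum to one bird per nest and reruns the Spearman
#' correlations of ratio against each indicator, removing any dominance of
#' large broods.  Deterministic mode picks, per nest, the bird with "typical
#' growth" — the ratio nearest the nest's within-stratum median (ties broken
#' towards the lower bird id).  Bootstrap mode picks the representative at
#' random, `B` times, and reports the fraction of resamples significant at
#' `alpha` for each indicator.
#'
#' @param ratios,nest_ids,bird_ids per-bird vectors for one stratum.
#' @param indicators per-nest indicator table as in [shuffle_null()].
#' @param mode `"deterministic"` or `"bootstrap"`.
#' @param B bootstrap replicates.
#' @param alpha significance level used in bootstrap mode.
#' @param seed optional integer seed (bootstrap mode).
#' @return Deterministic mode: data frame with one row per indicator
#'   (`indicator`, `rho`, `p_value`, `n`).  Bootstrap mode: data frame with
#'   `indicator`, `frac_significant`, `B`.
#' @export
representative_resampling <- function(ratios, nest_ids, bird_ids, indicators,
                                      mode = c("deterministic", "bootstrap"),
                                      B = 1000, alpha = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(ratios) == length(nest_ids),
            length(ratios) == length(bird_ids))
  if (!is.null(seed)) set.seed(seed)
  ind <- as.data.frame(indicators)
  nid_col <- match("nest_id", names(ind))
  nest_key <- if (!is.na(nid_col)) as.character(ind[[nid_col]])
              else rownames(ind)
  if (!is.na(nid_col)) ind <- ind[, -nid_col, drop = FALSE]
  nests <- unique(as.character(nest_ids))
  pick_rows <- function(random) {
    vapply(nests, function(nid) {
      in_nest <- which(as.character(nest_ids) == nid)
      if (random) return(in_nest[sample.int(length(in_nest), 1)])
      med <- stats::median(ratios[in_nest])
      d <- abs(ratios[in_nest] - med)
      cand <- in_nest[d <= min(d) + 1e-12]
      cand[order(bird_ids[cand])][1]
    }, integer(1))
  }
  run_tests <- function(sel) {
    env_rows <- match(as.character(nest_ids[sel]), nest_key)
    vapply(names(ind), function(v) {
      st <- spearman_test(ratios[sel], ind[env_rows, v])
      c(rho = st$rho, p_value = st$p_value)
    }, numeric(2))
  }
  if (mode == "deterministic") {
    sel <- pick_rows(random = FALSE)
    res <- run_tests(sel)
    out <- data.frame(indicator = colnames(res), rho = res["rho", ],
                      p_value = res["p_value", ], n = length(sel),
                      row.names = NULL)
    attr(out, "bird_ids") <- bird_ids[sel]
    return(out)
  }
  hits <- matrix(0, nrow = B, ncol = ncol(ind),
                 dimnames = list(NULL, names(ind)))
  for (bi in seq_len(B)) {
    sel <- pick_rows(random = TRUE)
    env_rows <- match(as.character(nest_ids[sel]), nest_key)
    r <- stats::cor(rank(ratios[sel]),
                    apply(as.matrix(ind[env_rows, , drop = FALSE]), 2, rank))
    hits[bi, ] <- spearman_p_approx(as.numeric(r), length(sel)) <= alpha
  }
  data.frame(indicator = names(ind), frac_significant = colMeans(hits),
             B = B, row.names = NULL)
}

#' Run the three-test battery for every stratum and indicator
#'
#' For each stratum (species by sex) and each indicator, runs test a
#' (Spearman correlation of ratio vs indicator), test b (Mann-Whitney on the
#' ratio after a median split of the indicator) and test c (Mann-Whitney on
#' the indicator after classifying birds as high/low ratio).  Tests that
#' cannot run (an empty class) yield `NA` p-values.
#'
#' @param birds data frame with columns `stratum`, `ratio`, and one column
#'   per indicator named in `indicators`.
#' @param indicators character vector of indicator column names.
#' @param ratio_threshold high-ratio cutoff for test c.
#' @return Data frame of class `bp_battery`, one row per stratum x indicator:
#'   `stratum`, `indicator`, `n`, `rho`, `p_a`, `ratio_high`, `ratio_low`,
#'   `p_b`, `ind_high`, `ind_low`, `p_c`.
#' @export
run_test_battery <- function(birds, indicators, ratio_threshold = 0.5) {
  stopifnot(all(c("stratum", "ratio") %in% names(birds)),
            all(indicators %in% names(birds)))
  out <- list()
  for (st in unique(birds$stratum)) {
    sub <- birds[birds$stratum == st, , drop = FALSE]
    for (v in indicators) {
      a <- tryCatch(spearman_test(sub$ratio, sub[[v]]),
                    error = function(e) list(rho = NA, p_value = NA))
      b <- tryCatch(median_split_test(sub$ratio, sub[[v]]),
                    error = function(e) list(median_ratio_high = NA,
                                             median_ratio_low = NA,
                                             p_value = NA))
      cc <- tryCatch(ratio_class_test(sub$ratio, sub[[v]], ratio_threshold),
                     error = function(e) list(median_indicator_high = NA,
                                              median_indicator_low = NA,
                                              p_value = NA))
      out[[length(out) + 1]] <- data.frame(
        stratum = st, indicator = v, n = nrow(sub),
        rho = a$rho, p_a = a$p_value,
        ratio_high = b$median_ratio_high, ratio_low = b$median_ratio_low,
        p_b = b$p_value,
        ind_high = cc$median_indicator_high, ind_low = cc$median_indicator_low,
        p_c = cc$p_value)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("bp_battery", class(res))
  res
}

#' Reliability verdict for an association
#'
#' An association between the ratio and an indicator is deemed reliable when,
#' within a stratum, (1) all three tests are significant at `alpha`, (2) at
#' least one of them is highly significant (`p <= alpha_high`), and (3) the
#' association holds with the same direction (sign of Spearman rho) in at
#' least two strata.
#'
#' @param battery a [run_test_battery()] result.
#' @param alpha,alpha_high significance thresholds (defaults 0.05 and 0.01).
#' @return Data frame with one row per indicator x direction that passes in
#'   at least one stratum: `indicator`, `direction` (+1/-1), `n_strata_pass`,
#'   `strata` (comma-joined), `reliable`.
#' @export
reliability_verdict <- function(battery, alpha = 0.05, alpha_high = 0.01) {
  stopifnot(inherits(battery, "bp_battery") || is.data.frame(battery))
  b <- battery
  p3 <- cbind(b$p_a, b$p_b, b$p_c)
  pass <- apply(p3 <= alpha, 1, function(z) all(!is.na(z)) && all(z)) &
    apply(p3 <= alpha_high, 1, function(z) any(z, na.rm = TRUE))
  b$direction <- sign(b$rho)
  rows <- which(pass & !is.na(b$direction) & b$direction != 0)
  if (length(rows) == 0)
    return(data.frame(indicator = character(), direction = numeric(),
                      n_strata_pass = integer(), strata = character(),
                      reliable = logical()))
  key <- paste(b$indicator[rows], b$direction[rows])
  agg <- lapply(split(rows, key), function(idx) data.frame(
    indicator = b$indicator[idx[1]],
    direction = b$direction[idx[1]],
    n_strata_pass = length(idx),
    strata = paste(sort(unique(b$stratum[idx])), collapse = ","),
    reliable = length(unique(b$stratum[idx])) >= 2))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
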