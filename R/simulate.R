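#' Design of a synthetic nestling growth study
#'
#' Describes the study to be simulated: number of nest boxes, stratum sizes
#' (species by sex), brood-size limits, weighing days, the multiplicative
#' measurement-noise level, and the covariate effects on the shape ratio.
#' Defaults mirror a two-species urban nest-box study: 20 nests, 81 birds in
#' strata 26/31/12/12 (female/male blue tits, female/male great tits), eight
#' weighings at odd days 1 to 15, lognormal mass error with sigma 0.05 on the
#' log scale, and negative effects of impervious surface and light pollution
#' on the ratio.
#'
#' @param nests number of nest boxes.
#' @param strata named integer vector of stratum sizes; names must be
#'   `blue_f`, `blue_m`, `great_f`, `great_m`.
#' @param brood_range minimum and maximum surviving chicks per nest.
#' @param days weighing days (day 1 = hatching; internally day `d` maps to
#'   `t = d - 1`).
#' @param sigma standard deviation of the log-mass measurement error.
#' @param effects named numeric vector: indicator name -> slope on the logit
#'   of the true ratio per standard deviation of the indicator.  Use `NULL`
#'   for a null (no-effect) design.
#' @param sd_logit standard deviation of the individual logit-ratio noise.
#' @param baselines named per-stratum baseline ratios.
#' @param exponent_family how a true ratio is mapped back to an exponent
#'   pair: `"generalized-logistic"` places all birds on the line `b = a + 1`
#'   (where ratio `= a/(a+1)` exactly); `"scatter"` draws the exponent
#'   difference uniformly in [0.5, 2.5] and solves the ratio contour for `a`.
#' @param indicator_corr optional correlation matrix for the latent Gaussian
#'   copula of the nest indicators (rownames/colnames must name latent
#'   indicators); default has a moderate positive block among the
#'   urbanisation variables (ISA, light, sound).
#' @return Object of class `study_design`.
#' @export
study_design <- function(nests = 20,
                         strata = c(blue_f = 26, blue_m = 31,
                                    great_f = 12, great_m = 12),
                         brood_range = c(1, 9),
                         days = seq(1, 15, by = 2),
                         sigma = 0.05,
                         effects = c(isa = -0.5, light = -0.5),
                         sd_logit = 0.5,
                         baselines = c(blue_f = 0.511, blue_m = 0.503,
                                       great_f = 0.459, great_m = 0.528),
                         exponent_family = c("generalized-logistic",
                                             "scatter"),
                         indicator_corr = NULL) {
  exponent_family <- match.arg(exponent_family)
  stopifnot(nests >= 1, all(strata >= 0), sigma >= 0, sd_logit >= 0,
            length(days) >= 5, all(diff(days) > 0), days[1] >= 1,
            brood_range[1] >= 1, brood_range[2] >= brood_range[1],
            setequal(names(strata), c("blue_f", "blue_m", "great_f",
                                      "great_m")))
  if (!is.null(effects) && is.null(names(effects)))
    stop("'effects' must be a named vector (indicator -> slope)")
  structure(list(nests = as.integer(nests), strata = strata,
                 brood_range = brood_range, days = days, sigma = sigma,
                 effects = effects, sd_logit = sd_logit,
                 baselines = baselines, exponent_family = exponent_family,
                 indicator_corr = indicator_corr), class = "study_design")
}

# Latent indicator definitions: marginal quantile transforms anchored at the
# published per-indicator medians.  `drop` is latent (brood attrition); the
# observed count indicators are derived from it.
indicator_marginals <- function() {
  list(
    hatching_day   = function(u) round(stats::qnorm(u, 38, 2)),
    hatch_initial  = function(u) 4 + stats::qbinom(u, 8, 0.5),
    drop           = function(u) stats::qbinom(u, 7, 0.42),
    human_activity = function(u) stats::qlnorm(u, log(1.1), 0.3),
    isa            = function(u) 100 * stats::qbeta(u, 2, 35),
    light          = function(u) stats::qlnorm(u, log(3160), 0.5),
    ndvi           = function(u) pmin(pmax(stats::qnorm(u, 0.76, 0.06), -1), 1),
    path           = function(u) stats::qlnorm(u, log(14.3), 0.6),
    road           = function(u) stats::qlnorm(u, log(85.4), 0.7),
    sound          = function(u) stats::qnorm(u, 65.44, 2),
    temperature    = function(u) stats::qnorm(u, 10.86, 0.8),
    tree_cover     = function(u) 100 * stats::qbeta(u, 3, 7.15))
}

#' The 13 nest indicator names
#' @return Character vector of indicator column names in canonical order.
#' @export
nest_indicator_names <- function() {
  c("hatching_day", "hatchlings_initial", "hatchlings_final",
    "nest_size_diff", "human_activity", "isa", "light", "ndvi", "path",
    "road", "sound", "temperature", "tree_cover")
}

default_indicator_corr <- function(latent_names) {
  k <- length(latent_names)
  R <- diag(k)
  dimnames(R) <- list(latent_names, latent_names)
  set_r <- function(i, j, v) {
    R[i, j] <<- v; R[j, i] <<- v
  }
  set_r("isa", "light", 0.5)
  set_r("isa", "sound", 0.4)
  set_r("light", "sound", 0.4)
  set_r("ndvi", "tree_cover", 0.5)
  set_r("isa", "ndvi", -0.3)
  R
}

#' Generate per-nest environments
#'
#' Draws the 13 brood and environmental indicators for each nest from a
#' Gaussian copula with configurable correlation matrix and marginals whose
#' medians are anchored at the published per-indicator medians (e.g. ISA
#' 4.59%, light 3160 lx, sound 65.44 dB).  Count indicators are internally
#' consistent: `hatchlings_final <= hatchlings_initial` within the brood
#' range and `nest_size_diff = hatchlings_initial - hatchlings_final`.
#'
#' @param design a [study_design()].
#' @return Data frame with `nest_id` and one column per indicator.
#' @export
generate_environments <- function(design) {
  stopifnot(inherits(design, "study_design"))
  marg <- indicator_marginals()
  latent <- names(marg)
  R <- design$indicator_corr
  if (is.null(R)) R <- default_indicator_corr(latent)
  stopifnot(identical(sort(rownames(R)), sort(latent)))
  R <- R[latent, latent]
  ev <- eigen(R, symmetric = TRUE)
  if (any(ev$values < 1e-10))
    stop("indicator correlation matrix is not positive definite")
  L <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  n <- design$nests
  Z <- matrix(stats::rnorm(n * length(latent)), n) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- latent
  vals <- lapply(latent, function(v) marg[[v]](U[, v]))
  names(vals) <- latent
  init <- vals$hatch_initial
  final <- pmin(pmax(init - vals$drop, design$brood_range[1]),
                design$brood_range[2])
  data.frame(nest_id = sprintf("N%02d", seq_len(n)),
             hatching_day = vals$hatching_day,
             hatchlings_initial = init,
             hatchlings_final = final,
             nest_size_diff = init - final,
             human_activity = vals$human_activity,
             isa = vals$isa, light = vals$light, ndvi = vals$ndvi,
             path = vals$path, road = vals$road, sound = vals$sound,
             temperature = vals$temperature, tree_cover = vals$tree_cover)
}

# Solve the ratio contour for the exponent pair: given target ratio r and
# exponent difference d, (a/(a+d))^(1/d) = r  =>  a = d r^d / (1 - r^d).
ratio_to_exponents <- function(r, d = 1) {
  stopifnot(all(r > 0), all(r < 1), all(d > 0))
  a <- d * r^d / (1 - r^d)
  cbind(a = a, b = a + d)
}

# Time-scale the unit-q trajectory so m(t_end) = frac * m_max: BP solutions
# satisfy m_{s p, s q}(t) = m_{p, q}(s t), so one root-find fixes q.
calibrate_time_scale <- function(a, b, c, m_max, t_end, frac = 0.95) {
  p1 <- m_max^(b - a)
  unit <- bp_params(a, b, c, p1, 1)
  target <- frac * m_max
  t_hi <- 1
  for (i in 1:60) {
    if (bp_solve(unit, t_hi)[1] > target) break
    t_hi <- t_hi * 2
  }
  t_star <- stats::uniroot(function(t) bp_solve(unit, t)[1] - target,
                           lower = 0, upper = t_hi, tol = 1e-8)$root
  s <- t_star / t_end
  list(p = s * p1, q = s)
}

#' Generate synthetic birds with known growth curves
#'
#' Assigns birds of each stratum to nests, draws each bird's true shape ratio
#' from `logit(r) = logit(baseline[stratum]) + sum(effect * standardised
#' indicator) + N(0, sd_logit^2)`, converts the ratio to an exponent pair
#' along the configured family, scales `(c, p, q)` to species-typical hatch
#' (~1 g) and asymptotic (~11 g blue tit, ~16 g great tit) masses with the
#' curve reaching 95% of the asymptote at the last weighing, and observes
#' masses under multiplicative lognormal noise — the error model the SSLE
#' objective assumes.
#'
#' @param design a [study_design()].
#' @param environments a [generate_environments()] table.
#' @return List with `birds` (data frame: ids, stratum, species, sex, nest,
#'   mass columns `mass_d<day>`) and `truth` (data frame: per-bird true
#'   `a, b, c, p, q` and `true_ratio`).
#' @export
generate_birds <- function(design, environments) {
  stopifnot(inherits(design, "study_design"), is.data.frame(environments))
  strata_meta <- data.frame(
    stratum = c("blue_f", "blue_m", "great_f", "great_m"),
    species = c("blue tit", "blue tit", "great tit", "great tit"),
    sex = c("female", "male", "female", "male"),
    hatch_mass = c(1.1, 1.1, 1.6, 1.6),
    adult_mass = c(11, 11, 16, 16))
  n_birds <- sum(design$strata)
  n_blue <- sum(design$strata[c("blue_f", "blue_m")])
  nests_blue <- max(1, min(design$nests - 1,
                           round(design$nests * n_blue / n_birds)))
  nest_species <- c(rep("blue tit", nests_blue),
                    rep("great tit", design$nests - nests_blue))
  names(nest_species) <- environments$nest_id

  # standardised indicators at nest level, for the effect map
  zenv <- environments
  for (v in nest_indicator_names()) {
    s <- stats::sd(environments[[v]])
    zenv[[v]] <- if (s > 0)
      (environments[[v]] - mean(environments[[v]])) / s else 0
  }

  assign_nests <- function(k, species) {
    pool <- environments$nest_id[nest_species == species]
    if (length(pool) == 0) stop("no nests allocated to ", species)
    # every nest of the species gets a bird first, then uniform, capped
    cap <- design$brood_range[2]
    counts <- stats::setNames(integer(length(pool)), pool)
    out <- character(k)
    for (i in seq_len(k)) {
      open <- names(counts)[counts < cap]
      empty <- names(counts)[counts == 0]
      pick <- if (length(empty) > 0) empty[1]
              else open[sample.int(length(open), 1)]
      counts[pick] <- counts[pick] + 1
      out[i] <- pick
    }
    out
  }

  rows <- list(); truths <- list(); bid <- 0
  times <- design$days - 1
  t_end <- max(times)
  for (si in seq_len(nrow(strata_meta))) {
    meta <- strata_meta[si, ]
    k <- design$strata[[meta$stratum]]
    if (k == 0) next
    nest_of <- assign_nests(k, meta$species)
    erow <- match(nest_of, environments$nest_id)
    eta <- stats::qlogis(design$baselines[[meta$stratum]]) +
      stats::rnorm(k, 0, design$sd_logit)
    if (!is.null(design$effects) && length(design$effects) > 0) {
      for (v in names(design$effects))
        eta <- eta + design$effects[[v]] * zenv[[v]][erow]
    }
    r <- stats::plogis(eta)
    d <- if (design$exponent_family == "scatter")
      stats::runif(k, 0.5, 2.5) else rep(1, k)
    ab <- ratio_to_exponents(r, d)
    for (i in seq_len(k)) {
      bid <- bid + 1
      c0 <- meta$hatch_mass * exp(stats::rnorm(1, 0, 0.05))
      m_max <- meta$adult_mass * exp(stats::rnorm(1, 0, 0.05))
      sc <- calibrate_time_scale(ab[i, "a"], ab[i, "b"], c0, m_max, t_end)
      pars <- bp_params(ab[i, "a"], ab[i, "b"], c0, sc$p, sc$q)
      mu <- bp_solve(pars, times)
      obs <- mu * exp(stats::rnorm(length(mu), 0, design$sigma))
      row <- data.frame(bird_id = sprintf("B%03d", bid),
                        nest_id = nest_of[i],
                        species = meta$species, sex = meta$sex,
                        stratum = meta$stratum)
      row[paste0("mass_d", design$days)] <- as.list(obs)
      rows[[bid]] <- row
      truths[[bid]] <- data.frame(bird_id = row$bird_id,
                                  stratum = meta$stratum,
                                  a = ab[i, "a"], b = ab[i, "b"],
                                  c = c0, p = sc$p, q = sc$q,
                                  true_ratio = r[i])
    }
  }
  list(birds = do.call(rbind, rows), truth = do.call(rbind, truths))
}

#' Simulate a complete synthetic study
#'
#' Chains [generate_environments()] and [generate_birds()] and joins the
#' per-nest indicators onto the bird table, producing the flat study-table
#' layout the reader/writer and the analysis functions consume.
#'
#' @param design a [study_design()].
#' @param seed optional integer seed; identical seeds give identical tables.
#' @return List with `table` (one row per bird: ids, stratum, 13 indicators,
#'   masses), `truth`, `environments`, `design`.
#' @export
simulate_study <- function(design = study_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  env <- generate_environments(design)
  gb <- generate_birds(design, env)
  tab <- merge(gb$birds, env, by = "nest_id", sort = FALSE)
  ord <- c("bird_id", "nest_id", "species", "sex", "stratum",
           nest_indicator_names(), paste0("mass_d", design$days))
  tab <- tab[order(tab$bird_id), ord]
  rownames(tab) <- NULL
  list(table = tab, truth = gb$truth, environments = env, design = design)
}

#' Simulate a mass series from explicit BP parameters
#'
#' Evaluates the BP trajectory at the given times and applies multiplicative
#' lognormal measurement noise, `m_i = m(t_i) exp(e_i)`,
#' `e_i ~ N(0, sigma^2)` — the error model the SSLE objective assumes.
#'
#' @param params a [bp_params()] object.
#' @param times observation times (days since first weighing).
#' @param sigma log-scale noise standard deviation (0 for noiseless data).
#' @return A [mass_series()].
#' @export
simulate_mass_series <- function(params, times = seq(0, 14, by = 2),
                                 sigma = 0.05) {
  mu <- bp_solve(params, times)
  mass_series(times, mu * exp(stats::rnorm(length(mu), 0, sigma)))
}

#' Ratio-recovery experiment on synthetic birds
#'
#' Generates `n_birds` synthetic individuals with known shape ratios — drawn
#' from the generator's logit-normal ratio model and realised on the
#' generalized-logistic exponent line, scaled to blue-tit-like hatch and
#' asymptotic masses — observes their trajectories under lognormal noise,
#' refits each bird by grid search, and returns true and fitted ratios side
#' by side.  This is the package's scaled-down check that the fitting
#' pipeline recovers the quantity the analysis consumes.
#'
#' @param n_birds number of synthetic birds.
#' @param sigma log-scale measurement noise.
#' @param baseline,sd_logit centre and logit-scale spread of the true ratios.
#' @param grid a [bp_grid()]; the default is a reduced grid (spacing 0.05)
#'   sized for a desk-scale run.
#' @param config a [bp_anneal_config()]; the default is a light budget that
#'   relies on warm starts across neighbouring grid points.
#' @param hatch_mass,adult_mass species-typical scale for the curves (g).
#' @param seed integer seed.
#' @return Data frame with `true_ratio`, `fit_ratio`, fitted `a`, `b`,
#'   `rl2`, `boundary_hit` per bird, plus attribute `summary` holding
#'   `median_abs_err` and `spearman`.
#' @export
ratio_recovery_experiment <- function(n_birds = 50, sigma = 0.05,
                                      baseline = 0.5, sd_logit = 0.5,
                                      grid = bp_grid(a_max = 2.5, b_max = 4,
                                                     spacing = 0.05,
                                                     min_gap = 0.05,
                                                     max_extensions = 2),
                                      config = bp_anneal_config(iters = 120,
                                                                restarts = 1,
                                                                polish = 60),
                                      hatch_mass = 1.1, adult_mass = 11,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- stats::plogis(stats::qlogis(baseline) +
                       stats::rnorm(n_birds, 0, sd_logit))
  ab <- ratio_to_exponents(r)
  times <- seq(0, 14, by = 2)
  out <- vector("list", n_birds)
  for (i in seq_len(n_birds)) {
    c0 <- hatch_mass * exp(stats::rnorm(1, 0, 0.05))
    m_max <- adult_mass * exp(stats::rnorm(1, 0, 0.05))
    sc <- calibrate_time_scale(ab[i, "a"], ab[i, "b"], c0, m_max, max(times))
    pars <- bp_params(ab[i, "a"], ab[i, "b"], c0, sc$p, sc$q)
    d <- simulate_mass_series(pars, times, sigma)
    fit <- bp_grid_search(d, grid, config)
    out[[i]] <- data.frame(true_ratio = r[i], fit_ratio = fit$shape$ratio,
                           a = fit$params$a, b = fit$params$b, rl2 = fit$rl2,
                           boundary_hit = fit$boundary_hit)
  }
  res <- do.call(rbind, out)
  attr(res, "summary") <- c(
    median_abs_err = stats::median(abs(res$fit_ratio - res$true_ratio)),
    spearman = stats::cor(res$true_ratio, res$fit_ratio,
                          method = "spearman"))
  res
}

#' Parameter-recovery report
#'
#' Scores fitted shape ratios against the generator's truth: per-stratum and
#' overall bias, mean and median absolute error, and Spearman rank
#' correlation between true and fitted ratio.  If the fits carry a good-fit
#' region median ratio (column `gfr_median_ratio`), also reports the fraction
#' of birds whose region median is within 0.05 of the best-fit ratio.
#'
#' @param truth `truth` table from [simulate_study()].
#' @param fits data frame with `bird_id`, `ratio`, optionally
#'   `gfr_median_ratio`.
#' @return Data frame with one row per stratum plus an `overall` row.
#' @export
recovery_report <- function(truth, fits) {
  stopifnot(all(c("bird_id", "true_ratio") %in% names(truth)),
            all(c("bird_id", "ratio") %in% names(fits)))
  m <- merge(truth, fits, by = "bird_id")
  if (nrow(m) != nrow(fits))
    stop("bird ids in fits do not match the truth table")
  score <- function(d, label) {
    err <- d$ratio - d$true_ratio
    rho <- if (nrow(d) >= 3 && stats::sd(d$true_ratio) > 0 &&
               stats::sd(d$ratio) > 0)
      stats::cor(d$true_ratio, d$ratio, method = "spearman") else NA_real_
    out <- data.frame(stratum = label, n = nrow(d), bias = mean(err),
                      mae = mean(abs(err)), medae = stats::median(abs(err)),
                      spearman = rho)
    if ("gfr_median_ratio" %in% names(d))
      out$frac_region_stable <-
        mean(abs(d$gfr_median_ratio - d$ratio) < 0.05, na.rm = TRUE)
    out
  }
  res <- do.call(rbind, lapply(split(m, m$stratum), function(d)
    score(d, d$stratum[1])))
  res <- rbind(res, score(m, "overall"))
  rownames(res) <- NULL
  res
}
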