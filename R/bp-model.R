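#' Bertalanffy-Putter model parameters
#'
#' Constructs and validates the parameter quintuple of the Bertalanffy-Putter
#' (BP) growth model \deqn{m'(t) = p m(t)^a - q m(t)^b,\qquad m(0) = c > 0,}
#' where `a < b` are the non-negative metabolic exponents and `p`, `q` the
#' scaling constants of anabolism and catabolism.  The exponent pair fixes the
#' curve's shape; `c`, `p`, `q` fix its scale in mass and time.  Named special
#' cases: Brody `BP(0,1)`, von Bertalanffy `BP(2/3,1)`, West `BP(3/4,1)`,
#' logistic `BP(1,2)`; the Gompertz model is the diagonal limit `BP(1,1)` and
#' is excluded here (the equation degenerates at `a = b`).
#'
#' @param a,b metabolic exponents, `0 <= a < b`.
#' @param c initial mass (g) at `t = 0`, positive.
#' @param p anabolic scaling constant (g^(1-a)/day), positive.
#' @param q catabolic scaling constant (g^(1-b)/day), non-negative;
#'   `q = 0` gives unbounded growth with infinite asymptotic mass.
#' @return An object of class `bp_params` (named list with elements
#'   `a`, `b`, `c`, `p`, `q`).
#' @examples
#' bp_params(1, 2, c = 0.1, p = 1, q = 1)  # logistic growth
#' @export
bp_params <- function(a, b, c, p, q) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            is.numeric(p), is.numeric(q),
            length(a) == 1, length(b) == 1, length(c) == 1,
            length(p) == 1, length(q) == 1)
  if (!is.finite(a) || a < 0) stop("exponent 'a' must be finite and >= 0")
  if (!is.finite(b) || b <= a)
    stop("exponent 'b' must be finite and strictly greater than 'a' ",
         "(the Gompertz diagonal a = b is excluded)")
  if (!is.finite(c) || c <= 0) stop("initial mass 'c' must be positive")
  if (!is.finite(p) || p <= 0) stop("scaling constant 'p' must be positive")
  if (!is.finite(q) || q < 0) stop("scaling constant 'q' must be >= 0")
  structure(list(a = a, b = b, c = c, p = p, q = q), class = "bp_params")
}

#' @export
print.bp_params <- function(x, ...) {
  cat(sprintf("BP(a = %g, b = %g) with c = %g, p = %g, q = %g\n",
              x$a, x$b, x$c, x$p, x$q))
  invisible(x)
}

#' Instantaneous growth rate of the BP model
#'
#' Evaluates the right-hand side `p*m^a - q*m^b` of the BP differential
#' equation at mass `m`.
#'
#' @param m mass (g), positive; vectorised.
#' @param params a [bp_params()] object.
#' @return Growth rate(s) in g/day.
#' @export
bp_growth_rate <- function(m, params) {
  stopifnot(inherits(params, "bp_params"))
  if (any(!is.finite(m)) || any(m <= 0))
    stop("mass must be positive and finite")
  params$p * m^params$a - params$q * m^params$b
}

#' Solve the BP growth trajectory
#'
#' Integrates the BP differential equation numerically from `m(0) = c` with
#' an adaptive solver (lsoda via \pkg{deSolve}; the approach to the asymptote
#' is stiff for large exponents, so a stiffness-switching method is used) and
#' returns the mass at the requested times.  Numerical integration is used
#' uniformly for all exponent pairs; closed forms exist only for special
#' exponents and are kept as independent oracles in the test-suite.
#'
#' @param params a [bp_params()] object.
#' @param times non-negative, nondecreasing times (days since the first
#'   observation).
#' @param rtol,atol relative and absolute integration tolerances.
#' @return Numeric vector of masses, one per time.
#' @examples
#' bp_solve(bp_params(1, 2, 0.1, 1, 1), c(0, 2.197))  # logistic: ~ (0.1, 0.5)
#' @export
bp_solve <- function(params, times, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "bp_params"), is.numeric(times))
  if (length(times) == 0) return(numeric(0))
  if (any(times < 0) || is.unsorted(times))
    stop("times must be non-negative and nondecreasing")
  tt <- unique(c(0, times))
  if (length(tt) == 1) return(rep(params$c, length(times)))  # all times at 0
  rhs <- function(t, y, parms) {
    y <- max(y, 1e-300)  # fractional powers of transient negatives are NaN
    list(parms$p * y^parms$a - parms$q * y^parms$b)
  }
  sol <- tryCatch(
    deSolve::ode(y = c(m = params$c), times = tt, func = rhs, parms = params,
                 method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 50000),
    warning = function(w) stop("BP integration failed for BP(", params$a, ",",
                               params$b, "): ", conditionMessage(w)),
    error = function(e) stop("BP integration failed for BP(", params$a, ",",
                             params$b, "): ", conditionMessage(e)))
  m <- sol[, "m"]
  if (any(!is.finite(m)))
    stop("BP integration produced non-finite masses for BP(",
         params$a, ",", params$b, ")")
  m[match(times, tt)]
}

#' Asymptotic mass of a BP curve
#'
#' `m_max = (p/q)^(1/(b-a))` for `q > 0`; for `q = 0` growth is unbounded and
#' the asymptotic mass is infinite (returned as `Inf`, never a large finite
#' sentinel).
#'
#' @param params a [bp_params()] object.
#' @return Asymptotic mass in g, possibly `Inf`.
#' @export
bp_asymptotic_mass <- function(params) {
  stopifnot(inherits(params, "bp_params"))
  if (params$q == 0) return(Inf)
  (params$p / params$q)^(1 / (params$b - params$a))
}

#' Mass at the inflection point of a BP curve
#'
#' `m_infl = (a/b)^(1/(b-a)) * m_max`.  There is no inflection point when
#' `a = 0` (Brody-type bounded exponential growth) or `q = 0` (unbounded
#' growth); by convention those cases return 0.
#'
#' @param params a [bp_params()] object.
#' @return Inflection mass in g (0 when no inflection point exists).
#' @export
bp_inflection_mass <- function(params) {
  stopifnot(inherits(params, "bp_params"))
  if (params$a == 0 || params$q == 0) return(0)
  bp_shape_ratio(params$a, params$b) * bp_asymptotic_mass(params)
}

#' Time of the inflection point of a BP curve
#'
#' Solves `m(t) = m_infl` on the numerically integrated trajectory by
#' bracketed root-finding (the trajectory is strictly increasing below
#' `m_max`, so the root is unique).  Returns 0 when the curve has no
#' inflection point, and 0 with attribute `flag = "before-start"` when the
#' initial mass already exceeds the inflection mass (the inflection lies
#' before the observation window).
#'
#' @param params a [bp_params()] object.
#' @param tol absolute tolerance on the root, days.
#' @return Inflection time in days since `t = 0`.
#' @examples
#' bp_inflection_time(bp_params(1, 2, 0.1, 1, 1))  # log(9) = 2.197
#' @export
bp_inflection_time <- function(params, tol = 1e-6) {
  stopifnot(inherits(params, "bp_params"))
  m_infl <- bp_inflection_mass(params)
  if (m_infl == 0) return(0)
  if (params$c >= m_infl)
    return(structure(0, flag = "before-start"))
  t_hi <- 1
  for (i in 1:60) {
    if (bp_solve(params, t_hi)[1] > m_infl) break
    t_hi <- t_hi * 2
  }
  if (bp_solve(params, t_hi)[1] <= m_infl)
    stop("could not bracket the inflection time for BP(",
         params$a, ",", params$b, ")")
  uniroot(function(t) bp_solve(params, t)[1] - m_infl,
          lower = 0, upper = t_hi, tol = tol)$root
}

#' Shape parameters of a BP curve
#'
#' Computes the asymptotic mass, inflection mass and time, and the
#' dimensionless shape ratio `m_infl/m_max` of a BP curve.  The ratio depends
#' on the exponent pair only; curves without an inflection point (`a = 0` or
#' `q = 0`) are recorded with `m_infl = 0`, `t_infl = 0`, `ratio = 0`.
#'
#' @param params a [bp_params()] object.
#' @param compute_time if `FALSE`, skip the (comparatively expensive)
#'   root-finding for `t_infl` and return `NA` there.
#' @return A list of class `bp_shape` with elements `m_max`, `m_infl`,
#'   `t_infl`, `ratio`, and logical `inflection_before_start`.
#' @export
bp_shape <- function(params, compute_time = TRUE) {
  stopifnot(inherits(params, "bp_params"))
  m_max <- bp_asymptotic_mass(params)
  no_infl <- params$a == 0 || params$q == 0
  m_infl <- if (no_infl) 0 else bp_inflection_mass(params)
  ratio <- if (no_infl) 0 else bp_shape_ratio(params$a, params$b)
  before <- !no_infl && params$c >= m_infl
  t_infl <- if (!compute_time) NA_real_
            else if (no_infl || before) 0
            else bp_inflection_time(params)
  structure(list(m_max = m_max, m_infl = m_infl,
                 t_infl = as.numeric(t_infl), ratio = ratio,
                 inflection_before_start = before),
            class = "bp_shape")
}

#' @export
print.bp_shape <- function(x, ...) {
  cat(sprintf("m_max = %g g, m_infl = %g g, t_infl = %g d, ratio = %g\n",
              x$m_max, x$m_infl, x$t_infl, x$ratio))
  if (x$inflection_before_start)
    cat("(inflection point precedes the observation window)\n")
  invisible(x)
}

#' Shape ratio m_infl/m_max from the exponent pair
#'
#' The ratio of inflection mass over asymptotic mass is
#' `(a/b)^(1/(b-a))`: it depends on the exponent pair only, not on
#' `c`, `p`, `q`.  It is 0 for `a = 0` and lies in `[0, 1)` for all
#' `0 <= a < b`.  Fixed-exponent models therefore have fixed ratios
#' (0.5 for logistic growth); the generalized logistic family `(a, a+1)`
#' has ratio `a/(a+1)`, so any ratio in (0,1) is attainable on that line.
#'
#' @param a,b exponent pair(s), `0 <= a < b`; vectorised.
#' @return Ratio(s) in `[0, 1)`.
#' @examples
#' bp_shape_ratio(1, 2)      # 0.5
#' bp_shape_ratio(2/3, 1)    # (2/3)^3 = 8/27
#' @export
bp_shape_ratio <- function(a, b) {
  if (any(a < 0) || any(b <= a)) stop("require 0 <= a < b")
  ifelse(a == 0, 0, (a / b)^(1 / (b - a)))
}

#' Named special-case growth models
#'
#' Maps a traditional model name to its exponent constraint within the BP
#' family: a fixed pair for the three-parameter models, a one-parameter
#' exponent family for the four-parameter models.
#'
#' @param name one of `"Brody"`, `"Bertalanffy"`, `"West"`, `"logistic"`,
#'   `"Gompertz"`, `"Richards"`, `"generalized-Bertalanffy"`,
#'   `"generalized-logistic"`.
#' @return A list with `name`, `kind` (`"fixed"`, `"family"`, or `"limit"`),
#'   and either `a`,`b` (fixed pair) or a `constraint` description string plus
#'   an `exponents(s)` function mapping the free family parameter to `(a, b)`.
#' @export
bp_named_model <- function(name) {
  name <- match.arg(name, c("Brody", "Bertalanffy", "West", "logistic",
                            "Gompertz", "Richards", "generalized-Bertalanffy",
                            "generalized-logistic"))
  fixed <- function(a, b) list(name = name, kind = "fixed", a = a, b = b)
  switch(name,
    "Brody"       = fixed(0, 1),
    "Bertalanffy" = fixed(2 / 3, 1),
    "West"        = fixed(3 / 4, 1),
    "logistic"    = fixed(1, 2),
    "Gompertz"    = list(name = name, kind = "limit", a = 1, b = 1,
                         note = "diagonal limit BP(1,1); not in the BP grid"),
    "Richards"    = list(name = name, kind = "family",
                         constraint = "a = 1, b > 1",
                         exponents = function(s) c(a = 1, b = s)),
    "generalized-Bertalanffy" = list(name = name, kind = "family",
                         constraint = "0 <= a < 1, b = 1",
                         exponents = function(s) c(a = s, b = 1)),
    "generalized-logistic" = list(name = name, kind = "family",
                         constraint = "b = a + 1, a > 0",
                         exponents = function(s) c(a = s, b = s + 1)))
}

#' Attainable shape-ratio interval of a four-parameter model family
#'
#' Sweeps the free exponent of a one-parameter family and returns the range
#' of attainable shape ratios.  The Richards family (`a = 1`, `b > 1`) is
#' bounded below by `1/e` (the limit of `(1/b)^(1/(b-1))` as `b -> 1+`); the
#' generalized Bertalanffy family (`b = 1`) is bounded above by the same
#' `1/e`; the generalized logistic family attains any ratio in (0, 1).
#'
#' @param family family name accepted by [bp_named_model()]; must be one of
#'   the three one-parameter families.
#' @param n number of sweep points.
#' @return Named numeric vector `c(lower, upper)`; both bounds are open
#'   except the generalized-Bertalanffy lower bound 0 (attained at `a = 0`).
#' @examples
#' bp_family_ratio_bounds("Richards")["lower"]  # 1/e = 0.368
#' @export
bp_family_ratio_bounds <- function(family, n = 20000) {
  fam <- bp_named_model(family)
  if (fam$kind != "family")
    stop("'", family, "' has a fixed exponent pair, hence a fixed ratio")
  eps <- 1e-9
  s <- switch(fam$name,
    "Richards"                = 1 + exp(seq(log(eps), log(1e6),
                                            length.out = n)),
    "generalized-Bertalanffy" = seq(0, 1 - eps, length.out = n),
    "generalized-logistic"    = exp(seq(log(eps), log(1e6), length.out = n)))
  ab <- vapply(s, fam$exponents, numeric(2))
  r <- bp_shape_ratio(ab[1, ], ab[2, ])
  c(lower = min(r), upper = max(r))
}

#' Near-diagonal test for an exponent pair
#'
#' An exponent pair is near-diagonal when the exponent difference is smaller
#' than 1.5 (`b - a < 1.5`); the boundary itself is not near-diagonal.
#'
#' @param a,b exponent pair(s), `a < b`; vectorised.
#' @return Logical.
#' @export
bp_is_near_diagonal <- function(a, b) {
  if (any(b <= a)) stop("require a < b")
  (b - a) < 1.5
}

#' Gompertz trajectory (diagonal limit of the BP family)
#'
#' The Gompertz model `m' = m (p - q log m)` is the `a = b = 1` limit of the
#' BP equation and is handled outside the BP grid.  Closed form:
#' `m(t) = exp(p/q + (log(c) - p/q) exp(-q t))`.
#'
#' @param c initial mass (g); `p,q` positive rate constants.
#' @param times non-negative times (days).
#' @return Masses at `times`.
#' @export
gompertz_solve <- function(c, p, q, times) {
  stopifnot(c > 0, p > 0, q > 0, all(times >= 0))
  exp(p / q + (log(c) - p / q) * exp(-q * times))
}
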