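#' Siler five-parameter mortality hazard
#'
#' The Siler model expresses mortality risk at age `a` as the sum of a
#' declining immature component, a constant, and an exponentially increasing
#' senescent component:
#' \deqn{h(a) = a_1 e^{-b_1 a} + a_2 + a_3 e^{b_3 a}.}
#'
#' @param a1 immature hazard scale (1/yr), >= 0.
#' @param b1 immature hazard decay rate (1/yr), >= 0 (0 is the linear
#'   limit).
#' @param a2 constant hazard (1/yr), >= 0.
#' @param a3 senescent hazard scale (1/yr), >= 0.
#' @param b3 senescent hazard growth rate (1/yr), >= 0 (0 is the linear
#'   limit).
#' @return an object of class `siler_params` (named numeric vector).
#' @export
#' @examples
#' p <- siler_params(a1 = 1.59, b1 = 3, a2 = 0.057, a3 = 0.017, b3 = 0.34)
#' siler_hazard(p, c(0, 1, 5, 15))
siler_params <- function(a1, b1, a2, a3, b3) {
  p <- c(a1 = a1, b1 = b1, a2 = a2, a3 = a3, b3 = b3)
  if (any(!is.finite(p)) || any(p < 0))
    stop("all Siler parameters must be finite and >= 0")
  # b1 = 0 / b3 = 0 are allowed: the cumulative hazard uses the linear limit
  structure(p, class = "siler_params")
}

as_siler <- function(p) {
  if (inherits(p, "siler_params")) return(p)
  siler_params(p[["a1"]], p[["b1"]], p[["a2"]], p[["a3"]], p[["b3"]])
}

#' Siler hazard at age
#'
#' @param params a [siler_params()] object (or named vector with fields
#'   `a1,b1,a2,a3,b3`).
#' @param age age in years, >= 0 (vectorized).
#' @return hazard (1/yr), nonnegative.
#' @export
siler_hazard <- function(params, age) {
  p <- as_siler(params)
  if (any(age < 0)) stop("age must be >= 0")
  p[["a1"]] * exp(-p[["b1"]] * age) + p[["a2"]] + p[["a3"]] * exp(p[["b3"]] * age)
}

#' Siler cumulative hazard (closed form)
#'
#' Integral of the hazard from 0 to `age`:
#' \deqn{H(a) = \frac{a_1}{b_1}(1 - e^{-b_1 a}) + a_2 a +
#'   \frac{a_3}{b_3}(e^{b_3 a} - 1).}
#' The degenerate rates `b1 = 0` / `b3 = 0` are handled by the limiting
#' linear terms `a1*a` / `a3*a` (and `expm1` keeps small rates accurate).
#'
#' @inheritParams siler_hazard
#' @return cumulative hazard (dimensionless), nondecreasing in age.
#' @export
siler_cumhaz <- function(params, age) {
  p <- as_siler(params)
  if (any(age < 0)) stop("age must be >= 0")
  t1 <- if (p[["b1"]] == 0) p[["a1"]] * age else
    p[["a1"]] / p[["b1"]] * (-expm1(-p[["b1"]] * age))
  t3 <- if (p[["b3"]] == 0) p[["a3"]] * age else
    p[["a3"]] / p[["b3"]] * expm1(p[["b3"]] * age)
  t1 + p[["a2"]] * age + t3
}

#' Siler survivorship
#'
#' Probability of surviving from birth to `age`: `exp(-siler_cumhaz(age))`.
#'
#' @inheritParams siler_hazard
#' @return probability in (0, 1], nonincreasing in age.
#' @export
siler_survivorship <- function(params, age) {
  exp(-siler_cumhaz(params, age))
}

#' Longevity: age attained by a given fraction of females
#'
#' Solves `S(a) = quantile` by bracketed root-finding. The default quantile
#' 0.001 gives the age exceeded by only 0.1% of females.
#'
#' @inheritParams siler_hazard
#' @param survivorship_quantile probability in (0, 1); default 0.001.
#' @param max_age search ceiling (yr).
#' @return age in years, to 1e-6 yr.
#' @export
#' @examples
#' # constant hazard 0.5/yr: longevity = -ln(0.001)/0.5
#' longevity(siler_params(0, 1, 0.5, 0, 1))
longevity <- function(params, survivorship_quantile = 0.001, max_age = 100) {
  stopifnot(survivorship_quantile > 0, survivorship_quantile < 1)
  p <- as_siler(params)
  f <- function(a) siler_cumhaz(p, a) + log(survivorship_quantile)
  if (f(max_age) < 0)
    stop("survivorship does not reach the quantile within max_age")
  uniroot(f, c(0, max_age), tol = 1e-9)$root
}

#' Life expectancy at birth
#'
#' Numerical integral of the survivorship function; there is no closed-form
#' antiderivative of the Siler survivorship, so adaptive quadrature is used
#' up to the age where survivorship drops below 1e-12.
#'
#' @inheritParams siler_hazard
#' @return expected lifespan in years.
#' @export
life_expectancy <- function(params) {
  p <- as_siler(params)
  if (p[["a2"]] <= 0 && p[["a3"]] <= 0)
    stop("life expectancy diverges unless a2 > 0 or a3 > 0")
  upper <- 1
  while (siler_survivorship(p, upper) > 1e-12 && upper < 1e4) upper <- upper * 2
  integrate(function(a) siler_survivorship(p, a), 0, upper,
            rel.tol = 1e-8, subdivisions = 500L)$value
}

#' Solve Siler parameters from annual-survival anchors
#'
#' Builds the baseline hazard curve passing through stated adult annual
#' survival rates and first-year survivorship. Annual survival at age `a` is
#' read as the instantaneous annualized rate `exp(-h(a))`, so each anchor
#' fixes the hazard at that age; first-year survivorship fixes the cumulative
#' hazard over (0, 1). With the immature decay rate `b1` held fixed this is a
#' square system in `(a1, a2, a3, b3)`, solved by damped Newton iteration on
#' the log scale.
#'
#' @param annual_survival named numeric vector of annual survival rates, names
#'   are ages in years (default the study anchors: 0.91 at 2, 0.57 at 10,
#'   0.02 at 16).
#' @param S1 survivorship to age 1 (default 0.56).
#' @param b1 fixed immature decay rate (1/yr).
#' @return a [siler_params()] object reproducing the anchors.
#' @export
#' @examples
#' p <- siler_from_anchors()
#' exp(-siler_hazard(p, c(2, 10, 16)))  # 0.91 0.57 0.02
#' siler_survivorship(p, 1)             # 0.56
siler_from_anchors <- function(annual_survival = c(`2` = 0.91, `10` = 0.57,
                                                   `16` = 0.02),
                               S1 = 0.56, b1 = 3) {
  ages <- as.numeric(names(annual_survival))
  stopifnot(length(ages) == 3L, all(is.finite(ages)))
  targets <- c(-log(annual_survival), -log(S1))
  resid <- function(th) {
    p <- exp(th)
    sp <- siler_params(p[1], b1, p[2], p[3], p[4])
    c(siler_hazard(sp, ages), siler_cumhaz(sp, 1)) - targets
  }
  th <- log(c(1.5, 0.06, 0.017, 0.34))
  for (it in 1:100) {
    f0 <- resid(th)
    if (max(abs(f0)) < 1e-12) break
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      e <- rep(0, 4); e[j] <- 1e-7
      J[, j] <- (resid(th + e) - f0) / 1e-7
    }
    step <- solve(J, f0)
    # damp to keep the log-scale Newton step stable far from the root
    th <- th - pmax(pmin(step, 2), -2)
  }
  if (max(abs(resid(th))) > 1e-8) stop("anchor solve did not converge")
  p <- exp(th)
  siler_params(p[1], b1, p[2], p[3], p[4])
}
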