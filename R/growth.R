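#' Per-capita growth rate of the Binary Switch Model
#'
#' Evaluates the continuum per-capita growth rate `(1/C) dC/dt` at density
#' `C`. The law is a degree-six polynomial in `C`: a binomial mixture of
#' the net low-density mechanisms (neighbour counts `j <= M`, weight
#' \eqn{r[1 - 6\alpha/(6-j)]}), the net high-density mechanisms
#' (`j > M`, weight `R [1 - 6 beta / (6 - j)]`), and the crowding death
#' term `-R beta C^6`. When `M = 5` the high-density proliferation sum is
#' empty (implemented as an empty index range, not a branch).
#'
#' @param C Density in `[0, 1]` (numeric vector).
#' @param params A [bsm_params()] object.
#' @param tol Tolerance on the domain check for `C`.
#' @return Per-capita rate, same length as `C`.
#' @examples
#' per_capita_rate(0, bsm_params(1, 1, 0.25, 0, M = 2))  # r (1 - alpha)
#' @export
per_capita_rate <- function(C, params, tol = 1e-12) {
  assert_params(params)
  if (any(C < -tol | C > 1 + tol))
    stop("'C' must lie in [0, 1]")
  C <- pmin(pmax(C, 0), 1)
  out <- -params$R * params$beta * C^6
  for (j in 0:params$M) {
    out <- out + params$r * choose(5, j) * C^j * (1 - C)^(6 - j) *
      (1 - 6 * params$alpha / (6 - j))
  }
  for (j in seq_len(5 - params$M) + params$M) {  # empty when M = 5
    out <- out + params$R * choose(5, j) * C^j * (1 - C)^(6 - j) *
      (1 - 6 * params$beta / (6 - j))
  }
  out
}

#' Per-capita growth rate from a general rate table
#'
#' Evaluates the general mean-field growth law for an arbitrary
#' neighbour-dependent rate table: with `gamma[n]` the net growth
#' coefficients of [gamma_coefficients()],
#' \deqn{(1/C)\,dC/dt = (1-C) \sum_{n=0}^{5} \gamma_n \binom{5}{n}
#'   C^n (1-C)^{5-n} - \gamma_6 C^6.}
#' Applied to [switch_rates()] this is an independent evaluation route for
#' [per_capita_rate()]; applied to other rate tables it is the mean field
#' of the lattice simulator in [simulate_abm()].
#'
#' @param C Density in `[0, 1]` (numeric vector).
#' @param rates A [neighbour_rates()] object.
#' @return Per-capita rate, same length as `C`.
#' @export
per_capita_rate_general <- function(C, rates) {
  gam <- gamma_coefficients(rates)
  out <- -gam[7] * C^6
  mix <- 0
  for (n in 0:5)
    mix <- mix + gam[n + 1] * choose(5, n) * C^n * (1 - C)^(5 - n)
  out + (1 - C) * mix
}

#' Growth rate of the Binary Switch Model
#'
#' `dC/dt = C * per_capita_rate(C, params)`; exactly zero at `C = 0`.
#'
#' @inheritParams per_capita_rate
#' @return Growth rate `dC/dt`, same length as `C`.
#' @examples
#' growth_rate(0.5, bsm_params(1, 1, 0, 0, M = 3))  # logistic collapse
#' @export
growth_rate <- function(C, params, tol = 1e-12) {
  C * per_capita_rate(C, params, tol = tol)
}

#' Polynomial coefficients of the growth rate
#'
#' Expands `dC/dt` into its exact power-basis form
#' `sum(coef[k+1] * C^k, k = 0..7)`. The constant coefficient is exactly
#' zero (density zero is always an equilibrium). This expansion is the
#' basis of the equilibrium analysis in [find_equilibria()].
#'
#' @param params A [bsm_params()] object.
#' @return Numeric vector of length 8, coefficients of `C^0 .. C^7`.
#' @examples
#' polynomial_coefficients(bsm_params(1, 1, 0, 0, M = 2))  # C - C^2
#' @export
polynomial_coefficients <- function(params) {
  assert_params(params)
  coef <- numeric(8)
  # C^(j+1) (1-C)^(6-j) expanded via the binomial theorem
  add_term <- function(coef, j, w) {
    q <- 6 - j
    i <- 0:q
    idx <- j + 1 + i + 1  # power j+1+i, 1-based
    coef[idx] <- coef[idx] + w * choose(q, i) * (-1)^i
    coef
  }
  for (j in 0:params$M)
    coef <- add_term(coef, j,
                     params$r * choose(5, j) * (1 - 6 * params$alpha / (6 - j)))
  for (j in seq_len(5 - params$M) + params$M)
    coef <- add_term(coef, j,
                     params$R * choose(5, j) * (1 - 6 * params$beta / (6 - j)))
  coef[8] <- coef[8] - params$R * params$beta
  coef[1] <- 0
  coef
}

# Evaluate a power-basis polynomial (ascending coefficients) by Horner.
poly_eval <- function(coef, x) {
  out <- rep(0, length(x))
  for (k in rev(seq_along(coef)))
    out <- out * x + coef[k]
  out
}

# Derivative of an ascending coefficient vector.
poly_deriv <- function(coef) {
  n <- length(coef)
  if (n <= 1) return(0)
  coef[-1] * seq_len(n - 1)
}

#' Integrate a model trajectory
#'
#' Solves `dC/dt = growth_rate(C, params)` from initial density `C0` over
#' the time grid `times`. The default integrator is an adaptive
#' Dormand-Prince 5(4) Runge-Kutta kernel operating on the exact
#' polynomial form of the growth rate; `method = "lsoda"` routes the same
#' right-hand side through [deSolve::ode()] as an independent integrator.
#'
#' @param params A [bsm_params()] object.
#' @param C0 Initial density in `[0, 1]`.
#' @param times Strictly increasing numeric vector of output times; the
#'   first entry is the initial time.
#' @param method `"rk45"` (default) or `"lsoda"`.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return An object of class `bsm_trajectory`: a data frame with columns
#'   `t` and `density`, with the parameters and `C0` stored as attributes.
#' @examples
#' tr <- solve_trajectory(bsm_params(1, 1, 0, 0, M = 2), 0.1, seq(0, 10, 0.5))
#' head(tr)
#' @export
solve_trajectory <- function(params, C0, times, method = c("rk45", "lsoda"),
                             rtol = 1e-8, atol = 1e-10) {
  assert_params(params)
  method <- match.arg(method)
  if (C0 < 0 || C0 > 1) stop("'C0' must lie in [0, 1]")
  if (length(times) < 1 || any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  coef <- polynomial_coefficients(params)
  dens <- switch(method,
    rk45 = polyode_rk45(coef, C0, times - times[1], rtol, atol),
    lsoda = {
      rhs <- function(t, y, p) list(poly_eval(coef, y))
      sol <- deSolve::ode(y = c(C = C0), times = times, func = rhs,
                          parms = NULL, method = "lsoda",
                          rtol = rtol, atol = atol)
      if (attr(sol, "istate")[1] < 0)
        stop("lsoda integration failed; diagnostics: ",
             paste(attr(sol, "istate"), collapse = " "))
      as.numeric(sol[, "C"])
    })
  if (any(!is.finite(dens)))
    stop("trajectory integration failed (non-finite densities)")
  structure(data.frame(t = times, density = dens),
            params = params, C0 = C0,
            class = c("bsm_trajectory", "data.frame"))
}

# Fast internal path used by the calibration objective: no validation,
# no object construction.
predict_density <- function(coef, C0, times) {
  polyode_rk45(coef, C0, times - times[1], 1e-8, 1e-10)
}
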