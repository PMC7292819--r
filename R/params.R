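#' Binary Switch Model parameters
#'
#' Constructs and validates the five-parameter set of the Binary Switch
#' Model: low/high-density proliferation rates `r` and `R`, the
#' death-to-proliferation ratios `alpha` (low density) and `beta` (high
#' density), and the integer threshold density `M`. An individual whose
#' number of occupied nearest-neighbour sites `n` satisfies `n <= M`
#' proliferates at rate `r` and dies at rate `r * alpha`; above the
#' threshold the rates are `R` and `R*beta`.
#'
#' @param r Low-density proliferation rate (per unit time, `>= 0`).
#' @param R High-density proliferation rate (per unit time, `>= 0`).
#' @param alpha Ratio of low-density death rate to `r`, in `[0, 1]`.
#' @param beta Ratio of high-density death rate to `R`, in `[0, 1]`.
#' @param M Threshold density, an integer in `{0, 1, 2, 3, 4, 5}`.
#' @param strict If `TRUE` (default) enforce the model's parameter ranges;
#'   set to `FALSE` only for exploratory use outside the defined ranges
#'   (`M` must still be a valid threshold).
#'
#' @return An object of class `bsm_params`.
#' @examples
#' bsm_params(r = 1, R = 2, alpha = 0.1, beta = 0.2, M = 2)
#' @export
bsm_params <- function(r, R, alpha, beta, M, strict = TRUE) {
  stopifnot(is.numeric(r), is.numeric(R), is.numeric(alpha),
            is.numeric(beta), length(r) == 1L, length(R) == 1L,
            length(alpha) == 1L, length(beta) == 1L, length(M) == 1L)
  if (!is.numeric(M) || M != round(M) || M < 0 || M > 5)
    stop("'M' must be an integer in {0, 1, 2, 3, 4, 5}")
  if (strict) {
    if (r < 0 || R < 0)
      stop("proliferation rates 'r' and 'R' must be non-negative")
    if (alpha < 0 || alpha > 1)
      stop("'alpha' must lie in [0, 1]")
    if (beta < 0 || beta > 1)
      stop("'beta' must lie in [0, 1]")
  }
  structure(
    list(r = as.numeric(r), R = as.numeric(R), alpha = as.numeric(alpha),
         beta = as.numeric(beta), M = as.integer(M)),
    class = "bsm_params")
}

#' @export
print.bsm_params <- function(x, ...) {
  cat("Binary Switch Model parameters\n")
  cat(sprintf("  r = %g, R = %g, alpha = %g, beta = %g, M = %d\n",
              x$r, x$R, x$alpha, x$beta, x$M))
  invisible(x)
}

is_bsm_params <- function(x) inherits(x, "bsm_params")

assert_params <- function(params) {
  if (!is_bsm_params(params))
    stop("'params' must be a 'bsm_params' object (see ?bsm_params)")
  invisible(params)
}

#' Neighbour-count-dependent proliferation and death rates
#'
#' Container for the general thirteen-parameter rate set of the underlying
#' lattice model: proliferation rates `p[n]` for occupied sites with
#' `n = 0..5` occupied neighbours and death rates `d[n]` for `n = 0..6`.
#' (A site with all six neighbours occupied cannot place a daughter, so no
#' proliferation rate is needed at `n = 6`.)
#'
#' @param p Numeric vector of length 6, proliferation rates for `n = 0..5`.
#' @param d Numeric vector of length 7, death rates for `n = 0..6`.
#' @return An object of class `bsm_rates`.
#' @seealso [switch_rates()] for the binary-switch special case,
#'   [gamma_coefficients()] for the net growth coefficients.
#' @examples
#' neighbour_rates(p = rep(1, 6), d = rep(0.1, 7))
#' @export
neighbour_rates <- function(p, d) {
  if (length(p) != 6L || length(d) != 7L)
    stop("'p' must have length 6 (n = 0..5) and 'd' length 7 (n = 0..6)")
  if (any(!is.finite(p)) || any(!is.finite(d)) || any(p < 0) || any(d < 0))
    stop("all rates must be finite and non-negative")
  structure(list(p = as.numeric(p), d = as.numeric(d)), class = "bsm_rates")
}

#' @export
print.bsm_rates <- function(x, ...) {
  cat("Neighbour-dependent rates (n = 0..6)\n")
  cat("  p:", format(x$p, digits = 4), "-\n")
  cat("  d:", format(x$d, digits = 4), "\n")
  invisible(x)
}

#' Binary-switch rate assignment
#'
#' Expands a `bsm_params` set into the full neighbour-dependent rate table:
#' `p[n] = r` and `d[n] = r*alpha` for `n <= M`, `p[n] = R` and
#' `d[n] = R * beta` for `n > M`.
#'
#' @param params A [bsm_params()] object.
#' @return A [neighbour_rates()] object.
#' @examples
#' switch_rates(bsm_params(1, 2, 0.1, 0.2, M = 2))
#' @export
switch_rates <- function(params) {
  assert_params(params)
  n_p <- 0:5
  n_d <- 0:6
  p <- ifelse(n_p <= params$M, params$r, params$R)
  d <- ifelse(n_d <= params$M, params$r * params$alpha, params$R * params$beta)
  neighbour_rates(p = p, d = d)
}

#' Net growth coefficients
#'
#' Collapses a neighbour-dependent rate table into the seven net growth
#' coefficients of the continuum law:
#' `gamma[n] = p[n] - 6 d[n] / (6 - n)` for `n = 0..5` and
#' `gamma[6] = d[6]`. Each `gamma[n]` (n <= 5) is the net growth
#' contribution of sites at local density `n`; `gamma[6]` enters the law
#' only through the crowding death term.
#'
#' @param rates A [neighbour_rates()] object.
#' @return Numeric vector of length 7 (`gamma[n]`, `n = 0..6`), with
#'   attribute `"rates"` holding the source rate table.
#' @examples
#' gamma_coefficients(switch_rates(bsm_params(1, 1, 0, 0, M = 2)))
#' @export
gamma_coefficients <- function(rates) {
  if (!inherits(rates, "bsm_rates"))
    stop("'rates' must be a 'bsm_rates' object (see ?neighbour_rates)")
  n <- 0:5
  gam <- c(rates$p - 6 * rates$d[1:6] / (6 - n), rates$d[7])
  structure(gam, rates = rates)
}

#' Classical growth model parameters
#'
#' Parameter container for the three classical reference growth laws:
#' logistic growth, the Weak Allee effect, and the Strong Allee effect.
#'
#' @param model One of `"logistic"`, `"weak_allee"`, `"strong_allee"`.
#' @param r Intrinsic rate (`> 0`).
#' @param K Carrying capacity (`> 0`).
#' @param A Weak-Allee deviation parameter (`> 0`); required for
#'   `"weak_allee"`.
#' @param B Strong-Allee extinction threshold (`0 < B < K`); required for
#'   `"strong_allee"`.
#' @return An object of class `classic_params`.
#' @examples
#' classic_params("strong_allee", r = 1, K = 1, B = 0.3)
#' @export
classic_params <- function(model = c("logistic", "weak_allee", "strong_allee"),
                           r, K, A = NULL, B = NULL) {
  model <- match.arg(model)
  if (r <= 0 || K <= 0) stop("'r' and 'K' must be positive")
  if (model == "weak_allee" && (is.null(A) || A <= 0))
    stop("weak Allee model requires A > 0")
  if (model == "strong_allee" && (is.null(B) || B <= 0 || B >= K))
    stop("strong Allee model requires 0 < B < K")
  structure(list(model = model, r = r, K = K, A = A, B = B),
            class = "classic_params")
}

#' Growth rate of the classical reference models
#'
#' Evaluates `dC/dt` for logistic growth \eqn{rC(1 - C/K)}, the Weak
#' Allee effect \eqn{rC(1 - C/K)(1 + C/A)}, or the Strong Allee effect
#' \eqn{rC(1 - C/K)(C/B - 1)}.
#'
#' @param C Density (numeric vector).
#' @param cp A [classic_params()] object.
#' @return Growth rate `dC/dt`, same length as `C`.
#' @examples
#' classic_rate(0.5, classic_params("logistic", r = 1, K = 1))
#' @export
classic_rate <- function(C, cp) {
  if (!inherits(cp, "classic_params"))
    stop("'cp' must be a 'classic_params' object")
  base <- cp$r * C * (1 - C / cp$K)
  switch(cp$model,
         logistic     = base,
         weak_allee   = base * (1 + C / cp$A),
         strong_allee = base * (C / cp$B - 1))
}
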