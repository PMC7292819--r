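#' Locate all equilibria of the Binary Switch Model in the unit interval
#'
#' Finds every root of the growth polynomial in the physical density range,
#' clusters numerically coincident roots into multiplicities, and assigns
#' stability. Roots of the (degree <= 7) polynomial are obtained from the
#' companion matrix and polished by Newton iteration. The zero equilibrium
#' is always present and reported first; density one is an equilibrium
#' exactly when `beta = 0`, which is tested on the parameter, not
#' numerically. The model supports at most three distinct equilibria in
#' `(0, 1]`.
#'
#' Stability at the domain boundaries 0 and 1 is one-sided (densities
#' cannot leave `[0, 1]`); interior roots of even multiplicity are
#' semi-stable.
#'
#' @param params A [bsm_params()] object.
#' @param tol Clustering tolerance in density used to merge near-coincident
#'   roots into a multiple root (and to accept near-real companion
#'   eigenvalues). Exact tangencies occupy measure-zero manifolds in
#'   parameter space; this tolerance is what makes them detectable in
#'   floating point.
#' @return An object of class `bsm_equilibria`: a data frame with columns
#'   `value`, `multiplicity`, `stability` (`"stable"`, `"unstable"` or
#'   `"semi-stable"`), ordered by `value`, with the parameters attached as
#'   an attribute.
#' @examples
#' find_equilibria(bsm_params(1, 1, 0.2, 0.2, M = 3))  # logistic: 0 and 0.8
#' @export
find_equilibria <- function(params, tol = 1e-6) {
  assert_params(params)
  coef <- polynomial_coefficients(params)
  scale <- max(abs(coef))
  if (scale == 0)
    stop("degenerate model: all rates are zero, growth is identically zero")
  # multiplicity of the root at zero = number of leading (near-)zero
  # coefficients; these vanish exactly for e.g. r = 0
  nz <- abs(coef) > 1e-13 * scale
  m0 <- which(nz)[1] - 1L
  q <- coef[(m0 + 1):length(coef)]
  q <- q[seq_len(max(which(abs(q) > 1e-13 * scale)))]  # trim degree

  # C* = 1 is an equilibrium iff the crowding death term R*beta vanishes
  # (tested on the parameters, not numerically). Its multiplicity can
  # reach 6 - M when R = 0, which scatters companion eigenvalues over
  # ~eps^(1/m); since the factor (C - 1)^m is known exactly, count the
  # vanishing derivatives at 1 and deflate it by synthetic division
  # (division by (x - 1) is a cumulative sum of descending coefficients)
  m1 <- 0L
  if (params$beta == 0 || params$R == 0) {
    dm <- coef
    while (m1 < length(q) - 1 && abs(poly_eval(dm, 1)) < 1e-7 * max(1, scale)) {
      m1 <- m1 + 1L
      dm <- poly_deriv(dm)
    }
    for (k in seq_len(m1)) {
      out <- cumsum(rev(q))
      q <- rev(out[-length(out)])
    }
  }

  interior <- numeric(0)
  if (length(q) > 1) {
    z <- pracma::roots(rev(q))
    # an m-fold real root perturbs its companion eigenvalues by ~eps^(1/m),
    # possibly off the real axis; keep a near-real conjugate pair only if
    # the polynomial genuinely vanishes (to tolerance) at its real part,
    # otherwise it is a true complex pair and carries no equilibrium
    real_keep <- abs(Im(z)) < 1e-7
    pair_cand <- which(!real_keep & Im(z) > 0 & abs(Im(z)) < 1e-4)
    x <- Re(z[real_keep])
    dcf <- poly_deriv(coef)
    sres0 <- max(1, scale)
    for (i in pair_cand) {
      xr <- Re(z[i])
      if (xr > -tol && xr < 1 + tol &&
          abs(poly_eval(coef, xr)) < 1e-9 * sres0 &&
          abs(poly_eval(dcf, xr)) < 1e-7 * sres0)
        x <- c(x, xr, xr)
    }
    x <- x[x > -tol & x < 1 + tol]
    # Newton polish on the deflated polynomial
    dq <- poly_deriv(q)
    for (i in seq_along(x)) {
      xi <- x[i]
      for (it in 1:30) {
        fx <- poly_eval(q, xi); fpx <- poly_eval(dq, xi)
        if (abs(fpx) < 1e-14 * scale) break
        step <- fx / fpx
        xi <- xi - step
        if (abs(step) < 1e-15) break
      }
      if (is.finite(xi) && abs(xi - x[i]) < 10 * tol) x[i] <- xi
    }
    interior <- sort(x[x > 1e-9 & x < 1 + tol])
  }
  interior <- pmin(interior, 1)

  # cluster into multiplicities; companion eigenvalues of an m-fold root
  # scatter by ~eps^(1/m), so after the tight pass adjacent clusters are
  # merged across a wider gap when both the polynomial and its derivative
  # vanish there (true for multiple roots, false for nearby simple pairs)
  vals <- numeric(0); mult <- integer(0)
  i <- 1
  while (i <= length(interior)) {
    jj <- i
    while (jj < length(interior) && interior[jj + 1] - interior[i] < tol)
      jj <- jj + 1
    vals <- c(vals, mean(interior[i:jj]))
    mult <- c(mult, jj - i + 1L)
    i <- jj + 1
  }
  dcoef <- poly_deriv(coef)
  sres <- max(1, scale)
  repeat {
    merged <- FALSE
    k <- 1
    while (k < length(vals)) {
      gap <- vals[k + 1] - vals[k]
      mid <- (vals[k] * mult[k] + vals[k + 1] * mult[k + 1]) /
        (mult[k] + mult[k + 1])
      if (gap < 1e-4 && abs(poly_eval(coef, mid)) < 1e-9 * sres &&
          abs(poly_eval(dcoef, mid)) < 1e-7 * sres) {
        vals[k] <- mid
        mult[k] <- mult[k] + mult[k + 1]
        vals <- vals[-(k + 1)]; mult <- mult[-(k + 1)]
        merged <- TRUE
      } else k <- k + 1
    }
    if (!merged) break
  }
  # multiple roots are better conditioned as roots of the derivative
  for (k in which(mult >= 2)) {
    dc <- if (mult[k] == 2) dcoef else poly_deriv(dcoef)
    xi <- vals[k]
    dd <- poly_deriv(dc)
    for (it in 1:30) {
      fp <- poly_eval(dd, xi)
      if (abs(fp) < 1e-14 * sres) break
      step <- poly_eval(dc, xi) / fp
      xi <- xi - step
      if (abs(step) < 1e-15) break
    }
    if (is.finite(xi) && abs(xi - vals[k]) < 1e-4) vals[k] <- xi
  }
  mult <- pmin(mult, 3L)
  if (m1 > 0) {
    keep <- vals < 1  # deflation already removed the root at 1
    vals <- c(vals[keep], 1)
    mult <- c(mult[keep], m1)
  }

  residual <- abs(poly_eval(coef, vals))
  if (any(residual > 1e-9 * max(1, scale)))
    stop("root residual exceeded tolerance: ",
         paste(sprintf("p(%.6g) = %.3g", vals[residual > 1e-9 * max(1, scale)],
                       residual[residual > 1e-9 * max(1, scale)]),
               collapse = ", "))

  values <- c(0, vals)
  mults <- c(m0, mult)
  stab <- character(length(values))
  for (k in seq_along(values)) {
    boundary <- if (values[k] == 0) "lower" else if (values[k] == 1) "upper" else "none"
    stab[k] <- stability_of_root(coef, values[k], mults[k], boundary = boundary)
  }
  structure(data.frame(value = values, multiplicity = mults, stability = stab),
            params = params, tol = tol,
            class = c("bsm_equilibria", "data.frame"))
}

#' Stability of a polynomial root
#'
#' Classifies an equilibrium `C*` of `dC/dt = p(C)` from the first
#' non-vanishing derivative of `p` at the root. For interior equilibria:
#' odd multiplicity with negative leading derivative is stable, positive is
#' unstable, and even multiplicity is semi-stable (attracting from one
#' side only). At the domain boundaries the classification is one-sided:
#' at `C* = 0` the sign of `p` just above zero decides, at `C* = 1` the
#' sign just below one.
#'
#' @param poly Ascending coefficient vector of `p`.
#' @param root The equilibrium value (must satisfy `p(root) ~ 0`).
#' @param multiplicity Root multiplicity (`>= 1`).
#' @param boundary `"none"` for interior roots, `"lower"` for `C* = 0`,
#'   `"upper"` for `C* = 1`.
#' @return One of `"stable"`, `"unstable"`, `"semi-stable"`.
#' @export
stability_of_root <- function(poly, root, multiplicity,
                              boundary = c("none", "lower", "upper")) {
  boundary <- match.arg(boundary)
  m <- as.integer(multiplicity)
  if (m < 1) stop("'multiplicity' must be at least 1")
  dm <- poly
  for (k in seq_len(m)) dm <- poly_deriv(dm)
  lead <- poly_eval(dm, root)  # p^(m)(root) / m! up to the factorial factor
  if (abs(lead) < 1e-12 * max(1, max(abs(poly))))
    stop("degenerate root: growth rate vanishes to order > multiplicity at C* = ",
         format(root))
  if (boundary == "lower") {
    # behaviour for C slightly above 0: p(C) ~ lead * C^m
    return(if (lead > 0) "unstable" else "stable")
  }
  if (boundary == "upper") {
    # behaviour for C slightly below 1: p(C) ~ lead * (C-1)^m
    left <- lead * (-1)^m
    return(if (left > 0) "stable" else "unstable")
  }
  if (m %% 2 == 0) return("semi-stable")
  if (lead < 0) "stable" else "unstable"
}

#' Classify the growth law into its qualitative regime
#'
#' Maps the equilibrium structure of a parameter set onto the model's
#' regime taxonomy: `Extinction`, `Logistic`, `WeakAllee`, `TriplePoint`,
#' `JunctionPoint`, `StrongAllee`, `ReverseAllee`,
#' `PositiveTangentialManifold`, `NegativeTangentialManifold`, or
#' `HyperAllee`. `Logistic` is reported only on the exact parameter
#' condition that `r` equals `R` and `alpha` equals `beta` (the no-switch
#' collapse), never
#' inferred from the root structure; the manifold/point labels are
#' returned only when a non-simple root is detected within the clustering
#' tolerance.
#'
#' @param params A [bsm_params()] object.
#' @param tol Clustering tolerance passed to [find_equilibria()].
#' @return A character scalar regime label, with the equilibrium set
#'   attached as attribute `"equilibria"`.
#' @examples
#' classify_regime(bsm_params(1, 1, 0.3, 0.3, M = 2))  # "Logistic"
#' @export
classify_regime <- function(params, tol = 1e-6) {
  assert_params(params)
  eq <- find_equilibria(params, tol = tol)
  zero <- eq[1, ]
  int <- eq[-1, , drop = FALSE]
  code <- c(stable = "S", unstable = "U", `semi-stable` = "SS")
  sig <- paste(code[eq$stability], collapse = ",")
  s <- paste(code[int$stability], collapse = ",")
  z <- zero$stability
  label <- NULL

  if (params$r == params$R && params$alpha == params$beta) {
    # no switch: logistic collapse with carrying capacity 1 - alpha
    label <- if (params$alpha < 1 && nrow(int) > 0) "Logistic" else "Extinction"
  } else if (nrow(int) == 0) {
    if (z == "stable") label <- "Extinction"
  } else if (nrow(int) == 1) {
    if (z == "unstable" && s == "S")
      # a high-multiplicity root at the boundary C* = 1 (R = 0 case) is
      # still plain Weak Allee; the Triple Point is an interior tangency
      label <- if (int$multiplicity >= 3 && int$value < 1) "TriplePoint"
               else "WeakAllee"
    else if (z == "stable" && s == "SS")
      label <- "JunctionPoint"
    else if (z == "stable" && s == "U" && int$value == 1)
      label <- "Extinction"  # alpha = 1 with R = 0: all C(0) < 1 decay to 0
  } else if (nrow(int) == 2) {
    if (z == "stable" && s == "U,S") label <- "StrongAllee"
    else if (z == "unstable" && s == "S,U") label <- "ReverseAllee"
    else if (z == "unstable" && s == "SS,S") label <- "PositiveTangentialManifold"
    else if (z == "unstable" && s == "S,SS") label <- "NegativeTangentialManifold"
  } else if (nrow(int) == 3) {
    if (z == "unstable" && s == "S,U,S") label <- "HyperAllee"
  }
  if (is.null(label))
    stop("unrecognised equilibrium signature {", sig, "} at r=", params$r,
         ", R=", params$R, ", alpha=", params$alpha, ", beta=", params$beta,
         ", M=", params$M, " - this should be unreachable; please report")
  structure(label, equilibria = eq)
}

#' @export
print.bsm_equilibria <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Equilibria of the Binary Switch Model (r=%g, R=%g, alpha=%g, beta=%g, M=%d)\n",
              p$r, p$R, p$alpha, p$beta, p$M))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
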