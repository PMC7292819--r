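#' @name case1
#' @title Case 1 equilibrium relation (no low-density turnover, r = 0)
#'
#' @description When individuals at or below the threshold neither
#' proliferate nor die (`r` = 0), the model has at most one equilibrium
#' `C1` in `(0, 1]`, and the high-density death ratio that produces it is
#' given in closed form by a rational function `beta = f_M(C1)`.
#' [case1_beta()] evaluates that function; [case1_equilibrium()] inverts
#' it, returning the unique equilibrium in `(0, 1]` when
#' `beta < (5 - M)/6` (and `M <= 4`) and `NA` otherwise — in that regime
#' only the zero equilibrium remains and the population goes extinct.
#'
#' @param M Threshold density. `f_M` is defined for `M` in `0..4`; for
#'   `M = 5` no interior equilibrium exists and [case1_beta()] errors.
#' @param C1 Equilibrium density in `(0, 1]` (vectorised).
#' @param beta High-density death ratio in `[0, 1]`.
#' @return [case1_beta()]: the value(s) of `beta`. [case1_equilibrium()]:
#'   the equilibrium density, or `NA` if none exists in `(0, 1]`.
#' @examples
#' case1_beta(4, 0.8)          # 0.1
#' case1_equilibrium(4, 0.1)   # 0.8
NULL

#' @rdname case1
#' @export
case1_beta <- function(M, C1) {
  if (length(M) != 1 || !(M %in% 0:5)) stop("'M' must be an integer in 0..5")
  if (M == 5)
    stop("f_5 is undefined: with M = 5 and r = 0 only the zero equilibrium exists")
  if (any(C1 <= 0 | C1 > 1)) stop("'C1' must lie in (0, 1]")
  x <- C1
  switch(as.character(M),
    "0" = (x^5 - 6*x^4 + 15*x^3 - 20*x^2 + 15*x - 5) /
          (x^5 - 6*x^4 + 15*x^3 - 20*x^2 + 15*x - 6),
    "1" = (4*x^4 - 19*x^3 + 35*x^2 - 30*x + 10) /
          (5*x^4 - 24*x^3 + 45*x^2 - 40*x + 15),
    "2" = (-6*x^3 + 21*x^2 - 25*x + 10) /
          (-10*x^3 + 36*x^2 - 45*x + 20),
    "3" = (4*x^2 - 9*x + 5) / (10*x^2 - 24*x + 15),
    "4" = (-x + 1) / (-5*x + 6))
}

#' @rdname case1
#' @export
case1_equilibrium <- function(M, beta) {
  if (length(M) != 1 || !(M %in% 0:5)) stop("'M' must be an integer in 0..5")
  if (beta < 0 || beta > 1) stop("'beta' must lie in [0, 1]")
  if (M == 5 || beta >= (5 - M) / 6) return(NA_real_)
  invert_monotone(function(x) case1_beta(M, x) - beta, 1e-12, 1)
}

#' @name case2
#' @title Case 2 equilibrium relation (no high-density turnover, R = 0)
#'
#' @description When individuals above the threshold neither proliferate
#' nor die (`R = 0`), densities 0 and 1 are always equilibria; a third
#' equilibrium `C1` in `(0, 1)` exists exactly when the low-density death
#' ratio satisfies `alpha = g_M(C1)`, a one-to-one rational function with
#' range `((6 - M)/6, 1)`. [case2_alpha()] evaluates `g_M`;
#' [case2_equilibrium()] inverts it (`NA` when no interior equilibrium
#' exists). Three equilibria give the Reverse Allee effect: 0 and 1
#' unstable, `C1` stable.
#'
#' @param M Threshold density. `g_M` is defined for `M` in `1..5`; for
#'   `M = 0` no interior equilibrium exists and [case2_alpha()] errors.
#' @param C1 Equilibrium density in `(0, 1)` (vectorised).
#' @param alpha Low-density death ratio in `[0, 1]`.
#' @return [case2_alpha()]: the value(s) of `alpha`.
#'   [case2_equilibrium()]: the interior equilibrium, or `NA`.
#' @examples
#' case2_alpha(1, 0.5)         # 3/3.5
#' case2_equilibrium(5, 0.5)   # interior equilibrium for M = 5
NULL

#' @rdname case2
#' @export
case2_alpha <- function(M, C1) {
  if (length(M) != 1 || !(M %in% 0:5)) stop("'M' must be an integer in 0..5")
  if (M == 0)
    stop("g_0 is undefined: with M = 0 and R = 0 no interior equilibrium exists")
  if (any(C1 <= 0 | C1 >= 1)) stop("'C1' must lie in (0, 1)")
  x <- C1
  switch(as.character(M),
    "1" = (4*x + 1) / (5*x + 1),
    "2" = (6*x^2 + 3*x + 1) / (10*x^2 + 4*x + 1),
    "3" = (4*x^3 + 3*x^2 + 2*x + 1) / (10*x^3 + 6*x^2 + 3*x + 1),
    "4" = (x^4 + x^3 + x^2 + x + 1) / (5*x^4 + 4*x^3 + 3*x^2 + 2*x + 1),
    "5" = 1 / (x^5 + x^4 + x^3 + x^2 + x + 1))
}

#' @rdname case2
#' @export
case2_equilibrium <- function(M, alpha) {
  if (length(M) != 1 || !(M %in% 0:5)) stop("'M' must be an integer in 0..5")
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (M == 0 || alpha <= (6 - M) / 6 || alpha >= 1) return(NA_real_)
  invert_monotone(function(x) case2_alpha(M, x) - alpha, 1e-12, 1 - 1e-12)
}

# Bracketed bisection + final Newton-free refinement for a monotone
# function with a sign change on [lo, hi]; tolerance 1e-12 in C.
invert_monotone <- function(f, lo, hi) {
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  uniroot(f, c(lo, hi), tol = 1e-13)$root
}

#' Tangential Manifold closed forms
#'
#' The Tangential Manifold is the set of parameters at which the growth
#' law has a double (tangential) root `C_hat` — a semi-stable equilibrium
#' separating the Weak Allee region of parameter space from the
#' Hyper-Allee region. With `r` fixed at 1 it is parametrised as
#' `R = F_M(C_hat, beta)`, `alpha = G_M(C_hat, beta)`.
#' `triple_point_beta()` (`H_M`) gives the `beta` at which the double root
#' degenerates into a stable triple root at density `C`, and
#' `junction_point_beta()` (`J_M`) the `beta` at which the Negative
#' Tangential Manifold reaches `alpha = 1`.
#'
#' These exist only for `M` in `1..4`: at `M = 0` or `M = 5` the defining
#' system forces `R = 0` and the manifold is empty.
#'
#' @param M Threshold density in `1..4`.
#' @param C_hat Double-root density in `(0, 1)` (vectorised).
#' @param beta High-density death ratio.
#' @param C Candidate Triple/Junction Point density in `[0, 1]`
#'   (vectorised).
#' @return Numeric value(s) of `R`, `alpha` or `beta` respectively.
#' @seealso [tangential_point()], [triple_point()], [junction_point()]
#' @name tangential_forms
NULL

check_M14 <- function(M) {
  if (length(M) != 1 || !(M %in% 1:4))
    stop("the Tangential Manifold exists only for M in {1, 2, 3, 4}")
}

#' @rdname tangential_forms
#' @export
tangential_R <- function(M, C_hat, beta) {
  check_M14(M)
  x <- C_hat
  switch(as.character(M),
    "1" = (x - 1)^6 /
          (x * (x^5 - 6*x^4 + 15*x^3 - 20*x^2 - 10*x - 30*beta + 20)),
    "2" = (x - 1)^5 * (6*x^2 + 8*x + 1) /
          (x^2 * (6*x^5 - 22*x^4 + 21*x^3 + 15*x^2 + 10*x + 60*beta - 30)),
    "3" = (x - 1)^4 * (6*x^4 + 16*x^3 + 21*x^2 + 6*x + 1) /
          (x^3 * (6*x^5 - 8*x^4 - 7*x^3 - 6*x^2 - 5*x - 60*beta + 20)),
    "4" = (x - 1)^3 * (x^6 + 4*x^5 + 10*x^4 + 20*x^3 + 10*x^2 + 4*x + 1) /
          (x^4 * (x^5 + x^4 + x^3 + x^2 + x + 30*beta - 5)))
}

#' @rdname tangential_forms
#' @export
tangential_alpha <- function(M, C_hat, beta) {
  check_M14(M)
  x <- C_hat
  switch(as.character(M),
    "1" = (beta * (x^5 - 6*x^4 + 15*x^3 - 20*x^2 + 15*x - 30) - 20*(x - 1)) /
          (x^5 - 6*x^4 + 15*x^3 - 20*x^2 - 10*x - 30*beta + 20),
    "2" = (beta * (6*x^5 - 22*x^4 + 21*x^3 + 15*x^2 - 40*x + 60) + 30*(x - 1)) /
          (6*x^5 - 22*x^4 + 21*x^3 + 15*x^2 + 10*x + 60*beta - 30),
    "3" = (beta * (6*x^5 - 8*x^4 - 7*x^3 - 6*x^2 + 45*x - 60) - 20*(x - 1)) /
          (6*x^5 - 8*x^4 - 7*x^3 - 6*x^2 - 5*x - 60*beta + 20),
    "4" = (beta * (x^5 + x^4 + x^3 + x^2 - 24*x + 30) + 5*(x - 1)) /
          (x^5 + x^4 + x^3 + x^2 + x + 30*beta - 5))
}

#' @rdname tangential_forms
#' @export
triple_point_beta <- function(M, C) {
  check_M14(M)
  x <- C
  switch(as.character(M),
    "1" = 2 * (1 - x) / 3,
    "2" = (1 - x) * (1 + 2*x) / (3*x + 2),
    "3" = (1 - x) * (1 + 2*x + 2*x^2) / (3*x^2 + 4*x + 3),
    "4" = (1 - x^2) * (2*x^2 + x + 2) / (3 * (x^3 + 2*x^2 + 3*x + 4)))
}

#' @rdname tangential_forms
#' @export
junction_point_beta <- function(M, C) {
  check_M14(M)
  x <- C
  switch(as.character(M),
    "1" = (x - 1) * (x^3 - 5*x^2 + 10*x - 10) /
          (x^4 - 6*x^3 + 15*x^2 - 20*x + 15),
    "2" = (x - 1) * (6*x^3 - 16*x^2 + 5*x + 20) /
          (6*x^4 - 22*x^3 + 21*x^2 + 15*x - 40),
    "3" = (x - 1) * (6*x^3 - 2*x^2 - 9*x - 15) /
          (6*x^4 - 8*x^3 - 7*x^2 - 6*x + 45),
    "4" = (x - 1) * (x^3 + 2*x^2 + 3*x + 4) /
          (x^4 + x^3 + x^2 + x - 24))
}

# The per-capita growth law V(C; R, alpha, beta, M) with r = 1 is linear
# in alpha and R separately: V = A0 + A1*alpha + A2*R. Returns the three
# component polynomials as ascending coefficient vectors (degree 6).
v_components <- function(beta, M) {
  a0 <- numeric(7); a1 <- numeric(7); a2 <- numeric(7)
  add <- function(vec, j, w) {
    q <- 6 - j; i <- 0:q
    vec[j + i + 1] <- vec[j + i + 1] + w * choose(q, i) * (-1)^i
    vec
  }
  for (j in 0:M) {           # low-density block: weight r=1, alpha part
    a0 <- add(a0, j, choose(5, j))
    a1 <- add(a1, j, -choose(5, j) * 6 / (6 - j))
  }
  for (j in seq_len(5 - M) + M) {  # high-density block, scales with R
    a2 <- add(a2, j, choose(5, j) * (1 - 6 * beta / (6 - j)))
  }
  a2[7] <- a2[7] - beta
  list(a0 = a0, a1 = a1, a2 = a2)
}

#' A point on the Tangential Manifold
#'
#' Computes the `(R, alpha)` pair for which the growth law has a double
#' root at `C_hat` given `beta`, by solving the defining 2x2 linear
#' system (per-capita rate and its density derivative both vanish at
#' `C_hat`; both equations are linear in `R` and `alpha`). The result
#' coincides with the closed forms [tangential_R()] / [tangential_alpha()]
#' and the residuals of the defining equations are verified to `1e-9`.
#' The branch is `"positive"` when `C_hat` is below the Triple Point
#' (semi-stable equilibrium below the stable one) and `"negative"` above
#' it.
#'
#' @param M Threshold density in `1..4`.
#' @param C_hat Double-root density in `(0, 1)`.
#' @param beta High-density death ratio in `[0, (5 - M)/6)`.
#' @return A list of class `tangential_point` with elements `M`, `C_hat`,
#'   `beta`, `R`, `alpha`, `branch`.
#' @examples
#' tangential_point(4, 0.5, 0.05)
#' @export
tangential_point <- function(M, C_hat, beta) {
  check_M14(M)
  if (C_hat <= 0 || C_hat >= 1) stop("'C_hat' must lie in (0, 1)")
  if (beta < 0 || beta >= (5 - M) / 6)
    stop("'beta' must lie in [0, (5 - M)/6) for the manifold to exist")
  vc <- v_components(beta, M)
  A <- rbind(c(poly_eval(vc$a1, C_hat), poly_eval(vc$a2, C_hat)),
             c(poly_eval(poly_deriv(vc$a1), C_hat),
               poly_eval(poly_deriv(vc$a2), C_hat)))
  b <- -c(poly_eval(vc$a0, C_hat), poly_eval(poly_deriv(vc$a0), C_hat))
  if (abs(det(A)) < 1e-12)
    stop("singular tangential system at C_hat = ", C_hat)
  sol <- solve(A, b)
  alpha <- sol[1]; R <- sol[2]
  # defining residuals
  v  <- poly_eval(vc$a0, C_hat) + alpha * poly_eval(vc$a1, C_hat) +
        R * poly_eval(vc$a2, C_hat)
  vp <- poly_eval(poly_deriv(vc$a0), C_hat) +
        alpha * poly_eval(poly_deriv(vc$a1), C_hat) +
        R * poly_eval(poly_deriv(vc$a2), C_hat)
  if (abs(v) > 1e-9 || abs(vp) > 1e-9)
    stop("tangential point residuals too large: |V| = ", abs(v),
         ", |dV/dC| = ", abs(vp))
  ctp <- triple_point(M, beta)$C_triple
  branch <- if (C_hat < ctp) "positive" else "negative"
  structure(list(M = M, C_hat = C_hat, beta = beta, R = R, alpha = alpha,
                 branch = branch),
            class = "tangential_point")
}

#' The Triple Point
#'
#' Solves `beta = H_M(C)` for the density at which the tangential double
#' root degenerates into a stable triple root, and cross-validates it
#' against the second-derivative condition of the growth law evaluated on
#' the Tangential Manifold. At `beta = 0` the Triple Point sits at density
#' 1 for every `M` in `1..4`; it decreases to 0 as `beta` approaches
#' `(5 - M)/6`.
#'
#' @param M Threshold density in `1..4`.
#' @param beta High-density death ratio in `[0, (5 - M)/6]`.
#' @return A list of class `triple_point` with elements `M`, `C_triple`,
#'   `beta`, or `NULL` when `beta` is outside `[0, (5 - M)/6]`.
#' @examples
#' triple_point(1, 0)$C_triple   # 1
#' @export
triple_point <- function(M, beta) {
  check_M14(M)
  if (beta < 0 || beta > (5 - M) / 6) return(NULL)
  f <- function(x) triple_point_beta(M, x) - beta
  C <- if (f(0) == 0) 0 else if (f(1) == 0) 1 else
    uniroot(f, c(0, 1), tol = 1e-13)$root
  structure(list(M = M, C_triple = C, beta = beta), class = "triple_point")
}

#' The Junction Point
#'
#' Solves `beta = J_M(C)` for the equilibrium density at which the
#' Negative Tangential Manifold reaches `alpha = 1` — the boundary between
#' the Extinction regime and the Strong Allee effect — and evaluates the
#' corresponding critical high-density rate `R_junction = F_M(C, beta)`.
#' The defining identity `G_M(C, beta) = 1` is verified to `1e-9`.
#'
#' @param M Threshold density in `1..4`.
#' @param beta High-density death ratio in `[0, (5 - M)/6]`.
#' @return A list of class `junction_point` with elements `M`,
#'   `C_junction`, `beta`, `R_junction`, or `NULL` when `beta` is outside
#'   `[0, (5 - M)/6]`.
#' @examples
#' junction_point(4, 0.05)
#' @export
junction_point <- function(M, beta) {
  check_M14(M)
  if (beta < 0 || beta > (5 - M) / 6) return(NULL)
  f <- function(x) junction_point_beta(M, x) - beta
  C <- if (f(0) == 0) 0 else if (f(1) == 0) 1 else
    uniroot(f, c(0, 1), tol = 1e-13)$root
  R <- if (C > 0 && C < 1) tangential_R(M, C, beta) else NA_real_
  g <- if (C > 0 && C < 1) tangential_alpha(M, C, beta) else 1
  if (abs(g - 1) > 1e-9)
    stop("junction point identity G_M(C, beta) = 1 violated: G = ", g)
  structure(list(M = M, C_junction = C, beta = beta, R_junction = R),
            class = "junction_point")
}

#' Regime map over the (alpha, R) plane
#'
#' Classifies every cell of an `alpha` x `R` grid (with `r` fixed at 1; other
#' values of `r` rescale time without moving equilibria) into the model's
#' regime taxonomy, reproducing the bifurcation-diagram structure of the
#' full model: Weak Allee, Hyper-Allee, Strong Allee and Extinction
#' regions bounded by the Tangential Manifold and the Junction Point.
#'
#' @param M Threshold density in `0..5`.
#' @param beta High-density death ratio in `[0, 1]`.
#' @param alpha_grid Increasing vector of `alpha` values in `[0, 1]`.
#' @param R_grid Increasing vector of `R` values (`>= 0`).
#' @return A data frame of class `bsm_regime_map` with columns `alpha`,
#'   `R`, `label`, one row per grid cell.
#' @examples
#' regime_map(4, 0.06, seq(0.9, 1, length.out = 5), seq(0.1, 1, length.out = 5))
#' @export
regime_map <- function(M, beta, alpha_grid = seq(0, 1, length.out = 201),
                       R_grid = seq(0, 3, length.out = 201)) {
  grid <- expand.grid(alpha = alpha_grid, R = R_grid)
  grid$label <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch(
      classify_regime(bsm_params(1, grid$R[i], grid$alpha[i], beta, M)),
      error = function(e) NA_character_)
  }, character(1))
  structure(grid, M = M, beta = beta,
            class = c("bsm_regime_map", "data.frame"))
}
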