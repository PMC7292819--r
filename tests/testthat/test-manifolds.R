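# Residual helpers: the Case 1/2 reduced laws S and T are the per-capita
# rate with (r = 0, R = 1) and (r = 1, R = 0) respectively.
case1_S <- function(C, beta, M)
  per_capita_rate(C, bsm_params(0, 1, 0, beta, M))
case2_T <- function(C, alpha, M)
  per_capita_rate(C, bsm_params(1, 0, alpha, 0, M))

test_that("Case 1 closed forms satisfy their defining equation", {
  C1 <- seq(0.002, 1, length.out = 500)
  for (M in 0:4) {
    beta <- case1_beta(M, C1)
    expect_lt(max(abs(mapply(case1_S, C1, beta, MoreArgs = list(M = M)))), 1e-10)
    expect_true(all(diff(beta) < 0))  # one-to-one on (0, 1]
  }
  expect_error(case1_beta(5, 0.5), "M = 5")
})

test_that("Case 1 handpicked values and limits are right", {
  expect_equal(case1_beta(4, 0.8), 0.1)
  expect_equal(case1_beta(0, 1), 0)
  expect_equal(case1_beta(2, 1e-9), 1/2, tolerance = 1e-6)
  # limiting beta at C1 -> 0+ equals (5 - M)/6 for every M
  for (M in 0:4)
    expect_equal(case1_beta(M, 1e-10), (5 - M) / 6, tolerance = 1e-8)
})

test_that("Case 1 inversion returns the equilibrium exactly when it exists", {
  expect_equal(case1_equilibrium(4, 0.1), 0.8, tolerance = 1e-9)
  expect_true(is.na(case1_equilibrium(4, 1/6)))
  expect_true(is.na(case1_equilibrium(5, 0.01)))
  set.seed(5)
  for (i in 1:40) {
    M <- sample(0:4, 1)
    b <- runif(1) * (5 - M) / 6 * 0.999
    C1 <- case1_equilibrium(M, b)
    expect_equal(case1_beta(M, C1), b, tolerance = 1e-9)
  }
})

test_that("Case 2 closed forms satisfy their defining equation", {
  C1 <- seq(0.002, 0.998, length.out = 500)
  for (M in 1:5) {
    alpha <- case2_alpha(M, C1)
    expect_lt(max(abs(mapply(case2_T, C1, alpha, MoreArgs = list(M = M)))), 1e-10)
    expect_true(all(diff(alpha) < 0))  # one-to-one on (0, 1)
  }
  expect_error(case2_alpha(0, 0.5), "M = 0")
})

test_that("Case 2 handpicked values and limits are right", {
  expect_equal(case2_alpha(5, 1 - 1e-10), 1/6, tolerance = 1e-8)
  expect_equal(case2_alpha(1, 1e-10), 1, tolerance = 1e-8)
  expect_equal(case2_alpha(1, 1 - 1e-10), 5/6, tolerance = 1e-8)
  # limiting alpha at C1 -> 1- equals (6 - M)/6 for every M
  for (M in 1:5)
    expect_equal(case2_alpha(M, 1 - 1e-10), (6 - M) / 6, tolerance = 1e-8)
})

test_that("tangential closed forms match the independent linear-system solve", {
  for (M in 1:4) {
    for (ch in seq(0.05, 0.95, length.out = 10)) {
      for (bfrac in c(0, 0.3, 0.7)) {
        beta <- bfrac * (5 - M) / 6 * 0.999
        tp <- tangential_point(M, ch, beta)  # internally the linear solve
        expect_lt(abs(tp$R - tangential_R(M, ch, beta)),
                  1e-9 * max(1, abs(tp$R)))
        expect_lt(abs(tp$alpha - tangential_alpha(M, ch, beta)),
                  1e-9 * max(1, abs(tp$alpha)))
      }
    }
  }
  expect_error(tangential_point(0, 0.5, 0.1), "M in")
  expect_error(tangential_point(5, 0.5, 0.1), "M in")
})

test_that("tangential points are genuine double roots of the growth law", {
  set.seed(13)
  for (i in 1:25) {
    M <- sample(1:4, 1)
    beta <- runif(1) * (5 - M) / 6 * 0.95
    ch <- runif(1, 0.05, 0.95)
    tp <- tangential_point(M, ch, beta)
    if (tp$R < 0 || tp$alpha < 0 || tp$alpha > 1) next  # outside model ranges
    p <- bsm_params(1, tp$R, tp$alpha, beta, M)
    pc <- per_capita_rate(c(ch - 1e-6, ch, ch + 1e-6), p)
    expect_lt(abs(pc[2]), 1e-9)
    expect_lt(abs((pc[3] - pc[1]) / 2e-6), 1e-3)  # flat tangency
  }
})

test_that("Triple Point: closed form, defining residual and limits", {
  # H_1(C) = 2(1 - C)/3: C = 0.25 maps to beta = 0.5
  expect_equal(triple_point_beta(1, 0.25), 0.5)
  for (M in 1:4) {
    expect_equal(triple_point(M, 0)$C_triple, 1)
    expect_equal(triple_point(M, (5 - M) / 6)$C_triple, 0)
    # defining residual: the second density derivative of the per-capita
    # law vanishes on the manifold at the Triple Point (exact polynomial
    # differentiation of the expanded growth law divided by C)
    for (b in c(0.2, 0.5, 0.8) * (5 - M) / 6) {
      ct <- triple_point(M, b)$C_triple
      p <- bsm_params(1, tangential_R(M, ct, b), tangential_alpha(M, ct, b),
                      b, M, strict = FALSE)
      pc <- polynomial_coefficients(p)[-1]  # per-capita coefficients
      k <- seq_along(pc) - 1
      d2 <- sum(pc[k >= 2] * k[k >= 2] * (k[k >= 2] - 1) * ct^(k[k >= 2] - 2))
      expect_lt(abs(d2), 1e-8)
    }
  }
  expect_null(triple_point(2, 0.6))  # beta out of range
})

test_that("Junction Point: closed form and the G = 1 identity", {
  expect_equal(junction_point_beta(4, 1), 0)
  expect_equal(junction_point_beta(4, 0), 1/6)
  for (M in 1:4) {
    for (b in c(0.15, 0.45, 0.8) * (5 - M) / 6) {
      jp <- junction_point(M, b)
      expect_equal(tangential_alpha(M, jp$C_junction, b), 1, tolerance = 1e-9)
      expect_equal(tangential_R(M, jp$C_junction, b), jp$R_junction)
    }
    # collapse at beta = (5 - M)/6: Triple and Junction Points coincide at 0
    expect_equal(junction_point(M, (5 - M) / 6)$C_junction, 0)
  }
})

test_that("the Negative Tangential Manifold is empty at beta = 0", {
  # Triple Point at beta = 0 is 1, so no double root can exceed it
  for (M in 1:4) {
    expect_equal(triple_point(M, 0)$C_triple, 1)
    expect_equal(tangential_point(M, 0.5, 0)$branch, "positive")
    expect_equal(tangential_point(M, 0.99, 0)$branch, "positive")
  }
})

test_that("branch labels agree with the semi-stable equilibrium position", {
  # positive branch: {U, SS, S}; negative branch: {U, S, SS}
  ct <- triple_point(4, 0.06)$C_triple
  jc <- junction_point(4, 0.06)$C_junction
  pos <- tangential_point(4, 0.6 * ct, 0.06)
  expect_equal(pos$branch, "positive")
  eqp <- find_equilibria(bsm_params(1, pos$R, pos$alpha, 0.06, 4))
  expect_equal(eqp$stability, c("unstable", "semi-stable", "stable"))
  neg <- tangential_point(4, (ct + jc) / 2, 0.06)
  expect_equal(neg$branch, "negative")
  eqn <- find_equilibria(bsm_params(1, neg$R, neg$alpha, 0.06, 4))
  expect_equal(eqn$stability, c("unstable", "stable", "semi-stable"))
})

test_that("regime maps have the structure the bifurcation analysis dictates", {
  # M = 0: no Tangential Manifold, so only Weak Allee and Extinction
  # appear. At alpha = 1 the low-density block vanishes identically and
  # the law reduces to the r = 0 case, whose regime is set by beta alone:
  # Weak Allee for beta < 5/6, Extinction for beta >= 5/6.
  map0 <- regime_map(0, 0.3, seq(0, 1, length.out = 9),
                     seq(0.2, 3, length.out = 7))
  expect_true(all(map0$label == "WeakAllee"))
  map0b <- regime_map(0, 0.9, seq(0, 1, length.out = 9),
                      seq(0.2, 3, length.out = 7))
  expect_true(all(map0b$label[map0b$alpha < 1] == "WeakAllee"))
  expect_true(all(map0b$label[map0b$alpha == 1] == "Extinction"))

  # M = 4 with beta >= 1/6: no Hyper-Allee or Strong Allee cells anywhere
  map_hi <- regime_map(4, 1/6, seq(0.5, 1, length.out = 9),
                       seq(0.2, 25, length.out = 9))
  expect_false(any(map_hi$label %in%
                     c("HyperAllee", "StrongAllee", "JunctionPoint")))

  # M = 4, beta = 0.06: Hyper-Allee region nonempty, bounded by the
  # Tangential Manifold: crossing the positive branch in R flips the label
  map_h <- regime_map(4, 0.06, seq(0.55, 0.75, length.out = 9),
                      seq(10, 25, length.out = 9))
  expect_gt(sum(map_h$label == "HyperAllee"), 0)
  for (ch in c(0.35, 0.45)) {
    tp <- tangential_point(4, ch, 0.06)
    inside <- classify_regime(bsm_params(1, tp$R * 0.97, tp$alpha, 0.06, 4))
    outside <- classify_regime(bsm_params(1, tp$R * 1.03, tp$alpha, 0.06, 4))
    expect_equal(inside, "HyperAllee", ignore_attr = TRUE)
    expect_equal(outside, "WeakAllee", ignore_attr = TRUE)
  }
})
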