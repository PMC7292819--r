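test_that("logistic collapse yields the textbook equilibrium pair", {
  eq <- find_equilibria(bsm_params(1, 1, 0.2, 0.2, 3))
  expect_equal(eq$value, c(0, 0.8), tolerance = 1e-9)
  expect_equal(eq$stability, c("unstable", "stable"))
})

test_that("Case 1 examples: high-density-only turnover", {
  # beta = 0.1, M = 4: (1 - C)/(6 - 5C) = 0.1 inverts to C = 0.8
  eq <- find_equilibria(bsm_params(0, 1, 0, 0.1, 4))
  expect_equal(eq$value[nrow(eq)], 0.8, tolerance = 1e-9)
  expect_equal(eq$stability, c("unstable", "stable"))
  # M = 5 or beta >= (5 - M)/6: only the zero equilibrium, stable
  eq2 <- find_equilibria(bsm_params(0, 1, 0, 0.5, 5))
  expect_equal(nrow(eq2), 1)
  expect_equal(eq2$stability, "stable")
})

test_that("stability labels follow the sign of the leading derivative", {
  # dC/dt = C - C^2: simple roots, slope -1 at C = 1 (but 1 is a boundary)
  poly <- c(0, 1, -1, 0)
  expect_equal(stability_of_root(poly, 0, 1, boundary = "lower"), "unstable")
  expect_equal(stability_of_root(poly, 1, 1, boundary = "upper"), "stable")
  # interior double root of -(C - 0.5)^2 = -C^2 + C - 0.25: semi-stable
  expect_equal(stability_of_root(c(-0.25, 1, -1), 0.5, 2), "semi-stable")
  # interior triple root with negative third derivative: stable
  # p(x) = -(x - 0.5)^3
  p3 <- c(0.125, -0.75, 1.5, -1)
  expect_equal(stability_of_root(p3, 0.5, 3), "stable")
  expect_equal(stability_of_root(-p3, 0.5, 3), "unstable")
  expect_error(stability_of_root(c(0, 0, 0, 1), 0, 4), "degenerate")
})

test_that("polynomial roots agree with a dense bisection scan of the growth rate", {
  set.seed(57)
  n_sets <- 2000
  for (p in random_params(n_sets)) {
    found <- find_equilibria(p)
    simple <- found$value[found$value > 1e-9 & found$multiplicity == 1]
    scanned <- scan_equilibria(p)
    # random parameters give simple roots almost surely: counts must match
    expect_equal(length(simple), length(scanned))
    if (length(simple))
      expect_lt(max(abs(sort(simple) - sort(scanned))), 1e-7)
  }
})

test_that("no parameter set produces more than three equilibria in (0, 1]", {
  set.seed(91)
  for (p in random_params(500, r_max = 3, R_max = 3))
    expect_lte(nrow(find_equilibria(p)) - 1, 3)
})

test_that("Case 1 structure: one stable interior equilibrium iff beta < (5-M)/6", {
  for (M in 0:4) {
    bmax <- (5 - M) / 6
    for (b in seq(0.05, 0.95, by = 0.15) * bmax) {
      eq <- find_equilibria(bsm_params(0, 1, 0, b, M))
      int <- eq[eq$value > 1e-9, ]
      expect_equal(nrow(int), 1)
      expect_equal(int$stability, "stable")
      expect_equal(int$value, case1_equilibrium(M, b), tolerance = 1e-9)
    }
    for (b in c(bmax, min(1, bmax + 0.05))) {
      eq <- find_equilibria(bsm_params(0, 1, 0, b, M))
      expect_equal(nrow(eq), 1)  # extinction: zero only
      expect_equal(eq$stability[1], "stable")
    }
  }
})

test_that("Case 2 structure: Reverse Allee signature for alpha in ((6-M)/6, 1)", {
  for (M in 1:5) {
    amin <- (6 - M) / 6
    for (a in amin + c(0.25, 0.6) * (1 - amin)) {
      eq <- find_equilibria(bsm_params(1, 0, a, 0, M))
      expect_equal(eq$stability, c("unstable", "stable", "unstable"))
      expect_equal(eq$value[3], 1)
      expect_equal(eq$value[2], case2_equilibrium(M, a), tolerance = 1e-9)
      expect_equal(classify_regime(bsm_params(1, 0, a, 0, M)), "ReverseAllee",
                   ignore_attr = TRUE)
    }
  }
})

test_that("maximal death at both densities forces extinction", {
  p <- bsm_params(1, 1, 1, 1, 3)
  grid <- seq(0, 1, length.out = 201)
  expect_true(all(growth_rate(grid, p) <= 0))
  expect_equal(classify_regime(p), "Extinction", ignore_attr = TRUE)
})

test_that("regime classification reproduces the full taxonomy", {
  expect_equal(classify_regime(bsm_params(1, 1, 0.3, 0.3, 2)), "Logistic",
               ignore_attr = TRUE)
  expect_equal(classify_regime(bsm_params(1, 1, 1, 1, 0)), "Extinction",
               ignore_attr = TRUE)
  # Case 1 Weak Allee / Extinction split
  expect_equal(classify_regime(bsm_params(0, 1, 0, 0.1, 4)), "WeakAllee",
               ignore_attr = TRUE)
  expect_equal(classify_regime(bsm_params(0, 1, 0, 0.4, 4)), "Extinction",
               ignore_attr = TRUE)
  # Case 2 Reverse Allee
  expect_equal(classify_regime(bsm_params(1, 0, 0.5, 0, 5)), "ReverseAllee",
               ignore_attr = TRUE)

  # Case 3 at M = 4, beta = 0.06: Extinction / Strong Allee split at the
  # Junction Point R, Hyper-Allee inside the Tangential Manifold wedge
  jp <- junction_point(4, 0.06)
  expect_equal(classify_regime(bsm_params(1, 0.7 * jp$R_junction, 1, 0.06, 4)),
               "Extinction", ignore_attr = TRUE)
  strong <- classify_regime(bsm_params(1, 1.3 * jp$R_junction, 1, 0.06, 4))
  expect_equal(strong, "StrongAllee", ignore_attr = TRUE)
  expect_equal(attr(strong, "equilibria")$stability,
               c("stable", "unstable", "stable"))
  expect_equal(classify_regime(bsm_params(1, jp$R_junction, 1, 0.06, 4)),
               "JunctionPoint", ignore_attr = TRUE)

  pos <- tangential_point(4, 0.4, 0.06)
  lab <- classify_regime(bsm_params(1, pos$R, pos$alpha, 0.06, 4))
  expect_equal(lab, "PositiveTangentialManifold", ignore_attr = TRUE)
  expect_equal(attr(lab, "equilibria")$stability,
               c("unstable", "semi-stable", "stable"))
  neg <- tangential_point(4, 0.82, 0.06)
  lab2 <- classify_regime(bsm_params(1, neg$R, neg$alpha, 0.06, 4))
  expect_equal(lab2, "NegativeTangentialManifold", ignore_attr = TRUE)
  expect_equal(attr(lab2, "equilibria")$stability,
               c("unstable", "stable", "semi-stable"))

  hyper <- classify_regime(bsm_params(1, 0.95 * pos$R, pos$alpha, 0.06, 4))
  expect_equal(hyper, "HyperAllee", ignore_attr = TRUE)
  expect_equal(attr(hyper, "equilibria")$stability,
               c("unstable", "stable", "unstable", "stable"))

  tp <- triple_point(4, 0.06)
  lab3 <- classify_regime(bsm_params(1, tangential_R(4, tp$C_triple, 0.06),
                                     tangential_alpha(4, tp$C_triple, 0.06),
                                     0.06, 4))
  expect_equal(lab3, "TriplePoint", ignore_attr = TRUE)
  expect_equal(attr(lab3, "equilibria")$multiplicity[2], 3)
})

test_that("the all-zero model is rejected as degenerate", {
  expect_error(find_equilibria(bsm_params(0, 0, 0.5, 0.5, 2)), "degenerate")
})
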