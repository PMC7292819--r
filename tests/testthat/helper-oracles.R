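# Independent oracles used across the test files. These deliberately
# re-derive quantities by different routes than the package code.

# Random parameter sets covering the full model ranges.
random_params <- function(n, r_max = 2, R_max = 2) {
  lapply(seq_len(n), function(i)
    bsm_params(runif(1, 0, r_max), runif(1, 0, R_max),
               runif(1), runif(1), sample(0:5, 1)))
}

# Event-based per-capita rate: expected per-capita birth minus death for a
# well-mixed population, summing directly over the neighbour-count
# distribution Binomial(6, C). A proliferation attempt succeeds with
# probability (6 - n)/6 (the chance the chosen neighbour site is empty).
# Algebraically equal to the continuum law, derived independently of it.
event_rate_oracle <- function(C, rates) {
  out <- 0
  for (n in 0:6) {
    w <- choose(6, n) * C^n * (1 - C)^(6 - n)
    if (n <= 5) out <- out + rates$p[n + 1] * w * (6 - n) / 6
    out <- out - rates$d[n + 1] * w
  }
  out
}

# Dense sign-change scan + bisection: locate all simple equilibria of the
# growth rate in (0, 1] without polynomial machinery.
scan_equilibria <- function(params, n_grid = 2001) {
  grid <- seq(0, 1, length.out = n_grid)
  grid[1] <- 1e-12  # so roots below the first grid step still flip the sign
  g <- growth_rate(grid, params)
  roots <- numeric(0)
  sgn <- sign(g)
  for (i in seq_len(n_grid - 1)) {
    if (sgn[i] != 0 && sgn[i + 1] != 0 && sgn[i] != sgn[i + 1]) {
      r <- uniroot(function(x) growth_rate(x, params),
                   c(grid[i], grid[i + 1]), tol = 1e-12)$root
      roots <- c(roots, r)
    } else if (sgn[i + 1] == 0 && i + 1 == n_grid) {
      roots <- c(roots, 1)
    }
  }
  roots[roots > 1e-9]
}

# Ground truth for the calibration recovery experiments: the reference
# M = 1 parameter estimates for the U87 glioblastoma curves.
recovery_truth <- function() {
  bsm_theta(1, 0.0168, 0.0345, 0.0608, 0.0692, c(0.0192, 0.0652, 0.188))
}
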