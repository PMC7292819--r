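#' Configuration for the lattice simulator
#'
#' Bundles everything one stochastic realisation of the hexagonal-lattice
#' exclusion process needs: the neighbour-dependent proliferation/death
#' rates, the motility rate, lattice dimensions, initial density, seed and
#' recording grid. Movement keeps the population well mixed, which is the
#' regime in which the ensemble mean tracks the continuum law; the default
#' motility is set two orders of magnitude above the fastest
#' proliferation/death rate, which keeps residual spatial correlation on a
#' 100 x 100 lattice below about 0.01 in density.
#'
#' @param rates A [neighbour_rates()] object (e.g. from [switch_rates()]).
#' @param motility Movement attempt rate `m >= 0` per individual. Default:
#'   one hundred times the largest proliferation/death rate.
#' @param rows,cols Lattice dimensions (each at least 4).
#' @param initial_density Probability that a site starts occupied.
#' @param seed Integer RNG seed.
#' @param record_times Increasing vector of times at which the density is
#'   recorded (first entry is the initial time).
#' @return An object of class `abm_config`.
#' @examples
#' abm_config(switch_rates(bsm_params(1, 0.5, 0.2, 0.1, M = 2)),
#'            rows = 20, cols = 20, initial_density = 0.1,
#'            record_times = seq(0, 5, 0.5))
#' @export
abm_config <- function(rates, motility = NULL, rows = 100, cols = 100,
                       initial_density = 0.1, seed = 1,
                       record_times = seq(0, 10, by = 0.25)) {
  if (!inherits(rates, "bsm_rates"))
    stop("'rates' must be a 'bsm_rates' object")
  if (is.null(motility))
    motility <- 100 * max(rates$p, rates$d, 0.01)
  if (motility < 0) stop("'motility' must be non-negative")
  if (rows < 4 || cols < 4)
    stop("lattice must be at least 4 x 4 (periodic neighbourhoods overlap otherwise)")
  if (initial_density < 0 || initial_density > 1)
    stop("'initial_density' must lie in [0, 1]")
  if (length(record_times) < 1 || any(diff(record_times) <= 0))
    stop("'record_times' must be strictly increasing")
  structure(list(rates = rates, motility = motility,
                 rows = as.integer(rows), cols = as.integer(cols),
                 initial_density = initial_density, seed = as.integer(seed),
                 record_times = as.numeric(record_times)),
            class = "abm_config")
}

#' Random initial lattice occupancy
#'
#' Each site of the `rows` x `cols` lattice is occupied independently with
#' probability `initial_density`, under the configuration seed.
#'
#' @param config An [abm_config()] object.
#' @return Integer 0/1 matrix of dimensions `rows` x `cols`.
#' @export
init_lattice <- function(config) {
  stopifnot(inherits(config, "abm_config"))
  set.seed(config$seed)
  matrix(rbinom(config$rows * config$cols, 1, config$initial_density),
         nrow = config$rows, ncol = config$cols)
}

#' Occupied-neighbour counts on the hexagonal lattice
#'
#' Counts, for every site, how many of its six axial neighbours
#' (offsets (1,0), (-1,0), (0,1), (0,-1), (1,-1), (-1,1), periodic wrap)
#' are occupied. Implemented with matrix shifts in R, independently of the
#' simulator's incremental bookkeeping, so the two can be tested against
#' each other.
#'
#' @param occ Integer 0/1 occupancy matrix.
#' @return Integer matrix of neighbour counts in `0..6`.
#' @export
neighbour_count <- function(occ) {
  shift <- function(mat, di, dj) {
    n <- nrow(mat); m <- ncol(mat)
    mat[(seq_len(n) - 1 + di) %% n + 1, (seq_len(m) - 1 + dj) %% m + 1,
        drop = FALSE]
  }
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  out <- matrix(0L, nrow(occ), ncol(occ))
  for (o in offs) out <- out + shift(occ, o[1], o[2])
  out
}

#' Simulate one realisation of the lattice exclusion process
#'
#' Runs an exact (Gillespie) stochastic simulation of the birth-death-
#' movement exclusion process on the periodic hexagonal lattice. Each
#' occupied site with `n` occupied neighbours dies at rate `d[n]`,
#' attempts to place a daughter on a uniformly chosen neighbour site at
#' rate `p[n]` (aborted if occupied), and attempts a move in the same way
#' at rate `motility`. `n` is re-evaluated at event execution time.
#'
#' @param config An [abm_config()] object.
#' @param occ0 Optional initial occupancy matrix; defaults to
#'   [init_lattice()] under the configuration seed.
#' @return A data frame of class `bsm_trajectory` with columns `t` and
#'   `density`.
#' @examples
#' cfg <- abm_config(switch_rates(bsm_params(1, 0.5, 0.2, 0.1, M = 2)),
#'                   rows = 20, cols = 20, initial_density = 0.1,
#'                   record_times = seq(0, 2, 0.5), seed = 7)
#' simulate_abm(cfg)
#' @export
simulate_abm <- function(config, occ0 = NULL) {
  stopifnot(inherits(config, "abm_config"))
  if (is.null(occ0)) occ0 <- init_lattice(config) else set.seed(config$seed)
  rt <- config$record_times
  dens <- hex_gillespie(occ0, config$rates$p, config$rates$d,
                        config$motility, rt - rt[1])
  structure(data.frame(t = rt, density = dens),
            config = config,
            class = c("bsm_trajectory", "data.frame"))
}

#' Ensemble mean and spread of lattice simulations
#'
#' Runs `replicates` independently seeded realisations of the same
#' configuration (seeds `config$seed + 0:(replicates-1)`) and returns the
#' pointwise mean and standard deviation of the density.
#'
#' @param config An [abm_config()] object.
#' @param replicates Number of independent realisations (`>= 1`).
#' @return A data frame with columns `t`, `mean`, `sd`, plus attribute
#'   `"replicates"` holding the per-replicate density matrix (time by
#'   replicate).
#' @export
ensemble_density <- function(config, replicates = 20) {
  stopifnot(inherits(config, "abm_config"), replicates >= 1)
  mat <- vapply(seq_len(replicates) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    simulate_abm(cfg)$density
  }, numeric(length(config$record_times)))
  mat <- matrix(mat, nrow = length(config$record_times))
  sds <- if (replicates > 1) apply(mat, 1, sd) else rep(0, nrow(mat))
  structure(data.frame(t = config$record_times,
                       mean = rowMeans(mat),
                       sd = sds),
            replicates = mat,
            class = c("bsm_ensemble", "data.frame"))
}
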