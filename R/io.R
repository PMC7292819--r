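#' Read and write package file formats
#'
#' The package's on-disk formats are deliberately minimal and lossless:
#' \itemize{
#'   \item parameter sets: JSON objects `{r, R, alpha, beta, M}`;
#'   \item trajectories: CSV with header `t,density`;
#'   \item growth datasets: CSV with header `t,density,dataset`.
#' }
#' Numbers are serialized with 17 significant digits so a write--read
#' round trip is bit-stable.
#'
#' @param path File path.
#' @param params A [bsm_params()] object.
#' @param trajectory A data frame with columns `t` and `density`.
#' @param datasets A list of [growth_dataset()] objects.
#' @name bsm_io
NULL

#' @rdname bsm_io
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  obj <- jsonlite::fromJSON(path)
  need <- c("r", "R", "alpha", "beta", "M")
  if (!all(need %in% names(obj)))
    stop("parameter JSON must contain fields ", paste(need, collapse = ", "))
  bsm_params(obj$r, obj$R, obj$alpha, obj$beta, obj$M)
}

#' @rdname bsm_io
#' @export
write_params_json <- function(params, path) {
  assert_params(params)
  jsonlite::write_json(params[c("r", "R", "alpha", "beta", "M")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname bsm_io
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(t = format(trajectory$t, digits = 17, trim = TRUE),
                   density = format(trajectory$density, digits = 17,
                                    trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname bsm_io
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  df <- read.csv(path)
  if (!all(c("t", "density") %in% names(df)))
    stop("trajectory CSV must have columns 't' and 'density'")
  df
}

#' @rdname bsm_io
#' @export
write_growth_csv <- function(datasets, path) {
  rows <- do.call(rbind, lapply(datasets, function(d)
    data.frame(t = format(d$t, digits = 17, trim = TRUE),
               density = format(d$density, digits = 17, trim = TRUE),
               dataset = d$label)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname bsm_io
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) stop("growth data file not found: ", path)
  df <- read.csv(path)
  if (!all(c("t", "density", "dataset") %in% names(df)))
    stop("growth CSV must have columns 't', 'density', 'dataset'")
  bad <- which(!is.finite(df$t) | !is.finite(df$density))
  if (length(bad))
    stop("unparseable rows (1-based, excluding header): ",
         paste(bad, collapse = ", "))
  if (nrow(df) == 0) stop("growth CSV contains no data rows")
  lapply(split(df, df$dataset), function(g)
    growth_dataset(g$dataset[1], g$t, g$density))
}
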