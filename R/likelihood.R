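#' Interim trial data
#'
#' The accumulating history of a trial: an ordered sequence of treated dose
#' combinations and binary toxicity outcomes.
#'
#' @param doses An n x 2 matrix (or data.frame) of level indices (j, k), one
#'   row per patient in enrollment order. May be empty (0 rows).
#' @param outcomes Binary vector of toxicity indicators, same length.
#' @param grid A [dose_grid()]; every dose must lie on it.
#' @return An `interim_data` object with fields `j`, `k`, `y`, `n`.
#' @export
interim_data <- function(doses, outcomes, grid) {
  doses <- as.matrix(doses)
  if (length(outcomes) == 0) doses <- matrix(integer(0), 0, 2)
  if (nrow(doses) != length(outcomes))
    stop("`doses` and `outcomes` must have the same length")
  if (length(outcomes) > 0) {
    if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1")
    ok <- doses[, 1] >= 1 & doses[, 1] <= grid$J &
      doses[, 2] >= 1 & doses[, 2] <= grid$K
    if (!all(ok)) stop("some doses are not on the grid")
  }
  structure(list(j = as.integer(doses[, 1]), k = as.integer(doses[, 2]),
                 y = as.integer(outcomes), n = length(outcomes)),
            class = "interim_data")
}

#' @export
print.interim_data <- function(x, ...) {
  cat(sprintf("interim_data: %d patients, %d toxicities\n", x$n, sum(x$y)))
  invisible(x)
}

# per-dose tallies: number treated and number with toxicity, as length-(J*K)
# vectors in dose_index() order
data_tallies <- function(data, grid) {
  D <- grid$J * grid$K
  n_d <- numeric(D); y_d <- numeric(D)
  if (data$n > 0) {
    idx <- dose_index(grid, data$j, data$k)
    n_d <- tabulate(idx, nbins = D)
    y_d <- as.numeric(tapply(data$y, factor(idx, levels = seq_len(D)), sum,
                             default = 0))
  }
  list(n = n_d, y = y_d)
}

#' Bernoulli log-likelihood of interim data under a model
#'
#' `sum_i [ y_i log F_{X_i}(theta) + (1 - y_i) log(1 - F_{X_i}(theta)) ]`;
#' returns 0 for empty data and -Inf only when some record's model probability
#' is exactly 0 or 1 against its observed outcome.
#'
#' @param data An [interim_data()].
#' @param spec A [model_spec()].
#' @param grid The [dose_grid()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(data, spec, grid) {
  if (data$n == 0) return(0)
  stop_if_inadmissible(spec, grid)
  f <- tox_matrix(spec, grid, check = FALSE)[cbind(data$j, data$k)]
  sum(ifelse(data$y == 1, log(f), log1p(-f)))
}
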