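#' Specify a dose-toxicity model
#'
#' Bundles a model family with a parameter vector. The parameter dimension is
#' validated against the family (for the generalized CRM it depends on the
#' number of agent-2 levels, so the grid is required at construction).
#'
#' @param family One of [model_families()].
#' @param theta Numeric parameter vector in the family's documented order.
#' @param grid A [dose_grid()] the model will be evaluated on.
#' @return An object of class `model_spec`.
#' @examples
#' g <- dose_grid(u = c(0.5, 1, 1.5), v = c(0.5, 1, 1.5))
#' m <- model_spec("logistic4", theta = c(-1, 0.5, 0.5, 0.1), grid = g)
#' tox_prob(m, g, 3, 3)
#' @export
model_spec <- function(family, theta, grid) {
  info <- check_family_grid(family, grid)
  p <- info$dim(grid)
  theta <- as.numeric(theta)
  if (length(theta) != p)
    stop(sprintf("family '%s' on this grid needs %d parameters, got %d",
                 family, p, length(theta)))
  structure(list(family = family, theta = theta,
                 theta_names = info$theta_names(grid)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %s\n", x$family))
  print(stats::setNames(signif(x$theta, 5), x$theta_names))
  invisible(x)
}

#' Check the partial-order parameter constraints of a model
#'
#' Evaluates the family's admissibility predicate on the attached grid. All
#' printed strict inequalities are enforced strictly, with a numerical margin
#' of 1e-10; parameter vectors on the boundary are inadmissible.
#'
#' @inheritParams tox_prob
#' @return A list with `admissible` (logical) and `violated` (character vector
#'   naming each violated inequality; empty when admissible).
#' @export
check_constraints <- function(spec, grid) {
  info <- check_family_grid(spec$family, grid)
  ok <- info$constraints(spec$theta, grid)
  list(admissible = all(ok), violated = names(ok)[!ok])
}

stop_if_inadmissible <- function(spec, grid) {
  chk <- check_constraints(spec, grid)
  if (!chk$admissible)
    stop(sprintf("inadmissible theta for family '%s'; violated: %s",
                 spec$family, paste(chk$violated, collapse = "; ")),
         call. = FALSE)
  invisible(chk)
}

#' Toxicity probability of one dose combination
#'
#' Evaluates the model surface F(u_j, v_k, theta) at grid cell (j, k).
#'
#' @param spec A [model_spec()].
#' @param grid A [dose_grid()].
#' @param j,k Level indices of agent 1 and agent 2.
#' @param check Validate admissibility of `theta` first (default TRUE).
#' @return Toxicity probability in \[0, 1\].
#' @export
tox_prob <- function(spec, grid, j, k, check = TRUE) {
  info <- check_family_grid(spec$family, grid)
  if (check) stop_if_inadmissible(spec, grid)
  if (!is_on_grid(grid, j, k)) stop("dose level (j, k) is not on the grid")
  as.numeric(info$eval(matrix(spec$theta, nrow = 1), grid, j, k))
}

#' Toxicity probability matrix
#'
#' The full J x K matrix of model toxicity probabilities. For an admissible
#' parameter vector the matrix respects the partial order (increasing along
#' rows and columns; the change-point family is constant on its plateau).
#'
#' @inheritParams tox_prob
#' @return A J x K numeric matrix.
#' @export
tox_matrix <- function(spec, grid, check = TRUE) {
  info <- check_family_grid(spec$family, grid)
  if (check) stop_if_inadmissible(spec, grid)
  jj <- rep(seq_len(grid$J), times = grid$K)
  kk <- rep(seq_len(grid$K), each = grid$J)
  matrix(info$eval(matrix(spec$theta, nrow = 1), grid, jj, kk),
         nrow = grid$J, ncol = grid$K)
}

# vectorized surface over many parameter vectors: Theta is n x p,
# returns n x (J*K) with column order matching dose_index()
tox_surface <- function(family, Theta, grid) {
  info <- check_family_grid(family, grid)
  jj <- rep(seq_len(grid$J), times = grid$K)
  kk <- rep(seq_len(grid$K), each = grid$J)
  info$eval(Theta, grid, jj, kk)
}

#' Partial-order conformity of a toxicity matrix
#'
#' Verifies that a J x K probability matrix increases along every row and every
#' column. `strict = FALSE` permits ties, which arise on the plateau of the
#' change-point model.
#'
#' @param mat Numeric J x K matrix.
#' @param strict Require strict increase (default TRUE).
#' @return TRUE/FALSE.
#' @export
check_partial_order <- function(mat, strict = TRUE) {
  cmp <- if (strict) function(d) all(d > 0) else function(d) all(d >= 0)
  rows_ok <- all(apply(mat, 2, function(col) cmp(diff(col))))
  cols_ok <- all(apply(mat, 1, function(row) cmp(diff(row))))
  rows_ok && cols_ok
}

#' Gradient of the toxicity surface in the parameters
#'
#' Central-difference gradient of F(u_j, v_k, theta) with step
#' `h_t = 1e-5 * max(1, |theta_t|)` per component. For the change-point family
#' the surface has a kink where `alpha + beta*u_j + gamma*v_k = w`; on (or
#' numerically near) that surface the function returns one-sided derivatives
#' and sets the `kink` flag.
#'
#' @inheritParams tox_prob
#' @return A list with `grad` (length-p vector) and `kink` (logical).
#' @export
grad_tox <- function(spec, grid, j, k, check = TRUE) {
  info <- check_family_grid(spec$family, grid)
  if (check) stop_if_inadmissible(spec, grid)
  theta <- spec$theta
  p <- length(theta)
  h <- 1e-5 * pmax(1, abs(theta))
  f_at <- function(th)
    as.numeric(info$eval(matrix(th, nrow = 1), grid, j, k))
  kink <- FALSE
  if (spec$family == "change_point") {
    gap <- theta[1] + theta[2] * grid$u[j] + theta[3] * grid$v[k] - theta[4]
    # kink reachable within the differencing stencil
    if (abs(gap) <= max(h) * (1 + abs(grid$u[j]) + abs(grid$v[k]) + 1))
      kink <- TRUE
  }
  grad <- vapply(seq_len(p), function(t) {
    up <- theta; up[t] <- up[t] + h[t]
    dn <- theta; dn[t] <- dn[t] - h[t]
    if (kink) (f_at(up) - f_at(theta)) / h[t]     # one-sided at the kink
    else (f_at(up) - f_at(dn)) / (2 * h[t])
  }, numeric(1))
  list(grad = grad, kink = kink)
}
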