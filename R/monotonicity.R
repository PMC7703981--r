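#' Check uniform monotonicity of a model family
#'
#' A surface F(u, v, theta) is uniformly monotone when, for every dose, F is
#' monotone in each parameter component with a direction that does not depend
#' on the dose. Uniform monotonicity is the easily-checked special case of the
#' posterior-update sign condition: it implies ND coherence outright. Many
#' published models satisfy it only for particular dose codings — the logistic
#' model is uniformly monotone under positive raw dosages but not under
#' mixed-sign standardized doses.
#'
#' The checker perturbs each parameter component at seeded admissible
#' parameter vectors and compares the surface across all grid cells. It is a
#' falsifier: a single direction is certified only up to the sampled set,
#' whereas a reported non-monotonicity comes with an explicit witness (a
#' parameter pair and two grid cells on which the perturbation moves F in
#' opposite directions).
#'
#' @param family One of [model_families()].
#' @param grid A [dose_grid()].
#' @param n_thetas Admissible parameter vectors to sample.
#' @param n_perturbations Step sizes tried per component and vector.
#' @param seed Seed for sampler and steps.
#' @param prior Optional `tox_prior` for the sampler.
#' @return A list with `directions` (character vector per parameter:
#'   "nondecreasing", "nonincreasing", or "not_uniformly_monotone"),
#'   `uniformly_monotone` (all components directed), and `witnesses` (per
#'   flagged component: theta, step, and grid cells with opposite movement).
#' @export
check_uniform_monotonicity <- function(family, grid, n_thetas = 50L,
                                       n_perturbations = 4L, seed = 1L,
                                       prior = NULL) {
  stopifnot(n_thetas >= 1, n_perturbations >= 1)
  info <- check_family_grid(family, grid)
  Theta <- sample_admissible_theta(family, grid, n_thetas, seed, prior)
  p <- ncol(Theta)
  set.seed(derive_seed(seed, 1L))
  steps <- stats::runif(n_perturbations, 0.02, 0.8)
  D <- grid$J * grid$K
  any_pos <- rep(FALSE, p); any_neg <- rep(FALSE, p)
  wit_pos <- vector("list", p); wit_neg <- vector("list", p)
  tol <- 1e-12
  admissible <- function(th) all(info$constraints(th, grid))
  cells <- cbind(rep(seq_len(grid$J), grid$K),
                 rep(seq_len(grid$K), each = grid$J))
  for (i in seq_len(n_thetas)) {
    th <- Theta[i, ]
    f0 <- tox_surface(family, matrix(th, 1), grid)
    for (t in seq_len(p)) {
      for (s in steps) {
        h <- s * max(1, abs(th[t]))
        up <- th; up[t] <- up[t] + h
        if (admissible(up)) {
          dF <- tox_surface(family, matrix(up, 1), grid) - f0
        } else {
          dn <- th; dn[t] <- dn[t] - h
          if (!admissible(dn)) next
          dF <- f0 - tox_surface(family, matrix(dn, 1), grid)
        }
        pos <- which(dF > tol); neg <- which(dF < -tol)
        if (length(pos) > 0 && !any_pos[t]) {
          any_pos[t] <- TRUE
          wit_pos[[t]] <- list(theta = th, component = t, step = h,
                               cell = cells[pos[1], ])
        }
        if (length(neg) > 0 && !any_neg[t]) {
          any_neg[t] <- TRUE
          wit_neg[[t]] <- list(theta = th, component = t, step = h,
                               cell = cells[neg[1], ])
        }
      }
    }
  }
  directions <- ifelse(any_pos & any_neg, "not_uniformly_monotone",
                       ifelse(any_neg, "nonincreasing", "nondecreasing"))
  witnesses <- lapply(seq_len(p), function(t)
    if (any_pos[t] && any_neg[t]) list(increase = wit_pos[[t]],
                                       decrease = wit_neg[[t]])
    else NULL)
  names(directions) <- info$theta_names(grid)
  list(directions = directions,
       uniformly_monotone = !any(any_pos & any_neg),
       witnesses = stats::setNames(witnesses, names(directions)))
}
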