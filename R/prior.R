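# Prior specifications for the model parameters.
#
# The paper-level designs leave the prior open; the package ships a default per
# family: normal(0, 2^2) on unconstrained components, exponential(1) on
# components constrained positive (negated for the log-linear interaction,
# constrained negative), uniform(0,1) on the scaled-logistic plateau rho — all
# multiplied by the family's joint admissibility indicator.
#
# Integration (and the generalized CRM's ordered intercepts) work in a
# *transformed* coordinate system in which the prior support is a box wherever
# possible: for the generalized CRM the coordinates are (alpha_1, the positive
# increments delta_2..delta_K, beta), mapped back linearly. The four-parameter
# logistic keeps natural coordinates; its interaction component has conditional
# support handled by the integrators.

#' Prior component constructors
#'
#' Build one marginal prior component for use in a prior specification:
#' `prior_normal(mean, sd)`, `prior_exp(rate)` (support x > 0),
#' `prior_nexp(rate)` (negated exponential, support x < 0), and
#' `prior_unif(a, b)`.
#'
#' Each component carries the truncation box used by the deterministic
#' integrators; for the unbounded types the box is wide enough that the prior
#' mass outside is below 1e-8.
#'
#' @param mean,sd,rate,a,b Distribution parameters.
#' @return A `prior_component` object.
#' @name prior_components
NULL

#' @rdname prior_components
#' @export
prior_normal <- function(mean = 0, sd = 2) {
  structure(list(type = "normal", mean = mean, sd = sd,
                 box = c(mean - 6 * sd, mean + 6 * sd)),
            class = "prior_component")
}

#' @rdname prior_components
#' @export
prior_exp <- function(rate = 1) {
  structure(list(type = "exp", rate = rate, box = c(0, 20 / rate)),
            class = "prior_component")
}

#' @rdname prior_components
#' @export
prior_nexp <- function(rate = 1) {
  structure(list(type = "nexp", rate = rate, box = c(-20 / rate, 0)),
            class = "prior_component")
}

#' @rdname prior_components
#' @export
prior_unif <- function(a, b) {
  stopifnot(b > a)
  structure(list(type = "unif", a = a, b = b, box = c(a, b)),
            class = "prior_component")
}

component_logdens <- function(comp, x) {
  switch(comp$type,
    normal = stats::dnorm(x, comp$mean, comp$sd, log = TRUE),
    exp    = stats::dexp(x, comp$rate, log = TRUE),
    nexp   = stats::dexp(-x, comp$rate, log = TRUE),
    unif   = stats::dunif(x, comp$a, comp$b, log = TRUE),
    stop("unknown prior component type"))
}

component_sample <- function(comp, n) {
  switch(comp$type,
    normal = stats::rnorm(n, comp$mean, comp$sd),
    exp    = stats::rexp(n, comp$rate),
    nexp   = -stats::rexp(n, comp$rate),
    unif   = stats::runif(n, comp$a, comp$b),
    stop("unknown prior component type"))
}

#' Default prior for a model family
#'
#' @param family One of [model_families()].
#' @param grid A [dose_grid()] (the generalized CRM dimension depends on K).
#' @param components Optional list of [prior_components] overriding the
#'   defaults, in the family's (transformed-coordinate) parameter order.
#' @return A `tox_prior` object.
#' @export
default_prior <- function(family, grid, components = NULL) {
  info <- check_family_grid(family, grid)
  p <- info$dim(grid)
  comps <- switch(family,
    logistic4 = list(prior_normal(), prior_exp(), prior_exp(), prior_normal()),
    generalized_crm = c(list(prior_normal()),
                        rep(list(prior_exp()), grid$K - 1),
                        list(prior_exp())),
    scaled_logistic = list(prior_unif(0, 1), prior_normal(),
                           prior_exp(), prior_exp()),
    change_point = list(prior_normal(), prior_exp(), prior_exp(),
                        prior_normal()),
    clayton = rep(list(prior_exp()), 3),
    gumbel = rep(list(prior_exp()), 3),
    log_linear = list(prior_exp(), prior_exp(), prior_nexp()),
    six_param = rep(list(prior_exp()), 6))
  if (!is.null(components)) {
    stopifnot(length(components) == p)
    comps <- components
  }
  # transform from integration coordinates to natural parameters
  transform <- if (family == "generalized_crm") {
    K <- grid$K
    function(Zeta) {
      Theta <- Zeta
      if (K > 1)
        Theta[, seq_len(K)] <- t(apply(Zeta[, seq_len(K), drop = FALSE], 1,
                                       cumsum))
      Theta
    }
  } else identity
  structure(list(family = family, components = comps, transform = transform,
                 p = p),
            class = "tox_prior")
}

prior_boxes <- function(prior) {
  t(vapply(prior$components, function(c) c$box, numeric(2)))
}

prior_logdens <- function(prior, Zeta) {
  out <- 0
  for (d in seq_len(prior$p))
    out <- out + component_logdens(prior$components[[d]], Zeta[, d])
  out
}

#' Sample admissible parameter vectors
#'
#' Draws from the prior by rejection against the family's admissibility
#' predicate on the grid. Used by the monotonicity/condition checkers and the
#' theorem-6 probe; seeded for reproducibility.
#'
#' @param family,grid Model family and dose grid.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param prior Optional `tox_prior` (defaults to [default_prior()]).
#' @param max_tries Rejection budget.
#' @return An n x p matrix of admissible natural-coordinate parameter vectors.
#' @export
sample_admissible_theta <- function(family, grid, n, seed,
                                    prior = NULL, max_tries = 200L) {
  if (is.null(prior)) prior <- default_prior(family, grid)
  info <- check_family_grid(family, grid)
  set.seed(as.integer(seed))
  p <- prior$p
  out <- matrix(NA_real_, 0, p)
  for (i in seq_len(max_tries)) {
    m <- max(n, ceiling(1.5 * (n - nrow(out))))
    Zeta <- vapply(prior$components, component_sample, numeric(m), n = m)
    if (m == 1) Zeta <- matrix(Zeta, nrow = 1)
    Theta <- prior$transform(Zeta)
    keep <- apply(Theta, 1, function(th) all(info$constraints(th, grid)))
    out <- rbind(out, Theta[keep, , drop = FALSE])
    if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
  }
  stop("sample_admissible_theta: rejection budget exhausted; ",
       "prior puts too little mass on the admissible set")
}
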