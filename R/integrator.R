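# Reproducible posterior-mean machinery.
#
# Both integration methods evaluate the model surface once, at a fixed set of
# parameter points, when the integrator is built; every posterior update is
# then a reweighting of that fixed set. A useful consequence: the computed
# posterior mean is the *exact* posterior mean under the discrete prior
# supported on those points (with the corresponding weights), so finite-sample
# properties of exact Bayesian updating — in particular the sign condition
# driving coherence, which holds for any prior — carry over to the numerical
# estimates without stochastic error. Accuracy relative to the continuous
# prior is a separate question, assessed against the brute-force oracle.

default_nodes_per_axis <- function(p) {
  if (p <= 2) 48L else if (p == 3) 32L else if (p == 4) 20L else 12L
}

#' Build a posterior integrator
#'
#' Precomputes parameter nodes (deterministic tensor-product Gauss-Legendre
#' quadrature over the prior truncation box for moderate dimensions; seeded
#' importance draws from the prior for the six-parameter family) together with
#' the model toxicity surface at every node, so that posterior means along a
#' trial are deterministic, fast reweightings.
#'
#' For the four-parameter logistic model the admissible set is not a box (the
#' interaction parameter is constrained by `theta2 + theta4 v_k > 0` and
#' `theta3 + theta4 u_j > 0`); its quadrature maps the interaction nodes onto
#' the admissible interval computed per (theta2, theta3) node.
#'
#' @param family One of [model_families()].
#' @param grid A [dose_grid()].
#' @param prior A `tox_prior` (default [default_prior()]).
#' @param method "auto" (quadrature for p <= 5, importance otherwise),
#'   "quadrature", or "importance".
#' @param nodes_per_axis Gauss-Legendre nodes per parameter axis (default
#'   depends on dimension: 48 for p <= 2, 32 for p = 3, 20 for p = 4, 12 above).
#' @param n_draws Importance-sample size (default 20000).
#' @param seed Seed for the importance draws (ignored by quadrature).
#' @param tol Componentwise Monte-Carlo error reported threshold (estimates
#'   with larger `mc_error` are reported as such in summaries).
#' @param ess_min Effective-sample-size floor below which an importance-sample
#'   posterior is flagged unconverged (default 50). Quadrature estimates are
#'   never flagged: with a fixed node set the computed value is the exact
#'   posterior mean under the discretized prior.
#' @return An object of class `posterior_integrator`.
#' @export
make_integrator <- function(family, grid, prior = NULL,
                            method = c("auto", "quadrature", "importance"),
                            nodes_per_axis = NULL, n_draws = 20000L,
                            seed = 1L, tol = 5e-3, ess_min = 50) {
  method <- match.arg(method)
  check_family_grid(family, grid)
  if (is.null(prior)) prior <- default_prior(family, grid)
  p <- prior$p
  if (method == "auto") method <- if (p <= 5) "quadrature" else "importance"
  if (method == "quadrature") {
    if (is.null(nodes_per_axis)) nodes_per_axis <- default_nodes_per_axis(p)
    nd <- quadrature_nodes(family, grid, prior, nodes_per_axis)
  } else {
    Theta <- sample_admissible_theta(family, grid, n_draws, seed, prior)
    nd <- list(Theta = Theta, lw0 = rep(0, nrow(Theta)))
  }
  F <- tox_surface(family, nd$Theta, grid)
  obj <- list(family = family, grid = grid, prior = prior, method = method,
              Theta = nd$Theta, lw0 = nd$lw0,
              F = F,
              lF = log(pmax(F, 1e-300)),
              l1mF = log(pmax(1 - F, 1e-300)),
              S = nrow(nd$Theta), p = p, D = grid$J * grid$K,
              seed = seed, tol = tol, ess_min = ess_min)
  class(obj) <- "posterior_integrator"
  obj
}

#' @export
print.posterior_integrator <- function(x, ...) {
  cat(sprintf("posterior_integrator: %s, %s, %d nodes, p = %d\n",
              x$family, x$method, x$S, x$p))
  invisible(x)
}

# tensor Gauss-Legendre nodes over the prior box, with the logistic4
# conditional support mapping for the interaction component
quadrature_nodes <- function(family, grid, prior, n_axis) {
  p <- prior$p
  gl <- lapply(seq_len(p), function(d) {
    box <- prior$components[[d]]$box
    g <- pracma::gaussLegendre(n_axis, box[1], box[2])
    list(x = g$x, lw = log(g$w) + component_logdens(prior$components[[d]], g$x))
  })
  if (family != "logistic4") {
    idx <- do.call(expand.grid, lapply(seq_len(p), function(d) seq_len(n_axis)))
    Zeta <- vapply(seq_len(p), function(d) gl[[d]]$x[idx[[d]]],
                   numeric(nrow(idx)))
    lw0 <- Reduce(`+`, lapply(seq_len(p), function(d) gl[[d]]$lw[idx[[d]]]))
    return(list(Theta = prior$transform(Zeta), lw0 = lw0))
  }
  # logistic4: tensor over (theta1, theta2, theta3), then map reference nodes
  # onto the admissible theta4 interval for each (theta2, theta3)
  idx3 <- expand.grid(i1 = seq_len(n_axis), i2 = seq_len(n_axis),
                      i3 = seq_len(n_axis))
  z1 <- gl[[1]]$x[idx3$i1]; z2 <- gl[[2]]$x[idx3$i2]; z3 <- gl[[3]]$x[idx3$i3]
  lw3 <- gl[[1]]$lw[idx3$i1] + gl[[2]]$lw[idx3$i2] + gl[[3]]$lw[idx3$i3]
  iv <- logistic4_theta4_interval(z2, z3, grid,
                                  box = prior$components[[4]]$box)
  keep <- iv$up > iv$lo
  z1 <- z1[keep]; z2 <- z2[keep]; z3 <- z3[keep]; lw3 <- lw3[keep]
  lo <- iv$lo[keep]; up <- iv$up[keep]
  ref <- pracma::gaussLegendre(n_axis, -1, 1)
  m <- length(z1)
  ctr <- (lo + up) / 2; hw <- (up - lo) / 2
  th4 <- matrix(ctr, m, n_axis) + hw %o% ref$x
  lw4 <- log(hw %o% ref$w) +
    component_logdens(prior$components[[4]], th4)
  rep3 <- rep(seq_len(m), times = n_axis)
  Theta <- cbind(z1[rep3], z2[rep3], z3[rep3], as.vector(th4))
  list(Theta = Theta, lw0 = lw3[rep3] + as.vector(lw4))
}

# admissible theta4 interval given theta2, theta3 (vectors) and the grid:
# theta2 + theta4 v_k > 0 for all k, theta3 + theta4 u_j > 0 for all j
logistic4_theta4_interval <- function(th2, th3, grid, box) {
  lo <- rep(box[1], length(th2)); up <- rep(box[2], length(th2))
  for (v in grid$v) {
    if (v > 0) lo <- pmax(lo, -th2 / v)
    if (v < 0) up <- pmin(up, -th2 / v)
  }
  for (u in grid$u) {
    if (u > 0) lo <- pmax(lo, -th3 / u)
    if (u < 0) up <- pmin(up, -th3 / u)
  }
  list(lo = lo, up = up)
}

# log-weights after conditioning on interim data (vector over nodes)
post_logweights <- function(intg, data) {
  tl <- data_tallies(data, intg$grid)
  lw <- intg$lw0
  if (any(tl$y > 0)) lw <- lw + intg$lF %*% tl$y
  miss <- tl$n - tl$y
  if (any(miss > 0)) lw <- lw + intg$l1mF %*% miss
  as.numeric(lw)
}

post_stats <- function(intg, lw) {
  w <- exp(lw - max(lw))
  sw <- sum(w)
  theta_hat <- as.numeric(crossprod(intg$Theta, w)) / sw
  if (intg$method == "importance") {
    wn <- w / sw
    ess <- 1 / sum(wn^2)
    dev <- sweep(intg$Theta, 2, theta_hat)
    mc_error <- sqrt(colSums(wn^2 * dev^2))
  } else {
    ess <- Inf
    mc_error <- rep(0, intg$p)
  }
  list(theta_hat = theta_hat, mc_error = mc_error, ess = ess)
}

#' Posterior mean of the model parameters
#'
#' `E(theta | H_n)` under the integrator's constrained prior and the Bernoulli
#' likelihood of the interim data; the prior mean when the data are empty.
#'
#' @param data An [interim_data()] (may be empty).
#' @param integrator A [make_integrator()] object.
#' @return A `posterior_estimate`: `theta_hat`, `mc_error`, `method`, `ess`,
#'   `flagged` (TRUE when any Monte-Carlo error exceeds the integrator's
#'   tolerance), and the plug-in toxicity matrix `fhat = F(theta_hat)`.
#' @export
posterior_mean <- function(data, integrator) {
  st <- post_stats(integrator, post_logweights(integrator, data))
  fhat <- tox_matrix(
    model_spec(integrator$family, st$theta_hat, integrator$grid),
    integrator$grid, check = FALSE)
  structure(list(theta_hat = st$theta_hat, mc_error = st$mc_error,
                 method = integrator$method, seed = integrator$seed,
                 ess = st$ess,
                 flagged = st$ess < integrator$ess_min,
                 fhat = fhat),
            class = "posterior_estimate")
}

#' @export
print.posterior_estimate <- function(x, ...) {
  cat(sprintf("posterior_estimate (%s%s)\n", x$method,
              if (x$flagged) ", FLAGGED" else ""))
  cat("  theta_hat:", signif(x$theta_hat, 5), "\n")
  invisible(x)
}

#' Posterior-mean sequence along a history
#'
#' Sequential posterior means after 0, 1, ..., n patients, computed by
#' incremental reweighting of the integrator's fixed node set.
#'
#' @inheritParams posterior_mean
#' @return An (n+1) x p matrix; row i holds the posterior mean after i-1
#'   patients (row 1 is the prior mean).
#' @export
posterior_sequence <- function(data, integrator) {
  out <- matrix(NA_real_, data$n + 1, integrator$p)
  lw <- integrator$lw0
  out[1, ] <- post_stats(integrator, lw)$theta_hat
  for (i in seq_len(data$n)) {
    d <- dose_index(integrator$grid, data$j[i], data$k[i])
    lw <- lw + if (data$y[i] == 1) integrator$lF[, d] else integrator$l1mF[, d]
    out[i + 1, ] <- post_stats(integrator, lw)$theta_hat
  }
  out
}

#' Brute-force posterior-mean oracle
#'
#' Independent reference integrator used in tests: a dense midpoint (Riemann)
#' lattice over the prior support, evaluated in memory-bounded chunks and
#' normalized directly. With `extrapolate = TRUE` (the default) the lattice is
#' evaluated at `resolution` and `resolution/2` and the leading O(h^2)
#' midpoint error is removed by Richardson extrapolation of the raw integrals.
#' Exponential in the parameter dimension, so limited to p <= 4.
#'
#' @inheritParams posterior_mean
#' @param family,grid,prior Model family, dose grid, and prior.
#' @param resolution Lattice points per axis (default 32; even when
#'   extrapolating).
#' @param extrapolate Apply Richardson extrapolation (default TRUE).
#' @return Posterior-mean p-vector.
#' @export
posterior_mean_oracle <- function(data, family, grid, prior = NULL,
                                  resolution = 32L, extrapolate = TRUE) {
  if (is.null(prior)) prior <- default_prior(family, grid)
  if (prior$p > 4) stop("oracle supports p <= 4 only")
  hi <- oracle_raw_sums(data, family, grid, prior, resolution)
  if (!extrapolate)
    return(hi$I1 / hi$I0)
  lo <- oracle_raw_sums(data, family, grid, prior, resolution %/% 2L,
                        shift = hi$shift)
  as.numeric((4 * hi$I1 - lo$I1) / (4 * hi$I0 - lo$I0))
}

# midpoint-rule raw sums I0 = sum w, I1 = sum w * theta, computed in chunks
# with online rescaling; `shift` optionally fixes the log-scale offset so two
# resolutions can be combined coherently
oracle_raw_sums <- function(data, family, grid, prior, resolution,
                            shift = NULL) {
  p <- prior$p
  info <- check_family_grid(family, grid)
  boxes <- prior_boxes(prior)
  mids <- lapply(seq_len(p), function(d) {
    h <- (boxes[d, 2] - boxes[d, 1]) / resolution
    boxes[d, 1] + (seq_len(resolution) - 0.5) * h
  })
  dd <- if (data$n > 0) unique(cbind(data$j, data$k)) else NULL
  key <- paste(data$j, data$k)
  dkey <- if (!is.null(dd)) paste(dd[, 1], dd[, 2])
  fixed_shift <- !is.null(shift)
  if (!fixed_shift) shift <- -Inf
  I0 <- 0; I1 <- numeric(p)
  # chunk over the first axis to bound memory
  chunk <- max(1L, floor(3e6 / resolution^(p - 1)))
  starts <- seq(1L, resolution, by = chunk)
  rest <- do.call(expand.grid,
                  lapply(seq(2, length.out = p - 1),
                         function(d) seq_len(resolution)))
  for (s in starts) {
    i1 <- seq(s, min(s + chunk - 1L, resolution))
    idx1 <- rep(i1, each = nrow(rest))
    Zeta <- cbind(mids[[1]][idx1],
                  vapply(seq_len(p - 1),
                         function(d) mids[[d + 1]][rep(rest[[d]],
                                                       times = length(i1))],
                         numeric(nrow(rest) * length(i1))))
    lcell <- 0
    if (family == "logistic4") {
      # map the interaction lattice onto the admissible interval
      iv <- logistic4_theta4_interval(Zeta[, 2], Zeta[, 3], grid,
                                      box = prior$components[[4]]$box)
      width <- pmax(iv$up - iv$lo, 0)
      i4 <- (Zeta[, 4] - boxes[4, 1]) / (boxes[4, 2] - boxes[4, 1])  # in (0,1)
      Zeta[, 4] <- iv$lo + i4 * width
      lcell <- log(width / (boxes[4, 2] - boxes[4, 1]))  # cell-width ratio
    }
    Theta <- prior$transform(Zeta)
    lw <- prior_logdens(prior, Zeta) + lcell
    if (family != "logistic4") {
      ok <- apply(Theta, 1, function(th) all(info$constraints(th, grid)))
      lw[!ok] <- -Inf
    }
    if (data$n > 0) {
      Fsub <- info$eval(Theta, grid, dd[, 1], dd[, 2])
      if (!is.matrix(Fsub)) Fsub <- matrix(Fsub, ncol = nrow(dd))
      for (i in seq_len(data$n)) {
        f <- Fsub[, match(key[i], dkey)]
        lw <- lw + if (data$y[i] == 1) log(pmax(f, 1e-300))
                   else log(pmax(1 - f, 1e-300))
      }
    }
    m <- max(lw)
    if (!fixed_shift && m > shift) {
      resc <- exp(shift - m)
      I0 <- I0 * resc; I1 <- I1 * resc
      shift <- m
    }
    w <- exp(lw - shift)
    I0 <- I0 + sum(w)
    I1 <- I1 + as.numeric(crossprod(Theta, w))
  }
  h_prod <- prod((boxes[, 2] - boxes[, 1]) / resolution)
  list(I0 = I0 * h_prod, I1 = I1 * h_prod, shift = shift)
}
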