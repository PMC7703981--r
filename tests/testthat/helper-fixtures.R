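# Shared fixtures: one known-admissible parameter vector per family, compact
# integrators for the trial-engine tests (any fixed node set yields exact
# posterior means under the corresponding discretized prior, so coherence
# mechanics do not depend on the resolution), and a hand-rolled trace builder
# for audit unit tests.

adm_theta <- function(family, grid) {
  switch(family,
    logistic4 = c(-1, 0.8, 0.6, 0.05),
    generalized_crm = c(seq(-1.5, by = 0.6, length.out = grid$K), 0.9),
    scaled_logistic = c(0.6, -0.5, 0.9, 0.7),
    change_point = c(-0.5, 0.8, 0.7, 1.2),
    clayton = c(0.8, 1.2, 0.7),
    gumbel = c(0.8, 1.2, 0.7),
    log_linear = c(1.1, 0.9, -0.4),
    six_param = c(0.8, 0.7, 0.5, 1.2, 0.9, 1.1))
}

# small quadrature integrator cache for fast trial simulations
.intg_cache <- new.env(parent = emptyenv())
tiny_integrator <- function(family, grid = NULL, na = 8) {
  if (is.null(grid)) grid <- family_default_grid(family)
  key <- paste(family, grid$J, grid$K, na)
  if (is.null(.intg_cache[[key]]))
    .intg_cache[[key]] <- make_integrator(
      family, grid,
      method = if (family == "six_param") "importance" else "quadrature",
      nodes_per_axis = na, n_draws = 4000, seed = 99)
  .intg_cache[[key]]
}

# build a trial_trace by hand for audit unit tests: doses is n x 2, ys binary,
# nexts n x 2; fhats a list of n J x K estimate matrices (used for candidate
# sets); design "one_stage_nd" or "one_stage_d"
manual_trace <- function(grid, doses, ys, nexts, fhats, p_T = 0.3,
                         design = "one_stage_nd", family = "logistic4",
                         scenario = NULL, M = NA_integer_,
                         stage = NULL) {
  n <- length(ys)
  doses <- matrix(as.integer(doses), ncol = 2)
  nexts <- matrix(as.integer(nexts), ncol = 2)
  sets <- lapply(seq_len(n), function(i) {
    if (grepl("_d$", design))
      candidate_sets_d(doses[i, ], grid, fhats[[i]], "weak")
    else candidate_sets_nd(doses[i, ], grid)
  })
  df <- data.frame(n = seq_len(n), j = doses[, 1], k = doses[, 2],
                   y = as.integer(ys),
                   stage = if (is.null(stage)) rep("model", n) else stage,
                   next_j = nexts[, 1], next_k = nexts[, 2],
                   ess = Inf, flagged = FALSE)
  structure(list(design = design, family = family, grid = grid, p_T = p_T,
                 N = n, seed = 0L, df = df,
                 theta_hat = matrix(0, n + 1, 1),
                 fhat = c(list(fhats[[1]]), fhats), sets = sets,
                 M = M, scenario = scenario, path = NULL),
            class = "trial_trace")
}
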