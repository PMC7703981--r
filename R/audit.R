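# Transition-level coherence auditing.
#
# A design is coherent when it never escalates after an observed toxicity and
# never de-escalates after a non-toxicity. For combination trials the
# escalation/de-escalation sets are the candidate-set geometry of the design;
# for D-designs the anti-diagonal neighbors are classified by the model
# estimates (weak semantics) or the true toxicity probabilities (strong
# semantics) — the two audits can disagree only on diagonal moves under model
# misspecification.

in_set <- function(set, dose) {
  nrow(set) > 0 && any(set[, 1] == dose[1] & set[, 2] == dose[2])
}

#' Audit a trial trace for coherence
#'
#' Classifies every transition of a simulated trial: a violation is recorded
#' at patient n when the design escalated (moved into E_n) after a toxicity,
#' or de-escalated (moved into D_n) after a non-toxicity. Transitions whose
#' posterior estimate failed its Monte-Carlo error tolerance are excluded from
#' the verdict and counted separately.
#'
#' @param trace A [run_trial()] trace.
#' @param semantics "weak" (candidate sets classified by model estimates, as
#'   the design itself used) or "strong" (anti-diagonal neighbors reclassified
#'   by the true scenario). ND traces yield identical reports under both.
#' @param scenario True-probability matrix for strong semantics (defaults to
#'   the scenario stored in the trace).
#' @return A `coherence_report` with fields `semantics`, `n_transitions`,
#'   `violations` (data frame: n, type, from/to doses), `n_excluded`, `verdict`.
#' @export
audit_trace <- function(trace, semantics = c("weak", "strong"),
                        scenario = NULL) {
  semantics <- match.arg(semantics)
  diagonal <- grepl("_d$", trace$design)
  if (semantics == "strong" && diagonal) {
    if (is.null(scenario)) scenario <- trace$scenario
    if (is.null(scenario))
      stop("strong semantics requires the true scenario")
    if (inherits(scenario, "tox_scenario")) scenario <- scenario$p
  }
  df <- trace$df
  viol <- data.frame(n = integer(0), type = character(0),
                     from_j = integer(0), from_k = integer(0),
                     to_j = integer(0), to_k = integer(0))
  n_excluded <- 0L
  for (n in seq_len(trace$N)) {
    if (isTRUE(df$flagged[n])) { n_excluded <- n_excluded + 1L; next }
    cur <- c(df$j[n], df$k[n]); nxt <- c(df$next_j[n], df$next_k[n])
    sets <- if (!diagonal || semantics == "weak") trace$sets[[n]]
            else candidate_sets_d(cur, trace$grid, scenario, "strong")
    if (df$y[n] == 1 && in_set(sets$E, nxt))
      viol <- rbind(viol, data.frame(n = n, type = "escalate_after_tox",
                                     from_j = cur[1], from_k = cur[2],
                                     to_j = nxt[1], to_k = nxt[2]))
    if (df$y[n] == 0 && in_set(sets$D, nxt))
      viol <- rbind(viol, data.frame(n = n, type = "deescalate_after_no_tox",
                                     from_j = cur[1], from_k = cur[2],
                                     to_j = nxt[1], to_k = nxt[2]))
  }
  structure(list(semantics = semantics, n_transitions = trace$N,
                 violations = viol, n_excluded = n_excluded,
                 verdict = nrow(viol) == 0),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf("coherence_report (%s): %d transitions, %d violations%s -> %s\n",
              x$semantics, x$n_transitions, nrow(x$violations),
              if (x$n_excluded > 0)
                sprintf(" (%d excluded)", x$n_excluded) else "",
              if (x$verdict) "coherent" else "INCOHERENT"))
  if (nrow(x$violations) > 0) print(x$violations)
  invisible(x)
}

#' Check the sign condition on posterior updates along a trace
#'
#' The sufficient condition for ND coherence links, for every patient n and
#' every parameter t, the outcome residual, the posterior-mean shift, and the
#' model gradient:
#' `(Y_n - p_T)(theta_hat_{n,t} - theta_hat_{n-1,t}) dF/dtheta_t >= 0`,
#' with the gradient evaluated at the treated dose and, here, at the estimate
#' in force when the patient was dosed (`theta_hat_{n-1}`). Updates on the
#' change-point kink surface are skipped and counted.
#'
#' @param trace A [run_trial()] trace.
#' @param eps Numerical tolerance: verdict requires every product
#'   `>= -eps` (default 1e-6).
#' @return List with the N x p `products` matrix, `min_product`, `verdict`,
#'   `n_kink_skipped`, `n_excluded`.
#' @export
check_condition_A <- function(trace, eps = 1e-6) {
  grid <- trace$grid
  p <- ncol(trace$theta_hat)
  prods <- matrix(NA_real_, trace$N, p)
  n_kink <- 0L; n_excluded <- 0L
  for (n in seq_len(trace$N)) {
    if (isTRUE(trace$df$flagged[n])) { n_excluded <- n_excluded + 1L; next }
    th_prev <- trace$theta_hat[n, ]
    th_now <- trace$theta_hat[n + 1, ]
    spec_prev <- model_spec(trace$family, th_prev, grid)
    g <- grad_tox(spec_prev, grid, trace$df$j[n], trace$df$k[n], check = FALSE)
    if (g$kink) { n_kink <- n_kink + 1L; next }
    prods[n, ] <- (trace$df$y[n] - trace$p_T) * (th_now - th_prev) * g$grad
  }
  mp <- suppressWarnings(min(prods, na.rm = TRUE))
  list(products = prods,
       min_product = if (is.finite(mp)) mp else NA_real_,
       verdict = is.finite(mp) && mp >= -eps,
       n_kink_skipped = n_kink, n_excluded = n_excluded)
}

# anti-diagonal adjacent pairs {(j+1,k-1), (j,k)} on a grid, one row per pair
anti_diagonal_pairs <- function(grid) {
  out <- NULL
  for (j in seq_len(grid$J - 1))
    for (k in seq(2, length.out = max(0, grid$K - 1)))
      out <- rbind(out, c(j + 1, k - 1, j, k))
  out
}

#' Check the diagonal-order conditions for strong coherence
#'
#' Two conditions together upgrade a weakly coherent D-design to strong
#' coherence: (B1) the model surface increases in both dose coordinates for
#' every parameter value, and (B2) for every anti-diagonal adjacent pair the
#' model's toxicity order agrees in sign with the true order, again for every
#' parameter value. Both are verified empirically over a seeded sample of
#' admissible parameters — the check is a falsifier with a witness, not a
#' proof.
#'
#' @param family,grid Model family and dose grid.
#' @param scenario True-probability matrix (or [tox_scenario]).
#' @param n_thetas Number of sampled admissible parameter vectors.
#' @param seed Seed for the sampler.
#' @param prior Optional `tox_prior` restricting the sampled support.
#' @return List with elements `B1` (verdict + witness) and `B2` (verdict,
#'   per-pair detail, witness).
#' @export
check_condition_B <- function(family, grid, scenario, n_thetas = 200L,
                              seed = 1L, prior = NULL) {
  if (inherits(scenario, "tox_scenario")) scenario <- scenario$p
  Theta <- sample_admissible_theta(family, grid, n_thetas, seed, prior)
  F <- tox_surface(family, Theta, grid)   # n_thetas x (J*K)
  # B1: increasing along each coordinate (ties allowed on the change-point
  # plateau, where the surface is capped)
  strict <- family != "change_point"
  cmp <- if (strict) function(a, b) a < b else function(a, b) a <= b
  b1_witness <- NULL
  for (j in seq_len(grid$J - 1)) for (k in seq_len(grid$K)) {
    bad <- which(!cmp(F[, dose_index(grid, j, k)],
                      F[, dose_index(grid, j + 1, k)]))
    if (length(bad) > 0 && is.null(b1_witness))
      b1_witness <- list(theta = Theta[bad[1], ], cells = rbind(c(j, k), c(j + 1, k)))
  }
  for (j in seq_len(grid$J)) for (k in seq_len(grid$K - 1)) {
    bad <- which(!cmp(F[, dose_index(grid, j, k)],
                      F[, dose_index(grid, j, k + 1)]))
    if (length(bad) > 0 && is.null(b1_witness))
      b1_witness <- list(theta = Theta[bad[1], ], cells = rbind(c(j, k), c(j, k + 1)))
  }
  # B2: sign agreement on every anti-diagonal adjacent pair
  pairs <- anti_diagonal_pairs(grid)
  detail <- NULL; b2_witness <- NULL
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1:2]; b <- pairs[i, 3:4]
      model_sgn <- sign(F[, dose_index(grid, a[1], a[2])] -
                        F[, dose_index(grid, b[1], b[2])])
      true_sgn <- sign(scenario[a[1], a[2]] - scenario[b[1], b[2]])
      n_bad <- sum(model_sgn != true_sgn)
      detail <- rbind(detail,
                      data.frame(hi_j = a[1], hi_k = a[2], lo_j = b[1],
                                 lo_k = b[2], true_sign = true_sgn,
                                 n_mismatch = n_bad))
      if (n_bad > 0 && is.null(b2_witness))
        b2_witness <- list(theta = Theta[which(model_sgn != true_sgn)[1], ],
                           pair = rbind(a, b))
    }
  }
  list(B1 = list(verdict = is.null(b1_witness), witness = b1_witness),
       B2 = list(verdict = is.null(b2_witness),
                 vacuous = is.null(pairs),
                 detail = detail, witness = b2_witness))
}

#' Check the two-stage switch condition
#'
#' For a two-stage trial the only transition not covered by the stagewise
#' coherence results is the switch itself: from the last stage-1 patient
#' (whose outcome triggered the switch) to the first model-based dose. The
#' design is coherent when both stages are and the switch transition satisfies
#' `(Y - p_T) * (F(X_switch_to, theta) - F(X_switch_from, theta)) <= 0` for
#' every parameter value, where Y is the triggering patient's outcome —
#' verified here over a seeded sample of admissible parameters (an empirical
#' surrogate for "almost surely"), returning the maximizing witness when
#' falsified.
#'
#' @param trace A two-stage [run_trial()] trace.
#' @param n_thetas,seed,prior Sampler settings as in [check_condition_B()].
#' @return List with `applicable`, `verdict`, `max_value`, `witness`, and the
#'   doses/outcome entering the inequality.
#' @export
check_theorem6_condition <- function(trace, n_thetas = 200L, seed = 1L,
                                     prior = NULL) {
  M <- trace$M
  if (is.na(M) || M < 2 || (M - 1) > trace$N)
    return(list(applicable = FALSE, verdict = NA, max_value = NA_real_,
                witness = NULL))
  df <- trace$df
  from <- c(df$j[M - 1], df$k[M - 1])            # last stage-1 patient
  to <- if (M <= trace$N) c(df$j[M], df$k[M])    # first model-based dose
        else c(df$next_j[trace$N], df$next_k[trace$N])
  y_switch <- df$y[M - 1]
  Theta <- sample_admissible_theta(trace$family, trace$grid, n_thetas, seed,
                                   prior)
  info <- family_info(trace$family)
  vals <- (y_switch - trace$p_T) *
    (info$eval(Theta, trace$grid, to[1], to[2]) -
       info$eval(Theta, trace$grid, from[1], from[2]))
  i_max <- which.max(vals)
  list(applicable = TRUE, verdict = max(vals) <= 1e-12,
       max_value = max(vals),
       witness = if (max(vals) > 1e-12) Theta[i_max, ] else NULL,
       X_switch_from = from, X_switch_to = to, y_switch = y_switch)
}

#' Summarize a batch of coherence reports
#'
#' @param reports List of [audit_trace()] reports.
#' @return One-row data frame with totals: traces, transitions, violations by
#'   type, excluded transitions, and the overall verdict.
#' @export
summarize_batch <- function(reports) {
  v <- do.call(rbind, lapply(reports, function(r) r$violations))
  data.frame(
    n_traces = length(reports),
    n_transitions = sum(vapply(reports, function(r) r$n_transitions,
                               numeric(1))),
    n_violations = if (is.null(v)) 0L else nrow(v),
    n_escalate_after_tox =
      if (is.null(v)) 0L else sum(v$type == "escalate_after_tox"),
    n_deescalate_after_no_tox =
      if (is.null(v)) 0L else sum(v$type == "deescalate_after_no_tox"),
    n_excluded = sum(vapply(reports, function(r) r$n_excluded, numeric(1))),
    verdict = all(vapply(reports, function(r) r$verdict, logical(1))))
}

#' Run a seeded batch of trials and audit them
#'
#' Convenience driver for the empirical theorem suites: one integrator is
#' built per batch, each trial gets its own derived seed and (by default) its
#' own generated scenario, and every trace is audited under the requested
#' semantics.
#'
#' @param family Model family.
#' @param design Design kind (see [run_trial()]).
#' @param n_trials Number of trials.
#' @param N Patients per trial.
#' @param p_T Target toxicity probability.
#' @param seed Batch seed; trial i uses a seed derived from it.
#' @param grid Dose grid (default: the family's default 4x4 fixture grid).
#' @param prior Optional prior override.
#' @param scenario Optional fixed scenario (matrix or [tox_scenario]); when
#'   NULL a fresh scenario is generated per trial.
#' @param semantics Character vector of audit semantics to run.
#' @param integrator Optional prebuilt integrator (must match family/grid).
#' @param nodes_per_axis Optional quadrature resolution for the integrator
#'   built when `integrator` is NULL.
#' @param ... Passed to [run_trial()] (e.g. `restrict_candidates`, `start`).
#' @param ... Passed to [run_trial()] (e.g. `start`, `path`).
#' @return List with `traces`, `reports` (one list per semantics), `summary`
#'   (data frame, one row per semantics), and the `integrator`.
#' @export
run_batch <- function(family, design, n_trials, N = 30L, p_T = 0.3,
                      seed = 1L, grid = NULL, prior = NULL, scenario = NULL,
                      semantics = "weak", integrator = NULL,
                      nodes_per_axis = NULL, ...) {
  if (is.null(grid)) grid <- family_default_grid(family)
  if (is.null(integrator))
    integrator <- make_integrator(family, grid, prior = prior,
                                  nodes_per_axis = nodes_per_axis,
                                  seed = derive_seed(seed, 0L))
  traces <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    sc <- if (is.null(scenario))
      gen_scenario(grid$J, grid$K, p_T,
                   mtd_location = random_mtd_location(grid, derive_seed(seed, i)),
                   seed = derive_seed(seed, n_trials + i))
    else scenario
    traces[[i]] <- run_trial(design, integrator, sc, p_T, N,
                             seed = derive_seed(seed, 2L * n_trials + i), ...)
  }
  reports <- lapply(semantics, function(s)
    lapply(traces, audit_trace, semantics = s))
  names(reports) <- semantics
  summary <- do.call(rbind, lapply(semantics, function(s) {
    cbind(data.frame(family = family, design = design, semantics = s),
          summarize_batch(reports[[s]]))
  }))
  list(traces = traces, reports = reports, summary = summary,
       integrator = integrator)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(i) * 271 + 17) %%
               2147483629)
}

random_mtd_location <- function(grid, seed) {
  set.seed(seed)
  c(sample.int(grid$J, 1), sample.int(grid$K, 1))
}
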