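# Candidate-set geometry and dose-assignment rules.
#
# ND-design: escalation/de-escalation restricted to straight neighbors,
#   E = {(j+1,k),(j,k+1)}, D = {(j-1,k),(j,k-1)}.
# D-design: additionally the anti-diagonal neighbors (j+1,k-1), (j-1,k+1),
#   classified into E or D by an ordering matrix — model estimates (weak
#   semantics) or true toxicity probabilities (strong semantics). A diagonal
#   neighbor whose ordering value ties the current dose exactly is excluded
#   from both sets (its order relative to the current dose is indeterminate).
# The same-sign corners (j+1,k+1), (j-1,k-1) are never candidates: moving
# there skips a dose known to lie between.

new_candidate_sets <- function(current, E, D, design_kind, diagonal_semantics) {
  storage.mode(E) <- "integer"; storage.mode(D) <- "integer"
  A <- rbind(matrix(as.integer(current), 1, 2), E, D)
  structure(list(current = as.integer(current), E = E, D = D, A = A,
                 design_kind = design_kind,
                 diagonal_semantics = diagonal_semantics),
            class = "candidate_sets")
}

#' @export
print.candidate_sets <- function(x, ...) {
  fmt <- function(m) if (nrow(m) == 0) "{}" else
    paste0("{", paste(sprintf("(%d,%d)", m[, 1], m[, 2]), collapse = ", "), "}")
  cat(sprintf("candidate_sets (%s) at (%d,%d)\n  E = %s\n  D = %s\n",
              x$design_kind, x$current[1], x$current[2], fmt(x$E), fmt(x$D)))
  invisible(x)
}

clip_to_grid <- function(m, grid) {
  ok <- m[, 1] >= 1 & m[, 1] <= grid$J & m[, 2] >= 1 & m[, 2] <= grid$K
  m[ok, , drop = FALSE]
}

#' Candidate sets for the ND-design
#'
#' @param current Length-2 integer vector (j, k), the current dose.
#' @param grid A [dose_grid()].
#' @return A `candidate_sets` object with straight-neighbor E and D sets
#'   clipped to the grid.
#' @export
candidate_sets_nd <- function(current, grid) {
  j <- current[1]; k <- current[2]
  if (!is_on_grid(grid, j, k)) stop("current dose is not on the grid")
  E <- clip_to_grid(rbind(c(j + 1, k), c(j, k + 1)), grid)
  D <- clip_to_grid(rbind(c(j - 1, k), c(j, k - 1)), grid)
  new_candidate_sets(current, E, D, "ND", "none")
}

#' Candidate sets for the D-design
#'
#' Starts from the ND sets and assigns each in-grid anti-diagonal neighbor to
#' the escalation set if its ordering value exceeds the current dose's, to the
#' de-escalation set if below, excluding exact ties from both.
#'
#' @inheritParams candidate_sets_nd
#' @param ordering J x K matrix supplying the toxicity order: model estimates
#'   `F(theta_hat)` for weak semantics, the true scenario probabilities for
#'   strong semantics.
#' @param semantics Label recorded on the result: "weak" or "strong".
#' @return A `candidate_sets` object.
#' @export
candidate_sets_d <- function(current, grid, ordering,
                             semantics = c("weak", "strong")) {
  semantics <- match.arg(semantics)
  if (!is.matrix(ordering) || nrow(ordering) != grid$J ||
      ncol(ordering) != grid$K)
    stop("`ordering` must be a J x K matrix covering the grid")
  j <- current[1]; k <- current[2]
  base <- candidate_sets_nd(current, grid)
  E <- base$E; D <- base$D
  diag_nb <- clip_to_grid(rbind(c(j + 1, k - 1), c(j - 1, k + 1)), grid)
  cur_val <- ordering[j, k]
  for (i in seq_len(nrow(diag_nb))) {
    val <- ordering[diag_nb[i, 1], diag_nb[i, 2]]
    if (is.na(val) || is.na(cur_val))
      stop("ordering matrix has missing values at required cells")
    if (val > cur_val) E <- rbind(E, diag_nb[i, ])
    else if (val < cur_val) D <- rbind(D, diag_nb[i, ])
    # exact tie: excluded from both sets
  }
  new_candidate_sets(current, E, D, "D", semantics)
}

# TRUE iff dose a is at or below dose b in the known partial order
po_leq <- function(a, b) a[1] <= b[1] && a[2] <= b[2]

# deterministic argmin |fhat - p_T| over a candidate matrix; safety-first tie
# rule: current dose first, then partial-order-minimal candidates, then
# lexicographic (j, then k)
pick_argmin <- function(fhat, cand, p_T, current = NULL) {
  d <- abs(fhat[cand] - p_T)
  ties <- which(d == min(d))
  if (length(ties) > 1 && !is.null(current)) {
    is_cur <- cand[ties, 1] == current[1] & cand[ties, 2] == current[2]
    if (any(is_cur)) return(as.integer(current))
  }
  tc <- cand[ties, , drop = FALSE]
  if (nrow(tc) > 1) {
    minimal <- vapply(seq_len(nrow(tc)), function(i) {
      !any(vapply(seq_len(nrow(tc)), function(l)
        l != i && po_leq(tc[l, ], tc[i, ]) && !all(tc[l, ] == tc[i, ]),
        logical(1)))
    }, logical(1))
    tc <- tc[minimal, , drop = FALSE]
    tc <- tc[order(tc[, 1], tc[, 2]), , drop = FALSE]
  }
  as.integer(tc[1, ])
}

#' Model-based dose selection
#'
#' The assignment rule of CRM-type combination designs: the next patient is
#' treated at the admissible dose whose estimated toxicity probability is
#' closest to the target, `argmin_{(j,k) in A_n} |F_jk(theta_hat) - p_T|`.
#' Exact ties retain the current dose; remaining ties prefer doses lower in the
#' known partial order, then lexicographic order — a deterministic,
#' safety-first convention.
#'
#' @param fhat J x K matrix of model toxicity estimates.
#' @param sets A `candidate_sets` object.
#' @param p_T Target toxicity probability in (0, 1).
#' @return Length-2 integer vector: the selected (j, k).
#' @export
select_next_dose <- function(fhat, sets, p_T) {
  stopifnot(p_T > 0, p_T < 1, nrow(sets$A) >= 1)
  pick_argmin(fhat, sets$A, p_T, current = sets$current)
}

#' Default titration path
#'
#' A staircase chain of combinations with monotonically increasing toxicity,
#' `(1,1) -> (2,1) -> (2,2) -> (3,2) -> ...`, clipped to the grid and extended
#' along the remaining axis once one agent tops out.
#'
#' @param grid A [dose_grid()].
#' @return An m x 2 integer matrix of dose levels starting at (1,1), each step
#'   raising exactly one agent's level by 1.
#' @export
titration_path <- function(grid) {
  pos <- c(1L, 1L); path <- matrix(pos, 1, 2)
  raise_j <- TRUE
  while (pos[1] < grid$J || pos[2] < grid$K) {
    if (raise_j && pos[1] < grid$J) pos[1] <- pos[1] + 1L
    else if (pos[2] < grid$K) pos[2] <- pos[2] + 1L
    else pos[1] <- pos[1] + 1L
    path <- rbind(path, pos)
    raise_j <- !raise_j
  }
  unname(path)
}

validate_titration_path <- function(path, grid) {
  path <- as.matrix(path)
  if (!all(path[1, ] == c(1, 1))) stop("titration path must start at (1,1)")
  steps <- diff(path)
  if (nrow(path) > 1 &&
      !all(rowSums(steps) == 1 & apply(steps, 1, function(s) all(s %in% 0:1))))
    stop("each titration step must raise exactly one agent's level by 1")
  if (any(path[, 1] > grid$J) || any(path[, 2] > grid$K))
    stop("titration path leaves the grid")
  storage.mode(path) <- "integer"
  path
}

#' One titration step
#'
#' Stage-1 rule of the two-stage design: escalate along the pre-selected path
#' while no toxicity is observed; the first toxicity (and, under the default
#' switch rule, exhaustion of the path) triggers the switch to the model-based
#' stage.
#'
#' @param path Titration path matrix (see [titration_path()]).
#' @param position Current index on the path.
#' @param y Toxicity outcome (0/1) of the patient at `position`.
#' @param switch_rule "path_exhausted_or_first_toxicity" (default) or
#'   "first_toxicity" (on exhaustion without toxicity the dose is held).
#' @return A list with `action` ("continue", "switch", or "hold") and, when
#'   continuing, `next_position`.
#' @export
titration_next <- function(path, position, y,
                           switch_rule = c("path_exhausted_or_first_toxicity",
                                           "first_toxicity")) {
  switch_rule <- match.arg(switch_rule)
  if (y == 1) return(list(action = "switch"))
  if (position < nrow(path))
    return(list(action = "continue",
                next_position = as.integer(position) + 1L))
  if (switch_rule == "path_exhausted_or_first_toxicity")
    list(action = "switch")
  else list(action = "hold")
}

#' Simulate one trial
#'
#' Runs a model-based combination trial of N patients: outcomes are Bernoulli
#' draws from the true scenario probabilities (one seeded stream per trial, so
#' design variants are comparable under common random numbers); the posterior
#' mean is updated after every patient; and the next dose is chosen by
#' [select_next_dose()] over the design's candidate sets (or by titration in
#' stage 1 of the two-stage designs). Cohorts are of size 1.
#'
#' One-stage designs start at the prior estimate of the MTD (the dose whose
#' prior-mean toxicity estimate is closest to the target) unless `start` is
#' given; two-stage designs start at (1,1) on the titration path.
#'
#' @param design "one_stage_nd", "one_stage_d", "two_stage_nd", "two_stage_d".
#' @param integrator A [make_integrator()] for the working model.
#' @param scenario A [tox_scenario] (or bare J x K matrix of true DLT
#'   probabilities).
#' @param p_T Target toxicity probability.
#' @param N Number of patients.
#' @param seed Seed for the outcome stream.
#' @param start Optional (j, k) start for one-stage designs.
#' @param path Optional titration path for two-stage designs.
#' @param switch_rule Passed to [titration_next()].
#' @param restrict_candidates When TRUE (the default, and the published rule)
#'   the assignment argmin runs over the no-skipping candidate set `A_n`;
#'   FALSE replaces it by the unrestricted argmin over the whole grid — the
#'   classical single-agent assignment — used as a diagnostic control in the
#'   coherence analyses. Candidate sets are still recorded for auditing.
#' @return A `trial_trace`: per-patient data frame `df` (n, j, k, y, stage,
#'   ess, flagged), posterior-mean matrix `theta_hat` ((N+1) x p, row 1 =
#'   prior), plug-in estimate matrices `fhat` (list, length N+1), per-patient
#'   weak candidate sets `sets`, the switch patient `M` (NA if none), and the
#'   run configuration.
#' @export
run_trial <- function(design = c("one_stage_nd", "one_stage_d",
                                 "two_stage_nd", "two_stage_d"),
                      integrator, scenario, p_T, N, seed,
                      start = NULL, path = NULL,
                      switch_rule = "path_exhausted_or_first_toxicity",
                      restrict_candidates = TRUE) {
  design <- match.arg(design)
  grid <- integrator$grid
  p_true <- if (inherits(scenario, "tox_scenario")) scenario$p else scenario
  if (!is.matrix(p_true) || nrow(p_true) != grid$J || ncol(p_true) != grid$K)
    stop("scenario does not match the integrator's grid")
  stopifnot(p_T > 0, p_T < 1, N >= 1)
  two_stage <- grepl("^two_stage", design)
  diagonal <- grepl("_d$", design)

  set.seed(as.integer(seed))
  u_draws <- stats::runif(N)

  prior_est <- posterior_mean(interim_data(matrix(0, 0, 2), integer(0), grid),
                              integrator)
  all_doses <- cbind(rep(seq_len(grid$J), grid$K),
                     rep(seq_len(grid$K), each = grid$J))
  if (two_stage) {
    path <- if (is.null(path)) titration_path(grid)
            else validate_titration_path(path, grid)
    X <- path[1, ]
    pos <- 1L; in_titration <- TRUE
  } else {
    X <- if (!is.null(start)) as.integer(start)
         else pick_argmin(prior_est$fhat, all_doses, p_T)
    in_titration <- FALSE
  }

  p_dim <- integrator$p
  theta_hat <- matrix(NA_real_, N + 1, p_dim)
  theta_hat[1, ] <- prior_est$theta_hat
  fhat <- vector("list", N + 1)
  fhat[[1]] <- prior_est$fhat
  sets <- vector("list", N)
  df <- data.frame(n = seq_len(N), j = NA_integer_, k = NA_integer_,
                   y = NA_integer_, stage = NA_character_,
                   next_j = NA_integer_, next_k = NA_integer_,
                   ess = NA_real_, flagged = NA)
  M <- NA_integer_
  lw <- integrator$lw0

  for (n in seq_len(N)) {
    y <- as.integer(u_draws[n] < p_true[X[1], X[2]])
    d <- dose_index(grid, X[1], X[2])
    lw <- lw + if (y == 1) integrator$lF[, d] else integrator$l1mF[, d]
    st <- post_stats(integrator, lw)
    theta_hat[n + 1, ] <- st$theta_hat
    fh <- tox_matrix(model_spec(integrator$family, st$theta_hat, grid),
                     grid, check = FALSE)
    fhat[[n + 1]] <- fh
    sets[[n]] <- if (diagonal) candidate_sets_d(X, grid, fh, "weak")
                 else candidate_sets_nd(X, grid)
    df$j[n] <- X[1]; df$k[n] <- X[2]; df$y[n] <- y
    df$stage[n] <- if (in_titration) "titration" else "model"
    df$ess[n] <- st$ess
    df$flagged[n] <- st$ess < integrator$ess_min

    if (in_titration) {
      step <- titration_next(path, pos, y, switch_rule)
      if (step$action == "continue") {
        pos <- step$next_position
        X_next <- path[pos, ]
      } else if (step$action == "hold") {
        X_next <- X
      } else {
        in_titration <- FALSE
        if (is.na(M)) M <- n + 1L
        X_next <- if (restrict_candidates) select_next_dose(fh, sets[[n]], p_T)
                  else pick_argmin(fh, all_doses, p_T, current = X)
      }
    } else {
      X_next <- if (restrict_candidates) select_next_dose(fh, sets[[n]], p_T)
                else pick_argmin(fh, all_doses, p_T, current = X)
    }
    df$next_j[n] <- X_next[1]; df$next_k[n] <- X_next[2]
    X <- X_next
  }

  structure(list(design = design, family = integrator$family, grid = grid,
                 p_T = p_T, N = N, seed = seed,
                 df = df, theta_hat = theta_hat, fhat = fhat, sets = sets,
                 M = M, scenario = p_true,
                 path = if (two_stage) path else NULL),
            class = "trial_trace")
}

#' @export
print.trial_trace <- function(x, ...) {
  cat(sprintf("trial_trace: %s / %s, N = %d, seed = %d\n",
              x$design, x$family, x$N, x$seed))
  cat(sprintf("  doses: %s\n",
              paste(sprintf("(%d,%d)%s", x$df$j, x$df$k,
                            ifelse(x$df$y == 1, "*", "")), collapse = " ")))
  if (!is.na(x$M)) cat(sprintf("  switched to model-based at patient %d\n", x$M))
  invisible(x)
}
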