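# Run configuration, trace serialization, and the command surface behind the
# CLI script. A run is reproducible from its config plus seeds alone; floating
# point values are serialized at 17 significant digits so audits recompute
# transition classifications without drift.

#' Read a run configuration
#'
#' Configs are YAML or JSON with fields: `grid` (a [fixture_bank()] grid name
#' or a list with `u`, `v` and optional skeletons), `family`, `p_T`, `design`,
#' `N`, `n_trials`, `seed`, and optionally `prior` (list of component specs
#' `{type: normal|exp|nexp|unif, ...}`), `scenario` (matrix rows; generated
#' per trial when absent), `path`, `switch_rule`, `semantics`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`) or an already-parsed list.
#' @return A validated config list with the grid and prior resolved.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  # YAML 1.1 parses a bare `N` key as the boolean FALSE; accept that spelling
  # and the explicit alias `n_patients`
  if (is.null(cfg$N) && !is.null(cfg[["FALSE"]])) cfg$N <- cfg[["FALSE"]]
  if (is.null(cfg$N) && !is.null(cfg$n_patients)) cfg$N <- cfg$n_patients
  required <- c("family", "p_T", "design", "N", "n_trials", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0)
    stop("config is missing required fields: ", paste(missing, collapse = ", "))
  cfg$family <- match.arg(cfg$family, model_families())
  cfg$design <- match.arg(cfg$design, c("one_stage_nd", "one_stage_d",
                                        "two_stage_nd", "two_stage_d"))
  stopifnot(cfg$p_T > 0, cfg$p_T < 1, cfg$N >= 1, cfg$n_trials >= 1)
  cfg$grid <- resolve_grid(cfg$grid, cfg$family)
  cfg$prior <- if (!is.null(cfg$prior))
    default_prior(cfg$family, cfg$grid,
                  components = lapply(cfg$prior, parse_prior_component))
  else default_prior(cfg$family, cfg$grid)
  if (!is.null(cfg$scenario)) {
    m <- do.call(rbind, lapply(cfg$scenario, as.numeric))
    cfg$scenario <- tox_scenario(m)
  }
  cfg
}

resolve_grid <- function(grid, family) {
  if (is.null(grid)) return(family_default_grid(family))
  if (inherits(grid, "dose_grid")) return(grid)
  if (is.character(grid)) {
    bank <- fixture_bank()$grids
    if (!grid %in% names(bank))
      stop("unknown fixture grid '", grid, "'; available: ",
           paste(names(bank), collapse = ", "))
    return(bank[[grid]])
  }
  dose_grid(u = as.numeric(grid$u), v = as.numeric(grid$v),
            skeleton_p = grid$skeleton_p, skeleton_q = grid$skeleton_q)
}

parse_prior_component <- function(x) {
  switch(x$type,
    normal = prior_normal(x$mean %||% 0, x$sd %||% 2),
    exp    = prior_exp(x$rate %||% 1),
    nexp   = prior_nexp(x$rate %||% 1),
    unif   = prior_unif(x$a, x$b),
    stop("unknown prior component type '", x$type, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a trial trace to CSV
#'
#' One row per patient plus a leading row (n = 0) carrying the prior estimate;
#' posterior means and estimate surfaces at 17 significant digits; candidate
#' sets JSON-encoded.
#'
#' @param trace A [run_trial()] trace.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  grid <- trace$grid
  p <- ncol(trace$theta_hat)
  D <- grid$J * grid$K
  cells <- cbind(rep(seq_len(grid$J), grid$K),
                 rep(seq_len(grid$K), each = grid$J))
  fhat_cols <- paste0("fhat_", cells[, 1], "_", cells[, 2])
  rows <- lapply(0:trace$N, function(n) {
    fh <- trace$fhat[[n + 1]]
    base <- if (n == 0)
      data.frame(n = 0L, j = NA, k = NA, y = NA, stage = "prior",
                 next_j = NA, next_k = NA, ess = NA, flagged = NA)
    else trace$df[n, c("n", "j", "k", "y", "stage", "next_j", "next_k",
                       "ess", "flagged")]
    th <- as.data.frame(t(fmt17(trace$theta_hat[n + 1, ])))
    names(th) <- paste0("theta_hat_", seq_len(p))
    fm <- as.data.frame(t(fmt17(as.vector(fh))))
    names(fm) <- fhat_cols
    sets <- if (n == 0) data.frame(E_set = "", D_set = "")
    else data.frame(
      E_set = as.character(jsonlite::toJSON(trace$sets[[n]]$E)),
      D_set = as.character(jsonlite::toJSON(trace$sets[[n]]$D)))
    cbind(base, th, fm, sets)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Read a trial trace from CSV
#'
#' Rebuilds the trace structure written by [write_trace_csv()]; run metadata
#' (design, family, grid, target, scenario) comes from the accompanying
#' manifest, as written by [cmd_simulate()].
#'
#' @param file Trace CSV path.
#' @param meta List with `design`, `family`, `grid`, `p_T`, `scenario`, `seed`.
#' @return A `trial_trace`.
#' @export
read_trace_csv <- function(file, meta) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  grid <- meta$grid
  N <- max(x$n)
  p <- sum(grepl("^theta_hat_", names(x)))
  theta_hat <- as.matrix(x[, paste0("theta_hat_", seq_len(p))])
  fhat_cols <- grep("^fhat_", names(x), value = TRUE)
  fhat <- lapply(seq_len(N + 1), function(i)
    matrix(as.numeric(x[i, fhat_cols]), grid$J, grid$K))
  parse_set <- function(s) {
    m <- jsonlite::fromJSON(s)
    if (length(m) == 0) matrix(integer(0), 0, 2) else matrix(m, ncol = 2)
  }
  sets <- lapply(seq_len(N), function(n) {
    i <- n + 1
    cur <- c(x$j[i], x$k[i])
    E <- parse_set(x$E_set[i]); D <- parse_set(x$D_set[i])
    kind <- if (grepl("_d$", meta$design)) "D" else "ND"
    new_candidate_sets(cur, E, D, kind,
                       if (kind == "D") "weak" else "none")
  })
  df <- x[x$n > 0, c("n", "j", "k", "y", "stage", "next_j", "next_k",
                     "ess", "flagged")]
  rownames(df) <- NULL
  structure(list(design = meta$design, family = meta$family, grid = grid,
                 p_T = meta$p_T, N = N, seed = meta$seed,
                 df = df, theta_hat = unname(theta_hat), fhat = fhat,
                 sets = sets,
                 M = {
                   mm <- which(df$stage == "model")
                   if (grepl("^two_stage", meta$design) && length(mm) > 0)
                     mm[1] else NA_integer_
                 },
                 scenario = meta$scenario, path = NULL),
            class = "trial_trace")
}

#' Simulate trials from a run configuration
#'
#' Writes one CSV per trial plus `manifest.json` (the config echo, grid,
#' seeds, and per-trial scenarios) into `out_dir`.
#'
#' @param config Config path or list (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `files`, `manifest`, and `exit_code`
#'   (0 = clean, 3 = posterior convergence flags present).
#' @export
cmd_simulate <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  integrator <- make_integrator(cfg$family, cfg$grid, prior = cfg$prior,
                                seed = derive_seed(cfg$seed, 0L))
  files <- character(cfg$n_trials)
  scen_list <- vector("list", cfg$n_trials)
  any_flagged <- FALSE
  for (i in seq_len(cfg$n_trials)) {
    sc <- if (!is.null(cfg$scenario)) cfg$scenario
    else gen_scenario(cfg$grid$J, cfg$grid$K, cfg$p_T,
                      mtd_location = random_mtd_location(
                        cfg$grid, derive_seed(cfg$seed, i)),
                      seed = derive_seed(cfg$seed, cfg$n_trials + i))
    tr <- run_trial(cfg$design, integrator, sc, cfg$p_T, cfg$N,
                    seed = derive_seed(cfg$seed, 2L * cfg$n_trials + i),
                    path = cfg$path,
                    switch_rule = cfg$switch_rule %||%
                      "path_exhausted_or_first_toxicity")
    any_flagged <- any_flagged || any(tr$df$flagged)
    files[i] <- file.path(out_dir, sprintf("trace_%04d.csv", i))
    write_trace_csv(tr, files[i])
    scen_list[[i]] <- unname(apply(if (inherits(sc, "tox_scenario")) sc$p
                                   else sc, 1, fmt17, simplify = FALSE))
  }
  manifest <- list(
    family = cfg$family, design = cfg$design, p_T = cfg$p_T, N = cfg$N,
    n_trials = cfg$n_trials, seed = cfg$seed,
    grid = list(u = fmt17(cfg$grid$u), v = fmt17(cfg$grid$v),
                skeleton_p = if (!is.null(cfg$grid$skeleton_p))
                  fmt17(cfg$grid$skeleton_p),
                skeleton_q = if (!is.null(cfg$grid$skeleton_q))
                  fmt17(cfg$grid$skeleton_q)),
    scenarios = scen_list, files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(files = files, manifest = manifest,
                 exit_code = if (any_flagged) 3L else 0L))
}

read_manifest <- function(dir) {
  m <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                          simplifyVector = TRUE)
  g <- m$grid
  m$grid <- dose_grid(as.numeric(g$u), as.numeric(g$v),
                      skeleton_p = if (!is.null(g$skeleton_p))
                        as.numeric(g$skeleton_p),
                      skeleton_q = if (!is.null(g$skeleton_q))
                        as.numeric(g$skeleton_q))
  m
}

#' Audit simulated trial logs
#'
#' Reads the traces written by [cmd_simulate()], audits each under the
#' requested semantics, and writes `report.json` plus `summary.csv`.
#'
#' @param dir Directory holding `manifest.json` and trace CSVs.
#' @param semantics "weak" or "strong".
#' @param scenario Optional scenario CSV path or matrix overriding the
#'   manifest scenarios (required if the manifest lacks them under strong
#'   semantics).
#' @return Invisibly, list with `reports`, `summary`, `exit_code` (0 = clean,
#'   2 = coherence violation present).
#' @export
cmd_audit <- function(dir, semantics = c("weak", "strong"), scenario = NULL) {
  semantics <- match.arg(semantics)
  m <- read_manifest(dir)
  if (!is.null(scenario) && is.character(scenario))
    scenario <- as.matrix(utils::read.csv(scenario, header = FALSE))
  reports <- vector("list", length(m$files))
  for (i in seq_along(m$files)) {
    sc <- if (!is.null(scenario)) scenario
    else matrix(as.numeric(t(m$scenarios[[i]])), m$grid$J, m$grid$K,
                byrow = TRUE)
    meta <- list(design = m$design, family = m$family, grid = m$grid,
                 p_T = m$p_T, scenario = sc, seed = m$seed)
    tr <- read_trace_csv(file.path(dir, m$files[i]), meta)
    reports[[i]] <- audit_trace(tr, semantics, scenario = sc)
  }
  summ <- summarize_batch(reports)
  jsonlite::write_json(
    list(semantics = semantics,
         n_traces = summ$n_traces, n_transitions = summ$n_transitions,
         violations = do.call(rbind, lapply(reports, function(r)
           r$violations)),
         verdict = summ$verdict),
    file.path(dir, sprintf("report_%s.json", semantics)),
    auto_unbox = TRUE, dataframe = "rows")
  utils::write.csv(summ, file.path(dir, sprintf("summary_%s.csv", semantics)),
                   row.names = FALSE)
  invisible(list(reports = reports, summary = summ,
                 exit_code = if (summ$verdict) 0L else 2L))
}

#' Run a named condition check
#'
#' Dispatches to the audit-layer checkers: "uniform_monotonicity",
#' "condition_A" (runs a trial first), "condition_B", or "theorem6" (two-stage
#' trial first).
#'
#' @param check Check name.
#' @param family Model family.
#' @param grid Grid, fixture name, or NULL for the family default.
#' @param p_T,N,seed Trial settings where a trial is needed.
#' @param scenario Scenario for condition_B / the trial runs (generated when
#'   NULL).
#' @param out Optional path for a JSON verdict report.
#' @return The checker's verdict list (with `check` and `family` fields).
#' @export
cmd_check <- function(check = c("uniform_monotonicity", "condition_A",
                                "condition_B", "theorem6"),
                      family, grid = NULL, p_T = 0.3, N = 30L, seed = 1L,
                      scenario = NULL, out = NULL) {
  check <- match.arg(check)
  grid <- resolve_grid(grid, family)
  if (is.null(scenario) && check != "uniform_monotonicity")
    scenario <- gen_scenario(grid$J, grid$K, p_T, seed = derive_seed(seed, 7L))
  res <- switch(check,
    uniform_monotonicity =
      check_uniform_monotonicity(family, grid, seed = seed),
    condition_A = {
      intg <- make_integrator(family, grid, seed = derive_seed(seed, 0L))
      tr <- run_trial("one_stage_nd", intg, scenario, p_T, N, seed = seed)
      check_condition_A(tr)
    },
    condition_B = check_condition_B(family, grid, scenario, seed = seed),
    theorem6 = {
      intg <- make_integrator(family, grid, seed = derive_seed(seed, 0L))
      tr <- run_trial("two_stage_nd", intg, scenario, p_T, N, seed = seed)
      check_theorem6_condition(tr, seed = derive_seed(seed, 3L))
    })
  res$check <- check; res$family <- family
  if (!is.null(out)) {
    res_json <- res
    res_json$products <- NULL   # large matrix; verdict + min suffice on disk
    jsonlite::write_json(res_json, out, auto_unbox = TRUE, force = TRUE,
                         null = "null")
  }
  res
}
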