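# Dose-toxicity surfaces: closed-form limits, constraint predicates,
# partial-order conformity, and gradients.

test_that("closed-form boundary identities hold to 1e-12", {
  # logistic at theta = 0 is 1/2 everywhere (evaluated without the
  # admissibility gate, which rightly rejects the boundary theta)
  g <- dose_grid(u = c(0.7), v = c(1.3))
  spec0 <- structure(list(family = "logistic4", theta = rep(0, 4)),
                     class = "model_spec")
  expect_equal(tox_prob(spec0, g, 1, 1, check = FALSE), 0.5, tolerance = 1e-12)

  # hand-evaluated logistic value
  spec <- model_spec("logistic4", c(-1, 0.5, 0.5, 0.1), dose_grid(1, 1))
  expect_equal(tox_prob(spec, dose_grid(1, 1), 1, 1), plogis(0.1),
               tolerance = 1e-12)

  # Clayton copula collapses to the single-agent term as p_j -> 0
  sp <- c(1e-16, 0.2); sq <- c(0.1, 0.3)
  gc <- dose_grid(u = c(-2, 0), v = c(-2, -1), skeleton_p = sp,
                  skeleton_q = sq)
  th <- c(2, 1.2, 0.7)
  expect_equal(tox_prob(model_spec("clayton", th, gc), gc, 1, 2),
               sq[2]^th[2], tolerance = 1e-12)

  # Gumbel at gamma = 0 is the independence limit 1 - (1-p^a)(1-q^b)
  spg <- structure(list(family = "gumbel", theta = c(0.8, 1.2, 0)),
                   class = "model_spec")
  a <- sp[2]^0.8; b <- sq[2]^1.2
  expect_equal(tox_prob(spg, gc, 2, 2, check = FALSE), 1 - (1 - a) * (1 - b),
               tolerance = 1e-12)

  # log-linear at gamma = 0 drops the interaction
  gu <- dose_grid(u = c(0.2, 0.5), v = c(0.3, 0.6))
  spl <- structure(list(family = "log_linear", theta = c(1.1, 0.9, 0)),
                   class = "model_spec")
  expect_equal(tox_prob(spl, gu, 2, 1, check = FALSE),
               1 - (1 - 0.5)^1.1 * (1 - 0.3)^0.9, tolerance = 1e-12)

  # six-parameter model vanishes at the dose origin
  g6 <- dose_grid(u = c(0, 0.5), v = c(0, 0.5))
  sp6 <- model_spec("six_param", rep(1, 6), g6)
  expect_equal(tox_prob(sp6, g6, 1, 1), 0, tolerance = 1e-12)

  # change-point plateau: once past the threshold, F = logit^-1(w)
  gcp <- dose_grid(u = c(1, 10), v = c(1, 10))
  spc <- model_spec("change_point", c(0, 1, 1, 1.5), gcp)
  expect_equal(tox_prob(spc, gcp, 2, 2), plogis(1.5), tolerance = 1e-12)
})

test_that("constraint predicates name each violated inequality", {
  g <- std_dose_grid(c(0.2, 0.35, 0.55, 0.7), c(0.25, 0.45, 0.6, 0.7))
  ok <- check_constraints(model_spec("logistic4", c(0, 1, 1, 0), g), g)
  expect_true(ok$admissible)

  # large negative interaction violates theta2 + theta4 v_k > 0 at v_K > 0
  bad <- check_constraints(model_spec("logistic4", c(0, 1, 1, -2), g), g)
  expect_false(bad$admissible)
  expect_true(any(grepl("theta2 \\+ theta4", bad$violated)))

  bad2 <- check_constraints(
    structure(list(family = "log_linear", theta = c(1, 1, 0.5)),
              class = "model_spec"),
    dose_grid(u = c(0.2, 0.4), v = c(0.2, 0.4)))
  expect_false(bad2$admissible)
  expect_identical(bad2$violated, "gamma < 0")

  # boundary thetas are inadmissible under the strict reading
  b3 <- check_constraints(
    structure(list(family = "clayton", theta = c(0, 1, 1)),
              class = "model_spec"),
    family_default_grid("clayton"))
  expect_false(b3$admissible)
})

test_that("toxicity matrices obey the partial order for sampled admissible theta", {
  for (fam in model_families()) {
    g <- family_default_grid(fam)
    Theta <- sample_admissible_theta(fam, g, 60, seed = 21)
    F <- combcoherence:::tox_surface(fam, Theta, g)
    strict <- fam != "change_point"
    for (i in seq_len(nrow(Theta))) {
      m <- matrix(F[i, ], g$J, g$K)
      expect_true(check_partial_order(m, strict = strict),
                  info = sprintf("%s theta #%d", fam, i))
      expect_true(all(m >= 0 & m <= 1))
    }
  }
})

test_that("tox_matrix agrees with scalar evaluation cell by cell", {
  for (fam in c("logistic4", "clayton", "six_param")) {
    g <- family_default_grid(fam, 2, 2)
    spec <- model_spec(fam, adm_theta(fam, g), g)
    m <- tox_matrix(spec, g)
    for (j in 1:2) for (k in 1:2)
      expect_equal(m[j, k], tox_prob(spec, g, j, k), tolerance = 1e-14)
  }
})

test_that("scaled-logistic stays below its plateau; change-point below its cap", {
  g <- family_default_grid("scaled_logistic")
  Theta <- sample_admissible_theta("scaled_logistic", g, 50, seed = 3)
  F <- combcoherence:::tox_surface("scaled_logistic", Theta, g)
  expect_true(all(F < Theta[, 1]))  # sup F < rho

  gcp <- family_default_grid("change_point")
  Th <- sample_admissible_theta("change_point", gcp, 50, seed = 4)
  Fc <- combcoherence:::tox_surface("change_point", Th, gcp)
  expect_true(all(Fc <= plogis(Th[, 4]) + 1e-15))
})

test_that("central-difference gradients match analytic forms", {
  # logistic4: full analytic gradient at 100 sampled admissible points
  g <- family_default_grid("logistic4")
  Theta <- sample_admissible_theta("logistic4", g, 100, seed = 7)
  for (i in seq_len(nrow(Theta))) {
    spec <- model_spec("logistic4", Theta[i, ], g)
    j <- 1 + (i %% g$J); k <- 1 + (i %% g$K)
    an <- combcoherence:::.logistic4_grad(Theta[i, ], g, j, k)
    cd <- grad_tox(spec, g, j, k)$grad
    expect_equal(cd, an, tolerance = 1e-6)
  }

  # six-parameter model: dF/dalpha1 = u^b1 / (1+G)^2 >= 0
  g6 <- family_default_grid("six_param")
  Th6 <- sample_admissible_theta("six_param", g6, 30, seed = 8)
  for (i in seq_len(nrow(Th6))) {
    spec <- model_spec("six_param", Th6[i, ], g6)
    an <- combcoherence:::.six_param_grad_a1(Th6[i, ], g6, 2, 3)
    cd <- grad_tox(spec, g6, 2, 3)$grad[1]
    expect_gte(an, 0)
    expect_equal(cd, an, tolerance = 1e-6 * max(1, an))
  }

  # clayton: F is nonincreasing in alpha everywhere
  gc <- family_default_grid("clayton")
  Thc <- sample_admissible_theta("clayton", gc, 30, seed = 9)
  for (i in seq_len(nrow(Thc)))
    expect_lte(grad_tox(model_spec("clayton", Thc[i, ], gc), gc, 2, 2)$grad[1],
               0)
})

test_that("change-point gradients near the kink are flagged", {
  bank <- fixture_bank()
  kg <- bank$kink_change_point$grid
  spec <- model_spec("change_point", bank$kink_change_point$theta, kg)
  g_on <- grad_tox(spec, kg, 2, 2)   # linear predictor equals w here
  expect_true(g_on$kink)
  g_off <- grad_tox(spec, kg, 1, 1)
  expect_false(g_off$kink)
})

test_that("copula families demand skeletons and misdimensioned theta errors", {
  g_nosk <- dose_grid(u = c(-1, 0), v = c(-1, 0))
  expect_error(model_spec("clayton", c(1, 1, 1), g_nosk), "skeleton")
  g <- family_default_grid("logistic4")
  expect_error(model_spec("logistic4", c(1, 1), g), "4 parameters")
  expect_error(model_spec("generalized_crm", rep(1, 3), g), "5 parameters")
})
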