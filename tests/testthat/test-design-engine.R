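# Candidate-set geometry, the argmin selection rule, titration, and the trial
# simulator's structural invariants.

test_that("candidate-set invariants hold exhaustively on grids up to 5x5", {
  for (J in 1:5) for (K in 1:5) {
    grid <- dose_grid(u = seq_len(J), v = seq_len(K))
    # a generic strictly increasing ordering matrix with distinct diagonals
    ord <- outer(seq_len(J) * 1.13, seq_len(K) * 0.91, `+`)
    for (j in seq_len(J)) for (k in seq_len(K)) {
      for (kind in c("nd", "d")) {
        s <- if (kind == "nd") candidate_sets_nd(c(j, k), grid)
             else candidate_sets_d(c(j, k), grid, ord)
        # A = {current} u E u D, disjoint union
        expect_equal(nrow(s$A), 1 + nrow(s$E) + nrow(s$D))
        both <- rbind(s$E, s$D)
        if (nrow(both) > 1)
          expect_equal(anyDuplicated(both), 0)
        for (m in list(s$E, s$D)) {
          if (nrow(m) == 0) next
          dj <- m[, 1] - j; dk <- m[, 2] - k
          # in-grid
          expect_true(all(m[, 1] >= 1 & m[, 1] <= J & m[, 2] >= 1 & m[, 2] <= K))
          # adjacency: straight neighbors, plus anti-diagonal for D
          if (kind == "nd") expect_true(all(abs(dj) + abs(dk) == 1))
          else expect_true(all(abs(dj) + abs(dk) == 1 |
                                 (abs(dj) == 1 & abs(dk) == 1 & dj * dk < 0)))
          # the same-sign corners are never candidates
          expect_false(any(dj == 1 & dk == 1))
          expect_false(any(dj == -1 & dk == -1))
        }
      }
    }
  }
})

test_that("D-design classifies anti-diagonal neighbors by the ordering matrix", {
  grid <- dose_grid(u = 1:3, v = 1:3)
  ord <- outer(1:3, 1:3, function(a, b) 0.1 * a + 0.1 * b)
  ord[3, 1] <- ord[2, 2] + 0.05   # ranked above current
  ord[1, 3] <- ord[2, 2] - 0.05   # ranked below current
  s <- candidate_sets_d(c(2, 2), grid, ord)
  expect_true(combcoherence:::in_set(s$E, c(3, 1)))
  expect_true(combcoherence:::in_set(s$D, c(1, 3)))

  # an exact tie excludes the neighbor from both sets
  ord[3, 1] <- ord[2, 2]
  s2 <- candidate_sets_d(c(2, 2), grid, ord)
  expect_false(combcoherence:::in_set(s2$E, c(3, 1)))
  expect_false(combcoherence:::in_set(s2$D, c(3, 1)))
  expect_true(combcoherence:::in_set(s2$A, c(1, 3)))

  expect_error(candidate_sets_d(c(2, 2), grid, ord[1:2, ]), "J x K")
})

test_that("selection takes the unique argmin and breaks ties deterministically", {
  grid <- dose_grid(u = 1:3, v = 1:3)
  fhat <- matrix(0.5, 3, 3)
  fhat[1, 1] <- 0.10; fhat[2, 1] <- 0.28; fhat[1, 2] <- 0.45
  s <- candidate_sets_nd(c(1, 1), grid)
  expect_identical(select_next_dose(fhat, s, 0.30), c(2L, 1L))

  # exact tie between current and an escalation candidate: current retained
  tie <- fixture_bank()$tie_eq2
  st <- candidate_sets_nd(tie$current, tie$grid)
  expect_identical(abs(tie$fhat[1, 1] - tie$p_T), abs(tie$fhat[2, 1] - tie$p_T))
  expect_identical(select_next_dose(tie$fhat, st, tie$p_T), c(1L, 1L))

  # tie between two incomparable candidates: lexicographic (j, then k)
  fh2 <- matrix(c(0.10, 0.25, 0.60,
                  0.25, 0.40, 0.60,
                  0.40, 0.60, 0.80), 3, 3, byrow = TRUE)
  s2 <- candidate_sets_nd(c(2, 2), grid)   # E = {(3,2),(2,3)} both at 0.60
  expect_identical(fh2[3, 2], fh2[2, 3])
  pick <- select_next_dose(fh2, s2, 0.55)
  expect_identical(pick, c(2L, 3L))
  # permutation of the candidate presentation order does not matter
  s2perm <- s2; s2perm$A <- s2$A[rev(seq_len(nrow(s2$A))), ]
  expect_identical(select_next_dose(fh2, s2perm, 0.55), pick)

  # singleton candidate set returns the current dose
  g1 <- dose_grid(u = 1, v = 1)
  s1 <- candidate_sets_nd(c(1, 1), g1)
  expect_identical(select_next_dose(matrix(0.9, 1, 1), s1, 0.3), c(1L, 1L))
})

test_that("titration paths are monotone staircases and steps follow the rules", {
  g <- family_default_grid("logistic4")
  path <- titration_path(g)
  expect_identical(path[1, ], c(1L, 1L))
  expect_identical(path[nrow(path), ], c(4L, 4L))
  steps <- diff(path)
  expect_true(all(rowSums(steps) == 1 & steps >= 0))

  expect_identical(titration_next(path, 1, 0),
                   list(action = "continue", next_position = 2L))
  expect_identical(titration_next(path, 1, 1), list(action = "switch"))
  expect_identical(titration_next(path, nrow(path), 0), list(action = "switch"))
  expect_identical(titration_next(path, nrow(path), 0,
                                  switch_rule = "first_toxicity"),
                   list(action = "hold"))

  expect_error(combcoherence:::validate_titration_path(rbind(c(1, 2)), g),
               "start at")
  expect_error(combcoherence:::validate_titration_path(
    rbind(c(1, 1), c(2, 2)), g), "exactly one")
})

test_that("trials are seed-deterministic and never skip doses", {
  for (fam in c("clayton", "logistic4")) {
    intg <- tiny_integrator(fam)
    sc <- gen_scenario(4, 4, 0.3, seed = 3)
    a <- run_trial("one_stage_nd", intg, sc, 0.3, 12, seed = 77)
    b <- run_trial("one_stage_nd", intg, sc, 0.3, 12, seed = 77)
    expect_identical(a$df, b$df)
    expect_identical(a$theta_hat, b$theta_hat)

    for (design in c("one_stage_nd", "one_stage_d", "two_stage_nd")) {
      tr <- run_trial(design, intg, sc, 0.3, 15, seed = 31)
      dj <- diff(c(tr$df$j, tr$df$next_j[15]))
      dk <- diff(c(tr$df$k, tr$df$next_k[15]))
      if (grepl("_d$", design))
        expect_true(all(abs(dj) + abs(dk) <= 1 |
                          (abs(dj) == 1 & abs(dk) == 1 & dj * dk < 0)))
      else expect_true(all(abs(dj) + abs(dk) <= 1))
      # the same-sign corner moves never occur
      expect_false(any(dj == 1 & dk == 1))
      expect_false(any(dj == -1 & dk == -1))
    }
  }
})

test_that("a single-patient trial records the configured start and no transition", {
  intg <- tiny_integrator("clayton")
  sc <- gen_scenario(4, 4, 0.3, seed = 9)
  tr <- run_trial("one_stage_nd", intg, sc, 0.3, N = 1, seed = 5,
                  start = c(2, 2))
  expect_equal(nrow(tr$df), 1)
  expect_identical(c(tr$df$j, tr$df$k), c(2L, 2L))
})

test_that("two-stage trials follow the path until the switch, then the model rule", {
  intg <- tiny_integrator("logistic4")
  # near-zero toxicity: pure titration to the end of the path, then
  # model-based escalations only (never a de-escalation without toxicity)
  sc0 <- matrix(1e-4, 4, 4) * outer(1:4, 1:4) / 16 +
    outer(1:4, 1:4, function(a, b) (a + b) * 1e-5)
  tr <- run_trial("two_stage_nd", intg, sc0, 0.3, 12, seed = 11)
  path <- titration_path(intg$grid)
  n_tit <- sum(tr$df$stage == "titration")
  expect_equal(n_tit, nrow(path))
  expect_identical(unname(as.matrix(tr$df[seq_len(n_tit), c("j", "k")])),
                   path)
  expect_true(all(tr$df$y == 0))
  dj <- diff(c(tr$df$j, tr$df$next_j[12]))
  dk <- diff(c(tr$df$k, tr$df$next_k[12]))
  expect_true(all(dj >= 0 & dk >= 0))
  expect_identical(tr$M, nrow(path) + 1L)   # switch on path exhaustion

  # certain toxicity at (1,1): immediate switch, M = 2
  sc1 <- tox_scenario(matrix(plogis(outer(1:4, 1:4) + 2), 4, 4) * 0.999)
  tr2 <- run_trial("two_stage_nd", intg, sc1$p, 0.3, 6, seed = 12)
  expect_identical(tr2$df$y[1], 1L)
  expect_identical(tr2$M, 2L)
  expect_identical(tr2$df$stage, c("titration", rep("model", 5)))
})

test_that("one-stage trials start at the prior estimate of the MTD", {
  intg <- tiny_integrator("clayton")
  sc <- gen_scenario(4, 4, 0.3, seed = 2)
  tr <- run_trial("one_stage_nd", intg, sc, 0.3, 2, seed = 8)
  empty <- interim_data(matrix(0, 0, 2), integer(0), intg$grid)
  f0 <- posterior_mean(empty, intg)$fhat
  expect_equal(abs(f0[tr$df$j[1], tr$df$k[1]] - 0.3), min(abs(f0 - 0.3)),
               tolerance = 1e-12)
})

test_that("the unrestricted-argmin control selects the global argmin each step", {
  intg <- tiny_integrator("clayton")
  sc <- gen_scenario(4, 4, 0.3, seed = 14)
  tr <- run_trial("one_stage_nd", intg, sc, 0.3, 8, seed = 3,
                  restrict_candidates = FALSE)
  all_doses <- cbind(rep(1:4, 4), rep(1:4, each = 4))
  for (n in 1:8) {
    fh <- tr$fhat[[n + 1]]
    pick <- combcoherence:::pick_argmin(fh, all_doses, 0.3,
                                        current = c(tr$df$j[n], tr$df$k[n]))
    expect_identical(c(tr$df$next_j[n], tr$df$next_k[n]), pick)
  }
})
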