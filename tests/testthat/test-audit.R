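# Transition classification under weak/strong semantics, the condition
# checkers, and batch summaries — exercised on hand-built micro-traces where
# the expected classification is enumerable.

test_that("audit flags exactly the transitions Definition-1 forbids", {
  grid <- dose_grid(u = 1:3, v = 1:3)
  fh <- outer(1:3, 1:3, function(a, b) 0.1 * a + 0.08 * b)
  # four transitions: escalate after tox (bad), de-escalate after no tox
  # (bad), de-escalate after tox (fine), stay after no tox (fine)
  tr <- manual_trace(grid,
                     doses = rbind(c(2, 2), c(2, 3), c(2, 2), c(1, 2)),
                     ys = c(1, 0, 1, 0),
                     nexts = rbind(c(2, 3), c(2, 2), c(1, 2), c(1, 2)),
                     fhats = rep(list(fh), 4))
  rep <- audit_trace(tr, "weak")
  expect_false(rep$verdict)
  expect_equal(nrow(rep$violations), 2)
  expect_identical(rep$violations$type,
                   c("escalate_after_tox", "deescalate_after_no_tox"))
  expect_identical(rep$violations$n, c(1L, 2L))

  # a coherent trace passes
  tr_ok <- manual_trace(grid,
                        doses = rbind(c(2, 2), c(1, 2), c(1, 2)),
                        ys = c(1, 0, 0),
                        nexts = rbind(c(1, 2), c(1, 2), c(2, 2)),
                        fhats = rep(list(fh), 3))
  expect_true(audit_trace(tr_ok, "weak")$verdict)

  # flagged (unconverged) transitions are excluded but counted
  tr$df$flagged[1] <- TRUE
  rep2 <- audit_trace(tr, "weak")
  expect_equal(rep2$n_excluded, 1L)
  expect_equal(nrow(rep2$violations), 1)
})

test_that("weak and strong audits disagree exactly on misordered diagonals", {
  grid <- dose_grid(u = 1:3, v = 1:3)
  # model ranks (3,1) above (2,2); truth ranks it below
  fh <- outer(1:3, 1:3, function(a, b) 0.15 * a + 0.02 * b)
  truth <- plogis(outer(1:3, 1:3, function(a, b) 0.1 * a + 1.0 * b) - 2)
  expect_gt(fh[3, 1], fh[2, 2])
  expect_lt(truth[3, 1], truth[2, 2])
  tr <- manual_trace(grid, doses = rbind(c(2, 2)), ys = 0,
                     nexts = rbind(c(3, 1)), fhats = list(fh),
                     design = "one_stage_d", scenario = truth)
  expect_true(audit_trace(tr, "weak")$verdict)        # moved into weak E
  strong <- audit_trace(tr, "strong")
  expect_false(strong$verdict)                        # truly a de-escalation
  expect_identical(strong$violations$type, "deescalate_after_no_tox")

  # ND traces give identical reports under both semantics
  tr_nd <- manual_trace(grid, doses = rbind(c(2, 2)), ys = 0,
                        nexts = rbind(c(3, 2)), fhats = list(fh),
                        scenario = truth)
  expect_identical(audit_trace(tr_nd, "weak")$verdict,
                   audit_trace(tr_nd, "strong")$verdict)
})

test_that("with one agent the audit reduces to single-agent coherence", {
  grid <- dose_grid(u = 1:4, v = 0)    # K = 1
  fh <- matrix(c(0.1, 0.25, 0.4, 0.55), 4, 1)
  cases <- list(
    list(from = 2, y = 1, to = 3, bad = TRUE),   # escalate after tox
    list(from = 2, y = 0, to = 1, bad = TRUE),   # de-escalate after no tox
    list(from = 2, y = 1, to = 1, bad = FALSE),
    list(from = 2, y = 0, to = 3, bad = FALSE),
    list(from = 2, y = 1, to = 2, bad = FALSE),
    list(from = 2, y = 0, to = 2, bad = FALSE))
  for (cs in cases) {
    s <- candidate_sets_nd(c(cs$from, 1), grid)
    expect_identical(nrow(s$E), if (cs$from < 4) 1L else 0L)
    tr <- manual_trace(grid, doses = rbind(c(cs$from, 1)), ys = cs$y,
                       nexts = rbind(c(cs$to, 1)), fhats = list(fh))
    expect_identical(!audit_trace(tr, "weak")$verdict, cs$bad,
                     info = sprintf("from %d y %d to %d", cs$from, cs$y,
                                    cs$to))
  }
})

test_that("condition-A products have the expected structure on a real trace", {
  intg <- tiny_integrator("clayton")
  sc <- gen_scenario(4, 4, 0.3, seed = 6)
  tr <- run_trial("one_stage_nd", intg, sc, 0.3, 10, seed = 21)
  ca <- check_condition_A(tr)
  expect_equal(dim(ca$products), c(10, 3))
  expect_true(all(is.finite(ca$products)))
  # the first update from the product prior always satisfies the inequality
  expect_true(all(ca$products[1, ] >= -1e-12))
  expect_identical(ca$verdict, ca$min_product >= -1e-6)
})

test_that("condition-A skips change-point updates on the kink", {
  bank <- fixture_bank()
  kg <- bank$kink_change_point$grid
  th <- bank$kink_change_point$theta
  tr <- structure(list(
    design = "one_stage_nd", family = "change_point", grid = kg, p_T = 0.3,
    N = 1, seed = 0,
    df = data.frame(n = 1L, j = 2L, k = 2L, y = 0L, stage = "model",
                    next_j = 2L, next_k = 2L, ess = Inf, flagged = FALSE),
    theta_hat = rbind(th, th + 1e-3),
    fhat = list(matrix(0.3, 4, 4), matrix(0.3, 4, 4)),
    sets = list(candidate_sets_nd(c(2, 2), kg)),
    M = NA_integer_, scenario = NULL), class = "trial_trace")
  ca <- check_condition_A(tr)
  expect_equal(ca$n_kink_skipped, 1L)
  expect_true(is.na(ca$min_product))
})

test_that("condition B certifies B1 and judges B2 against the true diagonal order", {
  cd <- certified_diag_pair(4, 4, 0.3)
  cb <- check_condition_B(cd$family, cd$grid, cd$scenario, n_thetas = 100,
                          seed = 3, prior = cd$prior)
  expect_true(cb$B1$verdict)
  expect_true(cb$B2$verdict)
  expect_equal(nrow(cb$B2$detail), 9)   # 3x3 interior anti-diagonal pairs

  # reversing the true diagonal order falsifies B2 with a witness
  mis <- gen_misspecified_pair(3, 3, 0.3, seed = 1)
  cb2 <- check_condition_B(mis$family, mis$grid, mis$scenario, n_thetas = 100,
                           seed = 3, prior = mis$prior)
  expect_false(cb2$B2$verdict)
  expect_false(is.null(cb2$B2$witness))
  # the witness reproduces the sign mismatch
  w <- cb2$B2$witness
  fw <- tox_matrix(model_spec(mis$family, w$theta, mis$grid), mis$grid,
                   check = FALSE)
  a <- w$pair[1, ]; b <- w$pair[2, ]
  expect_true(sign(fw[a[1], a[2]] - fw[b[1], b[2]]) !=
                sign(mis$scenario$p[a[1], a[2]] - mis$scenario$p[b[1], b[2]]))

  # K = 1: no anti-diagonal pairs, B2 vacuously true
  g1 <- dose_grid(u = qlogis(c(0.2, 0.4, 0.6)), v = 0)
  sc1 <- matrix(c(0.1, 0.3, 0.5), 3, 1)
  cb3 <- check_condition_B("logistic4", g1, sc1, n_thetas = 20, seed = 4)
  expect_true(cb3$B2$verdict)
  expect_true(cb3$B2$vacuous)
})

test_that("the two-stage switch condition is judged over sampled parameters", {
  grid <- family_default_grid("clayton")
  fh <- matrix(0.3, 4, 4)
  mk <- function(y_last, to) {
    tr <- manual_trace(grid,
                       doses = rbind(c(2, 1), c(2, 2), to),
                       ys = c(0, y_last, 0),
                       nexts = rbind(c(2, 2), to, to),
                       fhats = rep(list(fh), 3), family = "clayton",
                       M = 3L, stage = c("titration", "titration", "model"))
    tr
  }
  # toxicity then a partial-order de-escalation: holds for every theta
  expect_true(check_theorem6_condition(mk(1, c(2, 1)), n_thetas = 100,
                                       seed = 5)$verdict)
  # toxicity then a partial-order escalation: violated, witness returned
  bad <- check_theorem6_condition(mk(1, c(3, 2)), n_thetas = 100, seed = 5)
  expect_false(bad$verdict)
  expect_false(is.null(bad$witness))
  # no toxicity (path exhaustion) then escalation: holds
  expect_true(check_theorem6_condition(mk(0, c(3, 2)), n_thetas = 100,
                                       seed = 5)$verdict)
  # not applicable without a switch
  tr_na <- mk(1, c(2, 1)); tr_na$M <- NA_integer_
  expect_false(check_theorem6_condition(tr_na)$applicable)
})

test_that("batch summaries total the violation types", {
  grid <- dose_grid(u = 1:3, v = 1:3)
  fh <- outer(1:3, 1:3, function(a, b) 0.1 * a + 0.08 * b)
  bad <- manual_trace(grid, doses = rbind(c(2, 2)), ys = 1,
                      nexts = rbind(c(3, 2)), fhats = list(fh))
  ok <- manual_trace(grid, doses = rbind(c(2, 2)), ys = 0,
                     nexts = rbind(c(3, 2)), fhats = list(fh))
  s <- summarize_batch(list(audit_trace(bad, "weak"), audit_trace(ok, "weak")))
  expect_equal(s$n_traces, 2)
  expect_equal(s$n_transitions, 2)
  expect_equal(s$n_violations, 1)
  expect_equal(s$n_escalate_after_tox, 1)
  expect_false(s$verdict)
})
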