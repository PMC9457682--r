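test_that("net drift is the weighted attribute difference plus the bias", {
  trials <- stim_with_diffs(taste = 2, health = -1)
  p <- ddm_params(c(taste = 0.05, health = 0.02))
  expect_equal(net_drift(trials, p), 0.08)

  # zero weights leave only the constant, whatever the stimulus
  p0 <- ddm_params(c(taste = 0, health = 0), drift_constant = 0.37)
  expect_equal(net_drift(stim_with_diffs(3, 3), p0), 0.37)
  expect_equal(net_drift(stim_with_diffs(-2, 1), p0), 0.37)

  # exactly cancelling weights and differences give zero drift
  pc <- ddm_params(c(taste = 0.04, health = 0.02))
  expect_equal(net_drift(stim_with_diffs(1, -2), pc), 0)

  expect_error(net_drift(trials, ddm_params(c(taste = 0.1, other = 0.2))),
               "must match")
})

test_that("the noiseless limit crosses in ceiling(B / (d dt)) steps", {
  # drift chosen so the deterministic ramp clears the boundary strictly
  # between steps (no exact-boundary float ambiguity)
  d <- 0.11
  dt <- 0.01
  p <- ddm_params(c(taste = d, health = 0), threshold = 0.15,
                  noise_sd = 1e-9, step_duration = dt)
  sims <- simulate_ddm(stim_with_diffs(taste = 1), p, n_sims = 20)
  expect_true(all(sims$choice == 1))
  n <- ceiling(0.15 / (d * dt))
  expect_true(all(sims$decision_steps == n))
  # deterministic ramp: EA_k = k d dt, so the activity integral is exact
  expect_equal(sims$neural_activity,
               rep(d * dt^2 * n * (n + 1) / 2, 20), tolerance = 1e-6)
})

test_that("zero net drift yields symmetric choices", {
  set.seed(42)
  p <- ddm_params(c(taste = 0, health = 0))
  sims <- simulate_ddm(stim_with_diffs(0, 0), p, n_sims = 10000)
  p1 <- mean(sims$choice == 1, na.rm = TRUE)
  expect_lt(abs(p1 - 0.5), 3 * p_se(0.5, sum(!is.na(sims$choice))))
})

test_that("mirroring the stimulus and bias mirrors the choice distribution", {
  set.seed(7)
  for (cfg in list(c(1, -2, 0.02), c(2, 1, -0.03), c(-3, 2, 0))) {
    p_fwd <- ddm_params(c(taste = 0.04, health = 0.03),
                        drift_constant = cfg[3])
    p_rev <- ddm_params(c(taste = 0.04, health = 0.03),
                        drift_constant = -cfg[3])
    s1 <- simulate_ddm(stim_with_diffs(cfg[1], cfg[2]), p_fwd, n_sims = 6000)
    s2 <- simulate_ddm(stim_with_diffs(-cfg[1], -cfg[2]), p_rev,
                       n_sims = 6000)
    p1 <- mean(s1$choice == 1, na.rm = TRUE)
    p2 <- mean(s2$choice == 2, na.rm = TRUE)
    expect_lt(abs(p1 - p2), 4 * p_se(p1, 6000))
  }
})

test_that("simulation outcomes satisfy their structural invariants", {
  set.seed(1)
  p <- ddm_params(c(taste = 0.05, health = 0.02), ndt = 0.3)
  sims <- simulate_ddm(build_attribute_grid(c(-3, 3)), p, n_sims = 500)
  done <- !sims$hit_max_steps
  expect_true(all(sims$rt >= p$ndt))
  expect_true(all(sims$decision_steps >= 1))
  # the final evidence sample alone is at least B, so the |EA| integral
  # is at least B * dt
  expect_true(all(sims$neural_activity[done] >=
                    p$threshold * p$step_duration - 1e-12))
  expect_true(all(sims$neural_activity > 0))
})

test_that("paths that never cross are flagged, not dropped", {
  set.seed(2)
  p <- ddm_params(c(taste = 0, health = 0), noise_sd = 0.01)
  sims <- simulate_ddm(stim_with_diffs(0, 0), p, n_sims = 50, max_steps = 3)
  expect_equal(nrow(sims), 50)
  expect_true(all(is.na(sims$choice[sims$hit_max_steps])))
  expect_true(any(sims$hit_max_steps))
  expect_error(simulate_ddm(stim_with_diffs(0, 0), p, max_steps = 0),
               "positive")
  bad <- stim_with_diffs(NA_real_, 1)
  expect_error(simulate_ddm(bad, p), "finite")
})

test_that("simulated boundary-hit rates approach the Wiener closed form", {
  set.seed(3)
  # fine time step so boundary overshoot is negligible
  for (d in c(-0.05, 0, 0.08)) {
    p <- ddm_params(c(taste = d, health = 0), threshold = 0.15,
                    step_duration = 0.002)
    sims <- simulate_ddm(stim_with_diffs(taste = 1), p, n_sims = 8000,
                         max_steps = 50000)
    target <- wiener_upper_prob(d, 0.15, 0.1)
    p1 <- mean(sims$choice == 1, na.rm = TRUE)
    expect_lt(abs(p1 - target), 3 * p_se(target, 8000) + 0.004)
  }
})

test_that("stronger drift speeds decisions and lowers the activity proxy", {
  set.seed(4)
  ladder <- c(0, 0.03, 0.06, 0.09, 0.12)
  stats <- vapply(ladder, function(d) {
    p <- ddm_params(c(taste = d, health = 0))
    s <- simulate_ddm(stim_with_diffs(taste = 1), p, n_sims = 10000)
    ok <- !s$hit_max_steps
    c(rt = mean(s$rt[ok]), act = mean(s$neural_activity[ok]))
  }, numeric(2))
  expect_true(all(diff(stats["rt", ]) < 0))
  expect_true(all(diff(stats["act", ]) < 0))
})

test_that("choices are classified against the normative attribute", {
  # generous: accepting a proposal that favors the partner
  prop <- tibble::tibble(
    attr_self_o1 = 30, attr_self_o2 = 50,
    attr_other_o1 = 70, attr_other_o2 = 50
  )
  expect_equal(as.character(classify_normative(prop, 1, normative = "other")),
               "normative")
  expect_equal(as.character(classify_normative(prop, 2, normative = "other")),
               "hedonistic")
  # rejecting a food healthier than the reference is hedonistic
  food <- stim_with_diffs(taste = 2, health = 1)
  expect_equal(as.character(classify_normative(food, 2)), "hedonistic")
  # exact ties are undefined
  tie <- stim_with_diffs(taste = 2, health = 0)
  expect_equal(as.character(classify_normative(tie, 1)), "undefined")
  # censored choices propagate NA; unknown ids error
  expect_true(is.na(classify_normative(food, NA_integer_)))
  expect_error(classify_normative(food, 3), "Unknown option")
})

test_that("conflict classification follows the sign structure", {
  expect_equal(as.character(classify_conflict(stim_with_diffs(2, -1))),
               "conflict")
  expect_equal(as.character(classify_conflict(stim_with_diffs(2, 3))),
               "no_conflict")
  expect_equal(as.character(classify_conflict(stim_with_diffs(2, 0))),
               "degenerate")
  expect_error(classify_conflict(stim_with_diffs(1, 1), hedonic = "taste",
                                 normative = "taste"), "distinct")
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(ddm_params(c(taste = 0.1), threshold = 0), "threshold")
  expect_error(ddm_params(c(taste = 0.1), noise_sd = 0), "noise_sd")
  expect_error(ddm_params(c(taste = 0.1), ndt = -0.1), "ndt")
  expect_error(ddm_params(c(0.1, 0.2)), "named")
  expect_error(ddm_params(c(taste = Inf)), "finite")
})
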