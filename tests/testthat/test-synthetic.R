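test_that("altruistic proposals always pit one party against the default", {
  set.seed(10)
  tr <- generate_altruistic_trials(1000)
  self_above <- tr$attr_self_o1 > 50
  other_above <- tr$attr_other_o1 > 50
  expect_true(all(xor(self_above, other_above)))
  expect_true(all(tr$attr_self_o1 >= 0 & tr$attr_self_o1 <= 100))
  expect_true(all(tr$attr_other_o1 >= 0 & tr$attr_other_o1 <= 100))
  expect_equal(tr$attr_fairness_o1,
               abs(tr$attr_self_o1 - tr$attr_other_o1))
  expect_true(all(tr$attr_fairness_o2 == 0))

  # the $0-40 / $20-default geometry
  tr2 <- generate_altruistic_trials(500, default = c(20, 20),
                                    range = c(0, 40))
  expect_true(all(xor(tr2$attr_self_o1 > 20, tr2$attr_other_o1 > 20)))
  expect_true(all(tr2$attr_self_o1 <= 40 & tr2$attr_other_o1 <= 40))

  expect_equal(nrow(generate_altruistic_trials(0)), 0)
  expect_error(generate_altruistic_trials(5, default = c(120, 50)),
               "within")
  # a coarser lattice keeps the constraint and the granularity
  tr3 <- generate_altruistic_trials(200, step = 5)
  expect_true(all(tr3$attr_self_o1 %% 5 == 0))
  expect_true(all(xor(tr3$attr_self_o1 > 50, tr3$attr_other_o1 > 50)))
})

test_that("food stimuli cover the requested sign quadrants", {
  set.seed(11)
  tr <- generate_food_trials(400)
  conf <- table(classify_conflict(tr))
  expect_equal(conf[["degenerate"]], 0L)
  expect_lt(abs(conf[["conflict"]] - conf[["no_conflict"]]),
            0.1 * max(conf))

  pos <- generate_food_trials(100, quadrant_probs = c(1, 0, 0, 0))
  expect_true(all(classify_conflict(pos) == "no_conflict"))
  expect_true(all(pos$attr_taste_o1 > 0 & pos$attr_health_o1 > 0))

  # uniform draws over an odd scale produce zero-difference trials at the
  # combinatorial rate 1 - (6/7)^2
  set.seed(12)
  u <- generate_food_trials(4000, scale = -3:3, method = "uniform")
  p_deg <- mean(classify_conflict(u) == "degenerate")
  expect_lt(abs(p_deg - (1 - (6 / 7)^2)), 3 * p_se(13 / 49, 4000))

  expect_equal(nrow(generate_food_trials(0)), 0)
})

test_that("behavior generation respects the deadline and the schema", {
  set.seed(13)
  p <- food_params()
  tr <- generate_behavior(generate_food_trials(120), p)
  expect_true(all(is.na(tr$rt_s[tr$missed])))
  expect_true(all(is.na(tr$choice_binary[tr$missed])))
  expect_true(all(is.na(tr$response_4pt[tr$missed])))
  obs <- !tr$missed
  expect_true(all(tr$rt_s[obs] > 0 & tr$rt_s[obs] <= 4))
  expect_true(all(tr$choice_binary[obs] %in% c("accept", "reject")))
  expect_true(all(tr$response_4pt[obs] %in%
                    c("StrongNo", "No", "Yes", "StrongYes")))
  expect_equal(tr$onset_s, (seq_len(120) - 1) * 8)

  # an impossible deadline censors everything
  slow <- ddm_params(c(taste = 0.004, health = 0.002), ndt = 0.5)
  all_miss <- generate_behavior(generate_food_trials(10), slow,
                                deadline_s = 0.001)
  expect_true(all(all_miss$missed))
})

test_that("generation is reproducible under a fixed seed", {
  set.seed(99)
  a <- generate_behavior(generate_food_trials(50), food_params())
  set.seed(99)
  b <- generate_behavior(generate_food_trials(50), food_params())
  expect_identical(a, b)
})

test_that("empirical choice fractions match the first-passage probability", {
  set.seed(14)
  # fine step so the continuum formula is the right reference
  p <- ddm_params(c(taste = 0.06, health = 0), step_duration = 0.002)
  stim <- stim_with_diffs(taste = 1)[rep(1, 4000), ]
  tr <- generate_behavior(stim, p, deadline_s = 30)
  acc <- mean(tr$choice_binary[!tr$missed] == "accept")
  target <- wiener_upper_prob(0.06, 0.15, 0.1)
  expect_lt(abs(acc - target), 3 * p_se(target, sum(!tr$missed)) + 0.004)
})

test_that("condition-specific parameters are dispatched by label", {
  set.seed(15)
  stim <- generate_food_trials(60)
  stim$condition <- rep(c("Taste", "Health"), each = 30)
  pars <- list(
    Taste = ddm_params(c(taste = 0.2, health = 0), noise_sd = 0.02),
    Health = ddm_params(c(taste = 0, health = 0.2), noise_sd = 0.02)
  )
  tr <- generate_behavior(stim, pars)
  # near-deterministic parameters: choices follow the dominant attribute
  taste_rows <- tr$condition == "Taste" & !tr$missed
  agree <- (tr$choice_binary[taste_rows] == "accept") ==
    (tr$attr_taste_o1[taste_rows] > 0)
  expect_gt(mean(agree), 0.95)
  expect_error(generate_behavior(stim, pars["Taste"]), "Health")
})

test_that("the synthetic cohort carries its generating truth", {
  set.seed(16)
  cohort <- generate_cohort(n_subjects = 3, n_trials = 20)
  expect_equal(nrow(cohort$trials), 3 * 2 * 20)
  expect_setequal(unique(cohort$truth$condition), c("Taste", "Health"))
  truth <- tidyr::pivot_wider(cohort$truth, names_from = "parameter",
                              values_from = "value")
  gap <- ifelse(truth$condition == "Taste",
                truth$w_taste - truth$w_health,
                truth$w_health - truth$w_taste)
  expect_true(all(gap >= 0.0015))
  expect_true(all(c("subject", "condition", "onset_s", "rt_s", "missed")
                  %in% names(cohort$trials)))
})
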