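test_that("gelman_rubin matches its definitional cases", {
  set.seed(30)
  # independent draws from one distribution: R close to 1
  x <- array(rnorm(1500 * 4 * 2), dim = c(1500, 4, 2),
             dimnames = list(NULL, NULL, c("a", "b")))
  r <- gelman_rubin(x)
  expect_named(r, c("a", "b"))
  expect_true(all(r < 1.02))

  # well-separated chains: between-chain variance dominates
  y <- cbind(rnorm(200, 0), rnorm(200, 10))
  expect_gt(gelman_rubin(y), 5)

  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(gelman_rubin(matrix(rnorm(8), ncol = 2)), "10 kept")
})

test_that("an impossible datum gets exactly the smoothing floor", {
  trials <- stim_with_diffs(taste = 1)
  trials$choice_binary <- "accept"
  trials$rt_s <- 0.2
  trials$missed <- FALSE
  p <- ddm_params(c(taste = 0.004, health = 0), ndt = 0.3,
                  step_duration = 0.05)
  set.seed(31)
  # a single trial trivially has one unique RT; that warning is expected
  ll <- suppressWarnings(approximate_log_likelihood(trials, p, n_sims = 500))
  n_bins <- 80
  eps <- 1 / (500 * n_bins)
  expect_equal(ll, log(eps / (500 + eps * (2 * n_bins + 1))))
})

test_that("symmetric stimuli give symmetric accept/reject likelihoods", {
  p <- ddm_params(c(taste = 0, health = 0), ndt = 0.4, step_duration = 0.05)
  base <- stim_with_diffs(taste = 1)[rep(1, 30), ]
  base$rt_s <- seq(0.6, 3.5, length.out = 30)
  base$missed <- FALSE
  acc <- rej <- base
  acc$choice_binary <- "accept"
  rej$choice_binary <- "reject"
  set.seed(32)
  ll_acc <- approximate_log_likelihood(acc, p, n_sims = 4000,
                                       density = "kernel")
  set.seed(32)
  ll_rej <- approximate_log_likelihood(rej, p, n_sims = 4000,
                                       density = "kernel")
  expect_lt(abs(ll_acc - ll_rej), 2)
})

test_that("relabeling the options leaves the likelihood unchanged", {
  set.seed(33)
  p <- ddm_params(c(taste = 0.05, health = 0.02), drift_constant = 0.01,
                  ndt = 0.4, step_duration = 0.05)
  tr <- generate_behavior(generate_food_trials(80),
                          ddm_params(c(taste = 0.05, health = 0.02),
                                     drift_constant = 0.01, ndt = 0.4))
  tr <- tr[!tr$missed, ]
  flipped <- tr
  for (col in c("attr_taste_o1", "attr_taste_o2", "attr_health_o1",
                "attr_health_o2")) {
    flipped[[col]] <- -tr[[col]]
  }
  flipped$choice_binary <- ifelse(tr$choice_binary == "accept", "reject",
                                  "accept")
  p_flip <- ddm_params(c(taste = 0.05, health = 0.02),
                       drift_constant = -0.01, ndt = 0.4,
                       step_duration = 0.05)
  ll1 <- replicate(8, approximate_log_likelihood(tr, p, n_sims = 1000,
                                                 density = "kernel"))
  ll2 <- replicate(8, approximate_log_likelihood(flipped, p_flip,
                                                 n_sims = 1000,
                                                 density = "kernel"))
  expect_lt(abs(mean(ll1) - mean(ll2)), 4 * sd(c(ll1, ll2)))
})

test_that("the likelihood is higher at the generating parameters", {
  set.seed(34)
  truth <- ddm_params(c(self = 0.004, other = 0.002, fairness = -0.001),
                      ndt = 0.4)
  stim <- generate_altruistic_trials(60, step = 5)[rep(1:60, 5), ]
  tr <- generate_behavior(stim, truth)
  at <- function(params) {
    mean(replicate(4, approximate_log_likelihood(
      tr, params, n_sims = 500, density = "kernel"
    )))
  }
  truth_fit <- ddm_params(c(self = 0.004, other = 0.002, fairness = -0.001),
                          ndt = 0.4, step_duration = 0.05)
  doubled <- ddm_params(c(self = 0.008, other = 0.004, fairness = -0.002),
                        ndt = 0.4, step_duration = 0.05)
  expect_gt(at(truth_fit), at(doubled))
})

test_that("out-of-bounds candidates are rejected outright", {
  set.seed(35)
  tr <- food_subject(30)
  b <- ddm_bounds(c("taste", "health"))
  p_out <- ddm_params(c(taste = 0.05, health = 0.001), ndt = 0.4,
                      step_duration = 0.05)
  expect_identical(
    approximate_log_likelihood(tr, p_out, n_sims = 200, bounds = b), -Inf)
  expect_error(
    approximate_log_likelihood(tr[0, ], food_params(), n_sims = 200),
    "empty")
  all_missed <- tr
  all_missed$missed <- TRUE
  all_missed$rt_s <- NA_real_
  all_missed$choice_binary <- NA_character_
  expect_error(
    approximate_log_likelihood(all_missed, food_params(), n_sims = 200),
    "missed")
  expect_error(
    approximate_log_likelihood(tr, food_params(), n_sims = 50), "100")
})

test_that("bounds construction enforces its invariants", {
  b <- ddm_bounds(c("taste", "health"))
  expect_setequal(b$parameter, c("w_taste", "w_health", "drift_constant",
                                 "threshold", "ndt"))
  expect_error(ddm_bounds(character(0)), "non-empty")
  expect_error(ddm_bounds("x", threshold = c(-1, 0.4)), "> 0")
  expect_error(ddm_bounds("x", weights = c(0.02, 0.01)), "lower")
})

test_that("a short DE-MCMC run produces a well-formed, in-bounds fit", {
  set.seed(36)
  tr <- food_subject(60)
  fit <- fit_ddm(tr, n_burn = 30, n_keep = 60, n_sims = 150,
                 density = "kernel", step_duration = 0.1)
  expect_s3_class(fit, "ddm_fit")
  expect_equal(fit$n_chains, 15)  # 3 x 5 free parameters
  expect_equal(dim(fit$samples), c(60, 15, 5))

  # posterior mass respects the uniform prior's support exactly
  b <- fit$bounds
  for (j in seq_along(fit$point_estimates)) {
    prm <- names(fit$point_estimates)[j]
    expect_true(all(fit$samples[, , j] >= b$lower[b$parameter == prm]))
    expect_true(all(fit$samples[, , j] <= b$upper[b$parameter == prm]))
  }
  # the default ndt upper bound respects the fastest observed response
  expect_lte(b$upper[b$parameter == "ndt"], min(tr$rt_s, na.rm = TRUE))

  td <- tidy(fit)
  expect_equal(td$term, names(fit$point_estimates))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_trials, 60)
  expect_true(gl$acceptance_rate >= 0 && gl$acceptance_rate <= 1)
  expect_s3_class(autoplot(fit), "ggplot")

  expect_error(fit_ddm(tr, n_chains = 6), "twice")

  path <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_fit_json(fit, path, chains_csv = csv)
  rep <- jsonlite::read_json(path)
  expect_equal(unlist(rep$point_estimates), fit$point_estimates,
               tolerance = 1e-9)
  chains <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(chains), 60 * 15 * 5)
})

test_that("fitting is reproducible under a recorded seed", {
  set.seed(37)
  tr <- food_subject(40)
  f1 <- fit_ddm(tr, n_burn = 10, n_keep = 20, n_sims = 120, seed = 7,
                density = "kernel", step_duration = 0.1)
  f2 <- fit_ddm(tr, n_burn = 10, n_keep = 20, n_sims = 120, seed = 7,
                density = "kernel", step_duration = 0.1)
  expect_identical(f1$samples, f2$samples)
  expect_equal(f1$seed, 7)
})
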