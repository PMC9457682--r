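#' Simulated (binned first-passage) log-likelihood
#'
#' The model has no closed-form choice/RT likelihood once drift varies by
#' trial, so it is approximated by simulation: for each distinct stimulus,
#' `n_sims` decisions are simulated under the candidate parameters and
#' binned into a choice x RT-bin histogram (`bin_width` seconds wide, RT
#' measured from stimulus onset, one extra cell for paths still undecided
#' at the deadline). Each observed trial contributes the log of its cell's
#' Laplace-smoothed relative frequency, with pseudo-count
#' `eps = 1 / (n_sims * n_bins)` so no observed datum has probability zero;
#' missed trials contribute the censoring mass at the deadline. The
#' estimate is stochastic - fix the RNG seed for repeatable values.
#'
#' With `density = "kernel"` the RT histogram is replaced by a Gaussian
#' kernel density over the simulated RTs of the matching choice (bandwidth
#' `kernel_bw` seconds), floored at `1 / (n_sims * deadline)`; missed
#' trials use the smoothed censoring fraction. The kernel estimator has a
#' markedly lower Monte-Carlo variance than the histogram at the same
#' `n_sims`, which matters when the estimate sits inside a sampler.
#'
#' @param trials A behavioral trial table with paired `attr_*_o1` /
#'   `attr_*_o2` columns plus `choice_binary` (`"accept"` = option 1,
#'   `"reject"` = option 2), `rt_s` and `missed`.
#' @param params A [ddm_params()] candidate.
#' @param n_sims Simulated decisions per distinct stimulus (default 500).
#' @param bin_width RT bin width in seconds (default 0.05).
#' @param deadline Response deadline in seconds (default 4).
#' @param bounds Optional [ddm_bounds()]; a candidate outside the bounds
#'   returns `-Inf` (zero prior mass).
#' @param density `"histogram"` (default) or `"kernel"`; see Details.
#' @param kernel_bw Gaussian kernel bandwidth in seconds (default 0.1,
#'   kernel mode only).
#' @return A single log-likelihood value.
#' @examples
#' set.seed(1)
#' truth <- ddm_params(c(taste = 0.004, health = 0.002), ndt = 0.4)
#' trials <- generate_behavior(generate_food_trials(40), truth)
#' approximate_log_likelihood(trials, truth, n_sims = 200)
#' @export
approximate_log_likelihood <- function(trials, params, n_sims = 500,
                                       bin_width = 0.05, deadline = 4,
                                       bounds = NULL,
                                       density = c("histogram", "kernel"),
                                       kernel_bw = 0.1) {
  stopifnot(is_ddm_params(params))
  attrs <- names(params$weights)
  ll_fn <- make_loglik_fn(trials, attrs, params$noise_sd,
                          params$step_duration, n_sims, bin_width, deadline,
                          bounds, density = match.arg(density),
                          kernel_bw = kernel_bw)
  theta <- c(params$weights, params$drift_constant, params$threshold,
             params$ndt)
  ll_fn(unname(theta))
}

# Precompute everything that does not depend on the candidate parameters
# and return theta -> log-likelihood. theta layout: weights (in `attributes`
# order), drift_constant, threshold, ndt.
make_loglik_fn <- function(trials, attributes, noise_sd, step_duration,
                           n_sims, bin_width, deadline, bounds = NULL,
                           density = "histogram", kernel_bw = 0.1) {
  if (!nrow(trials)) abort("`trials` is empty.")
  if (n_sims < 100) abort("`n_sims` must be at least 100.")
  req <- c("choice_binary", "rt_s", "missed")
  miss_cols <- setdiff(req, names(trials))
  if (length(miss_cols)) {
    abort(paste0("`trials` is missing columns: ",
                 paste(miss_cols, collapse = ", ")))
  }
  missed <- as.logical(trials$missed)
  if (all(missed)) abort("All trials are missed; nothing to fit.")
  rt <- trials$rt_s
  choice <- choice_to_boundary(trials$choice_binary)
  if (any(!missed & (is.na(rt) | is.na(choice)))) {
    abort("Non-missed trials must have `choice_binary` and `rt_s`.")
  }
  if (any(!missed & (rt <= 0 | rt > deadline))) {
    abort("`rt_s` must lie in (0, deadline] on non-missed trials.")
  }
  if (length(unique(rt[!missed])) == 1) {
    warn("All observed RTs are identical; RT carries no information.")
  }

  D <- attribute_diffs(trials, attributes)
  key <- apply(D, 1, paste, collapse = "\r")
  u_idx <- match(key, unique(key))
  Du <- D[!duplicated(key), , drop = FALSE]

  n_bins <- as.integer(ceiling(deadline / bin_width))
  row_len <- 2L * n_bins + 1L
  eps <- 1 / (n_sims * n_bins)
  denom <- n_sims + eps * row_len

  obs_bin <- pmin(floor(rt / bin_width), n_bins - 1L)  # 0-based
  obs_cell <- ifelse(
    missed,
    (u_idx - 1L) * row_len + 2L * n_bins + 1L,
    (u_idx - 1L) * row_len + (choice - 1L) * n_bins + obs_bin + 1L
  )

  k <- length(attributes)
  lower <- upper <- NULL
  if (!is.null(bounds)) {
    validate_bounds(bounds)
    want <- c(paste0("w_", attributes), "drift_constant", "threshold", "ndt")
    pos <- match(want, bounds$parameter)
    if (anyNA(pos)) {
      abort(paste0("`bounds` is missing parameters: ",
                   paste(want[is.na(pos)], collapse = ", ")))
    }
    lower <- bounds$lower[pos]
    upper <- bounds$upper[pos]
  }

  # kernel mode bookkeeping
  obs_choice <- ifelse(missed, 0L, choice)
  obs_rt <- ifelse(missed, 0, rt)
  eps_dens <- 1 / (n_sims * deadline)
  sd_step <- noise_sd * sqrt(step_duration)

  function(theta) {
    if (!is.null(lower) && (any(theta < lower) || any(theta > upper))) {
      return(-Inf)
    }
    w <- theta[seq_len(k)]
    C <- theta[k + 1]
    B <- theta[k + 2]
    ndt <- theta[k + 3]
    if (B <= 0 || ndt < 0) return(-Inf)
    max_steps <- floor((deadline - ndt) / step_duration)
    if (max_steps < 1) {
      # every simulated path is censored at the deadline
      if (density == "kernel") {
        p <- ifelse(missed, (n_sims + 0.5) / (n_sims + 1), eps_dens)
      } else {
        p <- ifelse(missed, (n_sims + eps) / denom, eps / denom)
      }
      return(sum(log(p)))
    }
    drifts <- drop(Du %*% w) + C

    if (density == "histogram") {
      counts <- ddm_fp_histogram_cpp(drifts * step_duration,
                                     as.integer(n_sims), B, sd_step,
                                     as.integer(max_steps), ndt,
                                     step_duration, bin_width, n_bins)
      return(sum(log((counts[obs_cell] + eps) / denom)))
    }

    # kernel density mode
    ddm_kde_loglik_cpp(drifts * step_duration, as.integer(n_sims), B,
                       sd_step, as.integer(max_steps), ndt, step_duration,
                       kernel_bw, eps_dens, u_idx, obs_choice, obs_rt)
  }
}

choice_to_boundary <- function(choice_binary) {
  out <- dplyr::case_when(
    is.na(choice_binary) ~ NA_integer_,
    choice_binary %in% c("accept", "1", "yes") ~ 1L,
    choice_binary %in% c("reject", "2", "no") ~ 2L,
    TRUE ~ -1L
  )
  if (any(out == -1L, na.rm = TRUE)) {
    abort("`choice_binary` must be \"accept\" or \"reject\".")
  }
  out
}

#' Fit the attribute DDM by differential-evolution MCMC
#'
#' Samples the posterior over the free parameters (one weight per
#' attribute, drift constant C, threshold B, non-decision time) under
#' uniform priors, using the simulated likelihood of
#' [approximate_log_likelihood()] inside a differential-evolution MCMC
#' sampler: each chain's proposal is its state plus
#' `gamma * (theta_a - theta_b)` for two other randomly chosen chains plus
#' a small uniform jitter, accepted by a Metropolis step. Chains are
#' initialized over-dispersed (uniform over the prior box). Because the
#' likelihood estimate is stochastic, the current state's likelihood is by
#' default re-estimated alongside each proposal (`refresh = TRUE`), which
#' prevents chains from sticking to lucky estimates. The per-step noise
#' scale stays fixed at `noise_sd`.
#'
#' @inheritParams approximate_log_likelihood
#' @param bounds A [ddm_bounds()] prior box. By default, bounds for the
#'   trial attributes with the non-decision-time upper bound capped at the
#'   smallest observed RT.
#' @param n_chains Number of chains; default `3 * N` where N is the number
#'   of free parameters, minimum `2 * N`.
#' @param n_burn,n_keep Discarded and retained iterations per chain
#'   (defaults 500 and 1500).
#' @param noise_sd Fixed noise scale (default 0.1; not estimated).
#' @param step_duration Euler step used by the simulated likelihood
#'   (default 0.05 s, matching the RT bin width - resolving the simulation
#'   finer than the bins adds cost but no information).
#' @param gamma Differential-evolution step scale; default
#'   `2.38 / sqrt(2 N)`.
#' @param p_gamma1 Fraction of proposals using `gamma = 1` for mode
#'   jumping (default 0.1).
#' @param jitter_width Half-width of the uniform jitter added per
#'   dimension (default 1e-4).
#' @param refresh Re-estimate the current state's log-likelihood at every
#'   iteration (default `TRUE`).
#' @param density,kernel_bw Likelihood density estimator; see
#'   [approximate_log_likelihood()].
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called
#'   first and the value recorded in the result.
#' @return A `ddm_fit` object: posterior `samples` (iteration x chain x
#'   parameter array), posterior-mean `point_estimates`, per-parameter
#'   Gelman-Rubin `rhat`, `acceptance_rate`, the bounds and sampler
#'   settings. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' \donttest{
#' set.seed(7)
#' truth <- ddm_params(c(taste = 0.004, health = 0.002), ndt = 0.4)
#' trials <- generate_behavior(generate_food_trials(60), truth)
#' fit <- fit_ddm(trials, n_burn = 50, n_keep = 100, n_sims = 150)
#' tidy(fit)
#' }
#' @export
fit_ddm <- function(trials, bounds = NULL, n_chains = NULL, n_burn = 500,
                    n_keep = 1500, n_sims = 500, bin_width = 0.05,
                    deadline = 4, noise_sd = 0.1, step_duration = 0.05,
                    gamma = NULL, p_gamma1 = 0.1, jitter_width = 1e-4,
                    refresh = TRUE, seed = NULL,
                    density = c("histogram", "kernel"), kernel_bw = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  density <- match.arg(density)
  attributes <- trial_attributes(trials)
  if (is.null(bounds)) {
    min_rt <- suppressWarnings(min(trials$rt_s, na.rm = TRUE))
    ndt_hi <- if (is.finite(min_rt)) min(1.5, min_rt) else 1.5
    bounds <- ddm_bounds(attributes, ndt = c(min(0.1, ndt_hi / 2), ndt_hi))
  }
  n_par <- length(attributes) + 3L
  if (is.null(n_chains)) n_chains <- 3L * n_par
  if (n_chains < 2L * n_par) {
    abort("`n_chains` must be at least twice the number of free parameters.")
  }
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * n_par)
  stopifnot(n_burn >= 0, n_keep >= 1)

  ll_fn <- make_loglik_fn(trials, attributes, noise_sd, step_duration,
                          n_sims, bin_width, deadline, bounds,
                          density = density, kernel_bw = kernel_bw)
  par_names <- c(paste0("w_", attributes), "drift_constant", "threshold",
                 "ndt")
  pos <- match(par_names, bounds$parameter)
  lower <- bounds$lower[pos]
  upper <- bounds$upper[pos]

  # over-dispersed initialization: uniform over the prior box
  theta <- matrix(runif(n_chains * n_par, rep(lower, each = n_chains),
                        rep(upper, each = n_chains)),
                  nrow = n_chains)
  cur_ll <- apply(theta, 1, ll_fn)

  n_iter <- n_burn + n_keep
  samples <- array(NA_real_, dim = c(n_keep, n_chains, n_par),
                   dimnames = list(NULL, NULL, par_names))
  n_prop <- 0L
  n_acc <- 0L

  for (it in seq_len(n_iter)) {
    for (j in seq_len(n_chains)) {
      if (refresh) cur_ll[j] <- ll_fn(theta[j, ])
      others <- sample.int(n_chains - 1L, 2L)
      others <- others + (others >= j)
      g <- if (runif(1) < p_gamma1) 1 else gamma
      prop <- theta[j, ] + g * (theta[others[1], ] - theta[others[2], ]) +
        runif(n_par, -jitter_width, jitter_width)
      if (any(prop < lower) || any(prop > upper)) {
        prop_ll <- -Inf
      } else {
        prop_ll <- ll_fn(prop)
      }
      if (it > n_burn) n_prop <- n_prop + 1L
      if (is.finite(prop_ll) && log(runif(1)) < prop_ll - cur_ll[j]) {
        theta[j, ] <- prop
        cur_ll[j] <- prop_ll
        if (it > n_burn) n_acc <- n_acc + 1L
      }
    }
    if (it > n_burn) samples[it - n_burn, , ] <- theta
  }

  est <- apply(samples, 3, mean)
  structure(
    list(
      samples = samples,
      point_estimates = setNames(est, par_names),
      rhat = gelman_rubin(samples),
      acceptance_rate = n_acc / n_prop,
      n_chains = n_chains, n_burn = n_burn, n_keep = n_keep,
      bounds = bounds, attributes = attributes,
      settings = list(n_sims = n_sims, bin_width = bin_width,
                      deadline = deadline, noise_sd = noise_sd,
                      step_duration = step_duration, gamma = gamma,
                      p_gamma1 = p_gamma1, jitter_width = jitter_width,
                      refresh = refresh, density = density,
                      kernel_bw = kernel_bw),
      n_trials = nrow(trials),
      seed = seed
    ),
    class = "ddm_fit"
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the classic between/within-chain variance ratio diagnostic per
#' parameter: with m chains of n kept iterations,
#' \eqn{\hat{R} = \sqrt{((n-1)/n\,W + B/n) / W}}, where W is the mean
#' within-chain variance and B/n the variance of the chain means. Values
#' near 1 indicate that the chains have mixed; values above ~1.05 flag
#' non-convergence.
#'
#' @param samples Either an iteration x chain matrix (one parameter) or an
#'   iteration x chain x parameter array, e.g. `fit$samples` from
#'   [fit_ddm()].
#' @return Named numeric vector of \eqn{\hat{R}} values (length 1 for a
#'   matrix input).
#' @examples
#' x <- array(rnorm(4000), dim = c(500, 4, 2),
#'            dimnames = list(NULL, NULL, c("a", "b")))
#' gelman_rubin(x)
#' @export
gelman_rubin <- function(samples) {
  if (is.matrix(samples)) {
    samples <- array(samples, dim = c(dim(samples), 1L))
  }
  if (length(dim(samples)) != 3) {
    abort("`samples` must be an iteration x chain (x parameter) array.")
  }
  n <- dim(samples)[1]
  m <- dim(samples)[2]
  if (m < 2) abort("Gelman-Rubin needs at least 2 chains.")
  if (n < 10) abort("Gelman-Rubin needs at least 10 kept iterations.")
  out <- apply(samples, 3, function(x) {
    chain_means <- colMeans(x)
    W <- mean(apply(x, 2, var))
    B_over_n <- var(chain_means)
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  })
  names(out) <- dimnames(samples)[[3]]
  out
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "<ddm_fit> %d trials, %d chains x %d kept (+%d burn-in)\n",
    x$n_trials, x$n_chains, x$n_keep, x$n_burn
  ))
  cat(sprintf("  acceptance rate: %.3f, max R-hat: %.3f\n",
              x$acceptance_rate, max(x$rhat)))
  print(tidy(x))
  invisible(x)
}

#' Tidy a DDM fit
#'
#' @param x A `ddm_fit` object.
#' @param conf_level Central credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean
#'   (`estimate`), posterior sd (`std.error`), central credible interval
#'   and Gelman-Rubin `rhat`.
#' @method tidy ddm_fit
#' @export
tidy.ddm_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  flat <- apply(x$samples, 3, identity)  # (iter*chain) x param
  tibble::tibble(
    term = names(x$point_estimates),
    estimate = unname(x$point_estimates),
    std.error = apply(flat, 2, stats::sd),
    conf.low = apply(flat, 2, quantile, probs = a),
    conf.high = apply(flat, 2, quantile, probs = 1 - a),
    rhat = unname(x$rhat)
  )
}

#' One-row summary of a DDM fit
#'
#' @param x A `ddm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: trial count, sampler dimensions, acceptance
#'   rate and the largest per-parameter Gelman-Rubin statistic.
#' @method glance ddm_fit
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials,
    n_parameters = length(x$point_estimates),
    n_chains = x$n_chains,
    n_burn = x$n_burn,
    n_keep = x$n_keep,
    acceptance_rate = x$acceptance_rate,
    max_rhat = max(x$rhat)
  )
}

#' Write a fit report as JSON
#'
#' Serializes point estimates, convergence diagnostics, prior bounds and
#' sampler settings (including the seed, when one was recorded) to a JSON
#' file; posterior draws can optionally be written alongside as a flat CSV.
#'
#' @param fit A `ddm_fit` object.
#' @param path Output JSON path.
#' @param chains_csv Optional path for a long-format CSV of posterior draws
#'   (`iteration`, `chain`, `parameter`, `value`).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, chains_csv = NULL) {
  stopifnot(inherits(fit, "ddm_fit"))
  report <- list(
    point_estimates = as.list(fit$point_estimates),
    rhat = as.list(fit$rhat),
    acceptance_rate = fit$acceptance_rate,
    n_trials = fit$n_trials,
    n_chains = fit$n_chains, n_burn = fit$n_burn, n_keep = fit$n_keep,
    bounds = as.data.frame(fit$bounds),
    settings = fit$settings,
    seed = fit$seed
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(chains_csv)) {
    long <- as.data.frame.table(fit$samples, responseName = "value")
    names(long) <- c("iteration", "chain", "parameter", "value")
    long$iteration <- as.integer(long$iteration)
    long$chain <- as.integer(long$chain)
    readr::write_csv(tibble::as_tibble(long), chains_csv)
  }
  invisible(path)
}
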