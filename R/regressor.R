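#' Model-predicted trial-wise neural activity
#'
#' For each observed (non-missed) trial, simulates `n_sims` decisions under
#' the supplied (typically best-fitting) parameters and averages the neural
#' activity proxy \eqn{\sum_t |EA_t|} over the simulations that terminate in
#' the observed binary choice with a simulated RT (decision time plus
#' non-decision time) within `window_s` of the observed RT. When no
#' simulation matches, a fallback ladder engages, each level flagged in the
#' output: the RT window widens in `window_s` increments up to
#' `max_window_s`; failing that, simulations are matched on choice alone;
#' failing that, the prediction is `NA` (`fallback_level = "missing"`).
#'
#' @inheritParams approximate_log_likelihood
#' @param params A [ddm_params()] object (e.g. posterior means from
#'   [fit_ddm()] via [params_from_fit()]).
#' @param n_sims Simulations per trial (default 10000, minimum 100).
#' @param window_s RT matching half-window in seconds (default 0.25).
#' @param max_window_s Widest half-window tried before matching on choice
#'   only (default 1).
#' @param chunk_size Trials simulated per batch, to bound memory.
#' @return A `ddm_predictions` tibble with one row per trial: `trial`,
#'   `observed_choice`, `observed_rt`, `n_matching_sims`,
#'   `predicted_activity`, `window_used_s` and `fallback_level`
#'   (`none`, `widened_window`, `choice_only` or `missing`).
#' @examples
#' set.seed(1)
#' truth <- ddm_params(c(taste = 0.004, health = 0.002), ndt = 0.4)
#' trials <- dplyr::filter(generate_behavior(generate_food_trials(5), truth),
#'                         !missed)
#' predict_trial_activity(trials, truth, n_sims = 500)
#' @export
predict_trial_activity <- function(trials, params, n_sims = 10000,
                                   window_s = 0.25, max_window_s = 1,
                                   deadline = 4, chunk_size = 64) {
  stopifnot(is_ddm_params(params), window_s > 0,
            max_window_s >= window_s)
  if (n_sims < 100) abort("`n_sims` must be at least 100.")
  req <- setdiff(c("choice_binary", "rt_s", "missed"), names(trials))
  if (length(req)) {
    abort(paste0("`trials` is missing columns: ", paste(req, collapse = ", ")))
  }
  if (any(as.logical(trials$missed))) {
    abort("`trials` contains missed trials; drop them before predicting.")
  }
  obs_choice <- choice_to_boundary(trials$choice_binary)
  obs_rt <- trials$rt_s
  windows <- seq(window_s, max_window_s, by = window_s)

  n <- nrow(trials)
  out <- vector("list", ceiling(n / chunk_size))
  for (ci in seq_along(out)) {
    idx <- ((ci - 1) * chunk_size + 1):min(ci * chunk_size, n)
    sims <- simulate_ddm(trials[idx, , drop = FALSE], params,
                         n_sims = n_sims, deadline = deadline)
    out[[ci]] <- purrr::map_dfr(seq_along(idx), function(i) {
      s <- sims[sims$trial == i & !sims$hit_max_steps, ]
      ch_ok <- s$choice == obs_choice[idx[i]]
      dt <- abs(s$rt - obs_rt[idx[i]])
      level <- "missing"
      used <- NA_real_
      sel <- logical(0)
      for (w in windows) {
        sel <- ch_ok & dt <= w
        if (any(sel)) {
          level <- if (w == windows[1]) "none" else "widened_window"
          used <- w
          break
        }
      }
      if (!any(sel) && any(ch_ok)) {
        sel <- ch_ok
        level <- "choice_only"
      }
      tibble::tibble(
        trial = idx[i],
        observed_choice = obs_choice[idx[i]],
        observed_rt = obs_rt[idx[i]],
        n_matching_sims = sum(sel),
        predicted_activity = if (any(sel)) mean(s$neural_activity[sel])
                             else NA_real_,
        window_used_s = used,
        fallback_level = level
      )
    })
  }
  res <- dplyr::bind_rows(out)
  res$fallback_level <- factor(
    res$fallback_level,
    levels = c("none", "widened_window", "choice_only", "missing")
  )
  class(res) <- c("ddm_predictions", class(res))
  res
}

#' Point-estimate parameters from a fit
#'
#' Repackages a fit's posterior means as a [ddm_params()] object suitable
#' for simulation and regressor construction.
#'
#' @param fit A `ddm_fit` object.
#' @return A [ddm_params()] object.
#' @export
params_from_fit <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  est <- fit$point_estimates
  params_from_vector(unname(est), fit$attributes,
                     fit$settings$noise_sd, fit$settings$step_duration)
}

#' Assemble an fMRI event table from predictions
#'
#' Pairs trial-wise predictions with trial onsets to build the standard
#' three-column event representation: onset, duration (= observed RT) and
#' amplitude (= predicted activity, the parametric modulator of a boxcar
#' spanning the choice period). Trials with missing predictions are
#' dropped with a message; amplitudes can be mean-centered.
#'
#' @param predictions A `ddm_predictions` tibble from
#'   [predict_trial_activity()].
#' @param trials The trial table the predictions refer to (row-aligned via
#'   `predictions$trial`); must carry `onset_s` and `rt_s`.
#' @param mean_center Mean-center amplitudes (default `FALSE`).
#' @return A tibble with columns `onset_s`, `duration_s`, `amplitude`.
#' @examples
#' set.seed(1)
#' truth <- ddm_params(c(taste = 0.004, health = 0.002), ndt = 0.4)
#' trials <- dplyr::filter(generate_behavior(generate_food_trials(5), truth),
#'                         !missed)
#' preds <- predict_trial_activity(trials, truth, n_sims = 500)
#' build_event_table(preds, trials)
#' @export
build_event_table <- function(predictions, trials, mean_center = FALSE) {
  if (!all(c("onset_s", "rt_s") %in% names(trials))) {
    abort("`trials` must have `onset_s` and `rt_s` columns.")
  }
  keep <- !is.na(predictions$predicted_activity)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " trial(s) without a prediction omitted from the ",
            "event table.")
  }
  p <- predictions[keep, , drop = FALSE]
  out <- tibble::tibble(
    onset_s = trials$onset_s[p$trial],
    duration_s = trials$rt_s[p$trial],
    amplitude = p$predicted_activity
  )
  out <- dplyr::arrange(out, .data$onset_s)
  if (nrow(out) > 1 &&
      any(head(out$onset_s + out$duration_s, -1) > out$onset_s[-1])) {
    warn("Some events overlap the next trial's onset.")
  }
  if (mean_center && nrow(out)) {
    out$amplitude <- out$amplitude - mean(out$amplitude)
  }
  out
}

#' Write a three-column event file
#'
#' Writes `onset duration amplitude` rows, whitespace-delimited without a
#' header - the layout fMRI design tools expect for a single explanatory
#' variable.
#'
#' @param events An event table from [build_event_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_file <- function(events, path) {
  stopifnot(all(c("onset_s", "duration_s", "amplitude") %in% names(events)))
  utils::write.table(
    events[c("onset_s", "duration_s", "amplitude")], path,
    sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}
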