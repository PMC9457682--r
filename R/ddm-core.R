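#' Attribute columns of a trial table
#'
#' Trial tables represent each binary choice as a row, with the two options'
#' attribute values in paired columns named `attr_<name>_o1` (option 1, the
#' proposal / displayed food) and `attr_<name>_o2` (option 2, the default /
#' reference). `trial_attributes()` lists the attribute names present;
#' `attribute_diffs()` returns the per-trial option-1-minus-option-2
#' differences as a numeric matrix with one column per attribute.
#'
#' @param trials A data frame of trials with paired `attr_*_o1`/`attr_*_o2`
#'   columns.
#' @return `trial_attributes()`: a character vector. `attribute_diffs()`:
#'   a numeric matrix with `nrow(trials)` rows.
#' @examples
#' grid <- build_attribute_grid(-1:1)
#' trial_attributes(grid)
#' head(attribute_diffs(grid))
#' @export
trial_attributes <- function(trials) {
  nm <- names(trials)
  o1 <- sub("^attr_(.+)_o1$", "\\1", grep("^attr_.+_o1$", nm, value = TRUE))
  o2 <- sub("^attr_(.+)_o2$", "\\1", grep("^attr_.+_o2$", nm, value = TRUE))
  unpaired <- c(setdiff(o1, o2), setdiff(o2, o1))
  if (length(unpaired)) {
    abort(paste0("Attribute columns without an option pair: ",
                 paste(unique(unpaired), collapse = ", ")))
  }
  o1
}

#' @rdname trial_attributes
#' @param attributes Optional character vector selecting/ordering attributes;
#'   defaults to all attributes found in `trials`.
#' @export
attribute_diffs <- function(trials, attributes = NULL) {
  found <- trial_attributes(trials)
  if (is.null(attributes)) attributes <- found
  missing_a <- setdiff(attributes, found)
  if (length(missing_a)) {
    abort(paste0("Attributes not present in `trials`: ",
                 paste(missing_a, collapse = ", ")))
  }
  m1 <- as.matrix(trials[paste0("attr_", attributes, "_o1")])
  m2 <- as.matrix(trials[paste0("attr_", attributes, "_o2")])
  if (!is.numeric(m1) || !is.numeric(m2)) {
    abort("Attribute columns must be numeric.")
  }
  if (any(!is.finite(m1)) || any(!is.finite(m2))) {
    abort("Attribute values must be finite.")
  }
  d <- m1 - m2
  colnames(d) <- attributes
  d
}

#' Per-step net drift of each trial
#'
#' The deterministic part of the evidence accumulation rate:
#' \eqn{d = \sum_i w_i (A_{i1} - A_{i2}) + C}. Positive drift pushes the
#' accumulator toward option 1's boundary.
#'
#' @param trials A trial table (see [trial_attributes()]).
#' @param params A [ddm_params()] object whose weight names match the trial
#'   attributes exactly.
#' @return Numeric vector, one net drift rate per trial (evidence per
#'   second).
#' @examples
#' grid <- build_attribute_grid(-1:1)
#' net_drift(grid, ddm_params(c(taste = 0.05, health = 0.02)))
#' @export
net_drift <- function(trials, params) {
  stopifnot(is_ddm_params(params))
  attrs <- names(params$weights)
  found <- trial_attributes(trials)
  if (!setequal(attrs, found)) {
    abort(paste0(
      "Weight names and trial attributes must match. Weights: ",
      paste(sort(attrs), collapse = ", "), "; trials: ",
      paste(sort(found), collapse = ", ")
    ))
  }
  d <- attribute_diffs(trials, attrs)
  drop(d %*% params$weights) + params$drift_constant
}

#' Simulate the drift diffusion model over a trial table
#'
#' Runs the two-boundary accumulator `n_sims` times for every trial row:
#' evidence starts at 0 and moves each Euler step of length `step_duration`
#' by `net_drift * step_duration` plus
#' `N(0, noise_sd * sqrt(step_duration))` noise, until it first reaches
#' `+threshold` (choice of option 1) or `-threshold` (option 2), inclusive.
#' Paths that have not crossed after `max_steps` steps are returned with
#' `choice = NA` and `hit_max_steps = TRUE` rather than dropped.
#'
#' Randomness comes from R's RNG: call `set.seed()` beforehand for
#' reproducible simulations.
#'
#' @inheritParams net_drift
#' @param n_sims Simulated decisions per trial row.
#' @param deadline Response deadline in seconds, used for the default
#'   step cap. Default 4.
#' @param max_steps Cap on accumulation steps; default
#'   `ceiling(deadline / step_duration)`.
#' @return A tibble with one row per trial x simulation: `trial`, `sim`,
#'   `choice` (1, 2 or `NA`), `decision_steps`, `rt` (seconds,
#'   `ndt + decision_steps * step_duration`), `neural_activity` (the time
#'   integral \eqn{\sum_t |EA_t| \Delta t} over the decision, in
#'   evidence-seconds; non-decision time contributes nothing) and
#'   `hit_max_steps`.
#' @examples
#' set.seed(1)
#' grid <- build_attribute_grid(c(-3, 3))
#' sims <- simulate_ddm(grid, ddm_params(c(taste = 0.05, health = 0.02)),
#'                      n_sims = 100)
#' dplyr::count(sims, trial, choice)
#' @export
simulate_ddm <- function(trials, params, n_sims = 1, deadline = 4,
                         max_steps = NULL) {
  stopifnot(is_ddm_params(params), n_sims >= 1)
  if (is.null(max_steps)) {
    max_steps <- ceiling(deadline / params$step_duration)
  }
  if (max_steps <= 0) abort("`max_steps` must be a positive integer.")
  dt <- params$step_duration
  drifts <- net_drift(trials, params)
  n <- length(drifts)
  res <- ddm_simulate_cpp(rep(drifts * dt, each = n_sims),
                          params$threshold, params$noise_sd * sqrt(dt),
                          as.integer(max_steps))
  tibble::tibble(
    trial = rep(seq_len(n), each = n_sims),
    sim = rep(seq_len(n_sims), times = n),
    choice = res$choice,
    decision_steps = res$decision_steps,
    rt = params$ndt + res$decision_steps * dt,
    neural_activity = res$neural_activity * dt,
    hit_max_steps = res$hit_max_steps
  )
}

#' Classify choices as normative or hedonistic
#'
#' A choice is *normative* when the chosen option has the strictly larger
#' unweighted value on the normative attribute (e.g. accepting the more
#' generous proposal, or accepting a food healthier than the reference);
#' *hedonistic* when strictly smaller; and *undefined* on exact ties, which
#' downstream aggregates exclude.
#'
#' @inheritParams net_drift
#' @param chosen Integer vector of chosen options (1 = option 1 / upper
#'   boundary, 2 = option 2 / lower boundary), recycled if length 1. `NA`
#'   (e.g. censored simulations) yields `NA`.
#' @param normative Name of the normative attribute (default `"health"`).
#' @return Factor with levels `normative`, `hedonistic`, `undefined`.
#' @examples
#' trials <- tibble::tibble(attr_self_o1 = 30, attr_self_o2 = 50,
#'                          attr_other_o1 = 70, attr_other_o2 = 50)
#' classify_normative(trials, chosen = 1, normative = "other")
#' @export
classify_normative <- function(trials, chosen, normative = "health") {
  found <- trial_attributes(trials)
  if (!normative %in% found) {
    abort(paste0("Normative attribute `", normative, "` not in trials."))
  }
  n <- nrow(trials)
  if (length(chosen) == 1) chosen <- rep(chosen, n)
  if (length(chosen) != n) {
    abort("`chosen` must have one element per trial (or length 1).")
  }
  bad <- !is.na(chosen) & !chosen %in% c(1L, 2L)
  if (any(bad)) {
    abort(paste0("Unknown option id(s): ",
                 paste(unique(chosen[bad]), collapse = ", ")))
  }
  v1 <- trials[[paste0("attr_", normative, "_o1")]]
  v2 <- trials[[paste0("attr_", normative, "_o2")]]
  chosen_v <- ifelse(chosen == 1L, v1, v2)
  other_v <- ifelse(chosen == 1L, v2, v1)
  out <- dplyr::case_when(
    is.na(chosen) ~ NA_character_,
    chosen_v > other_v ~ "normative",
    chosen_v < other_v ~ "hedonistic",
    TRUE ~ "undefined"
  )
  factor(out, levels = c("normative", "hedonistic", "undefined"))
}

#' Classify trials by attribute conflict
#'
#' A trial is a *conflict* trial when the option-1-minus-option-2 differences
#' on the hedonic and normative attributes have strictly opposite signs (one
#' option is e.g. tastier while the other is healthier), *no_conflict* when
#' they share a sign, and *degenerate* when either difference is exactly 0.
#'
#' @inheritParams net_drift
#' @param hedonic,normative Names of the hedonic and normative attributes.
#' @return Factor with levels `conflict`, `no_conflict`, `degenerate`.
#' @examples
#' grid <- build_attribute_grid(c(-1, 0, 1))
#' table(classify_conflict(grid))
#' @export
classify_conflict <- function(trials, hedonic = "taste",
                              normative = "health") {
  if (identical(hedonic, normative)) {
    abort("`hedonic` and `normative` must be distinct attributes.")
  }
  d <- attribute_diffs(trials, c(hedonic, normative))
  dh <- d[, 1]
  dn <- d[, 2]
  out <- dplyr::case_when(
    dh == 0 | dn == 0 ~ "degenerate",
    sign(dh) != sign(dn) ~ "conflict",
    TRUE ~ "no_conflict"
  )
  factor(out, levels = c("conflict", "no_conflict", "degenerate"))
}

#' Closed-form boundary-hit probability in the diffusion limit
#'
#' For a continuous Wiener process with drift rate `d`, noise scale `sigma`
#' and symmetric boundaries at `+/-B`, the probability of absorption at the
#' upper boundary is \eqn{1 / (1 + \exp(-2 d B / \sigma^2))}. The simulated
#' accumulator converges to this value as `step_duration` shrinks (boundary
#' far relative to a single step's noise); at coarse steps boundary
#' overshoot biases the simulated probability away from it.
#'
#' @param drift Net drift rate.
#' @param threshold Boundary B.
#' @param noise_sd Per-step noise standard deviation.
#' @return Probability of hitting the upper (option 1) boundary.
#' @examples
#' wiener_upper_prob(0.05, threshold = 0.15, noise_sd = 0.1)
#' @export
wiener_upper_prob <- function(drift, threshold, noise_sd) {
  stats::plogis(2 * drift * threshold / noise_sd^2)
}
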