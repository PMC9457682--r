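#' Generate altruistic-choice (dictator-style) proposals
#'
#' Each trial offers a proposed prize pair (`$Self`, `$Other`) against a
#' constant default pair. Proposals are drawn (integer dollars) so that
#' exactly one party stands strictly above their default amount while the
#' other is at or below it - every trial therefore trades generosity
#' against self-interest. Three attribute columns are materialized relative
#' to the default: `self` and `other` payoffs, plus a derived `fairness`
#' attribute equal to the absolute self-other gap of each option (so the
#' accumulator itself stays attribute-agnostic). The chooser's decision is
#' implemented probabilistically in the original task (the chosen option is
#' delivered on 60% of trials); that payout rule only affects incentives,
#' not the decision model, and is not represented here.
#'
#' @param n Number of trials.
#' @param default Length-2 numeric, the default `c(self, other)` amounts
#'   (default `c(50, 50)`).
#' @param range Length-2 numeric, inclusive prize range (default
#'   `c(0, 100)`).
#' @param step Dollar granularity of the proposal lattice (default 1);
#'   coarser steps yield repeated stimuli, as in designs that present each
#'   proposal several times.
#' @return A tibble of `n` stimuli with `attr_self_*`, `attr_other_*` and
#'   `attr_fairness_*` columns. The hedonic attribute is `self`, the
#'   normative attribute `other`.
#' @examples
#' set.seed(1)
#' generate_altruistic_trials(3)
#' @export
generate_altruistic_trials <- function(n, default = c(50, 50),
                                       range = c(0, 100), step = 1) {
  stopifnot(n >= 0, length(default) == 2, length(range) == 2, step > 0)
  if (any(default < range[1]) || any(default > range[2])) {
    abort("`default` must lie within `range`.")
  }
  if (default[1] >= range[2] && default[2] >= range[2]) {
    abort("No prize strictly above the default fits in `range`.")
  }
  if (n == 0) {
    return(empty_altruistic())
  }
  draw_from <- function(vals) {
    if (!length(vals)) abort("Empty proposal lattice; check range/step.")
    vals[sample.int(length(vals), n, replace = TRUE)]
  }
  above <- function(default_amt) {
    if (default_amt + step > range[2]) return(numeric(0))
    seq(default_amt + step, range[2], by = step)
  }
  at_or_below <- function(default_amt) seq(range[1], default_amt, by = step)
  # which party receives more than their default on this proposal
  above_self <- runif(n) < 0.5
  self <- ifelse(above_self, draw_from(above(default[1])),
                 draw_from(at_or_below(default[1])))
  other <- ifelse(above_self, draw_from(at_or_below(default[2])),
                  draw_from(above(default[2])))
  tibble::tibble(
    attr_self_o1 = self, attr_self_o2 = default[1],
    attr_other_o1 = other, attr_other_o2 = default[2],
    attr_fairness_o1 = abs(self - other),
    attr_fairness_o2 = abs(default[1] - default[2])
  )
}

empty_altruistic <- function() {
  tibble::tibble(
    attr_self_o1 = numeric(), attr_self_o2 = numeric(),
    attr_other_o1 = numeric(), attr_other_o2 = numeric(),
    attr_fairness_o1 = numeric(), attr_fairness_o2 = numeric()
  )
}

#' Generate dietary-choice stimuli
#'
#' Each trial displays one food against a constant reference food rated
#' neutral (0) on both tastiness and healthiness; ratings are integer
#' offsets from that neutral point. With `method = "quadrant"` (default)
#' trials are drawn by sign quadrant - `(+,+)`, `(+,-)`, `(-,+)`, `(-,-)`
#' for (taste, health) - with configurable mixing proportions, so the
#' conflict / no-conflict composition is controlled by construction. With
#' `method = "uniform"` both ratings are drawn uniformly over `scale`,
#' which also produces zero-difference (degenerate) trials.
#'
#' @param n Number of trials.
#' @param scale Integer rating scale relative to neutral (default `-2:2`).
#' @param quadrant_probs Length-4 numeric mixing proportions for quadrants
#'   `(+,+)`, `(+,-)`, `(-,+)`, `(-,-)`; normalized internally. Default
#'   balanced.
#' @param method `"quadrant"` or `"uniform"`.
#' @return A tibble of `n` stimuli with `attr_taste_*` and `attr_health_*`
#'   columns (option 2 is the neutral reference at 0). The hedonic
#'   attribute is `taste`, the normative attribute `health`.
#' @examples
#' set.seed(1)
#' table(classify_conflict(generate_food_trials(400)))
#' @export
generate_food_trials <- function(n, scale = -2:2,
                                 quadrant_probs = rep(0.25, 4),
                                 method = c("quadrant", "uniform")) {
  method <- match.arg(method)
  stopifnot(n >= 0, length(quadrant_probs) == 4, all(quadrant_probs >= 0))
  scale <- sort(unique(as.integer(scale)))
  pos <- scale[scale > 0]
  neg <- scale[scale < 0]
  if (method == "quadrant" && (!length(pos) || !length(neg))) {
    abort("`scale` must contain positive and negative levels.")
  }
  if (n == 0) {
    return(tibble::tibble(
      attr_taste_o1 = integer(), attr_taste_o2 = integer(),
      attr_health_o1 = integer(), attr_health_o2 = integer()
    ))
  }
  if (method == "uniform") {
    taste <- sample(scale, n, replace = TRUE)
    health <- sample(scale, n, replace = TRUE)
  } else {
    q <- sample.int(4, n, replace = TRUE,
                    prob = quadrant_probs / sum(quadrant_probs))
    draw <- function(set) set[sample.int(length(set), n, replace = TRUE)]
    taste <- ifelse(q %in% c(1, 2), draw(pos), draw(neg))
    health <- ifelse(q %in% c(1, 3), draw(pos), draw(neg))
  }
  tibble::tibble(
    attr_taste_o1 = as.integer(taste), attr_taste_o2 = 0L,
    attr_health_o1 = as.integer(health), attr_health_o2 = 0L
  )
}

#' Generate choices and response times from known parameters
#'
#' Simulates each stimulus once with the accumulator under its condition's
#' true parameters: the boundary reached maps to an accept (option 1) /
#' reject (option 2) choice, RT is decision time plus non-decision time,
#' and trials whose RT would exceed `deadline_s` (or whose path never
#' crosses) are marked missed with choice and RT missing. A 4-point
#' response is synthesized as schema plumbing only: boundary sign gives
#' Yes/No, and trials whose absolute net drift exceeds the within-condition
#' median are labeled "Strong".
#'
#' @param stimuli A stimulus table (e.g. from
#'   [generate_altruistic_trials()] or [generate_food_trials()]). May
#'   already carry `subject` / `condition` columns.
#' @param params A [ddm_params()] object, or a named list of them keyed by
#'   condition label when `stimuli$condition` is present.
#' @param deadline_s Response deadline in seconds (default 4).
#' @param onset_spacing_s Trial onset asynchrony used to lay out
#'   `onset_s` (default 8).
#' @return A tibble in the canonical trial schema: `subject`, `condition`,
#'   `onset_s`, the stimulus `attr_*` columns, `response_4pt`,
#'   `choice_binary`, `rt_s`, `missed`.
#' @examples
#' set.seed(1)
#' truth <- ddm_params(c(taste = 0.004, health = 0.002), ndt = 0.4)
#' generate_behavior(generate_food_trials(5), truth)
#' @export
generate_behavior <- function(stimuli, params, deadline_s = 4,
                              onset_spacing_s = 8) {
  stopifnot(deadline_s > 0)
  n <- nrow(stimuli)
  condition <- if ("condition" %in% names(stimuli)) {
    as.character(stimuli$condition)
  } else {
    rep("Natural", n)
  }
  if (is_ddm_params(params)) {
    params <- setNames(
      rep(list(params), length(unique(condition))), unique(condition)
    )
  }
  missing_cond <- setdiff(unique(condition), names(params))
  if (length(missing_cond)) {
    abort(paste0("No parameters for condition(s): ",
                 paste(missing_cond, collapse = ", ")))
  }

  choice <- integer(n)
  rt <- numeric(n)
  drift <- numeric(n)
  strong <- logical(n)
  for (cond in unique(condition)) {
    idx <- which(condition == cond)
    p <- params[[cond]]
    stopifnot(is_ddm_params(p))
    sims <- simulate_ddm(stimuli[idx, , drop = FALSE], p, n_sims = 1,
                         deadline = deadline_s)
    choice[idx] <- sims$choice
    rt[idx] <- sims$rt
    d <- net_drift(stimuli[idx, , drop = FALSE], p)
    drift[idx] <- d
    strong[idx] <- abs(d) > median(abs(d))
  }
  missed <- is.na(choice) | rt > deadline_s
  choice_binary <- dplyr::if_else(choice == 1L, "accept", "reject")
  response_4pt <- dplyr::case_when(
    choice == 1L & strong ~ "StrongYes",
    choice == 1L ~ "Yes",
    choice == 2L & strong ~ "StrongNo",
    TRUE ~ "No"
  )
  out <- tibble::tibble(
    subject = if ("subject" %in% names(stimuli)) stimuli$subject else 1L,
    condition = condition,
    onset_s = (seq_len(n) - 1) * onset_spacing_s
  )
  out <- dplyr::bind_cols(
    out, dplyr::select(stimuli, dplyr::starts_with("attr_"))
  )
  dplyr::mutate(
    out,
    response_4pt = ifelse(missed, NA_character_, response_4pt),
    choice_binary = ifelse(missed, NA_character_, choice_binary),
    rt_s = ifelse(missed, NA_real_, rt),
    missed = missed
  )
}

#' Generate a synthetic cohort with known truth
#'
#' Convenience wrapper building a multi-subject, multi-condition dataset of
#' the kind the fitting and regressor stages expect, together with the
#' generating ("truth") parameter table used to score parameter recovery.
#' Per-subject true attribute weights are drawn uniformly with the dominant
#' attribute's weight at least `weight_gap` above the other's, mimicking a
#' goal manipulation that meaningfully separates the two weights.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param n_trials Trials per subject and condition (default 100).
#' @param conditions Named list: for each condition label, the attribute
#'   name that dominates (`"taste"` or `"health"`). Default
#'   `list(Taste = "taste", Health = "health")`.
#' @param weight_range Range the true weights are drawn from (default
#'   `c(0.001, 0.006)`).
#' @param weight_gap Minimum dominant-minus-subordinate weight gap
#'   (default 0.0015).
#' @param threshold,ndt,noise_sd,step_duration Remaining true parameters
#'   shared by all subjects.
#' @param deadline_s Response deadline (default 4).
#' @return A list with `trials` (canonical trial tibble over all subjects)
#'   and `truth` (tibble: `subject`, `condition`, `parameter`, `value`).
#' @examples
#' set.seed(1)
#' cohort <- generate_cohort(n_subjects = 2, n_trials = 20)
#' head(cohort$truth)
#' @export
generate_cohort <- function(n_subjects = 10, n_trials = 100,
                            conditions = list(Taste = "taste",
                                              Health = "health"),
                            weight_range = c(0.001, 0.006),
                            weight_gap = 0.0015,
                            threshold = 0.15, ndt = 0.4, noise_sd = 0.1,
                            step_duration = 0.01, deadline_s = 4) {
  stopifnot(n_subjects >= 1, n_trials >= 1,
            diff(weight_range) > weight_gap)
  trials <- list()
  truth <- list()
  for (s in seq_len(n_subjects)) {
    for (cond in names(conditions)) {
      dominant <- conditions[[cond]]
      w_hi <- runif(1, weight_range[1] + weight_gap, weight_range[2])
      w_lo <- runif(1, weight_range[1], w_hi - weight_gap)
      w <- if (dominant == "taste") c(taste = w_hi, health = w_lo) else
        c(taste = w_lo, health = w_hi)
      p <- ddm_params(w, drift_constant = 0, threshold = threshold,
                      ndt = ndt, noise_sd = noise_sd,
                      step_duration = step_duration)
      stim <- generate_food_trials(n_trials)
      stim$subject <- s
      stim$condition <- cond
      trials[[length(trials) + 1]] <-
        generate_behavior(stim, setNames(list(p), cond),
                          deadline_s = deadline_s)
      truth[[length(truth) + 1]] <- tibble::tibble(
        subject = s, condition = cond,
        parameter = c("w_taste", "w_health", "drift_constant", "threshold",
                      "ndt"),
        value = c(w[["taste"]], w[["health"]], 0, threshold, ndt)
      )
    }
  }
  list(trials = dplyr::bind_rows(trials), truth = dplyr::bind_rows(truth))
}
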