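#' Drift diffusion model parameters
#'
#' Bundles the parameters of the attribute-weighted two-boundary drift
#' diffusion model. Evidence evolves as
#' \deqn{EA_t = EA_{t-1} + \sum_i w_i (A_{i1} - A_{i2}) + C + \epsilon_t,}
#' where \eqn{A_{i1}}, \eqn{A_{i2}} are the attribute values of the two
#' options, \eqn{w_i} are attribute weights, \eqn{C} is a constant drift
#' bias toward option 1, and \eqn{\epsilon_t \sim N(0, \sigma)} is Gaussian
#' noise. A response is triggered the first time \eqn{|EA_t| \ge B} (upper
#' boundary = option 1, lower = option 2); response time is the decision
#' time plus a fixed non-decision time.
#'
#' The accumulation equation is interpreted as the unit-time update of a
#' continuous diffusion and simulated on an Euler grid: with step size
#' \eqn{\Delta t} (`step_duration`) the per-step increment is
#' \eqn{d \Delta t + \sigma \sqrt{\Delta t} Z}. Weights and the drift
#' constant are therefore rates (evidence per attribute unit per second and
#' evidence per second), `noise_sd` scales as evidence per \eqn{\sqrt{s}},
#' and results converge as `step_duration` shrinks; a smaller step costs
#' proportionally more simulation time. The defaults (\eqn{B = 0.15},
#' \eqn{\sigma = 0.1}, 10 ms steps) place typical decisions in the human
#' 0.5-4 s range.
#'
#' @param weights Named numeric vector of attribute weights. Names must match
#'   the attribute names used in the trial table (the `<name>` part of
#'   `attr_<name>_o1` / `attr_<name>_o2` columns).
#' @param drift_constant Constant drift bias \eqn{C} (positive favors
#'   option 1). Default 0.
#' @param threshold Boundary separation parameter \eqn{B > 0}; boundaries sit
#'   at \eqn{\pm B}. Default 0.15.
#' @param ndt Non-decision time in seconds (\eqn{\ge 0}). Default 0.
#' @param noise_sd Noise scale \eqn{\sigma > 0}. Default 0.1.
#' @param step_duration Euler step of the simulation, in seconds.
#'   Default 0.01.
#'
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(c(taste = 0.05, health = 0.02))
#' @export
ddm_params <- function(weights, drift_constant = 0, threshold = 0.15,
                       ndt = 0, noise_sd = 0.1, step_duration = 0.01) {
  if (!is.numeric(weights) || length(weights) < 1) {
    abort("`weights` must be a non-empty numeric vector.")
  }
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    abort("`weights` must be named after the trial attributes.")
  }
  if (anyDuplicated(names(weights))) abort("`weights` names must be unique.")
  stopifnot(
    is.numeric(drift_constant), length(drift_constant) == 1,
    is.numeric(threshold), length(threshold) == 1,
    is.numeric(ndt), length(ndt) == 1,
    is.numeric(noise_sd), length(noise_sd) == 1,
    is.numeric(step_duration), length(step_duration) == 1
  )
  if (!all(is.finite(c(weights, drift_constant, threshold, ndt, noise_sd,
                       step_duration)))) {
    abort("All DDM parameters must be finite.")
  }
  if (threshold <= 0) abort("`threshold` must be > 0.")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (ndt < 0) abort("`ndt` must be >= 0.")
  if (step_duration <= 0) abort("`step_duration` must be > 0.")
  structure(
    list(weights = weights, drift_constant = drift_constant,
         threshold = threshold, ndt = ndt, noise_sd = noise_sd,
         step_duration = step_duration),
    class = "ddm_params"
  )
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("<ddm_params>\n")
  cat("  weights:       ",
      paste(sprintf("%s = %g", names(x$weights), x$weights), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  drift_constant: %g /s\n", x$drift_constant))
  cat(sprintf("  threshold:      +/- %g\n", x$threshold))
  cat(sprintf("  ndt:            %g s\n", x$ndt))
  cat(sprintf("  noise_sd:       %g /sqrt(s)\n", x$noise_sd))
  cat(sprintf("  step_duration:  %g s\n", x$step_duration))
  invisible(x)
}

is_ddm_params <- function(x) inherits(x, "ddm_params")

#' Uniform prior bounds for DDM fitting
#'
#' Builds the box of uniform prior bounds over the free parameters of the
#' model: one weight per attribute, the drift constant, the threshold and the
#' non-decision time (the noise scale stays fixed during fitting). The
#' defaults bracket weight magnitudes typically estimated for dollar- or
#' rating-scaled attributes (on the order of 0.001-0.01 evidence per
#' attribute unit per second) with wide margins, and allow negative weights
#' (e.g. an inequity-aversion attribute can carry either sign).
#'
#' @param attributes Character vector of attribute names (weight parameters
#'   are named `w_<attribute>`).
#' @param weights Length-2 numeric `c(lower, upper)` applied to every
#'   attribute weight, or a named list of per-attribute length-2 vectors.
#' @param drift_constant,threshold,ndt Length-2 numeric bounds for the drift
#'   bias C, threshold B and non-decision time (seconds).
#'
#' @return A tibble with columns `parameter`, `lower`, `upper` and class
#'   `ddm_bounds`.
#' @examples
#' ddm_bounds(c("taste", "health"))
#' @export
ddm_bounds <- function(attributes,
                       weights = c(-0.01, 0.02),
                       drift_constant = c(-0.1, 0.1),
                       threshold = c(0.05, 0.4),
                       ndt = c(0.1, 1.5)) {
  if (!is.character(attributes) || length(attributes) < 1) {
    abort("`attributes` must be a non-empty character vector.")
  }
  if (is.list(weights)) {
    missing_w <- setdiff(attributes, names(weights))
    if (length(missing_w)) {
      abort(paste0("Missing weight bounds for: ",
                   paste(missing_w, collapse = ", ")))
    }
    w_bounds <- lapply(attributes, function(a) weights[[a]])
  } else {
    w_bounds <- rep(list(weights), length(attributes))
  }
  rows <- c(
    lapply(seq_along(attributes), function(i) {
      tibble::tibble(parameter = paste0("w_", attributes[i]),
                     lower = w_bounds[[i]][1], upper = w_bounds[[i]][2])
    }),
    list(tibble::tibble(parameter = "drift_constant",
                        lower = drift_constant[1], upper = drift_constant[2]),
         tibble::tibble(parameter = "threshold",
                        lower = threshold[1], upper = threshold[2]),
         tibble::tibble(parameter = "ndt", lower = ndt[1], upper = ndt[2]))
  )
  out <- dplyr::bind_rows(rows)
  validate_bounds(out)
  class(out) <- c("ddm_bounds", class(out))
  out
}

validate_bounds <- function(bounds) {
  if (!all(c("parameter", "lower", "upper") %in% names(bounds))) {
    abort("Bounds need columns `parameter`, `lower`, `upper`.")
  }
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper))) {
    abort("Bounds must be finite.")
  }
  if (any(bounds$lower >= bounds$upper)) {
    bad <- bounds$parameter[bounds$lower >= bounds$upper]
    abort(paste0("`lower` must be < `upper` for: ", paste(bad, collapse = ", ")))
  }
  thr <- bounds[bounds$parameter == "threshold", ]
  if (nrow(thr) && thr$lower <= 0) abort("Threshold lower bound must be > 0.")
  ndt <- bounds[bounds$parameter == "ndt", ]
  if (nrow(ndt) && ndt$lower < 0) abort("ndt lower bound must be >= 0.")
  invisible(bounds)
}

# Assemble a ddm_params from a free-parameter vector laid out as the bounds
# table (w_<attr>..., drift_constant, threshold, ndt).
params_from_vector <- function(theta, attributes, noise_sd, step_duration) {
  k <- length(attributes)
  ddm_params(
    weights = setNames(theta[seq_len(k)], attributes),
    drift_constant = theta[k + 1],
    threshold = theta[k + 2],
    ndt = theta[k + 3],
    noise_sd = noise_sd,
    step_duration = step_duration
  )
}
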