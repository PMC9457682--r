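# shared fixtures built in code

# a single-stimulus trial table with explicit attribute differences
stim_with_diffs <- function(taste = 0, health = 0) {
  tibble::tibble(
    attr_taste_o1 = taste, attr_taste_o2 = 0,
    attr_health_o1 = health, attr_health_o2 = 0
  )
}

food_params <- function(w_taste = 0.004, w_health = 0.002, ...) {
  ddm_params(c(taste = w_taste, health = w_health), ndt = 0.4, ...)
}

# Monte-Carlo standard error of a proportion
p_se <- function(p, n) sqrt(p * (1 - p) / n)

# one synthetic food-task subject in the canonical schema
food_subject <- function(n = 80, params = food_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  generate_behavior(generate_food_trials(n), params)
}
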