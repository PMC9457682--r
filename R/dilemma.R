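#' Attribute-difference grid of hypothetical dilemmas
#'
#' Builds the Cartesian product of hedonic and normative attribute
#' differences, each realized as a binary-choice stimulus in which option 2
#' (the default) sits at 0 on both attributes and option 1 carries the
#' stated differences. The classic design crosses differences in
#' `[-3, ..., +3]` on both attributes, giving 49 cells.
#'
#' @param levels Numeric vector of attribute-difference levels (used for
#'   both attributes). Default `-3:3`.
#' @param hedonic,normative Attribute names for the hedonic and normative
#'   dimensions. Defaults `"taste"` and `"health"`.
#' @return A tibble with columns `hedonic_diff`, `normative_diff` and the
#'   paired `attr_*_o1` / `attr_*_o2` stimulus columns.
#' @examples
#' nrow(build_attribute_grid())     # 49
#' build_attribute_grid(c(-1, 1))
#' @export
build_attribute_grid <- function(levels = -3:3, hedonic = "taste",
                                 normative = "health") {
  if (length(levels) < 1) abort("`levels` must be non-empty.")
  if (identical(hedonic, normative)) {
    abort("`hedonic` and `normative` must be distinct attributes.")
  }
  g <- tidyr::expand_grid(hedonic_diff = levels, normative_diff = levels)
  g[[paste0("attr_", hedonic, "_o1")]] <- g$hedonic_diff
  g[[paste0("attr_", hedonic, "_o2")]] <- 0
  g[[paste0("attr_", normative, "_o1")]] <- g$normative_diff
  g[[paste0("attr_", normative, "_o2")]] <- 0
  g
}

#' The four exemplar goal contexts
#'
#' Two hedonic-priority weight settings (hedonic weight 0.05 vs normative
#' 0.02, and 0.04 vs 0.03) and their two normative-priority mirror images.
#'
#' @return A tibble with columns `w_hedonic`, `w_normative`.
#' @export
exemplar_contexts <- function() {
  tibble::tibble(
    w_hedonic = c(0.05, 0.04, 0.03, 0.02),
    w_normative = c(0.02, 0.03, 0.04, 0.05)
  )
}

#' Goal-weight contexts on a factorial lattice
#'
#' Returns the exemplar contexts followed by every factorial combination of
#' hedonic and normative weights on the lattice
#' `seq(grid_min, grid_max, by = increment)` that is not already an
#' exemplar. With the default 0-0.05 range in 0.01 steps and the four
#' exemplars this yields 4 + 32 = 36 contexts.
#'
#' @param grid_min,grid_max,increment Lattice range and step for both
#'   weights; `increment` must divide the range.
#' @param exemplars A data frame with columns `w_hedonic`, `w_normative`
#'   listed first in the output (possibly zero rows). Default
#'   [exemplar_contexts()].
#' @return A tibble with columns `context_label`, `w_hedonic`,
#'   `w_normative`, `exemplar`.
#' @examples
#' nrow(build_weight_contexts())    # 36
#' @export
build_weight_contexts <- function(grid_min = 0, grid_max = 0.05,
                                  increment = 0.01,
                                  exemplars = exemplar_contexts()) {
  if (increment <= 0) abort("`increment` must be > 0.")
  n_steps <- (grid_max - grid_min) / increment
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    abort("`increment` must divide `grid_max - grid_min`.")
  }
  if (anyDuplicated(exemplars[c("w_hedonic", "w_normative")])) {
    abort("Duplicate exemplar contexts.")
  }
  lattice <- seq(grid_min, grid_max, by = increment)
  full <- tidyr::expand_grid(w_hedonic = lattice, w_normative = lattice)
  key <- function(d) paste(round(d$w_hedonic, 10), round(d$w_normative, 10))
  extra <- full[!key(full) %in% key(exemplars), ]
  out <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(exemplars), exemplar = TRUE),
    dplyr::mutate(extra, exemplar = FALSE)
  )
  dplyr::mutate(
    out,
    context_label = sprintf("w_hed=%.3g,w_norm=%.3g",
                            .data$w_hedonic, .data$w_normative),
    .before = 1
  )
}

#' Simulate the dilemma grid under each goal context
#'
#' For every goal context x grid cell, simulates `n_sims` decisions of the
#' accumulator (drift bias C = 0, non-decision time 0 - both irrelevant to
#' the grid aggregates) and tallies the frequency of normative choice and
#' the mean response time and mean neural activity
#' (\eqn{\sum_t |EA_t|}) separately for normative and hedonistic outcomes.
#' Cells with a zero normative difference have no defined normative option
#' and report `p_normative = NA`; censored paths (no crossing before the
#' step cap) are counted in `n_capped` and excluded from tallies.
#'
#' @param grid A grid from [build_attribute_grid()].
#' @param contexts Contexts from [build_weight_contexts()], or any data
#'   frame with `context_label`, `w_hedonic`, `w_normative`.
#' @param n_sims Simulated decisions per cell and context (default 10000).
#' @param threshold,noise_sd,step_duration Accumulator settings shared by
#'   all contexts.
#' @param deadline Seconds used to derive the step cap.
#' @return A `ddm_dilemma` tibble with one row per context x cell:
#'   weights, differences, `conflict_status`, `p_normative`,
#'   `mean_rt_norm`, `mean_rt_hed`, `mean_neural_norm`, `mean_neural_hed`,
#'   `n_norm`, `n_hed`, `n_capped`, `n_sims`, plus per-cell contrasts
#'   `delta_neural` and `delta_rt` (normative minus hedonistic; `NA`
#'   when either choice type has fewer than 20 instances in the cell).
#' @examples
#' set.seed(1)
#' cells <- run_dilemma_experiment(build_attribute_grid(c(-2, 2)),
#'                                 head(build_weight_contexts(), 2),
#'                                 n_sims = 500)
#' cells
#' @export
run_dilemma_experiment <- function(grid, contexts, n_sims = 10000,
                                   threshold = 0.15, noise_sd = 0.1,
                                   step_duration = 0.01, deadline = 4) {
  stopifnot(n_sims >= 1, nrow(grid) > 0, nrow(contexts) > 0)
  if (!all(c("hedonic_diff", "normative_diff") %in% names(grid))) {
    abort("`grid` must come from build_attribute_grid().")
  }
  max_steps <- as.integer(ceiling(deadline / step_duration))
  conflict <- classify_conflict_diffs(grid$hedonic_diff, grid$normative_diff)
  sd_step <- noise_sd * sqrt(step_duration)

  per_context <- function(label, w_h, w_n) {
    drift <- w_h * grid$hedonic_diff + w_n * grid$normative_diff
    tl <- ddm_tally_cpp(drift * step_duration, as.integer(n_sims),
                        threshold, sd_step, max_steps)
    # map upper/lower boundary tallies onto normative/hedonistic outcomes
    norm_is_up <- grid$normative_diff > 0
    undef <- grid$normative_diff == 0
    n_norm <- ifelse(norm_is_up, tl$n_up, tl$n_down)
    n_hed <- ifelse(norm_is_up, tl$n_down, tl$n_up)
    steps_norm <- ifelse(norm_is_up, tl$steps_up, tl$steps_down)
    steps_hed <- ifelse(norm_is_up, tl$steps_down, tl$steps_up)
    act_norm <- ifelse(norm_is_up, tl$activity_up, tl$activity_down)
    act_hed <- ifelse(norm_is_up, tl$activity_down, tl$activity_up)
    tibble::tibble(
      context_label = label, w_hedonic = w_h, w_normative = w_n,
      hedonic_diff = grid$hedonic_diff,
      normative_diff = grid$normative_diff,
      conflict_status = conflict,
      p_normative = ifelse(undef, NA_real_, n_norm / (n_norm + n_hed)),
      mean_rt_norm = ifelse(!undef & n_norm > 0,
                            steps_norm / n_norm * step_duration, NA_real_),
      mean_rt_hed = ifelse(!undef & n_hed > 0,
                           steps_hed / n_hed * step_duration, NA_real_),
      mean_neural_norm = ifelse(!undef & n_norm > 0,
                                act_norm / n_norm * step_duration,
                                NA_real_),
      mean_neural_hed = ifelse(!undef & n_hed > 0,
                               act_hed / n_hed * step_duration, NA_real_),
      n_norm = ifelse(undef, NA_integer_, as.integer(n_norm)),
      n_hed = ifelse(undef, NA_integer_, as.integer(n_hed)),
      n_capped = tl$n_capped,
      n_sims = as.integer(n_sims)
    ) |>
      dplyr::mutate(
        # cell-level contrasts are reported only when both choice types
        # are observed often enough to estimate them stably
        delta_neural = ifelse(
          !is.na(.data$n_norm) & .data$n_norm >= 20 & .data$n_hed >= 20,
          .data$mean_neural_norm - .data$mean_neural_hed, NA_real_),
        delta_rt = ifelse(
          !is.na(.data$n_norm) & .data$n_norm >= 20 & .data$n_hed >= 20,
          .data$mean_rt_norm - .data$mean_rt_hed, NA_real_)
      )
  }

  out <- purrr::pmap(
    list(contexts$context_label, contexts$w_hedonic, contexts$w_normative),
    per_context
  )
  out <- dplyr::bind_rows(out)
  class(out) <- c("ddm_dilemma", class(out))
  out
}

classify_conflict_diffs <- function(dh, dn) {
  out <- dplyr::case_when(
    dh == 0 | dn == 0 ~ "degenerate",
    sign(dh) != sign(dn) ~ "conflict",
    TRUE ~ "no_conflict"
  )
  factor(out, levels = c("conflict", "no_conflict", "degenerate"))
}

#' Aggregate grid cells by conflict status
#'
#' Collapses the cell-level experiment to one row per context x conflict
#' stratum (degenerate cells excluded): the overall normative-choice
#' fraction, and the differences (normative minus hedonistic) in mean
#' neural activity and mean RT, each pooled over all simulated choices of
#' that type in the stratum. Pooling matters: the grid cells a choice type
#' predominantly comes from differ between normative and hedonistic
#' choices, and this composition - not any within-cell asymmetry - carries
#' the characteristic conflict/no-conflict activity patterns.
#'
#' @param cells A `ddm_dilemma` tibble from [run_dilemma_experiment()].
#' @return A `ddm_conflict_summary` tibble with columns `context_label`,
#'   `w_hedonic`, `w_normative`, `priority` (which attribute the context
#'   weighs more), `conflict_status`, `p_normative`, `delta_neural`,
#'   `delta_rt`, `n_norm`, `n_hed`, `n_cells`.
#' @examples
#' set.seed(1)
#' cells <- run_dilemma_experiment(build_attribute_grid(c(-2, 2)),
#'                                 head(build_weight_contexts(), 2),
#'                                 n_sims = 500)
#' summarize_by_conflict(cells)
#' @export
summarize_by_conflict <- function(cells) {
  if (!nrow(cells)) abort("`cells` is empty.")
  kept <- dplyr::filter(cells, .data$conflict_status != "degenerate")
  out <- kept |>
    dplyr::group_by(.data$context_label, .data$w_hedonic, .data$w_normative,
                    .data$conflict_status) |>
    dplyr::summarise(
      p_normative = sum(.data$n_norm) / sum(.data$n_norm + .data$n_hed),
      delta_neural = pooled_delta(.data$mean_neural_norm,
                                  .data$mean_neural_hed,
                                  .data$n_norm, .data$n_hed),
      delta_rt = pooled_delta(.data$mean_rt_norm, .data$mean_rt_hed,
                              .data$n_norm, .data$n_hed),
      n_norm = sum(.data$n_norm),
      n_hed = sum(.data$n_hed),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      priority = dplyr::case_when(
        .data$w_hedonic > .data$w_normative ~ "hedonic",
        .data$w_hedonic < .data$w_normative ~ "normative",
        TRUE ~ "balanced"
      ),
      .after = "w_normative"
    )
  class(out) <- c("ddm_conflict_summary", class(out))
  out
}

# difference of count-weighted pooled means (sums over cells where the
# choice type occurred at all)
pooled_delta <- function(mean_a, mean_b, n_a, n_b) {
  ok_a <- !is.na(mean_a) & n_a > 0
  ok_b <- !is.na(mean_b) & n_b > 0
  if (!any(ok_a) || !any(ok_b)) return(NA_real_)
  sum(mean_a[ok_a] * n_a[ok_a]) / sum(n_a[ok_a]) -
    sum(mean_b[ok_b] * n_b[ok_b]) / sum(n_b[ok_b])
}
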