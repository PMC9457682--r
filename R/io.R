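#' Read and write the canonical trial table
#'
#' One CSV schema serves both task families: columns `subject`,
#' `condition`, `onset_s`, paired attribute columns `attr_<name>_o1` /
#' `attr_<name>_o2`, `response_4pt`, `choice_binary`, `rt_s`, `missed`.
#' `read_trials()` validates the schema and the record-level invariants
#' (attribute columns numeric and paired; missed trials carry no response
#' or RT) and reports offending row numbers. A derived fairness attribute
#' (`|self - other|` per option) can be materialized on read when `self`
#' and `other` attributes are present.
#'
#' @param path CSV file path.
#' @param add_fairness Compute `attr_fairness_*` columns from
#'   `attr_self_*` / `attr_other_*` when absent (default `FALSE`).
#' @return A tibble of validated trial records.
#' @export
read_trials <- function(path, add_fairness = FALSE) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject", "condition", "onset_s", "response_4pt",
                "choice_binary", "rt_s", "missed")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  attrs <- trial_attributes(trials)  # errors on unpaired columns
  if (!length(attrs)) abort("No attr_<name>_o1/o2 attribute columns found.")
  for (a in attrs) {
    for (side in c("o1", "o2")) {
      col <- paste0("attr_", a, "_", side)
      v <- trials[[col]]
      if (!is.numeric(v)) {
        abort(paste0("Column `", col, "` must be numeric."))
      }
      if (anyNA(v)) {
        abort(paste0("Non-numeric or missing attribute values in `", col,
                     "` at row(s): ", row_list(which(is.na(v)))))
      }
    }
  }
  trials$missed <- as.logical(trials$missed)
  if (anyNA(trials$missed)) {
    abort(paste0("`missed` must be logical/0-1; bad row(s): ",
                 row_list(which(is.na(trials$missed)))))
  }
  bad_rt <- which(trials$missed & !is.na(trials$rt_s))
  if (length(bad_rt)) {
    abort(paste0("Missed trials must have empty `rt_s`; row(s): ",
                 row_list(bad_rt)))
  }
  bad_resp <- which(trials$missed & (!is.na(trials$choice_binary) |
                                       !is.na(trials$response_4pt)))
  if (length(bad_resp)) {
    abort(paste0("Missed trials must have empty responses; row(s): ",
                 row_list(bad_resp)))
  }
  bad_obs <- which(!trials$missed & (is.na(trials$rt_s) |
                                       is.na(trials$choice_binary)))
  if (length(bad_obs)) {
    abort(paste0("Non-missed trials need `choice_binary` and `rt_s`; ",
                 "row(s): ", row_list(bad_obs)))
  }
  if (add_fairness && !"fairness" %in% attrs) {
    if (!all(c("self", "other") %in% attrs)) {
      abort("`add_fairness` needs `self` and `other` attributes.")
    }
    trials$attr_fairness_o1 <- abs(trials$attr_self_o1 - trials$attr_other_o1)
    trials$attr_fairness_o2 <- abs(trials$attr_self_o2 - trials$attr_other_o2)
  }
  trials
}

row_list <- function(rows, max_show = 5) {
  shown <- paste(head(rows, max_show), collapse = ", ")
  if (length(rows) > max_show) shown <- paste0(shown, ", ...")
  shown
}

#' @rdname read_trials
#' @param trials A trial tibble in the canonical schema.
#' @return `write_trials()`: `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' Write dilemma-experiment summaries
#'
#' Writes the tidy long-format cell table produced by
#' [run_dilemma_experiment()] (one row per context x grid cell).
#'
#' @param cells A `ddm_dilemma` tibble.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_dilemma_csv <- function(cells, path) {
  readr::write_csv(cells, path)
  invisible(path)
}
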