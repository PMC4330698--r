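#' Aggregate trials to occasion means and response-to-target ratios
#'
#' Averages the (up to three) trial responses within each subject x CR x
#' occasion x task x stimulus cell and expresses the mean relative to the
#' target duration, times 100: `ratio = 100 * mean(response_s) / stimulus_s`.
#' 100 means veridical timing, above 100 over-estimation/-production.
#'
#' @param trials A data.frame with columns `subject_id`, `cr`,
#'   `occasion_time_h`, `task`, `stimulus_s`, `response_s` (and optionally
#'   `trial_index`).
#' @return An occasion-level data.frame with columns `subject_id`, `cr`,
#'   `occasion_time_h`, `task`, `stimulus_s`, `n_trials`, `ratio`.
#' @export
aggregate_and_ratio <- function(trials) {
  need <- c("subject_id", "cr", "occasion_time_h", "task", "stimulus_s",
            "response_s")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(trials$response_s)))
    stop("non-finite responses", call. = FALSE)
  agg <- stats::aggregate(
    response_s ~ subject_id + cr + occasion_time_h + task + stimulus_s,
    data = trials, FUN = mean)
  cnt <- stats::aggregate(
    response_s ~ subject_id + cr + occasion_time_h + task + stimulus_s,
    data = trials, FUN = length)
  agg$n_trials <- cnt$response_s
  agg$ratio <- 100 * agg$response_s / as.numeric(agg$stimulus_s)
  agg$response_s <- NULL
  agg <- agg[order(agg$subject_id, agg$cr, agg$occasion_time_h,
                   agg$task, agg$stimulus_s), ]
  rownames(agg) <- NULL
  agg
}

#' Remove outlying occasion ratios
#'
#' Drops occasion records whose standardised outcome is at or above the
#' cut-off before any model fitting. Under the default `"ratio"` rule the
#' outcome itself (already standardised to the target, 100 = veridical) is
#' compared against the cut-off, i.e. responses of 2.5x the target or more
#' are removed; the alternative `"zscore"` rule standardises the ratios
#' within task-by-stimulus cell and applies the cut-off to |z| instead.
#'
#' @param occasions Occasion table with a `ratio` column.
#' @param cutoff Cut-off (default 250).
#' @param rule `"ratio"` (default) or `"zscore"`.
#' @return A list with `kept` and `removed` data.frames
#'   (`kept` + `removed` partition the input).
#' @export
filter_outliers <- function(occasions, cutoff = 250,
                            rule = c("ratio", "zscore")) {
  rule <- match.arg(rule)
  stopifnot("ratio" %in% names(occasions))
  crit <- if (rule == "ratio") {
    occasions$ratio
  } else {
    cell <- paste(occasions$task, occasions$stimulus_s)
    abs(stats::ave(occasions$ratio, cell,
                   FUN = function(v) (v - mean(v)) / stats::sd(v)))
  }
  out <- crit >= cutoff
  if (any(out))
    message(sum(out), " occasion record(s) removed as outliers (", rule,
            " >= ", cutoff, ")")
  list(kept = occasions[!out, , drop = FALSE],
       removed = occasions[out, , drop = FALSE])
}

#' Reference occasion times to each epoch's DLMO
#'
#' Adds `t_dlmo_h = occasion_time_h - dlmo_h` (signed; negative before DLMO),
#' joining each occasion with its own subject-epoch DLMO. Subject-epochs with
#' no DLMO estimate are dropped with a warning.
#'
#' @param occasions Occasion table (see [aggregate_and_ratio()]).
#' @param dlmo A data.frame with columns `subject_id`, `cr`, `dlmo_h`.
#' @return The occasion table with an added `t_dlmo_h` column.
#' @export
align_to_dlmo <- function(occasions, dlmo) {
  need <- c("subject_id", "cr", "dlmo_h")
  miss <- setdiff(need, names(dlmo))
  if (length(miss))
    stop("DLMO table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(occasions$subject_id, occasions$cr)
  dl_key <- paste(dlmo$subject_id, dlmo$cr)
  d <- dlmo$dlmo_h[match(key, dl_key)]
  drop_idx <- is.na(d)
  if (any(drop_idx)) {
    warning(sum(drop_idx), " occasion record(s) dropped: no DLMO for ",
            paste(unique(key[drop_idx]), collapse = ", "))
  }
  occasions <- occasions[!drop_idx, , drop = FALSE]
  occasions$t_dlmo_h <- occasions$occasion_time_h - d[!drop_idx]
  rownames(occasions) <- NULL
  occasions
}
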