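# internal helpers shared across modules

# population (n-denominator) z-score; errors on zero variance
zscore_pop <- function(x, what = "series") {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0) {
    abort(sprintf("Cannot z-score a constant %s (zero variance).", what),
          class = "coactr_degenerate_series")
  }
  (x - m) / s
}

# column names of a wide ROI series tibble (everything but the time axis)
roi_cols <- function(bold) {
  setdiff(names(bold), c("volume", "time_s"))
}

stopifnot_scalar_num <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", nm),
          class = "coactr_parameter_error")
  }
  invisible(x)
}

# check a schedule tibble for the columns and invariants the pipeline relies on
validate_schedule <- function(schedule) {
  need <- c("trial_id", "onset", "duration", "phase", "probe", "response",
            "reaction_time", "n_volumes", "tr_ms")
  miss <- setdiff(need, names(schedule))
  if (length(miss)) {
    abort(paste0("Schedule is missing column(s): ", paste(miss, collapse = ", ")),
          class = "coactr_schedule_error")
  }
  if (any(diff(schedule$onset) <= 0)) {
    abort("Trial onsets must be strictly increasing within a run.",
          class = "coactr_schedule_error")
  }
  run_ms <- schedule$n_volumes[1] * schedule$tr_ms[1]
  if (any(schedule$onset + schedule$duration > run_ms)) {
    abort("Trials must end within n_volumes * TR.",
          class = "coactr_schedule_error")
  }
  enc <- schedule$phase == "encoding"
  ret <- schedule$phase == "retrieval"
  if (any(schedule$probe[enc] != "n/a")) {
    abort("Encoding trials must have probe = \"n/a\".",
          class = "coactr_schedule_error")
  }
  if (any(schedule$probe[ret] == "n/a")) {
    abort("Retrieval trials must carry a probe type.",
          class = "coactr_schedule_error")
  }
  invisible(schedule)
}
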