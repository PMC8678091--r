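#' Detect supra-threshold source events in a stimulus series
#'
#' An event starts at each upward crossing of the threshold: a volume
#' whose z-value exceeds the threshold while the previous volume's does
#' not (the first volume counts if it already exceeds it). Each event
#' spans `window_len` consecutive volumes including the crossing;
#' crossings whose window would run past the end of the run are
#' discarded with a log message. Events are attributed to the most
#' recent same-phase trial whose onset is at or before the crossing
#' time; a gap above 12 s triggers a warning.
#'
#' @param series A `coact_series` tibble from [build_stimulus_series()].
#' @param schedule The trial schedule the series was built from (used
#'   for trial attribution); `NULL` leaves trial labels `NA`.
#' @param threshold Threshold in z-units (default 1).
#' @param window_len Event length in TRs (default 5).
#' @return A tibble of class `coact_events`: `event_id`, `phase`,
#'   `crossing` (0-based volume), `crossing_time_s`, `trial_id`,
#'   `probe`, `response`, and a `segment` list-column of `window_len`
#'   z-values. The run length is attached as attribute `n_volumes`.
#' @export
detect_source_events <- function(series, schedule = NULL,
                                 threshold = 1, window_len = 5) {
  z <- series$z
  n <- length(z)
  up <- which(z > threshold & c(-Inf, z[-n]) <= threshold)
  fits <- up + window_len - 1L <= n
  if (any(!fits)) {
    inform(sprintf("Discarding %d event(s) whose %d-TR window exceeds the run end.",
                   sum(!fits), window_len))
  }
  up <- up[fits]
  phase <- series$phase[1]
  tr_s <- attr(series, "tr_s") %||% diff(series$time_s[1:2])

  out <- tibble(
    event_id = seq_along(up),
    phase = phase,
    crossing = up - 1L,
    crossing_time_s = (up - 1L) * tr_s,
    trial_id = NA_integer_,
    probe = NA_character_,
    response = NA_character_,
    segment = lapply(up, function(k) z[k:(k + window_len - 1L)])
  )

  if (!is.null(schedule) && nrow(out)) {
    trials <- schedule[schedule$phase == phase, , drop = FALSE]
    idx <- findInterval(out$crossing_time_s * 1000, trials$onset)
    gap_s <- (out$crossing_time_s * 1000 - trials$onset[pmax(idx, 1)]) / 1000
    far <- idx == 0L | gap_s > 12
    if (any(far)) {
      warn(sprintf("%d event(s) have no trial onset within 12 s before the crossing.",
                   sum(far)))
    }
    ok <- idx > 0L
    out$trial_id[ok] <- trials$trial_id[idx[ok]]
    out$probe[ok] <- trials$probe[idx[ok]]
    out$response[ok] <- trials$response[idx[ok]]
    out$trial_onset_ms <- NA_real_
    out$trial_onset_ms[ok] <- trials$onset[idx[ok]]
    # encoding events take the probe type and response of the probe that
    # concludes the same memory-set trial, so encoding cells can be
    # keyed by probe and response like retrieval cells
    if (phase == "encoding" && "pair_id" %in% names(schedule)) {
      probes <- schedule[schedule$phase == "retrieval", , drop = FALSE]
      pr <- match(trials$pair_id[idx[ok]], probes$pair_id)
      hit <- !is.na(pr)
      out$probe[ok][hit] <- probes$probe[pr[hit]]
      out$response[ok][hit] <- probes$response[pr[hit]]
    }
    for (nm in intersect(c("subject", "session", "task"), names(schedule))) {
      out[[nm]] <- schedule[[nm]][1]
    }
  }
  attr(out, "n_volumes") <- n
  attr(out, "window_len") <- window_len
  class(out) <- c("coact_events", class(out))
  out
}

#' Extract time-matched BOLD target segments for source events
#'
#' The target segment of event *i* is the ROI's BOLD value at exactly
#' the volume indices of that event's source window.
#'
#' @param bold Wide ROI tibble aligned on the same volume grid as the
#'   stimulus series the events came from.
#' @param events A `coact_events` tibble.
#' @param roi ROI column name.
#' @return `events` with columns `roi` and a `target` list-column.
#' @export
extract_target_events <- function(bold, events, roi) {
  if (!roi %in% names(bold)) {
    abort(sprintf("ROI \"%s\" is not a column of `bold`.", roi),
          class = "coactr_key_error")
  }
  nv <- attr(events, "n_volumes")
  if (!is.null(nv) && nrow(bold) != nv) {
    abort("`bold` and the stimulus series must have the same number of volumes.",
          class = "coactr_shape_error")
  }
  wl <- attr(events, "window_len") %||% 5L
  col <- bold[[roi]]
  events$roi <- roi
  events$target <- lapply(events$crossing, function(c0) col[(c0 + 1):(c0 + wl)])
  events
}

#' Pearson correlation of one source/target event pair
#'
#' The product-moment correlation of the paired samples; `NA` (with a
#' log message suppressed for vector use) when either segment has zero
#' variance.
#'
#' @param source_segment,target_segment Numeric vectors of equal length
#'   (5 samples in the standard pipeline).
#' @param quiet Suppress the degenerate-segment message.
#' @return A correlation in `[-1, 1]`, or `NA`.
#' @export
event_correlation <- function(source_segment, target_segment, quiet = FALSE) {
  if (length(source_segment) != length(target_segment)) {
    abort("Source and target segments must have the same length.",
          class = "coactr_shape_error")
  }
  sx <- source_segment - mean(source_segment)
  sy <- target_segment - mean(target_segment)
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den == 0) {
    if (!quiet) inform("Zero-variance segment; correlation set to NA.")
    return(NA_real_)
  }
  sum(sx * sy) / den
}

#' Fisher transform with clamping
#'
#' `atanh(r)` after clamping `|r|` at `1 - clamp` so that perfect
#' five-point correlations stay finite.
#'
#' @param r Correlations.
#' @param clamp Clamping margin (default `1e-7`).
#' @return Fisher z values.
#' @export
fisher_z <- function(r, clamp = 1e-7) {
  atanh(pmax(pmin(r, 1 - clamp), -1 + clamp))
}

#' Aggregate per-event correlations into condition cells
#'
#' Averages the per-event correlations within each combination of the
#' key columns and Fisher-transforms the mean. Degenerate (missing)
#' correlations are excluded from the mean and from `n_events`; cells
#' left with no usable events are dropped with a log message.
#'
#' @param event_r A tibble with a numeric `r` column and key columns.
#' @param keys Key columns to aggregate over (defaults to the standard
#'   condition keys; only those present are used).
#' @return A tibble of class `coact_cells`: keys, `n_events`, `mean_r`,
#'   `fisher_z`.
#' @export
aggregate_cells <- function(event_r,
                            keys = c("subject", "session", "task",
                                     "phase", "probe", "response", "roi")) {
  keys <- intersect(keys, names(event_r))
  dropped <- sum(is.na(event_r$r))
  if (dropped) {
    inform(sprintf("Excluding %d degenerate event correlation(s) from cell means.",
                   dropped))
  }
  cells <- event_r |>
    group_by(across(all_of(keys))) |>
    summarise(n_events = sum(!is.na(.data$r)),
              mean_r = mean(.data$r, na.rm = TRUE),
              .groups = "drop") |>
    filter(.data$n_events >= 1L) |>
    mutate(fisher_z = fisher_z(.data$mean_r))
  class(cells) <- c("coact_cells", class(cells))
  cells
}

#' Full co-activation cell table for one run
#'
#' Convenience wrapper chaining the per-phase steps: build the stimulus
#' series, detect source events, extract the time-matched BOLD segments
#' of every ROI, correlate, and aggregate into condition cells.
#'
#' @param schedule Trial schedule of the run.
#' @param bold Wide ROI tibble (typically conditioned with
#'   [condition_series()]).
#' @param threshold,window_len Event detection parameters.
#' @param params HRF parameters for the stimulus series.
#' @param shape Stimulus indicator shape, see [build_stimulus_series()].
#' @param phases Phases to analyse.
#' @return A `coact_cells` tibble covering both phases and all ROIs.
#' @export
coactivation_cells <- function(schedule, bold, threshold = 1, window_len = 5,
                               params = hrf_params(), shape = "boxcar",
                               phases = c("encoding", "retrieval")) {
  rois <- roi_cols(bold)
  per_phase <- lapply(phases, function(ph) {
    series <- build_stimulus_series(schedule, ph, params = params, shape = shape)
    events <- detect_source_events(series, schedule,
                                   threshold = threshold, window_len = window_len)
    if (nrow(events) == 0L) return(NULL)
    event_r_matrix(events, bold, rois)
  })
  aggregate_cells(bind_rows(per_phase))
}

# vectorised per-event correlation of all ROIs against the source segments
event_r_matrix <- function(events, bold, rois) {
  wl <- attr(events, "window_len") %||% 5L
  idx <- outer(seq_len(wl), events$crossing, `+`)     # wl x E matrix of 1-based rows
  S <- matrix(unlist(events$segment), nrow = wl)
  Sc <- sweep(S, 2, colMeans(S))
  s_ss <- colSums(Sc^2)
  labels <- select(as_tibble(events), -"segment")
  out <- lapply(rois, function(rc) {
    T_ <- matrix(bold[[rc]][idx], nrow = wl)
    Tc <- sweep(T_, 2, colMeans(T_))
    den <- sqrt(s_ss * colSums(Tc^2))
    r <- ifelse(den == 0, NA_real_, colSums(Sc * Tc) / den)
    mutate(labels, roi = rc, r = r)
  })
  bind_rows(out)
}

#' Write the correlation-cell table to TSV
#'
#' Long format, one row per cell; this file is the response-GLM input
#' contract.
#'
#' @param cells A `coact_cells` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cells_tsv <- function(cells, path) {
  readr::write_tsv(as_tibble(cells), path)
  invisible(path)
}

#' @rdname write_cells_tsv
#' @export
read_cells_tsv <- function(path) {
  cells <- readr::read_tsv(path, show_col_types = FALSE)
  class(cells) <- c("coact_cells", class(cells))
  cells
}
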