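#' Find local peaks of a series
#'
#' Integer indices `k` (1-based) with `y[k] > y[k-1]` and
#' `y[k] > y[k+1]`. A flat plateau of equal values higher than both
#' neighbours yields a single peak at the plateau midpoint (rounded
#' down). Run endpoints are never peaks.
#'
#' @param y Numeric vector.
#' @return Integer vector of peak indices (empty when `length(y) < 3`).
#' @export
find_local_peaks <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  i <- 2:(k - 1)
  is_peak <- r$values[i] > r$values[i - 1] & r$values[i] > r$values[i + 1]
  peaks <- (starts[i] + ends[i]) %/% 2L
  as.integer(peaks[is_peak])
}

#' Parabolic sub-sample peak refinement
#'
#' Fits the parabola through three consecutive samples at unit (TR)
#' spacing and returns its vertex: offset
#' `delta = (y_minus - y_plus) / (2 (y_minus - 2 y_0 + y_plus))`, with
#' `delta = 0` when the three samples are collinear. Exact for any
#' quadratic through the samples.
#'
#' @param y_minus,y_0,y_plus Sample values at `t0 - 1`, `t0`, `t0 + 1`
#'   (vectorised).
#' @param t0 Time of the central sample (TR units).
#' @return A list with `time` (refined peak time) and `amplitude`
#'   (refined peak value).
#' @export
#' @examples
#' parabolic_refine(0, 1, 1, t0 = 5)$time  # 5.5
parabolic_refine <- function(y_minus, y_0, y_plus, t0 = 0) {
  den <- y_minus - 2 * y_0 + y_plus
  delta <- ifelse(den == 0, 0, (y_minus - y_plus) / (2 * den))
  amp <- y_0 - delta * (y_minus - y_plus) / 4
  list(time = t0 + delta, amplitude = amp)
}

#' Delays between stimulus-event peaks and the nearest following BOLD peak
#'
#' For each source event and region: the stimulus reference is the
#' parabolically refined maximum of the stimulus series within the event
#' window (or the trial onset with `anchor = "onset"`). Candidate BOLD
#' peaks are the local maxima whose integer volume index falls within
#' `search` TRs of the rounded reference; each is refined and the one
#' closest in time to the reference is chosen (ties go to the earlier
#' peak). The delay is their difference in TR units. Events with no
#' candidate are invalid with reason `"no-peak-in-window"`; refined
#' delays outside `keep` are invalid with reason `"outside-keep-range"`
#' (the keep range extends the search window by one TR on each side
#' because refinement at a window edge may move a peak slightly
#' outside).
#'
#' @param series The stimulus `coact_series` the events were detected in.
#' @param bold Wide ROI tibble on the same volume grid.
#' @param events `coact_events` tibble from [detect_source_events()].
#' @param rois ROI columns to process (default: all).
#' @param search Candidate window in TRs after the reference, default
#'   `c(0, 9)`.
#' @param keep Acceptance range for refined delays, default `c(-1, 10)`.
#' @param anchor `"peak"` (refined stimulus-series peak, default) or
#'   `"onset"` (trial onset) as the reference point.
#' @return A tibble of class `coact_delays`: event labels, `roi`,
#'   `stimulus_peak_time` and `bold_peak_time` (TR units from run
#'   start), `delay` (TRs), `valid`, `reason`.
#' @export
compute_delays <- function(series, bold, events, rois = NULL,
                           search = c(0, 9), keep = c(-1, 10),
                           anchor = c("peak", "onset")) {
  anchor <- match.arg(anchor)
  if (nrow(bold) != nrow(series)) {
    abort("`bold` and `series` must share the volume grid.",
          class = "coactr_shape_error")
  }
  rois <- rois %||% roi_cols(bold)
  wl <- attr(events, "window_len") %||% 5L
  z <- series$z
  n <- length(z)
  tr_s <- attr(series, "tr_s") %||% diff(series$time_s[1:2])

  # stimulus reference time per event, in TR units (0-based volumes)
  ref <- vapply(seq_len(nrow(events)), function(i) {
    if (anchor == "onset") {
      if (!"trial_onset_ms" %in% names(events) || is.na(events$trial_onset_ms[i])) {
        abort("`anchor = \"onset\"` needs events detected with a schedule (trial onsets).",
              class = "coactr_key_error")
      }
      return(events$trial_onset_ms[i] / (tr_s * 1000))
    }
    w <- (events$crossing[i] + 1):(events$crossing[i] + wl)
    kp <- w[which.max(z[w])]
    if (kp > 1 && kp < n) parabolic_refine(z[kp - 1], z[kp], z[kp + 1],
                                           t0 = kp - 1)$time else kp - 1
  }, numeric(1))

  labels <- select(as_tibble(events), -dplyr::any_of(c("segment", "target")))
  out <- lapply(rois, function(rc) {
    col <- bold[[rc]]
    pk <- find_local_peaks(col)
    rt <- if (length(pk)) {
      parabolic_refine(col[pk - 1], col[pk], col[pk + 1], t0 = pk - 1)$time
    } else numeric(0)
    res <- lapply(seq_along(ref), function(i) {
      lo <- round(ref[i]) + search[1]; hi <- round(ref[i]) + search[2]
      cand <- which((pk - 1) >= lo & (pk - 1) <= hi)
      if (!length(cand)) {
        return(tibble(stimulus_peak_time = ref[i], bold_peak_time = NA_real_,
                      delay = NA_real_, valid = FALSE,
                      reason = "no-peak-in-window"))
      }
      d <- rt[cand] - ref[i]
      best <- cand[order(abs(d), rt[cand])][1]
      delay <- rt[best] - ref[i]
      ok <- delay >= keep[1] & delay <= keep[2]
      tibble(stimulus_peak_time = ref[i], bold_peak_time = rt[best],
             delay = ifelse(ok, delay, NA_real_), valid = ok,
             reason = ifelse(ok, NA_character_, "outside-keep-range"))
    })
    dplyr::bind_cols(labels, mutate(bind_rows(res), roi = rc))
  })
  out <- bind_rows(out)
  class(out) <- c("coact_delays", class(out))
  out
}

#' Histogram of stimulus-to-BOLD delays
#'
#' Counts valid delays in bins of `bin_width` TRs over the keep range,
#' per group. Modes are the local maxima of the 3-bin moving-average
#' smoothed counts; invalid records are excluded and their count
#' reported as attribute `n_invalid`.
#'
#' @param records A `coact_delays` tibble.
#' @param group_keys Columns to group by (e.g. `"roi"`).
#' @param bin_width Bin width in TRs.
#' @param range Histogram support, default `c(-1, 10)`.
#' @return A tibble of class `coact_delay_hist`: group keys, `bin_left`,
#'   `bin_mid`, `count`; modes per group as attribute `modes`.
#' @export
delay_histogram <- function(records, group_keys = character(),
                            bin_width = 0.5, range = c(-1, 10)) {
  n_invalid <- sum(!records$valid)
  valid <- records[records$valid & !is.na(records$delay), , drop = FALSE]
  if (nrow(valid) == 0L) {
    warn("No valid delay records; returning an empty histogram.")
    out <- tibble(bin_left = numeric(0), bin_mid = numeric(0), count = integer(0))
    attr(out, "n_invalid") <- n_invalid
    class(out) <- c("coact_delay_hist", class(out))
    return(out)
  }
  breaks <- seq(range[1], range[2] + bin_width - 1e-9, by = bin_width)
  grid <- tibble(bin_left = breaks[-length(breaks)])
  groups <- if (length(group_keys)) distinct(valid[group_keys]) else tibble(.rows = 1)
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- valid
    for (k in group_keys) sub <- sub[sub[[k]] == groups[[k]][g], , drop = FALSE]
    cnt <- hist(pmin(pmax(sub$delay, range[1]), range[2] - 1e-9),
                breaks = breaks, plot = FALSE)$counts
    dplyr::bind_cols(groups[g, , drop = FALSE],
                     mutate(grid, bin_mid = .data$bin_left + bin_width / 2,
                            count = cnt))
  })
  out <- bind_rows(out)
  # modes: local maxima of the smoothed counts within each group
  modes <- out |>
    group_by(across(all_of(group_keys))) |>
    summarise(mode_bin_mid = list({
      cnt <- .data$count
      sm <- as.numeric(stats::filter(cnt, rep(1 / 3, 3), sides = 2))
      sm[is.na(sm)] <- cnt[is.na(sm)]
      .data$bin_mid[find_local_peaks_or_max(sm)]
    }), .groups = "drop") |>
    tidyr::unnest("mode_bin_mid")
  attr(out, "modes") <- modes
  attr(out, "n_invalid") <- n_invalid
  class(out) <- c("coact_delay_hist", class(out))
  out
}

# interior local maxima, falling back to the global maximum for
# monotone profiles (a histogram always has at least one mode)
find_local_peaks_or_max <- function(x) {
  p <- find_local_peaks(x)
  if (!length(p)) p <- which.max(x)
  p
}

#' @importFrom graphics hist
NULL
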