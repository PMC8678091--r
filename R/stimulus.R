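#' Build the z-scored stimulus ("source") time series for one task phase
#'
#' Encodes the selected stimuli as a 1 kHz indicator (by default a boxcar
#' equal to 1 for the full stimulus duration), convolves it with the
#' canonical HRF, samples the convolution at the volume acquisition times
#' `t = k * TR` (k = 0 ... n_volumes - 1), and z-scores the sampled series
#' over the whole run using the population (n-denominator) standard
#' deviation. Encoding (memory sets) and retrieval (probes) series are
#' built separately; mask trials, if present in the schedule, are never
#' part of either series.
#'
#' @param schedule A trial schedule tibble as produced by
#'   [generate_schedule()] or [read_events_tsv()]: columns `trial_id`,
#'   `onset` (ms), `duration` (ms), `phase`, `probe`, `response`,
#'   `reaction_time` (ms), `n_volumes`, `tr_ms` (plus any metadata columns).
#' @param phase `"encoding"` or `"retrieval"`.
#' @param params HRF parameters, see [hrf_params()]. `params$dt` sets the
#'   indicator sampling step (default 1 ms).
#' @param shape `"boxcar"` (indicator is 1 for the full stimulus duration)
#'   or `"impulse"` (a single 1-sample impulse at onset).
#'
#' @return A tibble of class `coact_series` with one row per volume:
#'   `volume` (0-based index), `time_s`, `z` (z-scored amplitude) and
#'   `phase`; the trial ids used are attached as attribute `onsets_used`
#'   and the TR in seconds as attribute `tr_s`.
#' @export
#' @examples
#' sch <- generate_schedule(design_spec(n_memory_sets = 6, n_positive = 3,
#'                                      n_lure = 2, n_negative = 1,
#'                                      n_volumes = 120), seed = 1)
#' s <- build_stimulus_series(sch, "encoding")
#' c(mean(s$z), sd(s$z))
build_stimulus_series <- function(schedule, phase,
                                  params = hrf_params(),
                                  shape = c("boxcar", "impulse")) {
  shape <- match.arg(shape)
  phase <- match.arg(phase, c("encoding", "retrieval"))
  validate_schedule(schedule)
  trials <- schedule[schedule$phase == phase, , drop = FALSE]
  if (nrow(trials) == 0L) {
    abort(sprintf("Schedule contains no trials of phase \"%s\".", phase),
          class = "coactr_empty_phase")
  }
  n_volumes <- schedule$n_volumes[1]
  tr_ms <- schedule$tr_ms[1]
  dt_ms <- params$dt * 1000

  run_len <- ceiling(n_volumes * tr_ms / dt_ms)
  indicator <- numeric(run_len)
  for (i in seq_len(nrow(trials))) {
    a <- floor(trials$onset[i] / dt_ms) + 1L
    b <- if (shape == "boxcar") {
      min(run_len, floor((trials$onset[i] + trials$duration[i]) / dt_ms))
    } else {
      a
    }
    if (a <= run_len) indicator[a:b] <- 1
  }

  conv <- convolve_causal(indicator, canonical_hrf(params))
  vol_idx <- round((seq_len(n_volumes) - 1) * tr_ms / dt_ms) + 1L
  sampled <- conv[vol_idx]
  z <- zscore_pop(sampled, what = "stimulus series")

  out <- tibble(
    volume = seq_len(n_volumes) - 1L,
    time_s = (seq_len(n_volumes) - 1L) * tr_ms / 1000,
    z = z,
    phase = phase
  )
  attr(out, "onsets_used") <- trials$trial_id
  attr(out, "tr_s") <- tr_ms / 1000
  class(out) <- c("coact_series", class(out))
  out
}

# causal FFT convolution truncated to the length of the signal;
# zero-padded to a 2-3-5-smooth length so the FFT stays O(n log n)
convolve_causal <- function(x, kernel) {
  n <- length(x); m <- length(kernel)
  N <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  xf <- fft(c(x, numeric(N - n)))
  kf <- fft(c(kernel, numeric(N - m)))
  Re(fft(xf * kf, inverse = TRUE))[seq_len(n)] / N
}

#' Write a stimulus series to a tab-separated file
#'
#' Columns `volume_index`, `time_s`, `z_value`.
#'
#' @param series A `coact_series` tibble from [build_stimulus_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stimulus_tsv <- function(series, path) {
  readr::write_tsv(
    tibble(volume_index = series$volume, time_s = series$time_s,
           z_value = series$z),
    path
  )
  invisible(path)
}
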