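# small design used throughout the unit tests: 12 trials in 120 volumes
tiny_spec <- function(n_volumes = 120) {
  design_spec(n_memory_sets = 12, n_positive = 5, n_lure = 5, n_negative = 2,
              n_volumes = n_volumes, n_rois = 4)
}

# wrap a raw z-vector as a stimulus-series tibble
make_series <- function(z, tr_s = 1.8, phase = "encoding") {
  out <- tibble::tibble(volume = seq_along(z) - 1L,
                        time_s = (seq_along(z) - 1L) * tr_s,
                        z = z, phase = phase)
  attr(out, "tr_s") <- tr_s
  class(out) <- c("coact_series", class(out))
  out
}

# wrap ROI columns as a wide BOLD tibble on the same grid
make_bold <- function(..., tr_s = 1.8) {
  cols <- list(...)
  n <- length(cols[[1]])
  tibble::tibble(volume = seq_len(n) - 1L,
                 time_s = (seq_len(n) - 1L) * tr_s,
                 !!!cols)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

roi_cols_for_test <- function(bold) {
  setdiff(names(bold), c("volume", "time_s"))
}

# conditioning used by the simulation-recovery harnesses: the generator
# gives every region the same response kernel, so the global-mean
# regressor would absorb the signal itself; it is left out here and the
# remaining confounds (motion, tissue proxies, drift) are kept
condition_no_global <- function(bold, nuisance, band = c(0.01, 0.1)) {
  condition_series(bold,
                   nuisance = nuisance[setdiff(names(nuisance), "global_signal")],
                   band = band)
}
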