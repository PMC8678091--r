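#' Parameters of the canonical double-gamma haemodynamic response function
#'
#' The canonical HRF is modelled as the difference of two gamma densities:
#' a positive response peaking about 5 s after stimulus onset and a delayed
#' undershoot, scaled by `undershoot_ratio`. The defaults are the widely
#' used canonical form (response delay 6 s, undershoot delay 16 s, unit
#' dispersions, ratio 1/6, 32 s of support).
#'
#' @param response_delay Delay of the positive response, seconds.
#' @param undershoot_delay Delay of the undershoot, seconds.
#' @param response_dispersion Dispersion (gamma scale) of the response, seconds.
#' @param undershoot_dispersion Dispersion of the undershoot, seconds.
#' @param undershoot_ratio Relative amplitude of the undershoot
#'   (dimensionless; 0 gives a single gamma with no undershoot).
#' @param kernel_length Length of the sampled kernel, seconds.
#' @param dt Sampling step of the kernel, seconds. The default (0.001 s)
#'   matches the 1 kHz stimulus indicator used by [build_stimulus_series()].
#'
#' @return A list of class `hrf_params`.
#' @seealso [canonical_hrf()]
#' @export
#' @examples
#' p <- hrf_params()
#' k <- canonical_hrf(p)
#' length(k) == ceiling(p$kernel_length / p$dt)
hrf_params <- function(response_delay = 6,
                       undershoot_delay = 16,
                       response_dispersion = 1,
                       undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6,
                       kernel_length = 32,
                       dt = 0.001) {
  p <- list(
    response_delay = response_delay,
    undershoot_delay = undershoot_delay,
    response_dispersion = response_dispersion,
    undershoot_dispersion = undershoot_dispersion,
    undershoot_ratio = undershoot_ratio,
    kernel_length = kernel_length,
    dt = dt
  )
  must_pos <- c("response_delay", "undershoot_delay", "response_dispersion",
                "undershoot_dispersion", "kernel_length", "dt")
  for (nm in must_pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm),
            class = "coactr_parameter_error")
    }
  }
  if (p$undershoot_ratio < 0) {
    abort("`undershoot_ratio` must be non-negative.",
          class = "coactr_parameter_error")
  }
  if (p$kernel_length < p$undershoot_delay) {
    abort("`kernel_length` must be at least `undershoot_delay` so the kernel covers the undershoot.",
          class = "coactr_parameter_error")
  }
  structure(p, class = "hrf_params")
}

#' Sample the canonical double-gamma HRF kernel
#'
#' Evaluates the difference of two gamma densities on a regular grid
#' `t = 0, dt, 2 dt, ...` spanning `kernel_length` seconds:
#' `g(t; delay/dispersion, dispersion) - ratio * g(t; ...)` where `g` is the
#' gamma density parameterised by shape `delay/dispersion` and scale
#' `dispersion`. With the defaults the kernel is zero at the origin, rises
#' to a single positive peak near 5 s, and is followed by a shallow
#' negative undershoot.
#'
#' @param params An [hrf_params()] object.
#' @return Numeric vector of kernel amplitudes, length
#'   `ceiling(kernel_length / dt)`, in density units (not normalised).
#' @export
canonical_hrf <- function(params = hrf_params()) {
  if (!inherits(params, "hrf_params")) params <- do.call(hrf_params, params)
  n <- ceiling(params$kernel_length / params$dt)
  t <- (seq_len(n) - 1) * params$dt
  dgamma(t,
         shape = params$response_delay / params$response_dispersion,
         scale = params$response_dispersion) -
    params$undershoot_ratio *
      dgamma(t,
             shape = params$undershoot_delay / params$undershoot_dispersion,
             scale = params$undershoot_dispersion)
}
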