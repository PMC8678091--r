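#' Extract mean ROI time series from a 4D image and an integer-label atlas
#'
#' Each atlas label contributes one column equal to the spatial mean over
#' that label's voxels at every volume, with labels sorted ascending.
#'
#' @param image4d A 4D numeric array, or a path to a NIfTI file (read
#'   with the RNifti package).
#' @param atlas A 3D integer array of labels (0 = background), or a path
#'   to a NIfTI label image on the same grid.
#' @param tr_s Repetition time in seconds (used for the `time_s` column).
#' @param labels Optional integer vector of expected labels; labels with
#'   no voxels are dropped with a warning.
#' @return A tibble with columns `volume` (0-based), `time_s` and one
#'   `roi_<label>` column per non-empty label.
#' @export
extract_roi_series <- function(image4d, atlas, tr_s = 1.8, labels = NULL) {
  if (is.character(image4d)) image4d <- as_nifti_array(image4d)
  if (is.character(atlas)) atlas <- as_nifti_array(atlas)
  di <- dim(image4d); da <- dim(atlas)
  if (length(di) != 4L || length(da) != 3L || !all(di[1:3] == da)) {
    abort("`image4d` must be 4D and `atlas` 3D on the same voxel grid.",
          class = "coactr_shape_error")
  }
  atlas <- as.integer(round(atlas))
  if (any(atlas < 0L)) {
    abort("Atlas labels must be non-negative integers (0 = background).",
          class = "coactr_shape_error")
  }
  present <- sort(unique(atlas[atlas > 0L]))
  if (!is.null(labels)) {
    empty <- setdiff(as.integer(labels), present)
    if (length(empty)) {
      warn(sprintf("Dropping label(s) with no voxels: %s",
                   paste(empty, collapse = ", ")))
    }
    present <- intersect(sort(as.integer(labels)), present)
  }
  n_vol <- di[4]
  mat <- matrix(image4d, prod(di[1:3]), n_vol)
  keep <- atlas > 0L & atlas %in% present
  sums <- rowsum(mat[keep, , drop = FALSE], atlas[keep])
  counts <- as.integer(table(factor(atlas[keep], levels = rownames(sums))))
  means <- t(sums / counts)
  colnames(means) <- sprintf("roi_%03d", as.integer(rownames(sums)))
  tibble(volume = seq_len(n_vol) - 1L,
         time_s = (seq_len(n_vol) - 1L) * tr_s,
         as_tibble(means))
}

as_nifti_array <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Reading NIfTI files requires the RNifti package.")
  }
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Condition ROI BOLD time series
#'
#' Applies, per region: (1) linear detrending, (2) ordinary-least-squares
#' residualisation against the nuisance regressors (plus an intercept;
#' collinear columns are dropped with a warning), and (3) an ideal
#' (frequency-domain rectangular) band-pass filter that zeroes all
#' discrete frequencies outside `band`, including the DC component, so
#' every output column has mean (numerically) zero.
#'
#' @param bold A wide ROI tibble (`volume`, `time_s`, one column per
#'   region), e.g. from [generate_bold()] or [extract_roi_series()].
#' @param nuisance Optional tibble/matrix of confound regressors with as
#'   many rows as `bold` (motion, global signal, white matter, CSF, ...).
#' @param band Pass band in Hz, `c(f_lo, f_hi)` with
#'   `0 < f_lo < f_hi < 1/(2 TR)`. `NULL` skips filtering.
#' @param tr_s Repetition time in seconds; inferred from `time_s` when
#'   absent.
#' @param detrend Remove a linear trend first?
#' @return A tibble of the same shape as `bold` with conditioned columns.
#' @export
condition_series <- function(bold, nuisance = NULL, band = c(0.01, 0.1),
                             tr_s = NULL, detrend = TRUE) {
  cols <- roi_cols(bold)
  if (!length(cols)) abort("`bold` has no ROI columns.", class = "coactr_shape_error")
  n <- nrow(bold)
  if (is.null(tr_s)) {
    if (!"time_s" %in% names(bold)) {
      abort("Provide `tr_s` or a `time_s` column.", class = "coactr_parameter_error")
    }
    tr_s <- diff(bold$time_s[1:2])
  }
  if (!is.null(band)) {
    nyq <- 1 / (2 * tr_s)
    if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
      abort(sprintf("Band must satisfy 0 < f_lo < f_hi < Nyquist (%.4g Hz).", nyq),
            class = "coactr_parameter_error")
    }
  }

  x <- as.matrix(bold[cols])
  if (anyNA(x) || any(!is.finite(x))) {
    abort("BOLD columns must be finite with no missing values.",
          class = "coactr_shape_error")
  }
  if (detrend) {
    tt <- cbind(1, seq_len(n))
    x <- matrix(stats::lm.fit(tt, x)$residuals, n,
                dimnames = list(NULL, cols))
  }
  if (!is.null(nuisance)) {
    z <- cbind(`(Intercept)` = 1, as.matrix(nuisance))
    qz <- qr(z)
    if (qz$rank < ncol(z)) {
      dropped <- colnames(z)[qz$pivot[(qz$rank + 1):ncol(z)]]
      warn(sprintf("Dropping collinear nuisance column(s): %s",
                   paste(dropped, collapse = ", ")))
      z <- z[, qz$pivot[seq_len(qz$rank)], drop = FALSE]
    }
    x <- matrix(stats::lm.fit(z, x)$residuals, n,
                dimnames = list(NULL, cols))
  }
  if (!is.null(band)) {
    x <- apply(x, 2, bandpass_ideal, tr_s = tr_s,
               f_lo = band[1], f_hi = band[2])
    x <- matrix(x, n, dimnames = list(NULL, cols))
  }
  out <- bold
  out[cols] <- as_tibble(x)
  out
}

# ideal band-pass: rectangular mask on the discrete-frequency grid
bandpass_ideal <- function(x, tr_s, f_lo, f_hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f)            # fold to two-sided frequencies
  mask <- f >= f_lo & f <= f_hi
  Re(fft(fft(x) * mask, inverse = TRUE)) / n
}

#' Framewise displacement from motion parameters
#'
#' The maximum over parameters of the absolute inter-volume difference;
#' rotation parameters (radians) are converted to millimetres of arc on
#' a sphere of `radius_mm` before taking the maximum. The first volume
#' has displacement 0.
#'
#' @param motion Tibble/matrix with translation columns (mm) and
#'   optionally rotation columns (`rot_*`, radians).
#' @param radius_mm Conversion radius for rotations.
#' @return Numeric vector of per-volume displacements (mm).
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  m <- as.matrix(motion)
  rot <- grepl("^rot", colnames(m))
  m[, rot] <- m[, rot] * radius_mm
  d <- abs(apply(m, 2, function(col) c(0, diff(col))))
  apply(d, 1, max)
}

#' Fraction of high-motion volumes overlapping stimulus events
#'
#' Computes per-volume framewise displacement, thresholds it, and
#' returns the fraction of supra-threshold volumes that fall within
#' `window` TRs (inclusive) after any source-event crossing.
#'
#' @param motion Motion parameter tibble (see
#'   [framewise_displacement()]), or a single-column tibble/vector of
#'   precomputed displacements named `fd`.
#' @param events A source-event tibble from [detect_source_events()]
#'   (only the `crossing` column is used).
#' @param displacement_threshold_mm Threshold in mm.
#' @param window Event window in TRs, default `c(0, 9)`.
#' @return The overlap fraction in `[0, 1]`.
#' @export
motion_event_overlap <- function(motion, events,
                                 displacement_threshold_mm = 1,
                                 window = c(0, 9)) {
  fd <- if (is.data.frame(motion) && identical(names(motion), "fd")) {
    motion$fd
  } else if (is.numeric(motion) && is.null(dim(motion))) {
    motion
  } else {
    framewise_displacement(motion)
  }
  if (nrow(events) == 0L) {
    warn("No stimulus events supplied; overlap fraction is 0.")
    return(0)
  }
  supra <- which(fd > displacement_threshold_mm) - 1L   # 0-based volumes
  if (!length(supra)) return(0)
  in_window <- vapply(supra, function(v) {
    any(v >= events$crossing + window[1] & v <= events$crossing + window[2])
  }, logical(1))
  mean(in_window)
}
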