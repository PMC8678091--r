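#' Write / read a trial schedule as a BIDS-style events TSV
#'
#' The TSV stores times in seconds (`onset`, `duration`,
#' `response_time`), a `trial_type` column (`memory_set`, `mask`,
#' `probe_positive`, `probe_lure`, `probe_negative`) and the run
#' metadata columns; `n_volumes` and the TR go to a JSON sidecar next
#' to the TSV. Reading converts back to the internal millisecond
#' representation.
#'
#' @param schedule A schedule tibble.
#' @param path TSV path; the sidecar is written at the same path with
#'   extension `.json`.
#' @return `path`, invisibly (writer); a schedule tibble (reader).
#' @export
write_events_tsv <- function(schedule, path) {
  tt <- ifelse(schedule$phase == "encoding", "memory_set",
               ifelse(schedule$phase == "mask", "mask",
                      paste0("probe_", schedule$probe)))
  out <- tibble(
    onset = schedule$onset / 1000,
    duration = schedule$duration / 1000,
    trial_type = tt,
    response = schedule$response,
    response_time = schedule$reaction_time / 1000,
    subject = schedule$subject,
    session = schedule$session,
    task = schedule$task,
    trial_id = schedule$trial_id,
    pair_id = if ("pair_id" %in% names(schedule)) schedule$pair_id else NA_integer_
  )
  readr::write_tsv(out, path, na = "n/a")
  sidecar <- list(n_volumes = schedule$n_volumes[1],
                  tr_ms = schedule$tr_ms[1])
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tsv$", ".json", path)

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path))
  phase <- ifelse(df$trial_type == "memory_set", "encoding",
                  ifelse(df$trial_type == "mask", "mask", "retrieval"))
  probe <- ifelse(grepl("^probe_", df$trial_type),
                  sub("^probe_", "", df$trial_type), "n/a")
  out <- tibble(
    subject = df$subject, session = df$session, task = df$task,
    trial_id = df$trial_id,
    pair_id = if ("pair_id" %in% names(df)) df$pair_id else NA_integer_,
    onset = df$onset * 1000,
    duration = df$duration * 1000,
    phase = phase, probe = probe,
    response = ifelse(is.na(df$response), "none", df$response),
    reaction_time = df$response_time * 1000,
    n_volumes = meta$n_volumes, tr_ms = meta$tr_ms
  )
  validate_schedule(out)
}

#' Write / read a wide ROI (or nuisance) table as TSV
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `path` invisibly, or the tibble.
#' @export
write_series_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a self-describing synthetic fixture bundle
#'
#' Generates one run from the design and ground truth and writes:
#' `events.tsv` (+ JSON sidecar), `roi_bold.tsv`, `nuisance.tsv`,
#' `truth.json`, and a `manifest.json` recording the seed, parameters
#' and MD5 checksums of every file. Optionally also writes a small
#' synthetic NIfTI pair (`bold.nii.gz`, `atlas.nii.gz`) in which every
#' voxel of a label carries that region's BOLD value, so ROI extraction
#' reproduces `roi_bold.tsv` exactly.
#'
#' @param out_dir Destination directory (created if needed).
#' @param spec A [design_spec()].
#' @param truth A [sim_truth()]; defaults to `spec$n_rois` regions.
#' @param seed Integer seed driving schedule and noise.
#' @param subject,session,task Run metadata.
#' @param nifti Also write the synthetic NIfTI pair? (Requires RNifti;
#'   intended for small `n_rois`.)
#' @return The manifest, invisibly.
#' @export
write_fixture_bundle <- function(out_dir, spec = design_spec(),
                                 truth = sim_truth(spec$n_rois),
                                 seed = 1, subject = "sub-01",
                                 session = "morning", task = "global",
                                 nifti = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- generate_schedule(spec, seed = seed, subject = subject,
                                session = session, task = task)
  sim <- generate_bold(schedule, truth, seed = seed + 1L)

  files <- c(events = "events.tsv", bold = "roi_bold.tsv",
             nuisance = "nuisance.tsv", truth = "truth.json")
  write_events_tsv(schedule, file.path(out_dir, files["events"]))
  write_series_tsv(sim$bold, file.path(out_dir, files["bold"]))
  write_series_tsv(sim$nuisance, file.path(out_dir, files["nuisance"]))
  jsonlite::write_json(
    list(amplitude = sim$truth$amplitude, ar = sim$truth$ar,
         noise_sd = sim$truth$noise_sd,
         drift_amplitude = sim$truth$drift_amplitude,
         beta = as.list(sim$truth$beta), seed = seed),
    file.path(out_dir, files["truth"]), auto_unbox = TRUE, digits = NA)

  if (nifti) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("Writing NIfTI fixtures requires the RNifti package.")
    }
    rois <- roi_cols(sim$bold)
    side <- ceiling(length(rois)^(1 / 3))
    dims <- c(side, side, max(2L, ceiling(length(rois) / side^2)))
    atlas <- array(0L, dims)
    atlas[seq_along(rois)] <- seq_along(rois)
    n_vol <- nrow(sim$bold)
    img <- array(0, c(dims, n_vol))
    flat <- matrix(img, prod(dims), n_vol)
    flat[seq_along(rois), ] <- t(as.matrix(sim$bold[rois]))
    img <- array(flat, c(dims, n_vol))
    RNifti::writeNifti(RNifti::asNifti(img), file.path(out_dir, "bold.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(atlas), file.path(out_dir, "atlas.nii.gz"))
    files <- c(files, bold_nii = "bold.nii.gz", atlas_nii = "atlas.nii.gz")
  }

  paths <- file.path(out_dir, c(files, events_json = "events.json"))
  manifest <- list(
    seed = seed, subject = subject, session = session, task = task,
    spec = unclass(spec),
    package_version = as.character(utils::packageVersion("coactr")),
    files = setNames(as.list(unname(tools::md5sum(paths))), basename(paths))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture bundle back
#'
#' @param dir Bundle directory written by [write_fixture_bundle()].
#' @return A list with `schedule`, `bold`, `nuisance`, `truth`,
#'   `manifest`.
#' @export
read_fixture_bundle <- function(dir) {
  list(
    schedule = read_events_tsv(file.path(dir, "events.tsv")),
    bold = read_series_tsv(file.path(dir, "roi_bold.tsv")),
    nuisance = read_series_tsv(file.path(dir, "nuisance.tsv")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
}
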