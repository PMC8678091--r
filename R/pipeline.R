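#' Validated pipeline configuration
#'
#' Collects the analysis constants (event threshold 1 z, 5-TR windows,
#' 0.01-0.1 Hz band, delay search `[0, 9]` TRs and keep range
#' `[-1, 10]` TRs) together with the simulation design, and validates
#' them against the module preconditions before any stage runs.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Integer seed for the simulation stage.
#' @param spec A [design_spec()] used by the `simulate` stage.
#' @param truth A [sim_truth()] used by the `simulate` stage.
#' @param subjects Subject labels to simulate.
#' @param sessions Sessions to simulate per subject.
#' @param task Task label.
#' @param threshold,window_len Event detection parameters.
#' @param band Band-pass in Hz.
#' @param search,keep Delay windows in TRs.
#' @param weight_by_events,reduce_aic GLM options.
#' @return A list of class `coact_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            spec = design_spec(), truth = sim_truth(spec$n_rois),
                            subjects = c("sub-01", "sub-02"),
                            sessions = c("morning", "evening"),
                            task = "global",
                            threshold = 1, window_len = 5,
                            band = c(0.01, 0.1),
                            search = c(0, 9), keep = c(-1, 10),
                            weight_by_events = FALSE, reduce_aic = FALSE) {
  stopifnot_scalar_num(threshold, "threshold")
  stopifnot_scalar_num(seed, "seed")
  if (window_len < 2) abort("`window_len` must be at least 2 TRs.",
                            class = "coactr_parameter_error")
  nyq <- 1 / (2 * spec$tr_ms / 1000)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    abort("`band` must satisfy 0 < f_lo < f_hi < Nyquist.",
          class = "coactr_parameter_error")
  }
  if (keep[1] > search[1] || keep[2] < search[2]) {
    abort("`keep` must contain `search`.", class = "coactr_parameter_error")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 truth = truth, subjects = subjects, sessions = sessions,
                 task = task, threshold = threshold, window_len = window_len,
                 band = band, search = search, keep = keep,
                 weight_by_events = weight_by_events, reduce_aic = reduce_aic),
            class = "coact_config")
}

#' Run the co-activation pipeline
#'
#' Chains the stages `simulate` (write fixture bundles), `preprocess`
#' (condition the ROI series), `correlate` (events and cells),
#' `delays` (delay records and histograms) and `glm` (model frame,
#' type-III table, marginal contrasts, behavioural summary). Stage
#' artifacts are tab-separated files under `config$out_dir`; the
#' configuration is echoed to `config.json` and every stage appends a
#' structured line to `pipeline.log` naming the config checksum, the
#' seed and the row counts it produced. Later stages re-read the
#' artifacts of earlier ones, so a rerun of a later stage on existing
#' upstream files is reproducible.
#'
#' @param config A [pipeline_config()].
#' @param stages Stages to run, or `"all"`.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  all_stages <- c("simulate", "preprocess", "correlate", "delays", "glm")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(list(seed = config$seed, spec = unclass(config$spec),
                            threshold = config$threshold,
                            window_len = config$window_len,
                            band = config$band, search = config$search,
                            keep = config$keep,
                            subjects = config$subjects,
                            sessions = config$sessions, task = config$task),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(stage, msg) {
    line <- sprintf("[%s] stage=%s config=%s seed=%d %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                    substr(cfg_hash, 1, 8), config$seed, msg)
    cat(line, "\n", file = log_path, append = TRUE)
    inform(line)
  }

  runs <- tidyr::crossing(subject = config$subjects, session = config$sessions)
  run_dir <- function(i) file.path(config$out_dir,
                                   sprintf("%s_%s", runs$subject[i], runs$session[i]))
  artifacts <- list(config = cfg_path, log = log_path)

  if ("simulate" %in% stages) {
    for (i in seq_len(nrow(runs))) {
      write_fixture_bundle(run_dir(i), spec = config$spec, truth = config$truth,
                           seed = config$seed + i,
                           subject = runs$subject[i], session = runs$session[i],
                           task = config$task)
    }
    log_line("simulate", sprintf("runs=%d volumes=%d rois=%d",
                                 nrow(runs), config$spec$n_volumes,
                                 config$spec$n_rois))
  }

  if ("preprocess" %in% stages) {
    for (i in seq_len(nrow(runs))) {
      b <- read_fixture_bundle(run_dir(i))
      cond <- condition_series(b$bold, nuisance = b$nuisance,
                               band = config$band)
      write_series_tsv(cond, file.path(run_dir(i), "roi_conditioned.tsv"))
    }
    log_line("preprocess", sprintf("runs=%d band=[%g,%g]Hz",
                                   nrow(runs), config$band[1], config$band[2]))
  }

  if ("correlate" %in% stages) {
    cells <- lapply(seq_len(nrow(runs)), function(i) {
      b <- read_fixture_bundle(run_dir(i))
      cond <- read_series_tsv(file.path(run_dir(i), "roi_conditioned.tsv"))
      coactivation_cells(b$schedule, cond, threshold = config$threshold,
                         window_len = config$window_len)
    })
    cells <- bind_rows(cells)
    artifacts$cells <- file.path(config$out_dir, "cells.tsv")
    write_cells_tsv(cells, artifacts$cells)
    log_line("correlate", sprintf("cells=%d", nrow(cells)))
  }

  if ("delays" %in% stages) {
    recs <- lapply(seq_len(nrow(runs)), function(i) {
      b <- read_fixture_bundle(run_dir(i))
      cond <- read_series_tsv(file.path(run_dir(i), "roi_conditioned.tsv"))
      per_phase <- lapply(c("encoding", "retrieval"), function(ph) {
        s <- build_stimulus_series(b$schedule, ph)
        ev <- detect_source_events(s, b$schedule, threshold = config$threshold,
                                   window_len = config$window_len)
        if (nrow(ev) == 0L) return(NULL)
        compute_delays(s, cond, ev, search = config$search, keep = config$keep)
      })
      bind_rows(per_phase)
    })
    recs <- bind_rows(recs)
    artifacts$delays <- file.path(config$out_dir, "delays.tsv")
    readr::write_tsv(as_tibble(recs), artifacts$delays)
    hist <- delay_histogram(recs, group_keys = "roi")
    artifacts$delay_hist <- file.path(config$out_dir, "delay_histogram.tsv")
    readr::write_tsv(as_tibble(hist), artifacts$delay_hist)
    log_line("delays", sprintf("records=%d invalid=%d", nrow(recs),
                               sum(!recs$valid)))
  }

  if ("glm" %in% stages) {
    cells <- read_cells_tsv(file.path(config$out_dir, "cells.tsv"))
    frame <- build_model_frame(cells)
    include_roi <- length(unique(frame$roi)) >= 2
    fit <- fit_logistic(frame, coact_terms(include_roi = include_roi),
                        weight_by_events = config$weight_by_events)
    trace <- NULL
    if (config$reduce_aic) {
      red <- reduce_by_aic(fit)
      fit <- red$fit
      trace <- red$trace
      artifacts$trace <- file.path(config$out_dir, "aic_trace.tsv")
      readr::write_tsv(trace, artifacts$trace)
    }
    an <- type3_anova(fit)
    artifacts$anova <- file.path(config$out_dir, "anova_type3.tsv")
    readr::write_tsv(as_tibble(an), artifacts$anova)
    by <- c("probe", "phase", if (include_roi) "roi")
    contr <- marginal_trends(fit, by = by, contrast_over = "probe")
    artifacts$contrasts <- file.path(config$out_dir, "contrasts.tsv")
    readr::write_tsv(as_tibble(contr), artifacts$contrasts)
    schedules <- bind_rows(lapply(seq_len(nrow(runs)), function(i)
      read_events_tsv(file.path(run_dir(i), "events.tsv"))))
    artifacts$behavior <- file.path(config$out_dir, "behavioral_summary.tsv")
    readr::write_tsv(behavioral_summary(schedules), artifacts$behavior)
    log_line("glm", sprintf("frame_rows=%d terms=%d anova_terms=%d",
                            nrow(frame), length(fit$terms), nrow(an)))
  }

  invisible(artifacts)
}
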