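# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Design of a simulated short-term memory (DRM) run
#'
#' Defaults reproduce the study design this package emulates: 60 memory
#' sets shown for 1,800 ms, each followed (after a 1,000 ms gap and a
#' mask) by a probe shown for 2,000 ms -- 25 positive, 25 lure and 10
#' negative probes -- with the mask-to-probe delay drawn from a truncated
#' exponential on 2,000-16,000 ms whose mean is 6,097 ms; 709 volumes at
#' TR = 1,800 ms; 90 atlas regions.
#'
#' @param n_memory_sets Number of memory-set (encoding) trials.
#' @param n_positive,n_lure,n_negative Probe counts; they must sum to
#'   `n_memory_sets` (every set is probed once).
#' @param set_duration_ms,probe_duration_ms,mask_duration_ms Stimulus
#'   durations, ms. The mask duration is not part of the published design
#'   and defaults to 500 ms.
#' @param mask_gap_ms Gap between memory set offset and mask onset, ms.
#' @param delay_range_ms Range of the mask-to-probe delay, ms.
#' @param delay_mean_ms Target mean of the mask-to-probe delay, ms.
#' @param n_volumes,tr_ms Number of volumes and repetition time (ms).
#' @param n_rois Number of regions of interest.
#' @param lead_in_ms,tail_ms Quiet time before the first trial and after
#'   the last probe offset.
#'
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(n_memory_sets = 60,
                        n_positive = 25, n_lure = 25, n_negative = 10,
                        set_duration_ms = 1800,
                        probe_duration_ms = 2000,
                        mask_duration_ms = 500,
                        mask_gap_ms = 1000,
                        delay_range_ms = c(2000, 16000),
                        delay_mean_ms = 6097,
                        n_volumes = 709,
                        tr_ms = 1800,
                        n_rois = 90,
                        lead_in_ms = 10000,
                        tail_ms = 20000) {
  if (n_positive + n_lure + n_negative != n_memory_sets) {
    abort("Probe counts must sum to `n_memory_sets`: every memory set is probed once.",
          class = "coactr_parameter_error")
  }
  if (delay_range_ms[1] >= delay_range_ms[2] ||
      delay_mean_ms <= delay_range_ms[1] || delay_mean_ms >= delay_range_ms[2]) {
    abort("`delay_mean_ms` must lie strictly inside `delay_range_ms`.",
          class = "coactr_parameter_error")
  }
  structure(
    list(n_memory_sets = n_memory_sets, n_positive = n_positive,
         n_lure = n_lure, n_negative = n_negative,
         set_duration_ms = set_duration_ms,
         probe_duration_ms = probe_duration_ms,
         mask_duration_ms = mask_duration_ms,
         mask_gap_ms = mask_gap_ms,
         delay_range_ms = delay_range_ms, delay_mean_ms = delay_mean_ms,
         n_volumes = n_volumes, tr_ms = tr_ms, n_rois = n_rois,
         lead_in_ms = lead_in_ms, tail_ms = tail_ms),
    class = "design_spec"
  )
}

# rate of a truncated exponential on [a, b] with the requested mean
truncexp_rate <- function(range, target_mean) {
  a <- range[1]; b <- range[2]; w <- b - a
  mean_at <- function(lam) a + 1 / lam - w * exp(-lam * w) / (1 - exp(-lam * w))
  # mean ranges from (a+b)/2 (lam -> 0) down to a (lam -> Inf)
  stats::uniroot(function(l) mean_at(l) - target_mean,
                 lower = 1e-8, upper = 1, tol = 1e-14)$root
}

#' Sample mask-to-probe delays
#'
#' Delays are drawn from an exponential distribution truncated to
#' `range_ms`, with the rate solved numerically so that the distribution
#' mean equals `mean_ms`. A truncated exponential is used because the
#' target mean sits well below the midpoint of the range, implying a
#' right-skewed delay distribution.
#'
#' @param n Number of draws.
#' @param range_ms Truncation range, ms.
#' @param mean_ms Target mean, ms.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Numeric vector of delays in ms.
#' @export
#' @examples
#' mean(sample_mask_probe_delays(1e4, seed = 1))
sample_mask_probe_delays <- function(n, range_ms = c(2000, 16000),
                                     mean_ms = 6097, seed = NULL) {
  rate <- truncexp_rate(range_ms, mean_ms)
  w <- range_ms[2] - range_ms[1]
  with_seed(seed, {
    u <- runif(n)
    range_ms[1] - log(1 - u * (1 - exp(-rate * w))) / rate
  })
}

# response-generation defaults: accuracies and RT moments per probe type,
# taken from the behavioural profile of the emulated task
behavior_defaults <- function() {
  list(
    p_correct = c(positive = 0.82, lure = 0.74, negative = 0.98),
    rt = tibble(
      probe    = rep(c("positive", "lure", "negative"), each = 2),
      correct  = rep(c(TRUE, FALSE), 3),
      rt_mean  = c(1277, 1452, 1295, 1392, 992, 1350),
      rt_sd    = c(226, 380, 201, 419, 161, 264)
    )
  )
}

#' Generate a synthetic trial schedule
#'
#' Lays out `n_memory_sets` trials, each consisting of a memory set, a
#' mask and a probe, on the run timeline. Probe types are randomly
#' ordered; mask-to-probe delays come from
#' [sample_mask_probe_delays()]; the inter-trial interval after each
#' probe is solved so the run fills `n_volumes * tr_ms` exactly (uniform
#' jitter, rescaled). Probe responses and reaction times are sampled from
#' per-probe accuracy and RT profiles.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; the schedule is a deterministic function of
#'   `(spec, seed, subject, session, task)`.
#' @param subject,session,task Run metadata; `session` is the diurnal
#'   condition (`"morning"` or `"evening"`), `task` the processing task
#'   (`"global"` or `"local"`).
#' @param behavior Response profile as in `coactr:::behavior_defaults()`;
#'   `NULL` leaves responses `"none"`.
#' @param max_retries Number of fresh delay draws attempted when the
#'   schedule does not fit the run.
#'
#' @return A tibble with one row per stimulus (memory set, mask, probe):
#'   `subject`, `session`, `task`, `trial_id`, `onset` (ms), `duration`
#'   (ms), `phase` (`encoding` / `mask` / `retrieval`), `probe`,
#'   `response`, `reaction_time` (ms), `n_volumes`, `tr_ms`. Mask rows
#'   are carried in the schedule but never enter a stimulus series.
#' @export
generate_schedule <- function(spec = design_spec(), seed = NULL,
                              subject = "sub-01", session = "morning",
                              task = "global",
                              behavior = behavior_defaults(),
                              max_retries = 20) {
  session <- match.arg(session, c("morning", "evening"))
  task <- match.arg(task, c("global", "local"))
  with_seed(seed, {
    n <- spec$n_memory_sets
    run_ms <- spec$n_volumes * spec$tr_ms
    probe_types <- sample(rep(c("positive", "lure", "negative"),
                              c(spec$n_positive, spec$n_lure, spec$n_negative)))
    for (try in seq_len(max_retries)) {
      delays <- sample_mask_probe_delays(n, spec$delay_range_ms, spec$delay_mean_ms)
      block <- spec$set_duration_ms + spec$mask_gap_ms + spec$mask_duration_ms +
        delays + spec$probe_duration_ms
      leftover <- run_ms - spec$lead_in_ms - spec$tail_ms - sum(block)
      if (leftover >= 500 * n) break
      if (try == max_retries) {
        abort("Design does not fit the run: increase `n_volumes` or shorten the trials.",
              class = "coactr_generation_error")
      }
      inform("Schedule draw did not fit the run; retrying with fresh delays.")
    }
    iti <- leftover / n * runif(n, 0.5, 1.5)
    iti <- iti * (leftover / sum(iti))

    onset_set <- spec$lead_in_ms + cumsum(c(0, (block + iti)[-n]))
    onset_mask <- onset_set + spec$set_duration_ms + spec$mask_gap_ms
    onset_probe <- onset_mask + spec$mask_duration_ms + delays

    resp <- rep("none", n); rt <- rep(NA_real_, n)
    if (!is.null(behavior)) {
      correct <- rbinom(n, 1, behavior$p_correct[probe_types]) == 1
      # "yes" is correct only for the positive probe
      resp <- ifelse(xor(probe_types == "positive", correct), "no", "yes")
      key <- match(paste(probe_types, correct),
                   paste(behavior$rt$probe, behavior$rt$correct))
      rt <- pmax(200, rnorm(n, behavior$rt$rt_mean[key], behavior$rt$rt_sd[key]))
      rt <- pmin(rt, spec$probe_duration_ms)
    }

    sched <- bind_rows(
      tibble(onset = onset_set, duration = spec$set_duration_ms,
             phase = "encoding", probe = "n/a",
             response = "none", reaction_time = NA_real_,
             pair_id = seq_len(n)),
      tibble(onset = onset_mask, duration = spec$mask_duration_ms,
             phase = "mask", probe = "n/a",
             response = "none", reaction_time = NA_real_,
             pair_id = seq_len(n)),
      tibble(onset = onset_probe, duration = spec$probe_duration_ms,
             phase = "retrieval", probe = probe_types,
             response = resp, reaction_time = rt,
             pair_id = seq_len(n))
    )
    sched <- arrange(sched, .data$onset)
    sched <- mutate(sched,
                    subject = subject, session = session, task = task,
                    trial_id = dplyr::row_number(),
                    n_volumes = spec$n_volumes, tr_ms = spec$tr_ms,
                    .before = 1)
    sched <- select(sched, "subject", "session", "task", "trial_id",
                    "pair_id", "onset", "duration", "phase", "probe",
                    "response", "reaction_time", "n_volumes", "tr_ms")
    validate_schedule(sched)
  })
}

#' Ground truth for the synthetic BOLD forward model
#'
#' Specifies, per region and stimulus class, the amplitude (peak height
#' of a single-event response, arbitrary BOLD units) and the temporal
#' shift (TR units) of the region's response, together with the noise
#' model: AR(1) noise (stationary SD `noise_sd`), a slow drift, and
#' scripted motion. With `amplitude = 1` and `noise_sd = 0.5` the
#' single-event peak SNR is 2.
#'
#' @param n_rois Number of regions; labels are `roi_001`, `roi_002`, ...
#' @param amplitude Response amplitude; scalar or length-`n_rois` vector
#'   (per-region), recycled over stimulus classes.
#' @param shift_tr Response shift in TR units; scalar or per-region vector.
#' @param ar AR(1) coefficient of the noise, in (-1, 1).
#' @param noise_sd Stationary SD of the AR(1) noise.
#' @param drift_amplitude Amplitude of the slow sinusoidal drift.
#' @param beta Named logit coefficients used by [generate_responses()].
#' @return A list of class `coact_truth` with an `amplitude` tibble
#'   (`roi`, `phase`, `probe`, `amplitude`, `shift_tr`) and noise fields.
#' @export
sim_truth <- function(n_rois = 90, amplitude = 1, shift_tr = 0,
                      ar = 0.3, noise_sd = 0.5, drift_amplitude = 0.3,
                      beta = c("(Intercept)" = 0, fisher_z = 1)) {
  if (abs(ar) >= 1) {
    abort("AR(1) coefficient must lie in (-1, 1).", class = "coactr_parameter_error")
  }
  rois <- sprintf("roi_%03d", seq_len(n_rois))
  amplitude <- rep_len(amplitude, n_rois)
  shift_tr <- rep_len(shift_tr, n_rois)
  classes <- tibble(phase = c("encoding", "retrieval", "retrieval", "retrieval"),
                    probe = c("n/a", "positive", "lure", "negative"))
  amp <- tidyr::crossing(tibble(roi = rois,
                                amplitude = amplitude,
                                shift_tr = shift_tr),
                         classes)
  structure(
    list(amplitude = select(amp, "roi", "phase", "probe", "amplitude", "shift_tr"),
         ar = ar, noise_sd = noise_sd, drift_amplitude = drift_amplitude,
         beta = beta),
    class = "coact_truth"
  )
}

#' Simulate ROI BOLD and nuisance series for one run
#'
#' Each region's signal is the sum over trials of
#' `amplitude * HRF(t - onset - shift * TR)` (boxcar convolution,
#' normalised so a single isolated event peaks at `amplitude`), plus
#' AR(1) noise and a slow drift. Mask trials contribute nothing. The
#' nuisance set carries six scripted motion series, the global (mean)
#' signal, white-matter and CSF proxies, and the drift regressor.
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param truth A [sim_truth()] object covering every (roi, phase, probe)
#'   class present in the schedule.
#' @param seed Integer seed for the noise draws.
#' @param params HRF parameters shared with the analysis.
#' @return A list with `bold` (tibble: `volume`, `time_s`, one column per
#'   region), `nuisance` (tibble of confound regressors), `truth`, and
#'   `seed`.
#' @export
generate_bold <- function(schedule, truth = sim_truth(), seed = NULL,
                          params = hrf_params()) {
  validate_schedule(schedule)
  n_volumes <- schedule$n_volumes[1]
  tr_ms <- schedule$tr_ms[1]
  dt_ms <- params$dt * 1000
  run_len <- ceiling(n_volumes * tr_ms / dt_ms)
  kernel <- canonical_hrf(params)

  stim <- schedule[schedule$phase != "mask", , drop = FALSE]
  classes <- distinct(stim, .data$phase, .data$probe, .data$duration)
  need <- dplyr::anti_join(classes, truth$amplitude, by = c("phase", "probe"))
  if (nrow(need)) {
    abort("`truth` lacks amplitude entries for some (phase, probe) classes in the schedule.",
          class = "coactr_key_error")
  }

  # unit responses per stimulus class at the indicator resolution,
  # normalised so one isolated event peaks at 1
  unit <- vector("list", nrow(classes))
  for (i in seq_len(nrow(classes))) {
    cl <- classes[i, ]
    trials <- stim[stim$phase == cl$phase & stim$probe == cl$probe, ]
    indicator <- numeric(run_len)
    for (j in seq_len(nrow(trials))) {
      a <- floor(trials$onset[j] / dt_ms) + 1L
      b <- min(run_len, floor((trials$onset[j] + trials$duration[j]) / dt_ms))
      if (a <= run_len) indicator[a:b] <- 1
    }
    dur_n <- ceiling(cl$duration / dt_ms)
    single <- convolve_causal(c(rep(1, dur_n), numeric(length(kernel))), kernel)
    unit[[i]] <- convolve_causal(indicator, kernel) / max(single)
  }

  vol_ms <- (seq_len(n_volumes) - 1) * tr_ms
  rois <- unique(truth$amplitude$roi)
  time_s <- vol_ms / 1000

  with_seed(seed, {
    drift <- truth$drift_amplitude *
      sin(2 * pi * time_s / 300 + runif(1, 0, 2 * pi))
    bold <- matrix(0, n_volumes, length(rois),
                   dimnames = list(NULL, rois))
    innov_sd <- truth$noise_sd * sqrt(1 - truth$ar^2)
    for (r in seq_along(rois)) {
      sig <- numeric(n_volumes)
      for (i in seq_len(nrow(classes))) {
        tr_row <- truth$amplitude[truth$amplitude$roi == rois[r] &
                                    truth$amplitude$phase == classes$phase[i] &
                                    truth$amplitude$probe == classes$probe[i], ]
        shift_ms <- tr_row$shift_tr[1] * tr_ms
        idx <- round((vol_ms - shift_ms) / dt_ms) + 1
        ok <- idx >= 1 & idx <= run_len
        sig[ok] <- sig[ok] + tr_row$amplitude[1] * unit[[i]][idx[ok]]
      }
      noise <- as.numeric(stats::filter(rnorm(n_volumes, sd = innov_sd),
                                        truth$ar, method = "recursive"))
      bold[, r] <- sig + noise + drift
    }

    motion <- vapply(seq_len(6), function(k) {
      as.numeric(stats::filter(rnorm(n_volumes, sd = 0.02),
                               rep(1 / 5, 5), sides = 1)) |>
        (\(x) { x[is.na(x)] <- 0; cumsum(x) })()
    }, numeric(n_volumes))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    wm <- as.numeric(stats::filter(rnorm(n_volumes, sd = innov_sd),
                                   truth$ar, method = "recursive")) + 0.5 * drift
    csf <- as.numeric(stats::filter(rnorm(n_volumes, sd = innov_sd),
                                    truth$ar, method = "recursive")) + 0.3 * drift

    list(
      bold = tibble(volume = seq_len(n_volumes) - 1L, time_s = time_s,
                    as_tibble(bold)),
      nuisance = tibble(as_tibble(motion),
                        global_signal = rowMeans(bold),
                        white_matter = wm, csf = csf, drift = drift),
      truth = truth, seed = seed
    )
  })
}

# factors of the response model with fixed alphabetical level order and
# sum-to-zero (deviation) contrasts
as_model_factors <- function(df) {
  for (nm in intersect(c("phase", "probe", "condition", "roi"), names(df))) {
    f <- factor(df[[nm]], levels = sort(unique(as.character(df[[nm]]))))
    if (nlevels(f) > 1) stats::contrasts(f) <- stats::contr.sum(nlevels(f))
    df[[nm]] <- f
  }
  df
}

#' Sample behavioural responses for correlation cells
#'
#' Draws each cell's response from a Bernoulli with
#' `P("no") = plogis(X beta)`, where `X` is the model matrix of
#' `formula` built from the cell's Fisher-z correlation and sum-coded
#' factors. This is the generative inverse of the logistic response
#' model and is used for coefficient-recovery testing.
#'
#' @param cells A tibble with a `fisher_z` column and any factors named
#'   in `formula` (`phase`, `probe`, `condition`, `roi`).
#' @param formula RHS-only formula for the linear predictor.
#' @param beta Named coefficients matching `colnames(model.matrix(...))`.
#' @param seed Integer seed.
#' @return `cells` with columns `p_no` and `response` (`"no"`/`"yes"`);
#'   the generating coefficients are attached as attribute `beta`.
#' @export
generate_responses <- function(cells, formula = ~fisher_z,
                               beta = c("(Intercept)" = 0, fisher_z = 1),
                               seed = NULL) {
  mm <- model.matrix(formula, data = as_model_factors(cells))
  if (!setequal(colnames(mm), names(beta))) {
    abort(paste0("`beta` must name exactly the model-matrix columns: ",
                 paste(colnames(mm), collapse = ", ")),
          class = "coactr_key_error")
  }
  eta <- drop(mm %*% beta[colnames(mm)])
  with_seed(seed, {
    p_no <- plogis(eta)
    out <- mutate(cells, p_no = p_no,
                  response = ifelse(rbinom(dplyr::n(), 1, p_no) == 1, "no", "yes"))
    attr(out, "beta") <- beta
    out
  })
}

#' Simulate a factorial correlation-cell table
#'
#' Builds the full factorial of subjects x condition (morning/evening) x
#' phase x probe x ROI, draws each cell's Fisher-z correlation from a
#' normal distribution, and samples responses via [generate_responses()].
#' This bypasses the BOLD forward model and is intended for testing the
#' response GLM at scale.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_rois Number of regions.
#' @param probes Probe types included (negative probes are excluded from
#'   the response model, so the default omits them).
#' @param z_mean,z_sd Moments of the simulated Fisher-z values.
#' @param formula,beta Passed to [generate_responses()].
#' @param seed Integer seed.
#' @return A cell tibble with `subject`, `condition`, `phase`, `probe`,
#'   `roi`, `n_events`, `fisher_z`, `response`.
#' @export
simulate_cell_table <- function(n_subjects = 8, n_rois = 90,
                                probes = c("positive", "lure"),
                                z_mean = 0.3, z_sd = 0.3,
                                formula = ~fisher_z,
                                beta = c("(Intercept)" = 0, fisher_z = 1),
                                seed = NULL) {
  with_seed(seed, {
    cells <- tidyr::crossing(
      subject = sprintf("sub-%02d", seq_len(n_subjects)),
      condition = c("morning", "evening"),
      phase = c("encoding", "retrieval"),
      probe = probes,
      roi = sprintf("roi_%03d", seq_len(n_rois))
    )
    cells <- mutate(cells,
                    n_events = 25L,
                    fisher_z = rnorm(dplyr::n(), z_mean, z_sd))
    generate_responses(cells, formula = formula, beta = beta)
  })
}
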