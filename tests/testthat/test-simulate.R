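test_that("schedules reproduce the design counts for any seed", {
  for (s in c(1, 99)) {
    sch <- generate_schedule(design_spec(), seed = s)
    expect_equal(sum(sch$phase == "encoding"), 60)
    expect_equal(sum(sch$phase == "mask"), 60)
    probes <- table(sch$probe[sch$phase == "retrieval"])
    expect_equal(as.integer(probes[c("positive", "lure", "negative")]),
                 c(25L, 25L, 10L))
    expect_true(all(diff(sch$onset) > 0))
    expect_true(all(sch$onset + sch$duration <= 709 * 1800))
  }
})

test_that("schedules are reproducible and seeds matter", {
  a <- generate_schedule(tiny_spec(), seed = 5)
  b <- generate_schedule(tiny_spec(), seed = 5)
  expect_identical(a, b)
  c_ <- generate_schedule(tiny_spec(), seed = 6)
  expect_false(identical(a$onset, c_$onset))
})

test_that("mask-to-probe delays hit the target mean and range", {
  d <- sample_mask_probe_delays(1e5, seed = 2)
  expect_true(all(d >= 2000 & d <= 16000))
  expect_lt(abs(mean(d) - 6097), 30)
  # right-skew: mean well below the range midpoint
  expect_lt(mean(d), 9000)
  expect_gt(median(d), 2000)
  expect_lt(median(d), mean(d))
})

test_that("design validation rejects impossible layouts", {
  expect_error(design_spec(n_positive = 30), class = "coactr_parameter_error")
  expect_error(design_spec(delay_mean_ms = 1000), class = "coactr_parameter_error")
  # a run too short for the trials errors after bounded retries
  expect_error(
    suppressMessages(generate_schedule(
      design_spec(n_memory_sets = 12, n_positive = 5, n_lure = 5,
                  n_negative = 2, n_volumes = 40), seed = 1)),
    class = "coactr_generation_error")
})

test_that("noise-free unit-amplitude BOLD correlates perfectly with the source", {
  sch <- generate_schedule(tiny_spec(), seed = 20)
  truth <- sim_truth(n_rois = 2, amplitude = 1, shift_tr = 0,
                     noise_sd = 1e-12, drift_amplitude = 0)
  # silence the retrieval classes so encoding windows see only their own kernel
  truth$amplitude$amplitude[truth$amplitude$phase == "retrieval"] <- 0
  sim <- generate_bold(sch, truth, seed = 21)
  s <- build_stimulus_series(sch, "encoding")
  ev <- detect_source_events(s, sch)
  te <- extract_target_events(sim$bold, ev, "roi_001")
  r <- vapply(seq_len(nrow(te)),
              function(i) event_correlation(te$segment[[i]], te$target[[i]],
                                            quiet = TRUE),
              numeric(1))
  expect_true(all(abs(r - 1) < 1e-6))
})

test_that("a known response shift is recovered by the delay estimator", {
  sch <- generate_schedule(tiny_spec(240), seed = 22)
  truth <- sim_truth(n_rois = 2, amplitude = 1, shift_tr = c(0, 3),
                     noise_sd = 1e-12, drift_amplitude = 0)
  sim <- generate_bold(sch, truth, seed = 23)
  s <- build_stimulus_series(sch, "encoding")
  ev <- detect_source_events(s, sch)
  recs <- compute_delays(s, sim$bold, ev)
  med <- dplyr::summarise(dplyr::group_by(dplyr::filter(recs, valid), roi),
                          m = median(delay), .groups = "drop")
  expect_lt(abs(med$m[med$roi == "roi_001"] - 0), 0.5)
  expect_lt(abs(med$m[med$roi == "roi_002"] - 3), 0.5)
})

test_that("zero-amplitude regions give correlations centred on zero", {
  sch <- generate_schedule(tiny_spec(), seed = 24)
  truth <- sim_truth(n_rois = 6, amplitude = 0)
  sim <- generate_bold(sch, truth, seed = 25)
  cells <- quiet(coactivation_cells(sch, sim$bold))
  expect_lt(abs(mean(cells$mean_r)), 0.1)
})

test_that("responses follow the logistic model and the seed", {
  cells <- tidyr::crossing(phase = c("encoding", "retrieval"),
                           probe = c("positive", "lure"),
                           condition = c("morning", "evening"),
                           rep = 1:625)
  cells$fisher_z <- seq(-1, 1, length.out = nrow(cells))

  r0 <- generate_responses(cells, beta = c("(Intercept)" = 0, fisher_z = 0),
                           seed = 26)
  expect_lt(abs(mean(r0$response == "no") - 0.5), 0.02)

  r1 <- generate_responses(cells, beta = c("(Intercept)" = 0, fisher_z = 3),
                           seed = 27)
  dec <- dplyr::mutate(r1, bin = dplyr::ntile(fisher_z, 10))
  frac <- dplyr::summarise(dplyr::group_by(dec, bin),
                           f = mean(response == "no"), .groups = "drop")
  expect_gt(cor(frac$bin, frac$f, method = "spearman"), 0.99)

  r2 <- generate_responses(cells, beta = c("(Intercept)" = 0, fisher_z = 3),
                           seed = 27)
  expect_identical(r1$response, r2$response)

  expect_error(generate_responses(cells, beta = c(slope = 1)),
               class = "coactr_key_error")
})

test_that("fixture bundles round-trip and carry checksums", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec()
  manifest <- write_fixture_bundle(dir, spec = spec,
                                   truth = sim_truth(n_rois = 3),
                                   seed = 7)
  b <- read_fixture_bundle(dir)
  orig <- generate_schedule(spec, seed = 7)
  expect_equal(as.data.frame(b$schedule), as.data.frame(orig),
               tolerance = 1e-9)
  expect_equal(nrow(b$bold), spec$n_volumes)
  expect_equal(length(roi_cols_for_test(b$bold)), 3)
  # manifest checksums match the files on disk
  for (f in names(manifest$files)) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))[[1]]),
                     manifest$files[[f]])
  }
  expect_equal(manifest$seed, 7)
})

test_that("same seed gives a bit-identical bundle", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_bundle(d1, spec = tiny_spec(), truth = sim_truth(n_rois = 2),
                       seed = 9)
  write_fixture_bundle(d2, spec = tiny_spec(), truth = sim_truth(n_rois = 2),
                       seed = 9)
  for (f in c("events.tsv", "roi_bold.tsv", "nuisance.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("synthetic NIfTI fixtures reproduce the ROI table exactly", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  write_fixture_bundle(dir, spec = tiny_spec(), truth = sim_truth(n_rois = 3),
                       seed = 11, nifti = TRUE)
  b <- read_fixture_bundle(dir)
  ts <- extract_roi_series(file.path(dir, "bold.nii.gz"),
                           file.path(dir, "atlas.nii.gz"))
  for (k in 1:3) {
    nm <- sprintf("roi_%03d", k)
    expect_equal(ts[[nm]], b$bold[[nm]], tolerance = 1e-6)
  }
})
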