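test_that("the model frame applies the a-priori filters and coding", {
  cells <- simulate_cell_table(n_subjects = 2, n_rois = 3,
                               probes = c("positive", "lure", "negative"),
                               seed = 31)
  fr <- build_model_frame(cells)
  expect_false(any(fr$probe == "negative"))
  expect_setequal(levels(fr$probe), c("lure", "positive"))
  expect_equal(fr$response_no, as.integer(fr$response == "no"))
  # sum-to-zero coding in force on every factor
  for (nm in c("phase", "probe", "condition", "roi")) {
    expect_equal(unname(colSums(stats::contrasts(fr[[nm]]))),
                 rep(0, nlevels(fr[[nm]]) - 1))
  }
  # at most two response rows per condition combination
  expect_lte(nrow(fr), 2 * 2 * 2 * 2 * 3)

  expect_error(build_model_frame(cells[0, ]), class = "coactr_design_error")
  one_phase <- dplyr::filter(cells, phase == "encoding")
  expect_error(build_model_frame(one_phase), "phase",
               class = "coactr_design_error")
})

test_that("the factorial term set respects the a-priori exclusions", {
  tms <- coact_terms()
  expect_length(tms, 17)
  expect_false("phase" %in% tms)
  expect_false("roi" %in% tms)
  expect_false("phase:probe" %in% tms)
  # every term beyond the three factor-only ones carries the correlation
  others <- setdiff(tms, c("probe", "condition", "probe:condition"))
  expect_true(all(grepl("fisher_z", others)))
  # marginality: sub-terms of the four-way interactions are present
  expect_true(all(c("fisher_z:phase", "fisher_z:probe", "fisher_z:phase:probe",
                    "fisher_z:roi", "fisher_z:phase:roi") %in% tms))
})

test_that("intercept-only fit on balanced outcomes gives logit(0.5) = 0", {
  fr <- build_model_frame(simulate_cell_table(
    n_subjects = 4, n_rois = 2, seed = 32,
    beta = c("(Intercept)" = 0, fisher_z = 0)))
  # force exact balance by construction: equal yes/no counts
  n <- nrow(fr)
  fr$response_no <- rep(c(0L, 1L), length.out = n)
  fit <- stats::glm(response_no ~ 1, family = binomial(), data = fr)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-9)
})

test_that("AIC matches its definition and coefficients recover the truth", {
  beta <- c("(Intercept)" = 0.3, fisher_z = 0.9, probe1 = -0.25,
            "fisher_z:probe1" = 0.5)
  cells <- simulate_cell_table(n_subjects = 60, n_rois = 6, seed = 33,
                               formula = ~ fisher_z * probe, beta = beta)
  fr <- build_model_frame(cells)
  fit <- fit_logistic(fr, c("fisher_z", "probe", "fisher_z:probe"))
  expect_equal(AIC(fit$glm),
               2 * length(coef(fit$glm)) - 2 * as.numeric(logLik(fit$glm)),
               tolerance = 1e-9)
  est <- coef(fit$glm)
  se <- summary(fit$glm)$coefficients[, 2]
  for (nm in names(beta)) {
    expect_lt(abs(est[nm] - beta[nm]) / se[nm], 3)
  }
})

test_that("type-III tests equal an independent two-fit likelihood ratio", {
  cells <- simulate_cell_table(n_subjects = 6, n_rois = 3, seed = 34,
                               formula = ~ fisher_z,
                               beta = c("(Intercept)" = 0, fisher_z = 0.8))
  fr <- build_model_frame(cells)
  fit <- fit_logistic(fr, coact_terms(include_roi = FALSE))
  an <- type3_anova(fit, terms = c("fisher_z:phase:probe",
                                   "fisher_z:probe:condition"))

  # oracle: refit the full and reduced models independently with glm()
  # (possible here for a maximal term, whose removal keeps a valid formula)
  full <- stats::glm(stats::reformulate(coact_terms(include_roi = FALSE),
                                        "response_no"),
                     family = binomial(), data = fr)
  reduced_terms <- setdiff(coact_terms(include_roi = FALSE),
                           "fisher_z:phase:probe")
  red <- stats::glm(stats::reformulate(reduced_terms, "response_no"),
                    family = binomial(), data = fr)
  oracle <- as.numeric(2 * (logLik(full) - logLik(red)))
  mine <- an$chisq[an$term == "fisher_z:phase:probe"]
  expect_equal(mine, oracle, tolerance = 1e-6)
  expect_equal(an$df[an$term == "fisher_z:phase:probe"], 1L)

  # degrees of freedom are products of (levels - 1) and slope df
  expect_equal(an$df[an$term == "fisher_z:probe:condition"], 1L)
  expect_true(all(an$chisq >= 0))
  expect_true(all(an$p > 0 & an$p <= 1))
})

test_that("type-III table agrees with car::Anova on a standard model", {
  skip_if_not_installed("car")
  cells <- simulate_cell_table(n_subjects = 8, n_rois = 4, seed = 35)
  fr <- build_model_frame(cells)
  fit <- fit_logistic(fr, coact_terms(include_roi = FALSE))
  an <- type3_anova(fit)
  ca <- car::Anova(fit$glm, type = 3, test.statistic = "LR")
  idx <- match(an$term, rownames(ca))
  expect_false(anyNA(idx))
  expect_equal(an$chisq, ca[idx, "LR Chisq"], tolerance = 1e-8)
  expect_equal(an$df, ca[idx, "Df"])
})

test_that("AIC reduction deletes a null term and never raises AIC", {
  deleted <- vapply(1:20, function(s) {
    cells <- simulate_cell_table(
      n_subjects = 25, n_rois = 2, seed = 100 + s,
      formula = ~ fisher_z * probe,
      beta = c("(Intercept)" = 0, fisher_z = 1, probe1 = 0.8,
               "fisher_z:probe1" = 0))
    fr <- build_model_frame(cells)
    fit <- fit_logistic(fr, c("probe", "fisher_z", "fisher_z:probe",
                              "fisher_z:condition"))
    red <- reduce_by_aic(fit)
    if (nrow(red$trace)) {
      expect_true(all(red$trace$aic_after <= red$trace$aic_before))
    }
    # the null interaction should be gone from the final model
    canon <- vapply(strsplit(red$fit$terms, ":", fixed = TRUE),
                    function(v) paste(sort(v), collapse = ":"), character(1))
    !"fisher_z:probe" %in% canon
  }, logical(1))
  # a true-null 1-df term survives single-term AIC deletion only when its
  # LRT statistic exceeds 2, i.e. with probability 1 - P(chisq_1 < 2)
  # ~ 0.157; over 20 seeds the exclusion count is binomial(20, ~0.84),
  # whose 3-sigma lower bound is 12
  expect_gte(sum(deleted), 12)
})

test_that("strongly significant terms stop the reduction immediately", {
  cells <- simulate_cell_table(
    n_subjects = 80, n_rois = 2, seed = 36,
    formula = ~ fisher_z * probe,
    beta = c("(Intercept)" = 0, fisher_z = 1.5, probe1 = 1,
             "fisher_z:probe1" = 1.2))
  fr <- build_model_frame(cells)
  fit <- fit_logistic(fr, c("fisher_z", "probe", "fisher_z:probe"))
  red <- reduce_by_aic(fit)
  expect_equal(nrow(red$trace), 0)
  expect_setequal(red$fit$terms, c("fisher_z", "probe", "fisher_z:probe"))
})

test_that("Sidak adjustment matches its closed form and is monotone", {
  expect_equal(sidak_adjust(0.01, m = 5), 1 - 0.99^5, tolerance = 1e-12)
  expect_equal(sidak_adjust(0.01, m = 5), 0.049010, tolerance = 1e-5)
  expect_equal(sidak_adjust(0.2, m = 1), 0.2)
  p <- runif(10)
  expect_true(all(sidak_adjust(p, m = 10) >= sidak_adjust(p, m = 3)))
  expect_true(all(sidak_adjust(p, m = 10) >= p))
})

test_that("marginal trends adjust within one Sidak family", {
  cells <- simulate_cell_table(n_subjects = 30, n_rois = 3, seed = 37,
                               formula = ~ fisher_z * probe,
                               beta = c("(Intercept)" = 0, fisher_z = 0.6,
                                        probe1 = 0.2, "fisher_z:probe1" = 0.7))
  fr <- build_model_frame(cells)
  fit <- fit_logistic(fr, coact_terms())
  mt <- marginal_trends(fit, by = c("probe", "phase", "roi"),
                        contrast_over = "probe")
  m <- attr(mt, "family_size")
  expect_equal(m, 2 * 3)  # one lure-positive contrast per phase x roi
  raw <- marginal_trends(fit, by = c("probe", "phase", "roi"),
                         contrast_over = "probe", adjust = "none")
  expect_equal(mt$p_adj, sidak_adjust(raw$p_adj, m = m), tolerance = 1e-9)
  # intervals contain their estimates; adjusted p never below raw
  expect_true(all(mt$ci_lo <= mt$estimate & mt$estimate <= mt$ci_hi))
  expect_true(all(mt$p_adj >= raw$p_adj - 1e-12))
  expect_error(marginal_trends(fit, by = "sex"), class = "coactr_key_error")
})

test_that("a simulated trend difference is found at the right region", {
  hits <- vapply(1:20, function(s) {
    cells <- tidyr::crossing(subject = sprintf("s%02d", 1:60),
                             condition = c("morning", "evening"),
                             phase = c("encoding", "retrieval"),
                             probe = c("positive", "lure"),
                             roi = sprintf("roi_%03d", 1:4))
    cells <- dplyr::mutate(cells, n_events = 25L)
    set.seed(200 + s)
    cells$fisher_z <- rnorm(nrow(cells), 0.3, 0.3)
    # probe-dependent slope only at roi_001
    slope <- ifelse(cells$roi == "roi_001" & cells$probe == "lure", 3, 0.3)
    p_no <- plogis(slope * cells$fisher_z)
    cells$response <- ifelse(rbinom(nrow(cells), 1, p_no) == 1, "no", "yes")
    fit <- fit_logistic(build_model_frame(cells),
                        c("probe", "fisher_z", "fisher_z:probe", "fisher_z:roi",
                          "fisher_z:probe:roi"))
    mt <- marginal_trends(fit, by = c("probe", "roi"), contrast_over = "probe")
    mt$roi[which.min(mt$p_adj)] == "roi_001"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("behavioural summaries count response classes correctly", {
  sch <- tibble::tibble(
    subject = "s", session = "morning", task = "global",
    trial_id = 1:7,
    onset = seq(0, 60000, length.out = 7), duration = 2000,
    phase = "retrieval",
    probe = c(rep("positive", 4), rep("lure", 3)),
    response = c("yes", "yes", "yes", "no", "no", "no", "yes"),
    reaction_time = c(1200, 1300, 1250, 1500, 1280, 1320, 1400),
    n_volumes = 100L, tr_ms = 1800
  )
  bs <- behavioral_summary(sch)
  expect_equal(bs$proportion[bs$probe == "positive" & bs$response_class == "hits"], 0.75)
  expect_equal(bs$proportion[bs$probe == "positive" & bs$response_class == "misses"], 0.25)
  expect_equal(bs$proportion[bs$probe == "lure" & bs$response_class == "correct_rejections"],
               2 / 3, tolerance = 1e-12)
  # proportions sum to one within each probe that has responses
  sums <- dplyr::summarise(dplyr::group_by(bs, probe),
                           s = sum(proportion), .groups = "drop")
  expect_true(all(is.na(sums$s) | abs(sums$s - 1) < 1e-12))
  # absent categories appear with zero counts
  expect_equal(bs$n[bs$probe == "negative"], c(0L, 0L))

  # all-correct responses give zero error proportions
  sch2 <- dplyr::mutate(sch,
                        response = ifelse(probe == "positive", "yes", "no"))
  bs2 <- behavioral_summary(sch2)
  expect_equal(bs2$proportion[bs2$response_class == "misses"], 0)
  expect_equal(bs2$proportion[bs2$probe == "lure" &
                                bs2$response_class == "false_alarms"], 0)
})

test_that("tidiers return broom-style tibbles", {
  cells <- simulate_cell_table(n_subjects = 4, n_rois = 2, seed = 38)
  fit <- fit_logistic(build_model_frame(cells), coact_terms(include_roi = FALSE))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(fit$frame))
  expect_equal(gl$aic, AIC(fit$glm))
})
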