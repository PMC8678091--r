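#' Build the model frame for the logistic response model
#'
#' Keeps positive and lure probe cells (negative probes carry too few
#' errors to be informative and are excluded), codes the outcome as
#' `response_no = 1` for "no" responses (so positive trends mean more
#' "no" responses), and stores the factors `phase`, `probe`, `condition`
#' and `roi` with a fixed alphabetical level order and sum-to-zero
#' contrasts (required for meaningful type-III tests). A `session`
#' column, if present, provides the diurnal `condition`.
#'
#' @param cells A `coact_cells` tibble (or any tibble with `fisher_z`,
#'   `response`, `phase`, `probe`, `roi` and `condition`/`session`).
#' @return A tibble of class `coact_frame`.
#' @export
build_model_frame <- function(cells) {
  df <- as_tibble(cells)
  if (!"condition" %in% names(df) && "session" %in% names(df)) {
    df <- rename(df, condition = "session")
  }
  need <- c("fisher_z", "response", "phase", "probe", "condition", "roi")
  miss <- setdiff(need, names(df))
  if (nrow(df) == 0L || length(miss)) {
    abort(paste0("Cells must provide column(s): ",
                 paste(if (length(miss)) miss else need, collapse = ", ")),
          class = "coactr_design_error")
  }
  df <- filter(df, .data$probe %in% c("positive", "lure"),
               .data$response %in% c("yes", "no"))
  if (anyNA(df$fisher_z)) {
    abort("Model frame must not contain missing fisher_z values.",
          class = "coactr_design_error")
  }
  for (nm in c("phase", "probe", "condition", "roi")) {
    if (length(unique(df[[nm]])) < 2L) {
      abort(sprintf("Factor `%s` has a single level; the factorial model needs two or more.", nm),
            class = "coactr_design_error")
    }
  }
  df <- as_model_factors(df)
  df$response_no <- as.integer(df$response == "no")
  if (!"n_events" %in% names(df)) df$n_events <- 1L
  class(df) <- c("coact_frame", class(df))
  df
}

#' The factorial term set of the response model
#'
#' All terms containing the correlation up to the four-way
#' `fisher_z:phase:probe:roi`-type interactions (correlation x ROI x
#' each pair from phase/probe/condition), plus `probe`, `condition` and
#' their interaction. The `phase` and `roi` main effects and their
#' correlation-free interactions are excluded a priori: responses do
#' not depend on those levels by design.
#'
#' @param include_roi Include the ROI-bearing terms? (`FALSE` gives the
#'   reduced "no-ROI" term set, useful at small scale.)
#' @return Character vector of term labels.
#' @export
coact_terms <- function(include_roi = TRUE) {
  base <- c("probe", "condition", "probe:condition",
            "fisher_z",
            "fisher_z:phase", "fisher_z:probe", "fisher_z:condition",
            "fisher_z:phase:probe", "fisher_z:phase:condition",
            "fisher_z:probe:condition")
  roi <- c("fisher_z:roi",
           "fisher_z:phase:roi", "fisher_z:probe:roi", "fisher_z:condition:roi",
           "fisher_z:phase:probe:roi", "fisher_z:phase:condition:roi",
           "fisher_z:probe:condition:roi")
  if (include_roi) c(base, roi) else base
}

#' Fit the logistic response model
#'
#' Maximum-likelihood logistic regression of `response_no` on the given
#' term set, with sum-to-zero factor coding. Convergence and separation
#' diagnostics are recorded rather than silently ignored.
#'
#' @param frame A `coact_frame` from [build_model_frame()].
#' @param terms Character vector of term labels, see [coact_terms()].
#' @param weight_by_events Weight each cell by its event count? The
#'   default treats every cell as one observation.
#' @return A list of class `coact_fit`: `glm` (the fitted
#'   [stats::glm()] object), `terms`, `frame`, `converged`,
#'   `separation` (any fitted probability within 1e-8 of 0/1).
#' @export
fit_logistic <- function(frame, terms = coact_terms(), weight_by_events = FALSE) {
  if (!inherits(frame, "coact_frame")) frame <- build_model_frame(frame)
  f <- reformulate(terms, response = "response_no")
  w <- if (weight_by_events) frame$n_events else NULL
  fit <- muffle_separation(
    do.call(stats::glm,
            list(formula = f, family = binomial(), data = frame, weights = w))
  )
  sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  if (!fit$converged) warn("IRLS did not converge; diagnostics recorded in the fit.")
  structure(list(glm = fit, terms = terms, frame = frame,
                 converged = fit$converged, separation = sep,
                 weight_by_events = weight_by_events),
            class = "coact_fit")
}

#' @export
print.coact_fit <- function(x, ...) {
  cat("Logistic co-activation response model\n")
  cat(sprintf("  terms: %d | coefficients: %d | n: %d\n",
              length(x$terms), length(coef(x$glm)), nrow(x$frame)))
  cat(sprintf("  logLik: %.2f | AIC: %.2f | converged: %s | separation: %s\n",
              as.numeric(logLik(x$glm)), AIC(x$glm), x$converged, x$separation))
  invisible(x)
}

# run a (re)fit while muffling the routine quasi-separation warning;
# separation is diagnosed explicitly on the fit object instead
muffle_separation <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Type-III likelihood-ratio ANOVA
#'
#' For each term, the model is refitted without that term's columns
#' (all other terms retained, sum-to-zero coding in force) and compared
#' with the full model by a likelihood-ratio chi-square; the degrees of
#' freedom are the number of parameters removed.
#'
#' @param fit A `coact_fit`.
#' @param terms Term labels to test (default: all fitted terms).
#' @return A tibble of class `coact_anova`: `term`, `chisq`, `df`, `p`.
#' @export
type3_anova <- function(fit, terms = NULL) {
  g <- fit$glm
  X <- model.matrix(g)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(g), "term.labels")
  terms <- terms %||% labels
  # match requested terms to model labels by variable set, so
  # "fisher_z:condition" and "condition:fisher_z" are the same term
  canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                              function(v) paste(sort(v), collapse = ":"),
                              character(1))
  idx <- match(canon(terms), canon(labels))
  if (anyNA(idx)) {
    abort(paste0("Term(s) not in the model: ",
                 paste(terms[is.na(idx)], collapse = ", ")),
          class = "coactr_key_error")
  }
  y <- g$y
  w <- stats::weights(g) %||% rep(1, length(y))
  dev_full <- g$deviance
  rows <- lapply(seq_along(terms), function(i) {
    tm <- terms[i]
    j <- idx[i]
    keep <- asgn != j
    refit <- muffle_separation(glm.fit(X[, keep, drop = FALSE], y, weights = w,
                                       family = binomial()))
    chisq <- refit$deviance - dev_full
    df <- sum(!keep)
    tibble(term = tm, chisq = chisq, df = df,
           p = pchisq(chisq, df, lower.tail = FALSE))
  })
  out <- bind_rows(rows)
  class(out) <- c("coact_anova", class(out))
  out
}

#' Backward model reduction by single-term AIC deletion
#'
#' Repeatedly considers every currently deletable term (deletions that
#' respect marginality), refits without each, and removes the one whose
#' deletion most lowers the AIC. Reduction stops when the AIC-minimising
#' deletion candidate is itself significant (likelihood-ratio p below
#' `alpha`), or when no deletion lowers the AIC.
#'
#' @param fit A `coact_fit`.
#' @param alpha Significance threshold of the stopping rule.
#' @param max_steps Safety cap on deletions.
#' @return A list with `fit` (the reduced `coact_fit`) and `trace`
#'   (tibble: `step`, `term`, `aic_before`, `aic_after`, `p`), where
#'   `p` is the deleted term's likelihood-ratio p-value.
#' @export
reduce_by_aic <- function(fit, alpha = 0.05, max_steps = 100) {
  g <- fit$glm
  trace <- list()
  for (step in seq_len(max_steps)) {
    d1 <- muffle_separation(drop1(g, test = "LRT"))
    cand <- d1[rownames(d1) != "<none>", , drop = FALSE]
    if (nrow(cand) == 0L) break
    aic_now <- d1["<none>", "AIC"]
    best <- which.min(cand$AIC)
    if (cand$AIC[best] >= aic_now) break
    if (cand[["Pr(>Chi)"]][best] < alpha) break
    tm <- rownames(cand)[best]
    g <- update(g, as.formula(paste(". ~ . -", tm)))
    trace[[step]] <- tibble(step = step, term = tm,
                            aic_before = aic_now, aic_after = cand$AIC[best],
                            p = cand[["Pr(>Chi)"]][best])
  }
  kept <- attr(stats::terms(g), "term.labels")
  out_fit <- structure(list(glm = g, terms = kept, frame = fit$frame,
                            converged = g$converged,
                            separation = any(g$fitted.values < 1e-8 |
                                               g$fitted.values > 1 - 1e-8),
                            weight_by_events = fit$weight_by_events),
                       class = "coact_fit")
  list(fit = out_fit,
       trace = if (length(trace)) bind_rows(trace) else
         tibble(step = integer(0), term = character(0),
                aic_before = numeric(0), aic_after = numeric(0), p = numeric(0)))
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` tests.
#'
#' @param p Raw p-values.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

#' Marginal correlation trends and contrasts on the probability scale
#'
#' Estimated marginal trends of the response probability with respect to
#' the Fisher-z correlation, for every combination of the `by` factors,
#' averaging the omitted factors with equal weights. Contrasts are taken
#' over `contrast_over` within the remaining `by` factors, the whole set
#' of contrasts forming one Sidak family. Estimates are back-transformed
#' from the logit to the probability scale by the delta method at the
#' mean correlation (via `emmeans`).
#'
#' @param fit A `coact_fit`.
#' @param by Model factors defining the trend combinations, e.g.
#'   `c("probe", "phase", "roi")`.
#' @param contrast_over The factor whose (alphabetical) pairwise
#'   differences are reported, default the first of `by`.
#' @param adjust Multiplicity adjustment (`"sidak"`).
#' @param conf_level Confidence level of the reported intervals.
#' @return A tibble of class `coact_contrasts`: `contrast`, the
#'   remaining `by` columns, `estimate`, `se`, `df`, `z_ratio`, `p_adj`,
#'   `ci_lo`, `ci_hi`; the per-combination trends are attached as
#'   attribute `trends` and the family size as `family_size`.
#' @export
marginal_trends <- function(fit, by, contrast_over = by[[1]],
                            adjust = "sidak", conf_level = 0.95) {
  factors <- c("phase", "probe", "condition", "roi")
  bad <- setdiff(by, factors)
  if (length(bad)) {
    abort(paste0("`by` must name model factors; unknown: ",
                 paste(bad, collapse = ", ")),
          class = "coactr_key_error")
  }
  specs <- as.formula(paste("~", paste(by, collapse = "*")))
  emt <- emmeans::emtrends(fit$glm, specs, var = "fisher_z",
                           regrid = "response")
  within <- setdiff(by, contrast_over)
  con <- emmeans::contrast(emt, method = "pairwise",
                           by = if (length(within)) within else NULL)
  s <- summary(con, by = NULL, adjust = adjust, infer = c(TRUE, TRUE),
               level = conf_level)
  out <- as_tibble(s)
  nm <- names(out)
  nm[nm == "SE"] <- "se"
  nm[nm == "z.ratio"] <- "z_ratio"
  nm[nm == "t.ratio"] <- "z_ratio"
  nm[nm == "p.value"] <- "p_adj"
  nm[nm == "asymp.LCL"] <- "ci_lo"
  nm[nm == "asymp.UCL"] <- "ci_hi"
  nm[nm == "lower.CL"] <- "ci_lo"
  nm[nm == "upper.CL"] <- "ci_hi"
  names(out) <- nm
  attr(out, "trends") <- as_tibble(summary(emt))
  attr(out, "family_size") <- nrow(out)
  class(out) <- c("coact_contrasts", class(out))
  out
}

#' Behavioural summary of responses and reaction times
#'
#' Per probe type: the proportion of each response class (hits and
#' misses for positive probes; correct rejections and false alarms for
#' lure and negative probes) among responded trials, with reaction-time
#' mean and SD. Proportions sum to 1 within each probe type; absent
#' classes are reported with count 0.
#'
#' @param schedule A trial schedule (or several row-bound runs) with
#'   responses.
#' @return A tibble: `probe`, `response_class`, `n`, `proportion`,
#'   `rt_mean`, `rt_sd`.
#' @export
behavioral_summary <- function(schedule) {
  probes <- filter(as_tibble(schedule), .data$phase == "retrieval",
                   .data$response %in% c("yes", "no"))
  probes <- mutate(probes,
    correct = (.data$response == "yes") == (.data$probe == "positive"),
    response_class = dplyr::case_when(
      .data$probe == "positive" & .data$correct ~ "hits",
      .data$probe == "positive" ~ "misses",
      .data$correct ~ "correct_rejections",
      TRUE ~ "false_alarms"
    ))
  classes <- tibble(
    probe = rep(c("positive", "lure", "negative"), each = 2),
    response_class = c("hits", "misses",
                       "correct_rejections", "false_alarms",
                       "correct_rejections", "false_alarms")
  )
  counts <- probes |>
    group_by(.data$probe, .data$response_class) |>
    summarise(n = dplyr::n(),
              rt_mean = mean(.data$reaction_time, na.rm = TRUE),
              rt_sd = sd(.data$reaction_time, na.rm = TRUE),
              .groups = "drop")
  out <- left_join(classes, counts, by = c("probe", "response_class"))
  out$n[is.na(out$n)] <- 0L
  out <- out |>
    group_by(.data$probe) |>
    mutate(proportion = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_) |>
    ungroup() |>
    select("probe", "response_class", "n", "proportion", "rt_mean", "rt_sd")
  out
}
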