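#' Bland-Altman agreement analysis of paired panel means
#'
#' Compares per-procedure/state mean utilities from two studies. Differences
#' are taken as validation minus original; the bias is their mean, the limits
#' of agreement are `bias +/- 1.96 * sd(differences)`, and the observed
#' extreme differences are reported alongside. Pairwise means are returned as
#' x-coordinates for the Bland-Altman plot.
#'
#' @param original,validation Paired numeric vectors of mean utilities
#'   (same procedures/states in the same order), length >= 2.
#' @param ids Optional identifiers for the pairs.
#' @return A list of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `diff_min`, `diff_max`, `n_pairs`, and `coords`
#'   (data.frame `id`, `mean`, `diff` for plotting).
#' @export
bland_altman <- function(original, validation, ids = NULL) {
  if (length(original) != length(validation))
    stop("`original` and `validation` must be the same length", call. = FALSE)
  n <- length(original)
  if (n < 2) stop("need at least 2 pairs (SD undefined otherwise)",
                  call. = FALSE)
  diffs <- validation - original
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    diff_min = min(diffs), diff_max = max(diffs), n_pairs = n,
    coords = data.frame(
      id = if (is.null(ids)) seq_len(n) else ids,
      mean = (original + validation) / 2, diff = diffs)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d pairs)\n  bias: %.4f\n  95%% LoA: [%.4f, %.4f]\n  observed differences: [%.4f, %.4f]\n",
    x$n_pairs, x$bias, x$loa_low, x$loa_high, x$diff_min, x$diff_max))
  invisible(x)
}

#' Random-intercept comparison model between two studies
#'
#' Fits, by REML through [lme4::lmer()], the model
#' `response ~ study + state + (1 | procedure)` with study coded
#' original = 0 / validation = 1 and state coded pre = 0 / post = 1. With
#' `response_kind = "score"` the response is the individual experts'
#' final-round utilities and the study coefficient is the standardized mean
#' difference between the studies' estimates; with `response_kind = "sd"`
#' the response is the per-(study, state, procedure) between-expert SD and
#' the study coefficient is the standardized difference in consensus.
#'
#' @param data Long-format data.frame with columns `response`, `study`
#'   (levels containing `"original"` and `"validation"`), `state`
#'   (`"pre"`/`"post"`) and `procedure`.
#' @param response_kind `"score"` or `"sd"` (label recorded in the result).
#' @return A list of class `ri_model`: `coefficients` (data.frame `term`,
#'   `estimate`, `se`, `ci_low`, `ci_high`; Wald normal 95% CIs),
#'   `random_intercepts` (data.frame `procedure`, `intercept`), `var_random`,
#'   `var_residual`, `fit_method`, `converged`, `singular`, `response_kind`,
#'   and `model` (the underlying `lmerMod`).
#' @export
fit_random_intercept_model <- function(data,
                                       response_kind = c("score", "sd")) {
  response_kind <- match.arg(response_kind)
  need <- c("response", "study", "state", "procedure")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("`data` lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  data$study <- factor(data$study, levels = c("original", "validation"))
  if (anyNA(data$study))
    stop("`study` must contain only \"original\"/\"validation\"",
         call. = FALSE)
  if (nlevels(droplevels(data$study)) < 2)
    stop("both study levels must be present", call. = FALSE)
  data$state <- factor(data$state, levels = c("pre", "post"))
  if (length(unique(data$procedure)) < 2)
    stop("need at least 2 procedures for a random intercept", call. = FALSE)

  fit <- lme4::lmer(response ~ study + state + (1 | procedure),
                    data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  conv <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (!conv)
    warning("mixed-model fit did not converge cleanly; inspect `model`",
            call. = FALSE)

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  coefs <- data.frame(
    term = names(est),
    estimate = as.numeric(est), se = as.numeric(se),
    ci_low = as.numeric(est - 1.96 * se),
    ci_high = as.numeric(est + 1.96 * se),
    stringsAsFactors = FALSE
  )
  re <- lme4::ranef(fit)$procedure
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = coefs,
    random_intercepts = data.frame(procedure = rownames(re),
                                   intercept = re[["(Intercept)"]],
                                   stringsAsFactors = FALSE),
    var_random = vc$vcov[vc$grp == "procedure"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    fit_method = "REML (lme4::lmer)",
    converged = conv || singular,
    singular = singular,
    response_kind = response_kind,
    model = fit
  ), class = "ri_model")
}

#' Study coefficient of a fitted comparison model
#'
#' @param fit An `ri_model`.
#' @return Named numeric: estimate, se, ci_low, ci_high for the study term.
#' @export
study_coefficient <- function(fit) {
  row <- fit$coefficients[fit$coefficients$term == "studyvalidation", ]
  if (nrow(row) != 1L) stop("no study term in fit", call. = FALSE)
  c(estimate = row$estimate, se = row$se,
    ci_low = row$ci_low, ci_high = row$ci_high)
}

#' Residual diagnostics for a comparison model
#'
#' Checks the model assumptions: residuals plotted against fitted values,
#' normal-quantile pairs, a Shapiro-Wilk normality test, and a
#' scale-location slope (regression of `sqrt(|standardized residual|)` on
#' fitted values) as a homoscedasticity indicator — a slope near zero means
#' similar residual spread across the fitted range.
#'
#' @param fit An `ri_model` (or any model with `residuals()`/`fitted()`).
#' @return A list of class `residual_diagnostics`: `residuals_vs_fitted`
#'   (data.frame `fitted`, `residual`), `qq` (data.frame `theoretical`,
#'   `sample`), `shapiro_w`, `shapiro_p` (NA, flagged, if n < 3 or residuals
#'   are constant), `scale_location_slope`, `n`.
#' @export
residual_diagnostics <- function(fit) {
  m <- if (inherits(fit, "ri_model")) fit$model else fit
  res <- stats::residuals(m)
  fitted <- stats::fitted(m)
  n <- length(res)
  qq <- stats::qqnorm(res, plot.it = FALSE)

  s <- stats::sd(res)
  # residuals at floating-point noise level count as a perfect fit
  constant <- !is.finite(s) ||
    s <= 1e-10 * max(1, stats::sd(fitted), abs(mean(fitted)))
  if (n >= 3 && n <= 5000 && !constant) {
    sw <- stats::shapiro.test(res)
    shapiro_w <- unname(sw$statistic); shapiro_p <- sw$p.value
  } else {
    shapiro_w <- NA_real_; shapiro_p <- NA_real_
  }
  std_res <- if (constant) res * 0 else res / s
  slope <- if (constant || stats::sd(fitted) == 0) 0 else
    unname(stats::coef(stats::lm(sqrt(abs(std_res)) ~ fitted))[2])
  structure(list(
    residuals_vs_fitted = data.frame(fitted = fitted, residual = res),
    qq = data.frame(theoretical = qq$x, sample = qq$y),
    shapiro_w = shapiro_w, shapiro_p = shapiro_p,
    normality_test_available = !is.na(shapiro_p),
    scale_location_slope = slope, n = n
  ), class = "residual_diagnostics")
}

#' Assemble the long table for the score comparison model
#'
#' Turns a two-panel expert-score table into the long format expected by
#' [fit_random_intercept_model()] with `response_kind = "score"`: one row per
#' individual final-round expert score, response on the utility scale.
#' GBD-derived procedures (identical fixed weights in both panels) should be
#' excluded upstream — they carry no between-panel information.
#'
#' @param scores Expert-score data.frame with panels named `"original"` and
#'   `"validation"`.
#' @param use_round Round to use; default the last round present.
#' @return Data.frame `response`, `study`, `state`, `procedure`.
#' @export
score_model_table <- function(scores, use_round = max(scores$round)) {
  final <- scores[scores$round == use_round, , drop = FALSE]
  data.frame(response = final$vas / 100,
             study = final$panel,
             state = final$state,
             procedure = final$procedure_id,
             stringsAsFactors = FALSE)
}

#' Assemble the long table for the consensus (SD) model
#'
#' One row per (study, state, procedure): the between-expert SD of
#' final-round scores, by default on the utility scale.
#'
#' @inheritParams score_model_table
#' @param scale `"utility"` or `"vas"` (see [consensus_sd_table()]).
#' @return Data.frame `response`, `study`, `state`, `procedure`.
#' @export
sd_model_table <- function(scores, scale = c("utility", "vas"),
                           use_round = max(scores$round)) {
  tab <- consensus_sd_table(scores, scale = scale, use_round = use_round)
  data.frame(response = tab$sd,
             study = tab$panel,
             state = tab$state,
             procedure = tab$procedure_id,
             stringsAsFactors = FALSE)
}
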