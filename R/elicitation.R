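#' Map a VAS score to a utility
#'
#' The visual analogue scale runs from 0 (worst imaginable health) to 100
#' (best imaginable health); utilities are the scores divided by 100.
#'
#' @param v Numeric vector of VAS scores in \[0, 100\].
#' @return Utilities in \[0, 1\].
#' @export
vas_to_qol <- function(v) {
  if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 100))
    stop("VAS scores must be numeric in [0, 100]", call. = FALSE)
  v / 100
}

#' Map a disability weight to a utility
#'
#' Quality of life = 1 - disability weight, the standard conversion from
#' Global Burden of Disease severity weights.
#'
#' @param dw Numeric vector of disability weights in \[0, 1\].
#' @return Utilities in \[0, 1\].
#' @export
qol_from_disability_weight <- function(dw) {
  if (!is.numeric(dw) || anyNA(dw) || any(dw < 0 | dw > 1))
    stop("disability weights must be numeric in [0, 1]", call. = FALSE)
  1 - dw
}

check_one_cell <- function(scores) {
  keys <- c("panel", "round", "procedure_id", "state")
  keys <- keys[keys %in% names(scores)]
  for (k in keys) {
    if (length(unique(scores[[k]])) > 1L)
      stop("scores mix multiple values of `", k,
           "`; supply one procedure/state/panel/round cell", call. = FALSE)
  }
}

#' Summarise one Delphi round
#'
#' Median, interquartile range (type-7 linear interpolation), mean and sample
#' SD of the VAS scores of one procedure/state/panel/round cell — the summary
#' fed back to experts between Delphi rounds.
#'
#' @param scores Data.frame of expert scores for a single cell (must contain
#'   `vas`; key columns, if present, must be constant).
#' @return A list of class `round_summary`: `median`, `iqr_low`, `iqr_high`,
#'   `mean`, `sd`, `n` (VAS scale).
#' @export
round_summary <- function(scores) {
  if (is.numeric(scores)) scores <- data.frame(vas = scores)
  if (!is.data.frame(scores) || nrow(scores) == 0L)
    stop("`scores` must be a non-empty data.frame (or numeric vector)",
         call. = FALSE)
  check_one_cell(scores)
  v <- scores$vas
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(
    median = q[2], iqr_low = q[1], iqr_high = q[3],
    mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
    n = length(v)
  ), class = "round_summary")
}

#' Aggregate final-round scores into a quality-of-life estimate
#'
#' The panel's estimate for one procedure/state is the mean of the experts'
#' final scores, mapped to the utility scale; the between-expert SD is the
#' consensus measure. The 95% CI uses the t distribution (small panels) and
#' is truncated to \[0, 1\].
#'
#' @param scores Data.frame of final-round expert scores for a single
#'   procedure/state/panel cell (column `vas`; key columns constant).
#' @param panel Panel label for the result; default taken from the data.
#' @return A one-row data.frame (`qol_estimate`): `procedure_id`, `state`,
#'   `panel`, `q_mean`, `q_sd`, `q_se`, `ci_low`, `ci_high`, `n`. With a
#'   single score, `q_se`, `ci_low`, `ci_high` are `NA` (flagged
#'   unavailable).
#' @export
finalize_estimate <- function(scores, panel = NULL) {
  if (is.numeric(scores)) scores <- data.frame(vas = scores)
  if (!is.data.frame(scores) || nrow(scores) == 0L)
    stop("`scores` must be a non-empty data.frame (or numeric vector)",
         call. = FALSE)
  check_one_cell(scores)
  q <- vas_to_qol(scores$vas)
  n <- length(q)
  q_mean <- mean(q)
  if (n >= 2L) {
    q_sd <- stats::sd(q)
    q_se <- q_sd / sqrt(n)
    half <- stats::qt(0.975, df = n - 1) * q_se
    ci_low <- max(0, q_mean - half)
    ci_high <- min(1, q_mean + half)
  } else {
    warning("single score: SE and CI unavailable", call. = FALSE)
    q_sd <- 0; q_se <- NA_real_; ci_low <- NA_real_; ci_high <- NA_real_
  }
  out <- data.frame(
    procedure_id = if (!is.null(scores$procedure_id))
      scores$procedure_id[1] else NA_character_,
    state = if (!is.null(scores$state)) scores$state[1] else NA_character_,
    panel = if (!is.null(panel)) panel else
      if (!is.null(scores$panel)) scores$panel[1] else NA_character_,
    q_mean = q_mean, q_sd = q_sd, q_se = q_se,
    ci_low = ci_low, ci_high = ci_high, n = n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("qol_estimate", "data.frame")
  out
}

#' Pool two panels' final scores into one estimate
#'
#' Concatenates the individual expert scores of both panels (equal weight per
#' expert) and aggregates with [finalize_estimate()]; the result's panel is
#' `"pooled"`.
#'
#' @param scores_a,scores_b Final-round score data.frames for the *same*
#'   procedure/state from two panels.
#' @param method `"experts"` (default) concatenates individual expert scores,
#'   weighting each expert equally; `"panel_means"` averages the two panel
#'   means instead, weighting each panel equally (SE combined as
#'   `sqrt(se_a^2 + se_b^2)/2`, normal CI).
#' @return A one-row `qol_estimate` data.frame with `panel = "pooled"`.
#' @export
pool_panels <- function(scores_a, scores_b,
                        method = c("experts", "panel_means")) {
  method <- match.arg(method)
  if (is.numeric(scores_a)) scores_a <- data.frame(vas = scores_a)
  if (is.numeric(scores_b)) scores_b <- data.frame(vas = scores_b)
  if (nrow(scores_b) == 0L) {
    warning("second panel empty; pooled estimate equals the first panel's",
            call. = FALSE)
    return(finalize_estimate(scores_a, panel = "pooled"))
  }
  for (k in c("procedure_id", "state")) {
    if (k %in% names(scores_a) && k %in% names(scores_b) &&
        !identical(unique(scores_a[[k]]), unique(scores_b[[k]])))
      stop("panels disagree on `", k, "`; cannot pool", call. = FALSE)
  }
  if (method == "panel_means") {
    ea <- finalize_estimate(scores_a)
    eb <- finalize_estimate(scores_b)
    out <- ea
    out$panel <- "pooled"
    out$q_mean <- (ea$q_mean + eb$q_mean) / 2
    out$q_sd <- sqrt((ea$q_sd^2 + eb$q_sd^2) / 2)
    out$q_se <- sqrt(ea$q_se^2 + eb$q_se^2) / 2
    out$ci_low <- max(0, out$q_mean - 1.96 * out$q_se)
    out$ci_high <- min(1, out$q_mean + 1.96 * out$q_se)
    out$n <- ea$n + eb$n
    return(out)
  }
  common <- intersect(names(scores_a), names(scores_b))
  pooled <- rbind(scores_a[common], scores_b[common])
  finalize_estimate(pooled, panel = "pooled")
}

#' Per-cell quality-of-life estimates for a whole score table
#'
#' Applies [finalize_estimate()] to the final round of every
#' (panel, procedure, state) cell of a long-format score table.
#'
#' @param scores Expert-score data.frame (`panel`, `round`, `expert_id`,
#'   `procedure_id`, `state`, `vas`).
#' @param use_round Round to aggregate; default the last round present.
#' @return A `qol_estimate` data.frame, one row per cell.
#' @export
estimate_qol <- function(scores, use_round = max(scores$round)) {
  final <- scores[scores$round == use_round, , drop = FALSE]
  if (nrow(final) == 0L) stop("no scores in round ", use_round, call. = FALSE)
  cells <- split(final,
                 list(final$panel, final$procedure_id, final$state),
                 drop = TRUE)
  out <- do.call(rbind, lapply(cells, finalize_estimate))
  out <- out[order(out$panel, out$procedure_id, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Between-expert SD table (consensus measure)
#'
#' Computes, for the final round of each (panel, state, procedure) cell, the
#' between-expert standard deviation of the scores — a lower SD means a
#' higher degree of consensus. Input to the consensus mixed model.
#'
#' @param scores Expert-score data.frame.
#' @param scale `"utility"` (SD of vas/100, default) or `"vas"`.
#' @param use_round Round to use; default the last round present.
#' @return Data.frame: `panel`, `procedure_id`, `state`, `sd`, `n`.
#' @export
consensus_sd_table <- function(scores, scale = c("utility", "vas"),
                               use_round = max(scores$round)) {
  scale <- match.arg(scale)
  final <- scores[scores$round == use_round, , drop = FALSE]
  agg <- stats::aggregate(vas ~ panel + procedure_id + state, data = final,
                          FUN = function(v) c(sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(panel = agg$panel, procedure_id = agg$procedure_id,
                    state = agg$state,
                    sd = agg$vas[, "sd"], n = agg$vas[, "n"],
                    stringsAsFactors = FALSE)
  if (scale == "utility") out$sd <- out$sd / 100
  out[order(out$panel, out$procedure_id, out$state), , drop = FALSE]
}
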