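#' Decision-model inputs for one procedure
#'
#' The cohort state-transition model uses, per procedure: the age of the
#' average patient at the moment surgery is indicated, the pre- and
#' postoperative utilities, the monthly probability of disease-related death
#' while waiting, the one-time perioperative mortality, the long-term
#' post-surgery survival fraction over `horizon_years` (converted to a
#' constant monthly excess hazard), and a background-mortality life table.
#'
#' @param procedure_id Identifier.
#' @param age0 Age in years at the decision point.
#' @param q_pre,q_post Utilities in \[0, 1\] for the pre-/postoperative state.
#' @param p_wait_death Monthly probability of disease-related death while
#'   waiting, in \[0, 1\].
#' @param p_periop_death One-time probability of death at surgery, in
#'   \[0, 1\].
#' @param s_long Long-term post-surgery survival fraction over
#'   `horizon_years`, in (0, 1\].
#' @param horizon_years Years over which `s_long` applies (default 5).
#' @param life_table Data.frame with columns `age`, `p_month` (see
#'   [generate_life_table()]).
#' @return A list of class `procedure_params`.
#' @export
procedure_params <- function(procedure_id, age0, q_pre, q_post,
                             p_wait_death, p_periop_death, s_long,
                             horizon_years = 5,
                             life_table = generate_life_table()) {
  probs <- c(p_wait_death = p_wait_death, p_periop_death = p_periop_death)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  if (any(c(q_pre, q_post) < 0 | c(q_pre, q_post) > 1))
    stop("utilities must be in [0, 1]", call. = FALSE)
  if (s_long <= 0 || s_long > 1)
    stop("`s_long` must be in (0, 1]", call. = FALSE)
  if (!all(c("age", "p_month") %in% names(life_table)))
    stop("`life_table` needs columns `age` and `p_month`", call. = FALSE)
  structure(list(
    procedure_id = procedure_id, age0 = age0, q_pre = q_pre, q_post = q_post,
    p_wait_death = p_wait_death, p_periop_death = p_periop_death,
    s_long = s_long, horizon_years = horizon_years, life_table = life_table
  ), class = "procedure_params")
}

#' Convert a survival fraction to a constant monthly excess hazard
#'
#' A fraction `s` surviving over `years` under a constant hazard corresponds
#' to a monthly hazard of `-log(s) / (12 * years)`.
#'
#' @param s Survival fraction in (0, 1\].
#' @param years Duration in years (> 0).
#' @return Monthly excess hazard (>= 0).
#' @export
survival_to_monthly_hazard <- function(s, years) {
  if (any(s <= 0) || any(s > 1)) stop("`s` must be in (0, 1]", call. = FALSE)
  if (any(years <= 0)) stop("`years` must be > 0", call. = FALSE)
  -log(s) / (12 * years)
}

#' Model settings for the cohort simulation
#'
#' @param max_age Hard age cap (years) at which simulation stops.
#' @param min_alive Stop once the living fraction falls below this.
#' @param discount_rate Annual discount rate on QALYs (default 0, off).
#' @param half_cycle Use half-cycle correction (average of cycle-start and
#'   cycle-end occupancy) for QALY accrual; default `FALSE` (cycle-start).
#' @param max_cycles Optional explicit cap on the number of cycles.
#' @return A named list of settings.
#' @export
model_settings <- function(max_age = 100, min_alive = 1e-9,
                           discount_rate = 0, half_cycle = FALSE,
                           max_cycles = NULL) {
  list(max_age = max_age, min_alive = min_alive,
       discount_rate = discount_rate, half_cycle = half_cycle,
       max_cycles = max_cycles)
}

#' Run the cohort state-transition model for one delay scenario
#'
#' Simulates a closed cohort through Preop, Postop and Dead states in monthly
#' cycles. For cycles before `delay_months` the whole surviving cohort waits
#' in Preop, where the monthly death probability combines disease-related
#' waiting mortality and background mortality:
#' `1 - (1 - p_wait_death) * (1 - p_bg(age))`. At the start of cycle
#' `delay_months` the survivors undergo surgery: a fraction `p_periop_death`
#' dies, the remainder enters Postop, where background and post-surgery
#' excess mortality combine additively on the hazard scale:
#' `1 - exp(-(h_bg(age) + h_excess))`. QALYs accrue per cycle from
#' cycle-start occupancy: `(preop * q_pre + postop * q_post) / 12`
#' (half-cycle correction and discounting optional via `settings`).
#' Simulation stops at `max_age` or when the living fraction is negligible.
#'
#' @param params A [procedure_params()].
#' @param delay_months Non-negative integer delay before surgery (cycles).
#' @param settings See [model_settings()].
#' @return A list of class `cohort_trace`: `trace` (data.frame with `cycle`,
#'   `preop`, `postop`, `dead` at cycle start, after any surgery that cycle),
#'   `qaly_total` (years) and `delay_months`.
#' @export
run_cohort <- function(params, delay_months = 0, settings = model_settings()) {
  d <- delay_months
  if (length(d) != 1L || !is.numeric(d) || d < 0 || d != round(d))
    stop("`delay_months` must be a non-negative integer", call. = FALSE)
  d <- as.integer(d)
  lt <- params$life_table
  p_bg_by_age <- lt$p_month[order(lt$age)]
  age_min <- min(lt$age)
  h_excess <- survival_to_monthly_hazard(params$s_long, params$horizon_years)

  n_cycles <- as.integer(ceiling((settings$max_age - params$age0) * 12))
  if (!is.null(settings$max_cycles))
    n_cycles <- min(n_cycles, as.integer(settings$max_cycles))
  if (n_cycles < 1L) n_cycles <- 1L
  r_month <- (1 + settings$discount_rate)^(1 / 12) - 1

  preop <- 1; postop <- 0; dead <- 0
  occ <- matrix(NA_real_, nrow = n_cycles, ncol = 3,
                dimnames = list(NULL, c("preop", "postop", "dead")))
  qaly <- 0
  used <- 0L
  for (cycle in seq_len(n_cycles) - 1L) {
    if (cycle == d) {            # surgery at the start of this cycle
      dead <- dead + preop * params$p_periop_death
      postop <- postop + preop * (1 - params$p_periop_death)
      preop <- 0
    }
    occ[cycle + 1L, ] <- c(preop, postop, dead)
    used <- cycle + 1L

    age <- floor(params$age0 + cycle / 12)
    idx <- min(max(age - age_min, 0L) + 1L, length(p_bg_by_age))
    p_bg <- p_bg_by_age[idx]

    p_die_pre <- 1 - (1 - params$p_wait_death) * (1 - p_bg)
    h_bg <- if (p_bg < 1) -log(1 - p_bg) else Inf
    p_die_post <- 1 - exp(-(h_bg + h_excess))

    preop_next <- preop * (1 - p_die_pre)
    postop_next <- postop * (1 - p_die_post)
    dead_next <- 1 - preop_next - postop_next

    start_util <- preop * params$q_pre + postop * params$q_post
    util <- if (isTRUE(settings$half_cycle)) {
      (start_util + preop_next * params$q_pre +
         postop_next * params$q_post) / 2
    } else start_util
    disc <- if (r_month > 0) (1 + r_month)^(-cycle) else 1
    qaly <- qaly + disc * util / 12

    preop <- preop_next; postop <- postop_next; dead <- dead_next
    if (preop + postop < settings$min_alive) break
  }
  structure(list(
    trace = data.frame(cycle = seq_len(used) - 1L,
                       occ[seq_len(used), , drop = FALSE]),
    qaly_total = qaly,
    delay_months = d
  ), class = "cohort_trace")
}

#' Expected health loss (DALY) per month of surgical delay
#'
#' The urgency measure: QALYs lost per month that surgery is postponed,
#' computed as the difference in total expected QALYs between immediate
#' surgery and surgery delayed by `delay_months`, divided by the delay.
#'
#' @param params A [procedure_params()].
#' @param delay_months Delay in months (integer >= 1; default 1).
#' @param settings See [model_settings()].
#' @return DALY per month of delay (years of healthy life per month).
#' @export
daly_per_month <- function(params, delay_months = 1,
                           settings = model_settings()) {
  if (delay_months < 1) stop("`delay_months` must be >= 1", call. = FALSE)
  q0 <- run_cohort(params, 0L, settings)$qaly_total
  qd <- run_cohort(params, delay_months, settings)$qaly_total
  (q0 - qd) / delay_months
}

beta_from_moments <- function(mean, se, name) {
  if (se == 0) return(list(degenerate = TRUE, mean = mean))
  if (mean <= 0 || mean >= 1)
    stop("parameter `", name, "`: Beta moment matching needs mean in (0, 1)",
         call. = FALSE)
  v <- se^2
  if (v >= mean * (1 - mean))
    stop("parameter `", name, "`: SE too large for mean (", mean,
         "); Beta moment matching infeasible", call. = FALSE)
  k <- mean * (1 - mean) / v - 1
  list(degenerate = FALSE, shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Probabilistic sensitivity analysis of DALY/month
#'
#' Propagates parameter uncertainty through the delay model: each uncertain
#' parameter (`q_pre`, `q_post`, `p_wait_death`, `p_periop_death`, `s_long`)
#' is drawn from a Beta distribution matched to its mean and SE by the method
#' of moments (a zero SE keeps the parameter fixed), DALY/month is recomputed
#' for every draw, and the 2.5/97.5 percentiles form the interval. The point
#' estimate is the model run at the mean parameters.
#'
#' @param params A [procedure_params()] holding the parameter means.
#' @param se Named numeric vector of SEs, e.g.
#'   `c(q_pre = 0.05, q_post = 0.05)`; omitted parameters are fixed.
#' @param n_samples Number of Monte-Carlo draws (>= 2; default 1000).
#' @param seed Integer seed (required for reproducibility).
#' @param delay_months Delay (months) passed to [daly_per_month()].
#' @param settings See [model_settings()].
#' @return A one-row data.frame of class `urgency_result`: `procedure_id`,
#'   `daly_per_month`, `ci_low`, `ci_high`, `n_samples`, `seed`.
#' @export
run_psa <- function(params, se = numeric(), n_samples = 1000, seed,
                    delay_months = 1, settings = model_settings()) {
  if (n_samples < 2) stop("`n_samples` must be >= 2", call. = FALSE)
  if (any(se < 0)) stop("SEs must be >= 0", call. = FALSE)
  allowed <- c("q_pre", "q_post", "p_wait_death", "p_periop_death", "s_long")
  bad <- setdiff(names(se), allowed)
  if (length(bad))
    stop("unknown PSA parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  set.seed(as.integer(seed))

  draws <- matrix(NA_real_, nrow = n_samples, ncol = length(allowed),
                  dimnames = list(NULL, allowed))
  for (p in allowed) {
    m <- params[[p]]
    s <- if (p %in% names(se)) se[[p]] else 0
    spec <- beta_from_moments(m, s, p)
    draws[, p] <- if (spec$degenerate) rep(m, n_samples) else
      stats::rbeta(n_samples, spec$shape1, spec$shape2)
  }
  point <- daly_per_month(params, delay_months, settings)
  vals <- vapply(seq_len(n_samples), function(i) {
    pi <- params
    for (p in allowed) pi[[p]] <- draws[i, p]
    daly_per_month(pi, delay_months, settings)
  }, numeric(1))
  ci <- stats::quantile(vals, c(0.025, 0.975), type = 7, names = FALSE)
  out <- data.frame(procedure_id = params$procedure_id,
                    daly_per_month = point,
                    ci_low = ci[1], ci_high = ci[2],
                    n_samples = as.integer(n_samples),
                    seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  class(out) <- c("urgency_result", "data.frame")
  out
}
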