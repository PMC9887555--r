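#' Panel configuration for synthetic expert-score generation
#'
#' Bundles the generative parameters of one expert panel: its size, a
#' panel-level systematic shift of the elicited utilities (separately for the
#' preoperative and postoperative state), the between-expert dispersion of
#' final-round scores, procedure-level heterogeneity of the shift, and the
#' strength of the second Delphi round's shrinkage toward the first-round
#' panel median.
#'
#' All quality-of-life quantities are on the utility scale (0-1); scores are
#' emitted on the 0-100 visual analogue scale (VAS).
#'
#' @param panel Panel identifier (e.g. `"original"`, `"validation"`).
#' @param n_experts Number of experts (>= 2).
#' @param shift_pre,shift_post Panel-level mean shift of the preoperative /
#'   postoperative utilities (utility scale; negative = panel scores lower).
#' @param expert_sd Between-expert standard deviation of *final-round* scores,
#'   utility scale (> 0).
#' @param tau_shift SD of the procedure-level heterogeneity of the panel
#'   shift (utility scale); one deviation is drawn per procedure and applied
#'   to both health states.
#' @param round2_shrinkage Fraction in \[0, 1\] by which round-2 scores are
#'   pulled toward the round-1 panel median.
#' @param round2_noise_sd Optional explicit SD (utility scale) of the extra
#'   round-2 noise. Default `NULL` derives it so that the marginal final-round
#'   dispersion equals `expert_sd` (see Details).
#' @param seed Integer seed driving all randomness of this panel.
#'
#' @details
#' Round-1 scores are drawn with SD `expert_sd / (1 - round2_shrinkage/2)`;
#' round-2 scores are `r1 + s * (median(r1) - r1) + eps2` with `s =
#' round2_shrinkage`. When `round2_noise_sd` is `NULL` the SD of `eps2` is set
#' to `expert_sd * sqrt(1 - ((2 - 2*s)/(2 - s))^2)`, which makes the marginal
#' SD of final-round scores equal to `expert_sd` (the quantity all downstream
#' statistics use).
#'
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(panel, n_experts, shift_pre = 0, shift_post = 0,
                         expert_sd = 0.1, tau_shift = 0,
                         round2_shrinkage = 0.5, round2_noise_sd = NULL,
                         seed = NULL) {
  if (!is.numeric(n_experts) || length(n_experts) != 1L || n_experts < 2)
    stop("`n_experts` must be a single number >= 2", call. = FALSE)
  if (!is.numeric(expert_sd) || expert_sd <= 0)
    stop("`expert_sd` must be > 0", call. = FALSE)
  if (round2_shrinkage < 0 || round2_shrinkage > 1)
    stop("`round2_shrinkage` must be in [0, 1]", call. = FALSE)
  if (tau_shift < 0) stop("`tau_shift` must be >= 0", call. = FALSE)
  structure(list(
    panel = as.character(panel),
    n_experts = as.integer(n_experts),
    shift_pre = shift_pre,
    shift_post = shift_post,
    expert_sd = expert_sd,
    tau_shift = tau_shift,
    round2_shrinkage = round2_shrinkage,
    round2_noise_sd = round2_noise_sd,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "panel_config")
}

#' Default generation ranges for procedure truths
#'
#' Ranges for the per-procedure decision-model inputs used by
#' [generate_procedure_truth()]. Defaults describe a plausible mix of
#' semi-elective oncological, cardiothoracic, vascular and transplant
#' procedures in a tertiary centre: decision ages 50-80, preoperative
#' utilities 0.40-0.70 with a 0.05-0.20 post-surgery gain (capped at 0.85 —
#' patients needing these procedures rarely return to near-perfect health),
#' and perioperative mortality 0.5-3%.
#'
#' Two structural choices mirror how such a procedure portfolio is put
#' together in practice. First, long-term post-surgery survival is coupled
#' to disease severity rather than drawn independently: the monthly excess
#' hazard after surgery is a fraction (`excess_frac_range`, 0.1-0.5) of the
#' same procedure's waiting mortality, saturating at `excess_hazard_cap`
#' (successful surgery for even the most lethal untreated conditions — a
#' rupture-prone aneurysm, say — leaves a far better prognosis than the
#' untreated disease), so surgery always reduces the death hazard — these are procedures with an established indication, where
#' delay, not surgery, causes health loss. Second, the cohort's true
#' urgencies are laid out on an explicit ladder spanning
#' `urgency_range` DALY/month (linearly spaced over the lower third up to
#' `urgency_mid`, geometrically above it), and each procedure's monthly
#' waiting mortality is calibrated by root-solving the cohort model so its
#' true-QoL urgency sits on its (randomly assigned, jittered) ladder rung.
#' A portfolio *selected* for triage spans the urgency spectrum rather than
#' clustering; the ladder emulates that selection and guarantees the spec
#' of the cohort: all urgencies positive and spanning more than an order of
#' magnitude. Utility ranges keep score distributions away from the 0/100
#' VAS bounds so clipping bias stays negligible even at the validation
#' panel's wider round-1 dispersion.
#'
#' @param age_range Years at decision, `c(min, max)`.
#' @param q_pre_range Preoperative utility range.
#' @param q_gain_range Post-surgery utility gain range.
#' @param q_post_max Cap on postoperative utility.
#' @param p_periop_range Perioperative mortality probability range.
#' @param excess_frac_range Post-surgery monthly excess hazard as a fraction
#'   of the same procedure's waiting mortality (both reflect the underlying
#'   disease; the fraction < 1 encodes the surgical benefit).
#' @param excess_hazard_cap Waiting-mortality level at which the carried-over
#'   excess hazard saturates.
#' @param urgency_range True DALY/month span of the procedure ladder,
#'   `c(min, max)`.
#' @param urgency_mid Ladder value at which linear spacing (below) hands
#'   over to geometric spacing (above).
#' @param urgency_jitter Relative log-jitter applied to each ladder rung.
#' @param horizon_years Horizon over which `s_long` applies (years).
#' @return A named list of ranges.
#' @export
truth_ranges <- function(age_range = c(50, 80),
                         q_pre_range = c(0.40, 0.70),
                         q_gain_range = c(0.05, 0.20),
                         q_post_max = 0.85,
                         p_periop_range = c(0.005, 0.03),
                         excess_frac_range = c(0.1, 0.5),
                         excess_hazard_cap = 0.02,
                         urgency_range = c(0.02, 0.35),
                         urgency_mid = 0.06,
                         urgency_jitter = 0.02,
                         horizon_years = 5) {
  list(age_range = age_range, q_pre_range = q_pre_range,
       q_gain_range = q_gain_range, q_post_max = q_post_max,
       p_periop_range = p_periop_range,
       excess_frac_range = excess_frac_range,
       excess_hazard_cap = excess_hazard_cap,
       urgency_range = urgency_range, urgency_mid = urgency_mid,
       urgency_jitter = urgency_jitter, horizon_years = horizon_years)
}

urgency_ladder <- function(n, lo, mid, hi) {
  # lower third linearly spaced (absolute resolution), rest geometric
  n_lin <- floor(n / 3)
  n_geo <- n - n_lin
  lin <- if (n_lin >= 1) seq(lo, mid, length.out = n_lin + 1)[1:n_lin]
  geo <- if (n_geo == 1) mid else
    mid * (hi / mid)^((seq_len(n_geo) - 1) / (n_geo - 1))
  c(lin, geo)
}

#' Generate per-procedure ground truth
#'
#' Draws `n_proc` procedures with true pre/postoperative utilities and
#' decision-model survival parameters; `n_gbd` of them are flagged as
#' GBD-derived, i.e. their quality-of-life weights come from published
#' disability weights (utility = 1 - disability weight) rather than panel
#' elicitation, so both panels share them exactly.
#'
#' @param n_proc Number of procedures (>= 1).
#' @param n_gbd Number of GBD-derived procedures (0 <= n_gbd <= n_proc).
#' @param seed Integer seed.
#' @param ranges Generation ranges, see [truth_ranges()].
#' @param life_table Background life table used when calibrating waiting
#'   mortality to the urgency ladder.
#' @return A data.frame with one row per procedure: `procedure_id`,
#'   `true_q_pre`, `true_q_post`, `gbd_derived`, `age0`, `p_wait_death`,
#'   `p_periop_death`, `s_long`, `horizon_years`, `true_daly_month`.
#' @export
generate_procedure_truth <- function(n_proc, n_gbd = 0, seed = 1,
                                     ranges = truth_ranges(),
                                     life_table = generate_life_table()) {
  if (!is.numeric(n_proc) || length(n_proc) != 1L || n_proc < 1 ||
      n_proc != round(n_proc))
    stop("`n_proc` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_gbd) || n_gbd < 0 || n_gbd > n_proc ||
      n_gbd != round(n_gbd))
    stop("`n_gbd` must be an integer in [0, n_proc]", call. = FALSE)
  set.seed(as.integer(seed))
  n_proc <- as.integer(n_proc); n_gbd <- as.integer(n_gbd)
  q_pre <- stats::runif(n_proc, ranges$q_pre_range[1], ranges$q_pre_range[2])
  q_post <- pmin(q_pre + stats::runif(n_proc, ranges$q_gain_range[1],
                                      ranges$q_gain_range[2]),
                 ranges$q_post_max)
  gbd <- seq_len(n_proc) %in% sample.int(n_proc, n_gbd)
  age0 <- round(stats::runif(n_proc, ranges$age_range[1],
                             ranges$age_range[2]))
  p_periop <- stats::runif(n_proc, ranges$p_periop_range[1],
                           ranges$p_periop_range[2])
  excess_frac <- stats::runif(n_proc, ranges$excess_frac_range[1],
                              ranges$excess_frac_range[2])
  rungs <- urgency_ladder(n_proc, ranges$urgency_range[1],
                          ranges$urgency_mid, ranges$urgency_range[2])
  target <- sample(rungs) *
    exp(stats::runif(n_proc, -ranges$urgency_jitter, ranges$urgency_jitter))

  # calibrate waiting mortality so the true-QoL urgency hits its rung;
  # s_long is tied to it (treated course keeps a fraction of the hazard)
  p_wait <- numeric(n_proc)
  s_long <- numeric(n_proc)
  for (i in seq_len(n_proc)) {
    daly_at <- function(pw) {
      pp <- procedure_params(
        procedure_id = "cal", age0 = age0[i],
        q_pre = q_pre[i], q_post = q_post[i],
        p_wait_death = pw, p_periop_death = p_periop[i],
        s_long = exp(-12 * ranges$horizon_years * excess_frac[i] *
                       min(pw, ranges$excess_hazard_cap)),
        horizon_years = ranges$horizon_years, life_table = life_table)
      daly_per_month(pp, 1)
    }
    root <- stats::uniroot(function(pw) daly_at(pw) - target[i],
                           interval = c(1e-6, 0.6), tol = 1e-7)
    p_wait[i] <- root$root
    s_long[i] <- exp(-12 * ranges$horizon_years * excess_frac[i] *
                       min(p_wait[i], ranges$excess_hazard_cap))
  }
  data.frame(
    procedure_id = sprintf("P%02d", seq_len(n_proc)),
    true_q_pre = q_pre,
    true_q_post = q_post,
    gbd_derived = gbd,
    age0 = age0,
    p_wait_death = p_wait,
    p_periop_death = p_periop,
    s_long = s_long,
    horizon_years = ranges$horizon_years,
    true_daly_month = target,
    stringsAsFactors = FALSE
  )
}

#' Generate two-round expert scores for one panel
#'
#' For each non-GBD procedure x state x expert, draws a round-1 VAS score
#' around `100 * (truth + state shift + procedure-level shift)`, then forms
#' the round-2 (final) score by shrinking toward the round-1 panel median and
#' adding residual noise. GBD-derived procedures emit the fixed utility
#' (x 100) for every expert in both rounds, with zero dispersion. All scores
#' are clipped to \[0, 100\].
#'
#' @param truths Data.frame from [generate_procedure_truth()].
#' @param cfg A [panel_config()] (its `seed` must be set).
#' @return A data.frame of expert scores in long format: `panel`, `round`,
#'   `expert_id`, `procedure_id`, `state` (`"pre"`/`"post"`), `vas`.
#' @export
generate_panel_scores <- function(truths, cfg) {
  if (!inherits(cfg, "panel_config")) stop("`cfg` must be a panel_config",
                                           call. = FALSE)
  if (!is.data.frame(truths) || nrow(truths) == 0L)
    stop("`truths` must be a non-empty data.frame", call. = FALSE)
  if (is.null(cfg$seed)) stop("`cfg$seed` must be set", call. = FALSE)
  set.seed(cfg$seed)

  s <- cfg$round2_shrinkage
  sd_final <- 100 * cfg$expert_sd
  sd_r1 <- sd_final / (1 - s / 2)
  sd_r2 <- if (!is.null(cfg$round2_noise_sd)) {
    100 * cfg$round2_noise_sd
  } else {
    # derived so the marginal final-round SD equals expert_sd
    sd_final * sqrt(max(0, 1 - ((2 - 2 * s) / (2 - s))^2))
  }

  n_e <- cfg$n_experts
  experts <- sprintf("E%02d", seq_len(n_e))
  # one shift deviation per procedure, shared by both states
  proc_dev <- stats::rnorm(nrow(truths), 0, cfg$tau_shift)

  out <- vector("list", 2L * nrow(truths))
  k <- 0L
  for (i in seq_len(nrow(truths))) {
    for (state in c("pre", "post")) {
      truth_q <- if (state == "pre") truths$true_q_pre[i] else
        truths$true_q_post[i]
      if (truths$gbd_derived[i]) {
        v1 <- v2 <- rep(100 * truth_q, n_e)
      } else {
        shift <- if (state == "pre") cfg$shift_pre else cfg$shift_post
        centre <- 100 * (truth_q + shift + proc_dev[i])
        v1 <- pmin(pmax(stats::rnorm(n_e, centre, sd_r1), 0), 100)
        v2 <- v1 + s * (stats::median(v1) - v1) +
          stats::rnorm(n_e, 0, sd_r2)
        v2 <- pmin(pmax(v2, 0), 100)
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        panel = cfg$panel,
        round = rep(c(1L, 2L), each = n_e),
        expert_id = rep(experts, 2L),
        procedure_id = truths$procedure_id[i],
        state = state,
        vas = c(v1, v2),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Study-emulation preset: two panels, 43 procedures
#'
#' Returns the configuration of the package's reference two-panel validation
#' experiment: 43 procedures of which 9 carry fixed GBD-derived weights; an
#' 18-expert original panel with no systematic shift and final-round
#' dispersion 0.10; and a 15-expert validation panel scoring systematically
#' lower (-0.14 preoperative, -0.08 postoperative, i.e. -0.11 averaged over
#' states) with higher dispersion (0.16) and procedure-level shift
#' heterogeneity 0.06. Both panels shrink round-2 scores halfway toward the
#' round-1 median. All values on the utility scale.
#'
#' @return A list with elements `n_proc`, `n_gbd`, `ranges`, `original`
#'   and `validation` (two [panel_config()]s without seeds).
#' @export
study_emulation_preset <- function() {
  list(
    n_proc = 43L,
    n_gbd = 9L,
    ranges = truth_ranges(),
    original = panel_config("original", n_experts = 18,
                            shift_pre = 0, shift_post = 0,
                            expert_sd = 0.10, tau_shift = 0,
                            round2_shrinkage = 0.5),
    validation = panel_config("validation", n_experts = 15,
                              shift_pre = -0.14, shift_post = -0.08,
                              expert_sd = 0.16, tau_shift = 0.06,
                              round2_shrinkage = 0.5)
  )
}

#' Generate a Gompertz life table of monthly background mortality
#'
#' Monthly background death probability per integer age under a Gompertz
#' hazard `a * exp(b * age)` per year: `p = 1 - exp(-a * exp(b * age) / 12)`,
#' forced to 1 at `max_age` so the table's oldest age is absorbing.
#'
#' @param a Baseline hazard per year (> 0).
#' @param b Gompertz slope per year (>= 0).
#' @param max_age Last tabulated age (<= 120).
#' @return Data.frame with columns `age` (0..max_age) and `p_month`.
#' @export
generate_life_table <- function(a = 1e-4, b = 0.09, max_age = 100) {
  if (!is.numeric(a) || a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (b < 0) stop("`b` must be >= 0", call. = FALSE)
  if (max_age > 120) stop("`max_age` must be <= 120", call. = FALSE)
  age <- 0:max_age
  p <- 1 - exp(-a * exp(b * age) / 12)
  p[age == max_age] <- 1
  data.frame(age = age, p_month = pmin(p, 1))
}
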