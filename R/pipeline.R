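#' Derive a module sub-seed from the root seed
#'
#' All randomness in a pipeline run flows from one root seed; each module
#' draws from its own deterministic sub-stream so stages are independently
#' reproducible.
#'
#' @param seed Root integer seed.
#' @param k Sub-stream index (0 = truths, 1 = original panel, 2 = validation
#'   panel, 3 = PSA, ...).
#' @return An integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

#' Run configuration for the end-to-end analysis
#'
#' @param seed Root seed (required whenever any stochastic step is enabled).
#' @param delay_months Delay used for DALY/month (default 1).
#' @param psa Run probabilistic sensitivity analysis per procedure.
#' @param psa_n PSA draws per procedure.
#' @param pooling `"experts"` or `"panel_means"` (see [pool_panels()]).
#' @param discount_rate,half_cycle Model options, see [model_settings()].
#' @param sd_scale Scale of the consensus SDs, `"utility"` or `"vas"`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed, delay_months = 1, psa = FALSE, psa_n = 1000,
                       pooling = c("experts", "panel_means"),
                       discount_rate = 0, half_cycle = FALSE,
                       sd_scale = c("utility", "vas")) {
  structure(list(
    seed = as.integer(seed), delay_months = delay_months,
    psa = psa, psa_n = psa_n, pooling = match.arg(pooling),
    discount_rate = discount_rate, half_cycle = half_cycle,
    sd_scale = match.arg(sd_scale)
  ), class = "run_config")
}

#' Hash of a configuration (for output provenance)
#'
#' MD5 of the canonical JSON serialization; recorded in every output
#' manifest together with the seed that produced the file.
#'
#' @param config Any JSON-serializable list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  config <- config[!vapply(config, is.function, logical(1))]
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(js, f)
  unname(tools::md5sum(f))
}

#' Validate an expert-score table
#'
#' Checks the schema of a long-format score table: required columns, VAS
#' range, round values, and uniqueness of
#' (panel, round, expert_id, procedure_id, state). Errors name the file (if
#' given), row and column of the first violation.
#'
#' @param scores Data.frame to validate.
#' @param file Optional file name for error messages.
#' @return The validated data.frame, invisibly.
#' @export
validate_expert_scores <- function(scores, file = NULL) {
  where <- if (is.null(file)) "expert scores" else paste0("file ", file)
  need <- c("panel", "round", "expert_id", "procedure_id", "state", "vas")
  miss <- setdiff(need, names(scores))
  if (length(miss))
    stop(where, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(scores$vas) | scores$vas < 0 | scores$vas > 100)
  if (length(bad))
    stop(where, ", row ", bad[1], ", column vas: value ",
         scores$vas[bad[1]], " outside [0, 100]", call. = FALSE)
  bad <- which(!scores$round %in% c(1, 2))
  if (length(bad))
    stop(where, ", row ", bad[1], ", column round: value ",
         scores$round[bad[1]], " not in {1, 2}", call. = FALSE)
  bad <- which(!scores$state %in% c("pre", "post"))
  if (length(bad))
    stop(where, ", row ", bad[1], ", column state: value \"",
         scores$state[bad[1]], "\" not in {pre, post}", call. = FALSE)
  key <- paste(scores$panel, scores$round, scores$expert_id,
               scores$procedure_id, scores$state)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(where, ", row ", dup[1],
         ": duplicate (panel, round, expert, procedure, state) key",
         call. = FALSE)
  invisible(scores)
}

#' Read / write pipeline CSV tables
#'
#' Plain-CSV readers and writers for the pipeline's tables. Reading expert
#' scores validates the schema and reports the offending file/row/column on
#' failure.
#'
#' @param path CSV file path.
#' @param x Table to write.
#' @return The table (readers) or the path, invisibly (writers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_expert_scores <- function(path) {
  scores <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_expert_scores(scores, file = basename(path))
  scores
}

#' @rdname pipeline_io
#' @export
write_expert_scores <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_procedure_truths <- function(path) {
  truths <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("procedure_id", "true_q_pre", "true_q_post", "gbd_derived",
            "age0", "p_wait_death", "p_periop_death", "s_long",
            "horizon_years")
  miss <- setdiff(need, names(truths))
  if (length(miss))
    stop("file ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  truths$gbd_derived <- as.logical(truths$gbd_derived)
  truths
}

#' @rdname pipeline_io
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "p_month") %in% names(lt)))
    stop("file ", basename(path), ": needs columns age, p_month",
         call. = FALSE)
  lt
}

#' @rdname pipeline_io
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a two-panel elicitation study
#'
#' Generates procedure truths, a background life table, and both panels'
#' two-round score tables from a preset (default: the 43-procedure
#' study-emulation preset, see [study_emulation_preset()]). Sub-seeds for
#' truths and the two panels are derived deterministically from `seed`.
#'
#' @param seed Root integer seed.
#' @param preset A preset list as returned by [study_emulation_preset()],
#'   or the name `"study2023"`.
#' @param out_dir Optional directory; if given, writes `truths.csv`,
#'   `life_table.csv`, `scores.csv` and a `manifest.json` carrying the seed
#'   and config hash.
#' @return A list: `truths`, `life_table`, `scores` (both panels, both
#'   rounds), `preset`, `seed`.
#' @export
simulate_study <- function(seed, preset = "study2023", out_dir = NULL) {
  if (is.character(preset)) {
    known <- c("study2023")
    if (!preset %in% known)
      stop("unknown preset \"", preset, "\"; available: ",
           paste(known, collapse = ", "), call. = FALSE)
    preset <- study_emulation_preset()
  }
  truths <- generate_procedure_truth(preset$n_proc, preset$n_gbd,
                                     seed = derive_seed(seed, 0),
                                     ranges = preset$ranges)
  life_table <- generate_life_table()
  cfg_o <- preset$original; cfg_o$seed <- derive_seed(seed, 1)
  cfg_v <- preset$validation; cfg_v$seed <- derive_seed(seed, 2)
  class(cfg_o) <- class(cfg_v) <- "panel_config"
  scores <- rbind(generate_panel_scores(truths, cfg_o),
                  generate_panel_scores(truths, cfg_v))
  sim <- list(truths = truths, life_table = life_table, scores = scores,
              preset = preset, seed = as.integer(seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(truths, file.path(out_dir, "truths.csv"))
    write_table_csv(life_table, file.path(out_dir, "life_table.csv"))
    write_expert_scores(scores, file.path(out_dir, "scores.csv"))
    manifest <- list(seed = sim$seed,
                     config_hash = config_hash(
                       list(preset = preset[c("n_proc", "n_gbd")],
                            seed = sim$seed)),
                     files = c("truths.csv", "life_table.csv", "scores.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  sim
}

qol_input_table <- function(estimates, truths, panels, pooling = "experts") {
  # per-procedure q_pre/q_post under a QoL source: one panel or the pool
  get_q <- function(pid, state) {
    if (identical(panels, "pooled")) {
      rows <- estimates[estimates$procedure_id == pid &
                          estimates$state == state &
                          estimates$panel %in% c("original", "validation"), ]
      if (pooling == "panel_means") return(mean(rows$q_mean))
      stats::weighted.mean(rows$q_mean, rows$n)
    } else {
      rows <- estimates[estimates$procedure_id == pid &
                          estimates$state == state &
                          estimates$panel %in% panels, ]
      rows$q_mean[1]
    }
  }
  data.frame(
    procedure_id = truths$procedure_id,
    q_pre = vapply(truths$procedure_id, get_q, numeric(1), state = "pre"),
    q_post = vapply(truths$procedure_id, get_q, numeric(1), state = "post"),
    stringsAsFactors = FALSE
  )
}

#' Urgency (DALY/month) for every procedure under given QoL inputs
#'
#' Builds [procedure_params()] per procedure from the survival inputs in
#' `truths` and the supplied QoL table, and computes DALY per month of delay
#' (optionally with PSA intervals).
#'
#' @param truths Procedure table with survival inputs (see
#'   [generate_procedure_truth()]).
#' @param qol Data.frame `procedure_id`, `q_pre`, `q_post`.
#' @param life_table Background life table.
#' @param config A [run_config()].
#' @param psa_se Optional data.frame `procedure_id`, `se_pre`, `se_post`
#'   enabling Beta-PSA on the two utilities when `config$psa` is `TRUE`.
#' @return Data.frame `procedure_id`, `daly_per_month` (+ `ci_low`,
#'   `ci_high`, `n_samples`, `seed` when PSA is on).
#' @export
compute_urgency <- function(truths, qol, life_table, config,
                            psa_se = NULL) {
  settings <- model_settings(discount_rate = config$discount_rate,
                             half_cycle = config$half_cycle)
  rows <- lapply(seq_len(nrow(truths)), function(i) {
    pid <- truths$procedure_id[i]
    qi <- qol[qol$procedure_id == pid, ]
    params <- procedure_params(
      procedure_id = pid, age0 = truths$age0[i],
      q_pre = qi$q_pre, q_post = qi$q_post,
      p_wait_death = truths$p_wait_death[i],
      p_periop_death = truths$p_periop_death[i],
      s_long = truths$s_long[i],
      horizon_years = truths$horizon_years[i],
      life_table = life_table)
    if (isTRUE(config$psa)) {
      se <- c(q_pre = 0, q_post = 0)
      if (!is.null(psa_se)) {
        si <- psa_se[psa_se$procedure_id == pid, ]
        if (nrow(si)) se <- c(q_pre = si$se_pre, q_post = si$se_post)
      }
      run_psa(params, se = se[se > 0], n_samples = config$psa_n,
              seed = derive_seed(config$seed, 3) + i,
              delay_months = config$delay_months, settings = settings)
    } else {
      data.frame(procedure_id = pid,
                 daly_per_month = daly_per_month(
                   params, config$delay_months, settings),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Run the full two-panel validation analysis
#'
#' Chains elicitation, agreement and consensus statistics, the decision
#' model, and ranking robustness on a simulated or supplied study:
#' \enumerate{
#'   \item aggregate final-round scores into per-panel QoL estimates;
#'   \item Bland-Altman comparison of the panels' mean utilities, separately
#'     for the pre- and postoperative state (panel-rated procedures only);
#'   \item random-intercept mixed models on individual expert utilities and
#'     on between-expert SDs (consensus), with residual diagnostics;
#'   \item DALY/month per procedure under original-only vs pooled QoL inputs,
#'     and the Spearman comparison of the two urgency rankings.
#' }
#'
#' @param sim A list as returned by [simulate_study()] (`truths`,
#'   `life_table`, `scores`), or a directory containing `truths.csv`,
#'   `life_table.csv`, `scores.csv`.
#' @param config A [run_config()]; defaults to `run_config(sim$seed)`.
#' @return A list of class `study_report` with elements `seed`,
#'   `config_hash`, `estimates`, `bland_altman` (`pre`, `post`),
#'   `score_model`, `sd_model`, `diagnostics`, `urgency` (`original`,
#'   `pooled`), `ranking` (a `ranking_comparison`) and `headline` (flat named
#'   list of the headline numbers).
#' @export
run_study <- function(sim, config = NULL) {
  if (is.character(sim)) {
    dir <- sim
    sim <- list(truths = read_procedure_truths(file.path(dir, "truths.csv")),
                life_table = read_life_table(file.path(dir, "life_table.csv")),
                scores = read_expert_scores(file.path(dir, "scores.csv")),
                seed = NA_integer_)
  }
  validate_expert_scores(sim$scores)
  if (is.null(config)) config <- run_config(seed = sim$seed)

  estimates <- estimate_qol(sim$scores)
  panel_ids <- !sim$truths$gbd_derived
  panel_procs <- sim$truths$procedure_id[panel_ids]

  ba <- lapply(c(pre = "pre", post = "post"), function(st) {
    sub <- estimates[estimates$state == st &
                       estimates$procedure_id %in% panel_procs, ]
    wide <- merge(
      sub[sub$panel == "original", c("procedure_id", "q_mean")],
      sub[sub$panel == "validation", c("procedure_id", "q_mean")],
      by = "procedure_id", suffixes = c("_orig", "_val"))
    bland_altman(wide$q_mean_orig, wide$q_mean_val, ids = wide$procedure_id)
  })

  panel_scores <- sim$scores[sim$scores$procedure_id %in% panel_procs, ]
  score_fit <- fit_random_intercept_model(score_model_table(panel_scores),
                                          response_kind = "score")
  sd_fit <- fit_random_intercept_model(
    sd_model_table(panel_scores, scale = config$sd_scale),
    response_kind = "sd")
  diagnostics <- list(score = residual_diagnostics(score_fit),
                      sd = residual_diagnostics(sd_fit))

  qol_orig <- qol_input_table(estimates, sim$truths, "original")
  qol_pool <- qol_input_table(estimates, sim$truths, "pooled",
                              pooling = config$pooling)
  urg_orig <- compute_urgency(sim$truths, qol_orig, sim$life_table, config)
  urg_pool <- compute_urgency(sim$truths, qol_pool, sim$life_table, config)
  ranking <- compare_rankings(urg_orig, urg_pool)

  sc <- study_coefficient(score_fit)
  sd_c <- study_coefficient(sd_fit)
  report <- list(
    seed = config$seed,
    config_hash = config_hash(unclass(config)),
    estimates = estimates,
    bland_altman = ba,
    score_model = score_fit,
    sd_model = sd_fit,
    diagnostics = diagnostics,
    urgency = list(original = urg_orig, pooled = urg_pool),
    ranking = ranking,
    headline = list(
      bias_pre = ba$pre$bias, loa_pre = c(ba$pre$loa_low, ba$pre$loa_high),
      bias_post = ba$post$bias,
      loa_post = c(ba$post$loa_low, ba$post$loa_high),
      study_coef_score = unname(sc["estimate"]),
      study_coef_score_ci = unname(sc[c("ci_low", "ci_high")]),
      study_coef_sd = unname(sd_c["estimate"]),
      study_coef_sd_ci = unname(sd_c[c("ci_low", "ci_high")]),
      rho = ranking$rho,
      max_change_procedure = ranking$max_change_procedure,
      n_procedures = nrow(sim$truths),
      n_panel_rated = length(panel_procs))
  )
  class(report) <- "study_report"
  report
}

#' Write a study report to JSON (plus CSV side tables)
#'
#' Serializes the headline quantities, coefficient tables, Bland-Altman
#' results and rankings to one JSON file; optionally writes the plotting/
#' table CSVs next to it.
#'
#' @param report A `study_report` from [run_study()].
#' @param path Output JSON path.
#' @param tables Also write `estimates.csv`, `urgency_*.csv`, `ranking.csv`,
#'   `bland_altman_*.csv` beside the JSON.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, tables = FALSE) {
  ba_out <- lapply(report$bland_altman, function(b)
    b[c("bias", "sd_diff", "loa_low", "loa_high", "diff_min", "diff_max",
        "n_pairs")])
  out <- list(
    seed = report$seed,
    config_hash = report$config_hash,
    headline = report$headline,
    bland_altman = ba_out,
    score_model = list(coefficients = report$score_model$coefficients,
                       var_random = report$score_model$var_random,
                       var_residual = report$score_model$var_residual,
                       converged = report$score_model$converged),
    sd_model = list(coefficients = report$sd_model$coefficients,
                    var_random = report$sd_model$var_random,
                    var_residual = report$sd_model$var_residual,
                    converged = report$sd_model$converged),
    diagnostics = lapply(report$diagnostics, function(d)
      d[c("shapiro_w", "shapiro_p", "scale_location_slope", "n")]),
    ranking = list(rho = report$ranking$rho, n = report$ranking$n,
                   max_change_procedure = report$ranking$max_change_procedure,
                   max_change = report$ranking$max_change)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (tables) {
    dir <- dirname(path)
    write_table_csv(report$estimates, file.path(dir, "estimates.csv"))
    write_table_csv(report$urgency$original,
                    file.path(dir, "urgency_original.csv"))
    write_table_csv(report$urgency$pooled,
                    file.path(dir, "urgency_pooled.csv"))
    write_table_csv(report$ranking$table, file.path(dir, "ranking.csv"))
    for (st in names(report$bland_altman))
      write_table_csv(report$bland_altman[[st]]$coords,
                      file.path(dir, paste0("bland_altman_", st, ".csv")))
  }
  invisible(path)
}

#' @export
print.study_report <- function(x, ...) {
  h <- x$headline
  cat(sprintf(paste0(
    "Two-panel validation study (%d procedures, %d panel-rated)\n",
    "  Bland-Altman bias: pre %.3f [LoA %.3f, %.3f], post %.3f [LoA %.3f, %.3f]\n",
    "  study coefficient (scores): %.3f [%.3f, %.3f]\n",
    "  study coefficient (consensus SDs): %.3f [%.3f, %.3f]\n",
    "  ranking robustness: Spearman rho = %.3f (largest change: %s)\n"),
    h$n_procedures, h$n_panel_rated,
    h$bias_pre, h$loa_pre[1], h$loa_pre[2],
    h$bias_post, h$loa_post[1], h$loa_post[2],
    h$study_coef_score, h$study_coef_score_ci[1], h$study_coef_score_ci[2],
    h$study_coef_sd, h$study_coef_sd_ci[1], h$study_coef_sd_ci[2],
    h$rho, h$max_change_procedure))
  invisible(x)
}
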