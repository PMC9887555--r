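test_that("Bland-Altman bias and limits of agreement match hand computation", {
  # differences -0.1 and -0.2: bias -0.15, sd 0.070711
  ba <- bland_altman(original = c(0.8, 0.7), validation = c(0.7, 0.5))
  expect_equal(ba$bias, -0.15)
  expect_equal(ba$sd_diff, sd(c(-0.1, -0.2)))
  expect_equal(ba$loa_low, -0.15 - 1.96 * ba$sd_diff, tolerance = 1e-12)
  expect_equal(round(c(ba$loa_low, ba$loa_high), 4), c(-0.2886, -0.0114))
  expect_equal(c(ba$diff_min, ba$diff_max), c(-0.2, -0.1))
  expect_equal(ba$coords$mean, c(0.75, 0.6))

  same <- bland_altman(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))

  expect_error(bland_altman(0.5, 0.5), "2 pairs")
  expect_error(bland_altman(c(0.5, 0.6), 0.5), "length")
})

test_that("swapping the panels negates bias, limits and extremes", {
  set.seed(3)
  a <- runif(12, 0.3, 0.9); b <- a + rnorm(12, -0.1, 0.05)
  ab <- bland_altman(a, b); ba <- bland_altman(b, a)
  expect_equal(ba$bias, -ab$bias)
  expect_equal(ba$loa_low, -ab$loa_high)
  expect_equal(ba$loa_high, -ab$loa_low)
  expect_equal(ba$diff_min, -ab$diff_max)
  expect_equal(ba$diff_max, -ab$diff_min)
})

balanced_table <- function(delta = -0.1, noise_sd = 0, n_rep = 3,
                           n_proc = 4, seed = 1) {
  set.seed(seed)
  g <- expand.grid(rep = seq_len(n_rep),
                   study = c("original", "validation"),
                   state = c("pre", "post"),
                   procedure = sprintf("P%d", seq_len(n_proc)),
                   stringsAsFactors = FALSE)
  proc_eff <- setNames(runif(n_proc, 0.4, 0.7), sprintf("P%d", seq_len(n_proc)))
  g$response <- proc_eff[g$procedure] +
    ifelse(g$state == "post", 0.1, 0) +
    ifelse(g$study == "validation", delta, 0) +
    rnorm(nrow(g), 0, noise_sd)
  g
}

test_that("the random-intercept model recovers a noiseless study shift exactly", {
  # zero residual variance is numerically degenerate for REML, so the
  # optimizer may warn; the coefficient must still be exact
  fit <- suppressWarnings(
    fit_random_intercept_model(balanced_table(delta = -0.12), "score"))
  expect_equal(unname(study_coefficient(fit)["estimate"]), -0.12,
               tolerance = 1e-10)
  expect_equal(nrow(fit$random_intercepts), 4)
})

test_that("balanced-design study coefficient equals the difference of means", {
  # closed-form oracle: in a balanced design the GLS estimate of the
  # study effect reduces to mean(validation) - mean(original)
  tab <- balanced_table(delta = -0.08, noise_sd = 0.05, seed = 7)
  fit <- fit_random_intercept_model(tab, "score")
  oracle <- mean(tab$response[tab$study == "validation"]) -
    mean(tab$response[tab$study == "original"])
  expect_equal(unname(study_coefficient(fit)["estimate"]), oracle,
               tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("study coefficient is invariant to per-procedure constants", {
  tab <- balanced_table(delta = -0.08, noise_sd = 0.03, seed = 9)
  fit1 <- fit_random_intercept_model(tab, "score")
  shift <- setNames(runif(4, -0.3, 0.3), sprintf("P%d", 1:4))
  tab2 <- tab
  tab2$response <- tab2$response + shift[tab2$procedure]
  fit2 <- fit_random_intercept_model(tab2, "score")
  expect_equal(study_coefficient(fit1)["estimate"],
               study_coefficient(fit2)["estimate"], tolerance = 1e-6)
})

test_that("model fitting validates its inputs", {
  tab <- balanced_table()
  expect_error(fit_random_intercept_model(tab[, -5], "score"), "lacks")
  one_study <- tab[tab$study == "original", ]
  expect_error(fit_random_intercept_model(one_study, "score"),
               "both study levels")
  one_proc <- tab[tab$procedure == "P1", ]
  expect_error(fit_random_intercept_model(one_proc, "score"),
               "2 procedures")
})

test_that("procedure heterogeneity shows up in the random intercepts", {
  # panels that only differ by tau_shift: the heterogeneous set must show
  # a larger spread of per-procedure intercepts in the score model
  tr <- generate_procedure_truth(10, 0, seed = 21)
  mk <- function(tau, seed) {
    sc <- rbind(
      generate_panel_scores(tr, panel_config("original", 12, seed = seed)),
      generate_panel_scores(tr, panel_config("validation", 12,
                                             tau_shift = tau,
                                             seed = seed + 1)))
    fit_random_intercept_model(score_model_table(sc), "score")
  }
  f0 <- mk(0, 31); f1 <- mk(0.15, 31)
  expect_lt(sd(f0$random_intercepts$intercept) - 1e-9,
            sd(f1$random_intercepts$intercept))
})

test_that("residual diagnostics flag degenerate fits and detect heteroscedasticity", {
  perfect <- lm(y ~ x, data = data.frame(x = 1:10, y = (1:10) * 2))
  d0 <- residual_diagnostics(perfect)
  expect_equal(d0$scale_location_slope, 0, tolerance = 1e-6)
  expect_false(d0$normality_test_available)

  set.seed(2)
  x <- runif(300, 1, 10)
  het <- lm(y ~ x, data = data.frame(x = x, y = x + rnorm(300, 0, 0.2 * x)))
  dh <- residual_diagnostics(het)
  expect_gt(dh$scale_location_slope, 0)
  expect_equal(dh$n, 300)
  expect_equal(nrow(dh$residuals_vs_fitted), 300)
})

test_that("the normality check is calibrated on normal residuals", {
  pass <- replicate(100, {
    x <- runif(500)
    fit <- lm(y ~ x, data = data.frame(x = x, y = 2 * x + rnorm(500)))
    residual_diagnostics(fit)$shapiro_p > 0.05
  })
  expect_gte(mean(pass), 0.9)
})

test_that("consensus SD tables carry the between-expert dispersion per cell", {
  tr <- small_truths(n_proc = 3, n_gbd = 1)
  sc <- rbind(
    generate_panel_scores(tr, small_panel("original", seed = 13)),
    generate_panel_scores(tr, small_panel("validation", seed = 14,
                                          expert_sd = 0.2)))
  tab <- consensus_sd_table(sc)
  expect_equal(nrow(tab), 12)   # 2 panels x 3 procedures x 2 states
  gbd <- tr$procedure_id[tr$gbd_derived]
  expect_true(all(tab$sd[tab$procedure_id == gbd] == 0))
  vas <- consensus_sd_table(sc, scale = "vas")
  expect_equal(vas$sd, tab$sd * 100)
})
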