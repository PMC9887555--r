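test_that("procedure truth generation respects counts, flags and ordering", {
  tr <- generate_procedure_truth(43, 9, seed = 1)
  expect_equal(nrow(tr), 43)
  expect_equal(sum(tr$gbd_derived), 9)
  expect_true(all(tr$true_q_pre <= tr$true_q_post))
  expect_true(all(tr$true_q_pre >= 0 & tr$true_q_post <= 1))

  one <- generate_procedure_truth(1, 0, seed = 0)
  expect_equal(nrow(one), 1)
  expect_lte(one$true_q_pre, one$true_q_post)

  allg <- generate_procedure_truth(5, 5, seed = 2)
  expect_true(all(allg$gbd_derived))

  expect_error(generate_procedure_truth(0, 0), "positive integer")
  expect_error(generate_procedure_truth(3, 4), "n_gbd")
})

test_that("true urgencies are positive and span over an order of magnitude", {
  tr <- generate_procedure_truth(43, 9, seed = 7)
  expect_true(all(tr$true_daly_month > 0))
  expect_gte(max(tr$true_daly_month) / min(tr$true_daly_month), 10)
  # calibration: model at true QoL reproduces the assigned urgency
  lt <- generate_life_table()
  for (i in c(1, 20, 43)) {
    pp <- procedure_params(tr$procedure_id[i], tr$age0[i], tr$true_q_pre[i],
                           tr$true_q_post[i], tr$p_wait_death[i],
                           tr$p_periop_death[i], tr$s_long[i],
                           tr$horizon_years[i], lt)
    expect_equal(daly_per_month(pp, 1), tr$true_daly_month[i],
                 tolerance = 1e-4)
  }
})

test_that("zero-noise panels reproduce the truth exactly", {
  tr <- small_truths(n_proc = 3, n_gbd = 0)
  cfg <- panel_config("p", 5, shift_pre = 0, shift_post = 0,
                      expert_sd = 1e-9, tau_shift = 0, seed = 3)
  sc <- generate_panel_scores(tr, cfg)
  final <- sc[sc$round == 2, ]
  truth_vas <- ifelse(final$state == "pre",
                      tr$true_q_pre[match(final$procedure_id,
                                          tr$procedure_id)],
                      tr$true_q_post[match(final$procedure_id,
                                           tr$procedure_id)]) * 100
  expect_equal(final$vas, truth_vas, tolerance = 1e-5)
})

test_that("full shrinkage with zero round-2 noise collapses to the round-1 median", {
  tr <- small_truths(n_proc = 2, n_gbd = 0)
  cfg <- panel_config("p", 7, expert_sd = 0.1, round2_shrinkage = 1,
                      round2_noise_sd = 0, seed = 5)
  sc <- generate_panel_scores(tr, cfg)
  for (cell in split(sc, list(sc$procedure_id, sc$state))) {
    r1 <- cell$vas[cell$round == 1]
    r2 <- cell$vas[cell$round == 2]
    expect_equal(r2, rep(median(r1), length(r2)))
  }
})

test_that("GBD-derived procedures carry fixed identical weights in both panels", {
  tr <- small_truths(n_proc = 4, n_gbd = 2)
  sc_a <- generate_panel_scores(tr, small_panel("original", seed = 1))
  sc_b <- generate_panel_scores(tr, small_panel("validation", n_experts = 8,
                                                seed = 2,
                                                shift_pre = -0.1))
  gbd_ids <- tr$procedure_id[tr$gbd_derived]
  for (pid in gbd_ids) {
    for (st in c("pre", "post")) {
      va <- sc_a$vas[sc_a$procedure_id == pid & sc_a$state == st]
      vb <- sc_b$vas[sc_b$procedure_id == pid & sc_b$state == st]
      expect_equal(sd(va), 0)
      expect_equal(unique(va), unique(vb))
    }
  }
})

test_that("scores are clipped to the VAS range even under extreme shifts", {
  tr <- small_truths(n_proc = 3, n_gbd = 0)
  cfg <- panel_config("p", 10, shift_pre = -0.6, shift_post = 0.6,
                      expert_sd = 0.3, seed = 11)
  sc <- generate_panel_scores(tr, cfg)
  expect_true(all(sc$vas >= 0 & sc$vas <= 100))
})

test_that("identical seeds give byte-identical CSV output", {
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  simulate_study(99, out_dir = d1)
  simulate_study(99, out_dir = d2)
  for (f in c("truths.csv", "scores.csv", "life_table.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  d3 <- file.path(tempdir(), "sim3")
  simulate_study(100, out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "scores.csv")),
                         readLines(file.path(d3, "scores.csv"))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("final-round panel means are unbiased for truth plus shift", {
  shift_pre <- -0.1; shift_post <- -0.05; expert_sd <- 0.1
  err <- replicate(100, {
    s <- sample.int(1e6, 1)
    tr <- generate_procedure_truth(3, 0, seed = s)
    cfg <- panel_config("v", 12, shift_pre = shift_pre,
                        shift_post = shift_post, expert_sd = expert_sd,
                        tau_shift = 0, seed = s + 1)
    sc <- generate_panel_scores(tr, cfg)
    est <- estimate_qol(sc)
    truth <- ifelse(est$state == "pre",
                    tr$true_q_pre[match(est$procedure_id, tr$procedure_id)] +
                      shift_pre,
                    tr$true_q_post[match(est$procedure_id,
                                         tr$procedure_id)] + shift_post)
    mean(est$q_mean - truth)
  })
  expect_lt(abs(mean(err)), expert_sd / 10)
})

test_that("study-emulation preset encodes the reference panel structure", {
  p <- study_emulation_preset()
  expect_equal(p$n_proc, 43L)
  expect_equal(p$n_gbd, 9L)
  expect_equal(p$original$n_experts, 18L)
  expect_equal(p$validation$n_experts, 15L)
  expect_equal(p$validation$expert_sd - p$original$expert_sd, 0.06)
  expect_equal((p$validation$shift_pre + p$validation$shift_post) / 2, -0.11)
})

test_that("life table follows the Gompertz closed form and caps at max_age", {
  lt <- generate_life_table(a = 1e-4, b = 0.09, max_age = 100)
  expect_equal(lt$p_month[lt$age == 60],
               1 - exp(-1e-4 * exp(0.09 * 60) / 12))
  expect_equal(lt$p_month[lt$age == 100], 1)
  tiny <- generate_life_table(a = 1e-12, b = 0, max_age = 50)
  expect_true(all(tiny$p_month[tiny$age < 50] < 1e-10))
  expect_error(generate_life_table(a = 0), "`a`")
  expect_error(generate_life_table(max_age = 130), "max_age")
})
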