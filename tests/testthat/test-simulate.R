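test_that("simulation is reproducible and extensible under a master seed", {
  cfg5 <- sim_config(k_studies = 5, true_or = 1.4, tau = 0.2)
  a <- simulate_study_table(cfg5, seed = 31)
  b <- simulate_study_table(cfg5, seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(simulate_study_table(cfg5, seed = 32))))

  # adding studies leaves earlier ones untouched
  cfg8 <- sim_config(k_studies = 8, true_or = 1.4, tau = 0.2)
  c8 <- simulate_study_table(cfg8, seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(c8)[1:5, ])
})

test_that("control allele frequency and HWE behave as configured", {
  cfg <- sim_config(k_studies = 20, true_or = 1, control_allele_freq = 0.3,
                    n_controls = c(5000, 5000), n_cases = c(100, 100))
  s <- simulate_study_table(cfg, seed = 77)
  qhat <- with(as.data.frame(s),
               sum(2 * control_yy + control_xy) /
                 (2 * sum(control_xx + control_xy + control_yy)))
  expect_equal(qhat, 0.3, tolerance = 0.01)

  # f = 0: HWE rejection at roughly the nominal rate
  cfg0 <- sim_config(k_studies = 60, true_or = 1, inbreeding_f = 0,
                     n_controls = c(500, 500), n_cases = c(50, 50))
  scr0 <- hwe_screen(simulate_study_table(cfg0, seed = 5))
  expect_lt(mean(!scr0$in_hwe), 0.15)

  # strong inbreeding: the HWE screen fires nearly always
  cfgf <- sim_config(k_studies = 40, true_or = 1, inbreeding_f = 0.35,
                     n_controls = c(500, 500), n_cases = c(50, 50))
  scrf <- hwe_screen(simulate_study_table(cfgf, seed = 6))
  expect_gt(mean(!scrf$in_hwe), 0.8)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(control_allele_freq = 0), "degenerate")
  expect_error(sim_config(control_allele_freq = 1), "degenerate")
  expect_error(sim_config(tau = -1))
  expect_error(sim_config(inbreeding_f = 1))
})

test_that("pooling recovers the simulated odds ratio", {
  cfg <- sim_config(k_studies = 30, true_or = 1.5, control_allele_freq = 0.3,
                    n_cases = c(500, 500), n_controls = c(500, 500), tau = 0)
  s <- simulate_study_table(cfg, seed = 2024)
  fit <- snp_meta(s, "simSNP", "allele")
  expect_equal(fit$or, 1.5, tolerance = 0.08)
  expect_equal(fit$k, 30)
})

test_that("biased corpus generation censors as instructed and logs it", {
  cfg <- sim_config(k_studies = 15, true_or = 1, control_allele_freq = 0.3,
                    n_cases = c(50, 400), n_controls = c(50, 400))
  full <- simulate_study_table(cfg, seed = 9)
  none <- simulate_biased_corpus(cfg, p_omit = 0, seed = 9)
  expect_equal(as.data.frame(none), as.data.frame(full), ignore_attr = TRUE)
  log0 <- attr(none, "censoring_log")
  expect_false(any(log0$omitted))

  supp <- simulate_biased_corpus(cfg, p_omit = 1, side = "negative", seed = 9)
  log1 <- attr(supp, "censoring_log")
  expect_true(all(log1$omitted == (log1$censorable)))
  expect_equal(nrow(supp), 15 - sum(log1$omitted))
  # determinism
  supp2 <- simulate_biased_corpus(cfg, p_omit = 1, side = "negative", seed = 9)
  expect_identical(as.data.frame(supp), as.data.frame(supp2))
})

test_that("funnel asymmetry emerges under small-study suppression", {
  reps <- 150
  cfg <- sim_config(k_studies = 15, true_or = 1, control_allele_freq = 0.3,
                    n_cases = c(30, 500), n_controls = c(30, 500))
  p_null <- p_supp <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- simulate_study_table(cfg, seed = 60000 + r)
    p_null[r] <- egger_test(model_tables(s, "simSNP", "allele"))$p
    b <- simulate_biased_corpus(cfg, p_omit = 1, side = "negative",
                                seed = 60000 + r)
    p_supp[r] <- egger_test(model_tables(b, "simSNP", "allele"))$p
  }
  # unsuppressed corpora: false-positive rate near nominal
  expect_lt(mean(p_null < 0.05), 0.12)
  # suppression shifts the Egger p distribution toward zero
  expect_lt(mean(p_supp), mean(p_null) - 0.04)
  expect_gte(mean(p_supp < 0.05), mean(p_null < 0.05) - 0.02)
})
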