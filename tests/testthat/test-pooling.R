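test_that("study_effect computes the crude odds ratio and its variance", {
  sym <- study_effect(c(10, 10, 10, 10))
  expect_equal(sym$or, 1)
  expect_equal(sym$se, sqrt(0.4))
  expect_false(sym$corrected)

  # Esposito 2015 -1082 dominant: 51 vs 50 cases, 80 vs 38 controls
  esp <- study_effect(c(51, 50, 80, 38))
  expect_equal(esp$or, 51 * 38 / (50 * 80))
  expect_equal(esp$ci95, exp(esp$log_or + c(-1, 1) * 1.96 * esp$se))

  # zero cell: Haldane 0.5 on all four cells
  stv <- study_effect(c(0, 39, 19, 155))
  expect_true(stv$corrected)
  expect_equal(stv$or, (0.5 * 155.5) / (39.5 * 19.5))
  expect_true(is.finite(stv$log_or) && is.finite(stv$se))
  expect_error(study_effect(c(0, 39, 19, 155), correction = "none"),
               "undefined odds ratio")
})

test_that("replicated identical studies pool to the crude OR with Q = 0", {
  one <- data.frame(case_exposed = 12, case_unexposed = 30,
                    control_exposed = 9, control_unexposed = 33)
  three <- one[rep(1, 3), ]
  fit <- pool_fixed_mh(three)
  expect_equal(fit$or, (12 * 33) / (30 * 9))
  expect_equal(fit$q, 0)
  expect_equal(fit$i2, 0)
  expect_equal(select_and_pool(three)$method, "fixed_MH")
})

test_that("single-study MH pooling returns the crude OR exactly", {
  tabs <- random_tables(1, seed = 11)
  fit <- pool_fixed_mh(tabs, min_k = 1)
  crude <- study_effect(unlist(tabs[1, 2:5], use.names = FALSE))
  expect_equal(fit$or, crude$or)
})

test_that("MH and DL match independent oracles to 10+ significant digits", {
  skip_if_not_installed("metafor")
  for (seed in c(3, 17, 42, 99, 123)) {
    tabs <- random_tables(sample(3:5, 1), seed = seed)
    # brute-force transcription of the MH estimator
    a <- tabs$case_exposed; b <- tabs$case_unexposed
    cc <- tabs$control_exposed; d <- tabs$control_unexposed
    n <- a + b + cc + d
    or_brute <- sum(a * d / n) / sum(b * cc / n)
    fit <- pool_fixed_mh(tabs, min_k = 1)
    expect_equal(fit$or, or_brute, tolerance = 1e-12)

    m <- metafor::rma.mh(ai = a, bi = b, ci = cc, di = d, measure = "OR")
    expect_equal(fit$log_or, unname(coef(m)), tolerance = 1e-10)
    expect_equal(fit$se, m$se, tolerance = 1e-10)

    y <- log(a * d / (b * cc)); v <- 1 / a + 1 / b + 1 / cc + 1 / d
    oracle <- dl_oracle(y, v)
    dl <- pool_random_dl(tabs, min_k = 1)
    expect_equal(dl$log_or, oracle$est, tolerance = 1e-12)
    expect_equal(dl$se, oracle$se, tolerance = 1e-12)
    expect_equal(dl$tau2, oracle$tau2, tolerance = 1e-12)

    m2 <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(dl$log_or, unname(coef(m2)), tolerance = 1e-10)
    expect_equal(dl$tau2, m2$tau2, tolerance = 1e-10)
  }
})

test_that("swapping case and control arms inverts the OR, heterogeneity unchanged", {
  for (seed in c(5, 29)) {
    tabs <- random_tables(4, seed = seed)
    swapped <- tabs
    swapped$case_exposed <- tabs$control_exposed
    swapped$case_unexposed <- tabs$control_unexposed
    swapped$control_exposed <- tabs$case_exposed
    swapped$control_unexposed <- tabs$case_unexposed
    for (pool in list(pool_fixed_mh, pool_random_dl, select_and_pool)) {
      f1 <- pool(tabs); f2 <- pool(swapped)
      expect_equal(f2$or, 1 / f1$or, tolerance = 1e-10)
      expect_equal(f2$q, f1$q, tolerance = 1e-10)
      expect_equal(f2$i2, f1$i2, tolerance = 1e-10)
      expect_equal(f2$tau2, f1$tau2, tolerance = 1e-10)
      expect_equal(abs(f2$z), abs(f1$z), tolerance = 1e-8)
      expect_equal(f2$p, f1$p, tolerance = 1e-8)
    }
  }
})

test_that("DL reduces to inverse-variance fixed pooling when Q <= k - 1", {
  eff <- data.frame(log_or = c(0.10, 0.12, 0.09, 0.11),
                    se = c(0.20, 0.25, 0.22, 0.30))
  fit <- pool_random_dl(eff)
  expect_equal(fit$tau2, 0)
  w <- 1 / eff$se^2
  expect_equal(fit$log_or, sum(w * eff$log_or) / sum(w))
  expect_equal(fit$se, 1 / sqrt(sum(w)))
})

test_that("pooled results keep their invariants on random inputs", {
  for (seed in 1:10) {
    fit <- select_and_pool(random_tables(5, seed = seed * 37))
    expect_gte(fit$i2, 0); expect_lte(fit$i2, 100)
    expect_gte(fit$tau2, 0)
    expect_true(fit$ci[1] <= fit$or && fit$or <= fit$ci[2])
  }
})

test_that("analyses below the minimum study count are reported, not raised", {
  tabs <- random_tables(2, seed = 8)
  for (pool in list(pool_fixed_mh, pool_random_dl, select_and_pool)) {
    fit <- pool(tabs)
    expect_s3_class(fit, "snp_meta")
    expect_equal(fit$method, "not_computed")
    expect_match(fit$reason, "fewer than 3")
    expect_true(is.na(fit$or))
  }
})
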