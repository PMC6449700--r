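test_that("with zero random-effect variance the fit reduces to OLS", {
  set.seed(63)
  cfg <- recovery_config(n_participants = 20, sd_participant = 0,
                         sd_trial = 0, sd_resid = 0.3, miss_rate = 0)
  ft <- simulate_feature_table(cfg)
  fit <- fit_rt_model(ft$trials, c("alpha_db", "rmssd", "period"), order = 2)
  # both variance components are estimated at the boundary here, so the
  # mixed model degenerates exactly to ordinary least squares
  vc <- driverattn:::varcomps(fit)
  expect_lt(vc[["participant"]] + vc[["trial"]], 1e-12)
  ols <- lm(rt ~ (alpha_db + rmssd + period)^2, data = fit$data)
  expect_lt(max(abs(unname(lme4::fixef(fit$fit)) - unname(coef(ols)))), 1e-4)
})

test_that("information criteria satisfy their definitions exactly", {
  set.seed(61)
  ft <- simulate_feature_table(recovery_config(n_participants = 6))
  g <- glance(fit_rt_model(ft$trials, c("alpha_db", "rmssd", "period"),
                           order = 2))
  expect_equal(g$AIC, -2 * g$logLik + 2 * g$df, tolerance = 1e-8)
  expect_equal(g$BIC, -2 * g$logLik + g$df * log(g$nobs), tolerance = 1e-8)
})

test_that("self-comparison gives chi-square 0 and p = 1; misuse is fatal", {
  set.seed(62)
  ft <- simulate_feature_table(recovery_config(n_participants = 6))
  d <- ft$trials
  fit <- fit_rt_model(d, c("alpha_db", "period"), order = 2)
  self <- likelihood_ratio_test(fit, fit)
  expect_equal(self$chi_square, 0)
  expect_equal(self$p_value, 1)

  # REML fits are refused
  reml <- fit_rt_model(d, c("alpha_db", "period"), order = 2, ml = FALSE)
  expect_error(likelihood_ratio_test(reml, fit), "ML")

  # different rows (induced by missingness in an extra predictor) refused
  d2 <- d
  d2$ln_x[1:40] <- NA
  full <- fit_rt_model(d2, c("alpha_db", "ln_x", "period"), order = 1)
  null <- fit_rt_model(d2, c("alpha_db", "period"), order = 1)
  expect_error(likelihood_ratio_test(full, null), "different rows")

  # non-nested fixed effects refused
  a <- fit_rt_model(d, c("alpha_db", "period"), order = 1)
  b <- fit_rt_model(d, c("rmssd", "period"), order = 1)
  expect_error(likelihood_ratio_test(a, b), "nested")
})

test_that("the LRT statistic is invariant to affine predictor rescaling", {
  set.seed(63)
  ft <- simulate_feature_table(recovery_config(n_participants = 8))
  d <- ft$trials
  d2 <- d
  d2$alpha_db <- 3 * d2$alpha_db + 17
  d2$rmssd <- 0.1 * d2$rmssd - 4
  lrt1 <- likelihood_ratio_test(
    fit_rt_model(d, c("alpha_db", "rmssd", "period"), order = 2),
    fit_rt_model(d, c("alpha_db", "rmssd", "period"), order = 1))
  lrt2 <- likelihood_ratio_test(
    fit_rt_model(d2, c("alpha_db", "rmssd", "period"), order = 2),
    fit_rt_model(d2, c("alpha_db", "rmssd", "period"), order = 1))
  expect_equal(lrt1$chi_square, lrt2$chi_square, tolerance = 1e-3)
})

test_that("R2 components follow the variance-partition arithmetic", {
  r2 <- driverattn:::r2_from_components(2, 3, 1, 4)
  expect_equal(r2$marginal, 0.2)
  expect_equal(r2$conditional, 0.6)
  expect_warning(bad <- driverattn:::r2_from_components(0, 0, 0, 0), "undefined")
  expect_true(is.na(bad$marginal))
})

test_that("marginal R2 vanishes without fixed effects and never exceeds conditional", {
  set.seed(64)
  ft <- simulate_feature_table(null_coupling_config(n_participants = 10))
  d <- ft$trials
  d$period_dummy <- 0  # no informative fixed effects beyond intercept
  fit <- fit_rt_model(d, c("alpha_db", "rmssd"), order = 1)
  r2 <- nakagawa_r2(fit)
  expect_lt(r2$marginal, 0.02)
  expect_lte(r2$marginal, r2$conditional)
  expect_true(r2$conditional >= 0 && r2$conditional <= 1)
})

test_that("variance components are recovered across replicates", {
  set.seed(65)
  cfg <- generator_config(miss_rate = 0)
  reps <- purrr::map_dfr(1:15, function(i) {
    ft <- simulate_feature_table(cfg)
    glance(fit_rt_model(ft$trials,
                        c("alpha_db", "mean_rr", "rmssd", "period"),
                        order = 3))
  })
  expect_lt(abs(mean(reps$sigma2_participant) - 100^2) / 100^2, 0.2)
  expect_lt(abs(mean(reps$sigma2_residual) - 150^2) / 150^2, 0.2)
  expect_lt(abs(mean(reps$sigma2_trial) - 30^2) / 30^2, 0.5)
})

test_that("model_search emits the staged report with the expected structure", {
  set.seed(66)
  ft <- simulate_feature_table(recovery_config())
  report <- model_search(ft$trials)
  expect_s3_class(report, "rt_model_report")
  expect_equal(nrow(report$single_lrt), 4)
  expect_true(all(report$single_lrt$df == 1))
  expect_equal(report$reduced_lrt$df, 10)
  expect_equal(report$pairwise_lrt$df, rep(9, 3))
  expect_equal(nrow(report$fits_glance), 7)
  expect_lte(report$r2$marginal, report$r2$conditional)
  # the planted alpha x HRV coupling is detected
  expect_lt(report$reduced_lrt$p_value, 0.05)
})

test_that("the planted interaction is detected by a targeted df-1 LRT", {
  set.seed(67)
  p <- replicate(5, {
    ft <- simulate_feature_table(recovery_config())
    full <- fit_rt_model(ft$trials, c("alpha_db", "rmssd", "period"),
                         order = 1, add_terms = "alpha_db:rmssd")
    null <- fit_rt_model(ft$trials, c("alpha_db", "rmssd", "period"),
                         order = 1)
    likelihood_ratio_test(full, null)$p_value
  })
  expect_true(all(p < 0.05))
})

test_that("model reports serialize deterministically to JSON", {
  cfg <- recovery_config(n_participants = 6)
  set.seed(68); r1 <- model_search(simulate_feature_table(cfg)$trials)
  set.seed(68); r2 <- model_search(simulate_feature_table(cfg)$trials)
  expect_identical(as.character(write_model_report(r1)),
                   as.character(write_model_report(r2)))
})

test_that("tidy and autoplot expose the fixed effects", {
  set.seed(69)
  ft <- simulate_feature_table(recovery_config(n_participants = 6))
  fit <- fit_rt_model(ft$trials, c("alpha_db", "rmssd", "period"), order = 2)
  td <- tidy(fit)
  expect_true(all(c("(Intercept)", "alpha_db:rmssd") %in% td$term))
  expect_true(all(is.finite(td$std_error)))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
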