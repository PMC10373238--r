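test_that("recovery summaries reproduce the published validation-set statistics", {
  ref <- reference_table("validation_recoveries.csv")
  stat <- function(method, component) {
    r <- ref$recovery[ref$method == method & ref$component == component]
    recovery_summary(r, rep(100, length(r)))
  }
  cls_fv <- stat("cls", "FV")
  expect_equal(cls_fv$n, 12)
  expect_equal(round(cls_fv$mean_recovery, 2), 101.30)
  cls_rv <- stat("cls", "RV")
  expect_equal(round(cls_rv$mean_recovery, 2), 99.42)
  pcr_fv <- stat("pcr", "FV")
  expect_equal(round(pcr_fv$rsd_recovery, 3), 0.126)
  pls_rv <- stat("pls", "RV")
  expect_equal(round(pls_rv$rsd_recovery, 3), 0.035)
  expect_equal(round(pls_rv$mean_recovery, 2), 100.00)
})

test_that("recovery summary handles degenerate and invalid inputs", {
  const <- recovery_summary(c(4, 4, 4), c(4, 4, 4))
  expect_equal(const$mean_recovery, 100)
  expect_equal(const$sd_recovery, 0)
  expect_equal(const$rsd_recovery, 0)
  expect_equal(attr(const, "recoveries"), c(100, 100, 100))
  expect_error(recovery_summary(1:3, 1:2), class = "specmix_invalid_input")
  expect_error(recovery_summary(1:2, c(1, 0)), class = "specmix_invalid_input")
})

test_that("LOD and LOQ follow the 3.3/10 sigma-over-slope rules", {
  out <- lod_loq(0.1, 1)
  expect_equal(out$lod, 0.33)
  expect_equal(out$loq, 1.0)
  several <- lod_loq(0.037, -1.2)   # slope sign must not matter
  expect_equal(several$loq / several$lod, 10 / 3.3)
  zero <- lod_loq(0, 0.9)
  expect_equal(c(zero$lod, zero$loq), c(0, 0))
  expect_error(lod_loq(0.1, 0), class = "specmix_invalid_input")
})

test_that("linearity merits recover slope and residual SD of a known line", {
  nominal <- seq(1, 17, by = 2)
  exact <- suppressWarnings(linearity_merits(2 + 0.5 * nominal, nominal))
  expect_equal(exact$slope, 0.5)
  expect_equal(exact$sd_resid, 0, tolerance = 1e-12)
  # residual SD uses the n - 2 divisor of the regression line
  withr::with_seed(3, {
    y <- nominal + rnorm(length(nominal), sd = 0.2)
  })
  fit <- lm(y ~ nominal)
  merits <- linearity_merits(y, nominal)
  expect_equal(merits$sd_resid, summary(fit)$sigma)
  expect_equal(lod_loq(merits$sd_resid, merits$slope)$lod,
               3.3 * summary(fit)$sigma / coef(fit)[[2]])
})

test_that("the accuracy protocol pools nine recoveries and is exact without noise", {
  sets <- split_sets()
  pls <- fit_pls(sets$cal, sets$s_cal, 2)
  acc <- accuracy_protocol(pls, default_components(), noise_model(noise_sd = 0))
  expect_equal(nrow(acc$results), 9 * 2)
  expect_equal(acc$summary$n, c(9, 9))
  expect_equal(acc$summary$mean_recovery, c(100, 100), tolerance = 1e-8)
  expect_setequal(unique(acc$results$level), c(4, 8, 16))
  # seeded runs are bit-reproducible
  a1 <- accuracy_protocol(pls, default_components(), noise_model(seed = 77))
  a2 <- accuracy_protocol(pls, default_components(), noise_model(seed = 77))
  expect_identical(a1$summary, a2$summary)
  expect_warning(
    accuracy_protocol(pls, default_components(), noise_model(noise_sd = 0),
                      levels = c(4, 8, 20)),
    "linearity range")
})

test_that("the precision protocol separates repeatability from intermediate precision", {
  sets <- split_sets()
  pls <- fit_pls(sets$cal, sets$s_cal, 2)
  quiet <- precision_protocol(pls, default_components(),
                              noise_model(noise_sd = 0), day_seeds = 1:3)
  expect_equal(quiet$summary$repeatability_rsd, c(0, 0))
  expect_equal(quiet$summary$intermediate_rsd, c(0, 0))
  noisy <- precision_protocol(
    pls, default_components(),
    noise_model(noise_sd = 0.002, between_day_sd = 0.004, seed = 5))
  expect_equal(nrow(noisy$results), 27 * 2)
  expect_true(all(noisy$summary$intermediate_rsd >=
                    noisy$summary$repeatability_rsd))
  expect_error(
    precision_protocol(pls, default_components(), noise_model(noise_sd = 0),
                       day_seeds = 1:2),
    class = "specmix_missing_seed")
})

test_that("standard addition reproduces the published spiking statistics", {
  ref <- reference_table("standard_addition.csv")
  cls_fv <- standard_addition(ref[ref$method == "cls" & ref$component == "FV", ])
  expect_equal(round(cls_fv$rows$percent_recovery[1], 2), 100.67)
  expect_equal(round(cls_fv$summary$mean_recovery, 2), 100.52)
  expect_equal(round(cls_fv$summary$rsd_recovery, 3), 0.848)
  pcr_rv <- standard_addition(ref[ref$method == "pcr" & ref$component == "RV", ])
  expect_equal(round(pcr_rv$summary$mean_recovery, 2), 98.88)
  expect_equal(round(pcr_rv$summary$rsd_recovery, 3), 0.579)
  trivially <- standard_addition(data.frame(pure_added = c(2, 4),
                                            pure_found = c(2, 4)))
  expect_equal(trivially$rows$percent_recovery, c(100, 100))
  expect_error(standard_addition(data.frame(pure_added = 0, pure_found = 1)),
               class = "specmix_invalid_input")
})

test_that("the plasma recovery table's dispersion column is a plain sample SD", {
  ref <- reference_table("plasma_recoveries.csv")
  cls_fv <- ref$recovery[ref$method == "cls" & ref$component == "FV"]
  s <- recovery_summary(cls_fv, rep(100, 5))
  expect_equal(round(s$mean_recovery, 2), 94.26)
  expect_equal(round(s$sd_recovery, 2), 1.16)
  cls_rv <- ref$recovery[ref$method == "cls" & ref$component == "RV"]
  s2 <- recovery_summary(cls_rv, rep(100, 5))
  expect_equal(round(s2$mean_recovery, 2), 94.16)
  expect_equal(round(s2$sd_recovery, 2), 0.95)
})

test_that("t/F method comparison uses pooled variance and ordered variance ratio", {
  x <- c(99.6, 100.4, 99.8, 100.1, 100.2)
  y <- c(100.0, 100.3, 99.7, 99.9, 100.4)
  cmp <- compare_methods(x, y)
  expect_equal(round(cmp$t_critical, 3), 2.306)
  expect_equal(round(cmp$f_critical, 3), 6.388)
  # cross-check against the standard-library implementations
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(abs(cmp$t_statistic), abs(unname(tt$statistic)))
  expect_equal(cmp$t_df, unname(tt$parameter))
  vt <- var.test(x, y)
  expect_equal(cmp$f_statistic, max(unname(vt$statistic),
                                    1 / unname(vt$statistic)))
  expect_gte(cmp$f_statistic, 1)
  # symmetry: t flips sign, F is invariant
  rev <- compare_methods(y, x)
  expect_equal(rev$t_statistic, -cmp$t_statistic)
  expect_equal(rev$f_statistic, cmp$f_statistic)
})

test_that("method comparison verdicts and degenerate cases behave", {
  x <- c(99.6, 100.4, 99.8, 100.1, 100.2)
  same <- compare_methods(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$f_statistic, 1)
  expect_false(same$t_significant || same$f_significant)
  shifted <- compare_methods(x, x + 10)
  expect_true(shifted$t_significant)
  expect_error(compare_methods(c(1, 1), c(1, 1)),
               class = "specmix_invalid_input")
  expect_error(compare_methods(1, c(1, 2)), class = "specmix_invalid_input")
})
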