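test_that("quantile calibration recovers the standard log-normal", {
  z <- qnorm(0.75)
  fit <- calibrate_quantiles(1, exp(-z), exp(z), "lognormal")
  expect_equal(unname(fit$params["meanlog"]), 0, tolerance = 1e-3)
  expect_equal(unname(fit$params["sdlog"]), 1, tolerance = 1e-3)
})

test_that("fitted parameters reproduce their own implied quantiles", {
  fit <- calibrate_quantiles(379, 200, 600, "lognormal")
  q <- qlnorm(c(0.25, 0.5, 0.75), fit$params["meanlog"], fit$params["sdlog"])
  expect_equal(unname(q), unname(fit$fitted_quantiles), tolerance = 1e-9)
  expect_equal(unname(fit$fitted_quantiles["median"]), 379) # anchored exactly
  expect_lt(fit$residual, (0.15 * 600)^2) # quartiles within the fit's residual
  fit <- calibrate_quantiles(37, 18.5, 59, "scaled_beta", lower = 0, upper = 110)
  q <- fit$params["lower"] + (fit$params["upper"] - fit$params["lower"]) *
    qbeta(c(0.25, 0.5, 0.75), fit$params["shape1"], fit$params["shape2"])
  expect_equal(unname(q), unname(fit$fitted_quantiles), tolerance = 1e-6)
  expect_equal(unname(fit$fitted_quantiles["median"]), 37, tolerance = 1e-4)
})

test_that("infeasible calibration targets are rejected", {
  expect_error(calibrate_quantiles(10, 12, 20, "lognormal"), "q1 <= median")
  expect_error(calibrate_quantiles(10, 5, 8, "scaled_beta"), "calibration error")
  expect_error(calibrate_quantiles(50, 20, 120, "scaled_beta",
                                   lower = 0, upper = 100), "bounded range")
})

test_that("the packaged default configuration loads as published", {
  cfg <- generator_config() # no overrides
  expect_equal(cfg$n, 206)
  expect_equal(length(cfg$marginals), 21)
  expect_equal(unname(cfg$missingness[["nps"]]), 1 - 158 / 206)
  expect_equal(unname(cfg$missingness[["bec"]]), 1 - 153 / 206)
  expect_equal(sum(cfg$loadings != 0), 0)
})

test_that("generation is deterministic and honours n", {
  cfg <- generator_config(n = 80, seed = 9)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_equal(nrow(generate_cohort(generator_config(n = 0, seed = 1))), 0)
  c1 <- generate_cohort(generator_config(n = 80, seed = 9))
  c2 <- generate_cohort(generator_config(n = 80, seed = 10))
  expect_false(identical(c1, c2))
})

test_that("generated cohorts pass validation and round-trip size", {
  cfg <- generator_config(n = 120, seed = 21)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(validate_cohort(cohort)), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_equal(nrow(read_cohort(path)), cfg$n)
})

test_that("marginal recovery at scale matches the calibration targets", {
  cohort <- generate_cohort(generator_config(n = 20000, seed = 3001))
  targets <- c(disease_duration = 11.0, snot22 = 37.0, vas_tss = 41.0,
               vas_nb = 33.0, vas_los = 62.5, bec = 379.0, ige = 77.0)
  for (nm in names(targets)) {
    expect_lt(abs(median(cohort[[nm]]) - targets[nm]) / targets[nm], 0.03,
              label = sprintf("median of %s", nm))
  }
  # integer-valued score with a half-integer target: granularity 0.5
  expect_lt(abs(median(cohort$lund_mackay) - 14.5), 0.51)
  bern <- c(asthma = 59.7, allergy = 59.5, nerd = 24.0,
            biologic_initiated = 18.9, incs = 50.3, ics = 38.0)
  for (nm in names(bern)) {
    expect_lt(abs(100 * mean(cohort[[nm]]) - bern[nm]), 1.5,
              label = sprintf("prevalence of %s", nm))
  }
  expect_lt(abs(100 * mean(cohort$sex == "male") - 60.0), 1.5)
  smoking <- c(current = 13.3, ex = 35.2, never = 51.6) / 1.001 # renormalized
  for (nm in names(smoking)) {
    expect_lt(abs(100 * mean(cohort$smoking == nm) - smoking[nm]), 1.5)
  }
  expect_equal(mean(cohort$age), 50.5, tolerance = 0.01)
  expect_equal(sd(cohort$age), 12.1, tolerance = 0.05)
  expect_equal(mean(cohort$bmi), 26.0, tolerance = 0.01)
  ess <- c(`0` = 31.9, `1` = 39.4, `2` = 13.8, `3` = 8.5, `4` = 6.4)
  for (v in names(ess)) {
    expect_lt(abs(100 * mean(cohort$n_ess == as.integer(v)) - ess[v]), 1.5)
  }
})

test_that("zero loadings give uncorrelated fields", {
  cohort <- generate_cohort(generator_config(n = 6000, seed = 42))
  fields <- c("snot22", "vas_tss", "vas_los", "bec", "ige", "age")
  cm <- cor(as.matrix(cohort[, fields]))
  off <- cm[upper.tri(cm)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("a shared severity loading induces positive dependence", {
  cfg <- generator_config(n = 6000, seed = 42,
                          loadings = c(snot22 = 0.8, vas_tss = 0.8))
  cohort <- generate_cohort(cfg)
  expect_gt(cor(cohort$snot22, cohort$vas_tss, method = "spearman"), 0.4)
})

test_that("missingness masking is MCAR at the configured rates", {
  cfg <- generator_config(n = 5000, seed = 33)
  cohort <- generate_cohort(cfg)
  expect_identical(apply_missingness(cohort, c(nps = 0), seed = 1), cohort)
  all_one <- apply_missingness(cohort,
    stats::setNames(rep(1, 3), c("nps", "bec", "asthma")), seed = 1)
  expect_true(all(is.na(all_one$nps)))
  expect_true(all(is.na(all_one$bec)))
  expect_false(anyNA(all_one$patient_id))
  masked <- apply_missingness(cohort, cfg$missingness, seed = 2)
  expect_equal(mean(!is.na(masked$nps)), 158 / 206, tolerance = 0.03)
  expect_identical(apply_missingness(cohort, cfg$missingness, seed = 2), masked)
  expect_error(apply_missingness(cohort, c(nps = 1.5), seed = 1), "\\[0, 1\\]")
  expect_error(apply_missingness(cohort, c(patient_id = 0.5), seed = 1),
               "patient_id")
})

test_that("unknown-verdict fractions rise with uniform missingness", {
  cfg <- generator_config(n = 1500, seed = 55)
  cohort <- generate_cohort(cfg)
  rule_fields <- c("n_ess", "n_scs_past_year", "nps", "snot22", "vas_tss",
                   "vas_nb", "vas_los", "bec", "ige", "asthma")
  frac_unknown <- vapply(c(0, 0.2, 0.5), function(r) {
    masked <- apply_missingness(cohort,
      stats::setNames(rep(r, length(rule_fields)), rule_fields), seed = 56)
    mean(is.na(evaluate_ruleset(masked, "epos2023")$overall))
  }, numeric(1))
  expect_equal(frac_unknown[1], 0)
  expect_true(all(diff(frac_unknown) > 0))
})

test_that("eligible fractions respond in the expected direction to cutoffs", {
  cohort <- generate_cohort(generator_config(n = 4000, seed = 66))
  met_at <- function(rs) mean(evaluate_ruleset(cohort, rs)$overall)
  expect_lt(met_at(ruleset_euforea2021(nps_min = 6)),
            met_at(ruleset_euforea2021()))
  type2_at <- function(bec_min) mean(eval_type2(cohort$bec, cohort$ige,
                                                bec_min = bec_min))
  expect_gt(type2_at(50), type2_at(150))
})

test_that("configuration files round-trip through YAML and JSON", {
  cfg <- generator_config(n = 60, seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n = 60, seed = 5,
                        missingness = list(nps = 0.5)), path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$n, 60)
  expect_equal(cfg2$missingness[["nps"]], 0.5)
  expect_equal(cfg2$missingness[["bec"]], cfg$missingness[["bec"]])
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n = 25, seed = 8), jpath, auto_unbox = TRUE)
  expect_equal(read_generator_config(jpath)$n, 25)
})
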