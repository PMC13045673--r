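test_that("bundled rule sets carry the published thresholds", {
  rs21 <- ruleset_euforea2021()
  expect_equal(rs21$thresholds[["nps_min"]], 4)
  expect_equal(rs21$thresholds[["snot22_min"]], 35)
  expect_equal(rs21$thresholds[["vas_tss_min"]], 50)
  expect_equal(rs21$thresholds[["vas_nb_min"]], 50)
  expect_equal(rs21$thresholds[["vas_los_min"]], 52)
  expect_equal(rs21$thresholds[["scs_min"]], 1)
  rs23 <- ruleset_epos2023()
  expect_equal(rs23$thresholds[["bec_min"]], 150)
  expect_equal(rs23$thresholds[["ige_min"]], 100)
  expect_equal(rs23$thresholds[["scs_min"]], 2)
  expect_equal(rs23$thresholds[["snot22_min"]], 40)
  expect_equal(rs23$thresholds[["vas_los_min"]], 52)
  expect_equal(rs23$thresholds[["k_of_n"]], 3)
})

test_that("EUFOREA 2021 composite combines history, severity and symptoms", {
  rec <- function(...) tibble::as_tibble(list(patient_id = "P1", ...))
  v <- evaluate_record(rec(n_ess = 1, n_scs_past_year = 0, nps = 5,
                           snot22 = 40, vas_tss = NA, vas_nb = NA,
                           vas_los = NA), "euforea2021")
  expect_identical(v$overall, TRUE)
  expect_true(v$evaluable)
  v <- evaluate_record(rec(nps = 3, n_ess = 2, n_scs_past_year = NA,
                           snot22 = 60, vas_tss = NA, vas_nb = NA,
                           vas_los = 90), "euforea2021")
  expect_identical(v$overall, FALSE) # severity gate fails regardless of rest
  v <- evaluate_record(rec(nps = NA, n_ess = 1, n_scs_past_year = NA,
                           snot22 = 60, vas_tss = NA, vas_nb = NA,
                           vas_los = NA), "euforea2021")
  expect_identical(v$overall, NA) # only severity undetermined
  expect_false(v$evaluable)
})

test_that("EPOS/EUFOREA 2023 composite gates on surgery then 3-of-5", {
  rec <- function(...) tibble::as_tibble(list(patient_id = "P1", ...))
  v <- evaluate_record(rec(n_ess = 0, bec = 400, ige = 300,
                           n_scs_past_year = 3, snot22 = 80, vas_los = 90,
                           asthma = TRUE), "epos2023")
  expect_identical(v$overall, FALSE) # surgery gate
  v <- evaluate_record(rec(n_ess = 2, bec = 400, ige = NA,
                           n_scs_past_year = 2, snot22 = 45, vas_los = NA,
                           asthma = FALSE), "epos2023")
  expect_identical(v$overall, TRUE) # three determinate TRUE leaves
  v <- evaluate_record(rec(n_ess = 1, bec = 400, ige = NA,
                           n_scs_past_year = 0, snot22 = NA, vas_los = NA,
                           asthma = TRUE), "epos2023")
  expect_identical(v$overall, NA) # 2 TRUE, 1 FALSE, 2 UNKNOWN
})

test_that("verdict components cover every tree node in fixed order", {
  rs <- ruleset_epos2023()
  v <- evaluate_record(full_record(), rs)
  expect_named(v$components,
               names(crsbiologic:::criterion_nodes(rs$tree)))
  expect_true(all(c("ess", "bec", "ige", "scs", "snot22", "vas_los",
                    "asthma") %in% names(v$components)))
})

test_that("engine equals the completion-enumeration oracle on every node, exhaustively", {
  expect_true(check_engine_against_oracle(ruleset_euforea2021()))
  expect_true(check_engine_against_oracle(ruleset_epos2023()))
})

test_that("fully observed records always get determinate verdicts", {
  cfg <- generator_config(n = 400, seed = 314)
  cohort <- generate_cohort(cfg) # no missingness applied
  for (rs in c("euforea2021", "epos2023")) {
    ev <- evaluate_ruleset(cohort, rs)
    expect_false(anyNA(ev$overall))
    expect_true(all(ev$evaluable))
  }
})

test_that("filling in a missing field never flips a determinate verdict", {
  cfg <- generator_config(n = 250, seed = 2718)
  cohort <- apply_missingness(generate_cohort(cfg), cfg$missingness, seed = 99)
  set.seed(555)
  fills <- list(n_ess = 0:4, n_scs_past_year = 0:4, nps = 0:8,
                snot22 = 0:110, vas_tss = 0:100, vas_nb = 0:100,
                vas_los = 0:100, bec = c(0, 100, 200, 1000),
                ige = c(0, 50, 150, 400), asthma = c(TRUE, FALSE))
  for (rs_name in c("euforea2021", "epos2023")) {
    before <- evaluate_ruleset(cohort, rs_name)$overall
    for (rep in 1:3) {
      filled <- cohort
      for (i in seq_len(nrow(filled))) {
        missing_fields <- names(fills)[vapply(names(fills),
          function(f) is.na(filled[[f]][i]), logical(1))]
        if (length(missing_fields) == 0) next
        f <- sample(missing_fields, 1)
        filled[[f]][i] <- sample(fills[[f]], 1)
      }
      after <- evaluate_ruleset(filled, rs_name)$overall
      determinate <- !is.na(before)
      expect_identical(before[determinate], after[determinate])
    }
  }
})

test_that("the 2023 SCS leaf is strictly harder than the 2021 SCS leaf", {
  cfg <- generator_config(n = 500, seed = 12)
  cohort <- apply_missingness(generate_cohort(cfg), cfg$missingness, seed = 13)
  s21 <- eval_criterion(ruleset_euforea2021()$tree, cohort)$scs
  s23 <- eval_criterion(ruleset_epos2023()$tree, cohort)$scs
  idx <- !is.na(s23) & s23
  expect_true(all(s21[idx]))
})

test_that("rule sets round-trip through JSON with identical evaluation", {
  cfg <- generator_config(n = 120, seed = 77)
  cohort <- apply_missingness(generate_cohort(cfg), cfg$missingness, seed = 78)
  for (rs in list(ruleset_euforea2021(), ruleset_epos2023())) {
    path <- withr::local_tempfile(fileext = ".json")
    ruleset_to_json(rs, path)
    rs2 <- ruleset_from_json(path)
    expect_equal(rs2$name, rs$name)
    expect_equal(rs2$thresholds, rs$thresholds)
    expect_identical(evaluate_ruleset(cohort, rs2), evaluate_ruleset(cohort, rs))
  }
})

test_that("custom cutoffs express national variants", {
  # e.g. NPS >= 5 and SNOT-22 >= 50 as used in some reimbursement rules
  rs <- ruleset_euforea2021(nps_min = 5, snot22_min = 50)
  rec <- tibble::tibble(patient_id = "P1", n_ess = 1, n_scs_past_year = 1,
                        nps = 4, snot22 = 45, vas_tss = 10, vas_nb = 10,
                        vas_los = 10)
  expect_identical(evaluate_record(rec, rs)$overall, FALSE)
  expect_identical(evaluate_record(rec, ruleset_euforea2021())$overall, TRUE)
})
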