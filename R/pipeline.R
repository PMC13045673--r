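# End-to-end pipeline: cohort in (CSV or generator config), report
# bundle out (CSV tables, a single JSON document, optional markdown
# summary, and a manifest sufficient to re-run bit-identically).

#' Run the full indication-analysis pipeline
#'
#' Reads or generates a cohort, evaluates the requested rule sets, and
#' writes a report bundle: a cohort characteristics summary, one
#' indication table per rule set, the indication-by-treatment cross-tab
#' with Fisher's exact test and treatment-gap percentages, the
#' between-rule-set concordance (when both bundled sets are evaluated),
#' and a machine-readable manifest. On any error the partial outputs are
#' removed.
#'
#' @param out_dir Output directory (created if needed).
#' @param input_csv Path to a cohort CSV; exactly one of `input_csv` and
#'   `config` must be given.
#' @param config A `crs_generator_config` (or path to one): the cohort
#'   is generated, masked with the configured missingness, and its CSV
#'   written into the bundle.
#' @param rulesets Character vector of bundled rule-set names to
#'   evaluate (default both).
#' @param formats Report formats: any of `"csv"`, `"json"`, `"md"`.
#' @return Invisibly, a list with the computed report objects and the
#'   paths written.
#' @export
run_pipeline <- function(out_dir, input_csv = NULL, config = NULL,
                         rulesets = c("euforea2021", "epos2023"),
                         formats = c("csv", "json", "md")) {
  if (is.null(input_csv) == is.null(config)) {
    stop("exactly one of input_csv and config must be given", call. = FALSE)
  }
  formats <- match.arg(formats, several.ok = TRUE)
  rulesets <- match.arg(rulesets, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    if (!is.null(config)) {
      if (is.character(config)) config <- read_generator_config(config)
      cohort <- generate_cohort(config)
      cohort <- apply_missingness(cohort, config$missingness,
                                  seed = config$seed + 1L)
      cohort_path <- file.path(out_dir, "cohort.csv")
      write_cohort(cohort, cohort_path)
      written <- c(written, cohort_path)
      input_label <- "generated"
    } else {
      cohort <- read_cohort(input_csv)
      input_label <- input_csv
    }

    summary_tab <- cohort_summary(cohort)
    indication <- lapply(rulesets, function(rs) indication_table(cohort, rs))
    names(indication) <- rulesets
    comparison <- lapply(rulesets, function(rs) {
      xt <- crosstab_by_treatment(cohort, rs)
      fisher <- if ((xt$a + xt$b) > 0 && (xt$c + xt$d) > 0 &&
                    (xt$a + xt$b + xt$c + xt$d) > 0) {
        fisher_exact_2x2(xt$a, xt$b, xt$c, xt$d)
      }
      gap <- suppressWarnings(treatment_gap(xt))
      n_eval <- xt$a + xt$b + xt$c + xt$d
      tibble::tibble(
        ruleset_name = rs,
        n_treated_met = xt$a, n_treated_not_met = xt$b,
        n_untreated_met = xt$c, n_untreated_not_met = xt$d,
        n_evaluable = n_eval,
        pct_met_treated = if (xt$a + xt$b > 0) percent(xt$a, xt$a + xt$b) else NA_real_,
        pct_met_untreated = if (xt$c + xt$d > 0) percent(xt$c, xt$c + xt$d) else NA_real_,
        pct_met_total = if (n_eval > 0) percent(xt$a + xt$c, n_eval) else NA_real_,
        fisher_p = if (!is.null(fisher)) fisher$p_two_sided else NA_real_,
        odds_ratio = if (!is.null(fisher)) fisher$odds_ratio else NA_real_,
        pct_met_not_treated = gap$pct_met_not_treated,
        pct_treated_not_met = gap$pct_treated_not_met,
        n_excluded_unknown = xt$n_excluded_unknown,
        n_excluded_no_treatment = xt$n_excluded_no_treatment)
    })
    comparison <- dplyr::bind_rows(comparison)
    conc <- if (all(c("euforea2021", "epos2023") %in% rulesets)) {
      concordance(cohort)
    }

    report <- list(
      cohort_summary = summary_tab,
      indication = indication,
      treatment_comparison = comparison,
      concordance = if (!is.null(conc)) unclass(conc))

    if ("csv" %in% formats) {
      p <- file.path(out_dir, "cohort_summary.csv")
      readr::write_csv(summary_tab, p, na = ""); written <- c(written, p)
      for (rs in rulesets) {
        p <- file.path(out_dir, sprintf("indication_%s.csv", rs))
        readr::write_csv(indication[[rs]], p, na = ""); written <- c(written, p)
      }
      p <- file.path(out_dir, "treatment_comparison.csv")
      readr::write_csv(comparison, p, na = ""); written <- c(written, p)
      if (!is.null(conc)) {
        p <- file.path(out_dir, "concordance.csv")
        readr::write_csv(tibble::as_tibble(unclass(conc)), p, na = "")
        written <- c(written, p)
      }
    }
    if ("json" %in% formats) {
      p <- file.path(out_dir, "report.json")
      jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
      written <- c(written, p)
    }
    if ("md" %in% formats) {
      p <- file.path(out_dir, "summary.md")
      writeLines(render_markdown_summary(report, rulesets), p)
      written <- c(written, p)
    }

    manifest <- list(
      package = "crsbiologic",
      version = as.character(utils::packageVersion("crsbiologic")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      input = input_label,
      rulesets = rulesets,
      formats = formats,
      n_patients = nrow(cohort),
      exclusions = stats::setNames(lapply(seq_len(nrow(comparison)), function(i) {
        list(unknown_verdict = comparison$n_excluded_unknown[i],
             missing_treatment = comparison$n_excluded_no_treatment[i])
      }), comparison$ruleset_name),
      generator_config = if (!is.null(config)) {
        list(n = config$n, seed = config$seed,
             loadings = as.list(config$loadings),
             missingness = as.list(config$missingness))
      })
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    written <- c(written, p)

    invisible(list(report = report, manifest = manifest, paths = written,
                   cohort = cohort))
  }, error = on_fail)
}

render_markdown_summary <- function(report, rulesets) {
  lines <- c("# Biologic indication report", "")
  for (rs in rulesets) {
    tab <- report$indication[[rs]]
    lines <- c(lines, sprintf("## %s", rs), "",
               "| Criterion | Met, % (n/N) |", "|---|---|")
    for (i in seq_len(nrow(tab))) {
      pct <- if (is.na(tab$pct[i])) "-" else
        sprintf("%.1f (%d/%d)", tab$pct[i], tab$n_met[i], tab$n_evaluable[i])
      lines <- c(lines, sprintf("| %s | %s |", tab$label[i], pct))
    }
    lines <- c(lines, "")
  }
  cmp <- report$treatment_comparison
  lines <- c(lines, "## Indication vs biologic initiation", "",
             "| Rule set | Met (on biologics) | Met (not on biologics) | Fisher p | Met, not treated % | Treated, not met % |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(cmp))) {
    f1 <- if (is.na(cmp$pct_met_treated[i])) "-" else
      sprintf("%.1f%% (%d/%d)", cmp$pct_met_treated[i], cmp$n_treated_met[i],
              cmp$n_treated_met[i] + cmp$n_treated_not_met[i])
    f2 <- if (is.na(cmp$pct_met_untreated[i])) "-" else
      sprintf("%.1f%% (%d/%d)", cmp$pct_met_untreated[i], cmp$n_untreated_met[i],
              cmp$n_untreated_met[i] + cmp$n_untreated_not_met[i])
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s |",
      cmp$ruleset_name[i], f1, f2,
      ifelse(is.na(cmp$fisher_p[i]), "-", sprintf("%.3g", cmp$fisher_p[i])),
      ifelse(is.na(cmp$pct_met_not_treated[i]), "-",
             sprintf("%.1f", cmp$pct_met_not_treated[i])),
      ifelse(is.na(cmp$pct_treated_not_met[i]), "-",
             sprintf("%.1f", cmp$pct_treated_not_met[i]))))
  }
  if (!is.null(report$concordance)) {
    cc <- report$concordance
    lines <- c(lines, "", "## Concordance between rule sets", "",
      sprintf("Of %d patients evaluable under both rule sets, %d met both and %d met neither (agreement %.1f%%); %d met only %s and %d only %s (discordance %.1f%%).",
              cc$n_dual, cc$n_both, cc$n_neither, cc$agreement_pct,
              cc$n_only_1, cc$ruleset1, cc$n_only_2, cc$ruleset2,
              cc$discordance_pct))
  }
  lines
}
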