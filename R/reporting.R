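# Cohort-level reporting: criterion prevalence, indication-by-treatment
# cross-tabulation, treatment gap and between-rule-set concordance.
#
# All denominators are determinate-case: a patient enters a proportion's
# denominator exactly when the criterion in question has a determinate
# (TRUE/FALSE) verdict for them, so composite denominators can legally
# exceed component denominators — a patient with a missing component may
# still have a forced composite verdict.

prevalence_from_states <- function(states) {
  n_evaluable <- sum(!is.na(states))
  n_met <- sum(states, na.rm = TRUE)
  tibble::tibble(
    n_met = n_met, n_evaluable = n_evaluable,
    pct = if (n_evaluable > 0) percent(n_met, n_evaluable) else NA_real_)
}

#' Prevalence of one criterion in a cohort
#'
#' Evaluates a single criterion tree on the cohort and counts determinate
#' and met verdicts.
#'
#' @param cohort A validated cohort tibble.
#' @param criterion A `crs_criterion` tree (e.g. a node built with
#'   [crit_threshold()]), or a node id of `ruleset`'s tree.
#' @param ruleset Optional `crs_ruleset` supplying the tree when
#'   `criterion` is an id.
#' @return A one-row tibble: `criterion_id`, `n_met`, `n_evaluable`,
#'   `pct` (one decimal, `NA` when nothing is evaluable).
#' @export
criterion_prevalence <- function(cohort, criterion, ruleset = NULL) {
  if (is.character(criterion)) {
    stopifnot(!is.null(ruleset))
    if (is.character(ruleset)) ruleset <- get_ruleset(ruleset)
    node <- criterion_nodes(ruleset$tree)[[criterion]]
    if (is.null(node)) stop("no node '", criterion, "' in rule set", call. = FALSE)
    criterion <- node
  }
  states <- eval_criterion(criterion, cohort)[[criterion$id]]
  tibble::add_column(prevalence_from_states(states),
                     criterion_id = criterion$id, .before = 1)
}

#' Indication table for a rule set
#'
#' One row per leaf criterion, per named sub-composite, and for the
#' overall composite, in the fixed report order of the rule set, with
#' determinate-case denominators.
#'
#' @param cohort A validated cohort tibble.
#' @param ruleset A `crs_ruleset` or its name.
#' @return A tibble: `section`, `criterion_id`, `label`, `n_met`,
#'   `n_evaluable`, `pct`.
#' @export
indication_table <- function(cohort, ruleset) {
  if (is.character(ruleset)) ruleset <- get_ruleset(ruleset)
  states <- eval_criterion(ruleset$tree, cohort)
  nodes <- criterion_nodes(ruleset$tree)
  rows <- lapply(ruleset$report_ids, function(id) {
    row <- prevalence_from_states(states[[id]])
    tibble::add_column(row,
      section = unname(ruleset$sections[id]),
      criterion_id = id,
      label = nodes[[id]]$label,
      .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  check_report_percentages(out)
  out
}

# Internal consistency: every reported percentage must recompute from the
# counts sitting next to it. Run on every emitted report table.
check_report_percentages <- function(tab) {
  ok <- mapply(function(p, n, d) {
    if (is.na(p)) d == 0 else isTRUE(all.equal(p, percent(n, d)))
  }, tab$pct, tab$n_met, tab$n_evaluable)
  if (!all(ok)) {
    stop("internal consistency violation: a percentage does not recompute ",
         "from its own counts", call. = FALSE)
  }
  invisible(tab)
}

#' Indication-by-treatment cross-tabulation
#'
#' 2x2 table of biologic initiation against the rule set's overall
#' verdict, over patients with a determinate verdict and a recorded
#' treatment status. Patients with UNKNOWN verdicts are excluded
#' (determinate-case analysis); patients with missing
#' `biologic_initiated` are excluded with a warning.
#'
#' @param cohort A validated cohort tibble.
#' @param ruleset A `crs_ruleset` or its name.
#' @return A `crs_crosstab`: list with counts `a` (initiators meeting),
#'   `b` (initiators not meeting), `c` (non-initiators meeting), `d`
#'   (non-initiators not meeting), the exclusion counts
#'   `n_excluded_unknown` and `n_excluded_no_treatment`, and
#'   `ruleset_name`.
#' @export
crosstab_by_treatment <- function(cohort, ruleset) {
  if (is.character(ruleset)) ruleset <- get_ruleset(ruleset)
  verdict <- evaluate_ruleset(cohort, ruleset)$overall
  treated <- cohort$biologic_initiated
  no_trt <- is.na(treated)
  if (any(no_trt)) {
    warning(sum(no_trt), " patient(s) without recorded biologic_initiated ",
            "excluded from cross-tab", call. = FALSE)
  }
  keep <- !is.na(verdict) & !no_trt
  structure(list(
    a = sum(keep & treated & verdict, na.rm = TRUE),
    b = sum(keep & treated & !verdict, na.rm = TRUE),
    c = sum(keep & !treated & verdict, na.rm = TRUE),
    d = sum(keep & !treated & !verdict, na.rm = TRUE),
    n_excluded_unknown = sum(is.na(verdict) & !no_trt),
    n_excluded_no_treatment = sum(no_trt),
    ruleset_name = ruleset$name), class = "crs_crosstab")
}

#' @export
print.crs_crosstab <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("on biologics", "not on biologics"),
                              c("criteria met", "not met")))
  cat(sprintf("<crs_crosstab: %s> (%d unknown-verdict, %d missing-treatment excluded)\n",
              x$ruleset_name, x$n_excluded_unknown, x$n_excluded_no_treatment))
  print(m)
  invisible(x)
}

#' Treatment gap summary
#'
#' Two percentages describing the mismatch between indication and
#' prescription: the share of criteria-meeting patients not (yet) on a
#' biologic, and the share of biologic initiators whose determinate
#' verdict is "criteria not met".
#'
#' @param x A validated cohort tibble, or a `crs_crosstab`.
#' @param ruleset Required when `x` is a cohort.
#' @return A tibble: `ruleset_name`, `pct_met_not_treated`,
#'   `pct_treated_not_met` (one decimal; `NA` with a warning when a
#'   denominator is zero).
#' @export
treatment_gap <- function(x, ruleset = NULL) {
  xt <- if (inherits(x, "crs_crosstab")) x else crosstab_by_treatment(x, ruleset)
  safe_pct <- function(n, d, what) {
    if (d == 0) {
      warning("treatment_gap(): zero denominator for ", what, call. = FALSE)
      NA_real_
    } else percent(n, d)
  }
  tibble::tibble(
    ruleset_name = xt$ruleset_name,
    pct_met_not_treated = safe_pct(xt$c, xt$a + xt$c, "criteria-meeting patients"),
    pct_treated_not_met = safe_pct(xt$b, xt$a + xt$b, "biologic initiators"))
}

#' Concordance between two rule sets
#'
#' Cross-classifies patients with determinate verdicts under both rule
#' sets into meeting both, neither, or only one; agreement is the share
#' meeting both or neither.
#'
#' @param cohort A validated cohort tibble.
#' @param ruleset1,ruleset2 Rule sets (default the two bundled ones).
#' @return A `crs_concordance`: list with `n_dual`, `n_both`,
#'   `n_neither`, `n_only_1`, `n_only_2`, `agreement_pct`,
#'   `discordance_pct`, and the rule-set names.
#' @export
concordance <- function(cohort, ruleset1 = ruleset_euforea2021(),
                        ruleset2 = ruleset_epos2023()) {
  if (is.character(ruleset1)) ruleset1 <- get_ruleset(ruleset1)
  if (is.character(ruleset2)) ruleset2 <- get_ruleset(ruleset2)
  v1 <- evaluate_ruleset(cohort, ruleset1)$overall
  v2 <- evaluate_ruleset(cohort, ruleset2)$overall
  dual <- !is.na(v1) & !is.na(v2)
  n_dual <- sum(dual)
  n_both <- sum(dual & v1 & v2, na.rm = TRUE)
  n_neither <- sum(dual & !v1 & !v2, na.rm = TRUE)
  n_only_1 <- sum(dual & v1 & !v2, na.rm = TRUE)
  n_only_2 <- sum(dual & !v1 & v2, na.rm = TRUE)
  structure(list(
    ruleset1 = ruleset1$name, ruleset2 = ruleset2$name,
    n_dual = n_dual, n_both = n_both, n_neither = n_neither,
    n_only_1 = n_only_1, n_only_2 = n_only_2,
    agreement_pct = if (n_dual > 0) percent(n_both + n_neither, n_dual) else NA_real_,
    discordance_pct = if (n_dual > 0) percent(n_only_1 + n_only_2, n_dual) else NA_real_),
    class = "crs_concordance")
}

#' @export
print.crs_concordance <- function(x, ...) {
  cat(sprintf("<crs_concordance: %s vs %s> n = %d dual-evaluable\n",
              x$ruleset1, x$ruleset2, x$n_dual))
  cat(sprintf("  both %d, neither %d, only %s %d, only %s %d\n",
              x$n_both, x$n_neither, x$ruleset1, x$n_only_1,
              x$ruleset2, x$n_only_2))
  cat(sprintf("  agreement %.1f%%, discordance %.1f%%\n",
              x$agreement_pct, x$discordance_pct))
  invisible(x)
}

#' Cohort characteristics summary
#'
#' Descriptive summary in the style of a baseline-characteristics table:
#' mean +/- SD for age and BMI, median (IQR) for scores and labs,
#' category and prevalence percentages elsewhere, with non-missing
#' counts.
#'
#' @param cohort A validated cohort tibble.
#' @return A tibble: `variable`, `level`, `n`, `mean`, `sd`, `median`,
#'   `q1`, `q3`, `pct` (irrelevant cells `NA`).
#' @export
cohort_summary <- function(cohort) {
  dict <- column_dictionary()
  mean_fields <- c("age", "bmi")
  median_fields <- c("disease_duration", "snot22", "lund_mackay",
                     "vas_tss", "vas_nb", "vas_los", "bec", "ige")
  rows <- list()
  blank <- function(...) tibble::tibble(variable = NA_character_,
    level = NA_character_, n = NA_integer_, mean = NA_real_, sd = NA_real_,
    median = NA_real_, q1 = NA_real_, q3 = NA_real_, pct = NA_real_, ...)
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[i]
    if (nm == "patient_id") next
    x <- cohort[[nm]]
    n <- sum(!is.na(x))
    if (nm %in% mean_fields) {
      r <- blank(); r$variable <- nm; r$n <- n
      if (n > 0) { r$mean <- round_half_up(mean(x, na.rm = TRUE), 1)
                   r$sd <- round_half_up(stats::sd(x[!is.na(x)]), 1) }
      rows[[length(rows) + 1]] <- r
    } else if (nm %in% median_fields) {
      r <- blank(); r$variable <- nm; r$n <- n
      if (n > 0) { q <- median_iqr(x)
                   r$median <- round_half_up(q[["median"]], 1)
                   r$q1 <- round_half_up(q[["q1"]], 1)
                   r$q3 <- round_half_up(q[["q3"]], 1) }
      rows[[length(rows) + 1]] <- r
    } else if (dict$type[i] == "logical") {
      r <- blank(); r$variable <- nm; r$level <- "true"; r$n <- n
      if (n > 0) r$pct <- percent(sum(x, na.rm = TRUE), n)
      rows[[length(rows) + 1]] <- r
    } else if (dict$type[i] == "category") {
      levels <- strsplit(dict$levels[i], "|", fixed = TRUE)[[1]]
      for (lv in levels) {
        r <- blank(); r$variable <- nm; r$level <- lv; r$n <- n
        if (n > 0) r$pct <- percent(sum(x == lv, na.rm = TRUE), n)
        rows[[length(rows) + 1]] <- r
      }
    } else if (nm %in% c("n_ess", "n_scs_past_year", "nps")) {
      # banded counts mirror how history and endoscopy are usually reported
      bands <- if (nm == "nps") list("0-2" = 0:2, "3-4" = 3:4, "5-6" = 5:6,
                                     "7-8" = 7:8)
               else list("0" = 0, "1" = 1, "2" = 2, "3" = 3, ">3" = 4:1000)
      for (bn in names(bands)) {
        r <- blank(); r$variable <- nm; r$level <- bn; r$n <- n
        if (n > 0) r$pct <- percent(sum(x %in% bands[[bn]], na.rm = TRUE), n)
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  dplyr::bind_rows(rows)
}
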