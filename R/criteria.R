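# Declarative criterion trees and their three-valued evaluation.
#
# A rule set is data, not code: a tree of threshold / flag leaves under
# and / or / at-least-k connectives, serializable to JSON, so national
# variants (e.g. NPS >= 5, SNOT-22 >= 50) can be expressed by users
# without touching the engine. Only the two international rule sets are
# bundled.

#' Criterion tree constructors
#'
#' Build the nodes of a declarative criterion tree. `crit_threshold` is
#' an at-least comparison on a numeric record field; `crit_flag` lifts a
#' recorded boolean (missing becomes UNKNOWN); `crit_all`, `crit_any`
#' and `crit_at_least` combine children with Kleene conjunction,
#' disjunction and the at-least-k-of-n operator.
#'
#' @param id Unique node identifier within a tree (snake_case).
#' @param field Record field name (must be in [column_dictionary()]).
#' @param cutoff Numeric cutoff for `value >= cutoff`.
#' @param label Human-readable row label for report tables.
#' @param ... Child criterion nodes.
#' @param k Minimum number of children that must hold.
#' @return A `crs_criterion` node.
#' @name criterion
NULL

new_criterion <- function(kind, id, label, extra = list()) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  structure(c(list(kind = kind, id = id, label = label), extra),
            class = "crs_criterion")
}

#' @rdname criterion
#' @export
crit_threshold <- function(id, field, cutoff, label = NULL) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, is.finite(cutoff))
  if (!field %in% column_dictionary()$name) {
    stop("unknown record field: ", field, call. = FALSE)
  }
  if (is.null(label)) label <- sprintf("%s >= %s", field, cutoff)
  new_criterion("threshold", id, label, list(field = field, cutoff = cutoff))
}

#' @rdname criterion
#' @export
crit_flag <- function(id, field, label = NULL) {
  if (!field %in% column_dictionary()$name) {
    stop("unknown record field: ", field, call. = FALSE)
  }
  if (is.null(label)) label <- field
  new_criterion("flag", id, label, list(field = field))
}

#' @rdname criterion
#' @export
crit_all <- function(id, ..., label = NULL) {
  children <- list(...)
  stopifnot(length(children) >= 1)
  if (is.null(label)) label <- id
  new_criterion("all", id, label, list(children = children))
}

#' @rdname criterion
#' @export
crit_any <- function(id, ..., label = NULL) {
  children <- list(...)
  stopifnot(length(children) >= 1)
  if (is.null(label)) label <- id
  new_criterion("any", id, label, list(children = children))
}

#' @rdname criterion
#' @export
crit_at_least <- function(id, k, ..., label = NULL) {
  children <- list(...)
  if (!is.numeric(k) || k != round(k) || k < 1 || k > length(children)) {
    stop("crit_at_least(): k must be an integer in [1, #children]",
         call. = FALSE)
  }
  if (is.null(label)) label <- sprintf("at least %d of %d", k, length(children))
  new_criterion("at_least", id, label, list(k = as.integer(k), children = children))
}

# Depth-first pre-order walk; returns nodes as a flat named list.
criterion_nodes <- function(node) {
  out <- stats::setNames(list(node), node$id)
  for (child in node$children %||% list()) {
    out <- c(out, criterion_nodes(child))
  }
  out
}

criterion_leaves <- function(node) {
  Filter(function(n) n$kind %in% c("threshold", "flag"), criterion_nodes(node))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate a criterion tree on a cohort
#'
#' Vectorised strong-Kleene evaluation: every node of the tree is
#' evaluated for every patient, missing fields propagating as UNKNOWN
#' unless the known values already force the verdict.
#'
#' @param criterion A `crs_criterion` tree.
#' @param cohort A cohort tibble (or any data frame with the leaf fields).
#' @return A named list of logical vectors (one per node id, pre-order;
#'   `NA` = UNKNOWN), with the root first.
#' @export
eval_criterion <- function(criterion, cohort) {
  values <- new.env(parent = emptyenv())
  eval_node <- function(node) {
    v <- switch(node$kind,
      threshold = threshold_test(cohort[[node$field]], node$cutoff),
      flag = {
        x <- cohort[[node$field]]
        if (!is.logical(x)) x <- as.logical(x)
        x
      },
      all = Reduce(kleene_and, lapply(node$children, eval_node)),
      any = Reduce(kleene_or, lapply(node$children, eval_node)),
      at_least = at_least_k_rows(
        do.call(cbind, lapply(node$children, eval_node)), node$k),
      stop("unknown criterion kind: ", node$kind)
    )
    assign(node$id, v, envir = values)
    v
  }
  eval_node(criterion)
  ids <- names(criterion_nodes(criterion))
  stats::setNames(lapply(ids, get, envir = values), ids)
}

# ---- rule sets -------------------------------------------------------------

new_ruleset <- function(name, tree, thresholds, report_ids, sections) {
  structure(list(name = name, tree = tree, thresholds = thresholds,
                 report_ids = report_ids, sections = sections),
            class = "crs_ruleset")
}

#' EUFOREA 2021 biologic-indication rule set
#'
#' A patient is indicated when all three hold: a history of disease
#' burden (at least one endoscopic sinus surgery ever and/or at least
#' one systemic corticosteroid course in the past year), severe disease
#' (total nasal polyp score >= 4), and uncontrolled symptoms (SNOT-22
#' >= 35 and/or any of VAS total sinus symptoms >= 50 mm, VAS nasal
#' blockage >= 50 mm, VAS loss of smell >= 52 mm). Cutoffs may be
#' overridden to express national variants.
#'
#' @param nps_min,snot22_min,vas_tss_min,vas_nb_min,vas_los_min,scs_min,ess_min
#'   Leaf cutoffs; defaults are the published 2021 values.
#' @return A `crs_ruleset`.
#' @export
ruleset_euforea2021 <- function(nps_min = 4, snot22_min = 35, vas_tss_min = 50,
                                vas_nb_min = 50, vas_los_min = 52,
                                scs_min = 1, ess_min = 1) {
  tree <- crit_all("overall",
    crit_any("history",
      crit_threshold("ess", "n_ess", ess_min, "History of ESS"),
      crit_threshold("scs", "n_scs_past_year", scs_min,
                     sprintf("At least %d SCS course(s) last year", scs_min)),
      label = "History of ESS and/or at least 1 SCS course last year"),
    crit_all("uncontrolled_severe",
      crit_threshold("nps", "nps", nps_min,
                     sprintf("NPS >= %s points", nps_min)),
      crit_any("uncontrolled",
        crit_threshold("snot22", "snot22", snot22_min,
                       sprintf("SNOT-22 >= %s points", snot22_min)),
        crit_threshold("vas_tss", "vas_tss", vas_tss_min,
                       sprintf("VAS TSS >= %s mm", vas_tss_min)),
        crit_threshold("vas_nb", "vas_nb", vas_nb_min,
                       sprintf("VAS NB >= %s mm", vas_nb_min)),
        crit_threshold("vas_los", "vas_los", vas_los_min,
                       sprintf("VAS LoS >= %s mm", vas_los_min)),
        label = "Meets the SNOT-22 criterion and/or any of the 3 VAS criteria"),
      label = sprintf("NPS >= %s and meets at least 1 uncontrolled criterion",
                      nps_min)),
    label = "History plus uncontrolled severe")
  new_ruleset(
    name = "euforea2021", tree = tree,
    thresholds = c(nps_min = nps_min, snot22_min = snot22_min,
                   vas_tss_min = vas_tss_min, vas_nb_min = vas_nb_min,
                   vas_los_min = vas_los_min, scs_min = scs_min,
                   ess_min = ess_min),
    report_ids = c("ess", "scs", "history", "nps", "snot22", "vas_tss",
                   "vas_nb", "vas_los", "uncontrolled",
                   "uncontrolled_severe", "overall"),
    sections = c(ess = "History", scs = "History", history = "History",
                 nps = "Severe", snot22 = "Uncontrolled",
                 vas_tss = "Uncontrolled", vas_nb = "Uncontrolled",
                 vas_los = "Uncontrolled", uncontrolled = "Uncontrolled",
                 uncontrolled_severe = "Uncontrolled severe",
                 overall = "Criteria met"))
}

#' EPOS/EUFOREA 2023 biologic-indication rule set
#'
#' A patient is indicated when they have a history of endoscopic sinus
#' surgery and meet at least 3 of 5 uncontrolled-severe criteria:
#' type-2 inflammation (blood eosinophils >= 150 cells/uL and/or total
#' IgE >= 100 IU/mL), at least 2 systemic corticosteroid courses in the
#' past year, SNOT-22 >= 40, VAS loss of smell >= 52 mm, and comorbid
#' asthma. Cutoffs may be overridden to express national variants.
#'
#' @param bec_min,ige_min,scs_min,snot22_min,vas_los_min,ess_min Leaf
#'   cutoffs; defaults are the published 2023 values.
#' @param k Number of the five uncontrolled-severe criteria required.
#' @return A `crs_ruleset`.
#' @export
ruleset_epos2023 <- function(bec_min = 150, ige_min = 100, scs_min = 2,
                             snot22_min = 40, vas_los_min = 52,
                             ess_min = 1, k = 3) {
  tree <- crit_all("overall",
    crit_threshold("ess", "n_ess", ess_min, "History of ESS"),
    crit_at_least("uncontrolled_severe", k,
      crit_any("type2",
        crit_threshold("bec", "bec", bec_min,
                       sprintf("BEC >= %s cells/uL", bec_min)),
        crit_threshold("ige", "ige", ige_min,
                       sprintf("Serum total IgE >= %s IU/mL", ige_min)),
        label = sprintf("Type-2 (BEC >= %s and/or serum total IgE >= %s)",
                        bec_min, ige_min)),
      crit_threshold("scs", "n_scs_past_year", scs_min,
                     sprintf("At least %d SCS courses last year", scs_min)),
      crit_threshold("snot22", "snot22", snot22_min,
                     sprintf("Impaired QoL measured by SNOT-22 >= %s points",
                             snot22_min)),
      crit_threshold("vas_los", "vas_los", vas_los_min,
                     sprintf("Impaired smell measured by VAS LoS >= %s mm",
                             vas_los_min)),
      crit_flag("asthma", "asthma", "Asthma"),
      label = sprintf("Meets at least %d out of 5 uncontrolled severe criteria", k)),
    label = "Prior surgery and meets 3 out of 5 uncontrolled severe criteria")
  new_ruleset(
    name = "epos2023", tree = tree,
    thresholds = c(bec_min = bec_min, ige_min = ige_min, scs_min = scs_min,
                   snot22_min = snot22_min, vas_los_min = vas_los_min,
                   ess_min = ess_min, k_of_n = k),
    report_ids = c("ess", "bec", "ige", "type2", "scs", "snot22",
                   "vas_los", "asthma", "uncontrolled_severe", "overall"),
    sections = c(ess = "History", bec = "Blood values", ige = "Blood values",
                 type2 = "Uncontrolled severe", scs = "Uncontrolled severe",
                 snot22 = "Uncontrolled severe", vas_los = "Uncontrolled severe",
                 asthma = "Uncontrolled severe",
                 uncontrolled_severe = "Uncontrolled severe",
                 overall = "Criteria met"))
}

#' Fetch a bundled rule set by name
#'
#' @param name `"euforea2021"` or `"epos2023"`.
#' @return A `crs_ruleset`.
#' @export
get_ruleset <- function(name) {
  switch(match.arg(name, c("euforea2021", "epos2023")),
         euforea2021 = ruleset_euforea2021(),
         epos2023 = ruleset_epos2023())
}

#' @export
print.crs_ruleset <- function(x, ...) {
  cat(sprintf("<crs_ruleset: %s>\n", x$name))
  cat("thresholds:", paste(names(x$thresholds), x$thresholds,
                           sep = "=", collapse = ", "), "\n")
  print_node <- function(node, depth) {
    head <- switch(node$kind,
      threshold = sprintf("%s [%s >= %s]", node$id, node$field, node$cutoff),
      flag = sprintf("%s [%s]", node$id, node$field),
      at_least = sprintf("%s [at least %d of %d]", node$id, node$k,
                         length(node$children)),
      sprintf("%s [%s]", node$id, node$kind))
    cat(strrep("  ", depth), head, "\n", sep = "")
    for (ch in node$children %||% list()) print_node(ch, depth + 1)
  }
  print_node(x$tree, 0)
  invisible(x)
}

# ---- per-patient evaluation ------------------------------------------------

#' Evaluate a rule set on a whole cohort
#'
#' @param cohort A validated cohort tibble.
#' @param ruleset A `crs_ruleset` (or its name).
#' @return A tibble: `patient_id`, one logical column per tree node
#'   (`NA` = UNKNOWN), `overall`, and `evaluable` (overall determinate).
#' @export
evaluate_ruleset <- function(cohort, ruleset) {
  if (is.character(ruleset)) ruleset <- get_ruleset(ruleset)
  states <- eval_criterion(ruleset$tree, cohort)
  out <- tibble::as_tibble(states[setdiff(names(states), "overall")])
  out <- tibble::add_column(out, patient_id = cohort$patient_id, .before = 1)
  out$overall <- states$overall
  out$evaluable <- !is.na(states$overall)
  out
}

#' Per-patient verdict with component breakdown
#'
#' @param record A one-row cohort-shaped data frame.
#' @param ruleset A `crs_ruleset` (or its name).
#' @return A `crs_verdict`: list with `ruleset_name`, `overall`
#'   (logical, `NA` = UNKNOWN), `components` (named logical vector over
#'   every tree node in fixed pre-order), and `evaluable`.
#' @export
evaluate_record <- function(record, ruleset) {
  if (is.character(ruleset)) ruleset <- get_ruleset(ruleset)
  if (!is.data.frame(record)) record <- tibble::as_tibble(record)
  stopifnot(nrow(record) == 1)
  states <- eval_criterion(ruleset$tree, record)
  components <- vapply(states, `[`, logical(1), 1)
  structure(list(ruleset_name = ruleset$name,
                 overall = components[["overall"]],
                 components = components,
                 evaluable = !is.na(components[["overall"]])),
            class = "crs_verdict")
}

#' @export
print.crs_verdict <- function(x, ...) {
  cat(sprintf("<crs_verdict: %s> overall = %s (%s)\n", x$ruleset_name,
              tri_label(x$overall),
              if (x$evaluable) "evaluable" else "not evaluable"))
  comp <- x$components[setdiff(names(x$components), "overall")]
  cat(paste0("  ", names(comp), ": ", tri_label(comp), collapse = "\n"), "\n")
  invisible(x)
}

# ---- JSON serialization ----------------------------------------------------

node_to_list <- function(node) {
  base <- list(kind = node$kind, id = node$id, label = node$label)
  if (node$kind == "threshold") {
    c(base, list(field = node$field, cutoff = node$cutoff))
  } else if (node$kind == "flag") {
    c(base, list(field = node$field))
  } else {
    extra <- if (node$kind == "at_least") list(k = node$k) else list()
    c(base, extra, list(children = lapply(node$children, node_to_list)))
  }
}

node_from_list <- function(x) {
  switch(x$kind,
    threshold = crit_threshold(x$id, x$field, x$cutoff, x$label),
    flag = crit_flag(x$id, x$field, x$label),
    all = do.call(crit_all, c(list(x$id), lapply(x$children, node_from_list),
                              list(label = x$label))),
    any = do.call(crit_any, c(list(x$id), lapply(x$children, node_from_list),
                              list(label = x$label))),
    at_least = do.call(crit_at_least,
                       c(list(x$id, x$k), lapply(x$children, node_from_list),
                         list(label = x$label))),
    stop("unknown criterion kind in JSON: ", x$kind))
}

#' Serialize a rule set to JSON
#'
#' The document schema (name, thresholds, criterion tree with leaves as
#' field/cutoff pairs) is published at
#' `system.file("extdata", "ruleset-schema.json", package = "crsbiologic")`.
#'
#' @param ruleset A `crs_ruleset`.
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
ruleset_to_json <- function(ruleset, path = NULL) {
  doc <- list(name = ruleset$name,
              thresholds = as.list(ruleset$thresholds),
              report_ids = ruleset$report_ids,
              sections = as.list(ruleset$sections),
              tree = node_to_list(ruleset$tree))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Deserialize a rule set from JSON
#'
#' @param path Path to a rule-set JSON document, or a JSON string.
#' @return A `crs_ruleset`.
#' @export
ruleset_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  new_ruleset(name = doc$name,
              tree = node_from_list(doc$tree),
              thresholds = unlist(doc$thresholds),
              report_ids = unlist(doc$report_ids),
              sections = unlist(doc$sections))
}
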