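# Patient record schema, validation and CSV round-trip.
#
# A cohort is a tibble with one row per patient and the columns of
# column_dictionary(); every field except patient_id may be missing
# (empty cell or "NA" in CSV). Missingness is data, not an error:
# validation only rejects values that are present and out of range.

the_dictionary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "column_dictionary.csv",
                          package = "crsbiologic", mustWork = TRUE)
      cache <<- readr::read_csv(path, col_types = "ccddcc", progress = FALSE)
    }
    cache
  }
})

#' Cohort column dictionary
#'
#' The machine-readable schema of a cohort table: column name, storage
#' type, legal range or category levels, and a description. Shipped as
#' `extdata/column_dictionary.csv` and used by [read_cohort()] and
#' [validate_cohort()].
#'
#' @return A tibble with columns `name`, `type`, `lower`, `upper`,
#'   `levels` (pipe-separated), `description`.
#' @export
column_dictionary <- function() {
  the_dictionary()
}

dict_col_types <- function(dict) {
  # readr column spec from the dictionary types
  code <- vapply(dict$type, function(t) {
    switch(t, character = "c", category = "c", numeric = "d",
           integer = "i", logical = "l",
           stop("unknown dictionary type: ", t))
  }, character(1))
  paste(code, collapse = "")
}

#' Assemble and validate a cohort table
#'
#' Coerces a data frame to the cohort schema (adding absent optional
#' columns as all-missing, ordering columns as in the dictionary) and
#' checks the integrity invariants: unique `patient_id`, all present
#' values within their documented ranges.
#'
#' @param data A data frame with a `patient_id` column; other dictionary
#'   columns optional.
#' @param provenance Free-text source label attached as an attribute.
#' @return A validated cohort tibble.
#' @export
as_cohort <- function(data, provenance = "user") {
  dict <- column_dictionary()
  data <- tibble::as_tibble(data)
  if (!"patient_id" %in% names(data)) {
    stop("cohort must have a patient_id column", call. = FALSE)
  }
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[i]
    if (!nm %in% names(data)) {
      data[[nm]] <- switch(dict$type[i],
        character = NA_character_, category = NA_character_,
        numeric = NA_real_, integer = NA_integer_, logical = NA)
    }
  }
  data <- data[, dict$name]
  data$patient_id <- as.character(data$patient_id)
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[i]
    data[[nm]] <- switch(dict$type[i],
      character = as.character(data[[nm]]),
      category = as.character(data[[nm]]),
      numeric = as.numeric(data[[nm]]),
      integer = as.integer(data[[nm]]),
      logical = as.logical(data[[nm]]))
  }
  dup <- data$patient_id[duplicated(data$patient_id)]
  if (length(dup) > 0) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data$patient_id)) {
    stop("patient_id must never be missing", call. = FALSE)
  }
  viol <- validate_cohort(data)
  if (nrow(viol) > 0) {
    stop("cohort validation failed:\n",
         paste(utils::head(viol$message, 5), collapse = "\n"),
         if (nrow(viol) > 5) sprintf("\n... and %d more", nrow(viol) - 5),
         call. = FALSE)
  }
  attr(data, "provenance") <- provenance
  data
}

#' Validate every record of a cohort
#'
#' Range and category checks for all present values. Missing values are
#' never violations.
#'
#' @param cohort A cohort-shaped data frame.
#' @return A tibble of violations with columns `patient_id`, `field`,
#'   `value`, `message`; zero rows when the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  dict <- column_dictionary()
  out <- list()
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[i]
    if (!nm %in% names(cohort)) next
    x <- cohort[[nm]]
    bad <- rep(FALSE, length(x))
    msg <- NULL
    if (dict$type[i] %in% c("numeric", "integer")) {
      lo <- dict$lower[i]; hi <- dict$upper[i]
      if (!is.na(lo)) bad <- bad | (!is.na(x) & x < lo)
      if (!is.na(hi)) bad <- bad | (!is.na(x) & x > hi)
      msg <- sprintf("%s = %s outside [%s, %s]", nm, x,
                     ifelse(is.na(lo), "-Inf", lo), ifelse(is.na(hi), "Inf", hi))
    } else if (dict$type[i] == "category") {
      levels <- strsplit(dict$levels[i], "|", fixed = TRUE)[[1]]
      bad <- !is.na(x) & !(x %in% levels)
      msg <- sprintf("%s = '%s' not one of {%s}", nm, x,
                     paste(levels, collapse = ", "))
    }
    if (any(bad)) {
      out[[nm]] <- tibble::tibble(
        patient_id = as.character(cohort$patient_id[bad]),
        field = nm,
        value = as.character(x[bad]),
        message = paste0("patient ", cohort$patient_id[bad], ": ", msg[bad]))
    }
  }
  if (length(out) == 0) {
    tibble::tibble(patient_id = character(), field = character(),
                   value = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Validate a single patient record
#'
#' @param record A one-row cohort-shaped data frame (or named list).
#' @return A tibble of violations (see [validate_cohort()]); empty when
#'   the record is clean.
#' @export
validate_record <- function(record) {
  if (!is.data.frame(record)) record <- tibble::as_tibble(record)
  stopifnot(nrow(record) == 1)
  validate_cohort(record)
}

#' Read a cohort from CSV
#'
#' UTF-8 comma-separated, header row mandatory, one row per patient.
#' Empty cells and the literal string `NA` are read as missing. The
#' returned cohort has passed all integrity checks.
#'
#' @param path Path to the CSV file.
#' @param unknown_columns What to do with columns not in the dictionary:
#'   `"warn"` (drop with a warning, default), `"error"`, or `"ignore"`.
#'   The optional `prior_biologic` column is always understood.
#' @param drop_prior_biologic If the file carries a logical
#'   `prior_biologic` column, drop rows where it is `TRUE` (patients
#'   already on a biologic are outside the analysis population).
#' @return A validated cohort tibble; provenance attribute set to `path`.
#' @export
read_cohort <- function(path, unknown_columns = c("warn", "error", "ignore"),
                        drop_prior_biologic = TRUE) {
  unknown_columns <- match.arg(unknown_columns)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dict <- column_dictionary()
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE, show_col_types = FALSE))
  extra <- setdiff(header, c(dict$name, "prior_biologic"))
  if (length(extra) > 0) {
    msg <- paste("unknown columns:", paste(extra, collapse = ", "))
    if (unknown_columns == "error") stop(msg, call. = FALSE)
    if (unknown_columns == "warn") warning(msg, call. = FALSE)
  }
  types <- stats::setNames(as.list(strsplit(dict_col_types(dict), "")[[1]]),
                           dict$name)
  spec <- do.call(readr::cols, c(
    lapply(types[intersect(dict$name, header)], function(code) {
      switch(code, c = readr::col_character(), d = readr::col_double(),
             i = readr::col_integer(), l = readr::col_logical())
    }),
    if ("prior_biologic" %in% header) list(prior_biologic = readr::col_logical()),
    list(.default = readr::col_skip())
  ))
  data <- readr::read_csv(path, col_types = spec, na = c("", "NA"),
                          progress = FALSE)
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed CSV '%s': row %d, column '%s': expected %s, got '%s'",
                 path, probs$row[1], header[probs$col[1]],
                 probs$expected[1], probs$actual[1]),
         call. = FALSE)
  }
  if ("prior_biologic" %in% names(data)) {
    if (drop_prior_biologic) {
      keep <- !(data$prior_biologic %in% TRUE)
      if (sum(!keep) > 0) {
        message(sum(!keep), " patient(s) with prior biologic use dropped")
      }
      data <- data[keep, ]
    }
    data$prior_biologic <- NULL
  }
  as_cohort(data, provenance = path)
}

#' Write a cohort to CSV
#'
#' Missing values are written as empty cells; [read_cohort()] of the
#' result reproduces every value and missingness flag exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dict <- column_dictionary()
  readr::write_csv(cohort[, dict$name], path, na = "")
  invisible(path)
}
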