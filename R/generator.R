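# Synthetic CRSwNP cohort generator.
#
# Sampling is Gaussian-copula style: one shared standard-normal severity
# factor z per patient, a per-field loading lambda, and a per-field
# innovation e, giving a uniform rank u = Phi(lambda*z +
# sqrt(1-lambda^2)*e) that is pushed through the field's marginal
# quantile function. With all loadings 0 (the default) fields are
# independent; the published data only constrain the marginals.

# ---- quantile calibration --------------------------------------------------

z75 <- stats::qnorm(0.75)

#' Calibrate a distribution family to a median and quartiles
#'
#' Fits a two-parameter family to a published median/IQR triple. The
#' location is anchored so the theoretical median matches the target
#' exactly (closed form for the log-normal; a constrained search for the
#' scaled beta), and the remaining spread parameter minimizes the
#' squared error of the two theoretical quartiles against the targets
#' (bounded numerical search, tolerance 1e-6). Anchoring the median is
#' deliberate: with three targets and two parameters an unconstrained
#' joint fit trades median error against quartile error, and the median
#' is the quantity downstream analyses report.
#'
#' @param median,q1,q3 Target quantiles, `q1 <= median <= q3`.
#' @param family `"lognormal"` or `"scaled_beta"`.
#' @param lower,upper Support bounds (required for `scaled_beta`).
#' @return A list: `family`, `params` (named), `fitted_quantiles`
#'   (q1, median, q3 implied by the fit), `residual` (sum of squared
#'   quartile errors).
#' @export
#' @examples
#' calibrate_quantiles(1, exp(-qnorm(0.75)), exp(qnorm(0.75)), "lognormal")
calibrate_quantiles <- function(median, q1, q3,
                                family = c("lognormal", "scaled_beta"),
                                lower = NULL, upper = NULL) {
  family <- match.arg(family)
  if (!(q1 <= median && median <= q3)) {
    stop("calibration error: need q1 <= median <= q3", call. = FALSE)
  }
  if (family == "lognormal") {
    if (q1 <= 0) stop("calibration error: log-normal needs positive targets",
                      call. = FALSE)
    meanlog <- log(median)
    obj <- function(s) {
      (median * exp(-z75 * s) - q1)^2 + (median * exp(z75 * s) - q3)^2
    }
    sdlog <- stats::optimize(obj, c(1e-6, 10), tol = 1e-6)$minimum
    params <- c(meanlog = meanlog, sdlog = sdlog)
    fq <- stats::qlnorm(c(0.25, 0.5, 0.75), meanlog, sdlog)
  } else {
    if (is.null(lower) || is.null(upper) || lower >= upper) {
      stop("calibration error: scaled_beta needs bounds lower < upper",
           call. = FALSE)
    }
    if (q1 < lower || q3 > upper || median <= lower || median >= upper) {
      stop("calibration error: targets outside the bounded range",
           call. = FALSE)
    }
    m <- (median - lower) / (upper - lower)
    t1 <- (q1 - lower) / (upper - lower)
    t3 <- (q3 - lower) / (upper - lower)
    beta_for <- function(a) {
      # qbeta(0.5, a, b) is continuous and decreasing in b; extreme
      # shapes visited by the search emit accuracy warnings that do not
      # affect the optimum
      f <- function(lb) suppressWarnings(stats::qbeta(0.5, a, exp(lb))) - m
      exp(stats::uniroot(f, c(-12, 12), tol = 1e-9)$root)
    }
    obj <- function(la) {
      a <- exp(la); b <- beta_for(a)
      (stats::qbeta(0.25, a, b) - t1)^2 + (stats::qbeta(0.75, a, b) - t3)^2
    }
    la <- stats::optimize(obj, c(-5, 8), tol = 1e-6)$minimum
    a <- exp(la); b <- beta_for(a)
    params <- c(shape1 = a, shape2 = b, lower = lower, upper = upper)
    fq <- lower + (upper - lower) * stats::qbeta(c(0.25, 0.5, 0.75), a, b)
  }
  list(family = family, params = params,
       fitted_quantiles = c(q1 = fq[1], median = fq[2], q3 = fq[3]),
       residual = (fq[1] - q1)^2 + (fq[3] - q3)^2)
}

# ---- marginal specifications ----------------------------------------------

new_marginal <- function(family, spec) {
  structure(c(list(family = family), spec), class = "crs_marginal")
}

# Build a marginal object from a config-file style spec list.
build_marginal <- function(spec) {
  if (inherits(spec, "crs_marginal")) return(spec)
  stopifnot(is.list(spec), !is.null(spec$family))
  fam <- spec$family
  rounder <- spec$round
  m <- switch(fam,
    truncnorm = {
      stopifnot(spec$sd > 0, spec$lower < spec$upper)
      new_marginal("truncnorm", spec[c("mean", "sd", "lower", "upper")])
    },
    lognormal = {
      fit <- calibrate_quantiles(spec$median, spec$q1, spec$q3, "lognormal")
      new_marginal("lognormal", as.list(fit$params))
    },
    scaled_beta = {
      fit <- calibrate_quantiles(spec$median, spec$q1, spec$q3, "scaled_beta",
                                 lower = spec$lower, upper = spec$upper)
      new_marginal("scaled_beta", as.list(fit$params))
    },
    categorical = {
      p <- unlist(spec$probs)
      if (abs(sum(p) - 1) > 0.02 || any(p < 0)) {
        stop("categorical probabilities must be non-negative and sum to ~1",
             call. = FALSE)
      }
      new_marginal("categorical",
                   list(levels = unlist(spec$levels), probs = p / sum(p)))
    },
    banded_count = {
      p <- unlist(spec$probs)
      if (abs(sum(p) - 1) > 0.02 || any(p < 0)) {
        stop("band probabilities must be non-negative and sum to ~1",
             call. = FALSE)
      }
      bands <- lapply(spec$bands, function(b) as.integer(unlist(b)))
      stopifnot(length(bands) == length(p))
      new_marginal("banded_count", list(bands = bands, probs = p / sum(p)))
    },
    bernoulli = {
      stopifnot(spec$p >= 0, spec$p <= 1)
      new_marginal("bernoulli", list(p = spec$p))
    },
    stop("unknown marginal family: ", fam))
  m$round <- rounder
  m
}

# Marginal quantile transform: uniform rank u in (0,1) -> field values.
# Monotone in u for every family, so a positive loading on the severity
# factor shifts every field towards its severe end consistently.
quantile_marginal <- function(m, u) {
  switch(m$family,
    truncnorm = {
      plo <- stats::pnorm((m$lower - m$mean) / m$sd)
      phi <- stats::pnorm((m$upper - m$mean) / m$sd)
      m$mean + m$sd * stats::qnorm(plo + u * (phi - plo))
    },
    lognormal = stats::qlnorm(u, m$meanlog, m$sdlog),
    scaled_beta = m$lower + (m$upper - m$lower) *
      stats::qbeta(u, m$shape1, m$shape2),
    categorical = {
      idx <- pmin(findInterval(u, cumsum(m$probs), rightmost.closed = TRUE) + 1,
                  length(m$levels))
      m$levels[idx]
    },
    banded_count = {
      cum <- cumsum(m$probs)
      idx <- pmin(findInterval(u, cum, rightmost.closed = TRUE) + 1,
                  length(m$bands))
      lo <- c(0, cum)[idx]
      within <- pmin(pmax((u - lo) / m$probs[idx], 0), 1 - 1e-12)
      vapply(seq_along(u), function(i) {
        band <- m$bands[[idx[i]]]
        band[1 + floor(within[i] * length(band))]
      }, integer(1))
    },
    bernoulli = u > 1 - m$p)
}

# ---- generator configuration ----------------------------------------------

# A bare 'n:' key is a YAML 1.1 boolean token and parses as "FALSE";
# map it back so configuration files may write the key unquoted.
normalize_raw_config <- function(raw) {
  names(raw)[names(raw) == "FALSE"] <- "n"
  raw
}

default_config_raw <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "default_generator_config.yaml",
                          package = "crsbiologic", mustWork = TRUE)
      cache <<- normalize_raw_config(yaml::read_yaml(path))
    }
    cache
  }
})

missingness_from_raw <- function(raw) {
  rates <- numeric(0)
  if (!is.null(raw[["missingness_observed"]])) {
    den <- raw[["missingness_observed"]][["denominator"]]
    obs <- unlist(raw[["missingness_observed"]][["observed"]])
    rates <- 1 - obs / den
  }
  if (!is.null(raw[["missingness"]])) {
    user <- unlist(raw[["missingness"]])
    rates[names(user)] <- user
  }
  rates
}

#' Build a generator configuration
#'
#' Starts from the packaged default configuration (calibrated to the
#' published cohort characteristics) and applies per-field overrides.
#'
#' @param n Cohort size (default 206, the published cohort size).
#' @param seed Integer seed; the whole generation is deterministic given
#'   the configuration.
#' @param marginals Named list of per-field overrides, each either a
#'   `crs_marginal` or a config-style spec list (see the packaged
#'   `extdata/default_generator_config.yaml` for the format).
#' @param loadings Named numeric in `[-1, 1]`: per-field weights on the
#'   shared severity factor; unnamed fields default to 0 (independence).
#' @param missingness Named numeric in `[0, 1]`: per-field
#'   missing-completely-at-random rates overriding the defaults (which
#'   are one minus the published per-field observed fractions).
#' @return A `crs_generator_config`.
#' @export
generator_config <- function(n = NULL, seed = NULL, marginals = list(),
                             loadings = numeric(0), missingness = NULL) {
  raw <- default_config_raw()
  n <- as.integer(n %||% raw[["n"]])
  seed <- as.integer(seed %||% raw[["seed"]])
  if (length(n) != 1 || is.na(n) || n < 0) {
    stop("invalid configuration: n must be >= 0", call. = FALSE)
  }
  if (length(seed) != 1 || is.na(seed)) {
    stop("invalid configuration: seed must be an integer", call. = FALSE)
  }
  marg <- lapply(raw$marginals, build_marginal)
  for (nm in names(marginals)) marg[[nm]] <- build_marginal(marginals[[nm]])
  bad <- setdiff(names(marg), column_dictionary()$name)
  if (length(bad) > 0) stop("marginals for unknown fields: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  load <- unlist(raw$loadings) %||% numeric(0)
  if (is.null(load)) load <- numeric(0)
  load[names(loadings)] <- loadings
  if (length(load) > 0 && any(abs(load) > 1)) {
    stop("invalid configuration: loadings must lie in [-1, 1]", call. = FALSE)
  }
  rates <- missingness_from_raw(raw)
  if (!is.null(missingness)) {
    stopifnot(!is.null(names(missingness)))
    rates[names(missingness)] <- missingness
  }
  if (any(rates < 0 | rates > 1)) {
    stop("invalid configuration: missingness rates must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(n = n, seed = seed, marginals = marg,
                 loadings = load, missingness = rates),
            class = "crs_generator_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' The file may specify any subset of `n`, `seed`, `marginals`,
#' `loadings` and `missingness` (direct per-field rates) or
#' `missingness_observed` (published denominators); unspecified parts
#' fall back to the packaged defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `crs_generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    normalize_raw_config(yaml::read_yaml(path))
  }
  rates <- missingness_from_raw(raw)
  generator_config(n = raw$n, seed = raw$seed,
                   marginals = raw$marginals %||% list(),
                   loadings = unlist(raw$loadings) %||% numeric(0),
                   missingness = if (length(rates) > 0) rates)
}

#' @export
print.crs_generator_config <- function(x, ...) {
  cat(sprintf("<crs_generator_config> n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  %d marginals; %d nonzero loadings; missingness on %d fields\n",
              length(x$marginals), sum(x$loadings != 0),
              sum(x$missingness > 0)))
  invisible(x)
}

# ---- sampling --------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws `config$n` complete records (no missingness; see
#' [apply_missingness()]) from the configured marginals, coupled through
#' the shared severity factor, then rounded and clipped to the legal
#' range of each field. Deterministic given the configuration.
#'
#' @param config A `crs_generator_config`.
#' @return A validated cohort tibble with provenance `"synthetic"`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "crs_generator_config"))
  dict <- column_dictionary()
  n <- config$n
  withr::with_seed(config$seed, {
    z <- stats::rnorm(n)
    cols <- list(patient_id = sprintf("S%05d", seq_len(n)))
    for (i in seq_len(nrow(dict))) {
      nm <- dict$name[i]
      if (nm == "patient_id") next
      m <- config$marginals[[nm]]
      if (is.null(m)) {
        cols[[nm]] <- rep(NA, n)
        next
      }
      lam <- if (nm %in% names(config$loadings)) config$loadings[[nm]] else 0
      e <- stats::rnorm(n)
      u <- stats::pnorm(lam * z + sqrt(1 - lam^2) * e)
      # keep u strictly inside (0,1) for the quantile transforms
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      x <- quantile_marginal(m, u)
      if (is.numeric(x)) {
        if (!is.null(m$round)) x <- round(x, m$round)
        if (!is.na(dict$lower[i])) x <- pmax(x, dict$lower[i])
        if (!is.na(dict$upper[i])) x <- pmin(x, dict$upper[i])
      }
      cols[[nm]] <- x
    }
    as_cohort(tibble::as_tibble(cols), provenance = "synthetic")
  })
}

#' Mask fields missing-completely-at-random
#'
#' Each field listed in `rates` is independently blanked with its rate;
#' `patient_id` is never blanked. Deterministic given `seed`.
#'
#' @param cohort A cohort tibble.
#' @param rates Named numeric missingness probabilities in `[0, 1]`;
#'   defaults to the packaged rates (one minus the published per-field
#'   observed fractions).
#' @param seed Integer seed for the masking draws.
#' @return The cohort with values masked.
#' @export
apply_missingness <- function(cohort, rates = NULL, seed = 1L) {
  if (is.null(rates)) rates <- generator_config()$missingness
  if (length(rates) == 0) return(cohort)
  stopifnot(!is.null(names(rates)))
  if (any(rates < 0 | rates > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  if ("patient_id" %in% names(rates)) {
    stop("patient_id can never be masked", call. = FALSE)
  }
  bad <- setdiff(names(rates), column_dictionary()$name)
  if (length(bad) > 0) stop("missingness rates for unknown fields: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  n <- nrow(cohort)
  fields <- intersect(column_dictionary()$name, names(rates))
  withr::with_seed(as.integer(seed), {
    for (nm in fields) {
      mask <- stats::runif(n) < rates[[nm]]
      cohort[[nm]][mask] <- NA
    }
  })
  cohort
}
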