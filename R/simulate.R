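#' Simulate visit-level records for one institution
#'
#' Draws a full longitudinal cohort from an [institution_profile()]. Each
#' sample receives an outcome class by the profile's prevalence; each year
#' contributes one visit (checkup-style) or `1 + Poisson` visits
#' (hospital-style). Quantitative features are drawn per visit from the
#' class-conditional Gaussian (clipped at 0, the physiological lower bound),
#' qualitative features from the class-conditional category frequencies. Age
#' is drawn once per sample (its 2015 value follows the class-conditional
#' Gaussian) and advances by one per calendar year; Sex is fixed per sample.
#' During the outcome window (2016-2018) HbA1c and FPG follow the profile's
#' outcome trajectory model instead, so that a positive sample exceeds both
#' diagnostic thresholds on every occasion while a negative sample never
#' does, and the labelling stage can recover the generating class. Finally,
#' every value is masked missing independently with its feature's
#' `missing_rate`.
#'
#' @param profile An [institution_profile()].
#' @param seed Integer seed; identical `(profile, seed)` pairs yield
#'   identical output.
#' @return A data.frame of visit records with columns `sample_id`,
#'   `institution`, `year`, `visit_index`, then one column per catalogue
#'   feature (qualitative features as character, quantitative as numeric;
#'   `NA` marks a missing value). The generating class is attached as
#'   `attr(, "outcome_class")`, a named 0/1 vector keyed by `sample_id`,
#'   for validation against the re-derived labels.
#' @seealso [write_visit_csv()], [aggregate_by_year()]
#' @export
#' @examples
#' prof <- default_profiles()$checkup
#' prof$n_samples <- 20
#' visits <- generate_institution(prof, seed = 1)
#' head(visits[, 1:6])
generate_institution <- function(profile, seed) {
  stopifnot(inherits(profile, "institution_profile"))
  assert_scalar_number(seed, "seed")
  obs_years <- 2014:2015
  out_years <- 2016:2018
  if (!all(obs_years %in% profile$years) || !all(out_years %in% profile$years)) {
    stop("profile years must cover both the 2014-2015 observation window ",
         "and the 2016-2018 outcome window", call. = FALSE)
  }

  cat_df <- feature_catalogue()
  empty <- function() {
    out <- data.frame(sample_id = character(0), institution = character(0),
                      year = integer(0), visit_index = integer(0),
                      stringsAsFactors = FALSE)
    for (f in cat_df$feature) {
      out[[f]] <- if (feature_kind(f) == "quantitative") numeric(0)
                  else character(0)
    }
    attr(out, "outcome_class") <- integer(0)
    out
  }
  if (profile$n_samples == 0) return(empty())

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  n <- profile$n_samples
  ids <- sprintf("%s_%05d", profile$name, seq_len(n))
  cls <- stats::rbinom(n, 1, profile$prevalence)          # 1 = incident diabetes
  names(cls) <- ids

  # Per-sample constants.
  age_spec <- profile$feature_specs$Age
  age_2015 <- stats::rnorm(n, age_spec$mean[cls + 1L] + drift_of(profile, "Age"),
                           age_spec$sd[cls + 1L])
  sex_spec <- profile$feature_specs$Sex
  sex_lev <- category_levels("Sex")
  sex <- vapply(cls, function(ci) {
    fr <- if (ci == 1L) sex_spec$freq$pos else sex_spec$freq$neg
    sample(sex_lev, 1, prob = fr)
  }, character(1))

  # Visit grid: one row per (sample, year, visit).
  years <- profile$years
  if (identical(profile$visit_model$type, "fixed")) {
    nv <- matrix(profile$visit_model$visits %||% 1L, n, length(years))
  } else {
    nv <- matrix(1L + stats::rpois(n * length(years),
                                   profile$visit_model$mean_extra),
                 n, length(years))
  }
  si <- rep(seq_len(n), times = rowSums(nv))
  yr <- unlist(lapply(seq_len(n), function(i) rep(years, times = nv[i, ])),
               use.names = FALSE)
  vi <- unlist(lapply(seq_len(n), function(i) {
    unlist(lapply(nv[i, ], seq_len), use.names = FALSE)
  }), use.names = FALSE)
  N <- length(si)
  rcls <- cls[si]
  in_outcome <- yr %in% out_years

  out <- data.frame(sample_id = ids[si], institution = profile$name,
                    year = yr, visit_index = vi, stringsAsFactors = FALSE)

  for (f in cat_df$feature) {
    sp <- profile$feature_specs[[f]]
    if (f == "Age") {
      vals <- round(age_2015[si] + (yr - 2015))
      vals <- pmax(vals, 0)
    } else if (f == "Sex") {
      vals <- sex[si]
    } else if (sp$kind == "quantitative") {
      mu <- sp$mean[rcls + 1L] + drift_of(profile, f)
      vals <- stats::rnorm(N, mu, sp$sd[rcls + 1L])
      if (f %in% c("HbA1c", "FPG")) {
        om <- profile$outcome_model
        for (cl in 0:1) {
          sel <- in_outcome & rcls == cl
          if (!any(sel)) next
          par <- if (cl == 1L) om$pos[[f]] else om$neg[[f]]
          draw <- stats::rnorm(sum(sel), par$mean, par$sd)
          if (!is.null(par$floor)) draw <- pmax(draw, par$floor)
          if (!is.null(par$cap)) draw <- pmin(draw, par$cap)
          vals[sel] <- draw
        }
      }
      vals <- pmax(vals, 0)
      vals <- round(vals, 2)
    } else {
      lev <- category_levels(f)
      vals <- character(N)
      for (cl in 0:1) {
        sel <- rcls == cl
        if (!any(sel)) next
        fr <- if (cl == 1L) sp$freq$pos else sp$freq$neg
        vals[sel] <- sample(lev, sum(sel), replace = TRUE, prob = fr)
      }
    }
    rate <- sp$missing_rate %||% 0
    if (rate > 0) vals[stats::runif(N) < rate] <- NA
    out[[f]] <- vals
  }

  out <- out[order(out$sample_id, out$year, out$visit_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "outcome_class") <- cls
  out
}

drift_of <- function(profile, feature) {
  d <- profile$drift
  if (length(d) && feature %in% names(d)) d[[feature]] else 0
}

#' Write / read visit-level records as CSV
#'
#' The interchange dialect is deliberately plain: comma-separated, UTF-8,
#' header row, one row per visit, empty field for a missing value.
#'
#' @param visits Visit-level data.frame as from [generate_institution()].
#' @param path File path.
#' @return `write_visit_csv()` returns `path` invisibly; `read_visit_csv()`
#'   returns the visit data.frame.
#' @export
write_visit_csv <- function(visits, path) {
  check_feature_columns(visits)
  utils::write.csv(visits, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_visit_csv
#' @export
read_visit_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", fileEncoding = "UTF-8")
  check_feature_columns(out)
  for (f in intersect(colnames(out), feature_catalogue()$feature)) {
    if (feature_kind(f) == "quantitative") out[[f]] <- as.numeric(out[[f]])
    else out[[f]] <- as.character(out[[f]])
  }
  out
}
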