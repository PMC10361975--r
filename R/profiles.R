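#' Construct an institution profile for cohort simulation
#'
#' A profile describes one institution's visit-generating process: cohort
#' size, calendar coverage, how many visits a sample makes per year, the
#' class-conditional distribution of every common feature, per-feature
#' missingness, outcome prevalence, and an optional additive mean drift
#' against the other institution.
#'
#' @param name Institution label (e.g. `"checkup"`).
#' @param n_samples Number of samples (citizens or patients) to simulate.
#' @param years Calendar years covered; must include both the observation
#'   window (2014-2015) and the outcome window (2016-2018) for the default
#'   pipeline to apply.
#' @param visit_model Either `list(type = "fixed", visits = 1)` (one checkup
#'   per year) or `list(type = "poisson", mean_extra = 2)` (hospital-style:
#'   `1 + Poisson(mean_extra)` visits per year).
#' @param feature_specs Named list, one entry per catalogue feature. A
#'   quantitative spec is `list(kind, mean = c(neg, pos), sd = c(neg, pos),
#'   missing_rate)`; a qualitative spec is `list(kind, freq = list(neg, pos),
#'   missing_rate)` with frequencies over [category_levels()].
#' @param prevalence Fraction of positive-outcome (incident diabetes)
#'   samples, strictly inside (0, 1).
#' @param drift Named numeric vector of additive mean offsets applied to
#'   quantitative features (default none).
#' @param outcome_model Distributions of HbA1c and FPG during the outcome
#'   window, by class; see [default_profiles()] for the defaults. Positive
#'   samples are drawn at or above both diagnostic thresholds (HbA1c >= 6.5%,
#'   FPG >= 126 mg/dl) on every outcome-window occasion, negative samples
#'   strictly below at least one, so the downstream labeller can recover the
#'   generating class.
#'
#' @return An object of class `"institution_profile"`.
#' @seealso [default_profiles()], [generate_institution()]
#' @export
institution_profile <- function(name, n_samples, years = 2014:2018,
                                visit_model = list(type = "fixed", visits = 1),
                                feature_specs, prevalence,
                                drift = NULL, outcome_model = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  assert_scalar_number(n_samples, "n_samples")
  if (n_samples < 0) stop("n_samples must be >= 0", call. = FALSE)
  if (!is.numeric(years) || !length(years)) stop("invalid years", call. = FALSE)
  if (!is.list(visit_model) || !visit_model$type %in% c("fixed", "poisson")) {
    stop("visit_model$type must be 'fixed' or 'poisson'", call. = FALSE)
  }
  if (identical(visit_model$type, "poisson") &&
      (visit_model$mean_extra %||% -1) < 0) {
    stop("poisson visit model needs mean_extra >= 0", call. = FALSE)
  }
  assert_scalar_number(prevalence, "prevalence")
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  }
  cat <- feature_catalogue()
  missing_specs <- setdiff(cat$feature, names(feature_specs))
  if (length(missing_specs)) {
    stop("feature_specs missing: ", paste(missing_specs, collapse = ", "),
         call. = FALSE)
  }
  for (f in names(feature_specs)) {
    sp <- feature_specs[[f]]
    rate <- sp$missing_rate %||% 0
    if (rate < 0 || rate > 1) {
      stop("missing_rate for ", f, " outside [0, 1]", call. = FALSE)
    }
    if (identical(sp$kind, "quantitative")) {
      if (any(sp$sd <= 0)) stop("SD for ", f, " must be > 0", call. = FALSE)
    } else {
      lev <- category_levels(f)
      for (cls in c("neg", "pos")) {
        fr <- sp$freq[[cls]]
        if (length(fr) != length(lev) || abs(sum(fr) - 1) > 1e-8 ||
            any(fr < 0)) {
          stop("category frequencies for ", f, " (", cls,
               ") must be nonnegative and sum to 1", call. = FALSE)
        }
      }
    }
  }
  structure(
    list(name = name, n_samples = as.integer(n_samples),
         years = as.integer(sort(years)), visit_model = visit_model,
         feature_specs = feature_specs, prevalence = prevalence,
         drift = drift %||% numeric(0),
         outcome_model = outcome_model %||% default_outcome_model()),
    class = "institution_profile"
  )
}

#' @export
print.institution_profile <- function(x, ...) {
  cat("<institution_profile> ", x$name, "\n", sep = "")
  cat("  samples:    ", x$n_samples, "\n", sep = "")
  cat("  years:      ", paste(range(x$years), collapse = "-"), "\n", sep = "")
  cat("  visits/yr:  ",
      if (identical(x$visit_model$type, "fixed")) x$visit_model$visits
      else paste0("1 + Poisson(", x$visit_model$mean_extra, ")"), "\n",
      sep = "")
  cat("  prevalence: ", format(x$prevalence, digits = 3), "\n", sep = "")
  invisible(x)
}

# Outcome-window (2016-2018) trajectory model for the two diagnostic
# markers. Positive samples sit at or above both thresholds on every
# occasion (floor just above the cut), negatives are capped just below, so
# threshold co-occurrence reproduces the generating class exactly.
default_outcome_model <- function() {
  list(
    pos = list(HbA1c = list(mean = 7.0, sd = 0.7, floor = 6.6),
               FPG   = list(mean = 155, sd = 25, floor = 130)),
    neg = list(HbA1c = list(mean = 5.8, sd = 0.4, cap = 6.4),
               FPG   = list(mean = 100, sd = 15, cap = 124))
  )
}

quant_spec <- function(mean_neg, sd_neg, mean_pos, sd_pos, missing_rate = 0) {
  list(kind = "quantitative", mean = c(neg = mean_neg, pos = mean_pos),
       sd = c(neg = sd_neg, pos = sd_pos), missing_rate = missing_rate)
}

qual_spec <- function(freq_neg, freq_pos, missing_rate = 0) {
  list(kind = "qualitative",
       freq = list(neg = freq_neg / sum(freq_neg),
                   pos = freq_pos / sum(freq_pos)),
       missing_rate = missing_rate)
}

#' Default two-institution study profiles
#'
#' Returns the "checkup" profile (municipal health-checkup registry: 1399
#' samples, one visit per year, outcome prevalence 43/1399, fasting plasma
#' glucose and urinary glucose missing often enough that the 50% feature
#' filter removes them) and the "hospital" profile (university-hospital
#' history data: 1502 samples, multiple visits per year, prevalence
#' 209/1502, casual blood glucose and serum creatinine sparsely recorded in
#' the common-format extract). Class-conditional means and SDs of the eleven
#' features retained by the pipeline follow the published cohort statistics;
#' the remaining four features, which the sparsity filters remove, use
#' plausible clinical values. The two profiles deliberately disagree on some
#' markers (e.g. haemoglobin separates the classes in the checkup cohort but
#' not in the hospital cohort), emulating cross-institution distribution
#' shift.
#'
#' @return A list with elements `checkup` and `hospital`, both
#'   [institution_profile()] objects.
#' @export
#' @examples
#' p <- default_profiles()
#' p$checkup$feature_specs$HbA1c$mean
default_profiles <- function() {
  checkup_specs <- list(
    Age   = quant_spec(64.5, 6.8, 66.5, 3.8, 0.01),
    Sex   = qual_spec(c(650, 706), c(16, 27), 0),
    HbA1c = quant_spec(5.8, 0.4, 6.4, 0.4, 0.05),
    Hb    = quant_spec(12.0, 1.1, 14.5, 1.1, 0.05),
    FPG   = quant_spec(98, 12, 135, 25, 0.55),
    CBG   = quant_spec(115, 25, 160, 45, 0.30),
    RBC   = quant_spec(457.9, 34.9, 476.9, 34.2, 0.05),
    UG    = qual_spec(c(0.985, 0.010, 0.005, 0, 0),
                      c(0.70, 0.10, 0.10, 0.07, 0.03), 0.60),
    UP    = qual_spec(c(1279, 77, 0, 0, 0), c(40, 3, 0, 0, 0), 0.10),
    HDLC  = quant_spec(63.7, 15.3, 57.8, 14.4, 0.05),
    LDLC  = quant_spec(121.5, 26.8, 117.7, 25.0, 0.05),
    AST   = quant_spec(23.4, 5.6, 24.3, 6.4, 0.05),
    GGT   = quant_spec(29.3, 19.3, 34.9, 23.2, 0.05),
    Scr   = quant_spec(0.70, 0.15, 0.75, 0.20, 0.20),
    Hct   = quant_spec(42.1, 2.9, 43.6, 2.6, 0.05)
  )
  hospital_specs <- list(
    Age   = quant_spec(58.8, 18.8, 65.0, 13.5, 0.01),
    Sex   = qual_spec(c(600, 693), c(83, 126), 0),
    HbA1c = quant_spec(6.2, 0.8, 7.0, 0.9, 0.05),
    Hb    = quant_spec(13.0, 1.7, 12.9, 1.9, 0.08),
    FPG   = quant_spec(105, 18, 145, 35, 0.15),
    CBG   = quant_spec(120, 30, 175, 55, 0.88),
    RBC   = quant_spec(431.2, 56.8, 424.9, 62.3, 0.08),
    UG    = qual_spec(c(0.96, 0.01, 0.01, 0.01, 0.01),
                      c(0.60, 0.10, 0.12, 0.12, 0.06), 0.30),
    UP    = qual_spec(c(1160, 22, 34, 56, 21), c(166, 12, 9, 11, 11), 0.15),
    HDLC  = quant_spec(51.1, 10.7, 49.3, 11.8, 0.08),
    LDLC  = quant_spec(105.6, 22.1, 101.5, 24.5, 0.08),
    AST   = quant_spec(27.6, 14.4, 28.7, 15.0, 0.05),
    GGT   = quant_spec(40.7, 36.2, 44.2, 35.5, 0.05),
    Scr   = quant_spec(0.85, 0.35, 0.95, 0.45, 0.88),
    Hct   = quant_spec(38.8, 4.6, 38.4, 5.1, 0.08)
  )
  hosp_outcome <- default_outcome_model()
  hosp_outcome$neg$HbA1c$mean <- 6.2
  hosp_outcome$neg$FPG$mean <- 105
  list(
    checkup = institution_profile(
      name = "checkup", n_samples = 1399,
      visit_model = list(type = "fixed", visits = 1),
      feature_specs = checkup_specs, prevalence = 43 / 1399
    ),
    hospital = institution_profile(
      name = "hospital", n_samples = 1502,
      visit_model = list(type = "poisson", mean_extra = 2),
      feature_specs = hospital_specs, prevalence = 209 / 1502,
      outcome_model = hosp_outcome
    )
  )
}
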