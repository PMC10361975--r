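#' Catalogue of the common checkup features
#'
#' The two institutions share 15 measurements per visit: demographics (Age,
#' Sex), glycaemia markers (HbA1c, FPG, CBG), a blood panel (Hb, RBC, Hct),
#' lipids (HDLC, LDLC), liver enzymes (AST, GGT), kidney function (Scr), and
#' semi-quantitative urinalysis (UG, UP) on the usual (-), (+-), (+), (++),
#' (+++) dipstick scale. Quantitative features carry their clinical units;
#' qualitative features carry an ordered category set.
#'
#' @return A data.frame with one row per feature: `feature`, `kind`
#'   (`"quantitative"` or `"qualitative"`), and `unit`.
#' @export
#' @examples
#' feature_catalogue()
feature_catalogue <- function() {
  data.frame(
    feature = c("Age", "Sex", "HbA1c", "Hb", "FPG", "CBG", "RBC", "UG", "UP",
                "HDLC", "LDLC", "AST", "GGT", "Scr", "Hct"),
    kind = c("quantitative", "qualitative", rep("quantitative", 5),
             "qualitative", "qualitative", rep("quantitative", 6)),
    unit = c("years", "M/F", "%", "g/dl", "mg/dl", "mg/dl", "10^4/mm^3",
             "dipstick", "dipstick", "mg/dl", "mg/dl", "U/l", "U/l",
             "mg/dl", "%"),
    stringsAsFactors = FALSE
  )
}

# Dipstick scale shared by urinary glucose and urinary protein.
dipstick_levels <- function() c("(-)", "(+-)", "(+)", "(++)", "(+++)")

#' Ordered category levels for a qualitative feature
#'
#' Category order defines both the ordinal integer encoding (first level = 0)
#' and the tie-break used when aggregating repeated visits by mode: the
#' earliest level wins a tie, i.e. the most benign dipstick reading and,
#' for Sex, female (encoded 0).
#'
#' @param feature Feature name (`"Sex"`, `"UG"` or `"UP"`).
#' @return Character vector of levels in encoding order.
#' @export
category_levels <- function(feature) {
  switch(feature,
    Sex = c("F", "M"),
    UG = dipstick_levels(),
    UP = dipstick_levels(),
    stop("feature '", feature, "' is not qualitative", call. = FALSE)
  )
}

feature_kind <- function(feature) {
  cat <- feature_catalogue()
  idx <- match(feature, cat$feature)
  if (anyNA(idx)) {
    stop("unknown feature(s): ", paste(feature[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  cat$kind[idx]
}

#' Plausible physiological ranges used as public anchor bounds
#'
#' Per-feature [lo, hi] intervals wide enough to cover both institutions.
#' These are public reference ranges, deliberately independent of any
#' worker's private data, so that uniform anchor generation never leaks
#' sample statistics. Qualitative features are bounded on their ordinal
#' codes (Sex 0..1, dipstick 0..4).
#'
#' @return Named list of length-2 numeric vectors `c(lo, hi)`.
#' @export
default_reference_ranges <- function() {
  list(
    Age = c(40, 80), Sex = c(0, 1), HbA1c = c(4, 12), Hb = c(7, 19),
    FPG = c(60, 300), CBG = c(60, 400), RBC = c(300, 600), UG = c(0, 4),
    UP = c(0, 4), HDLC = c(20, 120), LDLC = c(40, 220), AST = c(5, 120),
    GGT = c(5, 250), Scr = c(0.3, 3), Hct = c(25, 55)
  )
}

id_columns <- function() c("sample_id", "institution", "year", "visit_index")

check_feature_columns <- function(df) {
  cat <- feature_catalogue()
  extra <- setdiff(colnames(df), c(id_columns(), cat$feature))
  if (length(extra)) {
    stop("unknown feature name(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
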