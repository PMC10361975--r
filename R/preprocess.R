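#' Aggregate visit-level records to one row per sample and year
#'
#' A sample may attend several checkups in the same year (hospital-style
#' data). Repeated measurements are collapsed to a yearly value: the mean of
#' the non-missing observations for a quantitative feature, the mode for a
#' qualitative feature (ties broken by the earliest declared category, i.e.
#' the most benign dipstick reading). A yearly cell is missing only when
#' every visit value was missing.
#'
#' @param visits Visit-level data.frame from one institution.
#' @return A yearly table: one row per `(sample_id, year)` with the same
#'   feature columns.
#' @export
aggregate_by_year <- function(visits) {
  check_feature_columns(visits)
  feats <- intersect(feature_catalogue()$feature, colnames(visits))
  if (length(unique(visits$institution)) > 1) {
    stop("aggregate_by_year() expects records from a single institution",
         call. = FALSE)
  }
  key <- paste(visits$sample_id, visits$year, sep = "\r")
  idx <- split(seq_len(nrow(visits)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- data.frame(sample_id = visits$sample_id[first],
                    institution = visits$institution[first],
                    year = visits$year[first], stringsAsFactors = FALSE)
  for (f in feats) {
    col <- visits[[f]]
    if (feature_kind(f) == "quantitative") {
      out[[f]] <- vapply(idx, function(i) {
        v <- col[i][!is.na(col[i])]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    } else {
      lev <- category_levels(f)
      bad <- !is.na(col) & !col %in% lev
      if (any(bad)) {
        stop("unknown category for ", f, ": ",
             paste(unique(col[bad]), collapse = ", "), call. = FALSE)
      }
      out[[f]] <- vapply(idx, function(i) mode_categorical(col[i], lev),
                         character(1))
    }
  }
  out <- out[order(out$sample_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep samples observed in every observation year
#'
#' Retains exactly the samples that have at least one non-missing feature in
#' each year of the observation window, so that two years of predictors
#' exist for every modelled sample.
#'
#' @param table Yearly table from [aggregate_by_year()].
#' @param obs_years Observation window (default 2014 and 2015).
#' @return The yearly table restricted to retained samples (all their rows,
#'   including outcome-window years, are kept).
#' @export
filter_observation_presence <- function(table, obs_years = c(2014, 2015)) {
  if (!length(obs_years)) stop("obs_years must be non-empty", call. = FALSE)
  feats <- intersect(feature_catalogue()$feature, colnames(table))
  has_obs <- function(rows) any(!is.na(unlist(table[rows, feats],
                                              use.names = FALSE)))
  keep <- vapply(split(seq_len(nrow(table)), table$sample_id), function(rows) {
    all(vapply(obs_years, function(y) {
      r <- rows[table$year[rows] == y]
      length(r) > 0 && has_obs(r)
    }, logical(1)))
  }, logical(1))
  retained <- names(keep)[keep]
  out <- table[table$sample_id %in% retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive diabetes onset labels from the outcome window
#'
#' A sample enters the labelled cohort only if HbA1c and FPG were both
#' measured on at least one occasion during the outcome window; it is
#' labelled diabetic (1) when, on at least one such occasion, HbA1c >= 6.5%
#' and FPG >= 126 mg/dl simultaneously, following the Japanese clinical
#' practice guideline thresholds, and non-diabetic (0) otherwise. When
#' visit-level records are supplied, co-occurrence is assessed per visit
#' (the two markers come from the same blood draw); a yearly table is
#' assessed per yearly row.
#'
#' @param records Visit-level data.frame or yearly table containing the
#'   outcome years.
#' @param outcome_years Outcome window (default 2016-2018).
#' @param hba1c_thr,fpg_thr Diagnostic thresholds; must be positive.
#' @return A list with `labels` (named 0/1 integer vector over retained
#'   samples) and `retained` (character vector of retained sample ids).
#' @export
assign_outcome_labels <- function(records, outcome_years = 2016:2018,
                                  hba1c_thr = 6.5, fpg_thr = 126) {
  if (hba1c_thr <= 0 || fpg_thr <= 0) {
    stop("diagnostic thresholds must be positive", call. = FALSE)
  }
  rows <- records$year %in% outcome_years
  sub <- records[rows, , drop = FALSE]
  both <- !is.na(sub$HbA1c) & !is.na(sub$FPG)
  sub <- sub[both, , drop = FALSE]
  retained <- sort(unique(sub$sample_id))
  hit <- sub$HbA1c >= hba1c_thr & sub$FPG >= fpg_thr
  pos <- unique(sub$sample_id[hit])
  labels <- stats::setNames(as.integer(retained %in% pos), retained)
  list(labels = labels, retained = retained)
}

#' Remove features with too many missing values
#'
#' Drops every feature whose fraction of missing cells over the
#' observation-window rows is `max_missing` (default 50%) *or more*. A
#' feature missing in exactly half of the cells is therefore removed.
#'
#' @param table Yearly table restricted to the labelled cohort.
#' @param obs_years Observation window over which missingness is assessed.
#' @param max_missing Removal threshold on the missing fraction.
#' @return The table without the dropped feature columns; the dropped names
#'   are attached as `attr(, "dropped_features")`.
#' @export
drop_sparse_features <- function(table, obs_years = c(2014, 2015),
                                 max_missing = 0.5) {
  feats <- intersect(feature_catalogue()$feature, colnames(table))
  obs <- table[table$year %in% obs_years, , drop = FALSE]
  frac <- vapply(feats, function(f) mean(is.na(obs[[f]])), numeric(1))
  dropped <- feats[frac >= max_missing]
  out <- table[, setdiff(colnames(table), dropped), drop = FALSE]
  attr(out, "dropped_features") <- dropped
  out
}

#' Remove samples with too few observed features
#'
#' A sample is excluded when it carries strictly fewer than `min_fraction`
#' (default half) of the possible feature cells across the observation
#' window, counted over the features that survived [drop_sparse_features()].
#' Missingness is assessed before imputation: afterwards no cell is missing
#' and the filter would be vacuous. A sample with exactly half of its cells
#' observed is retained.
#'
#' @param table Yearly table after feature filtering.
#' @param obs_years Observation window.
#' @param min_fraction Minimum observed fraction required to keep a sample.
#' @return The table restricted to retained samples.
#' @export
drop_sparse_samples <- function(table, obs_years = c(2014, 2015),
                                min_fraction = 0.5) {
  feats <- intersect(feature_catalogue()$feature, colnames(table))
  total <- length(feats) * length(obs_years)
  obs <- table[table$year %in% obs_years, , drop = FALSE]
  present <- vapply(split(seq_len(nrow(obs)), obs$sample_id), function(rows) {
    sum(!is.na(unlist(obs[rows, feats], use.names = FALSE)))
  }, numeric(1))
  keep <- names(present)[present / total >= min_fraction]
  out <- table[table$sample_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Impute remaining missing values by column mean or mode
#'
#' Quantitative gaps are filled with the column mean of the observed values,
#' qualitative gaps with the column mode (ties to the earliest category).
#' Observed values are never changed; the output contains no missing cell.
#'
#' @param table Yearly table after the sparsity filters.
#' @return The imputed table.
#' @export
impute_missing <- function(table) {
  feats <- intersect(feature_catalogue()$feature, colnames(table))
  for (f in feats) {
    col <- table[[f]]
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss)) {
      stop("feature '", f, "' is entirely missing and cannot be imputed",
           call. = FALSE)
    }
    fill <- if (feature_kind(f) == "quantitative") mean(col[!miss])
            else mode_categorical(col, category_levels(f))
    col[miss] <- fill
    table[[f]] <- col
  }
  table
}

#' Encode the cleaned yearly table as a model-ready matrix
#'
#' Each year-varying feature contributes one numeric column per observation
#' year (named `Feature_Year`). Dipstick urinalysis readings are
#' ordinal-coded `(-)`=0, `(+-)`=1, `(+)`=2, `(++)`=3, `(+++)`=4. Sex is a
#' single column (M=1, F=0); Age a single column taken from the first
#' observation year. With the eleven features retained by the default study
#' this yields 9 x 2 + 2 = 20 columns.
#'
#' @param table Imputed yearly table (or a `dc_prep` object from
#'   [preprocess_institution()]).
#' @param labels Named 0/1 vector as returned by [assign_outcome_labels()];
#'   taken from the `dc_prep` object when omitted.
#' @param obs_years Observation window.
#' @param features Optional feature subset to encode (used to restrict both
#'   institutions to their common surviving features); defaults to all
#'   feature columns present.
#' @return A `labeled_dataset`: list with numeric matrix `X` (samples x
#'   encoded features, no missing entries), labels `y`, `feature_names`, and
#'   `institution`.
#' @export
encode_features <- function(table, labels = NULL, obs_years = c(2014, 2015),
                            features = NULL) {
  if (inherits(table, "dc_prep")) {
    labels <- labels %||% table$labels
    features <- features %||% table$features
    obs_years <- table$obs_years %||% obs_years
    table <- table$table
  }
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  feats <- features %||% intersect(feature_catalogue()$feature,
                                   colnames(table))
  missing_cols <- setdiff(feats, colnames(table))
  if (length(missing_cols)) {
    stop("features absent from table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  obs <- table[table$year %in% obs_years, , drop = FALSE]
  samples <- names(labels)[names(labels) %in% unique(obs$sample_id)]

  yearly_feats <- setdiff(feats, c("Age", "Sex"))
  years <- sort(obs_years)
  by_year <- lapply(years, function(y) {
    sub <- obs[obs$year == y, , drop = FALSE]
    idx <- match(samples, sub$sample_id)
    if (anyNA(idx)) {
      stop("sample ", samples[which(is.na(idx))[1]],
           " lacks a row for observation year ", y, call. = FALSE)
    }
    sub[idx, , drop = FALSE]
  })
  names(by_year) <- as.character(years)

  col_of <- function(f, y) {
    v <- by_year[[as.character(y)]][[f]]
    if (anyNA(v)) {
      stop("missing value for ", f, " in ", y, " (impute first)",
           call. = FALSE)
    }
    if (feature_kind(f) == "quantitative") return(as.numeric(v))
    code <- match(v, category_levels(f)) - 1
    if (anyNA(code)) {
      stop("unknown category '", v[which(is.na(code))[1]], "' for ", f,
           call. = FALSE)
    }
    as.numeric(code)
  }

  cols <- character(0)
  mat <- list()
  for (f in yearly_feats) {
    for (y in years) {
      cols <- c(cols, paste0(f, "_", y))
      mat[[length(mat) + 1]] <- col_of(f, y)
    }
  }
  if ("Sex" %in% feats) {
    sex_by_year <- vapply(years, function(y) col_of("Sex", y),
                          numeric(length(samples)))
    sex_by_year <- matrix(sex_by_year, nrow = length(samples))
    # Mode across observation years; a disagreement ties to the earliest
    # level (lowest code), matching the aggregation tie-break.
    sex <- apply(sex_by_year, 1, function(v) {
      tab <- table(v)
      as.numeric(names(tab)[which.max(tab)])
    })
    cols <- c(cols, "Sex")
    mat[[length(mat) + 1]] <- sex
  }
  if ("Age" %in% feats) {
    cols <- c(cols, "Age")
    mat[[length(mat) + 1]] <- col_of("Age", min(obs_years))
  }
  X <- do.call(cbind, mat)
  dimnames(X) <- list(samples, cols)
  ds <- structure(
    list(X = X, y = labels[samples], feature_names = cols,
         institution = unique(table$institution)[1]),
    class = "labeled_dataset"
  )
  validate_labeled_dataset(ds)
  ds
}

encode_category <- function(feature, value) {
  lev <- category_levels(feature)
  code <- match(value, lev) - 1
  if (is.na(code)) {
    stop("unknown category '", value, "' for ", feature, call. = FALSE)
  }
  as.numeric(code)
}

validate_labeled_dataset <- function(ds) {
  stopifnot(is.matrix(ds$X), !anyNA(ds$X),
            all(ds$y %in% c(0L, 1L)),
            ncol(ds$X) == length(ds$feature_names),
            nrow(ds$X) == length(ds$y))
  invisible(ds)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", x$institution %||% "?", ": ",
      nrow(x$X), " samples x ", ncol(x$X), " encoded features, ",
      sum(x$y == 1), " positive\n", sep = "")
  invisible(x)
}

#' Run the full cleaning pipeline for one institution
#'
#' Applies, in order: per-year aggregation, the observation-window presence
#' filter, outcome labelling (on visit-level co-occurrence), the 50% sparse
#' feature filter, the pre-imputation sparse sample filter, and mean/mode
#' imputation. Encoding is left as a separate step so that two institutions
#' can first be restricted to their common surviving features (the
#' collaboration requires a shared input dimension).
#'
#' @param visits Visit-level data.frame for one institution.
#' @param obs_years,outcome_years Observation and outcome windows.
#' @param hba1c_thr,fpg_thr Diagnostic thresholds for the label.
#' @param max_feature_missing,min_sample_fraction Sparsity-filter thresholds.
#' @return A `dc_prep` object: cleaned observation-window table, `labels`,
#'   surviving `features`, `dropped_features`, the institution name, and a
#'   `log` data.frame of per-stage sample/feature counts.
#' @seealso [encode_features()], [prepare_datasets()]
#' @export
preprocess_institution <- function(visits, obs_years = c(2014, 2015),
                                   outcome_years = 2016:2018,
                                   hba1c_thr = 6.5, fpg_thr = 126,
                                   max_feature_missing = 0.5,
                                   min_sample_fraction = 0.5) {
  log <- list()
  note <- function(stage, unit, before, after) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, unit = unit,
                                          before = before, after = after,
                                          stringsAsFactors = FALSE)
  }
  yearly <- aggregate_by_year(visits)
  n0 <- length(unique(yearly$sample_id))
  note("aggregate_by_year", "samples", length(unique(visits$sample_id)), n0)

  yearly <- filter_observation_presence(yearly, obs_years)
  n1 <- length(unique(yearly$sample_id))
  note("filter_observation_presence", "samples", n0, n1)

  lab <- assign_outcome_labels(
    visits[visits$sample_id %in% unique(yearly$sample_id), , drop = FALSE],
    outcome_years, hba1c_thr, fpg_thr
  )
  note("assign_outcome_labels", "samples", n1, length(lab$retained))

  obs_tab <- yearly[yearly$sample_id %in% lab$retained &
                      yearly$year %in% obs_years, , drop = FALSE]
  f0 <- length(intersect(feature_catalogue()$feature, colnames(obs_tab)))
  obs_tab <- drop_sparse_features(obs_tab, obs_years, max_feature_missing)
  dropped <- attr(obs_tab, "dropped_features")
  note("drop_sparse_features", "features", f0, f0 - length(dropped))

  n2 <- length(unique(obs_tab$sample_id))
  obs_tab <- drop_sparse_samples(obs_tab, obs_years, min_sample_fraction)
  n3 <- length(unique(obs_tab$sample_id))
  note("drop_sparse_samples", "samples", n2, n3)

  obs_tab <- impute_missing(obs_tab)
  features <- intersect(feature_catalogue()$feature, colnames(obs_tab))
  keep <- unique(obs_tab$sample_id)
  structure(
    list(table = obs_tab, labels = lab$labels[names(lab$labels) %in% keep],
         features = features, dropped_features = dropped,
         obs_years = obs_years, institution = unique(visits$institution)[1],
         log = do.call(rbind, log)),
    class = "dc_prep"
  )
}

#' @export
print.dc_prep <- function(x, ...) {
  cat("<dc_prep> ", x$institution, ": ", length(x$labels), " samples, ",
      length(x$features), " surviving features (dropped: ",
      paste(x$dropped_features, collapse = ", "), ")\n", sep = "")
  print(x$log, row.names = FALSE)
  invisible(x)
}

#' Preprocess two institutions onto their common feature set
#'
#' Cleans each institution independently, intersects the features that
#' survive the sparsity filter in both (the collaboration needs a common
#' input dimension), and encodes both on that common set.
#'
#' @param checkup_visits,hospital_visits Visit-level data.frames.
#' @param ... Passed to [preprocess_institution()].
#' @return A list with `checkup` and `hospital` (`labeled_dataset`s sharing
#'   `feature_names`), `features` (the common base features), and `logs`.
#' @export
prepare_datasets <- function(checkup_visits, hospital_visits, ...) {
  p1 <- preprocess_institution(checkup_visits, ...)
  p2 <- preprocess_institution(hospital_visits, ...)
  common <- intersect(p1$features, p2$features)
  if (length(common) < 3) {
    stop("fewer than 3 common surviving features; check the inputs",
         call. = FALSE)
  }
  d1 <- encode_features(p1, features = common)
  d2 <- encode_features(p2, features = common)
  stopifnot(identical(d1$feature_names, d2$feature_names))
  list(checkup = d1, hospital = d2, features = common,
       logs = list(checkup = p1$log, hospital = p2$log),
       preps = list(checkup = p1, hospital = p2))
}
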