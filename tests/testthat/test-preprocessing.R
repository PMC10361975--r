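make_visits <- function(...) {
  rows <- list(...)
  base <- data.frame(sample_id = character(0), institution = character(0),
                     year = integer(0), visit_index = integer(0),
                     stringsAsFactors = FALSE)
  out <- NULL
  for (r in rows) out <- merge(out, r, all = TRUE, sort = FALSE) %||% r
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

visit <- function(id, year, vi = 1, ...) {
  row <- data.frame(sample_id = id, institution = "clinic", year = year,
                    visit_index = vi, stringsAsFactors = FALSE)
  vals <- list(...)
  for (f in names(vals)) row[[f]] <- vals[[f]]
  row
}

bind_visits <- function(...) {
  rows <- list(...)
  cols <- unique(unlist(lapply(rows, colnames)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, colnames(r))) r[[cc]] <- NA
    r[, cols]
  })
  do.call(rbind, rows)
}

test_that("yearly aggregation takes means, modes, and the benign tie-break", {
  v <- bind_visits(
    visit("A", 2014, 1, FPG = 100, UP = "(-)"),
    visit("A", 2014, 2, FPG = 110, UP = "(-)"),
    visit("A", 2014, 3, FPG = 120, UP = "(+)"),
    visit("B", 2014, 1, FPG = NA, UP = "(-)"),
    visit("B", 2014, 2, FPG = 90, UP = "(+)")
  )
  agg <- aggregate_by_year(v)
  a <- agg[agg$sample_id == "A", ]
  expect_equal(a$FPG, 110)              # mean of three visits
  expect_equal(a$UP, "(-)")             # unique mode
  b <- agg[agg$sample_id == "B", ]
  expect_equal(b$FPG, 90)               # missing visit ignored
  expect_equal(b$UP, "(-)")             # tie broken to the benign category

  # all-missing year stays missing; unknown features are rejected
  v2 <- bind_visits(visit("C", 2014, 1, FPG = NA), visit("C", 2014, 2, FPG = NA))
  expect_true(is.na(aggregate_by_year(v2)$FPG))
  v3 <- visit("D", 2014, 1, FPG = 100)
  v3$NotAFeature <- 1
  expect_error(aggregate_by_year(v3), "unknown feature")
  expect_error(aggregate_by_year(bind_visits(
    visit("E", 2014, 1, UP = "(?)"))), "unknown category")
})

test_that("observation-window filter keeps samples seen in every window year", {
  tab <- bind_visits(
    yearly_row("A", 2014, HbA1c = 5.5), yearly_row("A", 2015, HbA1c = 5.6),
    yearly_row("B", 2014, HbA1c = 5.7),                       # no 2015
    yearly_row("C", 2014, HbA1c = NA), yearly_row("C", 2015, HbA1c = 5.8),
    yearly_row("D", 2016, HbA1c = 6.0)                        # outside window
  )
  kept <- filter_observation_presence(tab, c(2014, 2015))
  expect_setequal(unique(kept$sample_id), "A")
  expect_error(filter_observation_presence(tab, integer(0)), "non-empty")
  empty <- tab[0, ]
  expect_equal(nrow(filter_observation_presence(empty)), 0)
})

test_that("outcome labelling requires marker co-occurrence and applies the
           diagnostic thresholds inclusively", {
  v <- bind_visits(
    visit("pos_exact", 2017, 1, HbA1c = 6.5, FPG = 126),
    visit("neg_below", 2016, 1, HbA1c = 6.4, FPG = 125),
    visit("neg_below", 2017, 1, HbA1c = 6.4, FPG = 125),
    visit("split_visits", 2016, 1, HbA1c = 7.0, FPG = 100),
    visit("split_visits", 2016, 2, HbA1c = 6.0, FPG = 160),
    visit("no_fpg", 2016, 1, HbA1c = 7.5, FPG = NA),
    visit("one_marker_each_year", 2016, 1, HbA1c = 7.0, FPG = NA),
    visit("one_marker_each_year", 2017, 1, HbA1c = NA, FPG = 170)
  )
  lab <- assign_outcome_labels(v)
  expect_setequal(lab$retained, c("pos_exact", "neg_below", "split_visits"))
  expect_equal(unname(lab$labels["pos_exact"]), 1L)
  expect_equal(unname(lab$labels["neg_below"]), 0L)
  # visit-level co-occurrence: the two threshold crossings never coincide
  expect_equal(unname(lab$labels["split_visits"]), 0L)

  # yearly aggregation merges the two visits, flipping the same sample
  agg <- aggregate_by_year(v)
  lab_y <- assign_outcome_labels(agg)
  expect_equal(unname(lab_y$labels["split_visits"]), 1L)

  expect_error(assign_outcome_labels(v, hba1c_thr = 0), "positive")
})

test_that("sparse-feature filter removes at exactly 50% missing", {
  mk <- function(n_missing, n = 10) {
    rows <- lapply(seq_len(n), function(i) {
      yearly_row(sprintf("S%02d", i), 2014,
                 HbA1c = if (i <= n_missing) NA else 5.5,
                 Hb = 13)
    })
    do.call(bind_visits, rows)
  }
  out <- drop_sparse_features(mk(5), obs_years = 2014)    # 50% exactly
  expect_false("HbA1c" %in% colnames(out))
  expect_equal(attr(out, "dropped_features"), "HbA1c")
  out <- drop_sparse_features(mk(0), obs_years = 2014)
  expect_true("HbA1c" %in% colnames(out))
  big <- mk(49, n = 100)                                  # 49% missing
  expect_true("HbA1c" %in% colnames(drop_sparse_features(big,
                                                         obs_years = 2014)))
})

test_that("sparse-sample filter excludes below half, keeps exactly half", {
  rows <- list()
  # 5 features x 2 years = 10 cells per sample
  mk_sample <- function(id, present) {
    vals <- function(j) {
      setNames(lapply(1:5, function(i) {
        if ((j - 1) * 5 + i <= present) 1 else NA
      }), c("HbA1c", "Hb", "RBC", "AST", "GGT"))
    }
    bind_visits(do.call(yearly_row, c(list(id, 2014), vals(1))),
                do.call(yearly_row, c(list(id, 2015), vals(2))))
  }
  tab <- bind_visits(mk_sample("four", 4), mk_sample("five", 5),
                     mk_sample("ten", 10))
  out <- drop_sparse_samples(tab, c(2014, 2015))
  expect_setequal(unique(out$sample_id), c("five", "ten"))
})

test_that("imputation fills mean/mode, never touches observed values", {
  tab <- bind_visits(
    yearly_row("A", 2014, HbA1c = 1, UP = "(-)"),
    yearly_row("B", 2014, HbA1c = 3, UP = "(-)"),
    yearly_row("C", 2014, HbA1c = NA, UP = "(+)"),
    yearly_row("D", 2014, HbA1c = 2, UP = NA)
  )
  out <- impute_missing(tab)
  expect_equal(out$HbA1c, c(1, 3, 2, 2))
  expect_equal(out$UP, c("(-)", "(-)", "(+)", "(-)"))
  expect_false(anyNA(out[, c("HbA1c", "UP")]))
  # identity on a complete column
  expect_equal(impute_missing(out), out)
  # an entirely missing column cannot be imputed
  tab$Hb <- NA_real_
  expect_error(impute_missing(tab), "entirely missing")
})

test_that("encoding uses the ordinal dipstick scale and single Sex/Age
           columns", {
  tab <- bind_visits(
    yearly_row("A", 2014, Age = 60, Sex = "M", HbA1c = 5.5, UP = "(++)"),
    yearly_row("A", 2015, Age = 61, Sex = "M", HbA1c = 5.7, UP = "(+++)"),
    yearly_row("B", 2014, Age = 50, Sex = "F", HbA1c = 6.0, UP = "(-)"),
    yearly_row("B", 2015, Age = 51, Sex = "F", HbA1c = 6.1, UP = "(+-)")
  )
  labels <- c(A = 0L, B = 1L)
  ds <- encode_features(tab, labels)
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(sort(ds$feature_names),
               sort(c("HbA1c_2014", "HbA1c_2015", "UP_2014", "UP_2015",
                      "Sex", "Age")))
  expect_equal(ds$X["A", "UP_2014"], 3)       # (++) -> 3
  expect_equal(ds$X["A", "UP_2015"], 4)       # (+++) -> 4
  expect_equal(ds$X["B", "UP_2015"], 1)       # (+-) -> 1
  expect_equal(unname(ds$X[, "Sex"]), c(1, 0))  # M=1, F=0
  expect_equal(unname(ds$X[, "Age"]), c(60, 50))  # first observation year
  expect_equal(unname(ds$y), c(0L, 1L))

  tab$UP[1] <- "(??)"
  expect_error(encode_features(tab, labels), "unknown category")
})

test_that("full pipeline recovers generating labels and is idempotent on
           its own output", {
  profs <- small_profiles(n_checkup = 400, prev_checkup = 0.2)
  v <- generate_institution(profs$checkup, seed = 31)
  prep <- preprocess_institution(v)
  cls <- attr(v, "outcome_class")
  agree <- mean(prep$labels == cls[names(prep$labels)])
  expect_gte(agree, 0.99)
  # the checkup missingness pattern always removes FPG and urinary glucose
  expect_setequal(prep$dropped_features, c("FPG", "UG"))
  # filters are idempotent: re-running them on cleaned output changes nothing
  tab <- prep$table
  expect_equal(drop_sparse_features(tab), tab, ignore_attr = TRUE)
  expect_equal(drop_sparse_samples(tab), tab)
  expect_equal(impute_missing(tab), tab)
  # the per-stage log tracks every filter
  expect_setequal(prep$log$stage,
                  c("aggregate_by_year", "filter_observation_presence",
                    "assign_outcome_labels", "drop_sparse_features",
                    "drop_sparse_samples"))
  ds <- encode_features(prep)
  expect_false(anyNA(ds$X))
  expect_equal(nrow(ds$X), length(prep$labels))
})
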