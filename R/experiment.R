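subset_fractions <- c(all = 1, half = 0.5, quarter = 0.25)

#' Configuration for one bootstrap experiment cell
#'
#' @param mode Analysis mode: `"individual"` (raw single-institution data),
#'   `"middle"` (the institution's own intermediate representation alone —
#'   isolating the cost of the confidentiality transform), or `"dc"`
#'   (collaborative representation pooling both institutions).
#' @param subset Fraction of the training pool used: `"all"`, `"half"`, or
#'   `"quarter"` (nested random subsets, emulating ever smaller
#'   municipalities).
#' @param model `"lr_l1"` or `"gbdt"` (see [model_spec()]).
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param test_size Held-out test samples per replicate, always drawn from
#'   the checkup institution (default 99).
#' @param seed Master seed; every random draw in the experiment derives
#'   from it.
#' @param lr_C Inverse regularisation strength for `lr_l1`.
#' @param dc List of collaboration settings: `method`, `l`, `k`, `r`,
#'   `anchor_strategy`, `ranges` (see [generate_anchor()]).
#' @param bootstrap `"test_split"` (default: re-draw the held-out test set
#'   per replicate, remainder = training pool) or `"train_resample"`
#'   (additionally resample the training pool with replacement).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(mode = c("individual", "middle", "dc"),
                              subset = c("all", "half", "quarter"),
                              model = c("lr_l1", "gbdt"),
                              n_replicates = 100, test_size = 99, seed = 1,
                              lr_C = 1, dc = list(),
                              bootstrap = c("test_split", "train_resample")) {
  mode <- match.arg(mode)
  subset <- match.arg(subset)
  model <- if (is.list(model)) model else match.arg(model)
  stopifnot(n_replicates >= 1, test_size >= 2)
  dc_defaults <- list(method = "pca", l = NULL, k = NULL, r = 1000,
                      anchor_strategy = "uniform", ranges = NULL,
                      scale = TRUE)
  dc <- utils::modifyList(dc_defaults, dc)
  structure(list(mode = mode, subset = subset, model = model,
                 n_replicates = as.integer(n_replicates),
                 test_size = as.integer(test_size), seed = seed,
                 lr_C = lr_C, dc = dc,
                 bootstrap = match.arg(bootstrap)),
            class = "experiment_config")
}

#' Bootstrap evaluation over the full mode x subset x model grid
#'
#' Per replicate, `test_size` test samples are drawn at random from the
#' checkup institution; the remaining samples form the training pool, and
#' the "half"/"quarter" subsets are nested random fractions of that pool
#' (the same permutation, so quarter is contained in half). The same test
#' split and pool are reused for every mode, subset and model within a
#' replicate, so comparisons across cells are paired. Mode `"dc"` always
#' adds the full hospital dataset through the collaboration; its test
#' samples are transformed with the checkup worker's maps. A replicate
#' whose test set or any requested training subset contains a single class
#' is redrawn (counted in `attr(, "resampled")`).
#'
#' @param checkup,hospital `labeled_dataset`s sharing `feature_names`.
#' @param modes,subsets,models Character vectors over the grid axes.
#' @param n_replicates,test_size,seed,lr_C,dc,bootstrap See
#'   [experiment_config()].
#' @return List with `results` (tidy data.frame: mode, subset, model,
#'   metric, replicate, value) and `summary` (mean and SD per cell and
#'   metric). Deterministic given `seed`.
#' @export
run_experiment_grid <- function(checkup, hospital = NULL,
                                modes = c("individual", "middle", "dc"),
                                subsets = c("all", "half", "quarter"),
                                models = c("lr_l1", "gbdt"),
                                n_replicates = 100, test_size = 99, seed = 1,
                                lr_C = 1, dc = list(),
                                bootstrap = "test_split") {
  stopifnot(all(modes %in% c("individual", "middle", "dc")),
            all(subsets %in% names(subset_fractions)))
  if ("dc" %in% modes && is.null(hospital)) {
    stop("dc mode needs the hospital dataset", call. = FALSE)
  }
  if (!is.null(hospital) &&
      !identical(checkup$feature_names, hospital$feature_names)) {
    stop("institutions must share the encoded feature set ",
         "(use prepare_datasets())", call. = FALSE)
  }
  m <- nrow(checkup$X)
  if (test_size >= m) {
    stop("test_size (", test_size, ") must be smaller than the checkup ",
         "sample count (", m, ")", call. = FALSE)
  }
  dc_defaults <- list(method = "pca", l = NULL, k = NULL, r = 1000,
                      anchor_strategy = "uniform", ranges = NULL,
                      scale = TRUE)
  dc <- utils::modifyList(dc_defaults, dc)
  d <- ncol(checkup$X)
  l_c <- dc$l %||% default_intermediate_dim(d)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  seeds <- derive_seeds(seed, n_replicates + 1L)
  anchor_seed <- seeds[n_replicates + 1L]

  needs_maps <- any(c("middle", "dc") %in% modes)
  anchor <- NULL
  hosp <- NULL
  if ("dc" %in% modes) {
    bounds <- anchor_bounds(checkup$feature_names,
                            dc$ranges %||% default_reference_ranges())
    anchor <- generate_anchor(bounds, r = dc$r,
                              strategy = dc$anchor_strategy,
                              seed = anchor_seed)
    l_h <- dc$l %||% default_intermediate_dim(d)
    f_h <- fit_intermediate_map(hospital$X, dc$method, l_h,
                                scale. = isTRUE(dc$scale),
                                fitted_on = hospital$institution)
    hosp <- list(f = f_h,
                 Xt = apply_map(f_h, hospital$X),
                 At = apply_map(f_h, anchor),
                 y = hospital$y)
  }

  records <- vector("list", 0)
  resampled <- 0L
  for (rep_i in seq_len(n_replicates)) {
    set.seed(seeds[rep_i])
    split <- draw_split(checkup$y, m, test_size, subsets, bootstrap)
    resampled <- resampled + split$retries
    test_idx <- split$test_idx
    pool <- split$pool
    Xte_raw <- checkup$X[test_idx, , drop = FALSE]
    yte <- checkup$y[test_idx]

    for (sub in subsets) {
      n_sub <- max(2L, floor(length(pool) * subset_fractions[[sub]]))
      idx <- pool[seq_len(n_sub)]
      Xtr_raw <- checkup$X[idx, , drop = FALSE]
      ytr <- checkup$y[idx]

      reps <- list(individual = list(Xtr = Xtr_raw, ytr = ytr, Xte = Xte_raw))
      if (needs_maps) {
        f1 <- fit_intermediate_map(Xtr_raw, dc$method, l_c,
                                   scale. = isTRUE(dc$scale),
                                   fitted_on = checkup$institution)
        if ("middle" %in% modes) {
          reps$middle <- list(Xtr = apply_map(f1, Xtr_raw), ytr = ytr,
                              Xte = apply_map(f1, Xte_raw))
        }
        if ("dc" %in% modes) {
          At1 <- apply_map(f1, anchor)
          g <- compute_collaboration_maps(list(At1, hosp$At), dc$k)
          G1 <- g$maps[[1]]; G2 <- g$maps[[2]]
          reps$dc <- list(
            Xtr = rbind(apply_map(f1, Xtr_raw) %*% G1, hosp$Xt %*% G2),
            ytr = c(ytr, hosp$y),
            Xte = apply_map(f1, Xte_raw) %*% G1
          )
        }
      }

      for (mode in modes) {
        rp <- reps[[mode]]
        for (mod in models) {
          spec <- if (is.list(mod)) model_spec(mod, seed = seeds[rep_i])
                  else model_spec(mod, C = lr_C, seed = seeds[rep_i])
          fit <- train_model(list(X = rp$Xtr, y = rp$ytr), spec)
          met <- evaluate(predict_scores(fit, rp$Xte), yte)
          records[[length(records) + 1]] <- data.frame(
            mode = mode, subset = sub,
            model = if (is.list(mod)) "custom" else mod,
            metric = names(met), replicate = rep_i, value = unname(met),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  results <- do.call(rbind, records)
  results <- results[order(results$mode, results$subset, results$model,
                           results$metric, results$replicate), ]
  rownames(results) <- NULL
  summary <- summarize_results(results)
  out <- list(results = results, summary = summary,
              config = list(modes = modes, subsets = subsets,
                            models = models, n_replicates = n_replicates,
                            test_size = test_size, seed = seed, lr_C = lr_C,
                            dc = dc, bootstrap = bootstrap))
  attr(out, "resampled") <- resampled
  out
}

# One replicate's test/pool split; redraws until the test set contains both
# classes and every requested nested subset has at least two samples per
# class (the minimum the penalised logistic fit accepts).
draw_split <- function(y, m, test_size, subsets, bootstrap) {
  fracs <- subset_fractions[subsets]
  for (try in 0:99) {
    test_idx <- sample.int(m, test_size)
    pool <- setdiff(seq_len(m), test_idx)
    pool <- pool[sample.int(length(pool))]
    if (identical(bootstrap, "train_resample")) {
      pool <- pool[sample.int(length(pool), replace = TRUE)]
    }
    ok <- length(unique(y[test_idx])) == 2 &&
      all(vapply(fracs, function(fr) {
        idx <- pool[seq_len(max(2L, floor(length(pool) * fr)))]
        min(table(factor(y[idx], levels = c(0, 1)))) >= 2
      }, logical(1)))
    if (ok) return(list(test_idx = test_idx, pool = pool, retries = try))
  }
  stop("could not draw a split with both classes in every subset; ",
       "the cohort is too small or too imbalanced", call. = FALSE)
}

# SD of a single replicate is reported as 0 (no spread observed), not NA.
sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)

summarize_results <- function(results) {
  agg <- stats::aggregate(value ~ mode + subset + model + metric,
                          data = results,
                          FUN = function(v) c(mean = mean(v), sd = sd0(v)))
  out <- data.frame(agg[, c("mode", "subset", "model", "metric")],
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$mode, out$subset, out$model, out$metric), ]
  rownames(out) <- NULL
  out
}

#' Bootstrap evaluation of a single experiment cell
#'
#' Convenience wrapper around [run_experiment_grid()] for one
#' (mode, subset, model) cell.
#'
#' @param checkup,hospital `labeled_dataset`s sharing `feature_names`
#'   (`hospital` may be `NULL` unless `cfg$mode == "dc"`).
#' @param cfg An [experiment_config()].
#' @return A `metrics_summary`: replicate-wise metric values with their
#'   means and standard deviations.
#' @export
bootstrap_experiment <- function(checkup, hospital = NULL,
                                 cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  grid <- run_experiment_grid(
    checkup, hospital, modes = cfg$mode, subsets = cfg$subset,
    models = if (is.list(cfg$model)) list(cfg$model) else cfg$model,
    n_replicates = cfg$n_replicates, test_size = cfg$test_size,
    seed = cfg$seed, lr_C = cfg$lr_C, dc = cfg$dc, bootstrap = cfg$bootstrap
  )
  res <- grid$results
  wide <- stats::reshape(res[, c("metric", "replicate", "value")],
                         idvar = "replicate", timevar = "metric",
                         direction = "wide")
  colnames(wide) <- sub("^value\\.", "", colnames(wide))
  wide <- wide[order(wide$replicate), c("replicate", "auc", "recall",
                                        "precision", "f1")]
  rownames(wide) <- NULL
  structure(
    list(replicates = wide,
         mean = colMeans(wide[, -1]),
         sd = vapply(wide[, -1], sd0, numeric(1)),
         config = cfg),
    class = "metrics_summary"
  )
}

#' @export
print.metrics_summary <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat("<metrics_summary> ", cfg$mode, " / ", cfg$subset, " / ",
      if (is.list(cfg$model)) "custom" else cfg$model, ", ",
      nrow(x$replicates), " replicates\n", sep = "")
  for (mtr in names(x$mean)) {
    cat(sprintf("  %-9s %0.*f +/- %0.*f\n", mtr, digits, x$mean[[mtr]],
                digits, x$sd[[mtr]]))
  }
  invisible(x)
}

#' Improvement of the collaboration over its baselines
#'
#' For each model, subset and metric, tabulates the gain of dc-mode over
#' the individual (raw data) analysis and over the middle-representation
#' analysis: the absolute difference in bootstrap means and the percentage
#' change relative to the baseline mean. Positive values mean the
#' collaboration helped.
#'
#' @param summary The `summary` data.frame from [run_experiment_grid()]
#'   (must contain the `individual`, `middle` and `dc` rows for every
#'   subset/model/metric combination present).
#' @return Data.frame with columns `model`, `metric`, `subset`, `baseline`,
#'   `delta`, `pct`.
#' @export
improvement_table <- function(summary) {
  need <- c("individual", "middle", "dc")
  cells <- unique(summary[, c("subset", "model", "metric")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    sub <- summary[summary$subset == cl$subset & summary$model == cl$model &
                     summary$metric == cl$metric, ]
    means <- stats::setNames(sub$mean, sub$mode)
    if (!all(need %in% names(means))) {
      stop("missing mode(s) ", paste(setdiff(need, names(means)),
                                     collapse = ", "),
           " for ", cl$model, "/", cl$subset, "/", cl$metric, call. = FALSE)
    }
    for (base in c("individual", "middle")) {
      delta <- means[["dc"]] - means[[base]]
      rows[[length(rows) + 1]] <- data.frame(
        model = cl$model, metric = cl$metric, subset = cl$subset,
        baseline = base, delta = delta,
        pct = 100 * delta / means[[base]], stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$model, out$metric, out$baseline,
                   match(out$subset, c("quarter", "half", "all"))), ]
  rownames(out) <- NULL
  out
}
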