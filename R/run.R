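#' Default run configuration
#'
#' One nested list drives a full study run: data source (simulate, or paths
#' to visit-level CSVs), preprocessing thresholds, collaboration settings,
#' the experiment grid, and a single master seed from which every stage's
#' randomness is derived.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    data = list(source = "simulate", checkup_csv = NULL, hospital_csv = NULL),
    profiles = list(checkup = list(), hospital = list()),
    preprocessing = list(obs_years = c(2014, 2015),
                         outcome_years = 2016:2018,
                         hba1c_threshold = 6.5, fpg_threshold = 126,
                         max_feature_missing = 0.5,
                         min_sample_fraction = 0.5),
    dc = list(method = "pca", l = NULL, k = NULL, r = 1000,
              anchor_strategy = "uniform"),
    experiments = list(modes = c("individual", "middle", "dc"),
                       subsets = c("all", "half", "quarter"),
                       models = c("lr_l1", "gbdt"),
                       n_replicates = 100, test_size = 99, lr_C = 1,
                       bootstrap = "test_split")
  )
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path Path to a YAML file.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

build_profiles <- function(config) {
  profs <- default_profiles()
  for (inst in c("checkup", "hospital")) {
    ov <- config$profiles[[inst]] %||% list()
    for (nm in names(ov)) profs[[inst]][[nm]] <- ov[[nm]]
  }
  profs
}

#' Simulate the two-institution cohort and write visit-level CSVs
#'
#' Institution seeds derive deterministically from the master seed, so a
#' repeated run reproduces the files byte for byte. A JSON manifest with
#' the resolved configuration and derived seeds is written alongside.
#'
#' @param config Configuration list (see [default_config()]).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths of the two CSVs and the manifest.
#' @export
cmd_simulate <- function(config = default_config(), outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  profs <- build_profiles(config)
  seeds <- derive_seeds(config$seed, 2)
  paths <- list()
  for (i in seq_along(profs)) {
    inst <- names(profs)[i]
    visits <- generate_institution(profs[[inst]], seed = seeds[i])
    paths[[inst]] <- file.path(outdir, paste0(inst, ".csv"))
    write_visit_csv(visits, paths[[inst]])
  }
  manifest <- list(stage = "simulate", seed = config$seed,
                   institution_seeds = as.list(stats::setNames(seeds,
                                                               names(profs))),
                   n_samples = lapply(profs, `[[`, "n_samples"))
  paths$manifest <- file.path(outdir, "simulate_manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full study: preprocess, collaborate, evaluate, report
#'
#' Loads (or simulates) the two institutions' visit records, runs the
#' cleaning pipeline with one log line per filter recording the
#' before/after sample or feature counts, restricts both institutions to
#' their common surviving features, executes the requested experiment grid,
#' and writes tidy results, a summary, the improvement table, a run log,
#' and a reproducibility manifest.
#'
#' @param config Configuration list (see [default_config()]).
#' @param outdir Output directory.
#' @param quiet Suppress progress messages (the log file is written either
#'   way).
#' @return Invisibly, a list with the grid output, preparation objects, and
#'   output paths.
#' @export
cmd_run <- function(config = default_config(), outdir = ".", quiet = FALSE) {
  ex <- config$experiments
  # Fail fast, before any simulation or model fitting.
  if (identical(config$data$source, "simulate")) {
    n_chk <- build_profiles(config)$checkup$n_samples
    if (ex$test_size >= n_chk) {
      stop("test_size (", ex$test_size, ") must be below the checkup ",
           "cohort size (", n_chk, ")", call. = FALSE)
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  if (identical(config$data$source, "simulate")) {
    say("simulating cohorts (seed ", config$seed, ")")
    sim_paths <- cmd_simulate(config, outdir)
    checkup_visits <- read_visit_csv(sim_paths$checkup)
    hospital_visits <- read_visit_csv(sim_paths$hospital)
  } else {
    checkup_visits <- read_visit_csv(config$data$checkup_csv)
    hospital_visits <- read_visit_csv(config$data$hospital_csv)
  }

  pp <- config$preprocessing
  prep <- prepare_datasets(
    checkup_visits, hospital_visits,
    obs_years = pp$obs_years, outcome_years = pp$outcome_years,
    hba1c_thr = pp$hba1c_threshold, fpg_thr = pp$fpg_threshold,
    max_feature_missing = pp$max_feature_missing,
    min_sample_fraction = pp$min_sample_fraction
  )
  for (inst in names(prep$logs)) {
    lg <- prep$logs[[inst]]
    for (i in seq_len(nrow(lg))) {
      say(inst, ": ", lg$stage[i], " ", lg$unit[i], " ",
          lg$before[i], " -> ", lg$after[i])
    }
  }
  say("common features (", length(prep$features), "): ",
      paste(prep$features, collapse = ", "))
  if (ex$test_size >= nrow(prep$checkup$X)) {
    stop("test_size (", ex$test_size, ") must be below the retained ",
         "checkup sample count (", nrow(prep$checkup$X), ")", call. = FALSE)
  }

  say("running grid: ", length(ex$modes), " modes x ", length(ex$subsets),
      " subsets x ", length(ex$models), " models, ", ex$n_replicates,
      " replicates")
  grid <- run_experiment_grid(
    prep$checkup, prep$hospital, modes = ex$modes, subsets = ex$subsets,
    models = ex$models, n_replicates = ex$n_replicates,
    test_size = ex$test_size, seed = config$seed, lr_C = ex$lr_C,
    dc = config$dc, bootstrap = ex$bootstrap %||% "test_split"
  )
  if (attr(grid, "resampled") > 0) {
    say("note: ", attr(grid, "resampled"),
        " replicate draw(s) redrawn for single-class splits")
  }

  paths <- list(
    results = file.path(outdir, "results.csv"),
    summary = file.path(outdir, "summary.csv"),
    improvements = file.path(outdir, "improvements.csv"),
    log = file.path(outdir, "run.log"),
    manifest = file.path(outdir, "run_manifest.json")
  )
  utils::write.csv(grid$results, paths$results, row.names = FALSE)
  utils::write.csv(grid$summary, paths$summary, row.names = FALSE)
  if (all(c("individual", "middle", "dc") %in% ex$modes)) {
    utils::write.csv(improvement_table(grid$summary), paths$improvements,
                     row.names = FALSE)
  }
  manifest <- list(
    stage = "run", seed = config$seed, config = config,
    config_hash = config_hash(config),
    counts = list(checkup = nrow(prep$checkup$X),
                  hospital = nrow(prep$hospital$X)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("dcollab"))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, paths$log)
  invisible(list(grid = grid, prep = prep, paths = paths,
                 log = log_lines))
}

# Stable fingerprint of the resolved configuration (order-independent
# within each level); enough to detect configuration drift between runs.
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  json <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  # Tiny polynomial rolling hash over the serialized bytes; a fingerprint,
  # not a cryptographic digest.
  bytes <- as.integer(charToRaw(as.character(json)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
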