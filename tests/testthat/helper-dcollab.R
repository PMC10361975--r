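# Shared fixtures and oracles, built in code at test time.

# Independent brute-force least-squares oracle (normal equations), kept
# separate from the package's pseudoinverse path on purpose.
ls_oracle <- function(A, Z) solve(t(A) %*% A, t(A) %*% Z)

frob <- function(M) sqrt(sum(M^2))

# Small profiles for fast cohort tests: default feature structure, but a
# cohort small enough to generate in milliseconds and a prevalence high
# enough that tiny training subsets still contain positives.
small_profiles <- function(n_checkup = 260, n_hospital = 300,
                           prev_checkup = 0.2, prev_hospital = 0.25) {
  profs <- default_profiles()
  profs$checkup$n_samples <- n_checkup
  profs$checkup$prevalence <- prev_checkup
  profs$hospital$n_samples <- n_hospital
  profs$hospital$prevalence <- prev_hospital
  profs
}

# A no-missing, one-visit profile useful for exact-structure assertions.
clean_profile <- function(n = 50, prevalence = 0.3) {
  prof <- default_profiles()$checkup
  prof$n_samples <- n
  prof$prevalence <- prevalence
  for (f in names(prof$feature_specs)) {
    prof$feature_specs[[f]]$missing_rate <- 0
  }
  prof
}

# Lazily built, session-cached small two-institution study used by the
# experiment and cli tests (generation + preprocessing ~3 s once).
.dcollab_cache <- new.env(parent = emptyenv())
tiny_study <- function() {
  if (!exists("prep", envir = .dcollab_cache)) {
    profs <- small_profiles()
    chk <- generate_institution(profs$checkup, seed = 101)
    hos <- generate_institution(profs$hospital, seed = 102)
    assign("prep", prepare_datasets(chk, hos), envir = .dcollab_cache)
  }
  get("prep", envir = .dcollab_cache)
}

# Default-scale study used by the acceptance tests (cached: ~10 s once).
full_study <- function() {
  if (!exists("full", envir = .dcollab_cache)) {
    profs <- default_profiles()
    chk <- generate_institution(profs$checkup, seed = 20140101)
    hos <- generate_institution(profs$hospital, seed = 20150101)
    assign("full", c(prepare_datasets(chk, hos),
                     list(checkup_class = attr(chk, "outcome_class"))),
           envir = .dcollab_cache)
  }
  get("full", envir = .dcollab_cache)
}

fixture_path <- function() {
  p <- system.file("extdata", "clinic_visits.csv", package = "dcollab")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata",
                                 "clinic_visits.csv")
  p
}

# Minimal yearly-table builder for preprocessing unit tests.
yearly_row <- function(sample_id, year, ..., institution = "clinic") {
  vals <- list(...)
  row <- data.frame(sample_id = sample_id, institution = institution,
                    year = year, stringsAsFactors = FALSE)
  for (f in names(vals)) row[[f]] <- vals[[f]]
  row
}
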