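# Shared, lazily-built synthetic cohorts. Heavy objects are computed once
# per test session and reused across files.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache, inherits = FALSE)
}

# small planted-signal cohort used by classifier unit tests
tiny_planted <- function() {
  cached("tiny_planted", {
    coh <- generate_cohort(cohort_config(
      n_pairs = 30, n_transcripts = 600, n_informative = 60,
      effect_lfc = 1.0, n_sex_transcripts = 0, sex_lfc = 0,
      stage_effect_scale = 1, seed = 42
    ))
    pp <- preprocess_cohort(coh$counts, coh$meta,
                            min_detected_transcripts = 100, ruv = FALSE)
    list(cohort = coh, norm = pp$norm, meta = pp$meta)
  })
}

# small null cohort for uniformity checks
tiny_null <- function() {
  cached("tiny_null", {
    coh <- generate_null_cohort(cohort_config(
      n_pairs = 50, n_transcripts = 2000, n_informative = 0,
      n_sex_transcripts = 0, sex_lfc = 0, seed = 77
    ))
    pp <- preprocess_cohort(coh$counts, coh$meta,
                            min_detected_transcripts = 300, ruv = FALSE)
    list(cohort = coh, norm = pp$norm, meta = pp$meta)
  })
}

# study-scale cohorts for the acceptance checks: 100 pairs, 2000 transcripts
accept_config <- function(seed, effect_lfc = 0, n_informative = 0) {
  cohort_config(
    n_pairs = 100, n_transcripts = 2000,
    n_informative = n_informative, effect_lfc = effect_lfc,
    n_sex_transcripts = 0, sex_lfc = 0,
    seed = seed
  )
}

accept_preprocess <- function(coh) {
  preprocess_cohort(coh$counts, coh$meta, min_detected_transcripts = 300)
}

# null pipeline runs (seeds fixed up front); ensemble = 100 LASSO iterations
accept_null_run <- function(seed) {
  cached(paste0("null_run_", seed), {
    coh <- generate_null_cohort(accept_config(seed))
    pp <- accept_preprocess(coh)
    ens <- suppressWarnings(
      iterate_models(pp$norm, pp$meta, n_iter = 100, base_seed = seed * 1000)
    )
    list(pp = pp, ensemble = ens, truth = coh$truth)
  })
}

# planted-signal pipeline runs: 100 informative transcripts at log2FC 1.0
accept_planted_run <- function(seed) {
  cached(paste0("planted_run_", seed), {
    coh <- generate_cohort(accept_config(seed, effect_lfc = 1.0,
                                         n_informative = 100))
    pp <- accept_preprocess(coh)
    ens <- suppressWarnings(
      iterate_models(pp$norm, pp$meta, n_iter = 100, base_seed = seed * 1000)
    )
    list(pp = pp, ensemble = ens, truth = coh$truth)
  })
}

ACCEPT_NULL_SEEDS <- 301:310
ACCEPT_PLANTED_SEEDS <- 401:405

# confounding fixtures: a cohort with the study's sex imbalance plus a
# planted sex effect, and its sex-free twin (same seed)
sex_pair_config <- function(seed, sex_lfc) {
  cohort_config(
    n_pairs = 60, n_transcripts = 1200, n_informative = 100, effect_lfc = 1.0,
    n_sex_transcripts = 200, sex_lfc = sex_lfc, seed = seed
  )
}

accept_sex_pair <- function(seed) {
  cached(paste0("sex_pair_", seed), {
    run_one <- function(sex_lfc) {
      coh <- generate_cohort(sex_pair_config(seed, sex_lfc))
      pp <- preprocess_cohort(coh$counts, coh$meta, min_detected_transcripts = 200)
      ens <- suppressWarnings(
        iterate_models(pp$norm, pp$meta, n_iter = 25, base_seed = seed * 100)
      )
      list(pp = pp, ensemble = ens, truth = coh$truth)
    }
    list(sexed = run_one(1.5), sexfree = run_one(0))
  })
}

# PSO-SVM runs on the acceptance cohorts (swarm defaults, cached)
accept_pso_run <- function(key, run, split_seed) {
  cached(paste0("pso_", key, "_", split_seed), {
    suppressWarnings(run_pso_svm(run$pp$norm, run$pp$meta, split_seed = split_seed))
  })
}
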