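# Synthetic tumor-educated-platelet cohort generator.
#
# Emulates a matched case/control platelet RNA-seq study at the count-matrix
# level: negative-binomial counts with log-normal library sizes, a planted
# case/control expression signal (attenuated in early-stage cases), a planted
# sex effect riding on a case/control sex imbalance, and clinical covariates
# (age, smoking, pack-years, alcohol) with matched-pair structure. Ground
# truth is returned alongside the data so every downstream stage is testable.

#' Default clinical covariate distributions
#'
#' Parameters for the covariate model used by [generate_cohort()]: case
#' covariates are drawn from the marginals given here, and each matched
#' control's covariates are the case's values perturbed by the `pair_*`
#' noise terms (emulating a cohort that has already been matched on these
#' variables).
#'
#' @return a named list of distribution parameters. Units: `age_*` in years,
#'   `pack_years_*` parameterize a gamma in pack-years (current/former
#'   smokers only), `alcohol_*` a gamma in units/week.
#' @export
default_covariate_spec <- function() {
  list(
    age_mean = 62, age_sd = 8,
    smoking_probs = c(never = 0.15, former = 0.45, current = 0.40),
    pack_years_shape = 4, pack_years_scale = 7,
    alcohol_shape = 2, alcohol_scale = 5,
    pair_age_sd = 2, pair_smoking_agree = 0.8,
    pair_pack_sd = 5, pair_alcohol_sd = 3
  )
}

#' Configure a synthetic platelet RNA-seq cohort
#'
#' Bundles and validates all generator parameters. Defaults describe the
#' emulated study: 101 matched case/control pairs; 6,500 annotated
#' transcripts whose baseline abundance spread is calibrated so that roughly
#' 5.5k survive the coverage filter at the scaled-down median library size
#' of one million reads; 70% male cases versus 35% male controls; 35% of
#' cases early stage with the expression effect attenuated by
#' `stage_effect_scale`.
#'
#' @param n_pairs number of case/control pairs (>= 2).
#' @param n_transcripts number of transcripts in the raw matrix.
#' @param n_informative number of transcripts carrying a case/control effect.
#' @param effect_lfc log2 fold-change of informative transcripts in cases
#'   (advanced stage; early-stage cases get `effect_lfc * stage_effect_scale`).
#' @param n_sex_transcripts number of transcripts carrying a sex effect,
#'   disjoint from the informative set.
#' @param sex_lfc log2 fold-change of sex-effect transcripts in males.
#' @param dispersion negative-binomial dispersion: a positive scalar
#'   (variance = mu + dispersion * mu^2), or length-2 `c(meanlog, sdlog)` to
#'   sample per-transcript dispersions from a log-normal.
#' @param libsize_log_mean,libsize_log_sd log-normal library-size parameters
#'   (natural log of reads).
#' @param baseline_log_mean,baseline_log_sd per-transcript baseline abundance
#'   on the natural-log scale; baselines are softmax-normalized so only the
#'   spread matters.
#' @param covariate_spec see [default_covariate_spec()].
#' @param stage_effect_scale multiplier on `effect_lfc` for early-stage cases.
#' @param prop_male_case,prop_male_control male fraction among cases/controls.
#' @param prop_early_stage fraction of cases with stage I/II disease.
#' @param prop_oropharynx fraction of cases labelled oropharyngeal (the
#'   subsite carrying an HPV status).
#' @param prop_hpv_pos HPV-positive fraction among oropharyngeal cases
#'   (assigned independently of expression).
#' @param seed integer RNG seed; generation is a pure function of the config.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 101L,
                          n_transcripts = 6500L,
                          n_informative = 300L,
                          effect_lfc = 0.8,
                          n_sex_transcripts = 200L,
                          sex_lfc = 1.5,
                          dispersion = 0.2,
                          libsize_log_mean = log(1e6),
                          libsize_log_sd = 0.25,
                          baseline_log_mean = 0,
                          baseline_log_sd = 0.6,
                          covariate_spec = default_covariate_spec(),
                          stage_effect_scale = 0.5,
                          prop_male_case = 0.70,
                          prop_male_control = 0.35,
                          prop_early_stage = 0.35,
                          prop_oropharynx = 0.40,
                          prop_hpv_pos = 0.55,
                          seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs), n_transcripts = as.integer(n_transcripts),
    n_informative = as.integer(n_informative), effect_lfc = effect_lfc,
    n_sex_transcripts = as.integer(n_sex_transcripts), sex_lfc = sex_lfc,
    dispersion = dispersion,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    covariate_spec = covariate_spec,
    stage_effect_scale = stage_effect_scale,
    prop_male_case = prop_male_case, prop_male_control = prop_male_control,
    prop_early_stage = prop_early_stage,
    prop_oropharynx = prop_oropharynx, prop_hpv_pos = prop_hpv_pos,
    seed = as.integer(seed)
  )
  if (cfg$n_pairs < 2L) stop("n_pairs must be >= 2", call. = FALSE)
  if (cfg$n_transcripts < 1L) stop("n_transcripts must be positive", call. = FALSE)
  if (cfg$n_informative < 0L || cfg$n_informative > cfg$n_transcripts) {
    stop("n_informative must lie in [0, n_transcripts]", call. = FALSE)
  }
  if (cfg$n_sex_transcripts < 0L ||
      cfg$n_sex_transcripts + cfg$n_informative > cfg$n_transcripts) {
    stop("n_sex_transcripts must be >= 0 and informative + sex transcript sets ",
         "(kept disjoint) must fit in n_transcripts", call. = FALSE)
  }
  if (!(length(cfg$dispersion) %in% 1:2) || any(cfg$dispersion[1] <= 0)) {
    stop("dispersion must be a positive scalar or c(meanlog, sdlog)", call. = FALSE)
  }
  for (p in c("prop_male_case", "prop_male_control", "prop_early_stage",
              "prop_oropharynx", "prop_hpv_pos")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Draw case covariates and matched-control covariates for n pairs.
#' @noRd
draw_pair_covariates <- function(n, cs) {
  smoking_levels <- c("never", "former", "current")
  case_age <- stats::rnorm(n, cs$age_mean, cs$age_sd)
  case_smoke <- sample(smoking_levels, n, replace = TRUE, prob = cs$smoking_probs)
  case_pack <- ifelse(case_smoke == "never", 0,
                      stats::rgamma(n, cs$pack_years_shape, scale = cs$pack_years_scale))
  case_alc <- stats::rgamma(n, cs$alcohol_shape, scale = cs$alcohol_scale)

  ctrl_age <- case_age + stats::rnorm(n, 0, cs$pair_age_sd)
  keep_smoke <- stats::runif(n) < cs$pair_smoking_agree
  ctrl_smoke <- ifelse(keep_smoke, case_smoke,
                       sample(smoking_levels, n, replace = TRUE, prob = cs$smoking_probs))
  ctrl_pack <- ifelse(ctrl_smoke == "never", 0,
                      pmax(0, case_pack + stats::rnorm(n, 0, cs$pair_pack_sd)))
  ctrl_pack[case_smoke == "never" & ctrl_smoke != "never"] <-
    stats::rgamma(sum(case_smoke == "never" & ctrl_smoke != "never"),
                  cs$pack_years_shape, scale = cs$pack_years_scale)
  ctrl_alc <- pmax(0, case_alc + stats::rnorm(n, 0, cs$pair_alcohol_sd))
  list(
    case = data.frame(age = case_age, smoking_status = case_smoke,
                      pack_years = case_pack, alcohol_use = case_alc,
                      stringsAsFactors = FALSE),
    control = data.frame(age = ctrl_age, smoking_status = ctrl_smoke,
                         pack_years = ctrl_pack, alcohol_use = ctrl_alc,
                         stringsAsFactors = FALSE)
  )
}

# Negative-binomial count matrix for given per-sample library sizes,
# softmax baselines and a transcripts x samples log2 fold-change matrix.
#' @noRd
draw_counts <- function(pi_t, libsize, lfc_mat, size_t) {
  mu <- outer(pi_t, libsize) * 2^lfc_mat
  n_t <- length(pi_t)
  n_s <- length(libsize)
  counts <- matrix(
    stats::rnbinom(n_t * n_s, mu = as.vector(mu), size = rep(size_t, times = n_s)),
    nrow = n_t, ncol = n_s
  )
  storage.mode(counts) <- "integer"
  counts
}

#' @noRd
transcript_dispersions <- function(cfg) {
  if (length(cfg$dispersion) == 1L) {
    rep(cfg$dispersion, cfg$n_transcripts)
  } else {
    stats::rlnorm(cfg$n_transcripts, cfg$dispersion[1], cfg$dispersion[2])
  }
}

#' Generate a synthetic matched TEP cohort with ground truth
#'
#' Draws a transcripts x samples negative-binomial count matrix with mean
#' `library_size * softmax(baseline) * 2^(group * effect_lfc) *
#' 2^(male * sex_lfc)`, plus clinical metadata with matched-pair structure.
#' Informative and sex-effect transcript sets are disjoint. Early-stage cases
#' carry `effect_lfc * stage_effect_scale`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `tep_cohort`: a list with `counts` (integer
#'   matrix, transcripts x samples), `meta` (one row per sample: `sample_id`,
#'   `group`, `pair_id`, `sex`, `age`, `smoking_status`, `pack_years`,
#'   `alcohol_use`, `stage`, `hpv`, `site`) and `truth` (informative and
#'   sex-effect transcript ids, per-sample group and pair).
#' @examples
#' coh <- generate_cohort(cohort_config(n_pairs = 5, n_transcripts = 50,
#'                                      n_informative = 5, seed = 7))
#' dim(coh$counts)
#' table(coh$meta$group)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created by cohort_config()", call. = FALSE)
  }
  cfg <- config
  local_seed(cfg$seed, {
    tx_ids <- sprintf("TX%05d", seq_len(cfg$n_transcripts))
    baseline <- stats::rnorm(cfg$n_transcripts, cfg$baseline_log_mean, cfg$baseline_log_sd)
    pi_t <- exp(baseline - max(baseline))
    pi_t <- pi_t / sum(pi_t)
    informative <- sort(sample(tx_ids, cfg$n_informative))
    sex_tx <- sort(sample(setdiff(tx_ids, informative), cfg$n_sex_transcripts))
    size_t <- 1 / transcript_dispersions(cfg)

    n <- cfg$n_pairs
    pair_id <- sprintf("P%03d", seq_len(n))
    case_id <- sprintf("case_%03d", seq_len(n))
    ctrl_id <- sprintf("ctrl_%03d", seq_len(n))

    case_male <- stats::runif(n) < cfg$prop_male_case
    ctrl_male <- stats::runif(n) < cfg$prop_male_control
    early <- stats::runif(n) < cfg$prop_early_stage
    stage <- ifelse(early,
                    sample(c("I", "II"), n, replace = TRUE),
                    sample(c("III", "IV"), n, replace = TRUE))
    site <- ifelse(stats::runif(n) < cfg$prop_oropharynx, "oropharynx", "other")
    hpv <- rep(NA_character_, n)
    oro <- site == "oropharynx"
    hpv[oro] <- ifelse(stats::runif(sum(oro)) < cfg$prop_hpv_pos, "positive", "negative")

    cov <- draw_pair_covariates(n, cfg$covariate_spec)

    meta <- data.frame(
      sample_id = c(case_id, ctrl_id),
      group = factor(rep(c("case", "control"), each = n), levels = c("case", "control")),
      pair_id = rep(pair_id, 2),
      sex = factor(ifelse(c(case_male, ctrl_male), "male", "female"),
                   levels = c("female", "male")),
      age = c(cov$case$age, cov$control$age),
      smoking_status = factor(c(cov$case$smoking_status, cov$control$smoking_status),
                              levels = c("never", "former", "current")),
      pack_years = c(cov$case$pack_years, cov$control$pack_years),
      alcohol_use = c(cov$case$alcohol_use, cov$control$alcohol_use),
      stage = c(stage, rep(NA_character_, n)),
      hpv = c(hpv, rep(NA_character_, n)),
      site = c(site, rep(NA_character_, n)),
      stringsAsFactors = FALSE
    )

    libsize <- stats::rlnorm(2 * n, cfg$libsize_log_mean, cfg$libsize_log_sd)

    # transcripts x samples log2 fold-change matrix
    lfc <- matrix(0, cfg$n_transcripts, 2 * n, dimnames = list(tx_ids, meta$sample_id))
    if (length(informative) && cfg$effect_lfc != 0) {
      case_eff <- ifelse(early, cfg$effect_lfc * cfg$stage_effect_scale, cfg$effect_lfc)
      lfc[informative, seq_len(n)] <-
        matrix(rep(case_eff, each = length(informative)), nrow = length(informative))
    }
    if (length(sex_tx) && cfg$sex_lfc != 0) {
      male <- meta$sex == "male"
      lfc[sex_tx, male] <- lfc[sex_tx, male] + cfg$sex_lfc
    }

    counts <- draw_counts(pi_t, libsize, lfc, size_t)
    dimnames(counts) <- list(tx_ids, meta$sample_id)

    structure(
      list(
        counts = counts,
        meta = meta,
        truth = list(
          informative = informative,
          sex_transcripts = sex_tx,
          group = stats::setNames(as.character(meta$group), meta$sample_id),
          pair = stats::setNames(meta$pair_id, meta$sample_id)
        ),
        config = cfg
      ),
      class = "tep_cohort"
    )
  })
}

#' Generate a null cohort (no case/control expression signal)
#'
#' Identical to [generate_cohort()] with `effect_lfc` forced to zero: the
#' same RNG stream is consumed, so the cohort matches what
#' `generate_cohort()` would produce for the same config with no planted
#' group effect, and `truth$informative` is empty. Used as the leakage guard
#' for the classifier pipelines.
#'
#' @inheritParams generate_cohort
#' @return a `tep_cohort` whose `truth$informative` is empty.
#' @export
generate_null_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created by cohort_config()", call. = FALSE)
  }
  config$effect_lfc <- 0
  coh <- generate_cohort(config)
  coh$truth$informative <- character(0)
  coh
}

#' Generate cases plus an oversized, confounded control pool
#'
#' For exercising propensity matching: draws `n_pairs` cases as in
#' [generate_cohort()] and `n_controls_pool` unmatched controls whose age,
#' pack-years and alcohol-use distributions are shifted downward by
#' `confound_shift` standard deviations, so matching measurably improves
#' covariate balance. No expression signal links covariates to counts.
#'
#' @inheritParams generate_cohort
#' @param n_controls_pool number of candidate controls (>= `n_pairs`).
#' @param confound_shift covariate shift in SD units applied to the pool.
#' @return a `tep_cohort` whose `meta` has `pair_id = NA` (nothing matched
#'   yet) and whose `truth$shifted_covariates` names the confounded
#'   covariates.
#' @export
generate_matching_pool <- function(config, n_controls_pool, confound_shift = 0) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created by cohort_config()", call. = FALSE)
  }
  n_controls_pool <- as.integer(n_controls_pool)
  if (n_controls_pool < config$n_pairs) {
    stop("n_controls_pool must be >= n_pairs", call. = FALSE)
  }
  cfg <- config
  cs <- cfg$covariate_spec
  local_seed(cfg$seed, {
    tx_ids <- sprintf("TX%05d", seq_len(cfg$n_transcripts))
    baseline <- stats::rnorm(cfg$n_transcripts, cfg$baseline_log_mean, cfg$baseline_log_sd)
    pi_t <- exp(baseline - max(baseline))
    pi_t <- pi_t / sum(pi_t)
    size_t <- 1 / transcript_dispersions(cfg)

    n_case <- cfg$n_pairs
    smoking_levels <- c("never", "former", "current")

    case_cov <- draw_pair_covariates(n_case, cs)$case
    # marginal SDs of the generating distributions, used to scale the shift
    sd_age <- cs$age_sd
    sd_pack <- sqrt(cs$pack_years_shape) * cs$pack_years_scale
    sd_alc <- sqrt(cs$alcohol_shape) * cs$alcohol_scale

    n_pool <- n_controls_pool
    pool_age <- stats::rnorm(n_pool, cs$age_mean - confound_shift * sd_age, cs$age_sd)
    pool_smoke <- sample(smoking_levels, n_pool, replace = TRUE, prob = cs$smoking_probs)
    pool_pack <- ifelse(pool_smoke == "never", 0,
                        pmax(0, stats::rgamma(n_pool, cs$pack_years_shape,
                                              scale = cs$pack_years_scale) -
                               confound_shift * sd_pack))
    pool_alc <- pmax(0, stats::rgamma(n_pool, cs$alcohol_shape, scale = cs$alcohol_scale) -
                       confound_shift * sd_alc)

    case_id <- sprintf("case_%03d", seq_len(n_case))
    pool_id <- sprintf("pool_%04d", seq_len(n_pool))
    meta <- data.frame(
      sample_id = c(case_id, pool_id),
      group = factor(rep(c("case", "control"), c(n_case, n_pool)),
                     levels = c("case", "control")),
      pair_id = NA_character_,
      sex = factor(ifelse(c(stats::runif(n_case) < cfg$prop_male_case,
                            stats::runif(n_pool) < cfg$prop_male_control),
                          "male", "female"), levels = c("female", "male")),
      age = c(case_cov$age, pool_age),
      smoking_status = factor(c(case_cov$smoking_status, pool_smoke),
                              levels = smoking_levels),
      pack_years = c(case_cov$pack_years, pool_pack),
      alcohol_use = c(case_cov$alcohol_use, pool_alc),
      stage = NA_character_, hpv = NA_character_, site = NA_character_,
      stringsAsFactors = FALSE
    )

    libsize <- stats::rlnorm(n_case + n_pool, cfg$libsize_log_mean, cfg$libsize_log_sd)
    lfc <- matrix(0, cfg$n_transcripts, n_case + n_pool)
    counts <- draw_counts(pi_t, libsize, lfc, size_t)
    dimnames(counts) <- list(tx_ids, meta$sample_id)

    structure(
      list(
        counts = counts, meta = meta,
        truth = list(
          informative = character(0), sex_transcripts = character(0),
          group = stats::setNames(as.character(meta$group), meta$sample_id),
          pair = stats::setNames(meta$pair_id, meta$sample_id),
          shifted_covariates = if (confound_shift != 0)
            c("age", "pack_years", "alcohol_use") else character(0),
          confound_shift = confound_shift
        ),
        config = cfg
      ),
      class = "tep_cohort"
    )
  })
}

#' @exportS3Method base::print
print.tep_cohort <- function(x, ...) {
  cat("Synthetic TEP cohort:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples\n")
  cat("  cases/controls:", sum(x$meta$group == "case"), "/",
      sum(x$meta$group == "control"), "\n")
  cat("  informative transcripts:", length(x$truth$informative),
      " sex-effect transcripts:", length(x$truth$sex_transcripts), "\n")
  invisible(x)
}
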