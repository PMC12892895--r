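# QC filters, pair enforcement, TMM, log-CPM and RUV correction.

make_counts <- function(values, n_tx = nrow(values), n_s = ncol(values)) {
  m <- matrix(as.integer(values), n_tx, n_s)
  dimnames(m) <- list(sprintf("T%04d", seq_len(n_tx)), sprintf("S%02d", seq_len(n_s)))
  m
}

test_that("transcript coverage filter uses strict inequalities on both sides", {
  # 10 samples; rows probe the >30-reads and >90%-of-samples boundaries
  m <- make_counts(rbind(
    rep(31L, 10),             # 31 reads in 10/10 -> kept
    c(rep(31L, 9), 30L),      # 31 reads in exactly 9/10: 0.9 not > 0.9 -> dropped
    rep(30L, 10),             # 30 not > 30 -> dropped
    rep(100L, 10)             # comfortably kept
  ))
  out <- filter_transcripts(m, min_reads = 30, min_fraction = 0.90)
  expect_identical(rownames(out$counts), c("T0001", "T0004"))
  expect_identical(out$report$removed_transcripts, c("T0002", "T0003"))
  expect_equal(out$report$transcripts_in, 4)
  expect_equal(out$report$transcripts_kept, 2)
  expect_equal(out$report$samples_kept, 10)
  expect_error(filter_transcripts(matrix(integer(0), 0, 0)), "non-empty")
})

test_that("sample quality filter pins both boundaries with reason codes", {
  n_tx <- 1000L
  good <- rep(5L, n_tx)
  # 749 detected transcripts, ample coverage -> low_transcript_count
  few_tx <- c(rep(10L, 749), rep(0L, n_tx - 749))
  # 999 detected transcripts each with 1 read: mean 0.999 < 1 -> low_mean_coverage
  low_cov <- c(rep(1L, 999), rep(0L, n_tx - 999))
  # exactly 750 detected and exactly 1000 reads -> kept on both boundaries
  boundary <- c(rep(2L, 250), rep(1L, 500), rep(0L, n_tx - 750))
  m <- cbind(good, few_tx, low_cov, boundary)
  m <- make_counts(m)
  out <- filter_samples(m, min_detected_transcripts = 750, min_mean_reads_per_gene = 1)
  expect_identical(colnames(out$counts), c("S01", "S04"))
  rem <- out$report$removed_samples
  expect_identical(rem$reason[rem$sample_id == "S02"], "low_transcript_count")
  expect_identical(rem$reason[rem$sample_id == "S03"], "low_mean_coverage")
  expect_error(filter_samples(make_counts(matrix(0L, 10, 2) + 1L),
                              min_detected_transcripts = 750),
               "all samples removed")
})

test_that("pair enforcement drops widowed samples and preserves the quoted cohort arithmetic", {
  n_pairs <- 107
  meta <- data.frame(
    sample_id = c(sprintf("case_%03d", 1:n_pairs), sprintf("ctrl_%03d", 1:n_pairs)),
    group = rep(c("case", "control"), each = n_pairs),
    pair_id = rep(sprintf("P%03d", 1:n_pairs), 2),
    stringsAsFactors = FALSE
  )
  full <- make_counts(matrix(50L, 5, 2 * n_pairs))
  colnames(full) <- meta$sample_id

  # 6 QC failures in 6 distinct pairs -> 101 complete pairs remain
  failed <- c(sprintf("case_%03d", 1:3), sprintf("ctrl_%03d", 4:6))
  out <- enforce_pairs(full[, setdiff(colnames(full), failed)], meta)
  expect_equal(ncol(out$counts), 202)
  expect_equal(sum(out$meta$group == "case"), 101)
  expect_equal(sum(out$meta$group == "control"), 101)
  expect_setequal(out$report$removed_samples$sample_id,
                  c(sprintf("ctrl_%03d", 1:3), sprintf("case_%03d", 4:6)))
  expect_true(all(out$report$removed_samples$reason == "unmatched_partner"))

  # no QC failures -> identity
  out2 <- enforce_pairs(full, meta)
  expect_identical(out2$counts, full)
  expect_equal(nrow(out2$report$removed_samples), 0)

  # both members of one pair already failed -> nothing more to remove
  out3 <- enforce_pairs(full[, setdiff(colnames(full), c("case_007", "ctrl_007"))],
                        meta)
  expect_equal(ncol(out3$counts), 2 * (n_pairs - 1))
  expect_equal(nrow(out3$report$removed_samples), 0)

  bad_meta <- rbind(meta, data.frame(sample_id = "case_xxx", group = "case",
                                     pair_id = "P001"))
  expect_error(enforce_pairs(full, bad_meta), "more than twice")
})

test_that("TMM factors are exact in degenerate designs and match the published formula", {
  # identical columns: all M-values zero -> factors exactly 1
  m <- make_counts(matrix(rep(c(5L, 50L, 500L, 31L, 77L), 4), 5, 4))
  expect_equal(unname(tmm_factors(m)), rep(1, 4))

  # proportional columns: composition identical -> factors 1
  base <- c(10L, 40L, 90L, 160L, 250L, 1000L)
  m2 <- make_counts(cbind(base, 2L * base, 5L * base))
  expect_equal(unname(tmm_factors(m2)), rep(1, 3), tolerance = 1e-12)

  # random NB matrices against the straight-line oracle
  for (seed in 1:5) {
    set.seed(seed)
    m3 <- matrix(rnbinom(200 * 6, mu = runif(200, 5, 500), size = 5), 200, 6)
    dimnames(m3) <- list(sprintf("T%03d", 1:200), sprintf("S%d", 1:6))
    f <- tmm_factors(m3)
    expect_equal(f, oracle_tmm(m3), tolerance = 1e-8)
    expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)
  }

  # permuting samples permutes factors identically
  f0 <- tmm_factors(m2)
  perm <- c(3, 1, 2)
  expect_equal(tmm_factors(m2[, perm]), f0[perm])

  expect_error(tmm_factors(make_counts(cbind(c(1L, 1L), c(0L, 0L)))), "positive total")
})

test_that("log-CPM matches its closed form and is monotone", {
  m <- make_counts(matrix(c(0L, 10L, 200L, 0L, 20L, 100L), 3, 2))
  f <- c(1, 1)
  norm <- log_cpm(m, f, prior_count = 1)
  lib <- colSums(m)
  expect_equal(norm$values[2, 1],
               log2((10 + 1) / (lib[[1]] * 1 + 2) * 1e6), tolerance = 1e-12)
  expect_equal(norm$values[3, 2],
               log2((100 + 1) / (lib[[2]] * 1 + 2) * 1e6), tolerance = 1e-12)
  # zero row with equal effective library sizes is constant
  m2 <- make_counts(matrix(c(0L, 100L, 0L, 100L), 2, 2))
  expect_equal(stats::sd(log_cpm(m2, c(1, 1))$values[1, ]), 0)
  # doubling one cell strictly increases its value
  m3 <- m
  m3[2, 1] <- 20L
  expect_gt(log_cpm(m3, f)$values[2, 1], norm$values[2, 1])
  expect_error(log_cpm(m, c(1, -1)), "positive")
})

test_that("RUV leaves a nuisance-free matrix untouched", {
  coh <- generate_cohort(cohort_config(
    n_pairs = 40, n_transcripts = 500, n_informative = 0, n_sex_transcripts = 0,
    sex_lfc = 0, libsize_log_sd = 0, seed = 201
  ))
  norm <- log_cpm(coh$counts)
  out <- ruv_correct(norm, coh$meta)
  expect_equal(out$ruv$k_removed, 0L)
  expect_equal(out$values, norm$values, tolerance = 1e-8)
})

test_that("RUV removes a planted sex effect and is idempotent", {
  for (seed in 211:215) {
    coh <- generate_cohort(cohort_config(
      n_pairs = 60, n_transcripts = 1000, n_informative = 0,
      n_sex_transcripts = 200, sex_lfc = 1.5, seed = seed
    ))
    pp <- filter_transcripts(coh$counts)
    norm <- log_cpm(pp$counts)
    sex <- coh$meta$sex[match(colnames(norm$values), coh$meta$sample_id)]
    planted <- intersect(coh$truth$sex_transcripts, rownames(norm$values))
    sex_p <- function(values) {
      apply(values[planted, ], 1,
            function(x) stats::t.test(x[sex == "male"], x[sex == "female"])$p.value)
    }
    expect_lt(stats::median(sex_p(norm$values)), 1e-4)
    corrected <- ruv_correct(norm, coh$meta)
    expect_gt(corrected$ruv$k_removed, 0L)
    expect_gt(stats::median(sex_p(corrected$values)), 0.05)
    # idempotence: nothing left for a second pass
    twice <- ruv_correct(corrected, coh$meta)
    expect_lt(sqrt(sum((twice$values - corrected$values)^2)), 1e-6)
  }
})

test_that("RUV warns and no-ops when a nuisance covariate is constant", {
  coh <- generate_cohort(cohort_config(
    n_pairs = 20, n_transcripts = 300, n_informative = 0, n_sex_transcripts = 0,
    sex_lfc = 0, libsize_log_sd = 0, prop_male_case = 1, prop_male_control = 1,
    seed = 31
  ))
  norm <- log_cpm(coh$counts)
  expect_warning(
    expect_warning(out <- ruv_correct(norm, coh$meta, nuisance = "sex"),
                   "constant"),
    "no usable nuisance"
  )
  expect_identical(out$values, norm$values)
})

test_that("the preprocessing pipeline is deterministic end to end", {
  coh <- generate_cohort(cohort_config(n_pairs = 20, n_transcripts = 400,
                                       n_informative = 20, n_sex_transcripts = 40,
                                       seed = 8))
  a <- preprocess_cohort(coh$counts, coh$meta, min_detected_transcripts = 50)
  b <- preprocess_cohort(coh$counts, coh$meta, min_detected_transcripts = 50)
  expect_identical(a$norm$values, b$norm$values)
  expect_identical(a$reports$transcripts$transcripts_kept,
                   b$reports$transcripts$transcripts_kept)
})

test_that("count, metadata and normalized-matrix files round-trip", {
  coh <- generate_cohort(cohort_config(n_pairs = 5, n_transcripts = 40,
                                       n_informative = 5, n_sex_transcripts = 5,
                                       seed = 2))
  tmp <- withr::local_tempdir()
  cf <- file.path(tmp, "counts.tsv")
  mf <- file.path(tmp, "meta.tsv")
  write_count_matrix(coh$counts, cf)
  write_sample_meta(coh$meta, mf)
  expect_identical(read_count_matrix(cf), coh$counts)
  meta2 <- read_sample_meta(mf)
  expect_identical(as.character(meta2$group), as.character(coh$meta$group))
  expect_equal(meta2$age, coh$meta$age, tolerance = 1e-12)

  norm <- log_cpm(coh$counts)
  nf <- file.path(tmp, "norm.tsv")
  write_normalized_matrix(norm, nf)
  norm2 <- read_normalized_matrix(nf)
  expect_equal(norm2$values, norm$values, tolerance = 1e-10)
  expect_equal(norm2$tmm_factors, norm$tmm_factors, tolerance = 1e-10)
})
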