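# Pair-preserving splits, ANOVA differential expression, FDR, SVM training,
# the particle swarm, locked validation and the clustering enrichment check.

test_that("split sizing follows the floor-then-remainder rule and keeps pairs intact", {
  pairs101 <- sprintf("P%03d", 1:101)
  s3 <- split_pairs(pairs101, c(0.4, 0.3, 0.3), seed = 1)
  expect_equal(as.vector(table(s3$set)[c("train", "eval", "validate")]),
               c(41, 30, 30))
  s2 <- split_pairs(pairs101, c(0.66, 0.34), seed = 1)
  expect_equal(as.vector(table(s2$set)[c("train", "validate")]), c(67, 34))

  s5 <- split_pairs(sprintf("P%02d", 1:10), c(0.5, 0.5), seed = 3)
  expect_equal(as.vector(table(s5$set)), c(5, 5))
  # pair co-assignment: duplicated pair ids map to a single set label
  dup <- split_pairs(rep(pairs101, 2), c(0.4, 0.3, 0.3), seed = 1)
  expect_equal(nrow(dup), 101)

  expect_identical(split_pairs(pairs101, c(0.4, 0.3, 0.3), seed = 7),
                   split_pairs(pairs101, c(0.4, 0.3, 0.3), seed = 7))
  expect_false(identical(s3$set, split_pairs(pairs101, c(0.4, 0.3, 0.3), seed = 2)$set))
  expect_error(split_pairs(pairs101, c(0.6, 0.3)), "sum to 1")
  expect_error(split_pairs("P001", c(0.5, 0.5)), "fewer pairs")
})

test_that("two-factor ANOVA matches hand-computed sums of squares on a balanced design", {
  # balanced 2x2, 3 replicates per cell
  grp <- factor(rep(c("case", "control"), each = 6), levels = c("case", "control"))
  sex <- factor(rep(rep(c("female", "male"), each = 3), 2))
  y <- c(5.1, 4.8, 5.3, 6.0, 6.2, 5.8, 3.9, 4.1, 4.3, 5.0, 5.2, 4.7)
  values <- matrix(y, 1, 12, dimnames = list("TX1", sprintf("s%02d", 1:12)))
  meta <- data.frame(sample_id = colnames(values), group = grp, sex = sex)

  # hand calculation: balanced additive ANOVA decomposition
  ybar <- mean(y)
  ss_a <- 6 * sum((tapply(y, grp, mean) - ybar)^2)
  ss_b <- 6 * sum((tapply(y, sex, mean) - ybar)^2)
  fitted_add <- ybar + (tapply(y, grp, mean) - ybar)[grp] +
    (tapply(y, sex, mean) - ybar)[sex]
  ss_e <- sum((y - fitted_add)^2)
  f_hand <- (ss_a / 1) / (ss_e / (12 - 3))
  p_hand <- stats::pf(f_hand, 1, 9, lower.tail = FALSE)

  p <- anova_de(values, meta)
  expect_equal(unname(p["TX1"]), p_hand, tolerance = 1e-10)
})

test_that("ANOVA handles degenerate transcripts and starved designs", {
  meta <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    group = factor(rep(c("case", "control"), each = 6), levels = c("case", "control")),
    sex = factor(rep(rep(c("female", "male"), each = 3), 2))
  )
  values <- rbind(TX1 = rep(2.5, 12), TX2 = rnorm(12))
  colnames(values) <- meta$sample_id
  p <- anova_de(values, meta)
  expect_true(is.na(p["TX1"]))
  expect_false(is.na(p["TX2"]))

  meta_starved <- meta
  meta_starved$sex <- factor(c("male", rep("female", 11)))
  expect_warning(p2 <- anova_de(values, meta_starved), "fewer than 2")
  expect_true(all(is.na(p2)))
})

test_that("group-effect p-values are uniform on a null cohort", {
  tn <- tiny_null()
  p <- anova_de(tn$norm, tn$meta)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment reproduces the step-up closed form", {
  expect_equal(unname(bh_fdr(c(0.01, 0.02, 0.03, 0.04))), rep(0.04, 4))
  expect_equal(bh_fdr(0.73), 0.73)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(10)
  p <- runif(200)^2
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-14)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the SVM separates a separable toy and is invariant to duplication", {
  set.seed(5)
  n <- 20
  values <- rbind(TXa = c(rnorm(n, 3), rnorm(n, -3)),
                  TXb = c(rnorm(n, -3), rnorm(n, 3)))
  colnames(values) <- sprintf("s%02d", 1:(2 * n))
  meta <- data.frame(sample_id = colnames(values),
                     group = factor(rep(c("case", "control"), each = n),
                                    levels = c("case", "control")))
  model <- train_svm(values, meta, c("TXa", "TXb"), cost = 10, gamma = 0.5,
                     tolerance = 1e-8)
  scores <- predict(model, values)
  expect_equal(roc_auc(scores, meta$group == "case")$auc, 1.0)
  expect_true(all((scores >= 0.5) == (meta$group == "case")))

  # duplicating every training sample leaves the decision function unchanged
  values_dup <- cbind(values, values)
  colnames(values_dup) <- c(colnames(values), paste0(colnames(values), "_dup"))
  meta_dup <- rbind(meta, transform(meta, sample_id = paste0(sample_id, "_dup")))
  model_dup <- train_svm(values_dup, meta_dup, c("TXa", "TXb"), cost = 10,
                         gamma = 0.5, tolerance = 1e-8)
  grid <- values + 0.3
  expect_equal(predict(model_dup, grid, type = "decision"),
               predict(model, grid, type = "decision"), tolerance = 1e-6)

  meta_one <- meta
  meta_one$group <- factor("case", levels = c("control", "case"))
  expect_error(train_svm(values, meta_one, c("TXa", "TXb")), "2 samples per class")
})

test_that("SVM decision values agree with an independent RBF-SVM implementation", {
  skip_if_not_installed("kernlab")
  set.seed(8)
  n <- 30
  p <- 5
  values <- matrix(rnorm(p * 2 * n), p, 2 * n,
                   dimnames = list(sprintf("TX%d", 1:p), sprintf("s%03d", 1:(2 * n))))
  values[1:2, 1:n] <- values[1:2, 1:n] + 1.5
  meta <- data.frame(sample_id = colnames(values),
                     group = factor(rep(c("case", "control"), each = n),
                                    levels = c("case", "control")))
  cost <- 2
  gamma <- 0.1
  model <- train_svm(values, meta, rownames(values), cost = cost, gamma = gamma,
                     tolerance = 1e-8)
  held <- matrix(rnorm(p * 40), p, 40,
                 dimnames = list(rownames(values), sprintf("h%02d", 1:40)))
  dv <- predict(model, held, type = "decision")

  Xs <- scale(t(values), model$center, model$scale)
  k <- kernlab::ksvm(Xs, meta$group, type = "C-svc", kernel = "rbfdot",
                     kpar = list(sigma = gamma), C = cost, scaled = FALSE,
                     tol = 1e-8)
  Hs <- scale(t(held), model$center, model$scale)
  dv_k <- as.numeric(kernlab::predict(k, Hs, type = "decision"))
  # orient kernlab's decision values toward the case class
  tr_k <- as.numeric(kernlab::predict(k, Xs, type = "decision"))
  if (mean(tr_k[meta$group == "case"]) < mean(tr_k[meta$group == "control"])) {
    dv_k <- -dv_k
  }
  expect_equal(unname(dv), dv_k, tolerance = 1e-3)
})

test_that("the swarm finds a known analytic optimum and improves monotonically", {
  bounds <- matrix(c(-5, 5), nrow = 2, dimnames = list(c("lower", "upper"), "x"))
  x0 <- 1.234
  res <- pso_optimize(NULL, NULL, NULL, bounds = bounds,
                      n_particles = 30, n_iterations = 200, seed = 11,
                      fitness_fn = function(theta) -(theta[1] - x0)^2)
  expect_lt(abs(res$best$theta[["x"]] - x0), 1e-3)
  expect_true(all(diff(res$history$best_fitness) >= 0))
  expect_error(pso_optimize(NULL, NULL, NULL, bounds = bounds, n_particles = 0,
                            fitness_fn = identity), "positive")
})

test_that("PSO is competitive with a full grid search over the same bounds", {
  tp <- tiny_planted()
  split <- split_pairs(tp$meta$pair_id, c(0.4, 0.3, 0.3), seed = 19)
  res <- pso_optimize(tp$norm, tp$meta, split, seed = 19)

  # independent grid-search oracle over the same fitness landscape
  train_ids <- tp$meta$sample_id[tp$meta$pair_id %in% split$pair_id[split$set == "train"]]
  eval_ids <- tp$meta$sample_id[tp$meta$pair_id %in% split$pair_id[split$set == "eval"]]
  q <- bh_fdr(anova_de(tp$norm, tp$meta, samples = train_ids))
  eval_case <- tp$meta$group[match(eval_ids, tp$meta$sample_id)] == "case"
  b <- pso_default_bounds()
  grid_fit <- 0
  for (thr in 10^seq(b[1, 1], b[2, 1], length.out = 10)) {
    panel <- names(q)[!is.na(q) & q < thr]
    if (length(panel) == 0) next
    for (cost in 2^seq(b[1, 2], b[2, 2], length.out = 10)) {
      for (gamma in 2^seq(b[1, 3], b[2, 3], length.out = 10)) {
        m <- train_svm(tp$norm, tp$meta, panel, cost = cost, gamma = gamma,
                       train_ids = train_ids)
        auc <- roc_auc(predict(m, tp$norm, eval_ids), eval_case)$auc
        grid_fit <- max(grid_fit, auc)
      }
    }
  }
  expect_gte(res$best$fitness, grid_fit - 0.02)
})

test_that("locked validation is reproducible and optimistic only on its own training data", {
  tp <- tiny_planted()
  r1 <- run_pso_svm(tp$norm, tp$meta, split_seed = 23, n_particles = 15,
                    n_iterations = 4)
  r2 <- run_pso_svm(tp$norm, tp$meta, split_seed = 23, n_particles = 15,
                    n_iterations = 4)
  expect_identical(r1$pso$best, r2$pso$best)
  expect_equal(r1$validation$auc, r2$validation$auc)
  expect_identical(r1$validation$panel, r2$validation$panel)

  train_res <- lock_and_validate(tp$norm, tp$meta, r1$split, r1$pso$best,
                                 score_set = "train")
  expect_gte(train_res$auc, r1$validation$auc)
  expect_error(lock_and_validate(tp$norm, tp$meta, r1$split, r1$pso$best,
                                 score_set = "eval"), "score_set")
})

test_that("clustering enrichment recovers a perfect split and matches the hypergeometric form", {
  set.seed(33)
  n <- 10
  values <- matrix(rnorm(5 * 2 * n), 5, 2 * n,
                   dimnames = list(sprintf("TX%d", 1:5), sprintf("s%02d", 1:(2 * n))))
  # group-specific transcript patterns (correlation distance ignores
  # per-sample constant shifts, so the pattern must differ across transcripts)
  values[1:2, 1:n] <- values[1:2, 1:n] + 6
  values[3:5, (n + 1):(2 * n)] <- values[3:5, (n + 1):(2 * n)] + 6
  labels <- rep(c("case", "control"), each = n)
  res <- cluster_enrichment(values, rownames(values), labels)
  expect_false(res$degenerate)
  expect_equal(sort(as.vector(res$table)), c(0, 0, 10, 10))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$p_value, oracle_fisher2x2(matrix(c(10, 0, 0, 10), 2)),
               tolerance = 1e-12)
  # base fisher.test agrees with the enumeration oracle on asymmetric tables
  for (tab in list(matrix(c(7, 3, 2, 8), 2), matrix(c(5, 5, 1, 9), 2),
                   matrix(c(9, 1, 4, 6), 2))) {
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher2x2(tab),
                 tolerance = 1e-9)
  }
  expect_error(cluster_enrichment(values, "TX1", labels), "at least 2")
})

test_that("clustering enrichment p-values are not anti-conservative under the null", {
  set.seed(44)
  p <- replicate(40, {
    values <- matrix(rnorm(10 * 24), 10, 24,
                     dimnames = list(sprintf("TX%d", 1:10), sprintf("s%02d", 1:24)))
    labels <- sample(rep(c("case", "control"), each = 12))
    cluster_enrichment(values, rownames(values), labels)$p_value
  })
  expect_lte(sum(p < 0.05), 4)
})

test_that("panel overlap counts match exhaustive set arithmetic", {
  a <- sprintf("TX%03d", 1:100)
  same <- panel_overlap(list(A = a, B = a))
  expect_equal(same$regions[["A&B"]], 100)
  disjoint <- panel_overlap(list(A = sprintf("TX%03d", 1:50),
                                 B = sprintf("TX%03d", 51:100)))
  expect_equal(disjoint$intersections["A", "B"], 0)

  set.seed(12)
  pool <- sprintf("TX%04d", 1:941)
  panels <- list(S1 = sample(pool, 200), S2 = sample(pool, 200), S3 = sample(pool, 200))
  ov <- panel_overlap(panels)
  core <- Reduce(intersect, panels)
  expect_equal(ov$regions[["S1&S2&S3"]] %||% 0, length(core))
  expect_equal(ov$intersections["S1", "S2"], length(intersect(panels$S1, panels$S2)))
  only1 <- setdiff(setdiff(panels$S1, panels$S2), panels$S3)
  expect_equal(ov$regions[["S1"]] %||% 0, length(only1))
  expect_equal(ov$union_size, length(unique(unlist(panels))))
  expect_error(panel_overlap(list(a)), "at least 2")
})
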