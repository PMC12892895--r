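# PSO-SVM classifier arm: two-factor ANOVA differential expression on the
# training set, FDR-ranked panel reduction, particle-swarm optimization of
# the FDR threshold and RBF-SVM hyperparameters against the evaluation set,
# locked validation, and the unsupervised-clustering enrichment check.

#' Two-factor ANOVA differential expression
#'
#' Per transcript, the p-value of the group main effect from a two-factor
#' ANOVA (`~ factor_b + factor_a`, no interaction): an F test comparing the
#' residual sum of squares of the second-factor-only model against the full
#' additive model. The design is shared across transcripts, so the fits are
#' vectorized through a single QR decomposition.
#'
#' @param norm a `tep_norm` object (or a numeric matrix of expression values).
#' @param meta sample metadata.
#' @param samples sample ids to use (training samples only, in a classifier
#'   context); defaults to all columns.
#' @param factor_a primary factor tested (default `"group"`).
#' @param factor_b secondary factor adjusted for (default `"sex"`).
#' @return named vector of p-values in (0, 1]; constant transcripts get NA.
#' @export
anova_de <- function(norm, meta, samples = NULL,
                     factor_a = "group", factor_b = "sex") {
  values <- if (inherits(norm, "tep_norm")) norm$values else norm
  if (is.null(samples)) samples <- colnames(values)
  m <- meta_for_samples(meta, samples)
  fa <- droplevels(factor(m[[factor_a]]))
  fb <- droplevels(factor(m[[factor_b]]))
  if (any(table(fa) < 2L) || any(table(fb) < 2L)) {
    warning("a factor level has fewer than 2 samples; returning NA p-values")
    return(stats::setNames(rep(NA_real_, nrow(values)), rownames(values)))
  }
  Y <- t(values[, samples, drop = FALSE])
  X_full <- stats::model.matrix(~ fb + fa)
  X_red <- stats::model.matrix(~ fb)
  qr_full <- qr(X_full)
  qr_red <- qr(X_red)
  rss_full <- colSums(qr.resid(qr_full, Y)^2)
  rss_red <- colSums(qr.resid(qr_red, Y)^2)
  df1 <- qr_full$rank - qr_red$rank
  df2 <- nrow(Y) - qr_full$rank
  Fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  tol <- 1e-12 * nrow(Y)
  degenerate <- rss_full < tol & (rss_red - rss_full) < tol
  p[degenerate] <- NA_real_
  p <- pmax(p, .Machine$double.xmin)
  stats::setNames(p, rownames(values))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; NAs are passed through.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same names and length.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Train a calibrated RBF-kernel SVM on a transcript panel
#'
#' Standardizes each panel transcript using training-set mean/SD (stored and
#' reused at prediction time), fits a C-classification SVM with an RBF
#' kernel, orients the decision values so larger means more case-like, and
#' fits a sigmoid (Platt) calibration of decision value to case probability
#' on the training data.
#'
#' @param norm `tep_norm` or expression matrix.
#' @param meta sample metadata.
#' @param panel transcript ids to use as features.
#' @param cost,gamma SVM hyperparameters.
#' @param train_ids training sample ids; defaults to all columns.
#' @param ... further arguments to [e1071::svm()] (e.g. `tolerance`).
#' @return a `tep_svm` model; use [predict.tep_svm()] for scores.
#' @export
train_svm <- function(norm, meta, panel, cost = 1, gamma = 1 / length(panel),
                      train_ids = NULL, ...) {
  values <- if (inherits(norm, "tep_norm")) norm$values else norm
  if (is.null(train_ids)) train_ids <- colnames(values)
  if (length(panel) == 0L) stop("panel must be non-empty", call. = FALSE)
  missing_tx <- setdiff(panel, rownames(values))
  if (length(missing_tx)) stop("panel transcripts absent from the matrix", call. = FALSE)
  m <- meta_for_samples(meta, train_ids)
  y <- factor(as.character(m$group), levels = c("control", "case"))
  if (nlevels(droplevels(y)) < 2L || min(table(y)) < 2L) {
    stop("training set needs at least 2 samples per class", call. = FALSE)
  }
  X <- t(values[panel, train_ids, drop = FALSE])
  center <- colMeans(X)
  # population-SD denominator: standardization is then invariant to
  # duplicating training samples, like the SVM solution itself
  scale_ <- sqrt(colMeans(X^2) - center^2)
  scale_[scale_ < 1e-12] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE, ...)
  dv <- attr(stats::predict(fit, Xs, decision.values = TRUE), "decision.values")[, 1]
  orient <- if (mean(dv[y == "case"]) >= mean(dv[y == "control"])) 1 else -1
  dv <- orient * dv
  calib <- suppressWarnings(
    stats::glm(I(y == "case") ~ dv, family = stats::binomial())
  )
  structure(
    list(panel = panel, cost = cost, gamma = gamma,
         center = center, scale = scale_, fit = fit, orient = orient,
         calib = stats::coef(calib), train_ids = train_ids),
    class = "tep_svm"
  )
}

#' Score samples with a trained SVM
#'
#' @param object a `tep_svm` from [train_svm()].
#' @param norm `tep_norm` or expression matrix containing the panel.
#' @param sample_ids samples to score; defaults to all columns.
#' @param type `"prob"` for calibrated case probabilities, `"decision"` for
#'   oriented decision values.
#' @param ... unused.
#' @return named numeric vector of scores.
#' @export
predict.tep_svm <- function(object, norm, sample_ids = NULL, type = c("prob", "decision"),
                            ...) {
  type <- match.arg(type)
  values <- if (inherits(norm, "tep_norm")) norm$values else norm
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  X <- t(values[object$panel, sample_ids, drop = FALSE])
  Xs <- scale(X, center = object$center, scale = object$scale)
  dv <- attr(stats::predict(object$fit, Xs, decision.values = TRUE),
             "decision.values")[, 1]
  dv <- object$orient * dv
  out <- if (type == "decision") dv else
    stats::plogis(object$calib[1] + object$calib[2] * dv)
  stats::setNames(as.numeric(out), sample_ids)
}

#' Default PSO search box
#'
#' Rows are lower/upper bounds; columns the searched parameters:
#' log10 FDR threshold (1e-6 .. 0.5), log2 SVM cost (2^-5 .. 2^15) and
#' log2 RBF gamma (2^-15 .. 2^3).
#'
#' @return 2 x 3 numeric matrix.
#' @export
pso_default_bounds <- function() {
  matrix(c(-6, log10(0.5),
           -5, 15,
           -15, 3),
         nrow = 2, dimnames = list(c("lower", "upper"),
                                   c("log10_fdr", "log2_cost", "log2_gamma")))
}

#' Particle-swarm optimization of panel threshold and SVM parameters
#'
#' Global-best PSO over (log10 FDR threshold, log2 cost, log2 gamma). The
#' fitness of a particle is the evaluation-set AUC of an SVM trained on the
#' training set using the panel of transcripts whose training-set q-value
#' falls below the particle's FDR threshold (fitness 0 when the panel is
#' empty). Velocities are clamped to half the box per dimension and
#' particles reflect off the bounds.
#'
#' @param norm `tep_norm` or expression matrix.
#' @param meta sample metadata.
#' @param split a `split_assignment` with `train` and `eval` sets.
#' @param bounds 2 x d bounds matrix, see [pso_default_bounds()].
#' @param n_particles,n_iterations swarm size and iteration budget (the
#'   initial evaluation counts as iteration 0).
#' @param inertia,c_cognitive,c_social velocity-update constants.
#' @param seed RNG seed for the swarm.
#' @param fitness_fn optional override of the fitness function (takes the
#'   raw position vector; used for testing the optimizer in isolation).
#' @return list with `best` (fdr_threshold, cost, gamma, panel, fitness),
#'   `history` (per-iteration global best fitness), `qvalues` (training-set
#'   q-values) and the swarm configuration.
#' @export
pso_optimize <- function(norm, meta, split, bounds = pso_default_bounds(),
                         n_particles = 50L, n_iterations = 10L,
                         inertia = 0.72, c_cognitive = 1.49, c_social = 1.49,
                         seed = 1L, fitness_fn = NULL) {
  if (n_particles < 1L || n_iterations < 1L) {
    stop("n_particles and n_iterations must be positive", call. = FALSE)
  }
  d <- ncol(bounds)
  lower <- bounds[1, ]
  upper <- bounds[2, ]

  qvalues <- NULL
  if (is.null(fitness_fn)) {
    stopifnot(inherits(split, "split_assignment"))
    train_ids <- split_samples(split, meta, "train")
    eval_ids <- split_samples(split, meta, "eval")
    if (length(train_ids) == 0L || length(eval_ids) == 0L) {
      stop("split must contain train and eval sets", call. = FALSE)
    }
    pv <- anova_de(norm, meta, samples = train_ids)
    qvalues <- bh_fdr(pv)
    eval_labels <- meta_for_samples(meta, eval_ids)$group
    fitness_fn <- function(theta) {
      thr <- 10^theta[1]
      panel <- names(qvalues)[!is.na(qvalues) & qvalues < thr]
      if (length(panel) == 0L) return(0)
      model <- train_svm(norm, meta, panel, cost = 2^theta[2], gamma = 2^theta[3],
                         train_ids = train_ids)
      scores <- predict.tep_svm(model, norm, eval_ids)
      fast_auc(scores, eval_labels)
    }
  }

  local_seed(seed, {
    pos <- matrix(stats::runif(n_particles * d, rep(lower, each = n_particles),
                               rep(upper, each = n_particles)),
                  n_particles, d)
    vmax <- (upper - lower) / 2
    vel <- matrix(stats::runif(n_particles * d, rep(-vmax, each = n_particles),
                               rep(vmax, each = n_particles)),
                  n_particles, d)
    fit <- apply(pos, 1, fitness_fn)
    pbest <- pos
    pbest_fit <- fit
    g <- which.max(fit)
    gbest <- pos[g, ]
    gbest_fit <- fit[g]
    history <- data.frame(iteration = 0L, best_fitness = gbest_fit)

    for (it in seq_len(n_iterations)) {
      r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
      r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
      vel <- inertia * vel +
        c_cognitive * r1 * (pbest - pos) +
        c_social * r2 * sweep(-pos, 2, gbest, "+")
      vel <- pmin(pmax(vel, rep(-vmax, each = n_particles)),
                  rep(vmax, each = n_particles))
      pos <- pos + vel
      # reflective boundaries
      for (j in seq_len(d)) {
        over <- pos[, j] > upper[j]
        pos[over, j] <- 2 * upper[j] - pos[over, j]
        vel[over, j] <- -vel[over, j]
        under <- pos[, j] < lower[j]
        pos[under, j] <- 2 * lower[j] - pos[under, j]
        vel[under, j] <- -vel[under, j]
        pos[, j] <- pmin(pmax(pos[, j], lower[j]), upper[j])
      }
      fit <- apply(pos, 1, fitness_fn)
      improved <- fit > pbest_fit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      if (max(pbest_fit) > gbest_fit) {
        g <- which.max(pbest_fit)
        gbest <- pbest[g, ]
        gbest_fit <- pbest_fit[g]
      }
      history <- rbind(history,
                       data.frame(iteration = it, best_fitness = gbest_fit))
    }

    best <- list(theta = stats::setNames(gbest, colnames(bounds)),
                 fdr_threshold = 10^gbest[1],
                 cost = 2^gbest[2], gamma = 2^gbest[3],
                 fitness = gbest_fit)
    if (!is.null(qvalues)) {
      best$panel <- names(qvalues)[!is.na(qvalues) & qvalues < best$fdr_threshold]
    }
    list(best = best, history = history, qvalues = qvalues,
         swarm = list(n_particles = n_particles, n_iterations = n_iterations,
                      inertia = inertia, c_cognitive = c_cognitive,
                      c_social = c_social, seed = seed, bounds = bounds))
  })
}

#' Lock the optimized settings and score the validation set
#'
#' Refits the SVM on the training set with the locked panel and
#' hyperparameters and scores the validation samples once. The three split
#' sets must be disjoint; scoring any sample that was available during
#' training or evaluation is a hard error (the `score_set` argument exists
#' so the optimism direction can be demonstrated explicitly).
#'
#' @param norm `tep_norm` or expression matrix.
#' @param meta sample metadata.
#' @param split a `split_assignment` with train/eval/validate sets.
#' @param best the `best` element returned by [pso_optimize()] (needs
#'   `fdr_threshold`, `cost`, `gamma`, and optionally `panel`).
#' @param panel locked transcript panel; recomputed from the training-set
#'   q-values at `best$fdr_threshold` when absent.
#' @param score_set which split set to score (`"validate"`; `"train"` is a
#'   deliberate optimism check, flagged in the result).
#' @return a `prediction_result` (see [evaluate_predictions()]) with the
#'   locked panel and parameters attached.
#' @export
lock_and_validate <- function(norm, meta, split, best, panel = best$panel,
                              score_set = "validate") {
  stopifnot(inherits(split, "split_assignment"))
  train_ids <- split_samples(split, meta, "train")
  eval_ids <- split_samples(split, meta, "eval")
  valid_ids <- split_samples(split, meta, "validate")
  if (length(intersect(valid_ids, c(train_ids, eval_ids)))) {
    stop("validation samples overlap the training/evaluation sets", call. = FALSE)
  }
  if (is.null(panel)) {
    pv <- anova_de(norm, meta, samples = train_ids)
    q <- bh_fdr(pv)
    panel <- names(q)[!is.na(q) & q < best$fdr_threshold]
  }
  ids <- switch(score_set, validate = valid_ids, train = train_ids,
                stop("score_set must be 'validate' or 'train'", call. = FALSE))
  labels <- meta_for_samples(meta, ids)$group
  if (length(panel) == 0L) {
    # no transcript clears the locked threshold: the locked classifier is the
    # constant (prevalence) predictor, whose tied scores give AUC 1/2
    warning("locked panel is empty; scoring with a constant classifier")
    scores <- stats::setNames(rep(0.5, length(ids)), ids)
    model <- NULL
  } else {
    model <- train_svm(norm, meta, panel, cost = best$cost, gamma = best$gamma,
                       train_ids = train_ids)
    scores <- predict.tep_svm(model, norm, ids)
  }
  res <- evaluate_predictions(scores, labels,
                              ci_level = if (length(panel)) 0.95 else NULL)
  res$panel <- panel
  res$parameters <- list(fdr_threshold = best$fdr_threshold,
                         cost = best$cost, gamma = best$gamma)
  res$score_set <- score_set
  res$model <- model
  res
}

#' Run the complete PSO-SVM arm on a preprocessed cohort
#'
#' Pair-preserving 40/30/30 split, training-set ANOVA + BH q-values, PSO of
#' the FDR threshold and SVM hyperparameters against the evaluation set, and
#' locked validation.
#'
#' @param norm `tep_norm` from [preprocess_cohort()].
#' @param meta metadata of the surviving samples.
#' @param split_seed seed for the pair shuffle.
#' @param fractions split fractions (default `c(0.4, 0.3, 0.3)`).
#' @param seed swarm seed.
#' @param ... further arguments to [pso_optimize()].
#' @return list with `split`, `pso` (optimizer output) and `validation`
#'   (the locked `prediction_result`).
#' @export
run_pso_svm <- function(norm, meta, split_seed = 1L,
                        fractions = c(0.4, 0.3, 0.3), seed = split_seed, ...) {
  split <- split_pairs(meta$pair_id, fractions, seed = split_seed)
  pso <- pso_optimize(norm, meta, split, seed = seed, ...)
  validation <- lock_and_validate(norm, meta, split, pso$best)
  list(split = split, pso = pso, validation = validation)
}

#' Unsupervised clustering enrichment of a transcript panel
#'
#' Hierarchically clusters the samples on the panel (distance = 1 - Pearson
#' correlation, Ward linkage), cuts the tree into two clusters, and tests
#' cluster membership against the case/control labels with a two-sided
#' Fisher exact test.
#'
#' @param norm `tep_norm` or expression matrix.
#' @param panel transcript ids (>= 2).
#' @param labels case/control labels aligned with the columns.
#' @return list with `p_value`, the 2 x 2 `table`, the cluster assignment
#'   and a `degenerate` flag (a singleton cluster).
#' @export
cluster_enrichment <- function(norm, panel, labels) {
  values <- if (inherits(norm, "tep_norm")) norm$values else norm
  if (length(panel) < 2L) stop("panel must contain at least 2 transcripts", call. = FALSE)
  X <- values[panel, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(X))
  cl <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = 2)
  tab <- table(cluster = cl, group = as.character(labels))
  degenerate <- min(table(cl)) <= 1L
  p <- stats::fisher.test(tab)$p.value
  list(p_value = p, table = tab, clusters = cl, degenerate = degenerate)
}

#' Venn decomposition of transcript panels
#'
#' @param panels named list (>= 2) of transcript id sets.
#' @return list with `regions` (counts per exclusive Venn region, names like
#'   `"A&B"`), `intersections` (pairwise intersection size matrix) and
#'   `union_size`.
#' @export
panel_overlap <- function(panels) {
  if (length(panels) < 2L) stop("need at least 2 panels", call. = FALSE)
  if (is.null(names(panels))) names(panels) <- LETTERS[seq_along(panels)]
  all_tx <- unique(unlist(panels))
  member <- vapply(panels, function(p) all_tx %in% p, logical(length(all_tx)))
  if (length(all_tx) == 1L) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, names(panels)))
  key <- apply(member, 1, function(row) paste(names(panels)[row], collapse = "&"))
  regions <- table(key)
  k <- length(panels)
  inter <- matrix(0L, k, k, dimnames = list(names(panels), names(panels)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    inter[i, j] <- length(intersect(panels[[i]], panels[[j]]))
  }
  list(regions = as.list(regions), intersections = inter,
       union_size = length(all_tx))
}
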