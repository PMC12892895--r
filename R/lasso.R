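# Iterated LASSO arm: L1-penalized logistic regression with lambda tuned by
# pair-preserving 10-fold cross-validation maximizing AUC, repeated over
# many random 66/34 pair-preserving splits, with stability selection
# against a binomial random-selection null.

# Pair-level fold assignment: both members of a pair share a fold; singleton
# "pairs" (unpaired designs) are stratified by class.
#' @noRd
assign_pair_folds <- function(meta, sample_ids, n_folds, seed) {
  m <- meta_for_samples(meta, sample_ids)
  pair_tab <- unique(data.frame(pair_id = m$pair_id, stringsAsFactors = FALSE))
  # stratum per pair: "mixed" for complete case/control pairs, else the class
  stratum <- vapply(pair_tab$pair_id, function(p) {
    g <- unique(as.character(m$group[m$pair_id == p]))
    if (length(g) == 2L) "mixed" else g
  }, character(1))
  min_stratum <- min(table(stratum))
  folds_used <- n_folds
  if (min_stratum < n_folds) {
    folds_used <- max(2L, min_stratum)
    warning("reducing CV folds from ", n_folds, " to ", folds_used,
            " (smallest pair stratum has ", min_stratum, " pairs)")
  }
  pair_fold <- local_seed(seed, {
    out <- integer(nrow(pair_tab))
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      out[idx] <- sample(rep_len(seq_len(folds_used), length(idx)))
    }
    out
  })
  stats::setNames(pair_fold[match(m$pair_id, pair_tab$pair_id)], m$sample_id)
}

#' Fit an L1-penalized logistic model with CV-AUC lambda selection
#'
#' Builds a log-spaced lambda grid (100 values from the data-derived
#' lambda_max down to `lambda_min_ratio * lambda_max`), assigns
#' pair-preserving cross-validation folds, computes the pooled out-of-fold
#' AUC for every lambda, picks the lambda maximizing CV-AUC (ties favour the
#' larger, sparser lambda), and refits on the full training set.
#'
#' @param norm `tep_norm` or expression matrix.
#' @param meta sample metadata.
#' @param train_ids training sample ids.
#' @param lambda optional explicit lambda grid (descending).
#' @param n_folds cross-validation folds (reduced with a warning when a pair
#'   stratum is too small).
#' @param seed seed for fold assignment.
#' @param nlambda,lambda_min_ratio grid parameters when `lambda` is NULL.
#' @param thresh convergence threshold for the final coefficient fit.
#' @return a `lasso_model`: nonzero `coefficients`, `intercept`, chosen
#'   `lambda`, `cv_auc` (per-lambda vector plus the maximum), `panel`
#'   (nonzero-coefficient transcripts) and the fold assignment.
#' @export
fit_lasso_cv <- function(norm, meta, train_ids, lambda = NULL, n_folds = 10L,
                         seed = 1L, nlambda = 100L, lambda_min_ratio = 1e-4,
                         thresh = 1e-9) {
  values <- if (inherits(norm, "tep_norm")) norm$values else norm
  x <- t(values[, train_ids, drop = FALSE])
  m <- meta_for_samples(meta, train_ids)
  y <- as.integer(m$group == "case")
  if (length(unique(y)) < 2L) stop("training set needs both classes", call. = FALSE)

  if (is.null(lambda)) {
    fit0 <- glmnet::glmnet(x, y, family = "binomial", nlambda = 5,
                           lambda.min.ratio = 0.5)
    lmax <- fit0$lambda[1]
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }

  fold <- assign_pair_folds(meta, train_ids, n_folds, seed)
  folds_used <- max(fold)
  oof <- matrix(NA_real_, nrow = length(y), ncol = length(lambda))
  for (k in seq_len(folds_used)) {
    hold <- fold[train_ids] == k
    fit_k <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                            family = "binomial", lambda = lambda)
    oof[hold, ] <- stats::predict(fit_k, x[hold, , drop = FALSE], s = lambda,
                                  type = "link")
  }
  cv_auc <- apply(oof, 2, function(sc) fast_auc(sc, y == 1))
  best_idx <- which.max(cv_auc) # grid descends, so first max = largest lambda
  lambda_best <- lambda[best_idx]

  fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda, thresh = thresh)
  beta <- as.numeric(stats::predict(fit, s = lambda_best, type = "coefficients"))
  names(beta) <- c("(Intercept)", colnames(x))
  nz <- beta[-1][beta[-1] != 0]
  if (length(nz) == 0L) {
    warning("all coefficients shrunk to zero at every candidate lambda; ",
            "returning an intercept-only model")
  }
  structure(
    list(coefficients = nz, intercept = beta[1], lambda = lambda_best,
         lambda_grid = lambda, cv_auc = cv_auc, cv_auc_best = cv_auc[best_idx],
         panel = names(nz), folds = fold, split_seed = seed),
    class = "lasso_model"
  )
}

#' @exportS3Method base::print
print.lasso_model <- function(x, ...) {
  cat("LASSO logistic model: lambda =", signif(x$lambda, 4),
      ", panel size =", length(x$panel),
      ", CV AUC =", round(x$cv_auc_best, 3), "\n")
  invisible(x)
}

#' Score samples with a fitted LASSO model
#'
#' @param object a `lasso_model`.
#' @param norm `tep_norm` or expression matrix.
#' @param sample_ids samples to score (default: all columns).
#' @param ... unused.
#' @return named vector of case probabilities.
#' @export
predict.lasso_model <- function(object, norm, sample_ids = NULL, ...) {
  values <- if (inherits(norm, "tep_norm")) norm$values else norm
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  eta <- rep(object$intercept, length(sample_ids))
  if (length(object$coefficients)) {
    eta <- eta + as.numeric(crossprod(values[object$panel, sample_ids, drop = FALSE],
                                      object$coefficients))
  }
  stats::setNames(stats::plogis(eta), sample_ids)
}

#' Iterate LASSO classifier development over random splits
#'
#' Iteration i splits the pairs 66/34 (pair-preserving, split seed
#' `base_seed + i`), fits [fit_lasso_cv()] on the training portion and
#' scores the held-out validation portion. Intercept-only iterations are
#' recorded (validation AUC is still computed from the constant score, i.e.
#' 0.5), never dropped. Iterations depend only on their own seed, so the
#' ensemble is order-insensitive.
#'
#' @param norm `tep_norm` or expression matrix.
#' @param meta sample metadata for the matrix columns.
#' @param n_iter number of iterations.
#' @param split_fractions training/validation fractions.
#' @param base_seed iteration i uses seed `base_seed + i`.
#' @param n_folds,nlambda,lambda_min_ratio passed to [fit_lasso_cv()].
#' @param keep_models keep the fitted `lasso_model` objects (memory-heavy
#'   for large ensembles; panels and metrics are always kept).
#' @param threshold classification threshold for accuracy.
#' @return a `lasso_ensemble`: `metrics` (per-iteration seed, lambda,
#'   panel_size, auc, accuracy), `panels` (list of nonzero-coefficient
#'   transcript sets), `median_auc`, `auc_interval` (2.5/97.5 percentiles),
#'   `median_accuracy`, `mean_scores` (per-sample mean validation score
#'   across the iterations holding that sample out) and `pool` (candidate
#'   transcripts).
#' @export
iterate_models <- function(norm, meta, n_iter = 1000L,
                           split_fractions = c(0.66, 0.34), base_seed = 0L,
                           n_folds = 10L, nlambda = 100L, lambda_min_ratio = 1e-4,
                           keep_models = FALSE, threshold = 0.5) {
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  values <- if (inherits(norm, "tep_norm")) norm$values else norm
  m <- meta_for_samples(meta, colnames(values))
  score_sum <- stats::setNames(numeric(nrow(m)), m$sample_id)
  score_n <- stats::setNames(integer(nrow(m)), m$sample_id)
  metrics <- vector("list", n_iter)
  panels <- vector("list", n_iter)
  models <- if (keep_models) vector("list", n_iter) else NULL

  for (i in seq_len(n_iter)) {
    seed_i <- base_seed + i
    split <- split_pairs(m$pair_id, split_fractions, seed = seed_i)
    train_ids <- split_samples(split, m, "train")
    valid_ids <- split_samples(split, m, "validate")
    model <- suppressWarnings(
      fit_lasso_cv(values, m, train_ids, n_folds = n_folds, seed = seed_i,
                   nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)
    )
    scores <- predict.lasso_model(model, values, valid_ids)
    labels <- meta_for_samples(m, valid_ids)$group
    is_case <- labels == "case"
    auc <- if (length(unique(is_case)) == 2L) fast_auc(scores, is_case) else NA_real_
    acc <- mean((scores >= threshold) == is_case)
    metrics[[i]] <- data.frame(iter = i, seed = seed_i, lambda = model$lambda,
                               panel_size = length(model$panel),
                               auc = auc, accuracy = acc)
    panels[[i]] <- model$panel
    score_sum[valid_ids] <- score_sum[valid_ids] + scores
    score_n[valid_ids] <- score_n[valid_ids] + 1L
    if (keep_models) models[[i]] <- model
  }
  metrics <- do.call(rbind, metrics)
  mean_scores <- ifelse(score_n > 0, score_sum / score_n, NA_real_)
  structure(
    list(metrics = metrics, panels = panels, models = models,
         median_auc = stats::median(metrics$auc, na.rm = TRUE),
         auc_interval = stats::quantile(metrics$auc, c(0.025, 0.975),
                                        na.rm = TRUE, names = FALSE),
         median_accuracy = stats::median(metrics$accuracy),
         mean_scores = mean_scores,
         pool = rownames(values), n_iter = n_iter, base_seed = base_seed,
         threshold = threshold),
    class = "lasso_ensemble"
  )
}

#' @exportS3Method base::print
print.lasso_ensemble <- function(x, ...) {
  cat("LASSO ensemble:", x$n_iter, "iterations over", length(x$pool),
      "candidate transcripts\n")
  cat(sprintf("  median validation AUC %.3f (2.5-97.5%%: %.3f-%.3f), median accuracy %.1f%%\n",
              x$median_auc, x$auc_interval[1], x$auc_interval[2],
              100 * x$median_accuracy))
  invisible(x)
}

#' Per-transcript selection frequency across an ensemble
#'
#' @param ensemble a `lasso_ensemble`, or a list of panels (character
#'   vectors of selected transcripts).
#' @param pool the candidate transcript universe (required when `ensemble`
#'   is a bare list).
#' @return named integer vector over the pool; never-selected transcripts
#'   report 0.
#' @export
selection_frequency <- function(ensemble, pool = NULL) {
  if (inherits(ensemble, "lasso_ensemble")) {
    panels <- ensemble$panels
    pool <- ensemble$pool
  } else {
    panels <- ensemble
    if (is.null(pool)) stop("`pool` required when passing a bare panel list",
                            call. = FALSE)
  }
  if (length(panels) == 0L) stop("need at least one model", call. = FALSE)
  tab <- table(factor(unlist(panels), levels = pool))
  stats::setNames(as.integer(tab), pool)
}

#' Overrepresentation of selection frequencies vs a random-selection null
#'
#' Null model: each of the `n_iter` models selects its panel uniformly at
#' random from the pool, so a transcript's selection count is
#' Binomial(n_iter, p0) with p0 = mean panel size / pool size. The p-value
#' is the exact binomial tail P(X >= observed), BH-adjusted across the pool;
#' transcripts with q below `fdr_level` are flagged.
#'
#' @param counts named per-transcript selection counts (see
#'   [selection_frequency()]).
#' @param n_iter number of models.
#' @param pool_size candidate pool size (default `length(counts)`).
#' @param mean_panel_size average panel size across models.
#' @param fdr_level FDR threshold for flagging.
#' @return a `stability_result`: data.frame (`transcript`, `observed`,
#'   `expected`, `p_value`, `q_value`, `flagged`) ordered as the input, with
#'   `min_flagged_count` (smallest observed count among flagged transcripts,
#'   NA when none), `p0`, `n_iter`, `pool_size` and `mean_panel_size` as
#'   attributes.
#' @export
overrepresentation_test <- function(counts, n_iter, pool_size = length(counts),
                                    mean_panel_size, fdr_level = 0.001) {
  p0 <- mean_panel_size / pool_size
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
    stop("null selection probability must lie in (0, 1); got ", p0, call. = FALSE)
  }
  p <- stats::pbinom(counts - 1, size = n_iter, prob = p0, lower.tail = FALSE)
  q <- bh_fdr(p)
  flagged <- q < fdr_level
  out <- data.frame(
    transcript = names(counts), observed = as.integer(counts),
    expected = n_iter * p0, p_value = p, q_value = q, flagged = flagged,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out,
            min_flagged_count = if (any(flagged)) min(out$observed[flagged]) else NA_integer_,
            p0 = p0, n_iter = n_iter, pool_size = pool_size,
            mean_panel_size = mean_panel_size, fdr_level = fdr_level,
            class = c("stability_result", "data.frame"))
}

#' Run stability selection on a LASSO ensemble
#'
#' Convenience wrapper: selection frequencies plus
#' [overrepresentation_test()] with the realized mean panel size.
#'
#' @param ensemble a `lasso_ensemble`.
#' @param fdr_level FDR threshold for flagging.
#' @return a `stability_result`.
#' @export
stability_selection <- function(ensemble, fdr_level = 0.001) {
  stopifnot(inherits(ensemble, "lasso_ensemble"))
  counts <- selection_frequency(ensemble)
  overrepresentation_test(counts, n_iter = ensemble$n_iter,
                          pool_size = length(ensemble$pool),
                          mean_panel_size = mean(ensemble$metrics$panel_size),
                          fdr_level = fdr_level)
}

#' Rank transcripts by selection frequency
#'
#' @param result a `stability_result`.
#' @param k number of top transcripts to return (default: all).
#' @return the result rows sorted by observed frequency descending, ties
#'   broken by transcript id.
#' @export
top_transcripts <- function(result, k = Inf) {
  stopifnot(inherits(result, "stability_result"))
  ord <- order(-result$observed, result$transcript)
  out <- result[ord, , drop = FALSE]
  utils::head(out, n = min(k, nrow(out)))
}
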