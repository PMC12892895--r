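# ROC/AUC machinery, DeLong confidence intervals, subgroup accuracy tables,
# and the HPV-prediction and downsampling experiments.

# Rank-based AUC (Mann-Whitney with ties counted 1/2); the workhorse used
# inside the optimizer and ensemble loops.
#' @noRd
fast_auc <- function(scores, labels) {
  is_case <- as_case_indicator(labels)
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`, with ties contributing 1/2. The ROC is traced at the
#' unique score thresholds (descending), starts at (0, 0) and ends at
#' (1, 1), and its trapezoidal area equals the rank AUC exactly.
#'
#' @param scores numeric scores, larger = more case-like.
#' @param labels case/control labels (factor/character `case`/`control`,
#'   logical, or 0/1).
#' @return list with `auc` and `roc` (data.frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  is_case <- as_case_indicator(labels)
  auc <- fast_auc(scores, is_case)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- is_case[ord]
  # collapse tied thresholds
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(!y)[last_of_tie]
  roc <- data.frame(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / sum(!is_case)),
    tpr = c(0, tp / sum(is_case))
  )
  list(auc = auc, roc = roc)
}

#' DeLong confidence interval for an AUC
#'
#' Normal-approximation interval from the DeLong variance estimate,
#' truncated to [0, 1]. A degenerate AUC of exactly 0 or 1 collapses the
#' interval, with a warning.
#'
#' @param scores numeric scores.
#' @param labels case/control labels.
#' @param level confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
auc_ci_delong <- function(scores, labels, level = 0.95) {
  is_case <- as_case_indicator(labels)
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("need at least 2 samples per class for a DeLong interval", call. = FALSE)
  }
  r <- pROC::roc(response = is_case, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  if (auc %in% c(0, 1)) {
    warning("degenerate AUC of ", auc, "; interval collapses to a point")
    return(c(auc, auc))
  }
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = level, method = "delong"))
  c(max(0, ci[1]), min(1, ci[3]))
}

#' Evaluate a set of prediction scores
#'
#' Full performance summary: per-sample predicted labels at the threshold,
#' accuracy, ROC curve, AUC and its DeLong confidence interval.
#'
#' @param scores named numeric case-probability scores.
#' @param labels case/control labels aligned with `scores`.
#' @param threshold classification threshold (score >= threshold -> case).
#' @param ci_level confidence level for the AUC interval (NULL to skip).
#' @return a `prediction_result`: `scores`, `labels`, `predicted`,
#'   `threshold`, `accuracy`, `auc`, `ci`, `roc`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5, ci_level = 0.95) {
  is_case <- as_case_indicator(labels)
  ra <- roc_auc(scores, is_case)
  predicted <- ifelse(scores >= threshold, "case", "control")
  accuracy <- mean((predicted == "case") == is_case)
  ci <- if (is.null(ci_level)) c(NA_real_, NA_real_) else
    suppressWarnings(auc_ci_delong(scores, is_case, ci_level))
  structure(
    list(scores = scores, labels = is_case, predicted = predicted,
         threshold = threshold, accuracy = accuracy,
         auc = ra$auc, ci = ci, roc = ra$roc),
    class = "prediction_result"
  )
}

#' @exportS3Method base::print
print.prediction_result <- function(x, ...) {
  cat(sprintf("Prediction result: AUC %.3f (95%% CI %.3f-%.3f), accuracy %.1f%% at threshold %.2f\n",
              x$auc, x$ci[1], x$ci[2], 100 * x$accuracy, x$threshold))
  invisible(x)
}

#' Accuracy within clinical subgroups
#'
#' Splits the case samples by disease stage (early = I/II vs advanced =
#' III/IV) or HPV status and reports the fraction correctly classified in
#' each subgroup at the threshold; controls are reported as their own row.
#'
#' @param scores named case-probability scores (e.g. the per-sample mean
#'   validation scores of a [iterate_models()] ensemble, or a single
#'   model's scores).
#' @param meta sample metadata for the scored samples.
#' @param partition `"stage"` or `"hpv"`.
#' @param threshold classification threshold.
#' @return a `subgroup_table` data.frame: `subgroup`, `n`, `n_correct`,
#'   `accuracy` (NA for empty subgroups).
#' @export
subgroup_accuracy <- function(scores, meta, partition = c("stage", "hpv"),
                              threshold = 0.5) {
  partition <- match.arg(partition)
  scores <- scores[!is.na(scores)]
  m <- meta_for_samples(meta, names(scores))
  is_case <- m$group == "case"
  correct <- (scores >= threshold) == is_case

  subgroup <- rep(NA_character_, nrow(m))
  subgroup[!is_case] <- "control"
  if (partition == "stage") {
    subgroup[is_case & m$stage %in% c("I", "II")] <- "early_stage"
    subgroup[is_case & m$stage %in% c("III", "IV")] <- "advanced_stage"
    levels_out <- c("early_stage", "advanced_stage", "control")
  } else {
    subgroup[is_case & !is.na(m$hpv) & m$hpv == "positive"] <- "hpv_positive"
    subgroup[is_case & !is.na(m$hpv) & m$hpv == "negative"] <- "hpv_negative"
    levels_out <- c("hpv_positive", "hpv_negative", "control")
  }
  rows <- lapply(levels_out, function(g) {
    idx <- !is.na(subgroup) & subgroup == g
    n <- sum(idx)
    data.frame(subgroup = g, n = n,
               n_correct = if (n) sum(correct[idx]) else 0L,
               accuracy = if (n) mean(correct[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("subgroup_table", "data.frame"))
}

#' Predict a clinical covariate from expression with the LASSO ensemble
#'
#' Relabels a subset of samples by a binary target covariate (by default
#' HPV status among oropharyngeal cases) and reuses the full iterated-LASSO
#' machinery with each sample as its own unit (no pairing).
#'
#' @param norm `tep_norm` or expression matrix.
#' @param meta sample metadata.
#' @param target metadata column used as the outcome (`"hpv"`, or
#'   `"group"` as a sanity identity).
#' @param positive level of `target` treated as case (default
#'   `"positive"`; for `target = "group"`, `"case"`).
#' @param subset logical vector over metadata rows selecting the analysis
#'   samples; default: oropharyngeal cases for `"hpv"`, everyone otherwise.
#' @param n_iter,base_seed,... passed to [iterate_models()].
#' @return a `lasso_ensemble`.
#' @export
predict_covariate <- function(norm, meta, target = "hpv",
                              positive = if (target == "group") "case" else "positive",
                              subset = NULL, n_iter = 100L, base_seed = 0L, ...) {
  values <- if (inherits(norm, "tep_norm")) norm$values else norm
  m <- meta_for_samples(meta, colnames(values))
  if (is.null(subset)) {
    subset <- if (target == "hpv") {
      m$group == "case" & !is.na(m$site) & m$site == "oropharynx"
    } else rep(TRUE, nrow(m))
  }
  m2 <- m[subset, , drop = FALSE]
  lab <- as.character(m2[[target]])
  if (anyNA(lab)) stop("target covariate has missing values on the subset", call. = FALSE)
  if (length(unique(lab)) != 2L) {
    stop("target covariate must be binary on the analyzed subset", call. = FALSE)
  }
  m2$group <- factor(ifelse(lab == positive, "case", "control"),
                     levels = c("case", "control"))
  m2$pair_id <- m2$sample_id  # unpaired design: each sample its own unit
  iterate_models(values[, m2$sample_id, drop = FALSE], m2,
                 n_iter = n_iter, base_seed = base_seed, ...)
}

#' Downsample the cohort and rerun the LASSO ensemble
#'
#' Randomly keeps `n_pairs_out` complete pairs (pair-preserving) and runs
#' [iterate_models()] on the subsample.
#'
#' @param norm `tep_norm` or expression matrix.
#' @param meta sample metadata.
#' @param n_pairs_out number of pairs to keep (>= 4, at most the number
#'   available; keeping all pairs reproduces the full analysis).
#' @param seed seed for the pair subsample.
#' @param n_iter,base_seed,... passed to [iterate_models()].
#' @return a `lasso_ensemble` on the subsample.
#' @export
downsample_experiment <- function(norm, meta, n_pairs_out, seed = 1L,
                                  n_iter = 100L, base_seed = 0L, ...) {
  values <- if (inherits(norm, "tep_norm")) norm$values else norm
  m <- meta_for_samples(meta, colnames(values))
  pairs <- unique(m$pair_id)
  if (n_pairs_out < 4L) stop("n_pairs_out must be >= 4 to allow splitting", call. = FALSE)
  if (n_pairs_out > length(pairs)) stop("n_pairs_out exceeds available pairs", call. = FALSE)
  keep_pairs <- if (n_pairs_out == length(pairs)) pairs else
    local_seed(seed, sample(pairs, n_pairs_out))
  keep <- m$pair_id %in% keep_pairs
  iterate_models(values[, m$sample_id[keep], drop = FALSE],
                 m[keep, , drop = FALSE],
                 n_iter = n_iter, base_seed = base_seed, ...)
}
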