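# Propensity-score matching: logistic propensity model, greedy
# nearest-neighbor 1:1 matching within a caliper on the logit score,
# and covariate balance diagnostics.

#' Configure propensity matching
#'
#' @param covariates covariate names entering the propensity model.
#' @param ratio controls per case (only 1 supported).
#' @param caliper maximum match distance, in standard deviations of the logit
#'   propensity score.
#' @return a `match_config` list.
#' @export
match_config <- function(covariates = c("age", "smoking_status", "pack_years",
                                        "alcohol_use"),
                         ratio = 1L, caliper = 0.2) {
  if (length(covariates) == 0L) stop("covariates must be non-empty", call. = FALSE)
  if (caliper <= 0) stop("caliper must be positive", call. = FALSE)
  if (ratio != 1L) stop("only 1:1 matching is supported", call. = FALSE)
  structure(list(covariates = covariates, ratio = 1L, caliper = caliper),
            class = "match_config")
}

#' Estimate case-vs-control propensity scores
#'
#' Fits a logistic regression of case status on the covariates and returns
#' fitted probabilities. Perfect separation is reported as a warning and the
#' fit is ridge-stabilized (small L2 penalty via `glmnet`).
#'
#' @param meta sample metadata with a `group` column.
#' @param covariates covariate names (factors allowed).
#' @return named numeric vector of propensities in (0, 1), one per sample.
#' @export
estimate_propensity <- function(meta, covariates = c("age", "smoking_status",
                                                     "pack_years", "alcohol_use")) {
  miss <- covariates[!covariates %in% names(meta)]
  if (length(miss)) stop("covariates not in metadata: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  dat <- meta[, covariates, drop = FALSE]
  if (anyNA(dat)) stop("missing covariate values; impute or drop before matching",
                       call. = FALSE)
  y <- as.integer(meta$group == "case")
  form <- stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  dat$y <- y
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) {
    warning("perfect separation in the propensity model; ",
            "using a ridge-stabilized fit")
    X <- stats::model.matrix(form, dat)[, -1, drop = FALSE]
    rfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = 0.01, standardize = TRUE)
    p <- as.numeric(stats::predict(rfit, X, type = "response"))
  } else {
    p <- stats::fitted(fit)
  }
  stats::setNames(pmin(pmax(as.numeric(p), 1e-12), 1 - 1e-12), meta$sample_id)
}

#' Greedy nearest-neighbor matching within a caliper
#'
#' Matches controls to cases 1:1 without replacement on the logit propensity
#' score. Cases are processed in order of descending propensity
#' (hardest-to-match first); a control is eligible when its logit distance is
#' within `caliper` standard deviations of the logit score (SD over all
#' samples); ties are broken by control id. Cases with no eligible control
#' are reported unmatched.
#'
#' @param propensity named propensity vector from [estimate_propensity()].
#' @param meta sample metadata.
#' @param config a [match_config()].
#' @return a `match_result`: `pairs` (case_id, control_id, distance),
#'   `unmatched_cases`, `propensity`, and the absolute caliper used.
#' @export
match_nearest <- function(propensity, meta, config = match_config()) {
  stopifnot(inherits(config, "match_config"))
  m <- meta_for_samples(meta, names(propensity))
  lp <- stats::qlogis(propensity)
  case_ids <- m$sample_id[m$group == "case"]
  ctrl_ids <- m$sample_id[m$group == "control"]
  if (length(ctrl_ids) == 0L) stop("no controls available to match", call. = FALSE)
  caliper_abs <- config$caliper * stats::sd(lp)

  case_order <- case_ids[order(-propensity[case_ids], case_ids)]
  available <- stats::setNames(rep(TRUE, length(ctrl_ids)), ctrl_ids)
  pairs <- vector("list", length(case_order))
  unmatched <- character(0)
  for (i in seq_along(case_order)) {
    cid <- case_order[i]
    cand <- names(available)[available]
    if (length(cand)) {
      d <- abs(lp[cand] - lp[cid])
      cand <- cand[d <= caliper_abs]
      d <- d[d <= caliper_abs]
    }
    if (length(cand) == 0L) {
      unmatched <- c(unmatched, cid)
      next
    }
    best <- cand[order(d, cand)][1]
    available[best] <- FALSE
    pairs[[i]] <- data.frame(case_id = cid, control_id = best,
                             distance = unname(abs(lp[best] - lp[cid])),
                             stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs)) pairs <- data.frame(case_id = character(0),
                                          control_id = character(0),
                                          distance = numeric(0))
  structure(
    list(pairs = pairs, unmatched_cases = sort(unmatched),
         propensity = propensity, caliper_abs = caliper_abs, config = config),
    class = "match_result"
  )
}

#' @exportS3Method base::print
print.match_result <- function(x, ...) {
  cat("Propensity match:", nrow(x$pairs), "pairs,",
      length(x$unmatched_cases), "unmatched cases",
      sprintf("(caliper %.3f on the logit scale)\n", x$caliper_abs))
  invisible(x)
}

# Numeric encoding of a covariate for standardized mean differences:
# factors become their level codes (ordinal for smoking status).
#' @noRd
covariate_numeric <- function(v) {
  if (is.factor(v) || is.character(v)) as.numeric(factor(v)) else as.numeric(v)
}

#' @noRd
smd <- function(x_case, x_ctrl) {
  s <- sqrt((stats::var(x_case) + stats::var(x_ctrl)) / 2)
  if (!is.finite(s) || s == 0) {
    if (mean(x_case) == mean(x_ctrl)) return(0)
    return(Inf)
  }
  (mean(x_case) - mean(x_ctrl)) / s
}

# Two-group test: t when both groups look normal (Shapiro-Wilk p > 0.05),
# Wilcoxon rank-sum otherwise.
#' @noRd
two_group_test <- function(x_case, x_ctrl, test = c("auto", "t", "wilcoxon")) {
  test <- match.arg(test)
  if (test == "auto") {
    normal <- function(x) {
      if (length(unique(x)) < 3L || length(x) < 3L) return(FALSE)
      tryCatch(stats::shapiro.test(x)$p.value > 0.05, error = function(e) FALSE)
    }
    test <- if (normal(x_case) && normal(x_ctrl)) "t" else "wilcoxon"
  }
  p <- if (test == "t") {
    stats::t.test(x_case, x_ctrl)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(x_case, x_ctrl)$p.value)
  }
  list(p = p, test = test)
}

#' Covariate balance before and after matching
#'
#' For each covariate: the standardized mean difference (SMD, pooled-SD
#' denominator) between cases and all controls (pre) and between matched
#' cases and matched controls (post), plus two-group test p-values (two-sided
#' t test when both groups pass a Shapiro-Wilk normality check, Wilcoxon
#' rank-sum otherwise). Categorical covariates are encoded by their level
#' codes.
#'
#' @param meta sample metadata.
#' @param result a `match_result` from [match_nearest()].
#' @param covariates covariate names to report.
#' @param test `"auto"` (default), or force `"t"` / `"wilcoxon"`.
#' @return data.frame with columns `covariate`, `smd_pre`, `smd_post`,
#'   `p_pre`, `p_post`, `test_pre`, `test_post`.
#' @export
balance_diagnostics <- function(meta, result,
                                covariates = c("age", "smoking_status",
                                               "pack_years", "alcohol_use"),
                                test = "auto") {
  stopifnot(inherits(result, "match_result"))
  if (nrow(result$pairs) == 0L) stop("no matched pairs to diagnose", call. = FALSE)
  case_all <- meta[meta$group == "case", , drop = FALSE]
  ctrl_all <- meta[meta$group == "control", , drop = FALSE]
  case_m <- meta_for_samples(meta, result$pairs$case_id)
  ctrl_m <- meta_for_samples(meta, result$pairs$control_id)
  rows <- lapply(covariates, function(cv) {
    xa <- covariate_numeric(case_all[[cv]]); xb <- covariate_numeric(ctrl_all[[cv]])
    xm <- covariate_numeric(case_m[[cv]]);   xn <- covariate_numeric(ctrl_m[[cv]])
    t_pre <- two_group_test(xa, xb, test)
    t_post <- two_group_test(xm, xn, test)
    data.frame(covariate = cv,
               smd_pre = smd(xa, xb), smd_post = smd(xm, xn),
               p_pre = t_pre$p, p_post = t_post$p,
               test_pre = t_pre$test, test_post = t_post$test,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
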