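# Preprocessing: coverage and sample QC filters, matched-pair integrity,
# TMM normalization, log-CPM, and factor-based removal of unwanted
# variation (sex, library size).

#' @noRd
new_filter_report <- function(transcripts_in, transcripts_kept,
                              samples_in, samples_kept,
                              removed_samples = data.frame(sample_id = character(0),
                                                           reason = character(0)),
                              removed_transcripts = character(0)) {
  structure(
    list(transcripts_in = transcripts_in, transcripts_kept = transcripts_kept,
         samples_in = samples_in, samples_kept = samples_kept,
         removed_samples = removed_samples,
         removed_transcripts = removed_transcripts),
    class = "filter_report"
  )
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat("Filter report: transcripts", x$transcripts_in, "->", x$transcripts_kept,
      "; samples", x$samples_in, "->", x$samples_kept, "\n")
  if (nrow(x$removed_samples)) {
    print(table(x$removed_samples$reason))
  }
  invisible(x)
}

#' Coverage filter for transcripts
#'
#' Keeps transcript t iff the fraction of samples with count strictly greater
#' than `min_reads` is strictly greater than `min_fraction` (default: more
#' than 30 reads in more than 90% of samples). Both inequalities are strict.
#'
#' @param counts integer count matrix, transcripts x samples.
#' @param min_reads read-count threshold (a sample "covers" a transcript when
#'   its count exceeds this).
#' @param min_fraction required fraction of covering samples.
#' @return list with the filtered `counts` and a `report` (`filter_report`).
#' @export
filter_transcripts <- function(counts, min_reads = 30L, min_fraction = 0.90) {
  stop_if_not_count_matrix(counts)
  frac <- rowSums(counts > min_reads) / ncol(counts)
  keep <- frac > min_fraction
  report <- new_filter_report(
    transcripts_in = nrow(counts), transcripts_kept = sum(keep),
    samples_in = ncol(counts), samples_kept = ncol(counts),
    removed_transcripts = rownames(counts)[!keep]
  )
  list(counts = counts[keep, , drop = FALSE], report = report)
}

#' Quality filter for samples
#'
#' Drops a sample when it detects fewer than `min_detected_transcripts`
#' transcripts (count > 0), or when its mean reads per transcript (total
#' reads / number of transcripts currently in the matrix) falls below
#' `min_mean_reads_per_gene`. Reason codes: `low_transcript_count` takes
#' precedence when a sample fails both.
#'
#' @param counts integer count matrix, transcripts x samples.
#' @param min_detected_transcripts minimum number of detected transcripts.
#' @param min_mean_reads_per_gene minimum mean reads per transcript.
#' @return list with the filtered `counts` and a `report`.
#' @export
filter_samples <- function(counts, min_detected_transcripts = 750L,
                           min_mean_reads_per_gene = 1.0) {
  stop_if_not_count_matrix(counts)
  detected <- colSums(counts > 0)
  mean_reads <- colSums(counts) / nrow(counts)
  low_tx <- detected < min_detected_transcripts
  low_cov <- mean_reads < min_mean_reads_per_gene
  drop <- low_tx | low_cov
  if (all(drop)) stop("all samples removed by quality filters", call. = FALSE)
  removed <- data.frame(
    sample_id = colnames(counts)[drop],
    reason = ifelse(low_tx[drop], "low_transcript_count", "low_mean_coverage"),
    stringsAsFactors = FALSE
  )
  report <- new_filter_report(
    transcripts_in = nrow(counts), transcripts_kept = nrow(counts),
    samples_in = ncol(counts), samples_kept = sum(!drop),
    removed_samples = removed
  )
  list(counts = counts[, !drop, drop = FALSE], report = report)
}

#' Enforce matched-pair integrity
#'
#' Removes every sample whose matched partner is no longer present in the
#' matrix (e.g. dropped during quality control), so the resulting cohort
#' consists only of complete case/control pairs.
#'
#' @param counts count matrix whose columns are the surviving samples.
#' @param meta metadata covering the original cohort (`sample_id`, `group`,
#'   `pair_id`).
#' @return list with the filtered `counts`, the matching `meta` rows, and a
#'   `report` whose removed samples carry reason `unmatched_partner`.
#' @export
enforce_pairs <- function(counts, meta) {
  stop_if_not_count_matrix(counts)
  if (any(table(meta$pair_id) > 2L)) {
    stop("a pair_id occurs more than twice in the metadata", call. = FALSE)
  }
  present <- colnames(counts)
  m <- meta_for_samples(meta, present)
  partner_present <- vapply(seq_along(present), function(i) {
    mates <- meta$sample_id[meta$pair_id == m$pair_id[i] &
                              meta$sample_id != present[i]]
    length(mates) == 1L && mates %in% present
  }, logical(1))
  removed <- data.frame(
    sample_id = present[!partner_present],
    reason = rep("unmatched_partner", sum(!partner_present)),
    stringsAsFactors = FALSE
  )
  kept <- counts[, partner_present, drop = FALSE]
  meta_kept <- m[partner_present, , drop = FALSE]
  if (sum(meta_kept$group == "case") != sum(meta_kept$group == "control")) {
    stop("pair enforcement did not yield equal case and control counts; ",
         "check pair_id/group consistency", call. = FALSE)
  }
  report <- new_filter_report(
    transcripts_in = nrow(counts), transcripts_kept = nrow(counts),
    samples_in = ncol(counts), samples_kept = ncol(kept),
    removed_samples = removed
  )
  list(counts = kept, meta = meta_kept, report = report)
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes the Robinson-Oshlack TMM scaling factor for each sample against a
#' reference (by default the sample whose upper quartile is closest to the
#' mean upper quartile): a precision-weighted mean of per-transcript
#' log-ratios (M-values) after trimming `trim_m` from the M tails and
#' `trim_a` from the A (abundance) tails. Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts integer count matrix with positive column sums.
#' @param trim_m two-sided trim fraction on M-values.
#' @param trim_a two-sided trim fraction on A-values.
#' @param reference optional sample id to use as the reference column.
#' @return named positive numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, reference = NULL) {
  stop_if_not_count_matrix(counts)
  if (any(colSums(counts) == 0)) {
    stop("every sample must have a positive total count", call. = FALSE)
  }
  ref_col <- NULL
  if (!is.null(reference)) {
    ref_col <- match(reference, colnames(counts))
    if (is.na(ref_col)) stop("reference sample not found: ", reference, call. = FALSE)
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref_col,
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(f, colnames(counts))
}

#' Log2 counts-per-million transform
#'
#' `value[t, s] = log2((count[t, s] + prior_count) /
#' (libsize_s * factor_s + 2 * prior_count) * 1e6)`, with `libsize_s` the
#' column total and `factor_s` its TMM factor.
#'
#' @param counts integer count matrix.
#' @param factors per-sample positive normalization factors (aligned with
#'   columns); defaults to [tmm_factors()].
#' @param prior_count positive pseudo-count.
#' @return a `tep_norm` object: `values` (log2-CPM matrix), `tmm_factors`,
#'   `lib_size`, `prior_count`, and an empty `ruv` audit slot.
#' @export
log_cpm <- function(counts, factors = tmm_factors(counts), prior_count = 1.0) {
  stop_if_not_count_matrix(counts)
  if (length(factors) != ncol(counts) || any(factors <= 0)) {
    stop("`factors` must be positive and aligned with the samples", call. = FALSE)
  }
  if (prior_count <= 0) stop("`prior_count` must be positive", call. = FALSE)
  lib <- colSums(counts)
  denom <- lib * factors + 2 * prior_count
  values <- log2(sweep(counts + prior_count, 2, denom, "/") * 1e6)
  structure(
    list(values = values,
         tmm_factors = stats::setNames(as.numeric(factors), colnames(counts)),
         lib_size = lib,
         prior_count = prior_count,
         ruv = list(k_removed = 0L, removed = integer(0), screen = NULL)),
    class = "tep_norm"
  )
}

#' @exportS3Method base::print
print.tep_norm <- function(x, ...) {
  cat("Normalized TEP matrix:", nrow(x$values), "transcripts x",
      ncol(x$values), "samples (log2 CPM, prior", x$prior_count, ")\n")
  cat("  RUV factors removed:", x$ruv$k_removed, "\n")
  invisible(x)
}

# Association screen for one candidate factor's sample scores.
#' @noRd
screen_factor <- function(scores, nuisance_df, group, assoc_alpha) {
  p_nuis <- vapply(names(nuisance_df), function(nm) {
    v <- nuisance_df[[nm]]
    if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      if (nlevels(droplevels(v)) < 2L) return(NA_real_)
      stats::t.test(scores ~ droplevels(v))$p.value
    } else {
      if (stats::sd(v) == 0) return(NA_real_)
      stats::cor.test(scores, v)$p.value
    }
  }, numeric(1))
  # protected covariate: partial association of scores with group, adjusting
  # for the nuisance covariates (a purely nuisance-driven factor shows no
  # residual group association even when nuisance and group are correlated)
  p_group <- NA_real_
  if (!is.null(group) && nlevels(droplevels(factor(group))) == 2L) {
    dat <- cbind(data.frame(.scores = scores, .group = factor(group)), nuisance_df)
    fit <- stats::lm(.scores ~ ., data = dat)
    tab <- summary(fit)$coefficients
    row <- grep("^\\.group", rownames(tab))
    if (length(row) == 1L) p_group <- tab[row, 4]
  }
  list(p_nuisance = p_nuis, p_group = p_group,
       remove = any(p_nuis < assoc_alpha, na.rm = TRUE) &&
         (is.na(p_group) || p_group >= assoc_alpha))
}

#' Remove unwanted variation from a normalized matrix
#'
#' Two-stage correction for known nuisance covariates (by default sex and
#' log library size). Stage 1 screens the leading `k_max` singular vectors
#' of the row-centered expression matrix: a factor is flagged when its
#' sample scores associate with a nuisance covariate at `p < assoc_alpha`
#' (Welch t for binary covariates, Pearson correlation otherwise); the
#' factor's partial association with the protected covariate (case/control
#' group, adjusting for the nuisance covariates) is recorded for audit.
#' Stage 2, entered only when some factor is flagged, removes the flagged
#' covariates' fitted per-transcript contributions by linear regression with
#' the protected covariate in the design, so the disease contrast is
#' preserved exactly even though sex and group are correlated in this study
#' design. When nothing is flagged the input is returned unchanged, and a
#' second application is always a no-op (idempotence).
#'
#' @param norm a `tep_norm` object from [log_cpm()].
#' @param meta sample metadata aligned with the matrix columns.
#' @param nuisance covariate names; `"log_libsize"` is derived from the
#'   stored library sizes, other names are metadata columns.
#' @param protected name of the protected covariate (default `"group"`).
#' @param k_max number of leading factors screened.
#' @param assoc_alpha screening significance level.
#' @return the corrected `tep_norm`, with `ruv` recording the number of
#'   flagged factors (`k_removed`), their indices, the covariates removed
#'   and the full screening table.
#' @export
ruv_correct <- function(norm, meta, nuisance = c("sex", "log_libsize"),
                        protected = "group", k_max = 5L, assoc_alpha = 0.01) {
  stopifnot(inherits(norm, "tep_norm"))
  m <- meta_for_samples(meta, colnames(norm$values))

  nuisance_df <- data.frame(row.names = seq_len(ncol(norm$values)))
  for (nm in nuisance) {
    v <- if (nm == "log_libsize") log(norm$lib_size) else m[[nm]]
    if (is.null(v)) stop("nuisance covariate not available: ", nm, call. = FALSE)
    if ((is.factor(v) || is.character(v)) && nlevels(droplevels(factor(v))) < 2L) {
      warning("nuisance covariate '", nm, "' is constant; skipping it")
      next
    }
    nuisance_df[[nm]] <- v
  }
  if (ncol(nuisance_df) == 0L) {
    warning("no usable nuisance covariate; returning input unchanged")
    return(norm)
  }
  group <- if (!is.null(protected) && protected %in% names(m)) m[[protected]] else NULL

  X <- norm$values
  Xc <- X - rowMeans(X)
  k <- min(k_max, ncol(X) - 1L)
  sv <- svd(Xc, nu = 0, nv = k)
  res <- lapply(seq_len(k), function(j) {
    screen_factor(sv$v[, j], nuisance_df, group, assoc_alpha)
  })
  screen <- data.frame(
    factor = seq_len(k),
    singular_value = sv$d[seq_len(k)],
    p_group_partial = vapply(res, `[[`, numeric(1), "p_group")
  )
  flagged_cov <- character(0)
  for (nm in names(nuisance_df)) {
    p_nm <- vapply(res, function(r) r$p_nuisance[[nm]], numeric(1))
    screen[[paste0("p_", nm)]] <- p_nm
    if (any(p_nm < assoc_alpha, na.rm = TRUE)) flagged_cov <- c(flagged_cov, nm)
  }
  flagged_factor <- vapply(res, function(r) {
    any(r$p_nuisance < assoc_alpha, na.rm = TRUE)
  }, logical(1))
  screen$flagged <- flagged_factor

  out <- norm
  if (length(flagged_cov)) {
    # group-protected regression: subtract the nuisance terms of a joint
    # per-transcript linear fit that includes the protected covariate
    Z <- stats::model.matrix(
      ~ .,
      data = cbind(
        if (!is.null(group)) data.frame(.group = factor(group)) else NULL,
        nuisance_df[flagged_cov]
      )
    )
    nuis_cols <- !(colnames(Z) %in% c("(Intercept)")) &
      !startsWith(colnames(Z), ".group")
    beta <- qr.coef(qr(Z), t(X))
    beta[is.na(beta)] <- 0
    out$values <- X - t(Z[, nuis_cols, drop = FALSE] %*%
                          beta[nuis_cols, , drop = FALSE])
  }
  out$ruv <- list(k_removed = sum(flagged_factor),
                  removed = which(flagged_factor),
                  covariates_removed = flagged_cov,
                  screen = screen)
  out
}

#' Run the full preprocessing pipeline
#'
#' Transcript coverage filter, sample quality filters, matched-pair
#' enforcement, TMM normalization, log2-CPM transform and RUV correction, in
#' that order.
#'
#' @param counts raw integer count matrix.
#' @param meta cohort metadata.
#' @param min_reads,min_fraction see [filter_transcripts()].
#' @param min_detected_transcripts,min_mean_reads_per_gene see
#'   [filter_samples()].
#' @param prior_count see [log_cpm()].
#' @param ruv logical; apply [ruv_correct()]?
#' @param k_max,assoc_alpha RUV screening parameters.
#' @return list with `norm` (`tep_norm`), `meta` (surviving samples) and
#'   `reports` (one `filter_report` per stage).
#' @export
preprocess_cohort <- function(counts, meta,
                              min_reads = 30L, min_fraction = 0.90,
                              min_detected_transcripts = 750L,
                              min_mean_reads_per_gene = 1.0,
                              prior_count = 1.0,
                              ruv = TRUE, k_max = 5L, assoc_alpha = 0.01) {
  st1 <- filter_transcripts(counts, min_reads, min_fraction)
  st2 <- filter_samples(st1$counts, min_detected_transcripts, min_mean_reads_per_gene)
  st3 <- enforce_pairs(st2$counts, meta)
  norm <- log_cpm(st3$counts, tmm_factors(st3$counts), prior_count)
  if (ruv) norm <- ruv_correct(norm, st3$meta, k_max = k_max, assoc_alpha = assoc_alpha)
  list(norm = norm, meta = st3$meta,
       reports = list(transcripts = st1$report, samples = st2$report,
                      pairs = st3$report))
}
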