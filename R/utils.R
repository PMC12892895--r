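# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so package functions are deterministic without clobbering the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
stop_if_not_count_matrix <- function(counts) {
  if (!is.matrix(counts) || length(counts) == 0L) {
    stop("`counts` must be a non-empty matrix of read counts", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry transcript rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate transcript or sample identifiers in `counts`", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must contain non-negative integer read counts", call. = FALSE)
  }
  invisible(counts)
}

# Normalize a case/control label vector to a logical is-case indicator.
#' @noRd
as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  lab <- as.character(labels)
  ok <- lab %in% c("case", "control")
  if (!all(ok, na.rm = TRUE)) {
    stop("labels must be 'case'/'control' (or logical/0-1)", call. = FALSE)
  }
  lab == "case"
}

# Align metadata rows to a set of sample ids, erroring on absences.
#' @noRd
meta_for_samples <- function(meta, sample_ids) {
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx)) {
    stop("metadata missing for samples: ",
         paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  meta[idx, , drop = FALSE]
}
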