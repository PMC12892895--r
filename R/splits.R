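# Pair-preserving random partitioning of a matched cohort.

#' Randomly split matched pairs into analysis sets
#'
#' Shuffles the pairs under `seed` and assigns `floor(fraction * n_pairs)`
#' pairs to each set, with the remainder going to the first (training) set.
#' Both members of a pair always share a set. Three fractions name the sets
#' `train`/`eval`/`validate`; two name them `train`/`validate`.
#'
#' @param pair_ids character vector of pair identifiers (duplicates allowed;
#'   the unique set is partitioned).
#' @param fractions numeric vector summing to 1 (length 2 or 3, or named).
#' @param seed integer seed for the shuffle.
#' @return a `split_assignment`: data.frame (`pair_id`, `set`) with the
#'   fractions and seed attached as attributes.
#' @examples
#' s <- split_pairs(sprintf("P%03d", 1:101), c(0.4, 0.3, 0.3), seed = 1)
#' table(s$set)
#' @export
split_pairs <- function(pair_ids, fractions, seed) {
  pairs <- unique(as.character(pair_ids))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (length(pairs) < length(fractions)) {
    stop("fewer pairs than sets", call. = FALSE)
  }
  set_names <- names(fractions)
  if (is.null(set_names)) {
    set_names <- switch(as.character(length(fractions)),
                        "2" = c("train", "validate"),
                        "3" = c("train", "eval", "validate"),
                        paste0("set", seq_along(fractions)))
  }
  n <- length(pairs)
  sizes <- floor(fractions * n)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  shuffled <- local_seed(seed, sample(pairs))
  assignment <- data.frame(
    pair_id = shuffled,
    set = rep(set_names, times = sizes),
    stringsAsFactors = FALSE
  )
  assignment <- assignment[order(match(assignment$pair_id, pairs)), , drop = FALSE]
  rownames(assignment) <- NULL
  structure(assignment, fractions = fractions, seed = as.integer(seed),
            class = c("split_assignment", "data.frame"))
}

# Sample ids belonging to a given set of a split.
#' @noRd
split_samples <- function(split, meta, set) {
  keep_pairs <- split$pair_id[split$set == set]
  meta$sample_id[meta$pair_id %in% keep_pairs]
}
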