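# Tab-separated readers/writers for count matrices, metadata and
# normalized matrices (values + JSON provenance sidecar).

#' Write / read a count matrix as tab-separated text
#'
#' Rows are transcripts (first column `transcript_id`), columns samples,
#' cells integer read counts.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param path file path.
#' @return `write_count_matrix()` returns `path` invisibly;
#'   `read_count_matrix()` returns an integer matrix with dimnames.
#' @export
write_count_matrix <- function(counts, path) {
  stop_if_not_count_matrix(counts)
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  stop_if_not_count_matrix(m)
}

#' Write / read a sample metadata table as tab-separated text
#'
#' Columns: `sample_id`, `group` (case/control), `pair_id`, `sex`, `age`,
#' `smoking_status`, `pack_years`, `alcohol_use`, `stage`, `hpv`, `site`.
#'
#' @param meta data.frame of per-sample metadata.
#' @param path file path.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("metadata must contain at least sample_id and group columns", call. = FALSE)
  }
  meta$group <- factor(meta$group, levels = c("case", "control"))
  if ("sex" %in% names(meta)) meta$sex <- factor(meta$sex, levels = c("female", "male"))
  if ("smoking_status" %in% names(meta)) {
    meta$smoking_status <- factor(meta$smoking_status,
                                  levels = c("never", "former", "current"))
  }
  meta
}

#' Write / read a normalized expression matrix with provenance
#'
#' The matrix of log2 counts-per-million is written as tab-separated text and
#' the normalization provenance (TMM factors, library sizes, prior count,
#' removed RUV factors) as a JSON sidecar at `<path>.json`.
#'
#' @param norm a `tep_norm` object from [log_cpm()] / [ruv_correct()].
#' @param path file path for the values table.
#' @export
write_normalized_matrix <- function(norm, path) {
  stopifnot(inherits(norm, "tep_norm"))
  df <- data.frame(transcript_id = rownames(norm$values), norm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    tmm_factors = as.list(norm$tmm_factors),
    lib_size = as.list(norm$lib_size),
    prior_count = norm$prior_count,
    ruv_factors_removed = norm$ruv$k_removed,
    ruv_removed_indices = norm$ruv$removed
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalized_matrix
#' @export
read_normalized_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(values = values,
         tmm_factors = unlist(side$tmm_factors),
         lib_size = unlist(side$lib_size),
         prior_count = side$prior_count,
         ruv = list(k_removed = side$ruv_factors_removed %||% 0L,
                    removed = side$ruv_removed_indices %||% integer(0),
                    screen = NULL)),
    class = "tep_norm"
  )
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
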