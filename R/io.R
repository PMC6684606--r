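#' Write a feature table to TSV
#'
#' Writes the intensity matrix (rows = samples, first column `sample_id`)
#' and, optionally, the sample metadata as tab-separated files.
#'
#' @param ft a [feature_table()].
#' @param path intensity TSV path.
#' @param metadata_path optional sample-metadata TSV path.
#' @return Invisibly, the paths written.
#' @export
write_feature_table <- function(ft, path, metadata_path = NULL) {
  df <- data.frame(sample_id = ft$samples$sample_id, ft$intensity,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(ft$samples, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(path, metadata_path))
}

#' Read a feature table from TSV
#'
#' Reads the TSV dialect written by [write_feature_table()]; exports with
#' components as rows are auto-detected (the orientation whose labels
#' match the metadata sample ids is used) and transposed to the internal
#' samples-as-rows convention.
#'
#' @param path intensity TSV path.
#' @param metadata_path sample-metadata TSV path (join key `sample_id`).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, metadata_path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("read_feature_table: metadata lacks a sample_id column",
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("read_feature_table: duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L], call. = FALSE)
  }
  first <- names(raw)[1L]
  if (first == "sample_id" || all(raw[[1L]] %in% meta$sample_id)) {
    ids <- as.character(raw[[1L]])
    mat_df <- raw[-1L]
  } else if (all(names(raw)[-1L] %in% meta$sample_id)) {
    # components-as-rows export: transpose
    ids <- names(raw)[-1L]
    mat_df <- as.data.frame(t(raw[-1L]))
    names(mat_df) <- as.character(raw[[1L]])
  } else {
    stop("read_feature_table: cannot match table labels to metadata ",
         "sample ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup_row <- which(duplicated(ids))[1L]
    stop("read_feature_table: duplicate sample_id '", ids[dup_row],
         "' at data row ", dup_row, call. = FALSE)
  }
  for (j in seq_along(mat_df)) {
    v <- mat_df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("read_feature_table: non-numeric cell at row ", bad,
           ", column '", names(mat_df)[j], "'", call. = FALSE)
    }
  }
  orphans <- setdiff(meta$sample_id, ids)
  if (length(orphans) > 0L) {
    stop("read_feature_table: metadata rows without matrix rows: ",
         paste(utils::head(orphans, 5L), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(ids, meta$sample_id)
  if (length(extra) > 0L) {
    stop("read_feature_table: matrix rows without metadata: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(mat_df)
  rownames(mat) <- ids
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  feature_table(mat, meta)
}
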