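#' Feature table container
#'
#' The object consumed and produced by every pipeline stage: a
#' samples-by-components intensity matrix with aligned sample metadata and
#' component annotations. Rows follow injection order; the matrix is kept
#' samples-as-rows internally regardless of the on-disk orientation of any
#' instrument export.
#'
#' @param intensity numeric matrix, samples x components, finite and
#'   non-negative, with row names equal to `samples$sample_id`.
#' @param samples `data.frame` of sample records (`sample_id`,
#'   `microcolony_id`, `diet`, `day`, `caste`, `injection_order`,
#'   `sample_class`), aligned to the matrix rows.
#' @param components optional `data.frame` of component annotations
#'   (`component_id`, optionally `mz`, `rt`), aligned to columns.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensity, samples, components = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("feature_table: intensity must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("feature_table: intensities must be finite", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("feature_table: intensities must be non-negative", call. = FALSE)
  }
  if (nrow(intensity) != nrow(samples)) {
    stop("feature_table: sample metadata rows must align with matrix rows",
         call. = FALSE)
  }
  if (is.null(rownames(intensity))) rownames(intensity) <- samples$sample_id
  if (!identical(rownames(intensity), as.character(samples$sample_id))) {
    stop("feature_table: matrix row names must equal samples$sample_id",
         call. = FALSE)
  }
  if (is.null(components)) {
    ids <- colnames(intensity)
    if (is.null(ids)) ids <- sprintf("C%04d", seq_len(ncol(intensity)))
    components <- data.frame(component_id = ids, stringsAsFactors = FALSE)
  }
  if (nrow(components) != ncol(intensity)) {
    stop("feature_table: component annotations must align with matrix columns",
         call. = FALSE)
  }
  colnames(intensity) <- components$component_id
  structure(list(intensity = intensity, samples = samples,
                 components = components),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$samples$sample_class)
  cat("feature_table: ", nrow(x$intensity), " samples x ",
      ncol(x$intensity), " components\n", sep = "")
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

# row subset keeping metadata aligned
ft_subset_samples <- function(ft, idx) {
  feature_table(ft$intensity[idx, , drop = FALSE],
                ft$samples[idx, , drop = FALSE],
                ft$components)
}

# column subset keeping annotations aligned
ft_subset_components <- function(ft, keep) {
  if (is.character(keep)) keep <- match(keep, ft$components$component_id)
  feature_table(ft$intensity[, keep, drop = FALSE],
                ft$samples,
                ft$components[keep, , drop = FALSE])
}

#' Restrict a feature table to experimental samples
#'
#' @param ft a [feature_table()].
#' @return The table without QC rows.
#' @export
experimental_samples <- function(ft) {
  ft_subset_samples(ft, ft$samples$sample_class == "experimental")
}
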