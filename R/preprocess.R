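#' Per-component %CV over internal QC injections
#'
#' Computes, for every component, the coefficient of variation
#' `100 * sd / mean` across the internal QC injections (pooled-extract
#' aliquots). Components with %CV below the repeatability threshold are
#' flagged as retained; components with a zero QC mean are flagged as not
#' retained. External conditioning QC injections never enter the
#' statistics. The standard deviation uses the n-1 denominator.
#'
#' @param table a [feature_table()] containing at least two
#'   `qc_internal` samples.
#' @param threshold_pct retention threshold; strictly below retains
#'   (default 30).
#' @return A `data.frame` (`component_id`, `cv_pct`, `retained`) of class
#'   `qc_cv_report`.
#' @export
compute_qc_cv <- function(table, threshold_pct = 30) {
  qc <- table$intensity[table$samples$sample_class == "qc_internal", ,
                        drop = FALSE]
  if (nrow(qc) < 2L) {
    stop("compute_qc_cv: at least 2 internal QC samples are required",
         call. = FALSE)
  }
  mu <- colMeans(qc)
  sdv <- apply(qc, 2L, stats::sd)
  cv <- ifelse(mu > 0, 100 * sdv / mu, NA_real_)
  rep <- data.frame(component_id = table$components$component_id,
                    cv_pct = cv,
                    retained = !is.na(cv) & cv < threshold_pct,
                    stringsAsFactors = FALSE)
  attr(rep, "threshold_pct") <- threshold_pct
  class(rep) <- c("qc_cv_report", "data.frame")
  rep
}

#' Drop components failing the QC repeatability filter
#'
#' @param table the [feature_table()] on which `report` was computed.
#' @param report a report from [compute_qc_cv()].
#' @param threshold_pct %CV threshold; components are kept when their QC
#'   %CV is strictly below it (default 30).
#' @return The filtered [feature_table()]; the numbers kept/removed are
#'   reported via `message()` and stored in attribute `"filter_log"`.
#' @export
filter_components <- function(table, report, threshold_pct = 30) {
  if (!identical(report$component_id, table$components$component_id)) {
    stop("filter_components: report was not computed on this table",
         call. = FALSE)
  }
  keep <- !is.na(report$cv_pct) & report$cv_pct < threshold_pct
  if (!any(keep)) {
    stop("filter_components: no components pass the %CV < ", threshold_pct,
         " filter", call. = FALSE)
  }
  out <- ft_subset_components(table, which(keep))
  message("filter_components: kept ", sum(keep), " of ", length(keep),
          " components (%CV < ", threshold_pct, ")")
  attr(out, "filter_log") <- list(kept = sum(keep),
                                  removed = sum(!keep),
                                  threshold_pct = threshold_pct)
  out
}

#' QC-pair drift normalization
#'
#' Divides the intensity of each component in every experimental sample by
#' the mean intensity of that component in the following two internal QC
#' injections (the duplicate QC pair injected after the sample's bracket).
#' Because drift acts multiplicatively and the QC pool is constant, the
#' division cancels instrument response drift up to the residual drift
#' accumulated between a sample and its following pair. QC rows are
#' dropped from the output.
#'
#' @param table a [feature_table()] in which every experimental sample has
#'   at least two internal QC injections at higher injection order.
#' @return The normalized experimental-only [feature_table()]; attribute
#'   `"normalization_audit"` maps each sample to the QC pair used.
#'   Components whose QC-pair mean is zero for some sample are removed
#'   with a warning.
#' @export
qc_bracket_normalize <- function(table) {
  smp <- table$samples
  qc_idx <- which(smp$sample_class == "qc_internal")
  exp_idx <- which(smp$sample_class == "experimental")
  if (length(exp_idx) == 0L) {
    stop("qc_bracket_normalize: table has no experimental samples ",
         "(already normalized?)", call. = FALSE)
  }
  if (length(qc_idx) < 2L) {
    stop("qc_bracket_normalize: at least one internal QC pair is required",
         call. = FALSE)
  }
  qc_orders <- smp$injection_order[qc_idx]
  norm <- table$intensity[exp_idx, , drop = FALSE]
  audit <- data.frame(sample_id = smp$sample_id[exp_idx],
                      qc1 = NA_character_, qc2 = NA_character_,
                      stringsAsFactors = FALSE)
  for (k in seq_along(exp_idx)) {
    i <- exp_idx[k]
    nxt <- qc_idx[qc_orders > smp$injection_order[i]]
    if (length(nxt) < 2L) {
      stop("qc_bracket_normalize: sample ", smp$sample_id[i],
           " has no following internal QC pair; regenerate the run with a ",
           "terminal QC pair", call. = FALSE)
    }
    pair <- nxt[1:2]
    ref <- colMeans(table$intensity[pair, , drop = FALSE])
    ref[ref == 0] <- NA_real_
    norm[k, ] <- norm[k, ] / ref
    audit$qc1[k] <- smp$sample_id[pair[1L]]
    audit$qc2[k] <- smp$sample_id[pair[2L]]
  }
  bad <- apply(norm, 2L, function(col) any(!is.finite(col)))
  if (any(bad)) {
    warning("qc_bracket_normalize: removed ", sum(bad),
            " component(s) with a zero QC-pair mean")
    norm <- norm[, !bad, drop = FALSE]
  }
  out <- feature_table(norm, smp[exp_idx, , drop = FALSE],
                       table$components[!bad, , drop = FALSE])
  attr(out, "normalization_audit") <- audit
  out
}

#' Column-wise centering and scaling
#'
#' Mean-centers every column and optionally scales: `"uv"` divides by the
#' column standard deviation (unit variance), `"pareto"` by its square
#' root, `"none"` centers only. Zero-variance columns are dropped with a
#' warning for `"uv"` and `"pareto"`. The fitted parameters are returned
#' so held-out data can be scaled with training-fold statistics.
#'
#' @param x numeric matrix.
#' @param method one of `"uv"`, `"pareto"`, `"none"`.
#' @return A list: `x` (scaled matrix), `center`, `scale`, `method`,
#'   `kept` (logical column mask).
#' @export
scale_center <- function(x, method = c("uv", "pareto", "none")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  ctr <- colMeans(x)
  v <- (colSums(x * x) - n * ctr^2) / (n - 1)
  v[v < 0] <- 0
  sdv <- sqrt(v)
  # treat columns as constant when their spread is at rounding level
  zero_var <- sdv <= 1e-10 * (abs(ctr) + 1)
  if (all(zero_var)) {
    stop("scale_center: all columns are constant", call. = FALSE)
  }
  kept <- rep(TRUE, ncol(x))
  if (method != "none") {
    kept <- !zero_var
    if (!all(kept)) {
      warning("scale_center: dropped ", sum(!kept), " zero-variance column(s)")
    }
  }
  scl <- switch(method,
                uv = sdv[kept],
                pareto = sqrt(sdv[kept]),
                none = rep(1, sum(kept)))
  xs <- sweep(x[, kept, drop = FALSE], 2L, ctr[kept], "-")
  xs <- sweep(xs, 2L, scl, "/")
  list(x = xs, center = ctr[kept], scale = scl, method = method, kept = kept,
       orig_names = colnames(x))
}

# apply stored scaling parameters to new data (columns already restricted)
apply_scaling <- function(x, scaling) {
  x <- x[, scaling$kept, drop = FALSE]
  xs <- sweep(x, 2L, scaling$center, "-")
  sweep(xs, 2L, scaling$scale, "/")
}
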