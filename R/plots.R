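# Cosmetic figure helpers (score plot, S-plot, pathway bubble plot).

#' OPLS-DA score plot
#'
#' Predictive score against the first orthogonal score (or sample index
#' when the model has no orthogonal component), colored by class.
#'
#' @param model an [fit_oplsda()] model.
#' @param class_labels class vector used at fit time.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plotted coordinates.
#' @export
plot_scores <- function(model, class_labels, ...) {
  y <- if (model$n_orth > 0L) model$T_o[, 1L] else seq_along(model$t_p)
  cls <- factor(class_labels)
  graphics::plot(model$t_p, y, col = as.integer(cls), pch = 19,
                 xlab = "t[p] (predictive)",
                 ylab = if (model$n_orth > 0L) "t[o] (orthogonal)" else
                   "sample index", ...)
  graphics::legend("topright", legend = levels(cls),
                   col = seq_len(nlevels(cls)), pch = 19, bty = "n")
  invisible(cbind(t_p = model$t_p, t_o = y))
}

#' S-plot
#'
#' @param coords output of [splot_coordinates()].
#' @param vip optional VIP table to highlight components with VIP > 1.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `coords`.
#' @export
plot_splot <- function(coords, vip = NULL, ...) {
  col <- "grey40"
  if (!is.null(vip)) {
    col <- ifelse(vip$vip[match(coords$component_id, vip$component_id)] > 1,
                  "red3", "grey40")
  }
  graphics::plot(coords$covariance, coords$correlation, col = col, pch = 20,
                 xlab = "cov(t[p], x)", ylab = "corr(t[p], x)", ...)
  invisible(coords)
}

#' Pathway impact bubble plot
#'
#' -log10(p) against topology impact, bubble area by hit count.
#'
#' @param results a `pathway_results` data frame from [analyze_pathways()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `results`.
#' @export
plot_pathway_impact <- function(results, ...) {
  graphics::plot(results$impact, -log10(results$p_value),
                 cex = 1 + results$hits,
                 col = ifelse(results$significant, "red3", "grey50"),
                 pch = 19, xlab = "pathway impact", ylab = "-log10(p)", ...)
  graphics::abline(h = -log10(0.05), lty = 2)
  invisible(results)
}
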