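#' Stratified dataset suite for the OPLS-DA models
#'
#' Defines the classification datasets built from the 2 (diet) x 2 (day)
#' x 2 (caste) design cells: four diet-contrast datasets (day-12 workers;
#' all day-12 bees; all workers; the total cohort), two age-contrast
#' datasets (each diet arm separately, plus the total cohort) and the
#' hierarchy-contrast datasets. With the default design the instance
#' counts are 48, 64, 58, 84, 42, 42, 84, 64, 20 and 84.
#'
#' @return A named list of dataset specifications; each has `name`,
#'   `contrast` (`"diet"`, `"age"` or `"hierarchy"`) and `strata`, a
#'   `data.frame` of included (day, caste) cells (both diet arms are
#'   always included so the contrast classes are present).
#' @export
dataset_specs <- function() {
  cells <- function(day, caste) data.frame(day = day, caste = caste,
                                           stringsAsFactors = FALSE)
  all_cells <- cells(c(6L, 6L, 12L, 12L),
                     rep(c("worker", "pseudo_queen"), 2L))
  specs <- list(
    `1` = list(contrast = "diet", strata = cells(12L, "worker")),
    `2` = list(contrast = "diet",
               strata = cells(c(12L, 12L), c("worker", "pseudo_queen"))),
    `3` = list(contrast = "diet",
               strata = cells(c(6L, 12L), c("worker", "worker"))),
    T_diet = list(contrast = "diet", strata = all_cells),
    `4` = list(contrast = "age", diet_arm = "control_50",
               strata = all_cells),
    `5` = list(contrast = "age", diet_arm = "stress_25",
               strata = all_cells),
    T_age = list(contrast = "age", strata = all_cells),
    `6` = list(contrast = "hierarchy",
               strata = cells(c(12L, 12L), c("worker", "pseudo_queen"))),
    `7` = list(contrast = "hierarchy",
               strata = cells(c(6L, 6L), c("worker", "pseudo_queen"))),
    T_hierarchy = list(contrast = "hierarchy", strata = all_cells)
  )
  for (nm in names(specs)) specs[[nm]]$name <- nm
  specs
}

#' Restrict a feature table to one dataset specification
#'
#' @param table an experimental-only [feature_table()] with design
#'   metadata.
#' @param spec one element of [dataset_specs()] (or a list with the same
#'   shape).
#' @return A list: `table` (row-restricted [feature_table()]) and `class`
#'   (the contrast class vector: diet arm, day, or caste per sample).
#' @export
build_dataset <- function(table, spec) {
  smp <- table$samples
  if (any(smp$sample_class != "experimental")) {
    stop("build_dataset: table still contains QC samples; normalize first",
         call. = FALSE)
  }
  keep <- rep(FALSE, nrow(smp))
  for (i in seq_len(nrow(spec$strata))) {
    cell <- smp$day == spec$strata$day[i] & smp$caste == spec$strata$caste[i]
    if (!is.null(spec$diet_arm)) cell <- cell & smp$diet == spec$diet_arm
    if (!any(cell)) {
      stop("build_dataset: empty stratum (day=", spec$strata$day[i],
           ", caste=", spec$strata$caste[i],
           if (!is.null(spec$diet_arm)) paste0(", diet=", spec$diet_arm),
           ")", call. = FALSE)
    }
    keep <- keep | cell
  }
  sub <- ft_subset_samples(table, which(keep))
  cls <- switch(spec$contrast,
                diet = sub$samples$diet,
                age = paste0("day", sub$samples$day),
                hierarchy = sub$samples$caste,
                stop("build_dataset: unknown contrast ", spec$contrast,
                     call. = FALSE))
  if (length(unique(cls)) != 2L) {
    stop("build_dataset: contrast '", spec$contrast,
         "' has a single class in the selected strata", call. = FALSE)
  }
  list(table = sub, class = cls)
}

#' Fit and validate OPLS-DA models over a dataset suite
#'
#' For each dataset specification: builds the dataset, chooses the number
#' of orthogonal components ([select_n_orth()]), fits the model, runs the
#' full validation ([validate_oplsda()]) and computes VIP scores.
#' Datasets failing validation are flagged (`validated = FALSE`) and are
#' excluded from downstream biomarker selection; per-dataset errors are
#' caught and recorded without aborting the suite.
#'
#' @param table experimental-only [feature_table()] (normalized).
#' @param specs list of dataset specifications (default [dataset_specs()]).
#' @param n_folds,n_permutations,scale chemometrics settings.
#' @param max_orth cap on orthogonal components.
#' @param seed integer seed for fold draws and permutations.
#' @return A named list per dataset: `spec`, `n`, `model`, `validation`,
#'   `vip`, `validated`, or `error` when the fit failed.
#' @export
run_model_suite <- function(table, specs = dataset_specs(), n_folds = 7L,
                            n_permutations = 100L, max_orth = 5L,
                            seed = 1L, scale = "uv") {
  out <- list()
  for (nm in names(specs)) {
    res <- tryCatch({
      ds <- build_dataset(table, specs[[nm]])
      set.seed(seed)
      sel <- select_n_orth(ds$table$intensity, ds$class, max_orth = max_orth,
                           n_folds = n_folds, seed = NULL, scale = scale)
      model <- fit_oplsda(ds$table$intensity, ds$class, sel$n_orth, scale)
      val <- validate_oplsda(ds$table$intensity, ds$class, sel$n_orth,
                             n_folds = n_folds,
                             n_permutations = n_permutations,
                             seed = NULL, scale = scale)
      list(spec = specs[[nm]], n = nrow(ds$table$intensity), model = model,
           n_orth = sel$n_orth, validation = val, vip = compute_vip(model),
           validated = val$verdict == "good")
    }, error = function(e) {
      warning("run_model_suite: dataset ", nm, " failed: ",
              conditionMessage(e))
      list(spec = specs[[nm]], error = conditionMessage(e), validated = FALSE)
    })
    out[[nm]] <- res
  }
  class(out) <- "model_suite"
  out
}

#' Intersect VIP > threshold component sets across datasets
#'
#' Components exceeding the VIP threshold in every contributing dataset
#' form the conserved untargeted biomarker set. Ties at exactly the
#' threshold are excluded (strict `>`). The per-dataset counts (the Venn
#' set sizes) are recorded in the result.
#'
#' @param vip_tables named list of VIP tables ([compute_vip()]) over a
#'   common component universe; at least two.
#' @param threshold VIP threshold (default 1.0).
#' @return A list of class `biomarker_set`: `members` (conserved component
#'   ids), `source = "untargeted_intersection"`, `per_dataset_counts`, and
#'   `vip` (per-dataset VIP values of the members). An empty intersection
#'   warns but does not error.
#' @export
intersect_vip_sets <- function(vip_tables, threshold = 1.0) {
  if (length(vip_tables) < 2L) {
    stop("intersect_vip_sets: at least 2 VIP tables are required",
         call. = FALSE)
  }
  sets <- lapply(vip_tables, function(v) v$component_id[v$vip > threshold])
  members <- Reduce(intersect, sets)
  if (length(members) == 0L) {
    warning("intersect_vip_sets: empty intersection at VIP > ", threshold)
  }
  vip_of <- function(v) v$vip[match(members, v$component_id)]
  structure(list(members = members,
                 source = "untargeted_intersection",
                 threshold = threshold,
                 per_dataset_counts = vapply(sets, length, integer(1)),
                 vip = if (length(members) > 0L) {
                   as.data.frame(c(list(component_id = members),
                                   lapply(vip_tables, vip_of)),
                                 stringsAsFactors = FALSE)
                 } else {
                   NULL
                 }),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("biomarker_set (", x$source, "): ", length(x$members), " member(s)\n",
      sep = "")
  if (length(x$members) > 0L) {
    cat("  ", paste(utils::head(x$members, 12L), collapse = ", "),
        if (length(x$members) > 12L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Targeted two-way ANOVA biomarker screen
#'
#' Per metabolite, fits a two-way ANOVA with diet, day and their
#' interaction on log intensities (the multiplicative effect scale
#' implied by abundance-ratio reporting) and selects metabolites whose
#' diet main effect has P below `alpha`. No multiple-testing correction
#' is applied. Tukey HSD comparisons across the four diet-by-day cell
#' means are reported alongside. Caste is not a screen factor; castes are
#' pooled.
#'
#' @param table experimental-only targeted [feature_table()] (normalized).
#' @param alpha significance level for the diet term (default 0.05).
#' @param log_scale fit on log intensities (default TRUE).
#' @return A list of class `biomarker_set`: `members` (selected
#'   metabolites), `source = "targeted_anova"`, `anova` (per-metabolite
#'   diet/day/interaction P-values), `tukey` (per-metabolite Tukey HSD
#'   tables).
#' @export
targeted_anova_screen <- function(table, alpha = 0.05, log_scale = TRUE) {
  smp <- table$samples
  if (any(smp$sample_class != "experimental")) {
    stop("targeted_anova_screen: table still contains QC samples",
         call. = FALSE)
  }
  diet <- factor(smp$diet)
  day <- factor(smp$day)
  if (nlevels(diet) < 2L || nlevels(day) < 2L) {
    stop("targeted_anova_screen: both diet and day factors need 2 levels",
         call. = FALSE)
  }
  mets <- table$components$component_id
  res <- data.frame(metabolite = mets, p_diet = NA_real_, p_day = NA_real_,
                    p_interaction = NA_real_, stringsAsFactors = FALSE)
  tukey <- vector("list", length(mets))
  names(tukey) <- mets
  for (j in seq_along(mets)) {
    v <- table$intensity[, j]
    if (log_scale) {
      if (any(v <= 0)) {
        warning("targeted_anova_screen: skipping ", mets[j],
                " (non-positive intensities on log scale)")
        next
      }
      v <- log(v)
    }
    cell_tab <- table(diet, day)
    if (any(cell_tab == 0L)) {
      warning("targeted_anova_screen: skipping ", mets[j],
              " (empty diet x day cell)")
      next
    }
    fit <- stats::aov(v ~ diet * day)
    pv <- summary(fit)[[1]][["Pr(>F)"]]
    res$p_diet[j] <- pv[1L]
    res$p_day[j] <- pv[2L]
    res$p_interaction[j] <- pv[3L]
    cellf <- interaction(diet, day, drop = TRUE)
    tukey[[j]] <- stats::TukeyHSD(stats::aov(v ~ cellf))$cellf
  }
  members <- res$metabolite[!is.na(res$p_diet) & res$p_diet < alpha]
  structure(list(members = members, source = "targeted_anova",
                 alpha = alpha, anova = res, tukey = tukey),
            class = "biomarker_set")
}

#' Combine untargeted and targeted biomarker sets
#'
#' @param untargeted,targeted `biomarker_set` objects.
#' @return A `biomarker_set` with `source = "combined"` whose members are
#'   the union of the two input sets.
#' @export
combine_biomarker_sets <- function(untargeted, targeted) {
  structure(list(members = union(untargeted$members, targeted$members),
                 source = "combined",
                 untargeted = untargeted$members,
                 targeted = targeted$members),
            class = "biomarker_set")
}

#' Stress-to-control abundance ratio table
#'
#' Per metabolite and per (day, caste) stratum, the ratio of the
#' stress-arm mean intensity to the control-arm mean intensity, on the
#' raw (un-logged) scale.
#'
#' @param table experimental-only targeted [feature_table()].
#' @return A `data.frame` with one row per metabolite and one ratio
#'   column per (day, caste) cell
#'   (`ratio_day6_pseudo_queen`, `ratio_day6_worker`,
#'   `ratio_day12_pseudo_queen`, `ratio_day12_worker`). Zero control
#'   means give `NA` with a warning.
#' @export
compute_ratio_table <- function(table) {
  smp <- table$samples
  if (any(smp$sample_class != "experimental")) {
    stop("compute_ratio_table: table still contains QC samples", call. = FALSE)
  }
  out <- data.frame(metabolite = table$components$component_id,
                    stringsAsFactors = FALSE)
  n_zero <- 0L
  for (day in c(6L, 12L)) {
    for (caste in c("pseudo_queen", "worker")) {
      in_cell <- smp$day == day & smp$caste == caste
      stress <- in_cell & smp$diet == "stress_25"
      control <- in_cell & smp$diet == "control_50"
      if (!any(stress) || !any(control)) {
        stop("compute_ratio_table: stratum day=", day, " caste=", caste,
             " lacks one diet arm", call. = FALSE)
      }
      ms <- colMeans(table$intensity[stress, , drop = FALSE])
      mc <- colMeans(table$intensity[control, , drop = FALSE])
      ratio <- ifelse(mc > 0, ms / mc, NA_real_)
      n_zero <- n_zero + sum(mc == 0)
      out[[sprintf("ratio_day%d_%s", day, caste)]] <- ratio
    }
  }
  if (n_zero > 0L) {
    warning("compute_ratio_table: ", n_zero,
            " ratio(s) undefined (zero control mean)")
  }
  out
}
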