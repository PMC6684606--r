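# Shared log-scale signal model for both generators.
#
# Each component i has a baseline log intensity drawn once. An experimental
# sample s observes
#   exp(baseline_i + shift_i(s) + bio_{s,i}) * exp(b_i * order_s) * analytical
# where shift_i(s) collects the planted diet/age/hierarchy log-e shifts for
# the sample's design cell, bio is biological noise (per bee), b_i is the
# per-component drift rate and analytical is per-injection noise. Internal
# and external QC injections are aliquots of the pooled cohort extract:
# their log intensity uses the cohort-mean planted shift and carries drift
# and analytical noise but no biological noise.
.simulate_matrix <- function(design, baselines, shift_mat_exp, drift_rates,
                             sigma_ana, sigma_bio) {
  n <- nrow(design)
  p <- length(baselines)
  is_exp <- design$sample_class == "experimental"
  log_int <- matrix(rep(baselines, each = n), nrow = n)
  qc_shift <- colMeans(shift_mat_exp)
  shift_all <- matrix(rep(qc_shift, each = n), nrow = n)
  shift_all[is_exp, ] <- shift_mat_exp
  log_int <- log_int + shift_all
  if (sigma_bio > 0) {
    bio <- matrix(stats::rnorm(sum(is_exp) * p, 0, sigma_bio), ncol = p)
    log_int[is_exp, ] <- log_int[is_exp, ] + bio
  }
  log_int <- log_int + outer(design$injection_order, drift_rates)
  log_int <- log_int + matrix(stats::rnorm(n * p, 0, 1), nrow = n) *
    matrix(rep(sigma_ana, each = n), nrow = n)
  exp(log_int)
}

# per-sample planted shift matrix (experimental rows only), natural-log units
.planted_shifts <- function(design_exp, p, spec) {
  ln2 <- log(2)
  vec <- function(idx, l2) {
    v <- numeric(p)
    if (length(idx) > 0L) v[idx] <- l2[seq_along(idx)] * ln2
    v
  }
  diet_v <- vec(spec$diet_components, spec$diet_log2_shift)
  age_v <- vec(spec$age_components, spec$age_log2_shift)
  hier_v <- vec(spec$hierarchy_components, spec$hierarchy_log2_shift)
  outer(as.numeric(design_exp$diet == "stress_25"), diet_v) +
    outer(as.numeric(design_exp$day == 12L), age_v) +
    outer(as.numeric(design_exp$caste == "pseudo_queen"), hier_v)
}

#' Generate the untargeted feature table with QC bracketing and drift
#'
#' Simulates the full injection run for the untargeted LC-MS assay:
#' log-normal component baselines, planted diet/age/hierarchy effects,
#' biological and analytical noise, per-component exponential
#' injection-order drift, and pooled-QC injections. Component annotations
#' (m/z in 53.4-800, retention time) are attached.
#'
#' @param design design table from [generate_design()].
#' @param effect an [effect_spec()]; defaults to
#'   [default_effect_spec()] for `config`.
#' @param config the [study_config()] used to build `design`.
#' @return A list with elements `table` (a [feature_table()] covering all
#'   injections) and `truth` (planted ground truth: diet/age/hierarchy
#'   shifts with the core-biomarker flag, per-component drift rates, and
#'   the analytically noisy component ids).
#' @export
generate_untargeted_table <- function(design, effect = NULL, config) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(effect)) effect <- default_effect_spec(config)
  p <- config$n_components
  universe <- seq_len(p)
  planted <- c(effect$diet_components, effect$age_components,
               effect$hierarchy_components, effect$noisy_components)
  if (length(planted) > 0L && !all(planted %in% universe)) {
    stop("generate_untargeted_table: effect components outside the ",
         "component universe (1..", p, ")", call. = FALSE)
  }

  set.seed(config$seed + 1001L)
  comp_ids <- sprintf("C%04d", universe)
  baselines <- stats::rnorm(p, log(5e6), 1)
  mz <- stats::runif(p, 53.4, 800)
  rt <- stats::runif(p, 0.5, 15)
  drift_rates <- -effect$drift_rate * stats::runif(p, 0.5, 1.5)

  sigma_ana <- rep(.lognorm_sd(effect$analytical_cv), p)
  if (length(effect$noisy_components) > 0L) {
    sigma_ana[effect$noisy_components] <- .lognorm_sd(effect$noisy_analytical_cv)
  }
  is_exp <- design$sample_class == "experimental"
  shifts <- .planted_shifts(design[is_exp, , drop = FALSE], p, effect)
  intensity <- .simulate_matrix(design, baselines, shifts, drift_rates,
                                sigma_ana, .lognorm_sd(effect$biological_cv))
  rownames(intensity) <- design$sample_id
  components <- data.frame(component_id = comp_ids, mz = mz, rt = rt,
                           stringsAsFactors = FALSE)
  tab <- feature_table(intensity, design, components)

  id_of <- function(idx) comp_ids[idx]
  truth <- list(
    diet = data.frame(
      component_id = id_of(effect$diet_components),
      log2_shift = effect$diet_log2_shift[seq_along(effect$diet_components)],
      core = effect$diet_components %in% effect$core_diet_components,
      stringsAsFactors = FALSE
    ),
    age = data.frame(
      component_id = id_of(effect$age_components),
      log2_shift = effect$age_log2_shift[seq_along(effect$age_components)],
      stringsAsFactors = FALSE
    ),
    hierarchy = data.frame(
      component_id = id_of(effect$hierarchy_components),
      log2_shift = effect$hierarchy_log2_shift[
        seq_along(effect$hierarchy_components)],
      stringsAsFactors = FALSE
    ),
    drift = data.frame(component_id = comp_ids, rate = drift_rates,
                       stringsAsFactors = FALSE),
    noisy_components = id_of(effect$noisy_components)
  )
  list(table = tab, truth = truth)
}

#' Default targeted metabolite panel
#'
#' A 64-metabolite semi-quantitative panel with the field-reported class
#' composition (20% amino acids, 19% carbohydrates, 25% carboxylic acids,
#' 36% various). Planted diet effects cover the nine key differential
#' metabolites: the syrup sugars sucrose and fructose decrease under the
#' low-carbohydrate diet, the blood sugar trehalose stays stable, and
#' histidine, arginine, asparagine, glutamine, acetylcarnitine and
#' homoserine increase. A modest age effect is planted on a subset of
#' metabolites.
#'
#' @param n_targeted panel size; panels smaller than 64 truncate the
#'   default list, larger panels append inert `various` metabolites.
#' @return A `data.frame` with columns `metabolite`, `chemical_class`,
#'   `diet_log2_shift`, `age_log2_shift`, `planted_direction`.
#' @export
default_targeted_panel <- function(n_targeted = 64L) {
  amino <- c("histidine", "arginine", "asparagine", "glutamine",
             "aspartic acid", "glutamic acid", "proline", "tryptophan",
             "beta-alanine", "homoserine", "hydroxyproline",
             "diaminopimelic acid", "beta-aminoisobutyric acid")
  carb <- c("sucrose", "fructose", "trehalose", "xylitol", "sorbitol",
            "ribose", "arabinose", "mannitol", "inositol", "erythritol",
            "rhamnose", "raffinose")
  carbox <- c("pipecolic acid", "dihydrocaffeic acid",
              "3,4-dihydroxybenzoic acid", "4-hydroxybenzoic acid",
              "3-hydroxybenzoic acid", "vanillic acid", "homovanillic acid",
              "3-hydroxycinnamic acid", "phenylacetic acid",
              "4-methylvaleric acid", "hexanoic acid", "myristoleic acid",
              "vaccenic acid", "citramalic acid", "alpha-ketoglutaric acid",
              "urocanic acid")
  various <- c("acetylcarnitine", "hypoxanthine", "inosine", "tryptamine",
               "phenylacetaldehyde", "trans-2-octenal", "3-methyl-2-butenal",
               "gamma-caprolactone", "methyl butyrate", "propyl acetate",
               "veratrole", "2,4-dimethyl-3-pentanone", "3-heptanone",
               "2-acetyl-5-methylfuran", "acetylpropionyl",
               "3-methyl-2-cyclohexen-1-one", "vanillylmandelic acid",
               "4-hexen-3-one", "3-phenyl-1-propanol", "styrene",
               "beta-pinene", "2,6-dimethylpyrazine", "pyrrole-2-carboxylic acid")
  panel <- data.frame(
    metabolite = c(amino, carb, carbox, various),
    chemical_class = rep(c("amino_acid", "carbohydrate", "carboxylic_acid",
                           "various"),
                         times = c(length(amino), length(carb),
                                   length(carbox), length(various))),
    stringsAsFactors = FALSE
  )
  panel$diet_log2_shift <- 0
  panel$age_log2_shift <- 0
  diet_eff <- c(sucrose = -1, fructose = -1, trehalose = 0,
                histidine = 0.4, arginine = 0.3, asparagine = 0.55,
                glutamine = 0.6, acetylcarnitine = 0.55, homoserine = 0.35)
  age_eff <- c(histidine = 0.4, arginine = 0.35, glutamine = 0.45,
               hydroxyproline = 0.5, "pipecolic acid" = 0.3,
               hypoxanthine = 0.6)
  panel$diet_log2_shift[match(names(diet_eff), panel$metabolite)] <- diet_eff
  panel$age_log2_shift[match(names(age_eff), panel$metabolite)] <- age_eff

  n_targeted <- as.integer(n_targeted)
  if (n_targeted < nrow(panel)) {
    panel <- panel[seq_len(n_targeted), , drop = FALSE]
  } else if (n_targeted > nrow(panel)) {
    extra <- data.frame(
      metabolite = sprintf("metabolite_%02d", seq.int(nrow(panel) + 1L,
                                                      n_targeted)),
      chemical_class = "various", diet_log2_shift = 0, age_log2_shift = 0,
      stringsAsFactors = FALSE
    )
    panel <- rbind(panel, extra)
  }
  panel$planted_direction <- ifelse(panel$diet_log2_shift > 0, "up",
                                    ifelse(panel$diet_log2_shift < 0,
                                           "down", "none"))
  rownames(panel) <- NULL
  panel
}

#' Generate the targeted metabolite table
#'
#' Simulates the semi-quantitative targeted assay over the same injection
#' run as the untargeted table, with one intensity column per panel
#' metabolite and the same noise/drift machinery. Metabolites with
#' `planted_direction = "down"` have lower stress-arm means, `"up"`
#' higher, `"none"` equal.
#'
#' @param design design table from [generate_design()].
#' @param panel a panel `data.frame` as from [default_targeted_panel()].
#' @param effect an [effect_spec()] supplying the noise and drift model
#'   (component index fields are ignored for the targeted assay).
#' @param config the [study_config()] used to build `design`.
#' @return A [feature_table()] whose `components` carry the panel
#'   annotations (chemical class, planted shifts and directions).
#' @export
generate_targeted_table <- function(design, panel = NULL, effect = NULL,
                                    config) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(panel)) panel <- default_targeted_panel(config$n_targeted)
  if (is.null(effect)) effect <- default_effect_spec(config)
  req <- c("metabolite", "diet_log2_shift", "age_log2_shift")
  if (!all(req %in% names(panel))) {
    stop("generate_targeted_table: panel must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  m <- nrow(panel)
  set.seed(config$seed + 2002L)
  baselines <- stats::rnorm(m, log(1e6), 0.8)
  drift_rates <- -effect$drift_rate * stats::runif(m, 0.5, 1.5)
  sigma_ana <- rep(.lognorm_sd(effect$analytical_cv), m)

  is_exp <- design$sample_class == "experimental"
  dexp <- design[is_exp, , drop = FALSE]
  ln2 <- log(2)
  shifts <- outer(as.numeric(dexp$diet == "stress_25"),
                  panel$diet_log2_shift * ln2) +
    outer(as.numeric(dexp$day == 12L), panel$age_log2_shift * ln2)
  intensity <- .simulate_matrix(design, baselines, shifts, drift_rates,
                                sigma_ana, .lognorm_sd(effect$biological_cv))
  rownames(intensity) <- design$sample_id
  components <- data.frame(component_id = panel$metabolite, panel[-1L],
                           stringsAsFactors = FALSE)
  feature_table(intensity, design, components)
}
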