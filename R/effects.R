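#' Planted effect specification for the synthetic feature tables
#'
#' Describes the signal and noise model used by the generators. Effects are
#' planted as log2 fold changes: diet shifts apply to the 25%-syrup stress
#' arm, age shifts to day-12 samples, hierarchy shifts to pseudo-queens.
#' The hierarchy shift defaults to zero, reflecting the observed absence of
#' a clear hierarchy signature in hemolymph. Noise is multiplicative
#' log-normal: a biological component drawn once per experimental sample
#' and an analytical component drawn per injection (QC injections carry
#' analytical noise only, since they are aliquots of one pooled extract).
#' Injection-order drift is a per-component exponential decay of
#' sensitivity over the run.
#'
#' @param diet_components component indices (into the untargeted component
#'   universe) carrying a diet effect. The default plants 8 strong "core"
#'   biomarker components together with a diffuse 250-component metabolic
#'   shift, emulating the pervasive hemolymph response to carbohydrate
#'   restriction.
#' @param diet_log2_shift signed log2 shift(s) applied to the stress arm;
#'   recycled along `diet_components`.
#' @param age_components component indices carrying an age (day-12) effect.
#' @param age_log2_shift signed log2 shift(s) applied to day-12 samples.
#' @param hierarchy_components component indices carrying a hierarchy
#'   (pseudo-queen) effect; empty by default.
#' @param hierarchy_log2_shift signed log2 shift(s) for pseudo-queens
#'   (default 0).
#' @param core_diet_components subset of `diet_components` designated as
#'   the strong core biomarkers used for recovery assessment.
#' @param drift_rate mean per-injection exponential decay rate of the
#'   log intensity; per-component rates are drawn uniformly in
#'   `drift_rate * [0.5, 1.5]` (all zero when `drift_rate = 0`).
#' @param analytical_cv analytical (injection-to-injection) coefficient of
#'   variation, as a fraction in (0, 2).
#' @param biological_cv biological (bee-to-bee) coefficient of variation,
#'   as a fraction in (0, 2).
#' @param noisy_components component indices given an inflated analytical
#'   CV, emulating poorly repeatable features that the QC %CV filter
#'   should remove.
#' @param noisy_analytical_cv analytical CV for `noisy_components`.
#'
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(diet_components = integer(),
                        diet_log2_shift = 1,
                        age_components = integer(),
                        age_log2_shift = 0.9,
                        hierarchy_components = integer(),
                        hierarchy_log2_shift = 0,
                        core_diet_components = integer(),
                        drift_rate = 0.003,
                        analytical_cv = 0.08,
                        biological_cv = 0.30,
                        noisy_components = integer(),
                        noisy_analytical_cv = 0.60) {
  spec <- list(
    diet_components = as.integer(diet_components),
    diet_log2_shift = rep_len(diet_log2_shift, max(1L, length(diet_components))),
    age_components = as.integer(age_components),
    age_log2_shift = rep_len(age_log2_shift, max(1L, length(age_components))),
    hierarchy_components = as.integer(hierarchy_components),
    hierarchy_log2_shift = rep_len(hierarchy_log2_shift,
                                   max(1L, length(hierarchy_components))),
    core_diet_components = as.integer(core_diet_components),
    drift_rate = drift_rate,
    analytical_cv = analytical_cv,
    biological_cv = biological_cv,
    noisy_components = as.integer(noisy_components),
    noisy_analytical_cv = noisy_analytical_cv
  )
  for (cv in c("analytical_cv", "biological_cv", "noisy_analytical_cv")) {
    if (!(spec[[cv]] > 0 && spec[[cv]] < 2)) {
      stop("effect_spec: ", cv, " must lie in (0, 2)", call. = FALSE)
    }
  }
  if (length(spec$core_diet_components) > 0L &&
      !all(spec$core_diet_components %in% spec$diet_components)) {
    stop("effect_spec: core_diet_components must be a subset of diet_components",
         call. = FALSE)
  }
  class(spec) <- "effect_spec"
  spec
}

#' Default effect specification for a component universe
#'
#' Plants, into a universe of `n_components` untargeted components:
#' 8 strong core diet biomarkers (log2 shift +/-2), a diffuse diet
#' response over 250 further components (log2 shift +/-1), an age response
#' over 120 components (log2 shift +/-0.9), no hierarchy effect, and
#' 40 analytically noisy components (CV 60%) targeted by the QC filter.
#' Component indices are deterministic contiguous blocks; the exported
#' ground truth records them.
#'
#' @param config a [study_config()]; only `n_components` is used.
#' @param ... overrides forwarded to [effect_spec()].
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function(config, ...) {
  p <- config$n_components
  n_core <- min(8L, p)
  n_diff <- min(250L, max(0L, p - n_core))
  n_age <- min(120L, max(0L, p - n_core - n_diff))
  core <- seq_len(n_core)
  diffuse <- if (n_diff > 0L) n_core + seq_len(n_diff) else integer()
  age <- if (n_age > 0L) n_core + n_diff + seq_len(n_age) else integer()
  n_noisy <- min(40L, max(0L, p - n_core - n_diff - n_age))
  noisy <- if (n_noisy > 0L) p - seq_len(n_noisy) + 1L else integer()
  args <- list(
    diet_components = c(core, diffuse),
    diet_log2_shift = c(rep(c(2, -2), length.out = n_core),
                        rep(c(1, -1), length.out = n_diff)),
    age_components = age,
    age_log2_shift = rep(c(0.9, -0.9), length.out = max(1L, n_age)),
    core_diet_components = core,
    noisy_components = noisy
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(effect_spec, args)
}

# log-sd of a multiplicative log-normal noise term with the given CV
.lognorm_sd <- function(cv) sqrt(log(1 + cv^2))
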