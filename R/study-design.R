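#' Study configuration for the simulated hemolymph cohort
#'
#' Defines the microcolony study design: queen-less microcolonies of
#' *Bombus terrestris* workers are assigned to a nutritional-stress arm
#' (25% sugar syrup) or a control arm (50% sugar syrup), and hemolymph is
#' sampled at day 6 (one worker and the dominant pseudo-queen per
#' microcolony) or at day 12 (three workers and the pseudo-queen).
#' The defaults reproduce the 26-microcolony / 130-bee cohort with
#' 84 experimental hemolymph samples.
#'
#' @param n_microcolonies_per_arm microcolonies per diet arm (default 13).
#' @param bees_per_microcolony workers housed per microcolony (default 5).
#' @param day6_microcolonies_per_arm microcolonies sampled at day 6 (default 5).
#' @param day6_specimens_per_microcolony specimens sampled per day-6
#'   microcolony; one is the pseudo-queen, the rest are workers (default 2).
#' @param day12_microcolonies_per_arm microcolonies sampled at day 12
#'   (default 8).
#' @param day12_specimens_per_microcolony specimens sampled per day-12
#'   microcolony; one is the pseudo-queen (default 4).
#' @param n_components number of untargeted LC-MS components (default 2197).
#' @param n_targeted number of targeted panel metabolites (default 64).
#' @param qc_every duplicate internal QC injections follow every
#'   `qc_every` experimental injections (default 9).
#' @param n_conditioning_qc external QC injections used to condition the
#'   instrument at the start of the run; excluded from all statistics
#'   (default 3).
#' @param seed integer seed controlling injection-order randomization and
#'   all downstream simulation noise.
#'
#' @return An object of class `study_config` (a validated list).
#' @export
#' @examples
#' cfg <- study_config()
#' des <- generate_design(cfg)
#' table(des$sample_class)
study_config <- function(n_microcolonies_per_arm = 13,
                         bees_per_microcolony = 5,
                         day6_microcolonies_per_arm = 5,
                         day6_specimens_per_microcolony = 2,
                         day12_microcolonies_per_arm = 8,
                         day12_specimens_per_microcolony = 4,
                         n_components = 2197,
                         n_targeted = 64,
                         qc_every = 9,
                         n_conditioning_qc = 3,
                         seed = 1L) {
  cfg <- list(
    n_microcolonies_per_arm = as.integer(n_microcolonies_per_arm),
    bees_per_microcolony = as.integer(bees_per_microcolony),
    day6_microcolonies_per_arm = as.integer(day6_microcolonies_per_arm),
    day6_specimens_per_microcolony = as.integer(day6_specimens_per_microcolony),
    day12_microcolonies_per_arm = as.integer(day12_microcolonies_per_arm),
    day12_specimens_per_microcolony = as.integer(day12_specimens_per_microcolony),
    n_components = as.integer(n_components),
    n_targeted = as.integer(n_targeted),
    qc_every = as.integer(qc_every),
    n_conditioning_qc = as.integer(n_conditioning_qc),
    seed = as.integer(seed)
  )
  counts <- cfg[setdiff(names(cfg), c("seed", "n_conditioning_qc"))]
  bad <- names(counts)[vapply(counts, function(x) is.na(x) || x < 1L, logical(1))]
  if (length(bad) > 0L) {
    stop("study_config: counts must be >= 1; violated by: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$n_conditioning_qc < 0L) {
    stop("study_config: n_conditioning_qc must be >= 0", call. = FALSE)
  }
  if (cfg$day6_microcolonies_per_arm + cfg$day12_microcolonies_per_arm !=
      cfg$n_microcolonies_per_arm) {
    stop("study_config: day6_microcolonies_per_arm + day12_microcolonies_per_arm",
         " must equal n_microcolonies_per_arm", call. = FALSE)
  }
  if (cfg$day6_specimens_per_microcolony > cfg$bees_per_microcolony ||
      cfg$day12_specimens_per_microcolony > cfg$bees_per_microcolony) {
    stop("study_config: specimens per microcolony cannot exceed ",
         "bees_per_microcolony", call. = FALSE)
  }
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  n_exp <- 2L * (x$day6_microcolonies_per_arm * x$day6_specimens_per_microcolony +
                 x$day12_microcolonies_per_arm * x$day12_specimens_per_microcolony)
  cat("Study configuration:\n")
  cat("  microcolonies: ", 2L * x$n_microcolonies_per_arm,
      " (", x$n_microcolonies_per_arm, " per arm), ",
      x$bees_per_microcolony, " bees each\n", sep = "")
  cat("  experimental hemolymph samples:", n_exp, "\n")
  cat("  untargeted components:", x$n_components,
      " targeted metabolites:", x$n_targeted, "\n")
  cat("  QC: duplicate internal pair after every", x$qc_every,
      "experimental injections;", x$n_conditioning_qc, "conditioning injections\n")
  invisible(x)
}

#' Generate the injection-sequence sample design
#'
#' Creates one record per injection: experimental hemolymph samples in a
#' randomized injection order, bracketed by duplicate internal QC
#' injections (pooled extract of all experimental samples) after every
#' `qc_every` experimental injections, preceded by external conditioning
#' QC injections. A terminal internal QC pair is always appended so that
#' every experimental sample has a following QC pair available for
#' drift normalization.
#'
#' @param config a [study_config()].
#' @return A `data.frame` with one row per injection and columns
#'   `sample_id`, `microcolony_id`, `diet`, `day`, `caste`,
#'   `injection_order`, `sample_class`. Design fields are `NA` for QC
#'   records. Deterministic for a fixed `config$seed`.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "study_config"))

  arms <- c("stress_25", "control_50")
  recs <- list()
  mc_counter <- 0L
  for (arm in arms) {
    for (phase in c("day6", "day12")) {
      n_mc <- if (phase == "day6") config$day6_microcolonies_per_arm else
        config$day12_microcolonies_per_arm
      n_spec <- if (phase == "day6") config$day6_specimens_per_microcolony else
        config$day12_specimens_per_microcolony
      day <- if (phase == "day6") 6L else 12L
      for (m in seq_len(n_mc)) {
        mc_counter <- mc_counter + 1L
        mc_id <- sprintf("MC%02d", mc_counter)
        # one dominant pseudo-queen per microcolony, remaining specimens workers
        castes <- c("pseudo_queen", rep("worker", n_spec - 1L))
        for (s in seq_len(n_spec)) {
          recs[[length(recs) + 1L]] <- data.frame(
            microcolony_id = mc_id, diet = arm, day = day,
            caste = castes[s], stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  exp_df <- do.call(rbind, recs)
  n_exp <- nrow(exp_df)
  exp_df$sample_id <- sprintf("S%03d", seq_len(n_exp))

  # randomized experimental injection order under the design seed
  set.seed(config$seed)
  exp_df <- exp_df[sample.int(n_exp), , drop = FALSE]

  qc_row <- function(id, class) {
    data.frame(sample_id = id, microcolony_id = NA_character_,
               diet = NA_character_, day = NA_integer_, caste = NA_character_,
               sample_class = class, stringsAsFactors = FALSE)
  }

  out <- list()
  for (k in seq_len(config$n_conditioning_qc)) {
    out[[length(out) + 1L]] <- qc_row(sprintf("QCext%02d", k), "qc_external")
  }
  n_int <- 0L
  since_qc <- 0L
  for (i in seq_len(n_exp)) {
    out[[length(out) + 1L]] <- data.frame(
      sample_id = exp_df$sample_id[i], microcolony_id = exp_df$microcolony_id[i],
      diet = exp_df$diet[i], day = exp_df$day[i], caste = exp_df$caste[i],
      sample_class = "experimental", stringsAsFactors = FALSE
    )
    since_qc <- since_qc + 1L
    if (since_qc == config$qc_every && i < n_exp) {
      for (d in 1:2) {
        n_int <- n_int + 1L
        out[[length(out) + 1L]] <- qc_row(sprintf("QCint%02d", n_int), "qc_internal")
      }
      since_qc <- 0L
    }
  }
  # terminal QC pair: every experimental sample needs a following pair
  for (d in 1:2) {
    n_int <- n_int + 1L
    out[[length(out) + 1L]] <- qc_row(sprintf("QCint%02d", n_int), "qc_internal")
  }
  design <- do.call(rbind, out)
  design$injection_order <- seq_len(nrow(design))
  rownames(design) <- NULL
  design[, c("sample_id", "microcolony_id", "diet", "day", "caste",
             "injection_order", "sample_class")]
}
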