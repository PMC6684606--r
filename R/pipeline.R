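#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end workflow
#' (simulate -> preprocess -> model -> select -> classify -> pathways).
#' All randomness derives from the single global `seed` via fixed
#' per-stage offsets, so changing a later stage's behavior never perturbs
#' earlier stages.
#'
#' @param seed global integer seed.
#' @param out_dir output directory (created if missing).
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L,
                                    out_dir = tempfile("beemetab-run-")) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, preprocess = TRUE, model = TRUE,
                  select = TRUE, classify = TRUE, pathways = TRUE),
    simulate = list(study = list(), effect = list()),
    preprocess = list(cv_threshold_pct = 30),
    model = list(n_folds = 7L, n_permutations = 100L, max_orth = 5L,
                 scale = "uv"),
    select = list(vip_threshold = 1.0, alpha = 0.05),
    classify = list(algorithms = .classifier_roster, n_folds = 10L,
                    datasets = c("1", "2", "3", "T_diet")),
    pathways = list(alpha = 0.05, adjust = "none")
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Values from the file override the defaults; unknown keys are rejected.
#' The file must set `seed`.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) {
    stop("read_pipeline_config: config must set a seed", call. = FALSE)
  }
  cfg <- default_pipeline_config(seed = user$seed)
  merged <- .merge_config(unclass(cfg), user, "")
  class(merged) <- "pipeline_config"
  merged
}

# recursive merge with unknown-key rejection; simulate overrides are free-form
.merge_config <- function(base, user, path) {
  free <- c(".simulate.study", ".simulate.effect")
  for (nm in names(user)) {
    here <- paste0(path, ".", nm)
    if (!nm %in% names(base) && !path %in% free) {
      stop("pipeline config: unknown key '", sub("^\\.", "", here), "'",
           call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        is.null(names(user[[nm]])) == FALSE) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]], here)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

.validate_pipeline_config <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    ref <- default_pipeline_config(seed = config$seed %||% 1L)
    config <- .merge_config(unclass(ref), config, "")
    class(config) <- "pipeline_config"
  }
  st <- config$stages
  deps <- list(preprocess = "simulate", model = "preprocess",
               select = "model", classify = "select", pathways = "select")
  for (stage in names(deps)) {
    if (isTRUE(st[[stage]]) && !isTRUE(st[[deps[[stage]]]])) {
      stop("pipeline config: stage '", stage, "' requires stage '",
           deps[[stage]], "' to be enabled", call. = FALSE)
    }
  }
  config
}

# merged untargeted + targeted experimental table for combined panels
.merge_tables <- function(unt, tgt) {
  stopifnot(identical(unt$samples$sample_id, tgt$samples$sample_id))
  feature_table(cbind(unt$intensity, tgt$intensity), unt$samples,
                data.frame(component_id = c(unt$components$component_id,
                                            tgt$components$component_id),
                           stringsAsFactors = FALSE))
}

#' Run the end-to-end biomarker-discovery pipeline
#'
#' Executes the enabled stages in order: cohort simulation, QC filtering
#' and QC-pair normalization, the stratified OPLS-DA model suite with
#' validation, biomarker selection (VIP intersection over the validated
#' diet datasets and the targeted ANOVA screen), biomarker-panel
#' classification, and pathway analysis. Stage outputs are written under
#' `config$out_dir` (TSV matrices, JSON reports) and a run manifest with
#' per-file MD5 checksums is returned and written as `manifest.json`.
#'
#' @param config a `pipeline_config` from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @return Invisibly, a list with `manifest` and the in-memory stage
#'   `results`. A stage failure aborts with the stage name; the partial
#'   manifest is still written.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  config <- .validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  manifest <- list(package_version =
                     as.character(utils::packageVersion("beemetab")),
                   seed = seed, started = format(Sys.time()),
                   stages = list(), warnings = character())
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  results <- list()
  warn_collector <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      status = "completed",
      outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  }
  run_stage <- function(stage, fn) {
    if (!isTRUE(config$stages[[stage]])) return(invisible(NULL))
    tryCatch(withCallingHandlers(fn(), warning = warn_collector),
             error = function(e) {
               manifest$stages[[stage]] <<- list(status = "failed",
                                                 error = conditionMessage(e))
               manifest$finished <<- format(Sys.time())
               jsonlite::write_json(manifest,
                                    file.path(out_dir, "manifest.json"),
                                    auto_unbox = TRUE, pretty = TRUE)
               stop("pipeline stage '", stage, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }

  run_stage("simulate", function() {
    study <- do.call(study_config,
                     c(list(seed = seed), config$simulate$study))
    effect <- do.call(default_effect_spec,
                      c(list(config = study), config$simulate$effect))
    design <- generate_design(study)
    unt <- generate_untargeted_table(design, effect, study)
    tgt <- generate_targeted_table(design, NULL, effect, study)
    files <- c(file.path(out_dir, "untargeted_raw.tsv"),
               file.path(out_dir, "sample_metadata.tsv"),
               file.path(out_dir, "targeted_raw.tsv"),
               file.path(out_dir, "ground_truth.json"))
    write_feature_table(unt$table, files[1L], files[2L])
    write_feature_table(tgt, files[3L])
    jsonlite::write_json(unt$truth, files[4L], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    results$study <<- study
    results$design <<- design
    results$untargeted <<- unt$table
    results$truth <<- unt$truth
    results$targeted <<- tgt
    record("simulate", files)
  })

  run_stage("preprocess", function() {
    cvrep <- compute_qc_cv(results$untargeted,
                           config$preprocess$cv_threshold_pct)
    filtered <- suppressMessages(
      filter_components(results$untargeted, cvrep,
                        config$preprocess$cv_threshold_pct))
    unt_norm <- qc_bracket_normalize(filtered)
    tgt_norm <- qc_bracket_normalize(results$targeted)
    files <- c(file.path(out_dir, "untargeted_normalized.tsv"),
               file.path(out_dir, "targeted_normalized.tsv"),
               file.path(out_dir, "preprocessing_report.json"))
    write_feature_table(unt_norm, files[1L])
    write_feature_table(tgt_norm, files[2L])
    report <- list(
      components_in = nrow(cvrep),
      components_retained = sum(cvrep$retained),
      components_removed = sum(!cvrep$retained),
      cv_threshold_pct = config$preprocess$cv_threshold_pct,
      cv_pct_summary = as.list(summary(cvrep$cv_pct))
    )
    jsonlite::write_json(report, files[3L], auto_unbox = TRUE, pretty = TRUE)
    results$qc_cv <<- cvrep
    results$untargeted_norm <<- unt_norm
    results$targeted_norm <<- tgt_norm
    record("preprocess", files)
  })

  run_stage("model", function() {
    suite <- suppressWarnings(run_model_suite(
      results$untargeted_norm, dataset_specs(),
      n_folds = config$model$n_folds,
      n_permutations = config$model$n_permutations,
      max_orth = config$model$max_orth,
      seed = seed + 11L, scale = config$model$scale))
    summ <- lapply(suite, function(d) {
      if (!is.null(d$error)) return(list(error = d$error))
      list(contrast = d$spec$contrast, n = d$n, n_orth = d$n_orth,
           r2x = d$model$r2x, r2y = d$model$r2y, q2 = d$validation$q2,
           cv_anova_p = d$validation$cv_anova_p,
           permutation_p = d$validation$permutation$p_value,
           verdict = d$validation$verdict)
    })
    f <- file.path(out_dir, "model_suite.json")
    jsonlite::write_json(summ, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    results$suite <<- suite
    record("model", f)
  })

  run_stage("select", function() {
    diet_names <- c("1", "2", "3", "T_diet")
    validated <- Filter(function(d) isTRUE(d$validated),
                        results$suite[diet_names])
    if (length(validated) < 2L) {
      stop("fewer than 2 validated diet datasets; cannot intersect VIP sets")
    }
    unt_set <- intersect_vip_sets(lapply(validated, `[[`, "vip"),
                                  config$select$vip_threshold)
    tgt_set <- targeted_anova_screen(results$targeted_norm,
                                     alpha = config$select$alpha)
    comb <- combine_biomarker_sets(unt_set, tgt_set)
    ratios <- compute_ratio_table(results$targeted_norm)
    files <- c(file.path(out_dir, "biomarkers.json"),
               file.path(out_dir, "ratio_table.tsv"))
    jsonlite::write_json(
      list(untargeted = list(members = unt_set$members,
                             per_dataset_counts =
                               as.list(unt_set$per_dataset_counts)),
           targeted = list(members = tgt_set$members,
                           anova = tgt_set$anova),
           combined = list(members = comb$members)),
      files[1L], auto_unbox = TRUE, pretty = TRUE, digits = NA)
    utils::write.table(ratios, files[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    results$untargeted_set <<- unt_set
    results$targeted_set <<- tgt_set
    results$combined_set <<- comb
    results$ratio_table <<- ratios
    record("select", files)
  })

  run_stage("classify", function() {
    merged <- .merge_tables(results$untargeted_norm, results$targeted_norm)
    panels <- list(targeted = results$targeted_set$members,
                   untargeted = results$untargeted_set$members,
                   combined = results$combined_set$members)
    panels <- Filter(function(p) length(p) > 0L, panels)
    specs <- dataset_specs()
    reports <- list()
    for (ds in config$classify$datasets) {
      bd <- build_dataset(merged, specs[[ds]])
      for (pn in names(panels)) {
        for (alg in config$classify$algorithms) {
          rep <- evaluate_panel(bd$table, bd$class, panels[[pn]], alg,
                                n_folds = config$classify$n_folds,
                                seed = seed + 17L)
          reports[[length(reports) + 1L]] <-
            list(dataset = ds, panel_name = pn, report = rep)
        }
      }
    }
    grid <- summarize_reports(reports)
    files <- c(file.path(out_dir, "classification_grid.tsv"),
               file.path(out_dir, "classification_grid.json"))
    utils::write.table(grid, files[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(grid = grid,
                              best_panel = attr(grid, "best_panel")),
                         files[2L], auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    results$classification <<- grid
    record("classify", files)
  })

  run_stage("pathways", function() {
    tgt_set <- results$targeted_set
    # direction of each selected metabolite: sign of the stress/control
    # log mean-intensity ratio over the whole cohort
    smp <- results$targeted_norm$samples
    dirs <- vapply(tgt_set$members, function(m) {
      v <- results$targeted_norm$intensity[, m]
      r <- mean(v[smp$diet == "stress_25"]) / mean(v[smp$diet == "control_50"])
      if (r >= 1) "up" else "down"
    }, character(1))
    pw <- analyze_pathways(tgt_set$members, dirs,
                           background =
                             results$targeted_norm$components$component_id,
                           alpha = config$pathways$alpha,
                           adjust = config$pathways$adjust)
    f <- file.path(out_dir, "pathway_results.json")
    jsonlite::write_json(pw, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results$pathways <<- pw
    record("pathways", f)
  })

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}
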