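# Reduced-scale fixtures built in code.

# small cohort: 20 experimental samples, 60 components, QC every 5
small_config <- function(seed = 1L, n_components = 60L, n_targeted = 12L,
                         qc_every = 5L) {
  study_config(n_microcolonies_per_arm = 3L, bees_per_microcolony = 5L,
               day6_microcolonies_per_arm = 1L,
               day6_specimens_per_microcolony = 2L,
               day12_microcolonies_per_arm = 2L,
               day12_specimens_per_microcolony = 4L,
               n_components = n_components, n_targeted = n_targeted,
               qc_every = qc_every, seed = seed)
}

# a hand-built feature table with explicit QC structure
toy_table <- function(intensity, classes, orders = seq_len(nrow(intensity))) {
  n <- nrow(intensity)
  smp <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    microcolony_id = ifelse(classes == "experimental", "MC01", NA),
    diet = ifelse(classes == "experimental", "stress_25", NA),
    day = ifelse(classes == "experimental", 12L, NA),
    caste = ifelse(classes == "experimental", "worker", NA),
    injection_order = orders,
    sample_class = classes,
    stringsAsFactors = FALSE
  )
  rownames(intensity) <- smp$sample_id
  feature_table(intensity, smp)
}

# two well-separated Gaussian clusters for classifier checks
separable_data <- function(n_per = 20L, p = 4L, gap = 6, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), ncol = p),
             matrix(rnorm(n_per * p, mean = gap), ncol = p))
  colnames(x) <- sprintf("F%d", seq_len(p))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

# wrap a plain matrix + labels as an experimental feature table (diet classes)
as_diet_table <- function(x, y) {
  n <- nrow(x)
  smp <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    microcolony_id = "MC01",
    diet = ifelse(y == unique(y)[1L], "stress_25", "control_50"),
    day = 12L, caste = "worker",
    injection_order = seq_len(n), sample_class = "experimental",
    stringsAsFactors = FALSE
  )
  rownames(x) <- smp$sample_id
  feature_table(x, smp)
}
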