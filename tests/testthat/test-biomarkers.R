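test_that("dataset suite sizes match the stratification arithmetic", {
  cfg <- study_config(seed = 2L)
  des <- generate_design(cfg)
  sim <- generate_untargeted_table(des, effect_spec(), cfg)
  norm <- qc_bracket_normalize(sim$table)
  specs <- dataset_specs()
  sizes <- vapply(specs, function(sp)
    nrow(build_dataset(norm, sp)$table$intensity), integer(1))
  expect_equal(unname(sizes[c("1", "2", "3", "T_diet", "4", "5",
                              "6", "7")]),
               c(48L, 64L, 58L, 84L, 42L, 42L, 64L, 20L))
  expect_equal(unname(sizes[c("T_age", "T_hierarchy")]), c(84L, 84L))

  # class vectors follow the contrast
  bd <- build_dataset(norm, specs$`1`)
  expect_setequal(unique(bd$class), c("stress_25", "control_50"))
  bd7 <- build_dataset(norm, specs$`7`)
  expect_setequal(unique(bd7$class), c("worker", "pseudo_queen"))
})

test_that("build_dataset names the offending empty stratum", {
  cfg <- small_config(seed = 3L)
  des <- generate_design(cfg)
  sim <- generate_untargeted_table(des, effect_spec(), cfg)
  norm <- qc_bracket_normalize(sim$table)
  bad <- list(name = "x", contrast = "diet",
              strata = data.frame(day = 9L, caste = "worker"))
  expect_error(build_dataset(norm, bad), "day=9")
  expect_error(build_dataset(sim$table, dataset_specs()$`1`), "QC samples")
})

test_that("VIP intersection follows set semantics", {
  mk <- function(ids, vips) data.frame(component_id = ids, vip = vips,
                                       stringsAsFactors = FALSE)
  tabs <- list(d1 = mk(c("a", "b", "c", "d"), c(2, 1.5, 1.2, 0.2)),
               d2 = mk(c("a", "b", "c", "d"), c(0.5, 1.4, 1.1, 0.1)),
               d3 = mk(c("a", "b", "c", "d"), c(0.9, 2.0, 1.3, 1.6)),
               d4 = mk(c("a", "b", "c", "d"), c(0.2, 1.1, 1.9, 0.3)))
  bs <- intersect_vip_sets(tabs)
  expect_setequal(bs$members, c("b", "c"))
  expect_equal(unname(bs$per_dataset_counts), c(3L, 2L, 3L, 2L))

  # strict threshold: a VIP of exactly 1.0 is excluded
  tied <- list(mk(c("a", "b"), c(1.0, 1.5)), mk(c("a", "b"), c(1.2, 1.5)))
  expect_setequal(intersect_vip_sets(tied)$members, "b")

  # empty intersection warns but returns a set
  disj <- list(mk(c("a", "b"), c(2, 0.1)), mk(c("a", "b"), c(0.1, 2)))
  expect_warning(e <- intersect_vip_sets(disj), "empty")
  expect_length(e$members, 0L)

  # monotone: raising the threshold never grows the set
  lo <- intersect_vip_sets(tabs, threshold = 0.5)$members
  hi <- suppressWarnings(intersect_vip_sets(tabs, threshold = 1.5)$members)
  expect_true(all(hi %in% lo))
  expect_error(intersect_vip_sets(tabs[1L]), "at least 2")
})

test_that("targeted ANOVA F statistics match the balanced closed form", {
  set.seed(30)
  diet <- rep(c("stress_25", "control_50"), each = 12L)
  day <- rep(rep(c(6L, 12L), each = 6L), 2L)
  v <- rnorm(24L) + 0.8 * (diet == "stress_25") + 0.5 * (day == 12L) +
    0.4 * (diet == "stress_25" & day == 12L)
  orc <- anova2_oracle(v, diet, day)
  fit <- summary(aov(v ~ factor(diet) * factor(day)))[[1]]
  expect_equal(fit[["F value"]][1L], orc$F_A, tolerance = 1e-10)
  expect_equal(fit[["F value"]][2L], orc$F_B, tolerance = 1e-10)
  expect_equal(fit[["F value"]][3L], orc$F_AB, tolerance = 1e-10)

  # the screen reports the same p-values on a feature table built from v
  smp <- data.frame(sample_id = sprintf("S%02d", 1:24), microcolony_id = "M",
                    diet = diet, day = day, caste = "worker",
                    injection_order = 1:24, sample_class = "experimental",
                    stringsAsFactors = FALSE)
  mat <- matrix(exp(v), ncol = 1L, dimnames = list(smp$sample_id, "met1"))
  scr <- targeted_anova_screen(feature_table(mat, smp))
  expect_equal(scr$anova$p_diet,
               pf(orc$F_A, 1, 20, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("planted-up glutamine is selected with a tiny diet p-value", {
  cfg <- study_config(seed = 31L)
  des <- generate_design(cfg)
  eff <- effect_spec(biological_cv = 0.08, analytical_cv = 0.02,
                     drift_rate = 0)
  tab <- generate_targeted_table(des, NULL, eff, cfg)
  scr <- targeted_anova_screen(qc_bracket_normalize(tab))
  expect_true("glutamine" %in% scr$members)
  expect_lt(scr$anova$p_diet[scr$anova$metabolite == "glutamine"], 1e-3)
  # Tukey HSD tables cover the four diet-by-day cells
  expect_equal(nrow(scr$tukey[["glutamine"]]), choose(4L, 2L))
})

test_that("null diet effects are selected at roughly the alpha rate", {
  set.seed(32)
  n_rep <- 120L
  diet <- rep(c("stress_25", "control_50"), each = 10L)
  day <- rep(rep(c(6L, 12L), each = 5L), 2L)
  hits <- replicate(n_rep, {
    v <- rnorm(20L)
    p <- summary(aov(v ~ factor(diet) * factor(day)))[[1]][["Pr(>F)"]][1L]
    p < 0.05
  })
  ci <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(sum(hits), ci[1L])
  expect_lte(sum(hits), ci[2L])
})

test_that("ratio table layout and construction cases", {
  cfg <- small_config(seed = 33L, n_targeted = 6L)
  des <- generate_design(cfg)
  panel <- default_targeted_panel(6L)

  # identical arms: all ratios near 1 under a null panel
  panel0 <- panel
  panel0$diet_log2_shift <- 0; panel0$age_log2_shift <- 0
  eff <- effect_spec(biological_cv = 1e-4, analytical_cv = 1e-4,
                     drift_rate = 0)
  tab0 <- generate_targeted_table(des, panel0, eff, cfg)
  rt0 <- compute_ratio_table(qc_bracket_normalize(tab0))
  expect_equal(ncol(rt0), 5L) # metabolite + 4 (day x caste) strata
  expect_true(all(grepl("^ratio_day", names(rt0)[-1L])))
  expect_equal(unlist(rt0[, -1L]), rep(1, 24L), tolerance = 1e-3,
               ignore_attr = TRUE)

  # stress means double the control means
  panel2 <- panel0
  panel2$diet_log2_shift <- 1
  tab2 <- generate_targeted_table(des, panel2, eff, cfg)
  rt2 <- compute_ratio_table(qc_bracket_normalize(tab2))
  expect_equal(unlist(rt2[, -1L]), rep(2, 24L), tolerance = 1e-2,
               ignore_attr = TRUE)
})

test_that("model suite flags failing datasets without aborting", {
  cfg <- small_config(seed = 34L)
  des <- generate_design(cfg)
  sim <- generate_untargeted_table(des, NULL, cfg)
  norm <- qc_bracket_normalize(sim$table)
  specs <- dataset_specs()[c("T_diet", "T_hierarchy")]
  suite <- suppressWarnings(
    run_model_suite(norm, specs, n_permutations = 20L, max_orth = 1L,
                    seed = 1L))
  expect_named(suite, c("T_diet", "T_hierarchy"))
  expect_true(suite$T_diet$validated)
  expect_false(suite$T_hierarchy$validated)

  # empty spec list gives an empty suite
  empty <- run_model_suite(norm, list())
  expect_length(empty, 0L)
})
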