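test_that("QC %CV follows the n-1 standard-deviation formula", {
  x <- cbind(A = c(100, 100, 100, 1, 1), B = c(90, 110, 100, 1, 1))
  tab <- toy_table(x, c("qc_internal", "qc_internal", "qc_internal",
                        "experimental", "experimental"))
  rep <- compute_qc_cv(tab)
  expect_equal(rep$cv_pct[rep$component_id == "A"], 0)
  # hand value for {90, 110, 100}: sd = 10, mean = 100
  expect_equal(rep$cv_pct[rep$component_id == "B"], 10)

  tab2 <- toy_table(cbind(B = c(90, 110, 1)),
                    c("qc_internal", "qc_internal", "experimental"))
  rep2 <- compute_qc_cv(tab2)
  # sd({90,110}) = 14.1421..., mean 100
  expect_equal(rep2$cv_pct, 100 * sd(c(90, 110)) / 100)
  expect_equal(rep2$cv_pct, 14.142, tolerance = 1e-4)
})

test_that("the %CV threshold is a strict inequality", {
  # component with QC values giving exactly 30.000...% CV
  qc <- c(100 - sqrt(450), 100 + sqrt(450)) # sd = 30, mean = 100
  tab <- toy_table(cbind(A = qc, B = c(100, 101)),
                   c("qc_internal", "qc_internal"))
  rep <- compute_qc_cv(tab)
  expect_equal(rep$cv_pct[1L], 30)
  expect_false(rep$retained[1L])
  expect_true(rep$retained[2L])
})

test_that("compute_qc_cv requires two internal QC samples", {
  tab <- toy_table(cbind(A = c(1, 2)), c("qc_internal", "experimental"))
  expect_error(compute_qc_cv(tab), "at least 2")
})

test_that("filter_components removes exactly the planted noisy components", {
  cfg <- small_config(seed = 4L, n_components = 50L)
  des <- generate_design(cfg)
  noisy <- c(3L, 7L, 11L, 19L, 23L, 29L, 31L, 37L, 41L, 47L)
  eff <- effect_spec(analytical_cv = 0.03, biological_cv = 0.2,
                     noisy_components = noisy, noisy_analytical_cv = 0.9)
  sim <- generate_untargeted_table(des, eff, cfg)
  rep <- compute_qc_cv(sim$table)
  filt <- suppressMessages(filter_components(sim$table, rep))
  removed <- setdiff(sim$table$components$component_id,
                     filt$components$component_id)
  expect_setequal(removed, sprintf("C%04d", noisy))
})

test_that("filter_components degenerate cases", {
  x <- cbind(A = c(10, 10.1, 10), B = c(5, 5.1, 5))
  tab <- toy_table(x, rep("qc_internal", 3L))
  rep <- compute_qc_cv(tab)
  # all pass: identity on columns
  kept <- suppressMessages(filter_components(tab, rep))
  expect_identical(kept$intensity, tab$intensity)
  # threshold 0 removes everything
  expect_error(suppressMessages(filter_components(tab, rep, 0)),
               "no components")
  # report from another table is rejected
  expect_error(filter_components(ft_subset_components(tab, 1L), rep),
               "not computed on this table")
})

test_that("QC-pair normalization divides by the following pair mean", {
  x <- cbind(A = c(500, 300, 500, 500, 10, 400, 600),
             B = c(300, 300, 400, 600, 10, 100, 100))
  cls <- c("experimental", "experimental", "qc_internal", "qc_internal",
           "experimental", "qc_internal", "qc_internal")
  tab <- toy_table(x, cls)
  norm <- qc_bracket_normalize(tab)
  # sample 1: 500 / mean(500, 500) = 1;  300 / mean(400, 600) = 0.6
  expect_equal(unname(norm$intensity["S01", ]), c(1, 0.6))
  # third experimental sample uses the second pair
  expect_equal(unname(norm$intensity["S05", "A"]), 10 / 500)
  expect_equal(nrow(norm$intensity), 3L)
  audit <- attr(norm, "normalization_audit")
  expect_equal(audit$qc1, c("S03", "S03", "S06"))
})

test_that("normalization errors and flags", {
  # missing terminal pair
  x <- cbind(A = c(1, 2, 3))
  tab <- toy_table(x, c("qc_internal", "qc_internal", "experimental"))
  expect_error(qc_bracket_normalize(tab), "following internal QC pair")

  # second pass (no QC rows left) errors
  x2 <- cbind(A = c(5, 10, 10))
  tab2 <- toy_table(x2, c("experimental", "qc_internal", "qc_internal"))
  norm <- qc_bracket_normalize(tab2)
  expect_error(qc_bracket_normalize(norm), "no experimental samples|QC pair")

  # zero QC-pair mean flags and removes the component
  x3 <- cbind(A = c(5, 10, 10), B = c(5, 0, 0))
  tab3 <- toy_table(x3, c("experimental", "qc_internal", "qc_internal"))
  expect_warning(n3 <- qc_bracket_normalize(tab3), "zero QC-pair mean")
  expect_equal(colnames(n3$intensity), "A")
})

test_that("shared multiplicative drift cancels in the QC ratio", {
  # drift constant within each bracket-plus-pair window cancels exactly
  x0 <- matrix(rep(c(4, 8), each = 8), ncol = 2) # constant per component
  drift <- rep(c(1, 0.8), each = 4) # two windows
  x <- x0 * drift
  cls <- rep(c("experimental", "experimental", "qc_internal", "qc_internal"),
             2L)
  tab <- toy_table(x, cls)
  norm <- qc_bracket_normalize(tab)
  expect_true(all(abs(norm$intensity - 1) < 1e-12))
})

test_that("filter then normalize commutes with normalize then filter", {
  cfg <- small_config(seed = 6L)
  des <- generate_design(cfg)
  sim <- generate_untargeted_table(des, NULL, cfg)
  rep <- compute_qc_cv(sim$table)
  a <- qc_bracket_normalize(suppressMessages(filter_components(sim$table,
                                                               rep)))
  b <- qc_bracket_normalize(sim$table)
  b <- ft_subset_components(b, a$components$component_id)
  expect_equal(a$intensity, b$intensity)
})

test_that("scale_center obeys the uv / pareto / none contracts", {
  set.seed(1)
  x <- matrix(rnorm(60, mean = 3, sd = 2), ncol = 3L)
  uv <- scale_center(x, "uv")
  expect_equal(unname(colMeans(uv$x)), rep(0, 3L))
  expect_equal(unname(apply(uv$x, 2L, sd)), rep(1, 3L))

  no <- scale_center(x, "none")
  expect_equal(unname(colMeans(no$x)), rep(0, 3L))
  expect_equal(apply(no$x, 2L, sd), apply(x, 2L, sd))

  pa <- scale_center(x, "pareto")
  expect_equal(unname(apply(pa$x, 2L, sd)),
               unname(sqrt(apply(x, 2L, sd))))

  # zero-variance column dropped with warning; all-constant errors
  xz <- cbind(x, 5)
  expect_warning(sz <- scale_center(xz, "uv"), "zero-variance")
  expect_equal(ncol(sz$x), 3L)
  expect_error(scale_center(matrix(1, 4L, 2L)), "constant")

  # held-out application reuses training parameters
  new <- apply_scaling(x[1:5, ], uv)
  expect_equal(new, uv$x[1:5, ])
})
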