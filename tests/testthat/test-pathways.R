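test_that("bundled pathway library loads with valid graphs", {
  lib <- load_pathway_library()
  expect_s3_class(lib, "pathway_library")
  expect_true(attr(lib, "synthetic"))
  expect_gte(length(lib), 8L)
  expect_true(all(vapply(lib, `[[`, logical(1), "connected")))
  for (pw in lib) {
    expect_false(anyDuplicated(pw$members) > 0L)
    expect_setequal(igraph::V(pw$graph)$name, pw$members)
  }
})

test_that("hypergeometric ORA closed cases", {
  bg <- letters[1:10]
  # zero hits
  expect_equal(as.numeric(ora_pvalue("a", letters[6:10], bg)), 1)
  # all five query metabolites inside a five-member pathway: 1 / C(10,5)
  p <- ora_pvalue(letters[1:5], letters[1:5], bg)
  expect_equal(as.numeric(p), 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(attr(p, "hits"), 5L)
  # contract: query must be inside the background
  expect_error(ora_pvalue("zz", letters[1:5], bg), "subset")
  expect_error(ora_pvalue("a", "zz", bg), "subset")
})

test_that("ORA matches exhaustive enumeration on all small grids", {
  for (N in c(6L, 9L, 12L)) {
    bg <- sprintf("m%02d", seq_len(N))
    for (K in c(1L, 3L, N %/% 2L)) {
      for (n in c(1L, 2L, N %/% 2L)) {
        path_m <- bg[seq_len(K)]
        for (draw in 1:3) {
          set.seed(N * 100 + K * 10 + n + draw)
          query <- sample(bg, n)
          k <- length(intersect(query, path_m))
          p_pkg <- as.numeric(ora_pvalue(query, path_m, bg))
          p_orc <- hyper_enum_oracle(N, K, n, k)
          expect_equal(p_pkg, p_orc, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("ORA p is non-increasing in the hit count", {
  bg <- sprintf("m%02d", 1:20)
  path_m <- bg[1:6]
  p_prev <- 1.01
  for (k in 0:4) {
    query <- c(bg[seq_len(k)], bg[seq.int(7L, 7L + (4L - k))])
    p <- as.numeric(ora_pvalue(query, path_m, bg))
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
})

test_that("pathway impact equals the path-enumeration betweenness oracle", {
  # 5-node path graph, hit = middle node
  g <- igraph::make_graph(~ a - b - c - d - e)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  orc <- betweenness_oracle(adj)
  # hand check: middle of a 5-path mediates 4 of the 10 pairs
  expect_equal(orc, c(0, 3, 4, 3, 0)[match(igraph::V(g)$name,
                                           c("a", "b", "c", "d", "e"))])
  imp <- pathway_impact("c", g)
  expect_equal(as.numeric(imp), 4 / 10)

  # every fixture graph agrees with the oracle
  lib <- load_pathway_library()
  for (pw in lib) {
    adj <- as.matrix(igraph::as_adjacency_matrix(pw$graph))
    orc <- betweenness_oracle(adj)
    btw <- igraph::betweenness(pw$graph, directed = FALSE)
    expect_equal(unname(btw), orc, tolerance = 1e-10)
  }
})

test_that("impact normalization and degenerate cases", {
  g <- igraph::make_graph(~ a - b - c - d - e)
  expect_equal(as.numeric(pathway_impact(c("a", "b", "c", "d", "e"), g)), 1)
  expect_equal(as.numeric(pathway_impact(character(), g)), 0)
  # relabeling invariance
  g2 <- igraph::make_graph(~ x - y - z - w - v)
  expect_equal(as.numeric(pathway_impact("z", g2)),
               as.numeric(pathway_impact("c", g)))
  # all-zero betweenness degenerates to the hit fraction, flagged
  star2 <- igraph::make_graph(~ a - b)
  imp <- pathway_impact("a", star2)
  expect_true(attr(imp, "degenerate"))
  expect_equal(as.numeric(imp), 0.5)
})

test_that("analyze_pathways resolves the planted biomarkers as designed", {
  panel <- default_targeted_panel()
  planted <- panel$metabolite[panel$planted_direction != "none"]
  dirs <- setNames(panel$planted_direction[panel$planted_direction != "none"],
                   planted)
  res <- analyze_pathways(planted, dirs)
  expect_s3_class(res, "pathway_results")
  five <- c("Starch and sucrose metabolism", "Aminoacyl-tRNA biosynthesis",
            "Alanine, aspartate and glutamate metabolism",
            "Arginine and proline metabolism",
            "D-Glutamine and D-glutamate metabolism")
  expect_true(all(res$significant[res$pathway %in% five]))
  expect_false(any(res$significant[!res$pathway %in% five]))
  # the down-shifted sugars land only in starch and sucrose metabolism
  expect_equal(res$direction[res$pathway == five[1L]], "down")
  expect_true(all(res$direction[res$pathway %in% five[-1L]] == "up"))
  expect_true(all(res$hits <= pmin(res$pathway_size, length(planted))))

  # alpha = 0 flags nothing
  res0 <- analyze_pathways(planted, dirs, alpha = 0)
  expect_false(any(res0$significant))
})

test_that("glutamine plus glutamate is most enriched in its toy pathway", {
  res <- analyze_pathways(c("glutamine", "glutamic acid"))
  expect_equal(res$pathway[which.min(res$p_value)],
               "D-Glutamine and D-glutamate metabolism")
})

test_that("unresolvable queries warn and return an empty result", {
  expect_warning(res <- analyze_pathways("veratrole"), "resolves")
  expect_false(any(res$significant))
})
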