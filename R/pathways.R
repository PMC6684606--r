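#' Load a metabolite pathway library
#'
#' Reads a pathway library from the documented JSON schema: an object with
#' `library_name`, `version`, optional `synthetic` flag, and `pathways`,
#' each pathway carrying `name`, `members` (metabolite names) and `edges`
#' (pairs of member names forming the undirected reaction graph). The
#' package bundles a small synthetic library
#' (`inst/extdata/pathway_library.json`) whose memberships are trimmed and
#' adjusted so that the planted nutritional-stress biomarkers enrich the
#' five pathways reported for carbohydrate restriction; it is a test
#' fixture, not a curated database.
#'
#' @param path JSON file path; default the bundled synthetic library.
#' @return A list of class `pathway_library`; each element has `name`,
#'   `members`, `graph` (an `igraph` object over the members) and
#'   `connected` flag.
#' @export
load_pathway_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathway_library.json",
                        package = "beemetab", mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$pathways)) {
    stop("load_pathway_library: JSON must contain a 'pathways' array",
         call. = FALSE)
  }
  lib <- lapply(raw$pathways, function(pw) {
    members <- tolower(unlist(pw$members))
    if (anyDuplicated(members)) {
      stop("load_pathway_library: duplicate members in pathway '", pw$name,
           "'", call. = FALSE)
    }
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(members), name = members)
    if (length(pw$edges) > 0L) {
      ep <- tolower(unlist(pw$edges))
      if (!all(ep %in% members)) {
        stop("load_pathway_library: edge endpoint outside members in '",
             pw$name, "'", call. = FALSE)
      }
      g <- igraph::add_edges(g, ep)
    }
    list(name = pw$name, members = members, graph = g,
         connected = igraph::is_connected(g))
  })
  names(lib) <- vapply(lib, `[[`, character(1), "name")
  attr(lib, "library_name") <- raw$library_name %||% "unnamed"
  attr(lib, "version") <- raw$version %||% "0"
  attr(lib, "synthetic") <- isTRUE(raw$synthetic)
  class(lib) <- "pathway_library"
  lib
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least the actual number of
#' pathway hits when `length(query)` metabolites are drawn without
#' replacement from the background.
#'
#' @param query character vector of significant metabolites (subset of
#'   `background`).
#' @param pathway_members character vector of pathway metabolites (subset
#'   of `background`).
#' @param background character vector: the reference metabolome.
#' @return p-value in (0, 1], with attribute `hits`.
#' @export
ora_pvalue <- function(query, pathway_members, background) {
  query <- unique(tolower(query))
  pathway_members <- unique(tolower(pathway_members))
  background <- unique(tolower(background))
  if (!all(query %in% background)) {
    stop("ora_pvalue: query must be a subset of the background",
         call. = FALSE)
  }
  if (!all(pathway_members %in% background)) {
    stop("ora_pvalue: pathway members must be a subset of the background",
         call. = FALSE)
  }
  N <- length(background)
  K <- length(pathway_members)
  n <- length(query)
  k <- length(intersect(query, pathway_members))
  p <- if (k == 0L) 1 else
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(p, hits = k)
}

#' Topology-based pathway impact
#'
#' Relative betweenness centrality of the hit metabolites within the
#' pathway's reaction graph: the summed betweenness of hit nodes divided
#' by the summed betweenness of all nodes. Isolated nodes have centrality
#' zero. When every node has zero betweenness (no paths of length > 1)
#' the impact degenerates to the hit fraction, flagged via attribute
#' `degenerate`.
#'
#' @param query character vector of significant metabolites.
#' @param graph an `igraph` undirected graph whose vertex names are
#'   metabolites.
#' @return Impact in `[0, 1]`.
#' @export
pathway_impact <- function(query, graph) {
  if (igraph::vcount(graph) == 0L) {
    return(structure(0, degenerate = TRUE))
  }
  btw <- igraph::betweenness(graph, directed = FALSE)
  hits <- tolower(igraph::V(graph)$name) %in% unique(tolower(query))
  total <- sum(btw)
  if (total == 0) {
    return(structure(sum(hits) / length(hits), degenerate = TRUE))
  }
  structure(sum(btw[hits]) / total, degenerate = FALSE)
}

#' Pathway over-representation and impact analysis
#'
#' Maps significant metabolites (with optional effect directions) onto a
#' pathway library, computes the hypergeometric over-representation
#' p-value and the topology impact per pathway, and summarizes member
#' directions. Pathway membership is intersected with the background
#' before testing; matching is case-insensitive. No multiple-testing
#' correction is applied by default (Holm available).
#'
#' @param metabolites character vector of significant metabolites.
#' @param directions optional named vector (`"up"`/`"down"`) along
#'   `metabolites`.
#' @param library a [load_pathway_library()] object (default: bundled).
#' @param background the reference metabolome (default: the 64-metabolite
#'   targeted panel).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A `data.frame` of class `pathway_results`: pathway, hits,
#'   pathway size (within background), background size, `p_value`,
#'   `impact`, `direction` (`up`/`down`/`mixed`/`NA`), `significant`.
#'   Returns an empty result with a warning when no metabolite resolves
#'   against the library vocabulary.
#' @export
analyze_pathways <- function(metabolites, directions = NULL, library = NULL,
                             background = NULL, alpha = 0.05,
                             adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.null(library)) library <- load_pathway_library()
  if (is.null(background)) background <- default_targeted_panel()$metabolite
  background <- unique(tolower(background))
  query <- unique(tolower(metabolites))
  query <- query[query %in% background]
  vocab <- unique(tolower(unlist(lapply(library, `[[`, "members"))))
  if (!any(query %in% vocab)) {
    warning("analyze_pathways: no query metabolite resolves against the ",
            "pathway library vocabulary")
  }
  dirs <- NULL
  if (!is.null(directions)) {
    dirs <- stats::setNames(as.character(directions), tolower(metabolites))
  }
  rows <- lapply(library, function(pw) {
    mem_bg <- intersect(pw$members, background)
    hits <- intersect(query, mem_bg)
    p <- if (length(mem_bg) == 0L) 1 else ora_pvalue(query, mem_bg, background)
    dir <- NA_character_
    if (length(hits) > 0L && !is.null(dirs)) {
      d <- unique(dirs[hits])
      d <- d[!is.na(d)]
      dir <- if (length(d) == 1L) d else if (length(d) > 1L) "mixed"
        else NA_character_
    }
    data.frame(pathway = pw$name, hits = length(hits),
               pathway_size = length(mem_bg),
               background_size = length(background),
               p_value = as.numeric(p),
               impact = as.numeric(pathway_impact(hits, pw$graph)),
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  p_adj <- if (adjust == "holm") stats::p.adjust(out$p_value, "holm")
    else out$p_value
  out$significant <- p_adj < alpha
  class(out) <- c("pathway_results", "data.frame")
  out
}
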