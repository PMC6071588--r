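#' Settings for functional annotation clustering
#'
#' Stringency parameters for kappa-based clustering of enriched terms.
#' The defaults are the relaxed stringency used for Cellular Component
#' clustering of familial variant gene lists: group memberships of 2, an
#' EASE threshold of 0.1, and the standard similarity settings (term
#' overlap 3, kappa threshold 0.50, multiple linkage threshold 0.5).
#'
#' @param initial_group_membership Minimum closed-neighbourhood size for
#'   a term to seed a candidate group.
#' @param final_group_membership Minimum member count for a reported
#'   cluster.
#' @param similarity_term_overlap Minimum shared input genes between two
#'   terms for an edge.
#' @param similarity_threshold Minimum kappa for an edge.
#' @param multiple_linkage_threshold Fraction of the smaller group that
#'   must be shared for two groups to merge.
#' @param ease_threshold Terms enter clustering only with EASE score at
#'   or below this value.
#' @return A list of class `famseg_cluster_settings`.
#' @export
cluster_settings <- function(initial_group_membership = 2,
                             final_group_membership = 2,
                             similarity_term_overlap = 3,
                             similarity_threshold = 0.50,
                             multiple_linkage_threshold = 0.5,
                             ease_threshold = 0.1) {
  stopifnot(initial_group_membership >= 1, final_group_membership >= 1,
            similarity_threshold >= 0, similarity_threshold <= 1,
            multiple_linkage_threshold >= 0,
            multiple_linkage_threshold <= 1,
            ease_threshold >= 0, ease_threshold <= 1)
  structure(
    list(initial_group_membership = as.integer(initial_group_membership),
         final_group_membership = as.integer(final_group_membership),
         similarity_term_overlap = as.integer(similarity_term_overlap),
         similarity_threshold = similarity_threshold,
         multiple_linkage_threshold = multiple_linkage_threshold,
         ease_threshold = ease_threshold),
    class = "famseg_cluster_settings"
  )
}

#' Cohen's kappa between two gene sets over an input universe
#'
#' Chance-corrected agreement of the two binary membership vectors of
#' `genes_i` and `genes_j` over `input_genes`. With contingency counts
#' a (both), b (i only), c (j only), d (neither) and T = a+b+c+d:
#' Po = (a+d)/T, Pe = ((a+b)(a+c) + (c+d)(b+d))/T^2 and
#' kappa = (Po - Pe)/(1 - Pe). When Pe = 1 (no variation to agree on),
#' kappa is defined as 0.
#'
#' @param genes_i,genes_j Character vectors (subsets of `input_genes`).
#' @param input_genes Character vector: the gene universe of the input
#'   list; must have at least 2 genes.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_similarity <- function(genes_i, genes_j, input_genes) {
  T_n <- length(unique(input_genes))
  if (T_n < 2) {
    rlang::abort("kappa_similarity() needs an input universe of >= 2 genes.",
                 class = "famseg_domain_error")
  }
  genes_i <- intersect(genes_i, input_genes)
  genes_j <- intersect(genes_j, input_genes)
  a <- length(intersect(genes_i, genes_j))
  b <- length(setdiff(genes_i, genes_j))
  c <- length(setdiff(genes_j, genes_i))
  d <- T_n - a - b - c
  po <- (a + d) / T_n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / T_n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Build the term-similarity graph for clustering
#'
#' Filters enrichment results to terms with EASE score at or below the
#' EASE threshold, restricts each term's gene set to the input list, and
#' connects two terms when their kappa similarity reaches the similarity
#' threshold and they share at least `similarity_term_overlap` input
#' genes.
#'
#' @param results A `famseg_enrichment` computed with `method = "ease"`
#'   (or any tibble with `term` and `p_raw`).
#' @param annotation_map The `famseg_annotation_map` the results were
#'   computed on.
#' @param input_genes The input gene list (mapped to the universe).
#' @param settings A [cluster_settings()].
#' @return A list of class `famseg_term_graph`: `graph` (igraph, vertices
#'   carry `ease` and gene sets), `term_genes` (named list restricted to
#'   the input), `ease` (named numeric), `settings`.
#' @export
build_term_graph <- function(results, annotation_map, input_genes,
                             settings = cluster_settings()) {
  mapped <- intersect(unique(input_genes), annotation_map$universe)
  keep <- results$p_raw <= settings$ease_threshold
  terms <- sort(results$term[keep])
  ease <- setNames(results$p_raw[match(terms, results$term)], terms)
  term_genes <- lapply(setNames(terms, terms), function(t) {
    intersect(annotation_map$term_genes[[t]], mapped)
  })

  edges <- NULL
  if (length(terms) >= 2) {
    pairs <- utils::combn(terms, 2)
    keep_edge <- apply(pairs, 2, function(p) {
      gi <- term_genes[[p[1]]]; gj <- term_genes[[p[2]]]
      length(intersect(gi, gj)) >= settings$similarity_term_overlap &&
        kappa_similarity(gi, gj, mapped) >= settings$similarity_threshold
    })
    edges <- pairs[, keep_edge, drop = FALSE]
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(terms)
  if (!is.null(edges) && ncol(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(edges))
  }
  structure(list(graph = g, term_genes = term_genes, ease = ease,
                 input_genes = mapped, settings = settings),
            class = "famseg_term_graph")
}

#' Cluster enriched terms by shared gene membership
#'
#' Three-phase fuzzy clustering over the term-similarity graph:
#' \enumerate{
#'   \item Seeding: every term whose closed neighbourhood (itself plus
#'     graph neighbours) has at least `initial_group_membership` members
#'     seeds a candidate group.
#'   \item Merging: any two groups sharing at least
#'     `multiple_linkage_threshold` of the smaller group's members are
#'     merged, iterated to a fixed point (groups scanned in term-id
#'     order for determinism).
#'   \item Pruning: groups with fewer than `final_group_membership`
#'     terms are dropped. Remaining overlaps are resolved by assigning
#'     each term to the cluster with the highest mean kappa to its
#'     members (ties broken lexicographically), so reported clusters are
#'     disjoint.
#' }
#' Clusters are scored by the mean of `-log10` of the member terms' EASE
#' scores and reported in decreasing score order.
#'
#' @param term_graph A [build_term_graph()] result.
#' @return A tibble of class `famseg_term_clusters`: one row per cluster
#'   with `cluster`, `enrichment_score`, `n_terms`, `terms` (list
#'   column), `genes` (list column: union of member gene sets).
#' @export
cluster_terms <- function(term_graph) {
  g <- term_graph$graph
  st <- term_graph$settings
  terms <- sort(igraph::V(g)$name)
  if (length(terms) == 0) return(empty_clusters())

  # phase 1: closed-neighbourhood seeds
  seeds <- purrr::map(terms, function(t) {
    nb <- sort(c(t, igraph::neighbors(g, t)$name))
    if (length(nb) >= st$initial_group_membership) nb else NULL
  })
  groups <- purrr::compact(seeds)
  groups <- unique(groups)

  # phase 2: iterative merging on shared-member fraction
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(groups)) {
      j <- i + 1
      while (j <= length(groups)) {
        shared <- length(intersect(groups[[i]], groups[[j]]))
        smaller <- min(length(groups[[i]]), length(groups[[j]]))
        if (smaller > 0 &&
            shared / smaller >= st$multiple_linkage_threshold) {
          groups[[i]] <- sort(union(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          merged <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    groups <- unique(groups)
    if (!merged) break
  }

  # phase 3: prune small groups, then make clusters disjoint
  groups <- purrr::keep(groups, ~ length(.x) >= st$final_group_membership)
  if (length(groups) == 0) return(empty_clusters())
  groups <- groups[order(purrr::map_chr(groups, ~ .x[1]))]

  assign_to <- function(t) {
    cand <- which(purrr::map_lgl(groups, ~ t %in% .x))
    if (length(cand) <= 1) return(cand)
    mean_kappa <- purrr::map_dbl(cand, function(ci) {
      others <- setdiff(groups[[ci]], t)
      mean(purrr::map_dbl(others, function(o) {
        kappa_similarity(term_graph$term_genes[[t]],
                         term_graph$term_genes[[o]],
                         term_graph$input_genes)
      }))
    })
    cand[which.max(mean_kappa)] # which.max is first-wins: lexicographic tie-break
  }
  all_terms <- sort(unique(unlist(groups)))
  assignment <- purrr::map_int(all_terms, ~ as.integer(assign_to(.x)[1]))
  disjoint <- split(all_terms, assignment)
  disjoint <- purrr::keep(disjoint, ~ length(.x) >= st$final_group_membership)
  if (length(disjoint) == 0) return(empty_clusters())

  scores <- purrr::map_dbl(disjoint, function(ts) {
    cluster_enrichment_score(ts, term_graph$ease)
  })
  ord <- order(-scores, purrr::map_chr(disjoint, ~ .x[1]))
  res <- tibble::tibble(
    cluster = seq_along(ord),
    enrichment_score = unname(scores[ord]),
    n_terms = lengths(disjoint)[ord],
    terms = unname(disjoint[ord]),
    genes = purrr::map(disjoint[ord], function(ts) {
      sort(unique(unlist(term_graph$term_genes[ts])))
    })
  )
  structure(res, class = c("famseg_term_clusters", class(res)))
}

empty_clusters <- function() {
  structure(
    tibble::tibble(cluster = integer(), enrichment_score = double(),
                   n_terms = integer(), terms = list(), genes = list()),
    class = c("famseg_term_clusters",
              class(tibble::tibble()))
  )
}

#' Cluster enrichment score
#'
#' The geometric-mean-based score of a term cluster: the mean of
#' `-log10(EASE score)` over member terms (equivalently, minus the log of
#' the geometric mean of the member p-values). Higher scores mean more
#' enriched clusters. EASE scores of exactly 0 are clamped to the
#' smallest representable positive double, with a warning.
#'
#' @param terms Character vector of member term ids.
#' @param ease_pvalues Named numeric vector of EASE scores.
#' @return Non-negative score.
#' @export
cluster_enrichment_score <- function(terms, ease_pvalues) {
  p <- ease_pvalues[terms]
  if (any(is.na(p))) {
    rlang::abort("EASE score missing for some cluster member terms.",
                 class = "famseg_input_error")
  }
  if (any(p == 0)) {
    rlang::warn("EASE score of 0 clamped to .Machine$double.xmin.")
    p[p == 0] <- .Machine$double.xmin
  }
  mean(-log10(p))
}
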