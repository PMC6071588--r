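#' Run the full analysis pipeline on a simulated or loaded cohort
#'
#' Drives every stage end to end: per-family filter cascade, cohort
#' aggregation, overrepresentation analysis (Fisher and binomial modes),
#' EASE scoring, kappa-based term clustering, cilia classification and
#' location table, per-family functional-category matrix, and a run
#' manifest (seed, configuration digest, per-stage counts) sufficient to
#' reproduce the run.
#'
#' @param cohort A [simulate_cohort()] result (or a list with the same
#'   shape built from files).
#' @param filter_cfg Optional [filter_config()]; defaults to the
#'   standard cascade with the cohort's artifact blacklist.
#' @param settings [cluster_settings()] for term clustering.
#' @param alpha Significance level for enrichment flags.
#' @return A list of class `famseg_run`: `cascades`, `cohort_summary`,
#'   `enrichment_fisher`, `enrichment_binomial`, `enrichment_ease`,
#'   `clusters`, `cilia_locations`, `category_tags`, `manifest`.
#' @export
run_pipeline <- function(cohort, filter_cfg = NULL,
                         settings = cluster_settings(), alpha = 0.05) {
  if (is.null(filter_cfg)) {
    filter_cfg <- filter_config(artifact_blacklist = cohort$blacklist)
  }
  cascades <- cascade_cohort(cohort, filter_cfg)
  cohort_summary <- summarize_cohort(cascades)

  amap <- propagate_annotations(cohort$ontology, cohort$gene2term,
                                universe = cohort$universe)
  input_genes <- cohort_summary$gene_families$gene
  enr_fisher <- run_enrichment(input_genes, amap, method = "fisher",
                               alpha = alpha, correction = "bonferroni")
  enr_binom <- run_enrichment(input_genes, amap, method = "binomial",
                              alpha = alpha, correction = "none")
  enr_ease <- run_enrichment(input_genes, amap, method = "ease",
                             alpha = alpha, correction = "none")
  tg <- build_term_graph(enr_ease, amap, input_genes, settings)
  clusters <- cluster_terms(tg)

  variants <- dplyr::bind_rows(purrr::map(cascades, tidy))
  evidence <- classify_cilia(cohort$evidence)
  cilia_locations <- aggregate_locations(variants, evidence)
  category_tags <- tag_categories(variants[, c("family", "gene")],
                                  cohort$category_lists)

  manifest <- tibble::tibble(
    seed = cohort$seed %||% NA_integer_,
    config_digest = rlang::hash(cohort$config),
    n_families = length(cascades),
    total_retained = cohort_summary$totals$total_variants,
    unique_genes = cohort_summary$totals$unique_genes,
    m_terms_tested = attr(enr_fisher, "m_tests"),
    package_version = as.character(utils::packageVersion("famseg"))
  )

  structure(
    list(cascades = cascades, cohort_summary = cohort_summary,
         enrichment_fisher = enr_fisher,
         enrichment_binomial = enr_binom,
         enrichment_ease = enr_ease,
         clusters = clusters, cilia_locations = cilia_locations,
         category_tags = category_tags, manifest = manifest,
         annotation_map = amap),
    class = "famseg_run"
  )
}

#' @export
print.famseg_run <- function(x, ...) {
  cat("<famseg_run>\n")
  print(x$manifest)
  invisible(x)
}

#' Export significant terms and their direct relatives as a graph
#'
#' Builds an annotated subgraph of the ontology for visualisation:
#' terms with raw p-value at or below `alpha`, plus their direct parents
#' and children (first-degree relatives, flagged non-significant unless
#' themselves significant). Node attributes: `p_raw` (1 for untested
#' relatives), `k` (input genes annotated, 0 for untested), `name`,
#' `significant`; edge attribute `relation` (`is_a`/`part_of`). Written
#' as GraphML when `path` is given.
#'
#' @param results A `famseg_enrichment`.
#' @param ontology The `famseg_ontology` the results were computed on.
#' @param alpha Raw-p significance cutoff.
#' @param path Optional output path for GraphML export.
#' @return The igraph object, invisibly when writing.
#' @export
export_enrichment_graph <- function(results, ontology, alpha = 0.05,
                                    path = NULL) {
  sig <- results$term[results$p_raw <= alpha]
  relatives <- unique(unlist(purrr::map(sig, function(t) {
    e <- ontology$edges
    c(e$parent[e$child == t], e$child[e$parent == t])
  })))
  keep <- union(sig, relatives)
  edges <- ontology$edges[ontology$edges$child %in% keep &
                            ontology$edges$parent %in% keep, ]
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = keep)
  )
  if (nrow(edges)) igraph::E(g)$relation <- edges$relation
  hit <- match(keep, results$term)
  igraph::V(g)$p_raw <- ifelse(is.na(hit), 1, results$p_raw[hit])
  igraph::V(g)$k <- ifelse(is.na(hit), 0L, results$k[hit])
  igraph::V(g)$significant <- keep %in% sig
  nm <- setNames(ontology$terms$name, ontology$terms$term)
  igraph::V(g)$term_name <- unname(nm[keep])
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}

#' Summarise exome sequencing coverage
#'
#' Parses coverage values (numeric or strings such as `"53X"`) and
#' reports the cohort summary statistics: count, minimum, maximum, mean
#' and rounded mean.
#'
#' @param coverage A data frame with a `coverage` column, or a vector.
#' @return One-row tibble: `n`, `min`, `max`, `mean`, `mean_rounded`.
#' @export
summarize_coverage <- function(coverage) {
  x <- if (is.data.frame(coverage)) coverage$coverage else coverage
  x <- as.numeric(sub("[Xx]$", "", as.character(x)))
  tibble::tibble(
    n = length(x),
    min = min(x),
    max = max(x),
    mean = mean(x),
    mean_rounded = round(mean(x))
  )
}

#' Validate gene-group tables against their printed gene counts
#'
#' For tables listing term groups with a claimed gene count and the
#' corresponding comma-separated gene list, computes the cardinality of
#' each list and whether it matches the claimed count.
#'
#' @param groups Data frame with columns `group`, `n_genes` and `genes`
#'   (comma-separated string or list column).
#' @return The input with `n_genes_listed` and `count_matches` columns.
#' @export
group_gene_table <- function(groups) {
  df <- tibble::as_tibble(groups)
  gene_sets <- if (is.list(df$genes)) {
    df$genes
  } else {
    strsplit(as.character(df$genes), "\\s*,\\s*")
  }
  df$n_genes_listed <- vapply(gene_sets,
                              function(g) length(unique(g[nzchar(g)])),
                              integer(1))
  df$count_matches <- df$n_genes_listed == df$n_genes
  df
}

#' Write the main pipeline outputs as tab-separated tables
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in names(run$cascades)) {
    write_family_report(run$cascades[[f]],
                        file.path(dir, paste0(f, ".variants.tsv")))
  }
  readr::write_tsv(run$cohort_summary$gene_families,
                   file.path(dir, "cohort_genes.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(run$enrichment_fisher),
                   file.path(dir, "enrichment_fisher.tsv"),
                   progress = FALSE)
  cl <- run$clusters |>
    dplyr::mutate(terms = purrr::map_chr(.data$terms, paste,
                                         collapse = ","),
                  genes = purrr::map_chr(.data$genes, paste,
                                         collapse = ","))
  readr::write_tsv(cl, file.path(dir, "clusters.tsv"), progress = FALSE)
  readr::write_tsv(run$cilia_locations,
                   file.path(dir, "cilia_locations.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Enrichment results as a fold/significance dot plot
#'
#' @param object A `famseg_enrichment`.
#' @param top Number of top terms (by raw p) to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot famseg_enrichment
#' @export
autoplot.famseg_enrichment <- function(object, top = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$label <- ifelse(is.na(df$name), df$term, df$name)
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_raw),
    y = stats::reorder(.data$label, -.data$p_raw),
    size = .data$k, colour = .data$significant
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](p[raw])), y = NULL,
                  size = "Genes", colour = "Significant")
}
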