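#' Summarise retained variants and shared genes across families
#'
#' Aggregates per-family filtered variant sets into cohort-level counts:
#' per-family variant and gene totals, the map from each gene to the
#' families carrying a qualifying variant in it, a sharing histogram
#' (number of genes found in exactly k families), and overall totals.
#' Sharing is at the gene level (any variant in the gene counts);
#' identical-variant sharing across families is reported as a secondary
#' table.
#'
#' Variant totals count per-family records: a variant retained in two
#' families contributes twice, mirroring how per-family lists are
#' combined; the unique-variant total is reported alongside.
#'
#' @param family_sets Either a list of [run_cascade()] results, or a
#'   single tibble of retained variants with columns `family`, `gene`,
#'   `chrom`, `pos`, `ref`, `alt` (e.g. bound rows of family reports).
#' @return An object of class `famseg_cohort`: list with
#'   `family_summary`, `gene_families`, `sharing_histogram`,
#'   `shared_variants` tibbles and `totals` (one-row tibble).
#' @export
summarize_cohort <- function(family_sets) {
  df <- if (is.data.frame(family_sets)) {
    tibble::as_tibble(family_sets)
  } else {
    dplyr::bind_rows(purrr::map(family_sets, tidy))
  }
  fam_ids <- unique(df$family)
  if (!is.data.frame(family_sets)) {
    ids <- purrr::map_chr(family_sets, "family_id")
    if (anyDuplicated(ids)) {
      rlang::abort("Duplicate family id(s) in cohort.",
                   class = "famseg_duplicate_family_error")
    }
    fam_ids <- ids
  }

  family_summary <- df |>
    dplyr::group_by(family = factor(.data$family, levels = fam_ids)) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_genes = dplyr::n_distinct(stats::na.omit(.data$gene)),
      .groups = "drop"
    ) |>
    dplyr::mutate(family = as.character(.data$family))

  gene_families <- df |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::distinct(.data$gene, .data$family) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_families = dplyr::n(),
      families = paste(sort(.data$family), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_families), .data$gene)

  sharing_histogram <- gene_families |>
    dplyr::count(.data$n_families, name = "n_genes") |>
    dplyr::arrange(.data$n_families)

  shared_variants <- df |>
    dplyr::mutate(key = variant_key(df)) |>
    dplyr::distinct(.data$key, .data$family) |>
    dplyr::count(.data$key, name = "n_families") |>
    dplyr::filter(.data$n_families >= 2) |>
    dplyr::arrange(dplyr::desc(.data$n_families), .data$key)

  totals <- tibble::tibble(
    total_variants = nrow(df),
    unique_variants = dplyr::n_distinct(variant_key(df)),
    unique_genes = nrow(gene_families),
    genes_shared_by_two_or_more = sum(gene_families$n_families >= 2)
  )

  structure(
    list(family_summary = family_summary,
         gene_families = gene_families,
         sharing_histogram = sharing_histogram,
         shared_variants = shared_variants,
         totals = totals),
    class = "famseg_cohort"
  )
}

#' Genes shared by exactly k families
#'
#' @param cohort A `famseg_cohort` from [summarize_cohort()].
#' @param k Number of families.
#' @return Character vector of gene symbols.
#' @export
genes_shared_by <- function(cohort, k) {
  cohort$gene_families$gene[cohort$gene_families$n_families == k]
}

#' @export
print.famseg_cohort <- function(x, ...) {
  cat("<famseg_cohort> ", nrow(x$family_summary), " families, ",
      x$totals$total_variants, " variants in ",
      x$totals$unique_genes, " genes (",
      x$totals$genes_shared_by_two_or_more,
      " shared by >= 2 families)\n", sep = "")
  invisible(x)
}

#' @method tidy famseg_cohort
#' @export
tidy.famseg_cohort <- function(x, ...) {
  x$gene_families
}

#' @method glance famseg_cohort
#' @export
glance.famseg_cohort <- function(x, ...) {
  dplyr::bind_cols(
    x$totals,
    tibble::tibble(n_families = nrow(x$family_summary),
                   min_family_variants = min(x$family_summary$n_variants),
                   max_family_variants = max(x$family_summary$n_variants))
  )
}

#' Gene-sharing histogram as a bar chart
#'
#' @param object A `famseg_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot famseg_cohort
#' @export
autoplot.famseg_cohort <- function(object, ...) {
  ggplot2::ggplot(object$sharing_histogram,
                  ggplot2::aes(x = factor(.data$n_families),
                               y = .data$n_genes)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Families sharing the gene", y = "Genes",
                  title = "Cross-family gene sharing")
}
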