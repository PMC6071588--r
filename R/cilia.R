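#' Classify genes as cilia genes from curated evidence
#'
#' Decision rule over per-gene evidence flags:
#' \itemize{
#'   \item `"yes"` when the gene is listed in a cilia gene database
#'     (SYSCILIA Gold Standard or CCDB) or published evidence localises
#'     its protein to the cilium;
#'   \item `"potential"` when (failing that) published evidence suggests
#'     the protein interacts with the cilium;
#'   \item `"no"` otherwise — including genes whose only evidence is a
#'     GO-term association ("cilium" or "microtubule cytoskeleton"),
#'     which by itself never upgrades a gene.
#' }
#'
#' @param evidence A data frame with logical columns `in_syscilia`,
#'   `in_ccdb`, `in_go_cilium`, `in_go_microtubule`,
#'   `literature_localization`, `literature_interaction` (and optionally
#'   `gene`, `location` which are carried through).
#' @return The input tibble with a `cilia_class` column
#'   (`"yes"`/`"potential"`/`"no"`).
#' @export
classify_cilia <- function(evidence) {
  ev <- tibble::as_tibble(evidence)
  ev |>
    dplyr::mutate(
      cilia_class = dplyr::case_when(
        .data$in_syscilia | .data$in_ccdb |
          .data$literature_localization ~ "yes",
        .data$literature_interaction ~ "potential",
        TRUE ~ "no"
      )
    )
}

CILIA_LOCATIONS <- c("axoneme", "basal_body_centriole", "base_of_cilia",
                     "other_unknown")

#' Tabulate cilia variants by ciliary location
#'
#' Counts retained variants (not genes: a gene carrying two variants
#' contributes two) per ciliary location and cilia class, for classes
#' `"yes"` and `"potential"`, with a totals row.
#'
#' @param variants Tibble of retained variants with a `gene` column
#'   (e.g. bound [tidy()] outputs of per-family cascades).
#' @param evidence Classified evidence tibble from [classify_cilia()]
#'   with columns `gene`, `cilia_class`, `location`.
#' @return Tibble with columns `location`, `n_yes`, `n_potential`,
#'   ending in a `"total"` row.
#' @export
aggregate_locations <- function(variants, evidence) {
  joined <- variants |>
    dplyr::inner_join(
      dplyr::select(evidence, "gene", "cilia_class", "location"),
      by = "gene"
    ) |>
    dplyr::filter(.data$cilia_class %in% c("yes", "potential"))
  counts <- joined |>
    dplyr::count(
      location = factor(.data$location, levels = CILIA_LOCATIONS),
      .data$cilia_class, .drop = FALSE
    ) |>
    tidyr::pivot_wider(names_from = "cilia_class", values_from = "n",
                       names_prefix = "n_",
                       values_fill = 0L)
  for (col in c("n_yes", "n_potential")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts |>
    dplyr::filter(!is.na(.data$location)) |>
    dplyr::mutate(location = as.character(.data$location)) |>
    dplyr::select("location", "n_yes", "n_potential")
  dplyr::bind_rows(
    counts,
    tibble::tibble(location = "total",
                   n_yes = sum(counts$n_yes),
                   n_potential = sum(counts$n_potential))
  )
}

#' Tag genes with functional category membership
#'
#' Flags each gene for membership in the actin-cytoskeleton,
#' microtubule-cytoskeleton, core-matrisome (extracellular matrix) and
#' stereocilium category lists, and — when a `family` mapping is
#' supplied — reports a per-family presence/absence matrix over the
#' three headline categories.
#'
#' @param genes Character vector of gene symbols, or a tibble with
#'   columns `family` and `gene`.
#' @param category_lists Named list of character vectors with elements
#'   `actin_cytoskeleton`, `microtubule_cytoskeleton`,
#'   `ecm_core_matrisome` and optionally `stereocilium`.
#' @return A list with `gene_categories` (tibble: gene + logical flags)
#'   and, when families were supplied, `family_matrix` (tibble: family +
#'   logical presence flags for the three categories).
#' @export
tag_categories <- function(genes, category_lists) {
  fam <- NULL
  if (is.data.frame(genes)) {
    fam <- tibble::as_tibble(genes)[, c("family", "gene")]
    genes <- unique(fam$gene)
  }
  cats <- c("actin_cytoskeleton", "microtubule_cytoskeleton",
            "ecm_core_matrisome", "stereocilium")
  gene_categories <- tibble::tibble(gene = sort(unique(genes)))
  for (cat in cats) {
    members <- category_lists[[cat]] %||% character()
    gene_categories[[cat]] <- gene_categories$gene %in% members
  }
  out <- list(gene_categories = gene_categories)
  if (!is.null(fam)) {
    out$family_matrix <- fam |>
      dplyr::distinct() |>
      dplyr::left_join(gene_categories, by = "gene") |>
      dplyr::group_by(.data$family) |>
      dplyr::summarise(
        actin_cytoskeleton = any(.data$actin_cytoskeleton),
        microtubule_cytoskeleton = any(.data$microtubule_cytoskeleton),
        ecm_core_matrisome = any(.data$ecm_core_matrisome),
        .groups = "drop"
      )
  }
  out
}

#' Read a curated cilia evidence table
#'
#' Tab-separated file: `gene`, six logical evidence flags and `location`
#' (empty/NA when unknown).
#'
#' @param path Path to the evidence file.
#' @return Tibble.
#' @export
read_evidence <- function(path) {
  readr::read_tsv(
    path, progress = FALSE, na = c("", "NA"),
    col_types = readr::cols(
      gene = "c", in_syscilia = "l", in_ccdb = "l", in_go_cilium = "l",
      in_go_microtubule = "l", literature_localization = "l",
      literature_interaction = "l", location = "c"
    )
  )
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to a plain-text file, one gene symbol per line.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x[nzchar(x)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
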