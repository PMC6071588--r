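#' Load an ontology from an OBO file
#'
#' Reads an OBO v1.2 term stanza file into a directed acyclic graph of
#' terms. `is_a` and `relationship: part_of` edges are kept (child to
#' parent); obsolete terms are dropped together with any edge touching
#' them; an optional namespace filter restricts the graph to one branch
#' (e.g. `"cellular_component"`). Edges pointing at terms outside the
#' kept set are discarded.
#'
#' @param path Path to an OBO file.
#' @param namespace Optional single namespace to keep; `NULL` keeps all.
#' @return An object of class `famseg_ontology`: a list with
#'   `terms` (tibble: `term`, `name`, `namespace`),
#'   `edges` (tibble: `child`, `parent`, `relation`),
#'   `graph` (igraph, edges child -> parent) and `roots`
#'   (terms with no parent).
#' @export
load_obo <- function(path, namespace = NULL) {
  lines <- readr::read_lines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) {
    rlang::abort("No [Term] stanzas found in OBO file.",
                 class = "famseg_parse_error")
  }
  # any stanza header ends the previous term block
  stanza_ends <- c(which(grepl("^\\[", lines)), length(lines) + 1)

  terms <- vector("list", length(starts))
  edges <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    e <- min(stanza_ends[stanza_ends > s]) - 1
    block <- lines[s + 1:max(0, e - s)]
    block <- block[nzchar(block)]
    field <- function(key) {
      hits <- block[startsWith(block, paste0(key, ": "))]
      sub("\\s*(!.*)?$", "", substring(hits, nchar(key) + 3))
    }
    id <- field("id")
    if (length(id) != 1) next
    if (any(field("is_obsolete") == "true")) next
    nm <- field("name"); ns <- field("namespace")
    terms[[i]] <- tibble::tibble(
      term = id,
      name = if (length(nm)) nm[1] else NA_character_,
      namespace = if (length(ns)) ns[1] else NA_character_
    )
    isa <- field("is_a")
    rel <- field("relationship")
    rel <- rel[startsWith(rel, "part_of ")]
    po <- sub("^part_of\\s+", "", rel)
    if (length(isa) + length(po) > 0) {
      edges[[i]] <- tibble::tibble(
        child = id,
        parent = c(isa, po),
        relation = c(rep("is_a", length(isa)), rep("part_of", length(po)))
      )
    }
  }
  terms <- dplyr::bind_rows(terms)
  edges <- dplyr::bind_rows(edges)
  if (!is.null(namespace)) {
    terms <- dplyr::filter(terms, .data$namespace == .env$namespace)
  }
  if (nrow(edges)) {
    edges <- dplyr::filter(edges, .data$child %in% terms$term,
                           .data$parent %in% terms$term)
  } else {
    edges <- tibble::tibble(child = character(), parent = character(),
                            relation = character())
  }
  new_ontology(terms, edges)
}

new_ontology <- function(terms, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms[, "term", drop = FALSE]
  )
  if (nrow(edges)) {
    igraph::E(g)$relation <- edges$relation
  }
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (length(cyc) == 0) cyc <- "(self-loop)"
    rlang::abort(
      paste0("Ontology contains a cycle involving: ",
             paste(sort(cyc), collapse = ", ")),
      class = "famseg_cycle_error"
    )
  }
  roots <- terms$term[!(terms$term %in% edges$child)]
  structure(list(terms = terms, edges = edges, graph = g, roots = roots),
            class = "famseg_ontology")
}

#' @export
print.famseg_ontology <- function(x, ...) {
  cat("<famseg_ontology> ", nrow(x$terms), " terms, ", nrow(x$edges),
      " edges, root(s): ", paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ancestors of an ontology term
#'
#' All terms reachable from `term` by following child-to-parent edges
#' (`is_a` and `part_of`), excluding the term itself.
#'
#' @param ontology A `famseg_ontology`.
#' @param term A single term id.
#' @return Character vector of ancestor term ids.
#' @export
term_ancestors <- function(ontology, term) {
  out <- igraph::subcomponent(ontology$graph, term, mode = "out")
  setdiff(names(out), term)
}

#' Descendants of an ontology term
#'
#' @inheritParams term_ancestors
#' @return Character vector of descendant term ids.
#' @export
term_descendants <- function(ontology, term) {
  out <- igraph::subcomponent(ontology$graph, term, mode = "in")
  setdiff(names(out), term)
}

#' Propagate gene annotations up the ontology DAG
#'
#' Applies the true-path rule: a gene directly annotated to a term is
#' implicitly annotated to every ancestor of that term. Direct annotations
#' on unknown term ids are skipped with a warning reporting how many were
#' dropped.
#'
#' @param ontology A `famseg_ontology`.
#' @param annotations A data frame with columns `gene` and `term` (direct
#'   annotations).
#' @param universe Optional character vector defining the background gene
#'   universe; defaults to the annotated genes. Genes in the universe with
#'   no annotation still count toward the background size.
#' @return A `famseg_annotation_map`: list with `term_genes` (named list,
#'   ancestor-closed gene sets per term), `direct` (the kept direct
#'   annotation tibble), `universe`, and `term_names` (named character
#'   vector, where the ontology carries names).
#' @export
propagate_annotations <- function(ontology, annotations, universe = NULL) {
  annotations <- tibble::as_tibble(annotations)[, c("gene", "term")]
  known <- annotations$term %in% ontology$terms$term
  if (any(!known)) {
    rlang::warn(paste0("Skipping ", sum(!known),
                       " annotation(s) to unknown term ids."))
    annotations <- annotations[known, ]
  }
  annotations <- dplyr::distinct(annotations)
  if (is.null(universe)) universe <- sort(unique(annotations$gene))
  if (!all(annotations$gene %in% universe)) {
    rlang::abort("Every annotated gene must be in the universe.",
                 class = "famseg_input_error")
  }

  # ancestor closure per distinct directly-annotated term, then invert
  anc <- lapply(
    setNames(unique(annotations$term), unique(annotations$term)),
    function(t) c(t, term_ancestors(ontology, t))
  )
  closed <- annotations |>
    dplyr::mutate(all_terms = anc[.data$term]) |>
    tidyr::unnest_longer("all_terms")
  term_genes <- split(closed$gene, closed$all_terms)
  term_genes <- lapply(term_genes, function(g) sort(unique(g)))

  nm <- ontology$terms$name
  term_names <- setNames(nm, ontology$terms$term)
  structure(
    list(term_genes = term_genes, direct = annotations,
         universe = universe, term_names = term_names),
    class = "famseg_annotation_map"
  )
}

#' @export
print.famseg_annotation_map <- function(x, ...) {
  cat("<famseg_annotation_map> ", length(x$term_genes),
      " annotated terms, ", length(unique(x$direct$gene)),
      " annotated genes, universe N = ", length(x$universe), "\n", sep = "")
  invisible(x)
}

#' Read a two-column gene-to-term annotation file
#'
#' @param path Tab-separated file with columns `gene` and `term` (header
#'   optional: a first line whose second field looks like a term id is
#'   treated as data).
#' @return Tibble with columns `gene`, `term`.
#' @export
read_gene2term <- function(path) {
  df <- readr::read_tsv(path, col_names = c("gene", "term"),
                        col_types = "cc", progress = FALSE)
  if (nrow(df) && identical(tolower(unlist(df[1, ])),
                            c("gene", "term"))) {
    df <- df[-1, ]
  }
  df
}

#' Write an ontology back to OBO format
#'
#' Emits a minimal OBO v1.2 document ([load_obo()] round-trips it).
#'
#' @param ontology A `famseg_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  hdr <- c("format-version: 1.2", "")
  blocks <- purrr::map(seq_len(nrow(ontology$terms)), function(i) {
    t <- ontology$terms[i, ]
    e <- ontology$edges[ontology$edges$child == t$term, ]
    c("[Term]",
      paste0("id: ", t$term),
      paste0("name: ", t$name),
      paste0("namespace: ", t$namespace),
      ifelse(e$relation == "is_a",
             paste0("is_a: ", e$parent),
             paste0("relationship: part_of ", e$parent)),
      "")
  })
  readr::write_lines(c(hdr, unlist(blocks)), path)
  invisible(path)
}
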