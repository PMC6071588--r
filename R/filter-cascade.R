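#' Filter configuration for the variant retention cascade
#'
#' Bundles the tunable thresholds of the four record-level retention
#' rules. Defaults follow the familial-exome design: keep only
#' protein-altering consequences, strip variants with a population allele
#' frequency strictly above 5%, strip blacklisted artifact positions, and
#' require at least one of the four damaging-prediction tools to call the
#' variant damaging when it is annotated in dbNSFP.
#'
#' @param maf_threshold Population allele-frequency cutoff in `[0, 1]`;
#'   a variant is removed only when its frequency is strictly greater.
#' @param required_consequences Consequence classes retained.
#' @param min_damaging_tools Minimum number of damaging predictor calls
#'   (of SIFT, Polyphen2, LRT, MutationTaster) for dbNSFP-annotated
#'   variants; 1 to 4.
#' @param artifact_blacklist Character vector of `chrom:pos:ref:alt` keys
#'   to strip (see [variant_key()]).
#' @return A list of class `famseg_filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.05,
                          required_consequences = c("nonsynonymous_snv",
                                                    "coding_indel",
                                                    "splice_site"),
                          min_damaging_tools = 1,
                          artifact_blacklist = character()) {
  stopifnot(maf_threshold >= 0, maf_threshold <= 1,
            min_damaging_tools >= 1, min_damaging_tools <= 4)
  structure(
    list(maf_threshold = maf_threshold,
         required_consequences = required_consequences,
         min_damaging_tools = as.integer(min_damaging_tools),
         artifact_blacklist = artifact_blacklist),
    class = "famseg_filter_config"
  )
}

#' Retain protein-altering consequences
#'
#' Keeps records whose `consequence` is one of the required classes
#' (non-synonymous SNVs, coding indels, splice-site variants by default).
#' Row order is preserved.
#'
#' @param records Annotated variant tibble.
#' @param required_consequences Consequence classes to keep.
#' @return Filtered tibble.
#' @export
filter_consequence <- function(records,
                               required_consequences = c(
                                 "nonsynonymous_snv", "coding_indel",
                                 "splice_site")) {
  records[records$consequence %in% required_consequences, ]
}

#' Strip common variants by population allele frequency
#'
#' Removes a record only when its population frequency is present and
#' strictly greater than the threshold; variants absent from the
#' reference population (missing `pop_af`) are retained.
#'
#' @param records Annotated variant tibble.
#' @param maf_threshold Frequency cutoff (default 0.05).
#' @return Filtered tibble.
#' @export
filter_population_frequency <- function(records, maf_threshold = 0.05) {
  keep <- is.na(records$pop_af) | records$pop_af <= maf_threshold
  records[keep, ]
}

#' Strip blacklisted artifact positions
#'
#' @param records Annotated variant tibble.
#' @param blacklist Character vector of `chrom:pos:ref:alt` keys.
#' @return Filtered tibble.
#' @export
filter_artifacts <- function(records, blacklist = character()) {
  records[!(variant_key(records) %in% blacklist), ]
}

#' Require damaging-prediction support for dbNSFP-annotated variants
#'
#' A record not annotated in dbNSFP is retained unconditionally; an
#' annotated record is retained only when at least `min_damaging_tools`
#' of its SIFT / Polyphen2 / LRT / MutationTaster flags are damaging.
#'
#' @param records Annotated variant tibble.
#' @param min_damaging_tools Minimum damaging predictor calls (default 1).
#' @return Filtered tibble.
#' @export
filter_damaging <- function(records, min_damaging_tools = 1) {
  n_damaging <- rowSums(as.matrix(records[, PREDICTOR_COLS]), na.rm = TRUE)
  keep <- !records$dbnsfp | n_damaging >= min_damaging_tools
  records[keep, ]
}

#' Family segregation filter
#'
#' Retains a variant only when every sequenced family member shares the
#' alternate allele: each call must be `het`, `hom_alt` or `missing`, and
#' at least one member must have an observed carrier call (a variant
#' missing in all sequenced members is removed). Zygosity need not match
#' across members.
#'
#' @param records Variant tibble.
#' @param genotypes Long genotype tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `member`, `call`) covering every sequenced member.
#' @param sequenced_members Character vector of sequenced member ids.
#' @return Filtered tibble.
#' @export
filter_family_segregation <- function(records, genotypes,
                                      sequenced_members) {
  absent <- setdiff(sequenced_members, unique(genotypes$member))
  if (length(absent)) {
    rlang::abort(
      paste0("Sequenced member(s) absent from genotype matrix: ",
             paste(absent, collapse = ", ")),
      class = "famseg_config_error"
    )
  }
  gt <- genotypes[genotypes$member %in% sequenced_members, ]
  stat <- gt |>
    dplyr::mutate(key = variant_key(gt)) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      all_share = all(.data$call %in% c("het", "hom_alt", "missing")),
      any_carrier = any(.data$call %in% c("het", "hom_alt")),
      n_members = dplyr::n(),
      .groups = "drop"
    )
  ok <- stat$key[stat$all_share & stat$any_carrier &
                   stat$n_members >= length(sequenced_members)]
  records[variant_key(records) %in% ok, ]
}

#' Run the full per-family retention cascade
#'
#' Applies, in order: consequence filter, population-frequency filter,
#' artifact blacklist, damaging-prediction rule, then the family
#' segregation rule. The four record-level filters are pointwise
#' predicates and commute; the order fixes the per-stage counts reported
#' for auditing.
#'
#' @param family_id Family identifier.
#' @param records Annotated variant tibble.
#' @param genotypes Long genotype tibble for the family's sequenced
#'   members.
#' @param sequenced_members Character vector of sequenced member ids.
#' @param config A [filter_config()].
#' @return An object of class `famseg_cascade`: list with `family_id`,
#'   `retained` (tibble), `genes` (unique non-missing gene symbols) and
#'   `stage_counts` (tibble of record counts entering/leaving each stage).
#' @export
run_cascade <- function(family_id, records, genotypes, sequenced_members,
                        config = filter_config()) {
  stages <- list(
    consequence = function(x)
      filter_consequence(x, config$required_consequences),
    population_frequency = function(x)
      filter_population_frequency(x, config$maf_threshold),
    artifacts = function(x)
      filter_artifacts(x, config$artifact_blacklist),
    damaging = function(x)
      filter_damaging(x, config$min_damaging_tools),
    segregation = function(x)
      filter_family_segregation(x, genotypes, sequenced_members)
  )
  out <- tibble::as_tibble(records)
  counts <- tibble::tibble(stage = character(), n_in = integer(),
                           n_out = integer())
  for (nm in names(stages)) {
    n_in <- nrow(out)
    out <- stages[[nm]](out)
    counts <- dplyr::add_row(counts, stage = nm, n_in = n_in,
                             n_out = nrow(out))
  }
  structure(
    list(family_id = family_id,
         retained = out,
         genes = sort(unique(stats::na.omit(out$gene))),
         stage_counts = counts),
    class = "famseg_cascade"
  )
}

#' @export
print.famseg_cascade <- function(x, ...) {
  cat("<famseg_cascade> family ", x$family_id, ": ",
      nrow(x$retained), " variants retained in ", length(x$genes),
      " genes\n", sep = "")
  print(x$stage_counts)
  invisible(x)
}

#' @method tidy famseg_cascade
#' @export
tidy.famseg_cascade <- function(x, ...) {
  dplyr::mutate(x$retained, family = x$family_id, .before = 1)
}

#' @method glance famseg_cascade
#' @export
glance.famseg_cascade <- function(x, ...) {
  tibble::tibble(
    family = x$family_id,
    n_input = x$stage_counts$n_in[1],
    n_retained = nrow(x$retained),
    n_genes = length(x$genes)
  )
}
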