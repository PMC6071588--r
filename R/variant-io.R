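#' Variant key helper
#'
#' Canonical `chrom:pos:ref:alt` key identifying a split (biallelic)
#' variant record.
#'
#' @param chrom,pos,ref,alt Vectors of equal length (or a data frame with
#'   those columns passed as `chrom`).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"))
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read a multi-sample VCF into variant and genotype tables
#'
#' Parses a VCF (via vcfR), splits multiallelic records into one row per
#' alternate allele, re-expresses every genotype call against each split
#' alternate, and returns tidy tables sorted by `(chrom, pos, alt)`.
#' Rows where no named member carries the alternate are kept (calls
#' `hom_ref`): downstream filters, not the reader, decide retention.
#'
#' Genotype calls are coded `hom_ref`, `het`, `hom_alt` by the number of
#' copies of the split alternate allele; any call containing `.` is
#' `missing`.
#'
#' @param path Path to a VCF file with GT fields.
#' @param family_members Character vector of sample ids that must be
#'   present in the VCF.
#' @return A list with `variants` (tibble: `chrom`, `pos`, `ref`, `alt`)
#'   and `genotypes` (tibble: `chrom`, `pos`, `ref`, `alt`, `member`,
#'   `call`).
#' @export
read_vcf <- function(path, family_members) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  absent <- setdiff(family_members, samples)
  if (length(absent)) {
    rlang::abort(
      paste0("Sample id(s) absent from VCF: ",
             paste(absent, collapse = ", ")),
      class = "famseg_missing_sample_error",
      absent = absent
    )
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- tibble::tibble(
    chrom = vcf@fix[, "CHROM"],
    pos = as.integer(vcf@fix[, "POS"]),
    ref = vcf@fix[, "REF"],
    alt = vcf@fix[, "ALT"]
  )

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$alt[i], ",", fixed = TRUE)[[1]]
    purrr::map(seq_along(alts), function(a) {
      calls <- vapply(family_members, function(m) {
        recode_gt(gt[i, m], a)
      }, character(1))
      list(chrom = fix$chrom[i], pos = fix$pos[i], ref = fix$ref[i],
           alt = alts[a], calls = calls)
    })
  })
  rows <- purrr::flatten(rows)

  variants <- tibble::tibble(
    chrom = purrr::map_chr(rows, "chrom"),
    pos = purrr::map_int(rows, "pos"),
    ref = purrr::map_chr(rows, "ref"),
    alt = purrr::map_chr(rows, "alt")
  )
  genotypes <- variants |>
    dplyr::mutate(call_list = purrr::map(rows, "calls")) |>
    tidyr::unnest_longer("call_list", values_to = "call",
                         indices_to = "member") |>
    dplyr::mutate(call = unname(.data$call)) |>
    dplyr::select("chrom", "pos", "ref", "alt", "member", "call")

  ord <- order(variants$chrom, variants$pos, variants$alt)
  variants <- variants[ord, ]
  genotypes <- dplyr::arrange(genotypes, .data$chrom, .data$pos,
                              .data$alt, .data$member)
  list(variants = variants, genotypes = genotypes)
}

recode_gt <- function(gt, alt_index) {
  if (is.na(gt)) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".") || length(alleles) != 2) return("missing")
  n_alt <- sum(alleles == as.character(alt_index))
  c("hom_ref", "het", "hom_alt")[n_alt + 1]
}

#' Read a variant annotation table
#'
#' Tab-separated table keyed by `(chrom, pos, ref, alt)` with the columns
#' `gene`, `consequence`, `pop_af`, `dbnsfp`, the four damaging-prediction
#' flags (`sift`, `polyphen2`, `lrt`, `mutationtaster`) and `artifact`.
#'
#' @param path Path to the table.
#' @return Tibble with typed columns.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(
    path, progress = FALSE,
    col_types = readr::cols(
      chrom = "c", pos = "i", ref = "c", alt = "c", gene = "c",
      consequence = "c", pop_af = "d", dbnsfp = "l",
      sift = "l", polyphen2 = "l", lrt = "l", mutationtaster = "l",
      artifact = "l"
    )
  )
}

#' Join variant records with their annotations
#'
#' Left-joins the annotation table onto the variant records by
#' `(chrom, pos, ref, alt)`. Records with no annotation row receive the
#' documented defaults: `consequence = "other"`, `pop_af` missing,
#' `dbnsfp = FALSE`, all predictor flags `FALSE`, `artifact = FALSE`,
#' `gene` missing.
#'
#' @param records Tibble of variant records (from [read_vcf()]).
#' @param annotations Annotation tibble (from [read_annotations()]).
#' @return The records tibble with annotation columns appended.
#' @export
attach_annotations <- function(records, annotations) {
  key <- variant_key(annotations)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    rlang::abort(
      paste0("Duplicate annotation key(s): ", paste(dup, collapse = ", ")),
      class = "famseg_duplicate_key_error"
    )
  }
  out <- dplyr::left_join(records, annotations,
                          by = c("chrom", "pos", "ref", "alt"))
  out |>
    dplyr::mutate(
      consequence = dplyr::coalesce(.data$consequence, "other"),
      dbnsfp = dplyr::coalesce(.data$dbnsfp, FALSE),
      sift = dplyr::coalesce(.data$sift, FALSE),
      polyphen2 = dplyr::coalesce(.data$polyphen2, FALSE),
      lrt = dplyr::coalesce(.data$lrt, FALSE),
      mutationtaster = dplyr::coalesce(.data$mutationtaster, FALSE),
      artifact = dplyr::coalesce(.data$artifact, FALSE)
    )
}

#' Read a pedigree file
#'
#' PED-like tab-separated format with columns
#' `family member father mother sex affected sequenced`. Founders carry
#' `0` for both parents. `affected` uses 1 = affected, 0 = unaffected;
#' `sequenced` is 0/1.
#'
#' @param path Path to the pedigree file.
#' @return Tibble with those columns (`affected`, `sequenced` logical).
#' @export
read_pedigree <- function(path) {
  readr::read_tsv(
    path, progress = FALSE,
    col_types = readr::cols(
      family = "c", member = "c", father = "c", mother = "c",
      sex = "c", affected = "i", sequenced = "i"
    )
  ) |>
    dplyr::mutate(affected = .data$affected == 1L,
                  sequenced = .data$sequenced == 1L)
}

#' Write a per-family filtered variant report
#'
#' Emits the per-family list of retained variants as a tab-separated
#' table, one row per variant in coordinate order, including any
#' functional-category columns present (`actin_cytoskeleton`,
#' `microtubule_cytoskeleton`, `ecm_core_matrisome`, `cilia_class`).
#'
#' @param fvs A cascade result from [run_cascade()] or a tibble of
#'   retained variants with a `family` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_report <- function(fvs, path) {
  df <- if (inherits(fvs, "famseg_cascade")) {
    dplyr::mutate(fvs$retained, family = fvs$family_id, .before = 1)
  } else {
    tibble::as_tibble(fvs)
  }
  base_cols <- c("family", "gene", "chrom", "pos", "ref", "alt",
                 "consequence", "pop_af", PREDICTOR_COLS)
  extra <- intersect(
    c("actin_cytoskeleton", "microtubule_cytoskeleton",
      "ecm_core_matrisome", "cilia_class", "cilia_location"),
    names(df)
  )
  missing_cols <- setdiff(base_cols, names(df))
  for (mc in missing_cols) df[[mc]] <- NA
  df <- df[, c(base_cols, extra)]
  df <- dplyr::arrange(df, .data$chrom, .data$pos, .data$alt)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read back a per-family variant report
#'
#' @param path Path written by [write_family_report()].
#' @return Tibble of retained variants.
#' @export
read_family_report <- function(path) {
  readr::read_tsv(
    path, progress = FALSE,
    col_types = readr::cols(
      family = "c", gene = "c", chrom = "c", pos = "i", ref = "c",
      alt = "c", consequence = "c", pop_af = "d",
      sift = "l", polyphen2 = "l", lrt = "l", mutationtaster = "l",
      .default = readr::col_guess()
    )
  )
}
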