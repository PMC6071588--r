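ann_record <- function(pos, consequence = "nonsynonymous_snv",
                       pop_af = NA_real_, dbnsfp = FALSE,
                       sift = FALSE, polyphen2 = FALSE, lrt = FALSE,
                       mutationtaster = FALSE, gene = paste0("G", pos)) {
  tibble::tibble(chrom = "1", pos = as.integer(pos), ref = "A",
                 alt = "G", gene = gene, consequence = consequence,
                 pop_af = pop_af, dbnsfp = dbnsfp, sift = sift,
                 polyphen2 = polyphen2, lrt = lrt,
                 mutationtaster = mutationtaster, artifact = FALSE)
}

test_that("consequence filter keeps protein-altering classes, preserving order", {
  recs <- dplyr::bind_rows(
    ann_record(1, "nonsynonymous_snv"),
    ann_record(2, "other"),
    ann_record(3, "coding_indel"),
    ann_record(4, "other"),
    ann_record(5, "splice_site"),
    ann_record(6, "other")
  )
  out <- filter_consequence(recs)
  expect_equal(out$pos, c(1L, 3L, 5L))
})

test_that("frequency filter removes strictly above threshold, keeps missing", {
  recs <- dplyr::bind_rows(
    ann_record(1, pop_af = 0.051),
    ann_record(2, pop_af = 0.05),
    ann_record(3, pop_af = NA_real_)
  )
  out <- filter_population_frequency(recs, 0.05)
  expect_equal(out$pos, c(2L, 3L)) # 0.05 exactly is retained
})

test_that("artifact filter strips blacklisted keys only", {
  recs <- dplyr::bind_rows(lapply(1:10, ann_record))
  expect_identical(filter_artifacts(recs, character()), recs)
  out <- filter_artifacts(recs, c("1:3:A:G", "1:7:A:G", "1:999:A:G"))
  expect_equal(nrow(out), 8)
  expect_false(any(out$pos %in% c(3L, 7L)))
})

test_that("damaging filter is conditional on dbNSFP annotation", {
  recs <- dplyr::bind_rows(
    ann_record(1, dbnsfp = TRUE, sift = TRUE, polyphen2 = TRUE),
    ann_record(2, dbnsfp = TRUE),                       # all tools benign
    ann_record(3, dbnsfp = FALSE)                       # not annotated
  )
  out <- filter_damaging(recs, 1)
  expect_equal(out$pos, c(1L, 3L))
  # stricter requirement
  out2 <- filter_damaging(recs, 3)
  expect_equal(out2$pos, 3L)
})

seg_fixture <- function(calls, members = paste0("m", seq_along(calls))) {
  list(
    records = ann_record(1),
    genotypes = tibble::tibble(chrom = "1", pos = 1L, ref = "A",
                               alt = "G", member = members,
                               call = calls),
    members = members
  )
}

test_that("segregation filter requires the allele in every informative member", {
  all_het <- seg_fixture(c("het", "het", "het"))
  expect_equal(nrow(filter_family_segregation(
    all_het$records, all_het$genotypes, all_het$members)), 1)

  tolerant <- seg_fixture(c("het", "missing", "hom_alt"))
  expect_equal(nrow(filter_family_segregation(
    tolerant$records, tolerant$genotypes, tolerant$members)), 1)

  broken <- seg_fixture(c("het", "hom_ref", "het"))
  expect_equal(nrow(filter_family_segregation(
    broken$records, broken$genotypes, broken$members)), 0)

  no_data <- seg_fixture(c("missing", "missing", "missing"))
  expect_equal(nrow(filter_family_segregation(
    no_data$records, no_data$genotypes, no_data$members)), 0)
})

test_that("segregation filter rejects members absent from the matrix", {
  fx <- seg_fixture(c("het", "het"))
  expect_error(
    filter_family_segregation(fx$records, fx$genotypes,
                              c(fx$members, "ghost")),
    "ghost", class = "famseg_config_error"
  )
})

test_that("run_cascade removes the engineered counts per stage", {
  # 20 records: stages remove 5 (consequence), 3 (frequency),
  # 1 (artifact), 4 (damaging), 2 (segregation) -> 5 retained
  recs <- dplyr::bind_rows(
    lapply(1:5, function(i) ann_record(i, consequence = "other")),
    lapply(6:8, function(i) ann_record(i, pop_af = 0.2)),
    ann_record(9),
    lapply(10:13, function(i) ann_record(i, dbnsfp = TRUE)),
    lapply(14:20, function(i) ann_record(i, dbnsfp = TRUE, sift = TRUE))
  )
  members <- c("m1", "m2", "m3")
  gts <- tidyr::expand_grid(pos = 1:20, member = members) |>
    dplyr::mutate(chrom = "1", ref = "A", alt = "G",
                  pos = as.integer(pos),
                  call = ifelse(pos %in% 14:15 & member == "m2",
                                "hom_ref", "het"))
  cfg <- filter_config(artifact_blacklist = "1:9:A:G")
  res <- run_cascade("FAM", recs, gts, members, cfg)
  removed <- res$stage_counts$n_in - res$stage_counts$n_out
  expect_equal(removed, c(5L, 3L, 1L, 4L, 2L))
  expect_equal(nrow(res$retained), 5)
  expect_setequal(res$retained$pos, 16:20)
  expect_setequal(res$genes, paste0("G", 16:20))
})

test_that("record-level filters commute, are idempotent and monotone", {
  cfg <- filter_config(artifact_blacklist = c("1:11:A:G", "2:999:C:T"))
  filters <- list(
    function(x) filter_consequence(x, cfg$required_consequences),
    function(x) filter_population_frequency(x, cfg$maf_threshold),
    function(x) filter_artifacts(x, cfg$artifact_blacklist),
    function(x) filter_damaging(x, cfg$min_damaging_tools)
  )
  for (seed in 1:60) {
    recs <- random_records(25, seed)
    ref_keys <- sort(variant_key(
      Reduce(function(x, f) f(x), filters, recs)))
    perm <- sample(4)
    perm_keys <- sort(variant_key(
      Reduce(function(x, f) f(x), filters[perm], recs)))
    expect_identical(perm_keys, ref_keys)
    for (f in filters) {
      once <- f(recs)
      expect_identical(f(once), once)              # idempotent
      expect_true(all(variant_key(once) %in% variant_key(recs)))
    }
  }
})

test_that("segregation on simulated pedigrees is sound", {
  cfg <- sim_config(n_background_variants = 40)
  for (seed in c(11, 12, 13)) {
    co <- simulate_cohort(cfg, seed = seed)
    for (fam in co$families) {
      members <- fam$pedigree$member[fam$pedigree$sequenced]
      wide <- tidyr::pivot_wider(fam$genotypes, names_from = member,
                                 values_from = call)
      calls <- as.matrix(wide[, members])
      carrier_all <- apply(calls, 1, function(r) {
        all(r %in% c("het", "hom_alt", "missing")) &&
          any(r %in% c("het", "hom_alt"))
      })
      kept <- variant_key(filter_family_segregation(
        fam$variants, fam$genotypes, members))
      expect_setequal(kept, variant_key(wide)[carrier_all])
    }
  }
})

test_that("the cascade is idempotent and monotone end to end", {
  co <- simulate_cohort(sim_config(n_background_variants = 60), seed = 3)
  fam <- co$families$A
  members <- fam$pedigree$member[fam$pedigree$sequenced]
  cfg <- filter_config(artifact_blacklist = co$blacklist)
  records <- attach_annotations(fam$variants[, c("chrom", "pos", "ref",
                                                 "alt")],
                                fam$annotations)
  once <- run_cascade("A", records, fam$genotypes, members, cfg)
  twice <- run_cascade("A", once$retained, fam$genotypes, members, cfg)
  expect_identical(twice$retained, once$retained)
  expect_true(all(variant_key(once$retained) %in% variant_key(records)))
})
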