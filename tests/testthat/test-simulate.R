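test_that("pedigree relatives land at the requested kinship degrees", {
  degree_member <- c("1" = "sib", "2" = "aunt", "3" = "cousin",
                     "4" = "pc", "5" = "sc")
  for (d in 1:5) {
    ped <- simulate_pedigree(d, family_id = "T")
    m <- degree_member[[as.character(d)]]
    expect_true(m %in% ped$member)
    expect_true(ped$sequenced[ped$member == m])
    # kinship phi = 2^-(degree + 1)
    expect_equal(kinship_coefficient(ped, "p", m), 2^-(d + 1))
  }
  expect_error(simulate_pedigree(c(1, 7)),
               class = "famseg_pedigree_error")
})

test_that("pedigree construction is deterministic and well-formed", {
  p1 <- simulate_pedigree(c(1, 2, 4), family_id = "A")
  p2 <- simulate_pedigree(c(1, 2, 4), family_id = "A")
  expect_identical(p1, p2)
  # every non-founder has both parents in the pedigree
  non_founders <- p1[p1$father != "0", ]
  expect_true(all(non_founders$father %in% p1$member))
  expect_true(all(non_founders$mother %in% p1$member))
})

test_that("the obligate-carrier family sequences an unaffected grandparent", {
  ped <- simulate_pedigree(c(3, 2), family_id = "B",
                           obligate_carrier = TRUE)
  gm <- ped[ped$member == "gm", ]
  expect_true(gm$sequenced)
  expect_false(gm$affected)
  expect_equal(sum(ped$sequenced), 3)
  others <- ped[ped$sequenced & ped$member != "gm", ]
  expect_true(all(others$affected))
})

test_that("default study design sequences 16 members across 5 families", {
  cfg <- sim_config()
  n_seq <- vapply(names(cfg$degrees), function(f) {
    ped <- simulate_pedigree(cfg$degrees[[f]], f,
                             f == cfg$obligate_carrier_family)
    sum(ped$sequenced)
  }, integer(1))
  expect_equal(sum(n_seq), 16L)
  expect_true(all(n_seq %in% 3:4))
})

test_that("injected variants are carried by every sequenced member", {
  cfg <- sim_config(n_background_variants = 30)
  for (seed in 21:24) {
    co <- simulate_cohort(cfg, seed = seed)
    for (fam in co$families) {
      inj_keys <- variant_key(fam$variants[fam$variants$injected, ])
      gt <- fam$genotypes[variant_key(fam$genotypes) %in% inj_keys, ]
      expect_true(all(gt$call %in% c("het", "hom_alt", "missing")))
      carriers <- gt |>
        dplyr::group_by(key = variant_key(gt)) |>
        dplyr::summarise(n_obs = sum(call != "missing"))
      expect_true(all(carriers$n_obs >= 1))
    }
  }
})

test_that("transmission is Mendelian: no de novo alleles", {
  # with allele frequency 0 everywhere, every call is hom_ref
  ped <- simulate_pedigree(c(1, 2), family_id = "Z")
  variants <- tibble::tibble(chrom = "1", pos = 1:20, ref = "A",
                             alt = "G", af = 0, injected = FALSE)
  set.seed(1)
  gt <- simulate_genotypes(ped, variants, missing_rate = 0)
  expect_true(all(gt$call == "hom_ref"))
})

test_that("founder genotypes follow the variant allele frequency", {
  # 1000 independent founders, one variant at af = 0.3: the realised
  # allele frequency stays within 3 binomial standard errors
  ped <- tibble::tibble(
    family = "HW", member = sprintf("f%04d", 1:1000),
    father = "0", mother = "0", sex = "F",
    affected = FALSE, sequenced = TRUE
  )
  variants <- tibble::tibble(chrom = "1", pos = 1L, ref = "A",
                             alt = "G", af = 0.3, injected = FALSE)
  set.seed(5)
  gt <- simulate_genotypes(ped, variants, missing_rate = 0)
  dosage <- c(hom_ref = 0, het = 1, hom_alt = 2)[gt$call]
  af_hat <- sum(dosage) / (2 * nrow(gt))
  se <- sqrt(0.3 * 0.7 / (2 * nrow(gt)))
  expect_lt(abs(af_hat - 0.3), 3 * se)
})

test_that("generation is bit-reproducible from (config, seed)", {
  cfg <- sim_config(n_background_variants = 25)
  co1 <- simulate_cohort(cfg, seed = 99)
  co2 <- simulate_cohort(cfg, seed = 99)
  expect_identical(co1$families$A$genotypes, co2$families$A$genotypes)
  expect_identical(co1$gene2term, co2$gene2term)
  expect_identical(co1$blacklist, co2$blacklist)
  co3 <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(co1$families$A$genotypes,
                         co3$families$A$genotypes))
  expect_error(simulate_cohort(cfg), class = "famseg_input_error")
})

test_that("injected annotations survive every record-level filter", {
  co <- simulate_cohort(sim_config(n_background_variants = 30), seed = 8)
  for (fam in co$families) {
    ann <- fam$annotations[variant_key(fam$annotations) %in%
                             variant_key(fam$variants[
                               fam$variants$injected, ]), ]
    surv <- ann |>
      filter_consequence() |>
      filter_population_frequency() |>
      filter_artifacts(co$blacklist) |>
      filter_damaging()
    expect_equal(nrow(surv), nrow(ann))
  }
})

test_that("segregation probability matches forward simulation", {
  ped <- simulate_pedigree(c(1, 2), family_id = "S")
  af <- 0.3 # common enough to measure the pass rate precisely
  p_exact <- segregation_prob(ped, af, missing_rate = 0)
  n_sim <- 4000
  variants <- tibble::tibble(chrom = "1", pos = seq_len(n_sim),
                             ref = "A", alt = "G", af = af,
                             injected = FALSE)
  set.seed(17)
  gt <- simulate_genotypes(ped, variants, missing_rate = 0)
  kept <- filter_family_segregation(variants, gt,
                                    ped$member[ped$sequenced])
  p_hat <- nrow(kept) / n_sim
  se <- sqrt(p_exact * (1 - p_exact) / n_sim)
  expect_lt(abs(p_hat - p_exact), 3 * se)
})

test_that("segregation probability handles missingness and edge frequencies", {
  ped <- simulate_pedigree(c(1), family_id = "S")
  expect_equal(segregation_prob(ped, 0, 0), 0)
  expect_equal(segregation_prob(ped, 1, 0), 1)
  # missingness can only increase the pass probability
  p0 <- segregation_prob(ped, 0.1, 0)
  p_mu <- segregation_prob(ped, 0.1, 0.1)
  expect_gt(p_mu, p0)
  # with everyone missing the variant never passes
  expect_equal(segregation_prob(ped, 0.5, 1), 0)
})

test_that("the synthetic supplementary cohort carries its planted structure", {
  df <- simulate_supplementary_reports(seed = 3)
  cs <- summarize_cohort(df)
  expect_equal(cs$totals$total_variants, 270)
  expect_equal(cs$totals$unique_genes, 246)
  expect_equal(sum(cs$sharing_histogram$n_genes[
    cs$sharing_histogram$n_families == 2]), 8)
  expect_equal(range(cs$family_summary$n_variants), c(19, 89))
})

test_that("cohort inputs round-trip through the file interface", {
  co <- simulate_cohort(sim_config(n_background_variants = 15), seed = 6)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  fam <- co$families$A
  members <- fam$pedigree$member[fam$pedigree$sequenced]
  back <- read_vcf(file.path(dir, "A.vcf"), members)
  expect_equal(back$variants,
               fam$variants[, c("chrom", "pos", "ref", "alt")])
  gt_want <- dplyr::arrange(fam$genotypes, chrom, pos, alt, member)
  expect_equal(dplyr::arrange(back$genotypes, chrom, pos, alt, member),
               gt_want)
  ann <- read_annotations(file.path(dir, "A.annotations.tsv"))
  expect_equal(ann$pop_af, fam$annotations$pop_af)
  ped <- read_pedigree(file.path(dir, "cohort.ped"))
  expect_equal(sum(ped$sequenced), 16)
  onto <- load_obo(file.path(dir, "ontology.obo"))
  expect_equal(onto$terms, co$ontology$terms)
})
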