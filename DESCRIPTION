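Package: famseg
Title: Familial Rare-Variant Segregation Filtering and GO Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for exome studies of multigenerational
    families, built around familial idiopathic scoliosis. Filters
    multi-sample variant calls per family with a four-stage retention
    cascade (functional consequence, population allele frequency,
    artifact blacklist, damaging-prediction flags) and a segregation
    rule that requires the alternate allele in every sequenced family
    member while tolerating missing genotypes; aggregates gene sets
    across families; computes Gene Ontology overrepresentation
    statistics (one-sided Fisher, binomial, EASE score, fold
    enrichment, Bonferroni correction) over an annotation-propagated
    ontology DAG; clusters enriched terms by kappa similarity of
    shared gene membership; classifies genes against cilia evidence
    and functional category lists; and simulates complete synthetic
    study inputs (pedigrees, Mendelian genotypes, annotations,
    ontologies) with planted signal for known-answer validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
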