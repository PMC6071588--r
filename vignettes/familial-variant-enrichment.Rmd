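---
title: "Familial rare-variant segregation filtering and GO enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial rare-variant segregation filtering and GO enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
library(dplyr)
```

## The analysis problem

Idiopathic scoliosis (IS) is a structural lateral spinal curvature of at
least 10 degrees that affects up to 3% of otherwise healthy children,
with strong evidence for a genetic, likely polygenic, aetiology. A
productive design for dissecting such phenotypes is exome sequencing of
multigenerational families: within one family, a variant contributing
to a dominant-acting phenotype should be carried by every affected
(sequenced) member, which yields a very stringent filter without any
case/control cohort.

`famseg` implements that design as a reusable pipeline:

1. **Per-family filtering** of multi-sample variant calls with a
   four-stage record-level cascade plus a family segregation rule.
2. **Cross-family aggregation**: per-family gene sets, genes shared by
   k families, cohort totals.
3. **GO-term overrepresentation** of the combined gene list over an
   annotation-propagated ontology DAG, in three complementary modes
   (exact Fisher, binomial, EASE score).
4. **Functional annotation clustering** of enriched terms by the kappa
   statistic of shared gene membership.
5. **Cilia-gene classification** and ciliary-location tabulation from
   curated evidence, plus actin/microtubule/ECM category tagging.
6. **Synthetic data generation** with planted signal, so that every
   stage has a known-answer test.

## The filter cascade and the segregation rule

A variant record enters the cascade with its annotations: gene symbol,
consequence class, population allele frequency (ExAC-style), a flag for
dbNSFP membership, and four binarised damaging predictions (SIFT,
Polyphen2, LRT, MutationTaster). The stages are pointwise predicates
and therefore commute; the fixed order only defines the per-stage audit
counts:

* **Consequence**: keep non-synonymous SNVs, coding indels and
  splice-site variants.
* **Population frequency**: remove a record only when its frequency is
  *strictly* greater than the threshold (default 0.05, reflecting the
  relatively high population prevalence of IS); records absent from the
  reference population are kept.
* **Artifacts**: remove records whose `chrom:pos:ref:alt` key is on a
  user-supplied blacklist.
* **Damaging predictions**: a record annotated in dbNSFP is kept only
  if at least `min_damaging_tools` (default 1) of the four predictors
  call it damaging; unannotated records pass unconditionally.
* **Segregation**: a variant is kept only when every sequenced family
  member's genotype is heterozygous, homozygous alternate or missing,
  with at least one observed carrier. "Shared" means carrying at least
  one copy of the same alternate allele; zygosity need not match,
  consistent with a dominant model across generations.

Three reading notes on the segregation rule. First, missing genotypes
are tolerated (exome coverage is uneven), but a variant observed in *no*
member is removed: the tolerance clause presumes informative members
remain. Second, an unaffected obligate carrier who was sequenced is
treated exactly like the affected members — she must carry the familial
variant under the model, so affection status is metadata, not a filter
input. Third, the frequency comparison is strict at the boundary
(a 5.0% variant is kept; 5.1% is removed).

```{r cascade-demo}
co <- simulate_cohort(sim_config(n_background_variants = 60), seed = 11)
cascades <- cascade_cohort(co)
cascades$A$stage_counts
summarize_cohort(cascades) |> glance()
```

## Overrepresentation statistics

All three statistics share the counts *k* (input genes in the term),
*n* (mapped input genes), *K* (background genes in the term) and *N*
(background universe):

* `fisher_overrep()` — the exact one-sided hypergeometric upper tail
  \(P(X \ge k)\), the classical Fisher overrepresentation test.
* `binomial_overrep()` — the binomial upper tail at \(p_0 = K/N\), the
  sampling-with-replacement variant used by network-visualising tools.
* `ease_score()` — the Fisher tail recomputed after removing one gene
  from the observed overlap; it dominates the Fisher p-value and
  penalises categories supported by one or two genes. An overlap of 0
  or 1 scores exactly 1.
* `fold_enrichment()` — \(kN/(nK)\), undefined when the expectation is
  zero.
* `bonferroni_adjust()` — \( \min(1, p\,m) \).

Tails are evaluated in log space, so p-values below `1e-300` do not
underflow prematurely. `run_enrichment()` tests only terms with at
least one input gene and uses that count as the Bonferroni *m*
(reported in the result attributes), because the effective number of
testable terms depends on the input list; ranking ties are broken by
term id for determinism.

Annotation propagation follows the true-path rule over both `is_a` and
`part_of` edges, which is the conventional behaviour for cellular
component analyses. Genes present in the universe without annotations
still count toward *N*: dropping them would silently inflate every
enrichment. Identifier-mapping losses between tools are treated as
data (an unmapped-gene report), not logic.

## Kappa clustering of enriched terms

Enriched terms are clustered by the agreement of their gene membership
*within the input list*, not the whole genome: two terms are similar
when the same input genes drive both. `kappa_similarity()` is Cohen's
kappa of the two binary membership vectors; an edge requires kappa at
least 0.50 **and** at least 3 shared genes. Clustering is a three-phase
fuzzy scheme: closed-neighbourhood seeding (minimum group membership
2), iterative merging of groups sharing at least half of the smaller
group, and pruning of groups below the final membership (2). The widely
used implementation of this scheme is proprietary in its details, so
the exact cluster assignment here is this package's defined contract:
deterministic given term ids, with post-merge overlaps resolved by
assigning each term to the cluster with the highest mean kappa (ties
lexicographic). The cluster enrichment score is the mean of
\(-\log_{10}\) EASE scores of member terms — minus the log of their
geometric mean — with terms entering only below the EASE threshold 0.1.
Defaults mirror the relaxed stringency settings appropriate for
moderately sized familial gene lists.

## Cilia classification

GO cilium annotations lag the cilia literature, so the classifier uses
curated evidence: membership in the SYSCILIA Gold Standard or CCDB
databases, or published evidence localising the protein to the cilium,
classifies a gene **yes**; published interaction evidence alone gives
**potential**; everything else — including genes whose *only* evidence
is a GO "cilium" association — is **no**. Literature evidence arrives
pre-digested as two booleans in the evidence file; the pipeline never
queries literature databases. The location table counts *variants*,
not genes, per ciliary region, because recurrence of a gene in a family
list reflects independent variants.

## The synthetic study generator

`simulate_cohort()` generates the full input bundle under the study
design it emulates: five families, sixteen sequenced members, with
relatives at 1st–5th degree to the proband (sibling, aunt, first
cousin, first cousin once removed, second cousin) and one family whose
second-degree member is an unaffected obligate-carrier grandmother.
Founder genotypes are drawn under Hardy–Weinberg at each variant's
population frequency; transmission is Mendelian with no de novo events
and no genotyping error other than missingness (default rate 0.02).
These simplifications are deliberate: they keep the segregation filter
analytically tractable, so `segregation_prob()` can compute the exact
pass probability of a background variant by enumerating the joint
genotype distribution over the pedigree's blood line (married-in
founders with a single relevant child are integrated out analytically;
enumeration is bounded at 12 members).

Background allele frequencies are drawn from a *discrete* mixture
(defaults 0.002, 0.01, 0.04 rare; 0.08, 0.2, 0.4 common; 40% weight on
the at-or-below-5% tail). A discrete grid rather than a continuous
density was chosen so the analytic leakage expectation is a small
cached set of exact pedigree computations; the cascade itself never
depends on this choice. Injected variants are forced heterozygous along
the pedigree paths connecting the sequenced members (the topmost common
ancestor carries one alternate allele and transmits it along each
path), so they survive the segregation filter by construction, and
their annotations are built to pass every record-level stage. Other
defaults: 120 background variants per family, 90% of background
variants with a frequency entry, 80% dbNSFP-annotated, 25% per-tool
damaging rate, 2% artifact rate, a 2000-gene universe, and a 60-term
single-rooted ontology of depth 4 with one planted term annotated to
every injected gene.

What the generator does *not* emulate: linkage disequilibrium,
sequencing error, de novo mutation, population stratification, and the
exome-scale variant counts of a real study (tens of thousands before
filtering). Passing tests therefore demonstrate the correctness of the
filtering, aggregation and enrichment machinery under the declared
model — not robustness to artefacts real exomes contain upstream of
this pipeline.

```{r planted}
run <- run_pipeline(co)
head(tidy(run$enrichment_fisher), 3)
co$planted_term
```

## Numerical and design choices

* Coordinates are 1-based as in VCF; multiallelic records are split
  into one record per alternate allele and genotypes re-expressed per
  alternate; indels are matched by exact `(pos, ref, alt)` strings
  (left-alignment is assumed upstream).
* `pop_af` is one global frequency; per-population maxima are out of
  scope.
* Kappa with zero expected disagreement (`Pe = 1`) is defined as 0.
* EASE scores of exactly 0 are clamped to the smallest positive double
  with a warning before the log-scale cluster score.
* All tables are tab-separated with fixed column orders; the graph
  export is GraphML with typed node/edge attributes (significance,
  p-value, gene count, relation type), leaving layout and colour to the
  renderer.
* Problem sizes in the test suite (for example 200 simulated cohorts
  for the retention/leakage checks, 1000 replicates for null
  calibration, universes of 2000 genes) were chosen as the smallest
  sizes at which the binomial/3-standard-error bounds are informative.

## Known limitations

* The segregation filter implements a dominant sharing model only; no
  compound-heterozygote, recessive or de novo models.
* The clustering contract reproduces the documented seed/merge/prune
  scheme, not any proprietary tool byte-for-byte; scores are comparable
  only within a run.
* No false-discovery-rate correction is offered (Bonferroni or none),
  matching the analyses this pipeline reproduces.
* pLI/pRec constraint scores pass through as annotations; they are
  never used as filters.
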