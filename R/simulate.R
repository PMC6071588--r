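#' Simulation configuration for synthetic familial exome studies
#'
#' Defines the study conditions emulated by the generator: five
#' multigenerational families with three to four sequenced members each
#' (16 in all) at the stated relationship degrees to the proband, one
#' family carrying an unaffected obligate-carrier grandparent, per-family
#' background variants with a mixed common/rare allele-frequency
#' distribution (rare tail at or below 5%), injected fully-shared rare
#' damaging variants, dbNSFP-style predictor flags, an artifact
#' blacklist, and a random ontology DAG with one planted enriched term.
#'
#' @param n_families Number of families.
#' @param degrees List (one element per family) of relationship degrees
#'   of the sequenced relatives to the proband (the proband is implicit).
#' @param obligate_carrier_family Family id whose first 2nd-degree slot
#'   is realised as an unaffected sequenced grandparent (obligate
#'   carrier); `NULL` for none.
#' @param n_background_variants Background variants per family.
#' @param n_injected_shared Injected fully-shared variants per family.
#' @param af_values,af_weights Discrete population allele-frequency
#'   mixture for background variants (a grid keeps the segregation
#'   expectation exactly computable); includes a tail at or below 0.05.
#' @param injected_af Allele frequency recorded for injected variants.
#' @param missing_rate Per-call missing-genotype probability.
#' @param p_consequence_qualifying Probability a background variant has a
#'   protein-altering consequence.
#' @param p_af_reported Probability a background variant has a population
#'   frequency entry (absent entries are retained by the frequency
#'   filter).
#' @param p_dbnsfp Probability a background variant is dbNSFP-annotated.
#' @param predictor_damaging_rate Per-tool damaging probability for
#'   background variants.
#' @param artifact_rate Fraction of background variant keys placed on the
#'   artifact blacklist.
#' @param universe_size Background gene universe size N.
#' @param n_go_terms Terms in the synthetic ontology.
#' @param dag_depth Maximum depth of the ontology DAG (>= 2).
#' @param mean_terms_per_gene Mean direct annotations per universe gene.
#' @param planted_term_effect Fraction of injected genes annotated to the
#'   planted term.
#' @param shared_gene_pairs Number of injected genes planted into exactly
#'   two families (cross-family shared genes).
#' @return A list of class `famseg_sim_config`.
#' @export
sim_config <- function(n_families = 5,
                       degrees = list(A = c(1, 2, 4),
                                      B = c(3, 2),
                                      C = c(4, 5),
                                      D = c(3, 2),
                                      E = c(2, 3)),
                       obligate_carrier_family = "B",
                       n_background_variants = 120,
                       n_injected_shared = 2,
                       af_values = c(0.002, 0.01, 0.04, 0.08, 0.2, 0.4),
                       af_weights = c(0.15, 0.15, 0.1, 0.2, 0.2, 0.2),
                       injected_af = 0.002,
                       missing_rate = 0.02,
                       p_consequence_qualifying = 0.5,
                       p_af_reported = 0.9,
                       p_dbnsfp = 0.8,
                       predictor_damaging_rate = 0.25,
                       artifact_rate = 0.02,
                       universe_size = 2000,
                       n_go_terms = 60,
                       dag_depth = 4,
                       mean_terms_per_gene = 2,
                       planted_term_effect = 1,
                       shared_gene_pairs = 0) {
  stopifnot(length(degrees) == n_families, dag_depth >= 2,
            abs(sum(af_weights) - 1) < 1e-8,
            missing_rate >= 0, missing_rate <= 1,
            planted_term_effect >= 0, planted_term_effect <= 1)
  if (is.null(names(degrees))) names(degrees) <- LETTERS[seq_len(n_families)]
  structure(as.list(environment()), class = "famseg_sim_config")
}

#' Simulate a pedigree with relatives at requested degrees
#'
#' Builds a deterministic multigenerational pedigree containing the
#' proband plus one sequenced relative per requested degree:
#' 1 = sibling, 2 = aunt (or, for the obligate-carrier family, the
#' grandmother herself), 3 = first cousin, 4 = first cousin once removed
#' (a parent's cousin), 5 = second cousin. All sequenced members are
#' affected except an obligate-carrier grandparent. Ancestor scaffolding
#' (grandparents, great-grandparents, married-in founders) is added as
#' needed so every non-founder has both parents in the pedigree.
#'
#' @param degrees Integer vector of relationship degrees (1-5).
#' @param family_id Family identifier.
#' @param obligate_carrier Realise the first degree-2 slot as an
#'   unaffected sequenced grandmother.
#' @return Pedigree tibble: `family`, `member`, `father`, `mother`,
#'   `sex`, `affected`, `sequenced`.
#' @export
simulate_pedigree <- function(degrees, family_id = "A",
                              obligate_carrier = FALSE) {
  if (any(!degrees %in% 1:5)) {
    rlang::abort(
      paste0("Unrealizable relationship degree(s): ",
             paste(setdiff(degrees, 1:5), collapse = ", ")),
      class = "famseg_pedigree_error"
    )
  }
  rows <- list()
  add <- function(member, father = "0", mother = "0", sex = "F",
                  affected = FALSE, sequenced = FALSE) {
    rows[[member]] <<- tibble::tibble(
      family = family_id, member = member, father = father,
      mother = mother, sex = sex, affected = affected,
      sequenced = sequenced)
  }

  need_ggp <- any(degrees >= 4)
  need_gp <- any(degrees >= 2) || obligate_carrier
  if (need_ggp) {
    add("ggf", sex = "M"); add("ggm")
  }
  if (need_gp) {
    if (need_ggp) add("gf", "ggf", "ggm", sex = "M") else add("gf", sex = "M")
    add("gm")
    add("fa", "gf", "gm", sex = "M")
  } else {
    add("fa", sex = "M")
  }
  add("mo")
  add("p", "fa", "mo", affected = TRUE, sequenced = TRUE)

  used_obligate <- FALSE
  n_at <- integer(5)
  for (d in degrees) {
    n_at[d] <- n_at[d] + 1L
    suffix <- if (n_at[d] > 1) as.character(n_at[d]) else ""
    if (d == 1) {
      add(paste0("sib", suffix), "fa", "mo", affected = TRUE,
          sequenced = TRUE)
    } else if (d == 2) {
      if (obligate_carrier && !used_obligate) {
        used_obligate <- TRUE
        rows[["gm"]]$sequenced <- TRUE # unaffected obligate carrier
      } else {
        add(paste0("aunt", suffix), "gf", "gm", affected = TRUE,
            sequenced = TRUE)
      }
    } else if (d == 3) {
      au <- paste0("aunt_c", suffix); sp <- paste0("aunt_c_sp", suffix)
      add(au, "gf", "gm"); add(sp, sex = "M")
      add(paste0("cousin", suffix), sp, au, affected = TRUE,
          sequenced = TRUE)
    } else if (d == 4) {
      ensure_guncle_line(rows, add, suffix)
      add(paste0("pc_sp", suffix), sex = "M")
      rows[[paste0("pc", suffix)]]$affected <- TRUE
      rows[[paste0("pc", suffix)]]$sequenced <- TRUE
    } else if (d == 5) {
      ensure_guncle_line(rows, add, suffix)
      if (!paste0("pc_sp", suffix) %in% names(rows)) {
        add(paste0("pc_sp", suffix), sex = "M")
      }
      add(paste0("sc", suffix), paste0("pc_sp", suffix),
          paste0("pc", suffix), affected = TRUE, sequenced = TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

# great-uncle branch down to the parent's cousin ("pc"); shared by
# degree-4 and degree-5 relatives with the same suffix
ensure_guncle_line <- function(rows, add, suffix) {
  if (!paste0("pc", suffix) %in% names(rows)) {
    if (!"gu" %in% names(rows)) {
      add("gu", "ggf", "ggm", sex = "M")
      add("gu_sp")
    }
    add(paste0("pc", suffix), "gu", "gu_sp")
  }
  invisible(NULL)
}

ped_depth <- function(ped) {
  depth <- setNames(rep(NA_integer_, nrow(ped)), ped$member)
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(ped))) {
      m <- ped$member[i]
      if (!is.na(depth[m])) next
      fa <- ped$father[i]; mo <- ped$mother[i]
      if (fa == "0" && mo == "0") {
        depth[m] <- 0L
      } else if (!is.na(depth[fa]) && !is.na(depth[mo])) {
        depth[m] <- 1L + max(depth[fa], depth[mo])
      } else {
        done <- FALSE
      }
    }
    if (done) break
  }
  depth
}

ped_ancestors <- function(ped, member) {
  fa <- setNames(ped$father, ped$member)
  mo <- setNames(ped$mother, ped$member)
  out <- character()
  frontier <- member
  while (length(frontier)) {
    ps <- setdiff(unique(c(fa[frontier], mo[frontier])), c("0", out))
    out <- c(out, ps)
    frontier <- ps
  }
  out
}

#' Kinship coefficient between two pedigree members
#'
#' Recursive computation of the kinship coefficient
#' \eqn{\varphi(a, b)}: the probability that alleles sampled at random,
#' one from each individual, are identical by descent. Founders are
#' assumed unrelated and non-inbred. The relationship degree `d`
#' corresponds to \eqn{\varphi = 2^{-(d+1)}}.
#'
#' @param ped Pedigree tibble from [simulate_pedigree()] or
#'   [read_pedigree()].
#' @param a,b Member ids.
#' @return Kinship coefficient in `[0, 0.5]` (for non-inbred pairs).
#' @export
kinship_coefficient <- function(ped, a, b) {
  fa <- setNames(ped$father, ped$member)
  mo <- setNames(ped$mother, ped$member)
  depth <- ped_depth(ped)
  memo <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    if (x > y) { tmp <- x; x <- y; y <- tmp }
    key <- paste(x, y)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      if (fa[x] == "0") 0.5 else 0.5 * (1 + phi(fa[x], mo[x]))
    } else {
      # recurse on the deeper individual; distinct founders are unrelated
      deeper <- if (depth[x] >= depth[y]) x else y
      other <- if (identical(deeper, x)) y else x
      if (fa[deeper] == "0") 0 else
        0.5 * (phi(fa[deeper], other) + phi(mo[deeper], other))
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

#' Simulate Mendelian genotypes for a family
#'
#' Draws founder genotypes at each variant's population allele frequency
#' under Hardy-Weinberg equilibrium and transmits alleles Mendelianly
#' down the pedigree (no de novo events, no genotyping error). Variants
#' flagged `injected` are forced onto the pedigree: the topmost common
#' ancestor of the sequenced members is made heterozygous and the
#' alternate allele is transmitted along every path to a sequenced
#' member, so all sequenced members carry it. Missing calls are applied
#' independently at `missing_rate`, except that an injected variant is
#' never missing in all sequenced members.
#'
#' @param ped Pedigree tibble.
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `af`, `injected`.
#' @param missing_rate Per-call missing probability.
#' @return Long genotype tibble (`chrom`, `pos`, `ref`, `alt`, `member`,
#'   `call`) for the sequenced members.
#' @export
simulate_genotypes <- function(ped, variants, missing_rate = 0.02) {
  nv <- nrow(variants)
  depth <- ped_depth(ped)
  ord <- ped$member[order(depth[ped$member])]
  fa <- setNames(ped$father, ped$member)
  mo <- setNames(ped$mother, ped$member)
  members <- ped$member
  A1 <- matrix(0L, length(members), nv, dimnames = list(members, NULL))
  A2 <- A1
  for (m in ord) {
    if (fa[m] == "0") {
      A1[m, ] <- stats::rbinom(nv, 1, variants$af)
      A2[m, ] <- stats::rbinom(nv, 1, variants$af)
    } else {
      pick1 <- stats::runif(nv) < 0.5
      A1[m, ] <- ifelse(pick1, A1[fa[m], ], A2[fa[m], ])
      pick2 <- stats::runif(nv) < 0.5
      A2[m, ] <- ifelse(pick2, A1[mo[m], ], A2[mo[m], ])
    }
  }

  sequenced <- ped$member[ped$sequenced]
  inj <- which(variants$injected)
  if (length(inj)) {
    ca <- common_ancestor(ped, sequenced)
    edges <- forced_edges(ped, ca, sequenced)
    A1[ca, inj] <- 1L
    A2[ca, inj] <- 0L
    if (length(edges)) {
      for (e in edges) {
        if (fa[e$child] == e$parent) A1[e$child, inj] <- 1L
        else A2[e$child, inj] <- 1L
      }
    }
  }

  G <- A1[sequenced, , drop = FALSE] + A2[sequenced, , drop = FALSE]
  calls <- matrix(c("hom_ref", "het", "hom_alt")[G + 1],
                  nrow = length(sequenced),
                  dimnames = list(sequenced, NULL))
  miss <- matrix(stats::runif(length(calls)) < missing_rate,
                 nrow = length(sequenced))
  if (length(inj)) {
    all_missing <- colSums(!miss[, inj, drop = FALSE]) == 0
    miss[1, inj[all_missing]] <- FALSE
  }
  calls[miss] <- "missing"

  tidyr::expand_grid(member = sequenced, idx = seq_len(nv)) |>
    dplyr::mutate(
      chrom = variants$chrom[.data$idx],
      pos = variants$pos[.data$idx],
      ref = variants$ref[.data$idx],
      alt = variants$alt[.data$idx],
      call = calls[cbind(match(.data$member, sequenced), .data$idx)]
    ) |>
    dplyr::select("chrom", "pos", "ref", "alt", "member", "call")
}

# topmost member whose descendant-or-self set covers every sequenced member
common_ancestor <- function(ped, sequenced) {
  depth <- ped_depth(ped)
  anc_or_self <- lapply(setNames(sequenced, sequenced), function(s) {
    c(s, ped_ancestors(ped, s))
  })
  candidates <- Reduce(intersect, anc_or_self)
  if (length(candidates) == 0) {
    rlang::abort("Sequenced members share no common ancestor.",
                 class = "famseg_pedigree_error")
  }
  candidates[which.min(depth[candidates])]
}

forced_edges <- function(ped, ca, sequenced) {
  fa <- setNames(ped$father, ped$member)
  mo <- setNames(ped$mother, ped$member)
  anc_cache <- lapply(setNames(ped$member, ped$member), function(m) {
    c(m, ped_ancestors(ped, m))
  })
  edges <- list()
  for (s in setdiff(sequenced, ca)) {
    cur <- s
    while (cur != ca) {
      parent <- if (ca %in% anc_cache[[fa[cur]]] || fa[cur] == ca) {
        fa[cur]
      } else {
        mo[cur]
      }
      edges[[paste(parent, cur)]] <- list(parent = parent, child = cur)
      cur <- parent
    }
  }
  unname(edges)
}

#' Exact segregation-filter pass probability for a background variant
#'
#' Computes, by exact enumeration of the joint genotype distribution over
#' the pedigree (founders Hardy-Weinberg at frequency `af`, Mendelian
#' transmission), the probability that a biallelic variant passes the
#' family segregation filter: every sequenced member's call is carrier or
#' missing, with at least one observed carrier. Married-in founders with
#' a single relevant child are integrated out analytically, so the
#' enumeration runs over the "blood line" only.
#'
#' @param ped Pedigree tibble.
#' @param af Population alternate-allele frequency.
#' @param missing_rate Independent per-call missing probability.
#' @return Probability in `[0, 1]`.
#' @export
segregation_prob <- function(ped, af, missing_rate = 0) {
  sequenced <- ped$member[ped$sequenced]
  fa <- setNames(ped$father, ped$member)
  mo <- setNames(ped$mother, ped$member)
  depth <- ped_depth(ped)

  blood <- unique(c(sequenced,
                    unlist(lapply(sequenced, ped_ancestors, ped = ped))))
  # integrate out married-in founders with a single child in the blood set
  integrated <- character()
  for (f in blood) {
    if (fa[f] != "0" || f %in% sequenced) next
    children <- ped$member[(ped$father == f | ped$mother == f) &
                             ped$member %in% blood]
    if (length(children) == 1) {
      co <- if (fa[children] == f) mo[children] else fa[children]
      if (co %in% blood && !co %in% integrated && co != f) {
        integrated <- c(integrated, f)
      }
    }
  }
  E <- setdiff(blood, integrated)
  E <- E[order(depth[E], E)]
  nE <- length(E)
  if (nE > 12) {
    rlang::abort("Pedigree too large for exact enumeration (> 12 blood members).",
                 class = "famseg_pedigree_error")
  }

  hw <- c((1 - af)^2, 2 * af * (1 - af), af^2)
  trans <- function(g) c(1 - g / 2, g / 2) # allele transmission probs
  M2 <- array(0, c(3, 3, 3))
  for (gp in 0:2) for (gq in 0:2) {
    tp <- trans(gp)[2]; tq <- trans(gq)[2]
    M2[gp + 1, gq + 1, ] <- c((1 - tp) * (1 - tq),
                              tp * (1 - tq) + (1 - tp) * tq,
                              tp * tq)
  }
  T1 <- matrix(0, 3, 3) # one enumerated parent, spouse ~ HW
  for (gp in 0:2) {
    T1[gp + 1, ] <- colSums(hw * t(sapply(0:2, function(gq) {
      M2[gp + 1, gq + 1, ]
    })))
  }

  # enumerate joint genotypes over E in base 3
  n_cfg <- 3^nE
  idx <- matrix(0L, n_cfg, nE)
  rem <- 0:(n_cfg - 1)
  for (j in seq_len(nE)) {
    idx[, j] <- rem %% 3L
    rem <- rem %/% 3L
  }
  colnames(idx) <- E

  p_cfg <- rep(1, n_cfg)
  for (j in seq_len(nE)) {
    m <- E[j]
    g <- idx[, j] + 1L
    if (fa[m] == "0") {
      p_cfg <- p_cfg * hw[g]
    } else {
      in_fa <- fa[m] %in% E
      in_mo <- mo[m] %in% E
      if (in_fa && in_mo) {
        gp <- idx[, match(fa[m], E)] + 1L
        gq <- idx[, match(mo[m], E)] + 1L
        p_cfg <- p_cfg * M2[cbind(gp, gq, g)]
      } else {
        par <- if (in_fa) fa[m] else mo[m]
        gp <- idx[, match(par, E)] + 1L
        p_cfg <- p_cfg * T1[cbind(gp, g)]
      }
    }
  }

  mu <- missing_rate
  q <- rep(1, n_cfg)
  for (s in sequenced) {
    carrier <- idx[, match(s, E)] >= 1L
    q <- q * ifelse(carrier, 1, mu)
  }
  sum(p_cfg * (q - mu^length(sequenced)))
}

#' Simulate variant annotations for a family
#'
#' Background variants draw their consequence class, population-frequency
#' entry, dbNSFP flag and per-tool damaging flags from the configured
#' mixtures, so each record-level cascade stage removes a nonzero
#' expected fraction. Injected variants are constructed to survive every
#' stage: qualifying consequence, rare frequency, dbNSFP-annotated with
#' at least one damaging call.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`, `af`,
#'   `injected`, `gene`.
#' @param config A [sim_config()].
#' @return Annotation tibble in the [read_annotations()] layout.
#' @export
simulate_annotations <- function(variants, config) {
  n <- nrow(variants)
  qualifying <- c("nonsynonymous_snv", "coding_indel", "splice_site")
  consequence <- ifelse(
    stats::runif(n) < config$p_consequence_qualifying,
    sample(qualifying, n, replace = TRUE, prob = c(0.7, 0.15, 0.15)),
    "other"
  )
  pop_af <- ifelse(stats::runif(n) < config$p_af_reported,
                   variants$af, NA_real_)
  dbnsfp <- stats::runif(n) < config$p_dbnsfp
  flags <- matrix(stats::runif(4 * n) < config$predictor_damaging_rate,
                  nrow = n)
  inj <- variants$injected
  consequence[inj] <- "nonsynonymous_snv"
  pop_af[inj] <- config$injected_af
  dbnsfp[inj] <- TRUE
  flags[inj, 1] <- TRUE

  tibble::tibble(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    gene = variants$gene,
    consequence = consequence,
    pop_af = pop_af,
    dbnsfp = dbnsfp,
    sift = flags[, 1], polyphen2 = flags[, 2],
    lrt = flags[, 3], mutationtaster = flags[, 4],
    artifact = FALSE
  )
}

#' Simulate a synthetic ontology with a planted enriched term
#'
#' Builds a single-rooted random DAG of `n_go_terms` terms (levels up to
#' `dag_depth`; mostly `is_a` edges with occasional `part_of`), annotates
#' every universe gene directly to a Poisson number of random non-root
#' terms, and plants one maximum-depth term to which a configurable
#' fraction of the injected genes is additionally annotated.
#'
#' @param config A [sim_config()].
#' @param universe Character vector of background gene symbols.
#' @param injected_genes Genes to annotate to the planted term.
#' @return List with `ontology` (a `famseg_ontology`), `annotations`
#'   (gene/term tibble of direct annotations), `planted_term`.
#' @export
simulate_ontology <- function(config, universe, injected_genes = character()) {
  nt <- config$n_go_terms
  ids <- sprintf("T%04d", seq_len(nt))
  level <- c(1L, sample(2:config$dag_depth, nt - 1, replace = TRUE))
  # guarantee at least one term on every level so the DAG reaches dag_depth
  for (l in 2:config$dag_depth) {
    if (!any(level == l)) level[sample(which(seq_len(nt) > 1), 1)] <- l
  }
  edges <- purrr::map(which(level > 1), function(i) {
    lower <- which(level < level[i])
    n_par <- if (length(lower) > 1 && stats::runif(1) < 0.2) 2 else 1
    parents <- ids[sample(lower, n_par)]
    tibble::tibble(
      child = ids[i], parent = parents,
      relation = ifelse(stats::runif(n_par) < 0.1, "part_of", "is_a")
    )
  }) |> dplyr::bind_rows()
  terms <- tibble::tibble(
    term = ids,
    name = paste("synthetic component", seq_len(nt)),
    namespace = "cellular_component"
  )
  ontology <- new_ontology(terms, edges)

  non_root <- ids[-1]
  n_direct <- 1L + stats::rpois(length(universe),
                                max(config$mean_terms_per_gene - 1, 0))
  annotations <- tibble::tibble(
    gene = rep(universe, n_direct),
    term = unlist(purrr::map(n_direct, function(k) {
      sample(non_root, min(k, length(non_root)))
    }))
  )
  planted <- ids[level == max(level)][1]
  take <- stats::runif(length(injected_genes)) < config$planted_term_effect
  if (any(take)) {
    annotations <- dplyr::bind_rows(
      annotations,
      tibble::tibble(gene = injected_genes[take], term = planted)
    )
  }
  list(ontology = ontology,
       annotations = dplyr::distinct(annotations),
       planted_term = planted)
}

#' Simulate a complete synthetic study cohort
#'
#' End-to-end generator: pedigrees for every family, background and
#' injected variants, Mendelian genotypes, annotation tables, an
#' artifact blacklist, a synthetic ontology with planted enrichment, and
#' curated-evidence/category inputs. All output is reproducible from
#' `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A list of class `famseg_sim_cohort` with elements `config`,
#'   `seed`, `families` (per family: `pedigree`, `variants`,
#'   `genotypes`, `annotations`), `blacklist`, `ontology`,
#'   `gene2term`, `planted_term`, `injected`, `universe`, `evidence`,
#'   `category_lists`.
#' @export
simulate_cohort <- function(config = sim_config(), seed) {
  if (missing(seed)) {
    rlang::abort("`seed` is mandatory for reproducibility.",
                 class = "famseg_input_error")
  }
  set.seed(seed)
  fam_ids <- names(config$degrees)
  universe <- sprintf("G%04d", seq_len(config$universe_size))

  # injected gene assignment, with optional cross-family shared genes
  n_inj_total <- config$n_injected_shared * config$n_families
  shared_k <- min(config$shared_gene_pairs, n_inj_total %/% 2)
  inj_pool <- sample(universe, n_inj_total - shared_k)
  slots <- tibble::tibble(
    family = rep(fam_ids, each = config$n_injected_shared),
    gene = NA_character_
  )
  gi <- 1
  if (shared_k > 0) {
    pairs <- utils::combn(fam_ids, 2)
    pair_idx <- rep_len(seq_len(ncol(pairs)), shared_k)
    for (s in seq_len(shared_k)) {
      g <- inj_pool[gi]; gi <- gi + 1
      for (f in pairs[, pair_idx[s]]) {
        free <- which(slots$family == f & is.na(slots$gene))[1]
        slots$gene[free] <- g
      }
    }
  }
  slots$gene[is.na(slots$gene)] <-
    inj_pool[seq(gi, length.out = sum(is.na(slots$gene)))]
  injected_genes <- unique(slots$gene)

  onto <- simulate_ontology(config, universe, injected_genes)

  families <- list()
  blacklist <- character()
  pos_base <- 0L
  nb <- config$n_background_variants
  # background genes distinct across the whole cohort, so cross-family
  # gene sharing comes only from planted shared genes
  avail <- setdiff(universe, injected_genes)
  if (nb * length(fam_ids) > length(avail)) {
    rlang::abort("universe_size too small for distinct background genes.",
                 class = "famseg_input_error")
  }
  bg_pool <- sample(avail, nb * length(fam_ids))
  for (fi in seq_along(fam_ids)) {
    f <- fam_ids[fi]
    ped <- simulate_pedigree(
      config$degrees[[f]], family_id = f,
      obligate_carrier = identical(f, config$obligate_carrier_family)
    )
    inj_genes_f <- slots$gene[slots$family == f]
    n_inj <- length(inj_genes_f)
    bg_genes <- bg_pool[((fi - 1) * nb + 1):(fi * nb)]
    variants <- tibble::tibble(
      chrom = as.character(sample(1:22, nb + n_inj, replace = TRUE)),
      pos = pos_base + sample.int(9e6, nb + n_inj),
      ref = sample(c("A", "C", "G", "T"), nb + n_inj, replace = TRUE),
      alt = NA_character_,
      af = c(sample(config$af_values, nb, replace = TRUE,
                    prob = config$af_weights),
             rep(config$injected_af, n_inj)),
      injected = c(rep(FALSE, nb), rep(TRUE, n_inj)),
      gene = c(bg_genes, inj_genes_f)
    )
    variants$alt <- unname(vapply(variants$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1)))
    # dedupe coordinate collisions, preferring injected records
    variants <- variants[order(-variants$injected), ]
    variants <- variants[!duplicated(variant_key(variants)), ]
    variants <- dplyr::arrange(variants, .data$chrom, .data$pos, .data$alt)

    genotypes <- simulate_genotypes(ped, variants, config$missing_rate)
    annotations <- simulate_annotations(variants, config)
    bg_keys <- variant_key(variants[!variants$injected, ])
    blacklist <- c(blacklist,
                   sample(bg_keys, round(config$artifact_rate *
                                           length(bg_keys))))
    families[[f]] <- list(pedigree = ped, variants = variants,
                          genotypes = genotypes,
                          annotations = annotations)
    pos_base <- pos_base + 10000000L
  }

  cohort_genes <- unique(unlist(purrr::map(families,
                                           ~ .x$variants$gene)))
  evidence <- simulate_evidence(cohort_genes)
  category_lists <- list(
    actin_cytoskeleton = sample(universe, round(0.05 *
                                                  length(universe))),
    microtubule_cytoskeleton = sample(universe,
                                      round(0.05 * length(universe))),
    ecm_core_matrisome = sample(universe, round(0.04 * length(universe))),
    stereocilium = sample(universe, round(0.01 * length(universe)))
  )

  structure(
    list(config = config, seed = seed, families = families,
         blacklist = unique(blacklist), ontology = onto$ontology,
         gene2term = onto$annotations, planted_term = onto$planted_term,
         injected = slots, universe = universe, evidence = evidence,
         category_lists = category_lists),
    class = "famseg_sim_cohort"
  )
}

simulate_evidence <- function(genes) {
  n <- length(genes)
  ev <- tibble::tibble(
    gene = genes,
    in_syscilia = stats::runif(n) < 0.03,
    in_ccdb = stats::runif(n) < 0.03,
    in_go_cilium = stats::runif(n) < 0.05,
    in_go_microtubule = stats::runif(n) < 0.05,
    literature_localization = stats::runif(n) < 0.02,
    literature_interaction = stats::runif(n) < 0.03
  )
  ev <- classify_cilia(ev)
  ev$location <- ifelse(
    ev$cilia_class == "no", NA_character_,
    sample(CILIA_LOCATIONS, n, replace = TRUE,
           prob = c(0.35, 0.15, 0.3, 0.2))
  )
  dplyr::select(ev, -"cilia_class")
}

#' @export
print.famseg_sim_cohort <- function(x, ...) {
  cat("<famseg_sim_cohort> seed ", x$seed, ": ", length(x$families),
      " families, ", nrow(x$families[[1]]$variants),
      " variants in family 1, planted term ", x$planted_term, "\n",
      sep = "")
  invisible(x)
}

#' Run the filter cascade on every family of a simulated cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config Optional [filter_config()]; defaults to the standard
#'   cascade with the cohort's blacklist.
#' @return Named list of [run_cascade()] results.
#' @export
cascade_cohort <- function(cohort, config = NULL) {
  if (is.null(config)) {
    config <- filter_config(artifact_blacklist = cohort$blacklist)
  }
  purrr::imap(cohort$families, function(fam, fid) {
    records <- attach_annotations(
      fam$variants[, c("chrom", "pos", "ref", "alt")],
      fam$annotations
    )
    run_cascade(fid, records, fam$genotypes,
                fam$pedigree$member[fam$pedigree$sequenced], config)
  })
}

#' Write a minimal multi-sample VCF
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes Long genotype tibble (`member`, `call` per variant).
#' @param members Sample order for the VCF columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, members, path) {
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
              missing = "./.")
  wide <- genotypes |>
    dplyr::mutate(gt = gt_map[.data$call]) |>
    dplyr::select("chrom", "pos", "ref", "alt", "member", "gt") |>
    tidyr::pivot_wider(names_from = "member", values_from = "gt")
  df <- dplyr::left_join(variants, wide,
                         by = c("chrom", "pos", "ref", "alt"))
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", members), collapse = "\t")
  )
  body <- apply(df, 1, function(r) {
    paste(c(r[["chrom"]], r[["pos"]], ".", r[["ref"]], r[["alt"]],
            ".", "PASS", ".", "GT", r[members]), collapse = "\t")
  })
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write all inputs of a simulated cohort to a directory
#'
#' Emits per-family VCFs and annotation tables, a cohort pedigree file,
#' the artifact blacklist, the ontology (OBO), the direct gene-to-term
#' annotations, the curated cilia-evidence table and the category gene
#' lists — the complete file-level interface of the pipeline.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  peds <- list()
  for (f in names(cohort$families)) {
    fam <- cohort$families[[f]]
    seq_members <- fam$pedigree$member[fam$pedigree$sequenced]
    write_vcf(fam$variants[, c("chrom", "pos", "ref", "alt")],
              fam$genotypes, seq_members,
              file.path(dir, paste0(f, ".vcf")))
    readr::write_tsv(fam$annotations,
                     file.path(dir, paste0(f, ".annotations.tsv")),
                     progress = FALSE)
    peds[[f]] <- fam$pedigree
  }
  ped <- dplyr::bind_rows(peds) |>
    dplyr::mutate(affected = as.integer(.data$affected),
                  sequenced = as.integer(.data$sequenced))
  readr::write_tsv(ped, file.path(dir, "cohort.ped"), progress = FALSE)
  readr::write_lines(cohort$blacklist, file.path(dir, "blacklist.txt"))
  write_obo(cohort$ontology, file.path(dir, "ontology.obo"))
  readr::write_tsv(cohort$gene2term, file.path(dir, "gene2term.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$evidence, file.path(dir, "evidence.tsv"),
                   progress = FALSE)
  for (cat in names(cohort$category_lists)) {
    readr::write_lines(cohort$category_lists[[cat]],
                       file.path(dir, paste0(cat, ".txt")))
  }
  invisible(dir)
}

#' Synthetic analogue of the per-family supplementary variant lists
#'
#' Builds five per-family filtered-variant report tables with a planted
#' cohort structure chosen to mirror the published study's headline
#' counts: 270 variant rows in total, per-family counts spanning 19 to
#' 89, 246 unique genes, exactly 8 genes appearing in two families and
#' none in three or more. This is a synthetic stand-in for the study's
#' deposited supplementary file, for exercising the report reader and
#' cohort summariser when the original download is unavailable.
#'
#' @param seed Integer seed (affects cosmetic coordinates only; the
#'   planted counts are structural).
#' @return Tibble of 270 variant rows with a `family` column.
#' @export
simulate_supplementary_reports <- function(seed = 1) {
  set.seed(seed)
  fam_ids <- LETTERS[1:5]
  n_variants <- c(A = 89, B = 67, C = 52, D = 43, E = 19)
  n_gene_slots <- c(A = 80, B = 63, C = 49, D = 43, E = 19)
  shared_pairs <- list(c("A", "B"), c("A", "B"), c("A", "B"),
                       c("A", "C"), c("A", "C"),
                       c("B", "D"), c("B", "D"), c("C", "E"))
  shared_genes <- sprintf("SHARED%02d", seq_along(shared_pairs))

  fam_genes <- setNames(vector("list", 5), fam_ids)
  for (i in seq_along(shared_pairs)) {
    for (f in shared_pairs[[i]]) {
      fam_genes[[f]] <- c(fam_genes[[f]], shared_genes[i])
    }
  }
  private_needed <- n_gene_slots - lengths(fam_genes)
  gi <- 0
  for (f in fam_ids) {
    fam_genes[[f]] <- c(fam_genes[[f]],
                        sprintf("GENE%04d", gi + seq_len(private_needed[f])))
    gi <- gi + private_needed[f]
  }

  rows <- purrr::imap(fam_genes, function(genes, f) {
    extra <- n_variants[f] - length(genes)
    gene_col <- c(genes, genes[seq_len(extra)]) # duplicated genes: second variant
    n <- length(gene_col)
    tibble::tibble(
      family = f,
      gene = gene_col,
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(2e8, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = NA_character_,
      consequence = sample(c("nonsynonymous_snv", "coding_indel",
                             "splice_site"), n, replace = TRUE,
                           prob = c(0.8, 0.1, 0.1)),
      pop_af = round(stats::runif(n, 0, 0.05), 4),
      sift = TRUE, polyphen2 = FALSE, lrt = FALSE, mutationtaster = FALSE
    )
  })
  df <- dplyr::bind_rows(rows)
  df$alt <- unname(vapply(df$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1)))
  df
}
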