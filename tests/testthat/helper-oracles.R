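# Independent oracles and fixture builders used across the suite.
# Each oracle is deliberately implemented by a different route than the
# package code it checks (enumeration, DFS, direct counting).

# Upper-tail hypergeometric P(X >= k) by exhaustive subset enumeration:
# count the n-subsets of a universe of size N (K marked) whose overlap
# with the marked set is at least k.
hyper_tail_enum <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K) # elements 1..K are the marked ones
  mean(overlaps >= k)
}

ease_enum <- function(k, n, K, N) {
  if (k <= 1) return(1)
  hyper_tail_enum(k - 1, n, K, N)
}

# Binomial upper tail by direct term summation.
binom_tail_sum <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p0))
}

# Ancestor closure per term via hand-rolled DFS over the edge table.
dfs_ancestors <- function(edges, term) {
  out <- character()
  stack <- term
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    parents <- edges$parent[edges$child == cur]
    new <- setdiff(parents, out)
    out <- c(out, new)
    stack <- c(stack, new)
  }
  out
}

# Propagated term -> gene map by per-gene DFS reachability.
propagate_dfs <- function(edges, annotations, terms) {
  res <- setNames(vector("list", length(terms)), terms)
  for (i in seq_len(nrow(annotations))) {
    g <- annotations$gene[i]; t <- annotations$term[i]
    for (tt in c(t, dfs_ancestors(edges, t))) {
      res[[tt]] <- union(res[[tt]], g)
    }
  }
  lapply(res, sort)
}

# Kappa via explicit 2x2 contingency table over membership vectors.
kappa_contingency <- function(i, j, universe) {
  vi <- universe %in% i
  vj <- universe %in% j
  tab <- table(factor(vi, c(TRUE, FALSE)), factor(vj, c(TRUE, FALSE)))
  T_n <- sum(tab)
  po <- sum(diag(tab)) / T_n
  pe <- sum(rowSums(tab) * colSums(tab)) / T_n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

# Cilia classification oracle: sequential evidence checks, coded
# independently of the package's case_when rule.
cilia_oracle <- function(row) {
  database_evidence <- row$in_syscilia + row$in_ccdb
  if (database_evidence > 0) return("yes")
  if (row$literature_localization) return("yes")
  if (row$literature_interaction) return("potential")
  "no"
}

# Gene-sharing histogram by brute-force incidence counting.
sharing_hist_brute <- function(df) {
  inc <- unique(df[!is.na(df$gene), c("gene", "family")])
  counts <- table(table(inc$gene))
  setNames(as.integer(counts), names(counts))
}

# Random annotated variant table exercising every record-level filter.
random_records <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    chrom = as.character(sample(1:5, n, replace = TRUE)),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = sprintf("G%03d", sample.int(50, n, replace = TRUE)),
    consequence = sample(c("nonsynonymous_snv", "coding_indel",
                           "splice_site", "other"), n, replace = TRUE),
    pop_af = ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 0.2)),
    dbnsfp = runif(n) < 0.7,
    sift = runif(n) < 0.3, polyphen2 = runif(n) < 0.3,
    lrt = runif(n) < 0.3, mutationtaster = runif(n) < 0.3,
    artifact = FALSE
  ) |>
    dplyr::distinct(chrom, pos, ref, alt, .keep_all = TRUE)
}

# Minimal OBO text written to a temp file (cleaned up with `env`).
write_obo_text <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = env)
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

# Minimal VCF written to a temp file.
write_vcf_text <- function(body, samples) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
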