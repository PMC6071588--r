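#' One-sided Fisher (hypergeometric) overrepresentation p-value
#'
#' Exact upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}: the chance of drawing at least
#' `k` genes of an annotation category of size `K` when sampling `n` genes
#' without replacement from a background universe of size `N`. This is the
#' classical one-sided Fisher exact test used by GO overrepresentation tools.
#'
#' All arguments are vectorised and recycled to a common length. Tails are
#' computed in log-space internally, so p-values far below `1e-300` do not
#' underflow to an uninformative zero prematurely.
#'
#' @param k Observed overlap: genes in the input list annotated to the term.
#' @param n Input-list size (genes mapped to the universe).
#' @param K Background genes annotated to the term.
#' @param N Background universe size.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @seealso [binomial_overrep()], [ease_score()], [fold_enrichment()]
#' @examples
#' fisher_overrep(k = 3, n = 3, K = 4, N = 10) # 1/30
#' @export
fisher_overrep <- function(k, n, K, N) {
  check_overrep_bounds(k, n, K, N)
  # upper tail P(X >= k) = P(X > k - 1); exact, via log-space survival
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' One-sided binomial overrepresentation p-value
#'
#' Exact upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Binomial}(n, p_0)}, where `p0` is the background
#' annotation fraction `K/N`. This is the sampling-with-replacement
#' approximation used by BiNGO-style overrepresentation tests.
#'
#' @param k Observed overlap count.
#' @param n Input-list size.
#' @param p0 Background success probability (term fraction `K/N`).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' binomial_overrep(k = 2, n = 10, p0 = 0.1)
#' @export
binomial_overrep <- function(k, n, p0) {
  bad <- k < 0 | k > n | p0 < 0 | p0 > 1 | n < 0
  if (any(bad, na.rm = TRUE)) {
    rlang::abort("binomial_overrep() requires 0 <= k <= n and 0 <= p0 <= 1.",
                 class = "famseg_domain_error")
  }
  exp(stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE))
}

#' EASE score: conservative Fisher overrepresentation p-value
#'
#' The EASE score is the one-sided Fisher p-value recomputed after removing
#' one gene from the observed overlap, i.e. the upper tail \eqn{P(X \ge k-1)}
#' with the list size unchanged. It penalises categories supported by very
#' few genes and is always at least as large as the plain Fisher p-value.
#' An overlap of zero or one gene scores 1.
#'
#' @inheritParams fisher_overrep
#' @return Numeric vector of EASE scores in `[0, 1]`.
#' @examples
#' ease_score(k = 3, n = 3, K = 4, N = 10) # 1/3
#' @export
ease_score <- function(k, n, K, N) {
  check_overrep_bounds(k, n, K, N)
  len <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(k, len); n <- rep_len(n, len)
  K <- rep_len(K, len); N <- rep_len(N, len)
  p <- ifelse(
    k <= 1, 1,
    exp(stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  )
  pmin(p, 1)
}

#' Fold enrichment of an overlap relative to chance
#'
#' Observed overlap divided by its expectation under random sampling:
#' \eqn{\mathrm{fold} = k / (nK/N) = kN/(nK)}. Values above 1 indicate
#' overrepresentation. Undefined (returned as `NA`) when `K = 0` or `n = 0`.
#'
#' @inheritParams fisher_overrep
#' @return Numeric vector; `NA` where the expectation is zero.
#' @examples
#' fold_enrichment(k = 6, n = 251, K = 42, N = 20544)
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_overrep_bounds(k, n, K, N)
  ifelse(K > 0 & n > 0, k * N / (n * K), NA_real_)
}

#' Bonferroni multiple-testing correction
#'
#' Maps each raw p-value to `min(1, p * m)` for `m` tests performed.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Number of tests; must be at least `length(p)` and at least 1.
#' @return Corrected p-values, capped at 1.
#' @examples
#' bonferroni_adjust(1.55e-5, m = 1348)
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    rlang::abort("`m` must be a single count >= 1.",
                 class = "famseg_domain_error")
  }
  if (m < length(p)) {
    rlang::abort("`m` must be at least the number of p-values supplied.",
                 class = "famseg_domain_error")
  }
  pmin(1, p * m)
}

check_overrep_bounds <- function(k, n, K, N) {
  bad <- k < 0 | k > n | k > K | K > N | n > N
  if (any(bad, na.rm = TRUE)) {
    rlang::abort(
      "Overrepresentation counts must satisfy 0 <= k <= min(n, K) and n, K <= N.",
      class = "famseg_domain_error"
    )
  }
  invisible(NULL)
}

#' Term overrepresentation analysis over a propagated annotation map
#'
#' Tests every ontology term with at least one input gene for
#' overrepresentation against the background universe, using either the
#' exact Fisher (hypergeometric) test, the binomial approximation, or the
#' conservative EASE score. Bonferroni correction uses `m` equal to the
#' number of terms actually tested (overlap of at least one gene), which is
#' reported alongside the results.
#'
#' @param input_genes Character vector of gene symbols to test.
#' @param annotation_map A `famseg_annotation_map` from
#'   [propagate_annotations()], or any list with elements `term_genes`
#'   (named list of character vectors) and `universe` (character vector).
#' @param method One of `"fisher"`, `"binomial"`, `"ease"`.
#' @param alpha Significance level used for the significance flags.
#' @param correction `"bonferroni"` or `"none"`.
#' @return A tibble of class `famseg_enrichment`, one row per tested term,
#'   sorted by raw p-value (ties broken by term id) with columns
#'   `term`, `name`, `k`, `n`, `K`, `N`, `expected`, `fold`, `p_raw`,
#'   `p_adjusted`, `significant`, `significant_raw`, plus attributes
#'   `m_tests`, `method`, `alpha`, `unmapped` (input genes outside the
#'   universe).
#' @export
run_enrichment <- function(input_genes, annotation_map,
                           method = c("fisher", "binomial", "ease"),
                           alpha = 0.05,
                           correction = c("bonferroni", "none")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  universe <- annotation_map$universe
  term_genes <- annotation_map$term_genes
  input_genes <- unique(input_genes)
  mapped <- intersect(input_genes, universe)
  unmapped <- setdiff(input_genes, universe)
  if (length(mapped) == 0) {
    rlang::abort("No input genes map to the annotation universe.",
                 class = "famseg_input_error")
  }

  N <- length(universe)
  n <- length(mapped)
  k <- vapply(term_genes, function(g) length(intersect(g, mapped)), integer(1))
  K <- lengths(term_genes)
  keep <- k >= 1
  terms <- names(term_genes)[keep]
  k <- k[keep]; K <- K[keep]
  m <- length(terms)

  p_raw <- switch(method,
    fisher   = fisher_overrep(k, n, K, N),
    binomial = binomial_overrep(k, n, K / N),
    ease     = ease_score(k, n, K, N)
  )
  p_adj <- if (correction == "bonferroni") bonferroni_adjust(p_raw, m) else p_raw

  term_names <- annotation_map$term_names
  res <- tibble::tibble(
    term = terms,
    name = if (is.null(term_names)) NA_character_ else
      unname(term_names[terms]),
    k = as.integer(k), n = as.integer(n),
    K = as.integer(K), N = as.integer(N),
    expected = n * K / N,
    fold = fold_enrichment(k, n, K, N),
    p_raw = p_raw,
    p_adjusted = p_adj,
    significant = p_adj <= alpha,
    significant_raw = p_raw <= alpha
  ) |>
    dplyr::arrange(.data$p_raw, .data$term)

  structure(res,
            class = c("famseg_enrichment", class(res)),
            m_tests = m, method = method, alpha = alpha,
            correction = correction, unmapped = unmapped)
}

#' @method glance famseg_enrichment
#' @export
glance.famseg_enrichment <- function(x, ...) {
  tibble::tibble(
    m_tests = attr(x, "m_tests"),
    method = attr(x, "method"),
    alpha = attr(x, "alpha"),
    correction = attr(x, "correction"),
    n_significant = sum(x$significant),
    n_significant_raw = sum(x$significant_raw),
    n_unmapped = length(attr(x, "unmapped"))
  )
}

#' @method tidy famseg_enrichment
#' @export
tidy.famseg_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}
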