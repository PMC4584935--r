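# Hypergeometric over-representation of gene sets against term annotations
# with Benjamini-Hochberg FDR control, plus the gene-family representation
# contrast.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn from a universe of
#' `N` containing `K` annotated ones. Delegates to [stats::phyper()], which
#' accumulates in log space.
#'
#' @param k Observed overlap.
#' @param K Term size in the universe.
#' @param n Query size in the universe.
#' @param N Universe size.
#' @return p in (0, 1\].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    .stopf("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1,
#' returned in the original order (delegates to [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in (0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Read gene-set annotations in GMT format
#'
#' @param path GMT file (term, description, member genes, tab-separated).
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene-set annotations in GMT format
#' @param annotations Named list of character gene vectors.
#' @param path Output file.
#' @param descriptions Optional character vector of term descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(annotations))
  lines <- vapply(seq_along(annotations), function(i) {
    paste(c(names(annotations)[i], descriptions[i], annotations[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a gene set
#'
#' Tests each annotation term for over-representation in the query set
#' relative to the universe, with BH FDR across the tested terms. Query
#' genes outside the universe are dropped with a warning; term memberships
#' are intersected with the universe; terms smaller than `min_term_size`
#' in the universe are excluded (logged).
#'
#' @param query Character vector of query gene symbols.
#' @param annotations Named list of term gene vectors, or a GMT file path.
#' @param universe Character vector of background gene symbols.
#' @param alpha Significance level on q (default 0.05).
#' @param min_term_size Minimum in-universe term size to test (default 3).
#' @return Data frame sorted by (q, p): `term`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, `significant`.
#' @export
enrich_gene_set <- function(query, annotations, universe, alpha = 0.05,
                            min_term_size = 3) {
  if (is.character(annotations) && length(annotations) == 1 &&
      file.exists(annotations))
    annotations <- read_gmt(annotations)
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) .stopf("empty universe")
  if (!length(query)) .stopf("empty query gene set")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    .warnf("%d query genes outside the universe were dropped", length(outside))
    query <- intersect(query, universe)
    if (!length(query)) .stopf("no query genes remain inside the universe")
  }
  terms <- lapply(annotations, intersect, universe)
  sizes <- lengths(terms)
  small <- sizes < min_term_size
  if (any(small))
    message(sprintf("excluding %d terms with fewer than %d genes in the universe",
                    sum(small), min_term_size))
  terms <- terms[!small]
  n <- length(query); N <- length(universe)
  k <- vapply(terms, function(tg) length(intersect(tg, query)), integer(1))
  K <- lengths(terms)
  p <- hypergeom_upper(k, K, n, N)
  q <- bh_adjust(p)
  out <- data.frame(term = names(terms), k = k, K = K, n = n, N = N,
                    p = p, q = q, significant = q < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Gene-family representation contrast
#'
#' Whether one gene family is over-represented among affected genes
#' compared with a reference family of comparable size (e.g. olfactory
#' receptors against histone/actin families): two-sided Fisher exact test
#' on (affected, unaffected) x (family, reference family).
#'
#' @param family Gene symbols of the family of interest (nonempty).
#' @param affected Gene symbols carrying qualifying variants.
#' @param universe Background gene symbols containing both families.
#' @param reference_family Gene symbols of the comparison family; must be
#'   disjoint from `family`.
#' @return A `fisher2x2` (see [fisher_exact_2x2()]).
#' @export
family_representation_test <- function(family, affected, universe,
                                       reference_family) {
  family <- unique(family); reference_family <- unique(reference_family)
  if (!length(family)) .stopf("empty gene family")
  if (!length(reference_family)) .stopf("empty reference family")
  if (length(intersect(family, reference_family)))
    .stopf("family and reference_family must be disjoint")
  family <- intersect(family, universe)
  reference_family <- intersect(reference_family, universe)
  aff <- intersect(unique(affected), universe)
  tab <- rbind(family = c(sum(family %in% aff), sum(!family %in% aff)),
               reference = c(sum(reference_family %in% aff),
                             sum(!reference_family %in% aff)))
  colnames(tab) <- c("affected", "unaffected")
  fisher_exact_2x2(tab)
}
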