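# Substitution-spectrum accounting and the novelty-stratified
# transition-excess test: elevated A<->G / C<->T transition fractions among
# novel SNVs are the editing signature this module quantifies.

.BASES <- c("A", "C", "T", "G")
.TRANSITIONS <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))

#' 4x4 substitution count matrix
#'
#' Counts SNVs by (reference allele, alternate allele); the diagonal is
#' undefined (NA). Input must contain SNVs only.
#'
#' @param snvs A `sample_callset` or variant data frame of SNVs.
#' @return 4x4 integer matrix indexed A, C, T, G (rows = ref, cols = alt),
#'   NA diagonal, with attribute `total`.
#' @export
substitution_matrix <- function(snvs) {
  v <- if (inherits(snvs, "sample_callset")) snvs$variants else snvs
  if (nrow(v) && any(v$var_class != "SNV", na.rm = TRUE))
    .stopf("substitution_matrix accepts SNVs only (found %d non-SNV records)",
           sum(v$var_class != "SNV", na.rm = TRUE))
  m <- matrix(0L, 4, 4, dimnames = list(ref = .BASES, alt = .BASES))
  if (nrow(v)) {
    tab <- table(factor(v$ref, .BASES), factor(v$alt, .BASES))
    m[] <- as.integer(tab)
  }
  total <- sum(m[row(m) != col(m)])
  diag(m) <- NA_integer_
  attr(m, "total") <- total
  m
}

#' Read a substitution count matrix from a TSV file
#'
#' Tab-separated 4x4 count table with a `ref` row-label column and columns
#' `A`, `C`, `T`, `G`; `#` starts a comment; the diagonal may be `NA`. The
#' package ships an example under
#' `system.file("extdata", "ibs_somatic_substitutions.tsv",
#' package = "exopattern")`.
#'
#' @param path Input file.
#' @return 4x4 matrix (rows = ref, cols = alt) with NA diagonal and a
#'   `total` attribute.
#' @export
read_substitution_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#", row.names = 1,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!all(.BASES %in% rownames(m)) || !all(.BASES %in% colnames(m)))
    .stopf("substitution matrix must be indexed by A, C, T, G")
  m <- m[.BASES, .BASES]
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("ref", "alt")
  attr(m, "total") <- sum(m[row(m) != col(m)], na.rm = TRUE)
  diag(m) <- NA_integer_
  m
}

#' Transition fraction of a substitution spectrum
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); everything else off-diagonal is a transversion.
#'
#' @param matrix A matrix from [substitution_matrix()].
#' @param stratum Optional label carried into the result.
#' @return A `titv_stratum` list: `stratum`, `transitions`, `transversions`,
#'   `fraction` = transitions / (transitions + transversions).
#' @export
transition_fraction <- function(matrix, stratum = NA_character_) {
  ti <- sum(matrix[.TRANSITIONS])
  total <- sum(matrix[row(matrix) != col(matrix)], na.rm = TRUE)
  if (total == 0) .stopf("empty spectrum: no substitutions counted")
  tv <- total - ti
  structure(list(stratum = stratum, transitions = as.integer(ti),
                 transversions = as.integer(tv), fraction = ti / total),
            class = "titv_stratum")
}

#' @export
print.titv_stratum <- function(x, ...) {
  cat(sprintf("<titv_stratum> %s: %d transitions / %d transversions (fraction %.4f)\n",
              x$stratum %||% "", x$transitions, x$transversions, x$fraction))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of
#' hypergeometric point probabilities at most that of the observed table
#' (within a relative tolerance of 1e-7, the standard convention). Point
#' probabilities are accumulated from log factorials, so the computation is
#' exact in practice for totals up to about 1e6. The reported odds ratio is
#' the sample estimate `(a d) / (b c)`, flagged as such. A zero row or
#' column margin carries no information: p = 1 with a warning.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A `fisher2x2` list: `table`, `odds_ratio`, `estimate_type`,
#'   `p_two_sided`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) .stopf("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) .stopf("counts must be nonnegative integers")
  odds <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    .warnf("zero margin in 2x2 table: p = 1")
    return(structure(list(table = tab, odds_ratio = NA_real_,
                          estimate_type = "sample", p_two_sided = 1),
                     class = "fisher2x2"))
  }
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)
  log_obs <- logp[x == tab[1, 1]]
  p <- sum(exp(logp[logp <= log_obs + 1e-7]))
  structure(list(table = tab, odds_ratio = odds,
                 estimate_type = "sample",
                 p_two_sided = min(1, p)),
            class = "fisher2x2")
}

#' @export
print.fisher2x2 <- function(x, ...) {
  cat(sprintf("<fisher2x2> OR (%s) = %.4g, two-sided p = %.4g\n",
              x$estimate_type, x$odds_ratio, x$p_two_sided))
  print(x$table)
  invisible(x)
}

#' Novelty-stratified transition/transversion test
#'
#' Splits a callset's SNVs into novel and known strata against a
#' known-variant catalog, computes the transition fraction in each, and
#' tests the 2x2 table (transitions, transversions) x (novel, known) with
#' the two-sided Fisher exact test. An excess transition fraction in the
#' novel stratum is the editing signature.
#'
#' @param callset A `sample_callset`.
#' @param catalog Known-variant catalog (see [read_variant_catalog()]).
#' @param af_threshold Novelty frequency threshold (default 0.01).
#' @return A `titv_test` list: `novel`, `known` (each a `titv_stratum`) and
#'   `fisher` (a `fisher2x2`).
#' @export
stratified_titv_test <- function(callset, catalog, af_threshold = 0.01) {
  v <- callset$variants
  snv <- v[v$var_class == "SNV", , drop = FALSE]
  if (!nrow(snv)) .stopf("callset has no SNVs")
  novelty <- classify_novelty(snv, catalog, af_threshold)
  for (s in c("novel", "known"))
    if (!any(novelty == s)) .stopf("stratum '%s' has zero SNVs", s)
  res <- lapply(c(novel = "novel", known = "known"), function(s) {
    transition_fraction(substitution_matrix(snv[novelty == s, , drop = FALSE]),
                        stratum = s)
  })
  tab <- rbind(novel = c(res$novel$transitions, res$novel$transversions),
               known = c(res$known$transitions, res$known$transversions))
  colnames(tab) <- c("transitions", "transversions")
  structure(list(novel = res$novel, known = res$known,
                 fisher = fisher_exact_2x2(tab)),
            class = "titv_test")
}

#' @export
print.titv_test <- function(x, ...) {
  cat(sprintf("<titv_test> novel Ti fraction %.3f (%d/%d), known %.3f (%d/%d); Fisher p = %.3g\n",
              x$novel$fraction, x$novel$transitions,
              x$novel$transitions + x$novel$transversions,
              x$known$fraction, x$known$transitions,
              x$known$transitions + x$known$transversions,
              x$fisher$p_two_sided))
  invisible(x)
}
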