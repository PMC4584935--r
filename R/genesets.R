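# Stratified gene-affection sets and binary scoring matrices: the
# exploratory-signature layer that feeds ordination and clustering.

#' Build a stratified gene-affection set for one sample
#'
#' Collects the gene symbols hit by qualifying variants of one class. The
#' default predicates follow the exploratory-analysis convention:
#' * SNV stratum: region in \{exonic, splicing\} and exonic function in
#'   \{nonsynonymous, stopgain, stoploss\} (synonymous changes are spared);
#' * INDEL stratum: region in \{exonic, splicing\}.
#'
#' Every qualifying variant contributes all of its annotated gene symbols.
#'
#' @param callset A classified `sample_callset`.
#' @param stratum `"SNV"` or `"INDEL"`.
#' @param filter_spec Optional predicate `function(variants_df) -> logical`
#'   replacing the default; its deparsed form is recorded for provenance.
#' @return A `gene_set` object (fields `sample_id`, `stratum`, `genes`,
#'   `filter_spec`).
#' @export
build_gene_sets <- function(callset, stratum = c("SNV", "INDEL"),
                            filter_spec = NULL) {
  stratum <- match.arg(stratum)
  v <- callset$variants
  if (is.null(filter_spec)) {
    desc <- if (stratum == "SNV") {
      "region %in% c('exonic','splicing') & exonic_function %in% c('nonsynonymous','stopgain','stoploss')"
    } else {
      "region %in% c('exonic','splicing')"
    }
    keep <- v$var_class == stratum & v$region %in% c("exonic", "splicing")
    if (stratum == "SNV") {
      keep <- keep & !is.na(v$exonic_function) &
        v$exonic_function %in% c("nonsynonymous", "stopgain", "stoploss")
    }
  } else {
    desc <- paste(deparse(filter_spec), collapse = " ")
    keep <- v$var_class == stratum & filter_spec(v)
  }
  genes <- sort(.split_genes(v$genes[keep]))
  structure(list(sample_id = callset$sample_id, stratum = stratum,
                 genes = genes, filter_spec = desc),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s / %s: %d genes\n", x$sample_id, x$stratum,
              length(x$genes)))
  invisible(x)
}

#' Binary gene-affection matrix
#'
#' Samples form rows and the union of genes forms (lexicographically
#' ordered) columns; a cell is 1 when the gene belongs to the sample's
#' gene set ("an affected gene is given a mark of 1") and 0 otherwise.
#'
#' @param gene_sets List of `gene_set` objects, one per sample, same stratum.
#' @return Integer 0/1 matrix with sample row names and gene column names.
#' @export
build_affection_matrix <- function(gene_sets) {
  if (length(gene_sets) < 2) .stopf("need at least two samples")
  ids <- vapply(gene_sets, function(g) g$sample_id, "")
  if (anyDuplicated(ids)) .stopf("duplicate sample ids: %s",
                                 paste(ids[duplicated(ids)], collapse = ", "))
  strata <- unique(vapply(gene_sets, function(g) g$stratum, ""))
  if (length(strata) > 1) .stopf("gene sets mix strata: %s",
                                 paste(strata, collapse = ", "))
  cols <- sort(unique(unlist(lapply(gene_sets, `[[`, "genes"))))
  m <- matrix(0L, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  for (g in gene_sets) {
    if (!length(g$genes)) .warnf("sample %s has an empty gene set (all-zero row)",
                                 g$sample_id)
    m[g$sample_id, g$genes] <- 1L
  }
  m
}

#' Pairwise distances between binary affection profiles
#'
#' `jaccard` is one minus intersection over union of the 1-columns (0 when
#' both rows are empty); `euclidean` is the ordinary Euclidean distance on
#' the 0/1 rows. Both are delegated to [stats::dist()] (`"binary"` is the
#' Jaccard distance for asymmetric binary data).
#'
#' @param matrix Binary affection matrix from [build_affection_matrix()].
#' @param method `"jaccard"` or `"euclidean"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
binary_distance <- function(matrix, method = c("jaccard", "euclidean")) {
  method <- match.arg(method)
  if (!all(matrix %in% c(0L, 1L))) .stopf("affection matrix must be binary")
  d <- switch(method,
              jaccard = stats::dist(matrix, method = "binary"),
              euclidean = stats::dist(matrix, method = "euclidean"))
  m <- as.matrix(d)
  m[is.nan(m)] <- 0  # two all-zero rows: empty sets are at distance 0
  diag(m) <- 0
  m
}

#' Venn-partition intersection counts of 2-5 gene sets
#'
#' Counts genes in every nonempty region of the Venn partition; counts sum
#' to the size of the union.
#'
#' @param gene_sets List of 2-5 `gene_set` objects (or plain character
#'   vectors, which are given names `set1..setk`).
#' @return Data frame with one logical membership column per set plus
#'   `count`, one row per nonempty partition cell.
#' @export
set_intersections <- function(gene_sets) {
  if (length(gene_sets) < 2 || length(gene_sets) > 5)
    .stopf("set_intersections supports 2-5 sets (got %d); use a table for more",
           length(gene_sets))
  sets <- lapply(gene_sets, function(g) if (inherits(g, "gene_set")) g$genes else g)
  ids <- vapply(seq_along(gene_sets), function(i) {
    g <- gene_sets[[i]]
    if (inherits(g, "gene_set")) g$sample_id else paste0("set", i)
  }, "")
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(universe))
  colnames(memb) <- ids
  pattern <- apply(memb, 1L, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pattern)
  out <- do.call(rbind, lapply(names(tab), function(p) {
    flags <- as.logical(as.integer(strsplit(p, "")[[1]]))
    row <- as.data.frame(as.list(flags))
    names(row) <- ids
    row$count <- as.integer(tab[[p]])
    row
  }))
  rownames(out) <- NULL
  out
}
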