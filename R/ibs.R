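# Identity-by-state somatic inference: variants present in every tumor and
# in a positive somatic catalog, but in no control, are called shared
# somatic (IBS between tumors). Pure set logic over normalized keys.

#' Infer shared somatic variants by identity-by-state set logic
#'
#' Computes `(intersection of tumor keys) intersect catalog keys minus
#' (union of control keys)`. Tumors act as cases, controls as germline
#' negative references, and the somatic catalog as positive control.
#' Matching is by exact normalized `(chrom, pos, ref, alt)` key by default;
#' `match_alleles = FALSE` matches on `(chrom, pos)` only, for catalogs with
#' divergent allele representations.
#'
#' @param tumors List of at least two tumor `sample_callset`s.
#' @param controls List of at least one control `sample_callset`.
#' @param catalog Positive somatic catalog (data frame with `chrom`, `pos`,
#'   `ref`, `alt`; see [read_variant_catalog()]).
#' @param match_alleles Require the catalog match to share the exact
#'   alternate allele (default `TRUE`).
#' @return An `ibs_result`: `variant_keys`, `genes`, `provenance` (data
#'   frame key -> matched catalog key) and `stages` (filter-stage counts).
#' @export
infer_ibs_somatic <- function(tumors, controls, catalog, match_alleles = TRUE) {
  if (length(tumors) < 2) .stopf("need at least two tumor callsets")
  if (length(controls) < 1) .stopf("need at least one control callset")
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(catalog)))
    .stopf("catalog key convention mismatch: need chrom/pos/ref/alt columns")
  tumor_keys <- lapply(tumors, callset_keys)
  shared <- Reduce(intersect, tumor_keys)
  ckeys_full <- variant_key(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
  if (!length(ckeys_full)) .warnf("positive catalog is empty after loading")
  if (match_alleles) {
    m <- match(shared, ckeys_full)
  } else {
    pos_of <- function(k) sub("^([^:]+:[^:]+):.*$", "\\1", k)
    m <- match(pos_of(shared), pos_of(ckeys_full))
  }
  matched <- shared[!is.na(m)]
  matched_to <- ckeys_full[m[!is.na(m)]]
  control_keys <- unique(unlist(lapply(controls, callset_keys)))
  keep <- !(matched %in% control_keys)
  result_keys <- matched[keep]
  # gene annotations come from the tumor callsets' own records
  vall <- do.call(rbind, lapply(tumors, function(cs) cs$variants))
  vkeys <- variant_key(vall$chrom, vall$pos, vall$ref, vall$alt)
  genes <- sort(.split_genes(vall$genes[vkeys %in% result_keys]))
  stages <- c(tumor_shared = length(shared),
              catalog_matched = length(matched),
              after_control_removal = length(result_keys),
              genes = length(genes))
  message(sprintf(
    "IBS filter: %d shared by all tumors -> %d catalog-matched -> %d after control removal (%d genes)",
    stages[1], stages[2], stages[3], stages[4]))
  structure(list(variant_keys = sort(result_keys), genes = genes,
                 provenance = data.frame(key = matched[keep],
                                         catalog_key = matched_to[keep],
                                         stringsAsFactors = FALSE),
                 stages = stages),
            class = "ibs_result")
}

#' @export
print.ibs_result <- function(x, ...) {
  cat(sprintf("<ibs_result> %d shared somatic variant keys over %d genes\n",
              length(x$variant_keys), length(x$genes)))
  invisible(x)
}

#' Per-stage count table for an IBS inference
#'
#' @param result An `ibs_result` from [infer_ibs_somatic()].
#' @return Data frame with columns `stage` and `count` for the
#'   tumor-shared, catalog-matched, control-removal and gene stages.
#' @export
ibs_stage_report <- function(result) {
  if (!inherits(result, "ibs_result")) .stopf("expected an ibs_result")
  data.frame(stage = names(result$stages),
             count = unname(as.integer(result$stages)),
             stringsAsFactors = FALSE)
}
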