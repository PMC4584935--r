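`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical variant identity key
#'
#' Variants are identified throughout the package by the normalized
#' `chrom:pos:ref:alt` string. Position-only keys (`chrom:pos`) are used
#' when allele-agnostic catalog matching is requested.
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @param alleles If `FALSE`, drop ref/alt from the key.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt, alleles = TRUE) {
  if (alleles) paste(chrom, pos, ref, alt, sep = ":") else paste(chrom, pos, sep = ":")
}

#' Variant keys of a callset
#' @param x A `sample_callset`.
#' @param alleles Include alleles in the key (default `TRUE`).
#' @return Character vector.
#' @export
callset_keys <- function(x, alleles = TRUE) {
  v <- x$variants
  variant_key(v$chrom, v$pos, v$ref, v$alt, alleles = alleles)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    .stopf("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

.REGIONS <- c("exonic", "splicing", "intronic", "UTR3", "UTR5",
              "upstream", "downstream", "intergenic", "other")
.EXFUNCS <- c("nonsynonymous", "synonymous", "stopgain", "stoploss",
              "frameshift", "nonframeshift", "unknown")

# split comma-joined gene fields into a unique symbol vector
.split_genes <- function(x) {
  g <- unlist(strsplit(x[!is.na(x) & nzchar(x)], ",", fixed = TRUE))
  unique(g[nzchar(g)])
}
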