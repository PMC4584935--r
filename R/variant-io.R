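# Annotated-variant I/O: normalized variant records, per-sample callsets,
# dialect readers/writers, novelty and deleteriousness classification,
# and per-class count summaries.

.VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "var_class", "region",
                   "exonic_function", "genes", "known_id", "pop_af",
                   "deleterious_score", "sample_gt")

#' Construct a per-sample callset
#'
#' A `sample_callset` holds one sample's annotated variants as a data frame
#' with one row per normalized `(chrom, pos, ref, alt)` key. Duplicate keys
#' are collapsed (first record wins) with a message.
#'
#' @param sample_id Sample label, e.g. `"P17"`.
#' @param phenotype `"tumor"` or `"control"`.
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `var_class`, `region`, `exonic_function`, `genes` (comma-joined
#'   symbols), `known_id`, `pop_af`, `deleterious_score`, `sample_gt`.
#' @return An object of class `sample_callset`.
#' @export
sample_callset <- function(sample_id, phenotype = c("control", "tumor"),
                           variants = NULL) {
  phenotype <- match.arg(phenotype)
  if (is.null(variants)) {
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character())
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in .VARIANT_COLS) {
    if (!col %in% names(variants)) {
      variants[[col]] <- switch(col,
        pos = integer(nrow(variants)),
        pop_af = , deleterious_score = rep(NA_real_, nrow(variants)),
        sample_gt = rep(1L, nrow(variants)),
        rep(NA_character_, nrow(variants)))
    }
  }
  variants <- variants[, .VARIANT_COLS, drop = FALSE]
  if (nrow(variants)) {
    variants$pos <- as.integer(variants$pos)
    if (any(variants$pos < 1L)) .stopf("variant positions must be >= 1")
    variants$ref <- toupper(variants$ref)
    variants$alt <- toupper(variants$alt)
    if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt)))
      .stopf("ref and alt alleles must be nonempty")
    if (any(variants$ref == variants$alt)) .stopf("null variant: ref equals alt")
    if (anyNA(variants$var_class)) {
      variants$var_class <- ifelse(
        nchar(variants$ref) == 1L & nchar(variants$alt) == 1L, "SNV", "INDEL")
    }
    snv <- variants$var_class == "SNV"
    bad <- snv & (!grepl("^[ACGT]$", variants$ref) | !grepl("^[ACGT]$", variants$alt))
    if (any(bad)) .stopf("SNV alleles must be single bases in {A,C,G,T}")
    # exonic_function only meaningful in exonic/splicing regions
    out_reg <- !(variants$region %in% c("exonic", "splicing"))
    variants$exonic_function[out_reg] <- NA_character_
    key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
    if (anyDuplicated(key)) {
      message(sprintf("collapsing %d duplicate variant keys in sample %s",
                      sum(duplicated(key)), sample_id))
      variants <- variants[!duplicated(key), , drop = FALSE]
    }
    rownames(variants) <- NULL
  }
  structure(list(sample_id = sample_id, phenotype = phenotype,
                 variants = variants),
            class = "sample_callset")
}

#' @export
print.sample_callset <- function(x, ...) {
  cat(sprintf("<sample_callset> %s (%s): %d variants (%d SNV, %d INDEL)\n",
              x$sample_id, x$phenotype, nrow(x$variants),
              sum(x$variants$var_class == "SNV"),
              sum(x$variants$var_class == "INDEL")))
  invisible(x)
}

#' Trim-normalize a variant representation
#'
#' Removes shared trailing bases, then shared leading bases (advancing the
#' position), always retaining at least one base in each allele. This gives a
#' canonical `(chrom, pos, ref, alt)` without requiring a reference genome;
#' it is idempotent.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing variants (1-based
#'   positions; nonempty uppercase alleles).
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("chr1", 100, "CAG", "CG")   # -> chr1:100 CA>C
#' normalize_variant("chr2", 50, "GCC", "GTC")   # -> chr2:51 C>T
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    .stopf("ref and alt must be nonempty")
  if (any(ref == alt)) .stopf("null variant: ref equals alt")
  pos <- as.integer(pos)
  n <- length(ref)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    # shared trailing bases
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # shared leading bases, advancing pos
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    # a leading shared base may remain when one allele is length 1 after
    # trailing trim only if trimming it would empty an allele
    if (nchar(r) > 1L && nchar(a) > 1L) {
      # unreachable: loop above exhausts this case
    }
    if (r == a) .stopf("null variant after trimming at %s:%d", chrom[i], pos[i])
    ref[i] <- r; alt[i] <- a
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Read annotated variants into a callset
#'
#' Supports two dialects: a minimal single-sample VCF 4.2 whose INFO field
#' carries `GENE`, `REGION`, `EXFUNC`, `CONDEL`, `KNOWN_ID` and `AF` keys,
#' and an ANNOVAR-style tab-separated table with a header
#' (`chrom, start, end, ref, alt, region, exonic_function, gene, known_id,
#' af, condel`). Multi-allelic VCF rows are split into one record per
#' alternate allele; all records are trim-normalized. Unknown region labels
#' are kept with `region = "other"` and a warning.
#'
#' @param path Input file.
#' @param dialect `"vcf"` or `"annovar_tsv"`.
#' @param sample_id Sample label; defaults to the file name without extension.
#' @param phenotype `"control"` or `"tumor"`.
#' @return A `sample_callset`.
#' @export
read_annotated_variants <- function(path, dialect = c("vcf", "annovar_tsv"),
                                    sample_id = NULL,
                                    phenotype = c("control", "tumor")) {
  dialect <- match.arg(dialect)
  phenotype <- match.arg(phenotype)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- switch(dialect,
               vcf = .read_vcf_dialect(path),
               annovar_tsv = .read_annovar_dialect(path))
  unknown <- !is.na(df$region) & !(df$region %in% .REGIONS)
  if (any(unknown)) {
    .warnf("%d records with unknown region label kept as region='other'",
           sum(unknown))
    df$region[unknown] <- "other"
  }
  df$region[is.na(df$region)] <- "other"
  norm <- normalize_variant(df$chrom, df$pos, df$ref, df$alt)
  df[c("chrom", "pos", "ref", "alt")] <- norm
  message(sprintf("read %d variant records from %s (%s dialect)",
                  nrow(df), basename(path), dialect))
  sample_callset(sample_id, phenotype, df)
}

.read_vcf_dialect <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character()))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos))
    .stopf("malformed VCF row: non-numeric POS at data line %d", which(is.na(pos))[1])
  info_field <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  df <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = pos,
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    region = info_field("REGION"),
    exonic_function = info_field("EXFUNC"),
    genes = info_field("GENE"),
    known_id = info_field("KNOWN_ID"),
    pop_af = suppressWarnings(as.numeric(info_field("AF"))),
    deleterious_score = suppressWarnings(as.numeric(info_field("CONDEL"))),
    stringsAsFactors = FALSE)
  if (any(is.na(df$ref) | !nzchar(df$ref)))
    .stopf("malformed VCF row: empty REF at data line %d",
           which(is.na(df$ref) | !nzchar(df$ref))[1])
  # split multi-allelic records: one row per alternate
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  idx <- rep(seq_len(n), lengths(alts))
  df <- df[idx, , drop = FALSE]
  df$alt <- unlist(alts)
  rownames(df) <- NULL
  df
}

.read_annovar_dialect <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "ref", "alt", "region",
           "exonic_function", "gene", "known_id", "af", "condel")
  miss <- setdiff(req, names(df))
  if (length(miss))
    .stopf("ANNOVAR-style table missing required columns: %s",
           paste(miss, collapse = ", "))
  bad <- is.na(suppressWarnings(as.integer(df$start)))
  if (any(bad)) .stopf("malformed row: non-numeric start at data line %d", which(bad)[1])
  data.frame(
    chrom = as.character(df$chrom),
    pos = as.integer(df$start),
    ref = as.character(df$ref),
    alt = as.character(df$alt),
    region = as.character(df$region),
    exonic_function = as.character(df$exonic_function),
    genes = as.character(df$gene),
    known_id = as.character(df$known_id),
    pop_af = suppressWarnings(as.numeric(df$af)),
    deleterious_score = suppressWarnings(as.numeric(df$condel)),
    stringsAsFactors = FALSE)
}

#' Write a callset in one of the supported dialects
#'
#' @param callset A `sample_callset`.
#' @param path Output file.
#' @param dialect `"vcf"` (minimal single-sample VCF 4.2 with the package's
#'   INFO keys) or `"annovar_tsv"`.
#' @return `path`, invisibly.
#' @export
write_annotated_variants <- function(callset, path,
                                     dialect = c("vcf", "annovar_tsv")) {
  dialect <- match.arg(dialect)
  v <- callset$variants
  if (dialect == "vcf") {
    esc <- function(x, d = ".") ifelse(is.na(x) | !nzchar(x), d, as.character(x))
    info <- paste0(
      "GENE=", esc(v$genes),
      ";REGION=", esc(v$region, "other"),
      ifelse(is.na(v$exonic_function), "", paste0(";EXFUNC=", v$exonic_function)),
      ifelse(is.na(v$deleterious_score), "",
             paste0(";CONDEL=", formatC(v$deleterious_score, format = "g", digits = 8))),
      ifelse(is.na(v$known_id), "", paste0(";KNOWN_ID=", v$known_id)),
      ifelse(is.na(v$pop_af), "",
             paste0(";AF=", formatC(v$pop_af, format = "g", digits = 8))))
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##source=exopattern"),
             sprintf("##sample=<ID=%s,Phenotype=%s>", callset$sample_id, callset$phenotype),
             '##INFO=<ID=GENE,Number=.,Type=String,Description="Gene symbols">',
             '##INFO=<ID=REGION,Number=1,Type=String,Description="Genomic region class">',
             '##INFO=<ID=EXFUNC,Number=1,Type=String,Description="Exonic function">',
             '##INFO=<ID=CONDEL,Number=1,Type=Float,Description="Consensus deleteriousness score">',
             '##INFO=<ID=KNOWN_ID,Number=1,Type=String,Description="Known-variant identifier">',
             '##INFO=<ID=AF,Number=1,Type=Float,Description="Population allele frequency">',
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    ord <- order(v$chrom, v$pos, v$ref, v$alt)
    rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                    v$chrom[ord], v$pos[ord], esc(v$known_id[ord]),
                    v$ref[ord], v$alt[ord], info[ord])
    writeLines(c(hdr, rows), path)
  } else {
    out <- data.frame(chrom = v$chrom, start = v$pos,
                      end = v$pos + nchar(v$ref) - 1L,
                      ref = v$ref, alt = v$alt, region = v$region,
                      exonic_function = v$exonic_function, gene = v$genes,
                      known_id = v$known_id, af = v$pop_af, condel = v$deleterious_score)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Classify variants as novel or known against a catalog
#'
#' A variant is *novel* when its normalized key is absent from the catalog,
#' or present with a recorded population allele frequency below
#' `af_threshold` (the "low allele frequency" clause). A cataloged variant
#' with unknown frequency is treated as known.
#'
#' @param callset A `sample_callset` (or a variant data frame).
#' @param catalog A known-variant catalog from [read_variant_catalog()] or a
#'   data frame with `chrom`, `pos`, `ref`, `alt` and optional `af`.
#' @param af_threshold Frequency below which cataloged variants still count
#'   as novel (default 0.01).
#' @return Character vector, `"novel"` or `"known"`, one per variant.
#' @export
classify_novelty <- function(callset, catalog, af_threshold = 0.01) {
  .assert_prob(af_threshold, "af_threshold")
  v <- if (inherits(callset, "sample_callset")) callset$variants else callset
  keys <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  ckeys <- variant_key(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
  af <- if ("af" %in% names(catalog)) catalog$af else rep(NA_real_, length(ckeys))
  m <- match(keys, ckeys)
  hit_af <- af[m]
  novel <- is.na(m) | (!is.na(hit_af) & hit_af < af_threshold)
  ifelse(novel, "novel", "known")
}

#' Flag damaging variants by deleteriousness score
#'
#' A variant is damaging when its consensus deleteriousness score (a
#' ConDel-like score in \[0, 1\]) is at or above `cutoff`. Variants without a
#' score are not damaging; the number of unscored nonsynonymous SNVs is
#' reported in a warning.
#'
#' @param callset A `sample_callset` or variant data frame.
#' @param cutoff Score cutoff in \[0, 1\]; default 0.522, the published
#'   operating point for ConDel.
#' @return Logical vector, one per variant.
#' @export
classify_damaging <- function(callset, cutoff = 0.522) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff > 1)
    .stopf("'cutoff' must be a single value in [0, 1]")
  v <- if (inherits(callset, "sample_callset")) callset$variants else callset
  score <- v$deleterious_score
  unscored_nonsyn <- sum(is.na(score) & v$var_class == "SNV" &
                           !is.na(v$exonic_function) &
                           v$exonic_function == "nonsynonymous")
  if (unscored_nonsyn > 0)
    .warnf("%d nonsynonymous SNVs lack a deleteriousness score (treated as not damaging)",
           unscored_nonsyn)
  !is.na(score) & score >= cutoff
}

#' Per-sample variant class count table
#'
#' One row per sample and variant class with `All`, `Novel` and region counts
#' plus the damaging-SNV count, mirroring the usual per-sample exome summary.
#'
#' @param callsets List of `sample_callset` objects.
#' @param catalog Optional known-variant catalog for novelty classification;
#'   when omitted, novelty falls back to absence of a `known_id`.
#' @param cutoff Damaging-score cutoff passed to [classify_damaging()].
#' @param af_threshold Novelty threshold passed to [classify_novelty()].
#' @return Data frame with columns `sample`, `phenotype`, `var_class`, `All`,
#'   `Novel`, `Exonic`, `Intronic`, `UTR3`, `UTR5`, `Splicing`, `Damaging`.
#' @export
summarize_callsets <- function(callsets, catalog = NULL, cutoff = 0.522,
                               af_threshold = 0.01) {
  if (!length(callsets)) .stopf("need at least one callset")
  rows <- lapply(callsets, function(cs) {
    v <- cs$variants
    novel <- if (nrow(v) == 0) character() else if (!is.null(catalog)) {
      classify_novelty(cs, catalog, af_threshold)
    } else ifelse(is.na(v$known_id), "novel", "known")
    dmg <- if (nrow(v)) suppressWarnings(classify_damaging(cs, cutoff)) else logical()
    do.call(rbind, lapply(c("SNV", "INDEL"), function(cls) {
      sel <- v$var_class == cls
      data.frame(
        sample = cs$sample_id, phenotype = cs$phenotype, var_class = cls,
        All = sum(sel),
        Novel = sum(sel & novel == "novel"),
        Exonic = sum(sel & v$region == "exonic"),
        Intronic = sum(sel & v$region == "intronic"),
        UTR3 = sum(sel & v$region == "UTR3"),
        UTR5 = sum(sel & v$region == "UTR5"),
        Splicing = sum(sel & v$region == "splicing"),
        Damaging = if (cls == "SNV") sum(sel & dmg) else NA_integer_,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a callset as BED intervals
#'
#' Writes BED3+1 lines in 0-based half-open coordinates
#' (`start = pos - 1`, `end = start + nchar(ref)`) with a `ref>alt` name
#' column, sorted by chromosome then start.
#'
#' @param callset A nonempty `sample_callset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(callset, path) {
  v <- callset$variants
  if (!nrow(v)) .stopf("cannot write BED for an empty callset")
  bed <- data.frame(chrom = v$chrom, start = v$pos - 1L,
                    end = v$pos - 1L + nchar(v$ref),
                    name = paste0(v$ref, ">", v$alt))
  bed <- bed[order(bed$chrom, bed$start, bed$name), ]
  con <- tryCatch(file(path, "w"), error = function(e)
    .stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED3+1 intervals back into variant keys
#'
#' Inverse of [write_bed()]: reconstructs 1-based positions and alleles from
#' the interval and the `ref>alt` name column.
#'
#' @param path BED file written by [write_bed()].
#' @param sample_id,phenotype Passed to [sample_callset()].
#' @return A `sample_callset` (positional and allele information only).
#' @export
read_bed <- function(path, sample_id = NULL, phenotype = "control") {
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "name"),
                   stringsAsFactors = FALSE)
  parts <- strsplit(df$name, ">", fixed = TRUE)
  sample_callset(sample_id, phenotype,
                 data.frame(chrom = df$chrom, pos = df$start + 1L,
                            ref = vapply(parts, `[`, "", 1L),
                            alt = vapply(parts, `[`, "", 2L)))
}

#' Read a known-variant catalog
#'
#' Tab-separated with a header containing `chrom`, `pos`, `ref`, `alt` and
#' optionally `af` (population allele frequency); `#` starts a comment.
#'
#' @param path Catalog file.
#' @return Data frame with a `catalog` subclass.
#' @export
read_variant_catalog <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("catalog missing columns: %s", paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos)
  class(df) <- c("variant_catalog", class(df))
  df
}

#' Write a known-variant catalog
#' @param catalog Data frame with `chrom`, `pos`, `ref`, `alt` and optional
#'   further columns (e.g. `af`, `sample_count`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variant_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
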