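test_that("trim normalization handles suffix, prefix and identity cases", {
  expect_equal(normalize_variant("chr1", 100, "CAG", "CG"),
               data.frame(chrom = "chr1", pos = 100L, ref = "CA", alt = "C"))
  expect_equal(normalize_variant("chr1", 100, "C", "T"),
               data.frame(chrom = "chr1", pos = 100L, ref = "C", alt = "T"))
  expect_equal(normalize_variant("chr2", 50, "GCC", "GTC"),
               data.frame(chrom = "chr2", pos = 51L, ref = "C", alt = "T"))
  expect_error(normalize_variant("chr1", 1, "AC", "AC"), "null variant")
})

test_that("normalization is idempotent on random allele pairs", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, sample.int(6, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample.int(6, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    n1 <- tryCatch(normalize_variant("chr1", 1000, ref, alt),
                   error = function(e) NULL)
    if (is.null(n1)) next  # alleles identical after trimming
    n2 <- normalize_variant(n1$chrom, n1$pos, n1$ref, n1$alt)
    expect_identical(n1, n2)
    expect_gte(nchar(n1$ref), 1L)
    expect_gte(nchar(n1$alt), 1L)
  }
})

test_that("VCF dialect reads, classifies and splits multi-allelic rows", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(toy_vcf_lines(), f)
  cs <- suppressMessages(read_annotated_variants(f, "vcf", sample_id = "S1"))
  expect_s3_class(cs, "sample_callset")
  expect_equal(nrow(cs$variants), 3)
  expect_equal(sort(paste(cs$variants$var_class, cs$variants$region)),
               sort(c("SNV exonic", "INDEL exonic", "SNV intronic")))
  # length rule: TAG>T is an INDEL
  expect_equal(cs$variants$var_class[cs$variants$ref == "TAG"], "INDEL")

  # multi-allelic split shares chrom/pos/ref
  f2 <- withr::local_tempfile(fileext = ".vcf")
  lines <- toy_vcf_lines()
  lines[9] <- "chr1\t100\t.\tC\tA,T\t.\t.\tGENE=GENEA;REGION=exonic;EXFUNC=nonsynonymous"
  writeLines(lines, f2)
  cs2 <- suppressMessages(read_annotated_variants(f2, "vcf"))
  at100 <- cs2$variants[cs2$variants$pos == 100, ]
  expect_equal(nrow(at100), 2)
  expect_setequal(at100$alt, c("A", "T"))
  expect_equal(unique(at100$ref), "C")
})

test_that("unknown region labels are kept as 'other' with a warning", {
  f <- withr::local_tempfile(fileext = ".vcf")
  lines <- toy_vcf_lines()
  lines[11] <- "chr2\t300\t.\tG\tA\t.\t.\tREGION=weird_label"
  writeLines(lines, f)
  expect_warning(cs <- suppressMessages(read_annotated_variants(f, "vcf")),
                 "unknown region")
  expect_equal(cs$variants$region[cs$variants$pos == 300], "other")
})

test_that("dialect writers round-trip the variant keys and class labels", {
  cs <- toy_callset()
  for (dial in c("vcf", "annovar_tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", substr(dial, 1, 3)))
    write_annotated_variants(cs, f, dial)
    back <- suppressMessages(read_annotated_variants(f, dial, sample_id = "S1"))
    expect_setequal(callset_keys(back), callset_keys(cs))
    v0 <- cs$variants[order(callset_keys(cs)), ]
    v1 <- back$variants[order(callset_keys(back)), ]
    expect_equal(v1$var_class, v0$var_class)
    expect_equal(v1$region, v0$region)
    expect_equal(v1$exonic_function, v0$exonic_function)
  }
})

test_that("novelty classification applies the absence-or-rare rule", {
  catalog <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                        ref = c("C", "G"), alt = c("T", "A"),
                        af = c(0.30, 0.005))
  v <- make_variants("chr1", c(100L, 200L, 300L), c("C", "G", "A"),
                     c("T", "A", "G"), region = "intronic")
  cs <- sample_callset("S", "control", v)
  expect_equal(classify_novelty(cs, catalog, 0.01),
               c("known", "novel", "novel"))
  # threshold boundary: af exactly at threshold stays known
  expect_equal(classify_novelty(cs, catalog, 0.005)[2], "known")
  # cataloged without af stays known
  catalog$af[1] <- NA
  expect_equal(classify_novelty(cs, catalog, 0.01)[1], "known")
})

test_that("damaging classification respects cutoff, boundary and missing scores", {
  v <- make_variants("chr1", 1:3, "C", "T", region = "exonic",
                     exonic_function = "nonsynonymous",
                     score = c(0.9, 0.522, NA))
  cs <- sample_callset("S", "control", v)
  expect_warning(d <- classify_damaging(cs), "1 nonsynonymous")
  expect_equal(d, c(TRUE, TRUE, FALSE))
  expect_error(classify_damaging(cs, cutoff = 1.5), "0, 1")
})

test_that("callset summaries count classes, regions and damaging SNVs", {
  tab <- suppressWarnings(summarize_callsets(list(toy_callset())))
  snv <- tab[tab$var_class == "SNV", ]
  ind <- tab[tab$var_class == "INDEL", ]
  expect_equal(snv$All, 2)
  expect_equal(ind$All, 1)
  expect_equal(snv$Exonic, 1)
  expect_equal(snv$Damaging, 1)
  # empty callset gives an all-zero row
  empty <- summarize_callsets(list(sample_callset("E")))
  expect_true(all(empty$All == 0))
})

test_that("BED export uses 0-based half-open intervals and round-trips", {
  cs <- sample_callset("S", "control",
                       make_variants("chr1", c(100L, 100L), c("C", "CA"),
                                     c("T", "C"), region = "intronic"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(cs, f)
  lines <- readLines(f)
  expect_true("chr1\t99\t100\tC>T" %in% lines)
  expect_true("chr1\t99\t101\tCA>C" %in% lines)
  back <- read_bed(f)
  expect_setequal(callset_keys(back), callset_keys(cs))
})
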