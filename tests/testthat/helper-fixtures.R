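# In-code fixtures: tiny callsets, catalogs, and dialect files built at
# test time.

make_variants <- function(chrom, pos, ref, alt, region = "exonic",
                          exonic_function = NA_character_,
                          genes = NA_character_, known_id = NA_character_,
                          pop_af = NA_real_, score = NA_real_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             region = region, exonic_function = exonic_function,
             genes = genes, known_id = known_id, pop_af = pop_af,
             deleterious_score = score, stringsAsFactors = FALSE)
}

# the worked three-variant callset: nonsynonymous SNV, frameshift deletion,
# intronic SNV
toy_callset <- function(sample_id = "S1", phenotype = "control") {
  sample_callset(sample_id, phenotype, make_variants(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 200L, 300L),
    ref = c("C", "TAG", "G"),
    alt = c("T", "T", "A"),
    region = c("exonic", "exonic", "intronic"),
    exonic_function = c("nonsynonymous", "frameshift", NA),
    genes = c("GENEA", "GENEB", NA),
    score = c(0.9, NA, NA)))
}

toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=.,Type=String,Description="Gene symbols">',
    '##INFO=<ID=REGION,Number=1,Type=String,Description="Region">',
    '##INFO=<ID=EXFUNC,Number=1,Type=String,Description="Exonic function">',
    '##INFO=<ID=CONDEL,Number=1,Type=Float,Description="Score">',
    '##INFO=<ID=KNOWN_ID,Number=1,Type=String,Description="Known id">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele frequency">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tC\tT\t.\t.\tGENE=GENEA;REGION=exonic;EXFUNC=nonsynonymous;CONDEL=0.9",
    "chr1\t200\trs1\tTAG\tT\t.\t.\tGENE=GENEB;REGION=exonic;EXFUNC=frameshift;KNOWN_ID=rs1;AF=0.2",
    "chr2\t300\t.\tG\tA\t.\t.\tREGION=intronic")
}

# random small callset of SNVs with arbitrary novelty structure
random_snv_callset <- function(n, sample_id = "R1", seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  sample_callset(sample_id, "control", make_variants(
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = ref, alt = alt, region = "exonic",
    exonic_function = "nonsynonymous",
    genes = sprintf("G%03d", sample.int(50, n, replace = TRUE))))
}

small_cfg <- function(seed = 1, ...) cohort_config(scale = 0.05, seed = seed, ...)
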