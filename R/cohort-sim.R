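# Synthetic five-sample family cohort with planted ground truth.
#
# The generator reproduces the statistical structure the analysis stages
# assume: germline variants gene-dropped through a mini-pedigree (so related
# samples share identical-by-descent variants), an excess somatic burden in
# the two tumor samples with a configurable shared-somatic fraction
# (identical-by-state sharing between tumors), an elevated transition
# fraction among novel SNVs, tumor INDELs preferentially hitting genes of
# planted annotation terms, and an interaction network with a planted
# unmutated hub wired to the nonsynonymously affected genes.

.SNV_REGION_PROBS <- c(exonic = 0.385, intronic = 0.465, UTR3 = 0.046,
                       UTR5 = 0.023, splicing = 0.005, upstream = 0.030,
                       downstream = 0.030, intergenic = 0.016)
.INDEL_REGION_PROBS <- c(exonic = 0.045, intronic = 0.720, UTR3 = 0.055,
                         UTR5 = 0.015, splicing = 0.005, upstream = 0.060,
                         downstream = 0.060, intergenic = 0.040)
.SOMATIC_INDEL_REGION_PROBS <- c(exonic = 0.080, intronic = 0.685,
                                 UTR3 = 0.055, UTR5 = 0.015, splicing = 0.005,
                                 upstream = 0.060, downstream = 0.060,
                                 intergenic = 0.040)
.TV_PAIRS <- rbind(c("A", "C"), c("A", "T"), c("C", "A"), c("C", "G"),
                   c("G", "C"), c("G", "T"), c("T", "A"), c("T", "G"))

#' Configuration for the synthetic family cohort
#'
#' Defaults emulate a five-sample familial tumor/control exome study: two
#' tumor samples (P17, P61) from two branches of an extended pedigree and
#' three controls (P39 — a sibling of P61, P26 — a first cousin, P84 — a
#' distant relative), with roughly 45k germline SNVs and 9k germline INDELs
#' per sample, a novel germline SNV fraction of ~7%, 1800 novel somatic SNVs
#' per tumor, a 2.4-fold tumor INDEL burden, transition probabilities of
#' 0.825 (novel) versus 0.68 (known) substitutions, half of the somatic
#' variants shared between the two tumors, planted term enrichment in tumor
#' INDEL targets, and an unmutated hub gene wired to nonsynonymously
#' affected genes.
#'
#' @param scale Proportional scale factor applied to the gene universe and
#'   all variant counts (1 = full study scale; use e.g. 0.05 for fast
#'   repeated-seed experiments).
#' @param n_genes Size of the gene universe.
#' @param n_terms Number of annotation terms in the generated GMT.
#' @param germline_snv_per_sample,germline_indel_per_sample Germline variant
#'   counts carried by each founder (hence expected per sample after
#'   gene-dropping).
#' @param tumor_somatic_snv Somatic SNVs per tumor (all novel).
#' @param indel_burden_multiplier Tumor INDEL excess factor; somatic INDELs
#'   per tumor are `(multiplier - 1) * germline_indel_per_sample`.
#' @param somatic_share_prob Probability a tumor somatic variant is shared
#'   by both tumors.
#' @param catalog_overlap_prob Probability a shared somatic variant also
#'   appears in the positive somatic catalog.
#' @param catalog_background Count of background (cohort-absent) entries in
#'   the positive catalog.
#' @param novel_transition_prob,known_transition_prob Probability that a
#'   novel / known SNV substitution is a transition.
#' @param germline_snv_novel_frac,germline_indel_novel_frac Novel fraction
#'   among germline variants.
#' @param snv_common_frac,indel_common_frac Fraction of each sample's
#'   germline variants belonging to a common population panel carried by
#'   every individual (the rest are founder-specific rare variants that
#'   gene-drop through the pedigree). Novel variants are always rare, so
#'   each common fraction must leave room for the novel fraction.
#' @param planted_terms Term ids enriched in tumor INDEL gene sets.
#' @param planted_pool_size Genes annotated to each planted term.
#' @param planted_draw_frac Fraction of tumor somatic exonic INDEL gene
#'   draws taken from the planted pools.
#' @param hub_gene Symbol of the planted network hub (kept variant-free).
#' @param hub_query_frac Probability the hub connects to a gene carrying a
#'   somatic nonsynonymous SNV.
#' @param hub_background_frac Probability the hub connects to any other gene.
#' @param network_density Erdős–Rényi density of the background network.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(scale = 1,
                          n_genes = 20000,
                          n_terms = 200,
                          germline_snv_per_sample = 45000,
                          germline_indel_per_sample = 9000,
                          tumor_somatic_snv = 1800,
                          indel_burden_multiplier = 2.4,
                          somatic_share_prob = 0.5,
                          catalog_overlap_prob = 0.5,
                          catalog_background = 2000,
                          novel_transition_prob = 0.825,
                          known_transition_prob = 0.68,
                          germline_snv_novel_frac = 0.072,
                          germline_indel_novel_frac = 0.40,
                          snv_common_frac = 0.70,
                          indel_common_frac = 0.50,
                          planted_terms = c("T0001", "T0002"),
                          planted_pool_size = 40,
                          planted_draw_frac = 0.5,
                          hub_gene = "HUB",
                          hub_query_frac = 0.4,
                          hub_background_frac = 0.02,
                          network_density = 0.002,
                          seed = 1L) {
  if (scale <= 0) .stopf("'scale' must be positive")
  cfg <- list(
    n_genes = max(50L, as.integer(round(n_genes * scale))),
    n_terms = max(10L, as.integer(round(n_terms * max(scale, 0.25)))),
    germline_snv_per_sample = max(10L, as.integer(round(germline_snv_per_sample * scale))),
    germline_indel_per_sample = max(10L, as.integer(round(germline_indel_per_sample * scale))),
    tumor_somatic_snv = max(5L, as.integer(round(tumor_somatic_snv * scale))),
    indel_burden_multiplier = indel_burden_multiplier,
    somatic_share_prob = somatic_share_prob,
    catalog_overlap_prob = catalog_overlap_prob,
    catalog_background = max(10L, as.integer(round(catalog_background * scale))),
    novel_transition_prob = novel_transition_prob,
    known_transition_prob = known_transition_prob,
    germline_snv_novel_frac = germline_snv_novel_frac,
    germline_indel_novel_frac = germline_indel_novel_frac,
    snv_common_frac = snv_common_frac,
    indel_common_frac = indel_common_frac,
    planted_terms = planted_terms,
    planted_pool_size = as.integer(planted_pool_size),
    planted_draw_frac = planted_draw_frac,
    hub_gene = hub_gene,
    hub_query_frac = hub_query_frac,
    hub_background_frac = hub_background_frac,
    network_density = network_density,
    seed = seed,
    tumors = c("P17", "P61"),
    controls = c("P39", "P26", "P84"))
  for (p in c("somatic_share_prob", "catalog_overlap_prob",
              "novel_transition_prob", "known_transition_prob",
              "germline_snv_novel_frac", "germline_indel_novel_frac",
              "snv_common_frac", "indel_common_frac",
              "planted_draw_frac", "hub_query_frac", "hub_background_frac",
              "network_density"))
    .assert_prob(cfg[[p]], p)
  if (snv_common_frac + germline_snv_novel_frac >= 1)
    .stopf("snv_common_frac leaves no room for the novel fraction")
  if (indel_common_frac + germline_indel_novel_frac >= 1)
    .stopf("indel_common_frac leaves no room for the novel fraction")
  if (indel_burden_multiplier < 1) .stopf("indel_burden_multiplier must be >= 1")
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed > 2^31 - 1000)
    .stopf("seed must be in [0, 2^31 - 1000]")
  cfg$seed <- as.integer(cfg$seed)
  if (length(cfg$planted_terms) && cfg$planted_pool_size * length(cfg$planted_terms) > cfg$n_genes / 2)
    .stopf("planted pools exceed half the gene universe")
  cfg$somatic_indel_per_tumor <- as.integer(round(
    (indel_burden_multiplier - 1) * cfg$germline_indel_per_sample))
  structure(cfg, class = "cohort_config")
}

.gene_universe <- function(config) sprintf("G%05d", seq_len(config$n_genes))

# draw variant records; positions must be globally unique across all calls
.sim_variants <- function(n, var_class, positions, region_probs, novel,
                          config, genes_pool, planted_pool = NULL,
                          planted_draw_frac = 0, score_shape = c(2, 4)) {
  if (n == 0) {
    return(sample_callset("empty")$variants[0, ])
  }
  if (length(novel) == 1) novel <- rep(novel, n)
  chrom <- paste0("chr", sample.int(22L, n, replace = TRUE))
  region <- sample(names(region_probs), n, replace = TRUE, prob = region_probs)
  if (var_class == "SNV") {
    p_ti <- ifelse(novel, config$novel_transition_prob, config$known_transition_prob)
    is_ti <- stats::runif(n) < p_ti
    pair_idx_ti <- sample.int(4L, n, replace = TRUE)
    pair_idx_tv <- sample.int(8L, n, replace = TRUE)
    ref <- ifelse(is_ti, .TRANSITIONS[pair_idx_ti, 1], .TV_PAIRS[pair_idx_tv, 1])
    alt <- ifelse(is_ti, .TRANSITIONS[pair_idx_ti, 2], .TV_PAIRS[pair_idx_tv, 2])
    exf <- rep(NA_character_, n)
    ex <- region == "exonic"
    exf[ex] <- sample(c("nonsynonymous", "synonymous", "stopgain", "stoploss"),
                      sum(ex), replace = TRUE, prob = c(0.50, 0.45, 0.03, 0.02))
    exf[region == "splicing"] <- "unknown"
    score <- rep(NA_real_, n)
    ns <- !is.na(exf) & exf == "nonsynonymous"
    score[ns] <- stats::rbeta(sum(ns), score_shape[1], score_shape[2])
  } else {
    base <- sample(.BASES, n, replace = TRUE)
    extra_len <- sample.int(3L, n, replace = TRUE)
    extra <- vapply(extra_len, function(L)
      paste(sample(.BASES, L, replace = TRUE), collapse = ""), "")
    is_del <- stats::runif(n) < 0.5
    ref <- ifelse(is_del, paste0(base, extra), base)
    alt <- ifelse(is_del, base, paste0(base, extra))
    exf <- rep(NA_character_, n)
    ex <- region == "exonic"
    exf[ex] <- sample(c("frameshift", "nonframeshift"), sum(ex),
                      replace = TRUE, prob = c(0.6, 0.4))
    exf[region == "splicing"] <- "unknown"
    score <- rep(NA_real_, n)
  }
  genes <- rep(NA_character_, n)
  genic <- region %in% c("exonic", "splicing")
  ng <- sum(genic)
  if (ng) {
    g <- sample(genes_pool, ng, replace = TRUE)
    if (!is.null(planted_pool) && planted_draw_frac > 0) {
      from_pool <- stats::runif(ng) < planted_draw_frac
      g[from_pool] <- sample(planted_pool, sum(from_pool), replace = TRUE)
    }
    genes[genic] <- g
  }
  known_id <- rep(NA_character_, n)
  pop_af <- rep(NA_real_, n)
  kn <- !novel
  known_id[kn] <- sprintf("K%09d", positions[kn])
  pop_af[kn] <- stats::runif(sum(kn), 0.01, 0.5)
  data.frame(chrom = chrom, pos = as.integer(positions), ref = ref, alt = alt,
             var_class = var_class, region = region, exonic_function = exf,
             genes = genes, known_id = known_id, pop_af = pop_af,
             deleterious_score = score, sample_gt = 1L,
             stringsAsFactors = FALSE)
}

#' Generate gene-set annotations (GMT) for the synthetic cohort
#'
#' Planted terms receive disjoint random gene pools (from which tumor
#' somatic exonic INDEL targets are preferentially drawn by
#' [simulate_cohort()]); remaining terms annotate random gene subsets of
#' size 10-100.
#'
#' @param config A `cohort_config`.
#' @return List with `annotations` (named list of gene vectors),
#'   `planted_pools` (named list) and `genes` (the universe).
#' @export
simulate_annotations <- function(config) {
  if (config$n_terms < length(config$planted_terms))
    .stopf("n_terms must be at least the number of planted terms")
  set.seed(config$seed + 101L)
  genes <- .gene_universe(config)
  n_pl <- length(config$planted_terms)
  pools <- list()
  pool_genes <- sample(genes, n_pl * config$planted_pool_size)
  for (i in seq_len(n_pl)) {
    pools[[config$planted_terms[i]]] <-
      sort(pool_genes[seq((i - 1) * config$planted_pool_size + 1,
                          i * config$planted_pool_size)])
  }
  ann <- pools
  n_other <- config$n_terms - n_pl
  if (n_other > 0) {
    sizes <- sample(10:min(100, config$n_genes %/% 2), n_other, replace = TRUE)
    other <- lapply(sizes, function(s) sort(sample(genes, s)))
    names(other) <- sprintf("T%04d", seq(n_pl + 1, config$n_terms))
    ann <- c(ann, other)
  }
  list(annotations = ann, planted_pools = pools, genes = genes)
}

#' Generate the synthetic interaction network
#'
#' An Erdős–Rényi background over the gene universe plus a planted hub
#' connected to a fraction `hub_query_frac` of the genes carrying somatic
#' nonsynonymous SNVs and `hub_background_frac` of all other genes. The
#' graph is simple and undirected.
#'
#' @param config A `cohort_config` (needs `n_genes >= 10`).
#' @param nonsyn_genes Genes carrying somatic nonsynonymous SNVs (the hub's
#'   preferred partners); when `NULL`, a random 2\% subset stands in.
#' @return Edge-list data frame (`from`, `to`).
#' @export
simulate_interaction_network <- function(config, nonsyn_genes = NULL) {
  if (config$n_genes < 10) .stopf("need n_genes >= 10")
  if (config$network_density > 1) .stopf("density exceeds the simple-graph maximum")
  set.seed(config$seed + 202L)
  genes <- .gene_universe(config)
  if (is.null(nonsyn_genes))
    nonsyn_genes <- sample(genes, max(1L, round(0.02 * config$n_genes)))
  g <- igraph::sample_gnp(config$n_genes, config$network_density,
                          directed = FALSE, loops = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = genes[el[, 1]], to = genes[el[, 2]],
                      stringsAsFactors = FALSE)
  in_a <- genes %in% nonsyn_genes
  p_hub <- ifelse(in_a, config$hub_query_frac, config$hub_background_frac)
  hub_to <- genes[stats::runif(config$n_genes) < p_hub]
  if (length(hub_to))
    edges <- rbind(edges, data.frame(from = config$hub_gene, to = hub_to,
                                     stringsAsFactors = FALSE))
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  edges <- edges[!duplicated(key) & edges$from != edges$to, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

# inherit each of a parent's variant rows with probability 1/2 (one meiosis)
.transmit <- function(parent_rows) {
  parent_rows[stats::runif(length(parent_rows)) < 0.5]
}

#' Simulate the five-sample family cohort
#'
#' Germline variation has two layers: a common population panel carried by
#' every individual (always cataloged as known), and founder-specific rare
#' variants gene-dropped through two branches descending from a common
#' grandparental couple
#' (tumor P17 and tumor P61 are first cousins; control P39 is P61's
#' sibling; control P26 is a first cousin; control P84 descends from
#' unrelated founders), so identical-by-descent sharing between relatives
#' arises mechanically. Each tumor additionally receives novel somatic SNVs
#' and INDELs, a `somatic_share_prob` fraction of which is shared by both
#' tumors (identical-by-state sharing); shared somatic variants enter the
#' positive catalog with probability `catalog_overlap_prob`. Somatic exonic
#' INDEL genes are drawn preferentially from the planted term pools. All
#' randomness derives from `config$seed`.
#'
#' @param config A `cohort_config`.
#' @return A `cohort_sim` list: `callsets` (named list of five
#'   `sample_callset`s), `known_catalog`, `somatic_catalog`, `annotations`,
#'   `planted_pools`, `network` (edge-list data frame), `truth` (planted
#'   shared-somatic keys, planted terms, hub gene, phenotypes) and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) .stopf("config must be a cohort_config")
  if (length(config$tumors) != 2 || length(config$controls) != 3)
    .stopf("pedigree requires exactly 2 tumor and 3 control samples")
  ann <- simulate_annotations(config)
  genes <- ann$genes
  planted_pool_all <- unlist(ann$planted_pools, use.names = FALSE)

  set.seed(config$seed + 303L)
  founders <- c("GF1", "GF2", "SPA", "SPB", "SPC", "F84A", "F84B")
  nf <- length(founders)
  # germline variants split into a common population panel (carried by every
  # individual; always known) and founder-specific rare variants that
  # gene-drop through the pedigree (all novel variants are rare)
  c_snv <- as.integer(round(config$snv_common_frac * config$germline_snv_per_sample))
  c_ind <- as.integer(round(config$indel_common_frac * config$germline_indel_per_sample))
  r_snv <- config$germline_snv_per_sample - c_snv
  r_ind <- config$germline_indel_per_sample - c_ind
  rare_novel_snv <- config$germline_snv_novel_frac * config$germline_snv_per_sample / r_snv
  rare_novel_ind <- config$germline_indel_novel_frac * config$germline_indel_per_sample / r_ind
  per_f <- r_snv + r_ind
  n_sh_snv <- stats::rbinom(1, config$tumor_somatic_snv, config$somatic_share_prob)
  n_sh_ind <- stats::rbinom(1, config$somatic_indel_per_tumor, config$somatic_share_prob)
  n_pr_snv <- config$tumor_somatic_snv - n_sh_snv
  n_pr_ind <- config$somatic_indel_per_tumor - n_sh_ind
  total_pos <- c_snv + c_ind + nf * per_f + n_sh_snv + n_sh_ind +
    2 * (n_pr_snv + n_pr_ind) + config$catalog_background
  pos_pool <- sample.int(2e8L, total_pos)
  take <- local({
    used <- 0L
    function(n) {
      out <- pos_pool[(used + 1L):(used + n)]
      used <<- used + n
      out
    }
  })

  common_df <- rbind(
    .sim_variants(c_snv, "SNV", take(c_snv), .SNV_REGION_PROBS,
                  novel = FALSE, config, genes),
    .sim_variants(c_ind, "INDEL", take(c_ind), .INDEL_REGION_PROBS,
                  novel = FALSE, config, genes))

  # founder-specific rare germline variants
  founder_df <- do.call(rbind, lapply(founders, function(f) {
    snv <- .sim_variants(r_snv, "SNV", take(r_snv), .SNV_REGION_PROBS,
                         novel = stats::runif(r_snv) < rare_novel_snv,
                         config, genes)
    ind <- .sim_variants(r_ind, "INDEL", take(r_ind), .INDEL_REGION_PROBS,
                         novel = stats::runif(r_ind) < rare_novel_ind,
                         config, genes)
    rbind(snv, ind)
  }))
  f_rows <- split(seq_len(nrow(founder_df)),
                  rep(founders, each = per_f))

  # gene-dropping: founders -> middle generation -> sampled individuals
  mid <- list(A = c(.transmit(f_rows$GF1), .transmit(f_rows$GF2)),
              B = c(.transmit(f_rows$GF1), .transmit(f_rows$GF2)),
              C = c(.transmit(f_rows$GF1), .transmit(f_rows$GF2)))
  germ <- list(
    P61 = c(.transmit(mid$A), .transmit(f_rows$SPA)),
    P39 = c(.transmit(mid$A), .transmit(f_rows$SPA)),
    P17 = c(.transmit(mid$B), .transmit(f_rows$SPB)),
    P26 = c(.transmit(mid$C), .transmit(f_rows$SPC)),
    P84 = c(.transmit(f_rows$F84A), .transmit(f_rows$F84B)))

  # somatic variants: shared pool (both tumors) + private draws
  shared_somatic <- rbind(
    .sim_variants(n_sh_snv, "SNV", take(n_sh_snv), .SNV_REGION_PROBS,
                  novel = TRUE, config, genes, score_shape = c(4, 2)),
    .sim_variants(n_sh_ind, "INDEL", take(n_sh_ind), .SOMATIC_INDEL_REGION_PROBS,
                  novel = TRUE, config, genes, planted_pool = planted_pool_all,
                  planted_draw_frac = config$planted_draw_frac))
  private_somatic <- lapply(config$tumors, function(s) {
    rbind(
      .sim_variants(n_pr_snv, "SNV", take(n_pr_snv), .SNV_REGION_PROBS,
                    novel = TRUE, config, genes, score_shape = c(4, 2)),
      .sim_variants(n_pr_ind, "INDEL", take(n_pr_ind), .SOMATIC_INDEL_REGION_PROBS,
                    novel = TRUE, config, genes, planted_pool = planted_pool_all,
                    planted_draw_frac = config$planted_draw_frac))
  })
  names(private_somatic) <- config$tumors

  phenos <- c(setNames(rep("tumor", 2), config$tumors),
              setNames(rep("control", 3), config$controls))
  callsets <- lapply(names(phenos), function(s) {
    v <- rbind(common_df, founder_df[germ[[s]], , drop = FALSE])
    if (phenos[[s]] == "tumor")
      v <- rbind(v, shared_somatic, private_somatic[[s]])
    sample_callset(s, phenos[[s]], v)
  })
  names(callsets) <- names(phenos)

  known <- rbind(common_df, founder_df[!is.na(founder_df$known_id), ])
  known_catalog <- data.frame(chrom = known$chrom, pos = known$pos,
                              ref = known$ref, alt = known$alt,
                              af = known$pop_af, stringsAsFactors = FALSE)
  class(known_catalog) <- c("variant_catalog", class(known_catalog))

  in_cat <- stats::runif(nrow(shared_somatic)) < config$catalog_overlap_prob
  nb <- config$catalog_background
  bg <- .sim_variants(nb, "SNV", take(nb), .SNV_REGION_PROBS, novel = TRUE,
                      config, genes)
  somatic_catalog <- data.frame(
    chrom = c(shared_somatic$chrom[in_cat], bg$chrom),
    pos = c(shared_somatic$pos[in_cat], bg$pos),
    ref = c(shared_somatic$ref[in_cat], bg$ref),
    alt = c(shared_somatic$alt[in_cat], bg$alt),
    sample_count = sample.int(50L, sum(in_cat) + nb, replace = TRUE),
    stringsAsFactors = FALSE)
  class(somatic_catalog) <- c("variant_catalog", class(somatic_catalog))

  truth <- list(
    shared_somatic_keys = sort(variant_key(shared_somatic$chrom,
                                           shared_somatic$pos,
                                           shared_somatic$ref,
                                           shared_somatic$alt)),
    planted_terms = config$planted_terms,
    hub_gene = config$hub_gene,
    phenotypes = phenos)

  nonsyn_genes <- unique(c(
    shared_somatic$genes[shared_somatic$var_class == "SNV" &
                           !is.na(shared_somatic$exonic_function) &
                           shared_somatic$exonic_function == "nonsynonymous"],
    unlist(lapply(private_somatic, function(v)
      v$genes[v$var_class == "SNV" & !is.na(v$exonic_function) &
                v$exonic_function == "nonsynonymous"]))))
  nonsyn_genes <- nonsyn_genes[!is.na(nonsyn_genes)]
  network <- simulate_interaction_network(config, nonsyn_genes)

  structure(list(callsets = callsets, known_catalog = known_catalog,
                 somatic_catalog = somatic_catalog,
                 annotations = ann$annotations,
                 planted_pools = ann$planted_pools,
                 common_panel_keys = variant_key(common_df$chrom, common_df$pos,
                                                 common_df$ref, common_df$alt),
                 somatic_keys = lapply(private_somatic, function(v)
                   sort(c(variant_key(v$chrom, v$pos, v$ref, v$alt),
                          truth$shared_somatic_keys))),
                 network = network, truth = truth, config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d samples (%s), %d planted shared somatic keys, %d terms, %d network edges\n",
              length(x$callsets), paste(names(x$callsets), collapse = ", "),
              length(x$truth$shared_somatic_keys), length(x$annotations),
              nrow(x$network)))
  invisible(x)
}

#' Write a simulated cohort bundle to disk
#'
#' Per-sample VCFs, known and positive catalogs (TSV), annotations (GMT),
#' interaction edges (TSV), ground truth (JSON) and a config echo (YAML).
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in sim$callsets)
    write_annotated_variants(cs, file.path(dir, paste0(cs$sample_id, ".vcf")))
  write_variant_catalog(sim$known_catalog, file.path(dir, "known_catalog.tsv"))
  write_variant_catalog(sim$somatic_catalog, file.path(dir, "somatic_catalog.tsv"))
  write_gmt(sim$annotations, file.path(dir, "annotations.gmt"))
  write_edge_list(sim$network, file.path(dir, "network.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
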