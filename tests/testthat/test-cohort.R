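test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(somatic_share_prob = 1.5), "probability")
  expect_error(cohort_config(indel_burden_multiplier = 0.5), ">= 1")
  expect_error(cohort_config(snv_common_frac = 0.95), "novel fraction")
  expect_error(cohort_config(seed = 2^31), "seed")
  expect_error(cohort_config(scale = 0), "positive")
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  s1 <- suppressMessages(simulate_cohort(small_cfg(seed = 17)))
  s2 <- suppressMessages(simulate_cohort(small_cfg(seed = 17)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(s1, d1); write_cohort(s2, d2)
  for (f in setdiff(list.files(d1), "config.yaml")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  s3 <- suppressMessages(simulate_cohort(small_cfg(seed = 18)))
  expect_false(identical(callset_keys(s1$callsets$P17),
                         callset_keys(s3$callsets$P17)))
})

test_that("zero somatic sharing makes tumor somatic key sets disjoint", {
  sim <- suppressMessages(simulate_cohort(small_cfg(seed = 3, somatic_share_prob = 0)))
  expect_length(sim$truth$shared_somatic_keys, 0)
  expect_length(intersect(sim$somatic_keys$P17, sim$somatic_keys$P61), 0)
  # every somatic key sits in its own tumor callset and in no control
  for (s in c("P17", "P61")) {
    expect_true(all(sim$somatic_keys[[s]] %in% callset_keys(sim$callsets[[s]])))
    for (ctl in c("P39", "P26", "P84"))
      expect_length(intersect(sim$somatic_keys[[s]],
                              callset_keys(sim$callsets[[ctl]])), 0)
  }
})

test_that("truth keys live in both tumors and, at full overlap, the catalog", {
  sim <- suppressMessages(simulate_cohort(small_cfg(seed = 5, catalog_overlap_prob = 1)))
  truth <- sim$truth$shared_somatic_keys
  expect_gt(length(truth), 0)
  expect_true(all(truth %in% callset_keys(sim$callsets$P17)))
  expect_true(all(truth %in% callset_keys(sim$callsets$P61)))
  ck <- variant_key(sim$somatic_catalog$chrom, sim$somatic_catalog$pos,
                    sim$somatic_catalog$ref, sim$somatic_catalog$alt)
  expect_true(all(truth %in% ck))
  # and in no control
  for (s in c("P39", "P26", "P84"))
    expect_length(intersect(truth, callset_keys(sim$callsets[[s]])), 0)
})

test_that("first-degree relatives share about half of the gene-dropped variants", {
  shares <- vapply(1:8, function(i) {
    sim <- suppressMessages(simulate_cohort(small_cfg(seed = 200 + i)))
    # P39 is P61's sibling and carries only germline variation; condition on
    # the rare (gene-dropped) stratum
    k39 <- setdiff(callset_keys(sim$callsets$P39), sim$common_panel_keys)
    mean(k39 %in% callset_keys(sim$callsets$P61))
  }, numeric(1))
  expect_equal(mean(shares), 0.5, tolerance = 0.05)
})

test_that("tumor INDEL burden exceeds every control's", {
  for (i in 1:5) {
    sim <- suppressMessages(simulate_cohort(small_cfg(seed = 300 + i)))
    tab <- suppressWarnings(summarize_callsets(sim$callsets, sim$known_catalog))
    ind <- tab[tab$var_class == "INDEL", ]
    expect_gt(min(ind$All[ind$phenotype == "tumor"]),
              max(ind$All[ind$phenotype == "control"]))
  }
})

test_that("novel-stratum transition fraction matches its generating probability", {
  sim <- suppressMessages(simulate_cohort(small_cfg(seed = 11)))
  v <- sim$callsets$P17$variants
  snv <- v[v$var_class == "SNV", ]
  novelty <- classify_novelty(snv, sim$known_catalog)
  tf <- transition_fraction(substitution_matrix(snv[novelty == "novel", ]))
  n <- tf$transitions + tf$transversions
  p0 <- sim$config$novel_transition_prob
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(tf$fraction - p0), 3 * se)
})

test_that("annotations and planted pools have the configured structure", {
  cfg <- small_cfg(seed = 13)
  ann <- simulate_annotations(cfg)
  expect_length(ann$annotations, cfg$n_terms)
  for (t in cfg$planted_terms)
    expect_length(ann$annotations[[t]], cfg$planted_pool_size)
  ann2 <- simulate_annotations(small_cfg(seed = 14))
  expect_false(identical(ann$annotations, ann2$annotations))
})

test_that("the simulated network is simple and hub-dominated", {
  cfg <- small_cfg(seed = 19)
  net <- simulate_interaction_network(cfg)
  key <- paste(pmin(net$from, net$to), pmax(net$from, net$to))
  expect_false(any(duplicated(key)))
  expect_false(any(net$from == net$to))
  g <- igraph::graph_from_data_frame(net, directed = FALSE)
  deg <- igraph::degree(g)
  expect_equal(names(which.max(deg)), cfg$hub_gene)
  # round trip through the edge-list file format
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- suppressMessages(read_edge_list(f))
  expect_equal(nrow(back), nrow(net))
  # degenerate parameters: hub isolated
  cfg0 <- small_cfg(seed = 19, hub_query_frac = 0, hub_background_frac = 0,
                    network_density = 0)
  net0 <- simulate_interaction_network(cfg0)
  expect_false(cfg0$hub_gene %in% c(net0$from, net0$to))
})
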