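edges_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
}

test_that("edge-list loading deduplicates and subnetwork modes induce correctly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# ppi", "a\tb", "b\ta", "b\tx", "c\tx", "d\td"), f)
  el <- suppressMessages(read_edge_list(f))
  expect_equal(nrow(el), 3)  # reversed duplicate and self-loop dropped
  g <- build_subnetwork(c("a", "b", "c"), el, "direct")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 1)  # only a-b survives induction
  gb <- build_subnetwork(c("a", "b", "c"), el, "plus_bridges")
  expect_true("x" %in% igraph::V(gb)$name)  # adjacent to b and c
  expect_equal(igraph::ecount(gb), 3)
  expect_true(igraph::V(gb)$bridge[igraph::V(gb)$name == "x"])
  expect_false(any(igraph::V(gb)$bridge[igraph::V(gb)$name != "x"]))
  # plus_bridges always contains the direct result
  expect_true(all(igraph::V(g)$name %in% igraph::V(gb)$name))
  expect_warning(ge <- build_subnetwork(c("q1", "q2"), el), "disjoint")
  expect_equal(igraph::vcount(ge), 0)
})

test_that("centrality matches closed forms on star and path graphs", {
  star <- edges_df("h", "l1", "h", "l2", "h", "l3", "h", "l4")
  cr <- centrality(build_subnetwork(c("h", paste0("l", 1:4)), star, "direct"))
  h <- cr[cr$node == "h", ]
  expect_equal(h$degree, 4L)
  expect_equal(h$betweenness, 6)  # all C(4,2) leaf pairs route via center
  expect_equal(h$degree_rank, 1L)
  expect_true(all(cr$betweenness[cr$node != "h"] == 0))
  path <- edges_df("A", "B", "B", "C")
  cp <- centrality(build_subnetwork(c("A", "B", "C"), path, "direct"))
  expect_equal(cp$closeness[cp$node == "B"], 1)
  expect_equal(cp$closeness[cp$node == "A"], 2 / 3)
  # degree sum identity
  expect_equal(sum(cp$degree), 2 * 2)
  expect_equal(nrow(centrality(igraph::make_empty_graph(0, directed = FALSE))), 0)
})

test_that("betweenness and closeness behave on random graphs vs the oracle", {
  set.seed(23)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    g <- igraph::sample_gnp(n, 0.45)
    igraph::V(g)$name <- letters[seq_len(n)]
    cr <- centrality(g)
    expect_equal(cr$betweenness, betweenness_oracle(g), tolerance = 1e-9)
    expect_true(all(cr$closeness >= 0 & cr$closeness <= 1))
    expect_equal(sum(cr$degree), 2 * igraph::ecount(g))
    iso <- igraph::degree(g) == 0
    if (any(iso)) expect_true(all(cr$closeness[iso] == 0))
  }
})

test_that("largest-component percentage covers connected, sparse and edgeless cases", {
  el <- edges_df("a", "b", "b", "c")
  g <- build_subnetwork(letters[1:5], el, "direct")
  expect_equal(suppressMessages(largest_component_fraction(g, letters[1:5])), 60)
  full <- edges_df("a", "b", "b", "c", "a", "c")
  gf <- build_subnetwork(c("a", "b", "c"), full, "direct")
  expect_equal(suppressMessages(largest_component_fraction(gf, c("a", "b", "c"))), 100)
  # edgeless: every query gene is its own singleton component
  ge <- suppressWarnings(build_subnetwork(letters[1:4], edges_df("x", "y"), "direct"))
  expect_equal(suppressMessages(largest_component_fraction(ge, letters[1:4])), 25)
  expect_error(largest_component_fraction(g, character()), "empty query")
})

test_that("network overlap reports shared structure and central sharing", {
  elA <- edges_df("a", "b", "b", "c", "c", "d")
  gA <- build_subnetwork(letters[1:4], elA, "direct")
  ov_same <- network_overlap(gA, gA)
  expect_equal(ov_same$node_jaccard, 1)
  expect_equal(ov_same$edge_jaccard, 1)
  elB <- edges_df("x", "y")
  gB <- build_subnetwork(c("x", "y"), elB, "direct")
  ov_disj <- network_overlap(gA, gB)
  expect_equal(ov_disj$node_jaccard, 0)
  expect_equal(ov_disj$edge_jaccard, 0)
  # brute-force set comparison on random graphs
  set.seed(29)
  for (i in 1:5) {
    g1 <- igraph::sample_gnp(6, 0.5); igraph::V(g1)$name <- letters[1:6]
    g2 <- igraph::sample_gnp(6, 0.5); igraph::V(g2)$name <- letters[3:8]
    ov <- network_overlap(g1, g2)
    ek <- function(g) {
      el <- igraph::as_edgelist(g)
      if (!nrow(el)) return(character())
      paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "--")
    }
    expect_setequal(ov$shared_nodes, intersect(letters[1:6], letters[3:8]))
    expect_setequal(ov$shared_edges, intersect(ek(g1), ek(g2)))
  }
})

test_that("hub adjacency contrast flags preferential interaction", {
  set.seed(37)
  A <- sprintf("a%02d", 1:10); B <- sprintf("b%02d", 1:10)
  hub_edges <- edges_df("HUB", A[1], "HUB", A[2], "HUB", A[3], "HUB", A[4],
                        "HUB", A[5], "HUB", A[6], "HUB", B[1],
                        A[7], B[2])
  res <- hub_interaction_contrast("HUB", A, B, hub_edges)
  expect_equal(unname(res$table["setA", ]), c(6, 4))
  expect_equal(unname(res$table["setB", ]), c(1, 9))
  expect_equal(res$p_two_sided, fisher_oracle(rbind(c(6, 4), c(1, 9))),
               tolerance = 1e-9)
  # equal adjacency fractions: no signal
  eq_edges <- edges_df("HUB", A[1], "HUB", B[1], A[2], B[2])
  res_eq <- hub_interaction_contrast("HUB", A, B, eq_edges)
  expect_gte(res_eq$p_two_sided, 0.99)
  expect_error(hub_interaction_contrast("NOPE", A, B, eq_edges), "absent")
  expect_error(hub_interaction_contrast("HUB", A, c(B, A[1]), eq_edges),
               "disjoint")
})
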