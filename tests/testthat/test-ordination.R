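test_that("gene-set predicates follow the exonic/splice filtering rules", {
  v <- make_variants(
    chrom = "chr1", pos = 1:5,
    ref = c("C", "C", "C", "CA", "C"),
    alt = c("T", "T", "T", "C", "T"),
    region = c("exonic", "exonic", "splicing", "exonic", "intronic"),
    exonic_function = c("synonymous", "nonsynonymous", "unknown", "frameshift", NA),
    genes = c("GENEX", "GENEA", "GENEB,GENEC", "GENEY", "GENEZ"))
  cs <- sample_callset("S", "control", v)
  snv <- build_gene_sets(cs, "SNV")
  # synonymous exonic SNV excluded; splicing 'unknown' also excluded by the
  # function predicate; multi-gene annotation contributes all symbols when
  # qualifying
  expect_false("GENEX" %in% snv$genes)
  expect_true("GENEA" %in% snv$genes)
  ind <- build_gene_sets(cs, "INDEL")
  expect_equal(ind$genes, "GENEY")
  # custom predicate: splicing SNVs included, multi-gene split honored
  snv2 <- build_gene_sets(cs, "SNV",
                          filter_spec = function(v) v$region %in% c("exonic", "splicing"))
  expect_true(all(c("GENEB", "GENEC") %in% snv2$genes))
})

test_that("affection matrix marks affected genes 1 over lexicographic columns", {
  gs <- list(structure(list(sample_id = "A", stratum = "SNV",
                            genes = c("A", "B")), class = "gene_set"),
             structure(list(sample_id = "B", stratum = "SNV",
                            genes = c("B", "C")), class = "gene_set"))
  m <- build_affection_matrix(gs)
  expect_equal(colnames(m), c("A", "B", "C"))
  expect_equal(unname(m), rbind(c(1L, 1L, 0L), c(0L, 1L, 1L)))
  gs[[2]]$sample_id <- "A"
  expect_error(build_affection_matrix(gs), "duplicate")
  gs[[2]]$sample_id <- "B"; gs[[2]]$genes <- character()
  expect_warning(m2 <- build_affection_matrix(gs), "empty gene set")
  expect_equal(sum(m2["B", ]), 0)
})

test_that("binary distances match their closed forms", {
  m <- rbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 1L), c = c(1L, 1L, 0L))
  d <- binary_distance(m, "jaccard")
  expect_equal(d["a", "b"], 2 / 3)
  expect_equal(d["a", "c"], 0)
  expect_equal(binary_distance(m, "euclidean")["a", "b"], sqrt(2))
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(c(0, 0, 0), c("a", "b", "c")))
  # both-empty rows are at distance 0, and Jaccard obeys the triangle
  # inequality on random binary rows
  m0 <- rbind(x = c(0L, 0L), y = c(0L, 0L), z = c(1L, 0L))
  expect_equal(binary_distance(m0, "jaccard")["x", "y"], 0)
  set.seed(5)
  for (i in 1:25) {
    mm <- matrix(rbinom(30, 1, 0.5), nrow = 3)
    mm[1, 1] <- 1L  # avoid all-empty degeneracies
    dd <- binary_distance(mm, "jaccard")
    expect_lte(dd[1, 3], dd[1, 2] + dd[2, 3] + 1e-12)
  }
})

test_that("isotonic fit pools violators and conserves the sum", {
  # already monotone: unchanged
  expect_equal(isotonic_fit(c(1, 2, 3), 1:3), c(1, 2, 3))
  # PAVA hand trace: (3,1,2) -> pool (3,1) to (2,2), then (2,2,2) monotone
  expect_equal(isotonic_fit(c(3, 1, 2), 1:3), c(2, 2, 2))
  set.seed(7)
  for (i in 1:20) {
    d <- runif(12)
    ord <- sample.int(12)
    fit <- isotonic_fit(d, ord)
    expect_equal(sum(fit), sum(d))
    expect_true(all(diff(fit[ord]) >= -1e-12))
  }
})

test_that("stress-1 matches its closed form", {
  expect_equal(stress1(c(1, 2), c(1, 2)), 0)
  expect_equal(stress1(c(1, 1), c(0, 0)), 1)
  expect_equal(stress1(c(1, 2), c(1.5, 1.5)), sqrt(0.5 / 5))
  expect_error(stress1(c(0, 0), c(0, 0)), "all-zero")
})

test_that("nmds recovers perfectly embeddable configurations", {
  # collinear points with gaps 1:1
  D <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  r <- nmds(D, k = 1, seed = 1)
  expect_lt(r$stress, 1e-8)
  g <- sort(abs(diff(sort(r$points[, 1]))))
  expect_equal(g[1] / g[2], 1, tolerance = 1e-6)
  # distances from a known 2-D configuration: stress ~ 0 and perfect rank
  # agreement of interpoint distances
  set.seed(3)
  X <- matrix(rnorm(16), 8, 2)
  DX <- as.matrix(dist(X))
  r2 <- nmds(DX, k = 2, seed = 3)
  expect_lt(r2$stress, 1e-6)
  expect_equal(cor(as.vector(dist(r2$points)), as.vector(dist(X)),
                   method = "spearman"), 1)
})

test_that("nmds in n-1 dimensions drives stress to zero on arbitrary matrices", {
  set.seed(42)
  for (i in 1:20) {
    D <- matrix(0, 5, 5)
    D[lower.tri(D)] <- runif(10, 0.2, 2)
    D <- D + t(D)
    r <- suppressWarnings(nmds(D, k = 4, seed = i, tol = 1e-12, max_iter = 2000))
    expect_lte(r$stress, 1e-6)
    expect_true(all(diff(r$stress_trace) <= 1e-12))
  }
})

test_that("nmds quality matches the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(1)
  for (i in 1:10) {
    X <- matrix(rnorm(14), 7, 2)
    D <- as.matrix(dist(X)) + matrix(runif(49, 0, 0.05), 7, 7)
    D <- (D + t(D)) / 2; diag(D) <- 0
    mine <- suppressWarnings(nmds(D, k = 2, seed = i, tol = 1e-9))
    ref <- MASS::isoMDS(as.dist(D), k = 2, trace = FALSE)
    expect_lte(mine$stress, ref$stress / 100 + 0.02)
  }
})

test_that("nmds rejects invalid inputs and flags degenerate ties", {
  D <- matrix(1, 4, 4); diag(D) <- 0
  expect_error(nmds(D, k = 4), "N-1")
  # three equidistant points embed as an equilateral triangle in the plane
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  expect_warning(r <- nmds(D3, k = 2), "degenerate ties")
  expect_lt(r$stress, 1e-8)
  Dn <- D; Dn[1, 2] <- 2
  expect_error(nmds(Dn, k = 2), "symmetric")
})

test_that("average-linkage clustering matches the brute-force oracle", {
  D3 <- rbind(c(0, 1, 5), c(1, 0, 5), c(5, 5, 0))
  dimnames(D3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  hc <- hierarchical_cluster(D3)
  expect_equal(hc$hclust$height[1], 1)
  expect_setequal(abs(hc$hclust$merge[1, ]), c(1, 2))  # first merge (A,B)
  expect_match(hc$newick, "\\(A:|\\(B:")
  # Newick parses back to the same tips
  phy <- ape::read.tree(text = hc$newick)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  set.seed(9)
  for (i in 1:10) {
    X <- matrix(rnorm(18), 6, 3)
    D <- as.matrix(dist(X))
    hc <- hierarchical_cluster(D, "average")
    expect_equal(sort(hc$hclust$height), sort(avg_linkage_oracle(D)),
                 tolerance = 1e-10)
  }
  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "at least two")
})

test_that("set intersections partition the union", {
  out <- set_intersections(list(c("A", "B", "C"), c("B", "C", "D")))
  expect_equal(sum(out$count), 4)
  both <- out$count[out$set1 & out$set2]
  expect_equal(both, 2)
  expect_equal(out$count[out$set1 & !out$set2], 1)
  # identical sets collapse into the full-intersection cell
  out2 <- set_intersections(list(c("A", "B"), c("A", "B")))
  expect_equal(nrow(out2), 1)
  expect_equal(out2$count, 2)
  # partition-sum property on random sets
  set.seed(13)
  for (i in 1:10) {
    sets <- replicate(4, sample(LETTERS, sample(3:15, 1)), simplify = FALSE)
    out <- set_intersections(sets)
    expect_equal(sum(out$count), length(unique(unlist(sets))))
  }
  expect_error(set_intersections(as.list(letters[1:6])), "2-5")
})
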