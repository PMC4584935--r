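# Independent brute-force oracles used to validate the package's
# statistics and graph algorithms on small inputs.

# Two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, comparing linear-space point probabilities (choose products).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  obs <- probs[x == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Upper-tail hypergeometric by direct summation of choose products.
hyper_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Betweenness by shortest-path counting through adjacency-matrix powers:
# sigma[s,t] = number of minimal-length walks (= shortest paths), and the
# pair dependency of v is sigma[s,v] * sigma[v,t] / sigma[s,t] whenever
# d(s,v) + d(v,t) = d(s,t).
betweenness_oracle <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- matrix(0, n, n); diag(S) <- 1
  Ak <- diag(n)
  for (L in seq_len(max(1, n - 1))) {
    Ak <- Ak %*% A
    newly <- is.infinite(D) & Ak > 0
    D[newly] <- L
    S[newly] <- Ak[newly]
  }
  btw <- numeric(n)
  if (n < 3) return(btw)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        btw[v] <- btw[v] + S[s, v] * S[v, t] / S[s, t]
    }
  }
  btw
}

# Average-linkage merge heights by naive O(n^3) agglomeration over the
# original distance matrix (mean of all between-cluster pairs).
avg_linkage_oracle <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- mean(D[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}
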