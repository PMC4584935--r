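# Non-metric multidimensional scaling by Kruskal's method: classical-scaling
# initialization, pool-adjacent-violators disparities, Guttman-transform
# configuration updates, and stress-1 as the loss.

#' Kruskal stress-1
#'
#' `sqrt( sum((d - dhat)^2) / sum(d^2) )`: the normalized monotone misfit
#' between configuration distances `d` and disparities `dhat`; 0 means a
#' perfect monotone embedding.
#'
#' @param d Configuration distances (nonnegative, not all zero).
#' @param dhat Disparities of the same length.
#' @return Stress-1 value in \[0, 1\].
#' @export
stress1 <- function(d, dhat) {
  if (length(d) != length(dhat)) .stopf("d and dhat must have equal length")
  ss <- sum(d^2)
  if (ss == 0) .stopf("all-zero configuration distances")
  sqrt(sum((d - dhat)^2) / ss)
}

#' Isotonic (monotone) disparities by pool-adjacent-violators
#'
#' Fits the least-squares monotone sequence to the configuration distances
#' `d` taken in the order of the input dissimilarities. Pooled blocks carry
#' their mean, so the sum of disparities equals the sum of `d`. Ties in the
#' dissimilarities follow Kruskal's primary approach: they keep the supplied
#' order and may take any disparity order.
#'
#' @param d Configuration distances.
#' @param order Permutation of `seq_along(d)` sorting the input
#'   dissimilarities ascending (e.g. `order(delta)`).
#' @return Disparities in the original element order, non-decreasing along
#'   `order`.
#' @export
isotonic_fit <- function(d, order) {
  if (length(d) != length(order)) .stopf("d and order must have equal length")
  fit <- stats::isoreg(seq_along(order), d[order])$yf
  out <- numeric(length(d))
  out[order] <- fit
  out
}

# one Guttman-transform update of configuration X toward disparities dhat
.guttman_update <- function(X, dhat_mat) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  ratio <- ifelse(D > 0, dhat_mat / D, 0)
  diag(ratio) <- 0
  B <- -ratio
  diag(B) <- rowSums(ratio)
  (B %*% X) / n
}

.lower <- function(m) m[lower.tri(m)]

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions preserving rank order.
#' The first start is the classical-scaling (Torgerson) configuration with
#' negative eigenvalues clipped; further starts perturb it randomly. Each
#' start iterates configuration distances -> isotonic disparities ->
#' stress-1 -> Guttman update, keeping only stress-decreasing steps so the
#' stress trace is non-increasing, and stops when the stress change drops
#' below `tol`, stress falls below 1e-8, or `max_iter` is reached. The best
#' start by final stress is returned.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param k Number of dimensions, `1 <= k <= n - 1`.
#' @param max_iter Maximum iterations per start (default 300).
#' @param tol Stress-change convergence tolerance (default 1e-6).
#' @param n_starts Number of starts (default 4: classical + 3 perturbed).
#' @param seed Seed for the random perturbations (default 1).
#' @return An `nmds_result`: `points` (n x k), `stress`, `n_iter`,
#'   `converged`, `stress_trace`, `start_used`.
#' @export
nmds <- function(d, k, max_iter = 300, tol = 1e-6, n_starts = 4, seed = 1L) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2) .stopf("need at least two points")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    .stopf("dissimilarity matrix must be symmetric")
  if (k < 1 || k > n - 1)
    .stopf("k must satisfy 1 <= k <= n - 1 (maximum number of dimensions is N-1 for N rows); got k=%d, n=%d", k, n)
  delta <- .lower(D)
  if (all(abs(delta - delta[1]) < 1e-12))
    .warnf("degenerate ties: all off-diagonal dissimilarities are equal")
  ord <- order(delta)

  init <- suppressWarnings(stats::cmdscale(D, k = k))
  if (ncol(init) < k)  # negative eigenvalues clipped: pad missing axes
    init <- cbind(init, matrix(0, n, k - ncol(init)))
  scale0 <- sqrt(mean(init^2))
  if (scale0 == 0) scale0 <- mean(delta)

  run_start <- function(X) {
    dd <- .lower(as.matrix(stats::dist(X)))
    dhat <- isotonic_fit(dd, ord)
    s <- stress1(dd, dhat)
    trace <- s
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(max_iter)) {
      dhat_mat <- matrix(0, n, n)
      dhat_mat[lower.tri(dhat_mat)] <- dhat
      dhat_mat <- dhat_mat + t(dhat_mat)
      X_new <- .guttman_update(X, dhat_mat)
      dd_new <- .lower(as.matrix(stats::dist(X_new)))
      if (all(dd_new == 0)) break  # collapsed configuration; keep previous
      dhat_new <- isotonic_fit(dd_new, ord)
      s_new <- stress1(dd_new, dhat_new)
      if (s_new > s + 1e-12) break  # only stress-decreasing steps are kept
      iters <- it
      X <- X_new; dhat <- dhat_new
      improvement <- s - s_new
      s <- s_new
      trace <- c(trace, s)
      if (s < 1e-8 || improvement < tol) { converged <- TRUE; break }
    }
    list(X = X, stress = s, trace = trace, n_iter = iters, converged = converged)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  best <- NULL
  for (st in seq_len(n_starts)) {
    X0 <- if (st == 1) init else init + matrix(stats::rnorm(n * k, sd = 0.25 * scale0), n, k)
    res <- run_start(X0)
    if (is.null(best) || res$stress < best$stress) {
      best <- res
      best$start_used <- st
    }
  }
  pts <- best$X
  dimnames(pts) <- list(rownames(D), paste0("dim", seq_len(k)))
  structure(list(points = pts, stress = best$stress, n_iter = best$n_iter,
                 converged = best$converged, stress_trace = best$trace,
                 start_used = best$start_used),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds_result> %d points in %d dims; stress-1 = %.4g (%s, %d iterations, start %d)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged",
              x$n_iter, x$start_used))
  invisible(x)
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Thin wrapper over [stats::hclust()] with average (UPGMA) linkage by
#' default; ties follow hclust's first-minimum rule, which for all-equal
#' distances merges in lexicographic pair order. The dendrogram is also
#' rendered as a Newick string (branch lengths are height differences).
#'
#' @param d Symmetric distance matrix or `dist`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return List with `hclust` (the stats object), `newick` (character) and
#'   `linkage`; class `hier_clust`.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  D <- stats::as.dist(d)
  if (attr(D, "Size") < 2) .stopf("need at least two observations")
  hc <- stats::hclust(D, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, newick = ape::write.tree(phy), linkage = linkage),
            class = "hier_clust")
}

#' @export
print.hier_clust <- function(x, ...) {
  cat(sprintf("<hier_clust> %s linkage over %d observations\n%s\n",
              x$linkage, length(x$hclust$order), x$newick))
  invisible(x)
}
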