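#' Pairwise distance matrix between multivariate points
#'
#' @param points numeric matrix, N points x p features.
#' @param metric `"euclidean"` or `"cosine"`. The cosine distance is
#'   `1 - cos(theta)` where `cos(theta)` is the inner product of the two
#'   vectors divided by the product of their lengths; it is invariant to
#'   positive rescaling of either point, which makes it robust to systematic
#'   platform scale differences. A zero vector has no direction; its cosine
#'   distance to any other point is defined as 1 (neutral angle) with a
#'   warning, never NaN.
#' @return Symmetric N x N matrix with zero diagonal and a `metric`
#'   attribute. Cosine entries lie in \[0, 2\].
#' @export
compute_distances <- function(points, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(points))
  } else {
    nrm <- sqrt(rowSums(points^2))
    zero <- nrm == 0
    if (any(zero)) {
      warning(sum(zero), " zero vector(s) under cosine metric; ",
              "distance to other points set to 1")
      nrm[zero] <- 1
    }
    u <- points / nrm
    sim <- tcrossprod(u)
    sim[zero, ] <- 0
    sim[, zero] <- 0
    d <- 1 - sim
    d <- pmin(pmax(d, 0), 2)
    diag(d) <- 0
  }
  dimnames(d) <- NULL
  attr(d, "metric") <- metric
  d
}

# Cross-set distances between columns of p x nA and p x nB matrices;
# used to precompute within/cross blocks once per cluster pair.
cross_dist <- function(A, B, metric) {
  if (metric == "euclidean") {
    d2 <- outer(colSums(A^2), colSums(B^2), "+") - 2 * crossprod(A, B)
    sqrt(pmax(d2, 0))
  } else {
    na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
    za <- na == 0; zb <- nb == 0
    na[za] <- 1; nb[zb] <- 1
    sim <- crossprod(A / rep(na, each = nrow(A)),
                     B / rep(nb, each = nrow(B)))
    sim[za, ] <- 0
    sim[, zb] <- 0
    pmin(pmax(1 - sim, 0), 2)
  }
}

#' Minimum spanning tree of a distance matrix
#'
#' Dense Prim's algorithm; ties are broken deterministically (smallest
#' vertex index enters first, smallest parent index wins among equal-weight
#' edges), so duplicate points and other degenerate geometries yield a
#' reproducible tree.
#'
#' @param dist symmetric distance matrix (e.g. from [compute_distances()]).
#' @return Integer matrix with N-1 rows and columns `from`, `to` (1-based
#'   vertex indices).
#' @export
build_mst <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop("distance matrix must be square")
  edges <- cpp_mst(dist)
  colnames(edges) <- c("from", "to")
  edges
}

fr_moments <- function(edges, N, m, n) {
  deg <- tabulate(as.vector(edges), N)
  C <- sum(deg * (deg - 1)) / 2
  e_runs <- 2 * m * n / N + 1
  var_runs <- (2 * m * n / (N * (N - 1))) *
    ((2 * m * n - N) / N +
       (C - N + 2) / ((N - 2) * (N - 3)) * (N * (N - 1) - 4 * m * n + 2))
  list(e_runs = e_runs, var_runs = var_runs)
}

#' Runs statistic of a labeled spanning tree
#'
#' Counts the runs R (maximal same-sample subtrees) of the minimum spanning
#' tree: R equals the number of edges joining the two samples plus one. The
#' permutation null moments are the classic closed forms
#' `E[R] = 2mn/N + 1` and
#' `Var[R] = (2mn/(N(N-1))) * ((2mn-N)/N + ((C-N+2)/((N-2)(N-3))) *
#' (N(N-1)-4mn+2))`,
#' where C is the number of tree edge pairs sharing a node, and the
#' standardized statistic is `W = (R - E[R]) / sqrt(Var[R])`. Fewer runs
#' than expected (W < 0) indicate the two samples are segregated on the
#' tree, i.e. drawn from different distributions.
#'
#' @param edges MST edge list from [build_mst()].
#' @param labels vector with exactly two distinct values, one per point,
#'   identifying the sample of each point.
#' @return Object of class `fr_test` with the runs count and null moments;
#'   no p-value yet (see [fr_pvalue()] / [permutation_pvalue()]).
#' @export
runs_statistic <- function(edges, labels) {
  labels <- as.vector(labels)
  N <- length(labels)
  lev <- unique(labels)
  if (length(lev) != 2)
    stop("labels must contain exactly two samples, got ", length(lev))
  if (N < 6) stop("need at least 6 points for the runs moments")
  if (nrow(edges) != N - 1) stop("edge list does not span the points")
  m <- sum(labels == lev[1])
  n <- N - m
  cross_edges <- sum(labels[edges[, 1]] != labels[edges[, 2]])
  runs <- cross_edges + 1L
  mom <- fr_moments(edges, N, m, n)
  w <- if (mom$var_runs > 0) (runs - mom$e_runs) / sqrt(mom$var_runs) else NaN
  structure(list(m = m, n = n, runs = runs, cross_edges = cross_edges,
                 e_runs = mom$e_runs, var_runs = mom$var_runs,
                 w_stat = w, p_value = NA_real_,
                 metric = NA_character_, p_method = NA_character_),
            class = "fr_test")
}

#' One-sided normal-approximation p-value of the runs statistic
#'
#' `p = pnorm(W)`: the lower tail of the standard normal, since few runs
#' mean segregated samples. Identical distributions give p spread over
#' \[0, 1\]; W = 0 gives exactly 0.5.
#'
#' @param result an `fr_test` object from [runs_statistic()].
#' @return The object with `p_value` and `p_method = "normal"` filled in.
#' @export
fr_pvalue <- function(result) {
  stopifnot(inherits(result, "fr_test"))
  if (!is.finite(result$var_runs) || result$var_runs <= 0)
    stop("runs variance is not positive (degenerate tree); ",
         "use permutation_pvalue()")
  result$p_value <- pnorm(result$w_stat)
  result$p_method <- "normal"
  result
}

#' Permutation p-value of the runs statistic
#'
#' Exact-null reference for the normal approximation: sample labels are
#' permuted over the fixed tree and
#' `p = (1 + #\{permuted R <= observed R\}) / (1 + n_perm)`.
#'
#' @param edges MST edge list.
#' @param labels two-sample label vector.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer for reproducibility.
#' @return An `fr_test` object with `p_method = "permutation"`.
#' @export
permutation_pvalue <- function(edges, labels, n_perm = 2000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  result <- runs_statistic(edges, labels)
  labels <- as.vector(labels)
  e1 <- edges[, 1]; e2 <- edges[, 2]
  perm_runs <- permuted_runs(e1, e2, labels, n_perm)
  result$p_value <- (1 + sum(perm_runs <= result$runs)) / (1 + n_perm)
  result$p_method <- "permutation"
  result
}

# Vectorized runs counts over random label permutations of a fixed tree.
permuted_runs <- function(e1, e2, labels, n_perm) {
  P <- replicate(n_perm, sample(labels))
  colSums(P[e1, , drop = FALSE] != P[e2, , drop = FALSE]) + 1L
}

#' Friedman-Rafsky two-sample test
#'
#' Pools two multivariate samples, builds the minimum spanning tree of
#' their pairwise distances, and tests whether the samples are segregated
#' on the tree via the runs statistic.
#'
#' @param x,y numeric matrices (observations in rows) with equal numbers of
#'   columns.
#' @param metric distance metric, `"euclidean"` (default) or `"cosine"`.
#' @param p_method `"normal"` for the one-sided asymptotic p-value
#'   (default), `"permutation"` for the permutation null. Degenerate trees
#'   with non-positive runs variance automatically fall back to the
#'   permutation method.
#' @param n_perm permutations for `p_method = "permutation"`.
#' @param seed optional seed for the permutation draw.
#' @return An object of class `fr_test`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 20)
#' y <- matrix(rnorm(200, mean = 1), 20)
#' fr_test(x, y)
#' @export
fr_test <- function(x, y, metric = c("euclidean", "cosine"),
                    p_method = c("normal", "permutation"),
                    n_perm = 2000, seed = NULL) {
  metric <- match.arg(metric)
  p_method <- match.arg(p_method)
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("x and y must have the same dimensionality")
  pts <- rbind(x, y)
  labels <- rep(c("x", "y"), c(nrow(x), nrow(y)))
  d <- compute_distances(pts, metric)
  edges <- build_mst(d)
  result <- runs_statistic(edges, labels)
  degenerate <- !is.finite(result$var_runs) || result$var_runs <= 0
  if (p_method == "permutation" || degenerate) {
    if (degenerate && p_method == "normal")
      warning("non-positive runs variance; falling back to permutation p")
    result <- permutation_pvalue(edges, labels, n_perm = n_perm, seed = seed)
  } else {
    result <- fr_pvalue(result)
  }
  result$metric <- metric
  result
}

#' @export
print.fr_test <- function(x, ...) {
  cat("Friedman-Rafsky multivariate runs test\n")
  cat(sprintf("  samples: m = %d, n = %d (%s distance)\n", x$m, x$n,
              if (is.na(x$metric)) "unspecified" else x$metric))
  cat(sprintf("  runs R = %d (cross edges %d), E[R] = %.3f, Var[R] = %.3f\n",
              x$runs, x$cross_edges, x$e_runs, x$var_runs))
  cat(sprintf("  W = %.4f, p = %.4g (%s)\n", x$w_stat, x$p_value,
              if (is.na(x$p_method)) "no p-value computed" else x$p_method))
  invisible(x)
}
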