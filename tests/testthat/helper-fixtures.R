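# Small programmatic fixtures shared across test files.

make_counts <- function(n_genes = 6, n_cells = 8, seed = 1, max_count = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, max_count / 2), n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("c", seq_len(n_cells))))
  gene_matrix(m, layer = "counts")
}

two_cluster_labels <- function(cells) {
  cluster_labels(cells, rep(c("A", "B"), length.out = length(cells)))
}

# Brute-force minimum spanning tree total weight: enumerate all edge
# subsets of size N-1 and keep the cheapest connected acyclic one.
brute_mst_weight <- function(d) {
  n <- nrow(d)
  pairs <- t(combn(n, 2))
  best <- Inf
  for (sel in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    e <- pairs[sel, , drop = FALSE]
    # connectivity check via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (r in seq_len(nrow(e))) {
      a <- find(e[r, 1]); b <- find(e[r, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(d[e]))
  }
  best
}

# Pure-R reference of the per-pair iterative matching engine, mirroring the
# compiled path draw-for-draw (same RNG consumption), with a full p-value
# trace per iteration. Used as an independent oracle and for trajectory
# properties.
r_reference_pair <- function(Xq, Xr, s, n_iter, seed, metric = "euclidean") {
  nq <- ncol(Xq); nr <- ncol(Xr)
  Dqq <- frcellmatch:::cross_dist(Xq, Xq, metric)
  Drr <- frcellmatch:::cross_dist(Xr, Xr, metric)
  Dqr <- frcellmatch:::cross_dist(Xq, Xr, metric)
  diag(Dqq) <- 0; diag(Drr) <- 0
  set.seed(seed)
  Qd <- vapply(seq_len(n_iter), function(i) sample.int(nq, s), integer(s))
  Rd <- vapply(seq_len(n_iter), function(i) sample.int(nr, s), integer(s))
  best <- rep(NA_real_, nq)
  trace <- matrix(NA_real_, nq, n_iter)
  p_iter <- numeric(n_iter)
  for (t in seq_len(n_iter)) {
    qi <- Qd[, t]; ri <- Rd[, t]
    d <- frcellmatch:::pool_dist(Dqq, Drr, Dqr, qi, ri)
    rs <- runs_statistic(build_mst(d), rep(0:1, each = s))
    p <- fr_pvalue(rs)$p_value
    p_iter[t] <- p
    upd <- is.na(best[qi]) | p > best[qi]
    best[qi[upd]] <- p
    trace[, t] <- best
  }
  list(best_p = best, p_iter = p_iter, trace = trace)
}

# p-value matrix stripped to plain numbers (drop bookkeeping attributes)
pv_core <- function(m) {
  a <- unclass(m)
  attributes(a) <- list(dim = dim(a), dimnames = dimnames(a))
  a
}

small_atlas_pair <- function(n_clusters = 3, cells = 40, seed = 7, ...) {
  simulate_cell_atlas_pair(
    synthetic_atlas(n_clusters = n_clusters, cells_per_cluster = cells),
    seed = seed, ...)
}
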