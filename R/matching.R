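#' Matching parameters
#'
#' Defaults follow the method's standard settings: 2000 subsampling
#' iterations of 10 cells per side, Benjamini-Hochberg correction, and a
#' 0.1 significance threshold on the maximum adjusted p-value.
#'
#' @param subsamp_iter subsampling iterations per cluster pair (>= 1).
#' @param subsamp_size cells drawn from each side per iteration (>= 3). If a
#'   cluster holds fewer cells, the draw size for pairs involving it shrinks
#'   to the cluster size (with a warning).
#' @param sig_level threshold on the maximum adjusted p below which a query
#'   unit is called [UNASSIGNED].
#' @param p_adj_method `"BH"` or `"none"`.
#' @param metric `"euclidean"` or `"cosine"` (scale-invariant; recommended
#'   across platforms).
#' @param seed integer seed; every cluster pair derives its own sub-seed
#'   from it, so results are independent of worker count.
#' @param n_workers parallel workers (forked; `1` = serial).
#' @param bh_scope `"global"` applies BH jointly over the whole flattened
#'   p-value matrix; `"row"` adjusts each query row separately.
#' @param auto_iter if `TRUE`, the iteration count for a pair is raised to
#'   `ceiling(target_draws * n_query / subsamp_size)` so that every query
#'   cell is expected to be drawn at least `target_draws` times.
#' @param target_draws expected minimum draws per cell under `auto_iter`.
#' @return Object of class `match_params`.
#' @export
match_params <- function(subsamp_iter = 2000, subsamp_size = 10,
                         sig_level = 0.1,
                         p_adj_method = c("BH", "none"),
                         metric = c("euclidean", "cosine"),
                         seed = 42, n_workers = 1,
                         bh_scope = c("global", "row"),
                         auto_iter = FALSE, target_draws = 20) {
  p_adj_method <- match.arg(p_adj_method)
  metric <- match.arg(metric)
  bh_scope <- match.arg(bh_scope)
  stopifnot(subsamp_iter >= 1, subsamp_size >= 3,
            sig_level > 0, sig_level < 1)
  structure(list(subsamp_iter = as.integer(subsamp_iter),
                 subsamp_size = as.integer(subsamp_size),
                 sig_level = sig_level, p_adj_method = p_adj_method,
                 metric = metric, seed = as.integer(seed),
                 n_workers = as.integer(n_workers), bh_scope = bh_scope,
                 auto_iter = isTRUE(auto_iter),
                 target_draws = as.integer(target_draws)),
            class = "match_params")
}

# Deterministic sub-seed for cluster pair t; keeps every derived seed a
# positive 32-bit integer so worker scheduling cannot change results.
pair_seed <- function(seed, t) {
  s <- (as.double(seed) + 7919 * as.double(t)) %% 2147483629
  as.integer(s) + 1L
}

pool_dist <- function(Dqq, Drr, Dqr, qi, ri) {
  cross <- Dqr[qi, ri, drop = FALSE]
  rbind(cbind(Dqq[qi, qi, drop = FALSE], cross),
        cbind(t(cross), Drr[ri, ri, drop = FALSE]))
}

check_marker_space <- function(query, reference) {
  if (!identical(rownames(query$values), rownames(reference$values)))
    stop("query and reference are not in the same marker feature space")
}

aligned_labels <- function(x, labels, side) {
  cells <- colnames(x$values)
  miss <- setdiff(cells, names(labels))
  if (length(miss))
    stop(side, " labels missing for cells: ", paste(miss, collapse = ", "))
  factor(as.character(labels[cells]))
}

# Shared engine for both matching schemes. Returns per-pair iteration
# p-values plus per-cell max-updated p-values and coverage counts.
match_engine <- function(query, reference, q_labels, r_labels, params) {
  check_marker_space(query, reference)
  if (nrow(query$values) < 1) stop("empty marker space")
  Xq <- query$values
  Xr <- reference$values
  qlab <- aligned_labels(query, q_labels, "query")
  rlab <- aligned_labels(reference, r_labels, "reference")
  qcl <- levels(qlab)
  rcl <- levels(rlab)
  qidx <- split(seq_len(ncol(Xq)), qlab)
  ridx <- split(seq_len(ncol(Xr)), rlab)
  pairs <- expand.grid(j = seq_along(qcl), k = seq_along(rcl))

  run_pair <- function(t) {
    j <- pairs$j[t]; k <- pairs$k[t]
    qi_all <- qidx[[j]]; ri_all <- ridx[[k]]
    nq <- length(qi_all); nr <- length(ri_all)
    if (min(nq, nr) < 3)
      return(list(j = j, k = k, skipped = TRUE, small = FALSE))
    s <- min(params$subsamp_size, nq, nr)
    n_iter <- params$subsamp_iter
    if (params$auto_iter)
      n_iter <- max(n_iter, ceiling(params$target_draws * nq / s))
    Dqq <- cross_dist(Xq[, qi_all, drop = FALSE], Xq[, qi_all, drop = FALSE],
                      params$metric)
    Drr <- cross_dist(Xr[, ri_all, drop = FALSE], Xr[, ri_all, drop = FALSE],
                      params$metric)
    Dqr <- cross_dist(Xq[, qi_all, drop = FALSE], Xr[, ri_all, drop = FALSE],
                      params$metric)
    diag(Dqq) <- 0; diag(Drr) <- 0
    set.seed(pair_seed(params$seed, t))
    Qd <- vapply(seq_len(n_iter), function(i) sample.int(nq, s),
                 integer(s))
    Rd <- vapply(seq_len(n_iter), function(i) sample.int(nr, s),
                 integer(s))
    if (s == 1L) { Qd <- matrix(Qd, 1L); Rd <- matrix(Rd, 1L) }
    res <- cpp_match_pair(Dqq, Drr, Dqr, Qd, Rd)
    # degenerate iterations (zero runs variance): permutation fallback
    for (tf in res$var_fail) {
      qi <- Qd[, tf]; ri <- Rd[, tf]
      d <- pool_dist(Dqq, Drr, Dqr, qi, ri)
      pv <- permutation_pvalue(build_mst(d), rep(0:1, each = s),
                               n_perm = 1000)$p_value
      res$p_iter[tf] <- pv
      upd <- is.na(res$best_p[qi]) | pv > res$best_p[qi]
      res$best_p[qi[upd]] <- pv
    }
    list(j = j, k = k, skipped = FALSE, small = s < params$subsamp_size,
         s = s, best_p = res$best_p, coverage = res$coverage,
         p_iter = res$p_iter)
  }

  results <- if (params$n_workers > 1) {
    parallel::mclapply(seq_len(nrow(pairs)), run_pair,
                       mc.cores = params$n_workers)
  } else {
    lapply(seq_len(nrow(pairs)), run_pair)
  }

  skipped <- vapply(results, `[[`, TRUE, "skipped")
  if (any(skipped)) {
    bad <- unique(unlist(lapply(results[skipped], function(r)
      c(qcl[r$j], rcl[r$k]))))
    warning("cluster pairs skipped (fewer than 3 cells): involving ",
            paste(bad, collapse = ", "))
  }
  if (any(vapply(results, function(r) isTRUE(r$small), TRUE)))
    warning("some clusters are smaller than subsamp_size; ",
            "draw size reduced to the cluster size for those pairs")
  list(results = results, qcl = qcl, rcl = rcl, qidx = qidx,
       cells = colnames(Xq), qlab = qlab)
}

new_pvalue_matrix <- function(values, scheme, params, coverage = NULL) {
  structure(values, class = c("pvalue_matrix", class(values)),
            scheme = scheme, adjusted = FALSE, params = params,
            coverage = coverage)
}

#' @export
print.pvalue_matrix <- function(x, ...) {
  cat(sprintf("<pvalue_matrix> %s, %d x %d, %s\n", attr(x, "scheme"),
              nrow(x), ncol(x),
              if (attr(x, "adjusted")) "adjusted" else "raw"))
  print(unclass(x)[seq_len(min(6, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Iterative cell-to-cluster matching
#'
#' For every (query cluster, reference cluster) pair and each of
#' `subsamp_iter` iterations, equal-size subsamples are drawn from both
#' sides and compared with the Friedman-Rafsky test; every drawn query cell
#' keeps the maximum p-value it has seen against that reference cluster
#' (max-update rule). Cells never drawn against some reference carry `NA`,
#' distinguishable from "always rejected"; per-cell draw counts are
#' recorded in the `coverage` attribute.
#'
#' @param query,reference normalized [gene_matrix()] objects in the same
#'   marker feature space.
#' @param q_labels,r_labels [cluster_labels()].
#' @param params a [match_params()].
#' @return A raw C x K `pvalue_matrix` (query cells x reference clusters).
#' @export
match_cell_to_cluster <- function(query, reference, q_labels, r_labels,
                                  params = match_params()) {
  eng <- match_engine(query, reference, q_labels, r_labels, params)
  C <- length(eng$cells); K <- length(eng$rcl)
  P <- matrix(NA_real_, C, K, dimnames = list(eng$cells, eng$rcl))
  cov <- matrix(0L, C, K, dimnames = dimnames(P))
  for (r in eng$results) {
    if (r$skipped) next
    rows <- eng$qidx[[r$j]]
    old <- P[rows, r$k]
    P[rows, r$k] <- ifelse(is.na(old), r$best_p, pmax(old, r$best_p))
    cov[rows, r$k] <- cov[rows, r$k] + r$coverage
  }
  new_pvalue_matrix(P, "cell2cluster", params, coverage = cov)
}

#' Cluster-to-cluster matching by median p-value
#'
#' For each (query cluster, reference cluster) pair the matching p-value is
#' the median over `subsamp_iter` Friedman-Rafsky tests between equal-size
#' subsamples of the two clusters — equivalent to assigning the same median
#' p to every cell of the query cluster.
#'
#' @inheritParams match_cell_to_cluster
#' @return A raw L x K `pvalue_matrix` (query clusters x reference
#'   clusters).
#' @export
match_cluster_to_cluster <- function(query, reference, q_labels, r_labels,
                                     params = match_params()) {
  eng <- match_engine(query, reference, q_labels, r_labels, params)
  L <- length(eng$qcl); K <- length(eng$rcl)
  P <- matrix(NA_real_, L, K, dimnames = list(eng$qcl, eng$rcl))
  for (r in eng$results) {
    if (r$skipped) next
    P[r$j, r$k] <- median(r$p_iter, na.rm = TRUE)
  }
  new_pvalue_matrix(P, "cluster2cluster", params)
}

#' Multiple-testing correction of a matching p-value matrix
#'
#' Benjamini-Hochberg step-up applied over all non-NA entries jointly (the
#' default) or within each query row; NA entries pass through. Adjusted
#' values are never smaller than raw values and are capped at 1.
#'
#' @param m a raw `pvalue_matrix`.
#' @param method `"BH"` or `"none"`.
#' @param scope `"global"` or `"row"`.
#' @return The matrix with adjusted values and `adjusted = TRUE`.
#' @export
adjust_pvalues <- function(m, method = c("BH", "none"),
                           scope = c("global", "row")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  stopifnot(inherits(m, "pvalue_matrix"))
  out <- m
  if (method == "BH") {
    if (scope == "global") {
      v <- as.vector(unclass(m))
      v[!is.na(v)] <- p.adjust(v[!is.na(v)], method = "BH")
      out[seq_along(v)] <- v
    } else {
      for (i in seq_len(nrow(m))) {
        v <- unclass(m)[i, ]
        v[!is.na(v)] <- p.adjust(v[!is.na(v)], method = "BH")
        out[i, ] <- v
      }
    }
  }
  attr(out, "adjusted") <- TRUE
  attr(out, "bh_scope") <- if (method == "BH") scope else "none"
  out
}

#' Call matches from an adjusted p-value matrix
#'
#' Each query unit (cell or cluster) is matched to the reference cluster
#' giving its maximum adjusted p-value, or called [UNASSIGNED] when that
#' maximum falls below `sig_level` (or the whole row is NA). Exact ties go
#' to the first reference cluster in column order and are flagged.
#'
#' @param adjusted an adjusted `pvalue_matrix`.
#' @param sig_level significance threshold (default 0.1).
#' @return A data frame with columns `unit`, `matched`, `confidence`,
#'   `tie`; the reference cluster set is kept in the `ref_clusters`
#'   attribute.
#' @export
assign_matches <- function(adjusted, sig_level = 0.1) {
  stopifnot(inherits(adjusted, "pvalue_matrix"))
  if (!isTRUE(attr(adjusted, "adjusted")))
    warning("assigning from a raw (unadjusted) p-value matrix")
  v <- unclass(adjusted)
  n <- nrow(v)
  matched <- character(n); conf <- numeric(n); tie <- logical(n)
  for (i in seq_len(n)) {
    row <- v[i, ]
    if (all(is.na(row))) {
      matched[i] <- UNASSIGNED; conf[i] <- NA_real_
      next
    }
    mx <- max(row, na.rm = TRUE)
    conf[i] <- mx
    if (mx < sig_level) {
      matched[i] <- UNASSIGNED
    } else {
      hits <- which(row == mx)
      matched[i] <- colnames(v)[hits[1]]
      tie[i] <- length(hits) > 1
    }
  }
  out <- data.frame(unit = rownames(v), matched = matched,
                    confidence = conf, tie = tie,
                    stringsAsFactors = FALSE)
  attr(out, "ref_clusters") <- colnames(v)
  attr(out, "scheme") <- attr(adjusted, "scheme")
  out
}

#' Per-query-cluster proportions of cell-level matches
#'
#' Summarizes cell-to-cluster assignments as the fraction of each query
#' cluster's cells matched to every reference cluster or [UNASSIGNED].
#' Columns are query clusters and sum to 1 exactly; the unassigned row is
#' last.
#'
#' @param assignments output of [assign_matches()] for a cell-to-cluster
#'   run.
#' @param q_labels query [cluster_labels()].
#' @param ref_clusters reference cluster names; defaults to the attribute
#'   carried by `assignments`.
#' @return A (K+1) x L matrix of proportions.
#' @export
cell2cluster_proportions <- function(assignments, q_labels,
                                     ref_clusters = NULL) {
  if (is.null(ref_clusters)) ref_clusters <- attr(assignments, "ref_clusters")
  if (is.null(ref_clusters))
    ref_clusters <- setdiff(unique(assignments$matched), UNASSIGNED)
  ql <- factor(as.character(q_labels[assignments$unit]))
  matched <- factor(assignments$matched,
                    levels = c(ref_clusters, UNASSIGNED))
  tab <- table(matched, ql)
  props <- sweep(unclass(tab), 2, colSums(tab), "/")
  dimnames(props) <- list(c(ref_clusters, UNASSIGNED), levels(ql))
  props
}

#' Two-way cluster-to-cluster matching
#'
#' A (query, reference) cluster pair is declared matched only when the
#' adjusted matching p-value is at or above `sig_level` in both directions
#' (query-to-reference and reference-to-query) — the conservative
#' bi-directional criterion.
#'
#' @param p_qr adjusted cluster-to-cluster `pvalue_matrix`, query rows x
#'   reference columns.
#' @param p_rq same with the roles swapped (reference rows x query
#'   columns).
#' @param sig_level significance threshold.
#' @return Data frame of matched pairs with the two directional p-values.
#' @export
two_way_match <- function(p_qr, p_rq, sig_level = 0.1) {
  stopifnot(inherits(p_qr, "pvalue_matrix"), inherits(p_rq, "pvalue_matrix"))
  if (attr(p_qr, "scheme") != "cluster2cluster" ||
      attr(p_rq, "scheme") != "cluster2cluster")
    stop("two-way matching requires cluster-to-cluster p-value matrices")
  if (!setequal(rownames(p_qr), colnames(p_rq)) ||
      !setequal(colnames(p_qr), rownames(p_rq)))
    stop("label sets of the two directions do not match")
  out <- data.frame(query = character(0), reference = character(0),
                    p_forward = numeric(0), p_reverse = numeric(0))
  for (l in rownames(p_qr)) {
    for (k in colnames(p_qr)) {
      pf <- unclass(p_qr)[l, k]
      pr <- unclass(p_rq)[k, l]
      if (!is.na(pf) && !is.na(pr) && pf >= sig_level && pr >= sig_level)
        out <- rbind(out, data.frame(query = l, reference = k,
                                     p_forward = pf, p_reverse = pr))
    }
  }
  out
}

#' Match query cell types against a reference atlas
#'
#' The main entry point: runs the full pipeline — log2(CPM) preprocessing
#' when raw counts are supplied, projection into the reference marker
#' feature space, cross-platform normalization, Friedman-Rafsky matching
#' under the chosen scheme, multiple-testing correction, and
#' assignment/unassigned calls.
#'
#' @param query,reference [gene_matrix()] objects (counts, logCPM, or
#'   already normalized).
#' @param q_labels,r_labels [cluster_labels()] for the two datasets.
#' @param markers a [marker_set()] (or character vector) defining the
#'   reference feature space; `NULL` if the matrices are already projected.
#' @param scheme `"cell2cluster"` (default), `"cluster2cluster"`, or
#'   `"two_way"`.
#' @param params a [match_params()].
#' @param normalization a [norm_config()].
#' @param missing_policy forwarded to [project_to_markers()].
#' @return An object of class `frmatch` with components `pvalues` (raw),
#'   `pvalues_adj`, `assignments`, `proportions` (cell-to-cluster only),
#'   `matched_pairs` (two-way only), the normalized matrices, and the
#'   parameter objects.
#' @examples
#' sim <- simulate_cell_atlas_pair(synthetic_atlas(n_clusters = 3,
#'                                                 cells_per_cluster = 30),
#'                                 seed = 1)
#' fit <- frmatch(sim$query, sim$reference, sim$q_labels, sim$r_labels,
#'                sim$markers, params = match_params(subsamp_iter = 50))
#' summary(fit)
#' @export
frmatch <- function(query, reference, q_labels, r_labels, markers = NULL,
                    scheme = c("cell2cluster", "cluster2cluster", "two_way"),
                    params = match_params(),
                    normalization = norm_config(),
                    missing_policy = "zero_fill") {
  scheme <- match.arg(scheme)
  cl <- match.call()
  prep <- function(x) if (x$layer == "counts") cpm_log2(x) else x
  query <- prep(query); reference <- prep(reference)
  if (!is.null(markers)) {
    if (!inherits(markers, "marker_set")) markers <- marker_set(markers)
    query <- project_to_markers(query, markers, missing_policy)
    reference <- project_to_markers(reference, markers, missing_policy)
  }
  if (query$layer != "normalized" || reference$layer != "normalized") {
    nz <- normalize_pair(query, reference, q_labels, r_labels, normalization)
    query <- nz$query; reference <- nz$reference
  }
  obj <- list(call = cl, scheme = scheme, params = params,
              normalization = normalization, markers = markers,
              query = query, reference = reference,
              q_labels = q_labels, r_labels = r_labels)
  if (scheme == "cell2cluster") {
    raw <- match_cell_to_cluster(query, reference, q_labels, r_labels, params)
    adj <- adjust_pvalues(raw, params$p_adj_method, params$bh_scope)
    asn <- assign_matches(adj, params$sig_level)
    obj$pvalues <- raw
    obj$pvalues_adj <- adj
    obj$assignments <- asn
    obj$proportions <- cell2cluster_proportions(asn, q_labels)
  } else if (scheme == "cluster2cluster") {
    raw <- match_cluster_to_cluster(query, reference, q_labels, r_labels,
                                    params)
    adj <- adjust_pvalues(raw, params$p_adj_method, params$bh_scope)
    obj$pvalues <- raw
    obj$pvalues_adj <- adj
    obj$assignments <- assign_matches(adj, params$sig_level)
  } else {
    raw_qr <- match_cluster_to_cluster(query, reference, q_labels, r_labels,
                                       params)
    raw_rq <- match_cluster_to_cluster(reference, query, r_labels, q_labels,
                                       params)
    adj_qr <- adjust_pvalues(raw_qr, params$p_adj_method, params$bh_scope)
    adj_rq <- adjust_pvalues(raw_rq, params$p_adj_method, params$bh_scope)
    obj$pvalues <- raw_qr
    obj$pvalues_adj <- adj_qr
    obj$pvalues_reverse <- adj_rq
    obj$matched_pairs <- two_way_match(adj_qr, adj_rq, params$sig_level)
  }
  class(obj) <- "frmatch"
  obj
}

#' @export
print.frmatch <- function(x, ...) {
  cat(sprintf("Friedman-Rafsky cell type matching (%s scheme)\n", x$scheme))
  cat(sprintf("  %d query cells in %d clusters vs %d reference cells in %d clusters\n",
              ncol(x$query$values), nlevels(factor(x$q_labels)),
              ncol(x$reference$values), nlevels(factor(x$r_labels))))
  cat(sprintf("  %d markers, %s distance, %d iterations x %d cells, sig level %.2g\n",
              nrow(x$query$values), x$params$metric, x$params$subsamp_iter,
              x$params$subsamp_size, x$params$sig_level))
  if (x$scheme == "two_way") {
    cat(sprintf("  %d two-way matched cluster pairs\n", nrow(x$matched_pairs)))
  } else {
    un <- mean(x$assignments$matched == UNASSIGNED)
    cat(sprintf("  unassigned fraction: %.3f\n", un))
  }
  invisible(x)
}

#' @export
summary.frmatch <- function(object, ...) {
  if (object$scheme == "two_way") {
    cat("Two-way matched cluster pairs:\n")
    print(object$matched_pairs)
    return(invisible(object$matched_pairs))
  }
  tab <- table(object$assignments$matched)
  print(object)
  cat("Matched counts per reference cluster:\n")
  print(tab)
  if (!is.null(object$proportions)) {
    cat("Proportions (reference rows x query columns):\n")
    print(round(object$proportions, 3))
  }
  invisible(tab)
}

#' @export
plot.frmatch <- function(x, file = NULL, ...) {
  if (x$scheme == "cell2cluster") {
    plot_cell2cluster(x$proportions, file = file, ...)
  } else {
    plot_cluster_grid(x$pvalues_adj, sig_level = x$params$sig_level,
                      file = file, ...)
  }
}
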