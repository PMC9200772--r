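norm_pair_for <- function(sim) {
  nz <- normalize_pair(project_to_markers(sim$query, sim$markers),
                       project_to_markers(sim$reference, sim$markers),
                       sim$q_labels, sim$r_labels, norm_config("none"))
  nz
}

test_that("compiled matching engine agrees with a pure-R reference", {
  sim <- small_atlas_pair(n_clusters = 2, cells = 25, seed = 31)
  nz <- norm_pair_for(sim)
  qcells <- names(sim$q_labels)[sim$q_labels == "C1"]
  rcells <- names(sim$r_labels)[sim$r_labels == "C1"]
  Xq <- nz$query$values[, qcells]
  Xr <- nz$reference$values[, rcells]

  # pair index of (j=1, k=1) in the engine's expand.grid order is 1
  seed <- frcellmatch:::pair_seed(42, 1)
  ref <- r_reference_pair(Xq, Xr, s = 10, n_iter = 60, seed = seed)

  pm <- match_cell_to_cluster(nz$query, nz$reference, sim$q_labels,
                              sim$r_labels,
                              match_params(subsamp_iter = 60, seed = 42))
  expect_equal(unname(unclass(pm)[qcells, "C1"]), ref$best_p)
})

test_that("max-update trajectories are non-decreasing", {
  sim <- small_atlas_pair(n_clusters = 2, cells = 20, seed = 32)
  nz <- norm_pair_for(sim)
  qcells <- names(sim$q_labels)[sim$q_labels == "C2"]
  rcells <- names(sim$r_labels)[sim$r_labels == "C2"]
  ref <- r_reference_pair(nz$query$values[, qcells],
                          nz$reference$values[, rcells],
                          s = 8, n_iter = 80, seed = 99)
  for (i in seq_len(nrow(ref$trace))) {
    tr <- ref$trace[i, !is.na(ref$trace[i, ])]
    if (length(tr) > 1) expect_true(all(diff(tr) >= 0))
  }
  # a cell's final p is the max over the iterations that drew it
  expect_equal(ref$best_p, apply(ref$trace, 1, function(z)
    if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)))
})

test_that("single-iteration semantics: drawn cells share p1, others are NA", {
  sim <- small_atlas_pair(n_clusters = 2, cells = 30, seed = 33)
  nz <- norm_pair_for(sim)
  pm <- match_cell_to_cluster(nz$query, nz$reference, sim$q_labels,
                              sim$r_labels,
                              match_params(subsamp_iter = 1, seed = 5))
  cov <- attr(pm, "coverage")
  for (k in colnames(pm)) {
    for (l in c("C1", "C2")) {
      rows <- names(sim$q_labels)[sim$q_labels == l]
      drawn <- rows[cov[rows, k] > 0]
      expect_length(drawn, 10)
      expect_length(unique(unclass(pm)[drawn, k]), 1)
      expect_true(all(is.na(unclass(pm)[setdiff(rows, drawn), k])))
    }
  }
})

test_that("matching is reproducible and independent of worker count", {
  sim <- small_atlas_pair(n_clusters = 3, cells = 20, seed = 34)
  nz <- norm_pair_for(sim)
  p1 <- match_cell_to_cluster(nz$query, nz$reference, sim$q_labels,
                              sim$r_labels,
                              match_params(subsamp_iter = 40, seed = 7))
  p2 <- match_cell_to_cluster(nz$query, nz$reference, sim$q_labels,
                              sim$r_labels,
                              match_params(subsamp_iter = 40, seed = 7))
  expect_identical(pv_core(p1), pv_core(p2))
  p4 <- match_cell_to_cluster(nz$query, nz$reference, sim$q_labels,
                              sim$r_labels,
                              match_params(subsamp_iter = 40, seed = 7,
                                           n_workers = 2))
  expect_equal(pv_core(p1), pv_core(p4))
  p3 <- match_cell_to_cluster(nz$query, nz$reference, sim$q_labels,
                              sim$r_labels,
                              match_params(subsamp_iter = 40, seed = 8))
  expect_false(identical(pv_core(p1), pv_core(p3)))
})

test_that("small clusters shrink the draw or are skipped with warnings", {
  sim <- small_atlas_pair(n_clusters = 2, cells = 30, seed = 35)
  nz <- norm_pair_for(sim)
  # shrink one query cluster to 5 cells, another to 2
  keep <- c(names(sim$q_labels)[sim$q_labels == "C1"][1:5],
            names(sim$q_labels)[sim$q_labels == "C2"][1:2])
  qlab <- cluster_labels(keep, as.character(sim$q_labels[keep]))
  qm <- gene_matrix(nz$query$values[, keep], layer = "normalized")
  expect_warning(expect_warning(
    pm <- match_cell_to_cluster(qm, nz$reference, qlab, sim$r_labels,
                                match_params(subsamp_iter = 20, seed = 1)),
    "subsamp_size"), "skipped")
  c2 <- names(qlab)[qlab == "C2"]
  expect_true(all(is.na(unclass(pm)[c2, ])))
})

test_that("cluster-to-cluster p is the median over iterations", {
  sim <- small_atlas_pair(n_clusters = 2, cells = 25, seed = 36)
  nz <- norm_pair_for(sim)
  seed <- frcellmatch:::pair_seed(11, 1)
  ref <- r_reference_pair(nz$query$values[, names(sim$q_labels)[sim$q_labels == "C1"]],
                          nz$reference$values[, names(sim$r_labels)[sim$r_labels == "C1"]],
                          s = 10, n_iter = 50, seed = seed)
  pm <- match_cluster_to_cluster(nz$query, nz$reference, sim$q_labels,
                                 sim$r_labels,
                                 match_params(subsamp_iter = 50, seed = 11))
  expect_equal(unclass(pm)["C1", "C1"], median(ref$p_iter))
  expect_equal(attr(pm, "scheme"), "cluster2cluster")
  expect_equal(dim(pm), c(2L, 2L))
})

test_that("the two matching schemes agree on separated data", {
  sim <- small_atlas_pair(n_clusters = 3, cells = 40, seed = 37)
  nz <- norm_pair_for(sim)
  par <- match_params(subsamp_iter = 300, seed = 2)
  cell <- match_cell_to_cluster(nz$query, nz$reference, sim$q_labels,
                                sim$r_labels, par)
  clus <- match_cluster_to_cluster(nz$query, nz$reference, sim$q_labels,
                                   sim$r_labels, par)
  for (l in levels(sim$q_labels)) {
    rows <- names(sim$q_labels)[sim$q_labels == l]
    for (k in colnames(clus)) {
      cell_med <- median(unclass(cell)[rows, k], na.rm = TRUE)
      if (l == k) {
        # both call the true pair significant at the 0.1 threshold
        expect_gte(cell_med, 0.1)
        expect_gte(unclass(clus)[l, k], 0.1)
      } else {
        # off-target pairs are rejected by both, with close medians
        expect_lt(unclass(clus)[l, k], 0.1)
        expect_lt(abs(cell_med - unclass(clus)[l, k]), 0.15)
      }
    }
  }
})

test_that("BH adjustment follows the step-up closed forms", {
  m <- matrix(c(0.01, 0.02, 0.03, 0.04), 2,
              dimnames = list(c("u1", "u2"), c("A", "B")))
  pm <- frcellmatch:::new_pvalue_matrix(m, "cell2cluster", match_params())
  adj <- adjust_pvalues(pm)
  expect_equal(unname(as.vector(unclass(adj))), rep(0.04, 4))
  expect_true(attr(adj, "adjusted"))

  ones <- frcellmatch:::new_pvalue_matrix(matrix(1, 2, 2,
                                                 dimnames = dimnames(m)),
                                          "cell2cluster", match_params())
  expect_equal(unname(as.vector(unclass(adjust_pvalues(ones)))), rep(1, 4))

  single <- frcellmatch:::new_pvalue_matrix(
    matrix(c(0.03, NA, NA, NA), 2, dimnames = dimnames(m)),
    "cell2cluster", match_params())
  asingle <- adjust_pvalues(single)
  expect_equal(unclass(asingle)[1, 1], 0.03)
  expect_equal(sum(is.na(asingle)), 3)

  # adjusted >= raw, capped at 1; row scope adjusts within rows
  set.seed(3)
  r <- matrix(runif(20), 4, dimnames = list(paste0("u", 1:4),
                                            paste0("k", 1:5)))
  rp <- frcellmatch:::new_pvalue_matrix(r, "cell2cluster", match_params())
  g <- adjust_pvalues(rp)
  expect_true(all(unclass(g) >= r & unclass(g) <= 1))
  rowadj <- adjust_pvalues(rp, scope = "row")
  expect_equal(unname(unclass(rowadj)[2, ]),
               unname(p.adjust(r[2, ], "BH")))
})

test_that("assignment applies argmax, threshold, ties and NA rules", {
  m <- rbind(a = c(0.05, 0.02, 0.08),
             b = c(0.05, 0.60, 0.08),
             c = c(0.60, 0.60, 0.10),
             d = c(NA, NA, NA))
  colnames(m) <- c("R1", "R2", "R3")
  pm <- frcellmatch:::new_pvalue_matrix(m, "cell2cluster", match_params())
  attr(pm, "adjusted") <- TRUE
  asn <- assign_matches(pm, sig_level = 0.1)
  expect_equal(asn$matched, c(UNASSIGNED, "R2", "R1", UNASSIGNED))
  expect_equal(asn$confidence[2], 0.6)
  expect_true(asn$tie[3])
  expect_true(is.na(asn$confidence[4]))
})

test_that("proportions are per query cluster and columns sum to one", {
  cells <- paste0("q", 1:20)
  qlab <- cluster_labels(cells, rep(c("L1", "L2"), each = 10))
  asn <- data.frame(unit = cells,
                    matched = c(rep("A", 10), rep(c("A", "B"), 5)),
                    confidence = 0.5, tie = FALSE)
  attr(asn, "ref_clusters") <- c("A", "B")
  pr <- cell2cluster_proportions(asn, qlab)
  expect_equal(pr["A", "L1"], 1)
  expect_equal(pr["A", "L2"], 0.5)
  expect_equal(pr["B", "L2"], 0.5)
  expect_equal(unname(colSums(pr)), c(1, 1))
  expect_equal(rownames(pr)[nrow(pr)], UNASSIGNED)

  set.seed(4)
  asn$matched <- sample(c("A", "B", UNASSIGNED), 20, replace = TRUE)
  expect_equal(unname(colSums(cell2cluster_proportions(asn, qlab))), c(1, 1))
})

test_that("two-way matching is the conjunction of both directions", {
  qr <- frcellmatch:::new_pvalue_matrix(
    matrix(c(0.5, 0.01, 0.5, 0.5), 2,
           dimnames = list(c("L1", "L2"), c("K1", "K2"))),
    "cluster2cluster", match_params())
  rq <- frcellmatch:::new_pvalue_matrix(
    matrix(c(0.5, 0.01, 0.01, 0.5), 2,
           dimnames = list(c("K1", "K2"), c("L1", "L2"))),
    "cluster2cluster", match_params())
  tw <- two_way_match(qr, rq, 0.1)
  expect_equal(nrow(tw), 2)
  expect_true(all(c("L1", "L2") %in% tw$query))
  expect_equal(tw$reference[tw$query == "L1"], "K1")
  # 0.5 one way / 0.01 the other is not matched
  expect_false(any(tw$query == "L1" & tw$reference == "K2"))

  bad <- frcellmatch:::new_pvalue_matrix(
    matrix(0.5, 2, 2, dimnames = list(c("X1", "X2"), c("L1", "L2"))),
    "cluster2cluster", match_params())
  expect_error(two_way_match(qr, bad), "label sets")
})

test_that("self-match via frmatch recovers the diagonal with high p", {
  sim <- small_atlas_pair(n_clusters = 3, cells = 40, seed = 38)
  fit <- frmatch(sim$query, sim$reference, sim$q_labels, sim$r_labels,
                 sim$markers, params = match_params(subsamp_iter = 200))
  truth <- as.character(sim$q_labels[fit$assignments$unit])
  expect_gte(mean(fit$assignments$matched == truth), 0.95)
  expect_equal(unname(colSums(fit$proportions)), rep(1, 3))

  # two-way self match keeps the full diagonal (same-platform pair:
  # min-max rescaling only, as weighting is a cross-platform step)
  tw <- frmatch(sim$query, sim$reference, sim$q_labels, sim$r_labels,
                sim$markers, scheme = "two_way",
                normalization = norm_config("none"),
                params = match_params(subsamp_iter = 100))
  diag_pairs <- with(tw$matched_pairs, query == reference)
  expect_true(all(levels(sim$q_labels) %in% tw$matched_pairs$query[diag_pairs]))
})
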