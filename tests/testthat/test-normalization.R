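rescaled <- function(v, ...) {
  gene_matrix(v, layer = "rescaled", ...)
}

test_that("min-max rescaling follows the formula and is idempotent", {
  v <- matrix(c(0, 2, 4,
                0, 0, 0,
                3, 3, 3), 3, byrow = TRUE,
              dimnames = list(paste0("G", 1:3), paste0("c", 1:3)))
  x <- minmax_rescale(gene_matrix(v, layer = "logCPM"))
  expect_equal(unname(x$values[1, ]), c(0, 0.5, 1))
  expect_equal(unname(x$values[2, ]), c(0, 0, 0)) # 0/0 defined as 0
  expect_equal(unname(x$values[3, ]), c(1, 1, 1))
  expect_equal(x$layer, "rescaled")
  expect_equal(minmax_rescale(x)$values, x$values)
})

test_that("cluster-summary weighting matches the hand-computed example", {
  # one cluster of two cells; rows (1,1) and (0.5,0); mean weights (1,0.25)
  v <- matrix(c(1, 1, 0.5, 0), 2, byrow = TRUE,
              dimnames = list(c("G1", "G2"), c("c1", "c2")))
  lab <- cluster_labels(c("c1", "c2"), c("A", "A"))
  w <- weight_by_cluster_summary(rescaled(v), lab, "mean")
  expect_equal(unname(w$values[1, ]), c(1, 1))
  expect_equal(unname(w$values[2, ]), c(0.125, 0))
  expect_equal(w$layer, "normalized")
})

test_that("median weighting zeroes genes expressed in a minority of cells", {
  set.seed(1)
  v <- matrix(0, 2, 10, dimnames = list(c("G1", "G2"), paste0("c", 1:10)))
  v["G1", ] <- 1                      # constant marker
  v["G2", sample(10, 3)] <- c(0.9, 0.8, 1)  # expressed in 3 of 10 cells
  lab <- cluster_labels(colnames(v), rep("A", 10))
  w <- weight_by_cluster_summary(rescaled(v), lab, "median")
  expect_true(all(w$values["G2", ] == 0))
  expect_equal(unname(w$values["G1", ]), rep(1, 10)) # weight-1 fixed point
})

test_that("weighting requires the rescaled layer", {
  x <- make_counts(4, 6, seed = 8)
  lab <- two_cluster_labels(colnames(x$values))
  expect_error(weight_by_cluster_summary(x, lab), "rescale")
})

test_that("all-zero weighted clusters are left at zero with a warning", {
  v <- matrix(c(0.4, 0, 0, 0.3, 0.3, 0.2), 1, 6,
              dimnames = list("G1", paste0("c", 1:6)))
  lab <- cluster_labels(colnames(v), rep(c("A", "B"), each = 3))
  # cluster A: median of (0.4, 0, 0) is 0 -> weighted submatrix all zero
  expect_warning(w <- weight_by_cluster_summary(rescaled(v), lab, "median"),
                 "'A'")
  expect_true(all(w$values[, 1:3] == 0))
  expect_false(all(w$values[, 4:6] == 0))
})

test_that("platform tags and config gate the weighting step", {
  sim <- small_atlas_pair(seed = 21, query_style = "bimodal",
                          reference_style = "rightskew")
  q <- project_to_markers(sim$query, sim$markers)
  r <- project_to_markers(sim$reference, sim$markers)
  expect_equal(q$platform, "smartseq")
  expect_equal(r$platform, "tenx")

  nz <- normalize_pair(q, r, sim$q_labels, sim$r_labels,
                       norm_config("median"))
  only_scaled <- minmax_rescale(r)$values
  expect_equal(nz$reference$values, only_scaled) # 10X side untouched
  expect_false(isTRUE(all.equal(nz$query$values,
                                minmax_rescale(q)$values)))

  none <- normalize_pair(q, r, sim$q_labels, sim$r_labels,
                         norm_config("none"))
  expect_equal(none$query$values, minmax_rescale(q)$values)
  expect_equal(none$reference$values, only_scaled)
  expect_equal(none$query$layer, "normalized")

  # determinism and feature-space check
  nz2 <- normalize_pair(q, r, sim$q_labels, sim$r_labels,
                        norm_config("median"))
  expect_identical(nz$query$values, nz2$query$values)
  r_bad <- r; rownames(r_bad$values)[1] <- "OTHER"
  expect_error(normalize_pair(q, r_bad, sim$q_labels, sim$r_labels),
               "feature space")
})

test_that("normalized output stays in [0,1] with per-cluster max 1", {
  sim <- small_atlas_pair(seed = 22, query_style = "bimodal")
  q <- project_to_markers(sim$query, sim$markers)
  nz <- normalize_pair(q, project_to_markers(sim$reference, sim$markers),
                       sim$q_labels, sim$r_labels, norm_config("mean"))
  v <- nz$query$values
  expect_true(all(v >= 0 & v <= 1))
  for (b in levels(sim$q_labels)) {
    sub <- v[, names(sim$q_labels)[sim$q_labels == b], drop = FALSE]
    expect_equal(max(sub), 1)
  }
})

test_that("weights on marker-structured plate-style data are near-binary", {
  sim <- small_atlas_pair(n_clusters = 5, cells = 100, seed = 23,
                          query_style = "bimodal")
  q <- minmax_rescale(project_to_markers(sim$query, sim$markers))
  weights <- c()
  for (b in levels(sim$q_labels)) {
    sub <- q$values[, names(sim$q_labels)[sim$q_labels == b], drop = FALSE]
    weights <- c(weights, rowMeans(sub))
  }
  expect_gte(mean(weights <= 0.2 | weights >= 0.8), 0.9)
})

test_that("weighting is a no-op for within-cluster-constant genes", {
  v <- matrix(rep(c(1, 0.5, 0.25, 1), each = 3), 4, 3, byrow = TRUE,
              dimnames = list(paste0("G", 1:4), paste0("c", 1:3)))
  lab <- cluster_labels(colnames(v), rep("A", 3))
  w <- weight_by_cluster_summary(rescaled(v), lab, "mean")
  # weights equal the constant row values; global max rescale restores 1
  expect_equal(unname(w$values[, 1]), c(1, 0.25, 0.0625, 1))
})

test_that("permuting cell order commutes with normalization", {
  sim <- small_atlas_pair(seed = 24, query_style = "bimodal")
  q <- project_to_markers(sim$query, sim$markers)
  r <- project_to_markers(sim$reference, sim$markers)
  nz <- normalize_pair(q, r, sim$q_labels, sim$r_labels,
                       norm_config("mean"))
  set.seed(1)
  perm <- sample(ncol(q$values))
  qp <- gene_matrix(q$values[, perm], layer = q$layer,
                    platform = q$platform)
  nzp <- normalize_pair(qp, r, sim$q_labels, sim$r_labels,
                        norm_config("mean"))
  expect_equal(nzp$query$values, nz$query$values[, perm])
})
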