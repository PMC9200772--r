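#' Multivariate normal two-sample scenario
#'
#' Describes a two-sample simulation design: both samples are p-dimensional
#' multivariate normal; alternatives move the second sample's location by
#' `delta` per coordinate and/or multiply its covariance by `sigma_scale`.
#' The base covariance is equicorrelated, `Sigma = (1-rho) I + rho J`.
#' `scale_y` multiplies the second sample by a positive constant after
#' drawing — the platform scale-mismatch distortion that motivates the
#' cosine metric. It is a nuisance, not a signal: it changes the scale of
#' the data, not the underlying biology, so it is applied under the null as
#' well and is kept orthogonal to the distributional alternative (the
#' alternative modifies the first sample, the platform factor the second).
#'
#' @param kind `"null"`, `"location"`, `"shape"`, or `"both"`.
#' @param p dimension (default 40).
#' @param m,n sample sizes.
#' @param delta per-coordinate location shift (location/both; default 1).
#' @param sigma_scale covariance multiplier (shape/both; default 1.5).
#' @param rho equicorrelation of the base covariance (default 0.2).
#' @param scale_y positive scale factor applied to the second sample
#'   (default 1 = no mismatch).
#' @param seed optional integer seed.
#' @return Object of class `mvn_scenario`.
#' @export
mvn_scenario <- function(kind = c("null", "location", "shape", "both"),
                         p = 40, m = 20, n = 20, delta = NULL,
                         sigma_scale = NULL, rho = 0.2, scale_y = 1,
                         seed = NULL) {
  kind <- match.arg(kind)
  if (p < 2) stop("p must be at least 2")
  if (rho <= -1 / (p - 1) || rho >= 1)
    stop("rho outside the positive-definite range")
  if (scale_y <= 0) stop("scale_y must be positive")
  delta <- if (kind %in% c("location", "both"))
    (if (is.null(delta)) 1 else delta) else 0
  sigma_scale <- if (kind %in% c("shape", "both"))
    (if (is.null(sigma_scale)) 1.5 else sigma_scale) else 1
  structure(list(kind = kind, p = p, m = m, n = n, delta = delta,
                 sigma_scale = sigma_scale, rho = rho, scale_y = scale_y,
                 seed = seed),
            class = "mvn_scenario")
}

chol_equicorr <- function(p, rho) {
  chol((1 - rho) * diag(p) + rho * matrix(1, p, p))
}

#' Draw the two samples of an MVN scenario
#'
#' @param scenario an [mvn_scenario()].
#' @return `list(x = m x p, y = n x p)` matrices; `x` carries the location
#'   shift and covariance scaling of the alternative, `y` the platform
#'   scale mismatch.
#' @export
simulate_mvn_two_sample <- function(scenario) {
  stopifnot(inherits(scenario, "mvn_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  p <- scenario$p
  L <- chol_equicorr(p, scenario$rho)
  x <- matrix(rnorm(scenario$m * p), scenario$m) %*%
    (L * sqrt(scenario$sigma_scale)) + scenario$delta
  y <- matrix(rnorm(scenario$n * p), scenario$n) %*% L
  y <- y * scenario$scale_y
  list(x = x, y = y)
}

#' Rank-based AUC of two p-value samples
#'
#' AUC = P(alternative p < null p) + 0.5 P(tie): the Mann-Whitney
#' probability that a randomly chosen alternative-hypothesis p-value
#' undercuts a randomly chosen null p-value, i.e. the area under the ROC
#' curve traced by thresholding p.
#'
#' @param p_alt p-values under the alternative.
#' @param p_null p-values under the null.
#' @return A number in \[0, 1\].
#' @export
auc_rank <- function(p_alt, p_null) {
  n1 <- length(p_alt); n0 <- length(p_null)
  r <- rank(c(p_null, p_alt))
  (sum(r[seq_len(n0)]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' Power/ROC study of the test over simulation scenarios
#'
#' For each scenario and metric, `n_reps` paired replicates are drawn: a
#' null pair (two samples from the scenario's first distribution, the
#' second carrying any scale mismatch) and an alternative pair (the
#' scenario as specified). The Friedman-Rafsky p-values of the two pair
#' types form the ROC; the AUC is the rank statistic of [auc_rank()].
#'
#' @param scenarios list of [mvn_scenario()] objects.
#' @param metrics character subset of `c("euclidean", "cosine")`.
#' @param n_reps replicates per scenario/metric (>= 100).
#' @param alpha_grid thresholds at which ROC points are reported.
#' @param seed integer seed for the whole study.
#' @return `list(table = data.frame, roc = list)`; the table has one row
#'   per (scenario, metric) with the AUC and the empirical power at 0.05.
#' @export
run_power_study <- function(scenarios, metrics = c("euclidean", "cosine"),
                            n_reps = 500,
                            alpha_grid = seq(0, 1, by = 0.05),
                            seed = 1) {
  if (n_reps < 100) stop("n_reps must be at least 100")
  metrics <- match.arg(metrics, c("euclidean", "cosine"),
                       several.ok = TRUE)
  rows <- list(); roc <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    null_sc <- sc
    null_sc$kind <- "null"; null_sc$delta <- 0; null_sc$sigma_scale <- 1
    null_sc$seed <- NULL
    alt_sc <- sc; alt_sc$seed <- NULL
    set.seed(seed + si)
    p_null <- matrix(NA_real_, n_reps, length(metrics),
                     dimnames = list(NULL, metrics))
    p_alt <- p_null
    for (r in seq_len(n_reps)) {
      s0 <- simulate_mvn_two_sample(null_sc)
      s1 <- simulate_mvn_two_sample(alt_sc)
      for (mt in metrics) {
        p_null[r, mt] <- fr_test(s0$x, s0$y, metric = mt)$p_value
        p_alt[r, mt] <- fr_test(s1$x, s1$y, metric = mt)$p_value
      }
    }
    for (mt in metrics) {
      key <- sprintf("scenario%d_%s", si, mt)
      roc[[key]] <- data.frame(
        alpha = alpha_grid,
        fpr = vapply(alpha_grid, function(a) mean(p_null[, mt] <= a), 0),
        tpr = vapply(alpha_grid, function(a) mean(p_alt[, mt] <= a), 0))
      rows[[key]] <- data.frame(
        scenario = si, kind = sc$kind, metric = mt, m = sc$m, n = sc$n,
        scale_y = sc$scale_y, delta = sc$delta,
        sigma_scale = sc$sigma_scale,
        auc = auc_rank(p_alt[, mt], p_null[, mt]),
        power_at_05 = mean(p_alt[, mt] <= 0.05),
        size_at_05 = mean(p_null[, mt] <= 0.05))
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       roc = roc)
}

#' Marker-structured synthetic atlas description
#'
#' Describes a multi-cluster atlas with near-binary marker structure: each
#' cluster owns a disjoint block of marker genes expressed at a high
#' negative-binomial mean in that cluster and at a low background mean
#' elsewhere, plus housekeeping-like noise genes shared by all clusters.
#' Platform styles distort the marginals: `"bimodal"` emulates deep
#' plate-based (SMART-seq-like) profiles with low-level off-target
#' background; `"rightskew"` emulates shallow droplet (10X-like) profiles
#' with heavy dropout and a long right tail.
#'
#' @param n_clusters number of cell type clusters (>= 2).
#' @param markers_per_cluster marker genes defining each cluster.
#' @param cells_per_cluster cells drawn per cluster.
#' @param n_noise_genes non-marker genes expressed everywhere.
#' @param platform_style `"bimodal"` or `"rightskew"`.
#' @param mu_on,mu_off,mu_noise negative-binomial means of on-target
#'   markers, off-target markers, and noise genes (defaults depend on the
#'   platform style).
#' @param nb_size negative-binomial dispersion (size) parameter.
#' @param dropout probability that an on-target marker count is zeroed.
#' @return Object of class `synthetic_atlas`.
#' @export
synthetic_atlas <- function(n_clusters = 5, markers_per_cluster = 4,
                            cells_per_cluster = 200, n_noise_genes = 30,
                            platform_style = c("bimodal", "rightskew"),
                            mu_on = NULL, mu_off = NULL, mu_noise = NULL,
                            nb_size = 2, dropout = NULL) {
  platform_style <- match.arg(platform_style)
  if (n_clusters < 2) stop("need at least 2 clusters")
  defaults <- if (platform_style == "bimodal") {
    # deep plate-based profiles: little dropout, sparse weak off-target
    # background expression (what cluster-summary weighting removes)
    list(mu_on = 50, mu_off = 0.2, mu_noise = 10, dropout = 0.05)
  } else {
    # shallow droplet profiles: heavy dropout, near-zero off-target signal
    list(mu_on = 8, mu_off = 0.05, mu_noise = 3, dropout = 0.5)
  }
  structure(list(n_clusters = n_clusters,
                 markers_per_cluster = markers_per_cluster,
                 cells_per_cluster = cells_per_cluster,
                 n_noise_genes = n_noise_genes,
                 platform_style = platform_style,
                 mu_on = if (is.null(mu_on)) defaults$mu_on else mu_on,
                 mu_off = if (is.null(mu_off)) defaults$mu_off else mu_off,
                 mu_noise = if (is.null(mu_noise)) defaults$mu_noise
                            else mu_noise,
                 nb_size = nb_size,
                 dropout = if (is.null(dropout)) defaults$dropout
                           else dropout),
            class = "synthetic_atlas")
}

atlas_cluster_names <- function(atlas) {
  paste0("C", seq_len(atlas$n_clusters))
}

# One dataset draw from the atlas description: counts -> log2(CPM).
draw_atlas <- function(atlas, prefix, platform_style = NULL) {
  style_atlas <- atlas
  if (!is.null(platform_style)) {
    style_atlas <- synthetic_atlas(
      n_clusters = atlas$n_clusters,
      markers_per_cluster = atlas$markers_per_cluster,
      cells_per_cluster = atlas$cells_per_cluster,
      n_noise_genes = atlas$n_noise_genes,
      platform_style = platform_style,
      nb_size = atlas$nb_size)
  }
  a <- style_atlas
  cls <- atlas_cluster_names(a)
  n_mark <- a$n_clusters * a$markers_per_cluster
  marker_names <- paste0("MK", seq_len(n_mark))
  owner <- rep(cls, each = a$markers_per_cluster)
  noise_names <- paste0("HK", seq_len(a$n_noise_genes))
  genes <- c(marker_names, noise_names)
  n_cells <- a$n_clusters * a$cells_per_cluster
  counts <- matrix(0, length(genes), n_cells,
                   dimnames = list(genes, paste0(prefix,
                                                 seq_len(n_cells))))
  clusters <- rep(cls, each = a$cells_per_cluster)
  for (b in cls) {
    idx <- which(clusters == b)
    nb <- length(idx)
    on <- owner == b
    counts[marker_names[on], idx] <-
      rnbinom(sum(on) * nb, mu = a$mu_on, size = a$nb_size) *
      rbinom(sum(on) * nb, 1, 1 - a$dropout)
    counts[marker_names[!on], idx] <-
      rnbinom(sum(!on) * nb, mu = a$mu_off, size = a$nb_size)
    counts[noise_names, idx] <-
      rnbinom(a$n_noise_genes * nb, mu = a$mu_noise, size = a$nb_size)
  }
  # guard against all-zero cells in extreme parameterizations
  zero <- colSums(counts) == 0
  if (any(zero)) counts[1, zero] <- 1
  platform <- if (a$platform_style == "bimodal") "smartseq" else "tenx"
  x <- cpm_log2(gene_matrix(counts, layer = "counts", platform = platform))
  list(matrix = x,
       labels = cluster_labels(colnames(counts), clusters),
       markers = marker_set(marker_names,
                            stats::setNames(owner, marker_names)))
}

#' Draw a query/reference dataset pair from a synthetic atlas
#'
#' The reference always holds every cluster; the query is an independent
#' draw from the same generators, optionally modified: `drop_cluster`
#' removes one cluster from the query, and `merge_clusters` relabels two
#' query clusters under one merged label (the under-partitioning scenario).
#' The returned truth map records the expected reference match of every
#' query cluster label.
#'
#' @param atlas a [synthetic_atlas()].
#' @param query_mod `"none"`, `"drop_cluster"`, or `"merge_clusters"`.
#' @param drop_cluster cluster name to drop from the query.
#' @param merge_clusters character vector of two cluster names to merge in
#'   the query.
#' @param query_style,reference_style optionally override the platform
#'   style of either side (cross-platform pairs).
#' @param seed integer seed.
#' @return List with `query`, `q_labels`, `reference`, `r_labels`,
#'   `markers`, and `truth` (named list mapping each query label to the
#'   expected reference cluster(s)).
#' @export
simulate_cell_atlas_pair <- function(atlas,
                                     query_mod = c("none", "drop_cluster",
                                                   "merge_clusters"),
                                     drop_cluster = NULL,
                                     merge_clusters = NULL,
                                     query_style = NULL,
                                     reference_style = NULL,
                                     seed = NULL) {
  query_mod <- match.arg(query_mod)
  stopifnot(inherits(atlas, "synthetic_atlas"))
  if (!is.null(seed)) set.seed(seed)
  cls <- atlas_cluster_names(atlas)
  ref <- draw_atlas(atlas, "R", reference_style)
  qry <- draw_atlas(atlas, "Q", query_style)
  q_labels <- qry$labels
  truth <- as.list(stats::setNames(cls, cls))
  if (query_mod == "drop_cluster") {
    if (is.null(drop_cluster) || !drop_cluster %in% cls)
      stop("drop_cluster must name an existing cluster")
    keep <- names(q_labels)[q_labels != drop_cluster]
    q_labels <- cluster_labels(keep, as.character(q_labels[keep]))
    qry$matrix <- gene_matrix(qry$matrix$values[, keep, drop = FALSE],
                              layer = qry$matrix$layer,
                              platform = qry$matrix$platform)
    truth[[drop_cluster]] <- NULL
  } else if (query_mod == "merge_clusters") {
    if (length(merge_clusters) != 2 || !all(merge_clusters %in% cls))
      stop("merge_clusters must name two existing clusters")
    merged <- paste(merge_clusters, collapse = "+")
    labs <- as.character(q_labels)
    labs[labs %in% merge_clusters] <- merged
    q_labels <- cluster_labels(names(q_labels), labs)
    truth[merge_clusters] <- NULL
    truth[[merged]] <- merge_clusters
  }
  list(query = qry$matrix, q_labels = q_labels,
       reference = ref$matrix, r_labels = ref$labels,
       markers = ref$markers, truth = truth)
}

#' Leave-one-reference-cluster-out validation of novelty detection
#'
#' For each reference cluster in turn, matching is re-run with that cluster
#' removed from the reference; query cells whose true match is the left-out
#' cluster should then be called [UNASSIGNED]. Scoring is a binary
#' classification per left-out cluster: observed positives are query cells
#' whose true match is the left-out cluster, predicted positives are cells
#' called unassigned; `accuracy = (TP + TN) / total` and
#' `type1_error = FP / (FP + TN)`.
#'
#' @param query,reference [gene_matrix()] objects (any layer; the pipeline
#'   re-normalizes per run, since dropping a cluster changes the reference).
#' @param q_labels,r_labels [cluster_labels()].
#' @param markers a [marker_set()].
#' @param params a [match_params()].
#' @param truth named list/vector mapping each query cluster label to its
#'   true reference cluster.
#' @param normalization a [norm_config()].
#' @return Data frame with one row per left-out cluster: `left_out`,
#'   `accuracy`, `type1_error`, `tp`, `fp`, `tn`, `fn`.
#' @export
loocv_unassigned_eval <- function(query, reference, q_labels, r_labels,
                                  markers, params = match_params(),
                                  truth = NULL,
                                  normalization = norm_config()) {
  rcl <- levels(factor(r_labels))
  if (is.null(truth))
    truth <- as.list(stats::setNames(levels(factor(q_labels)),
                                     levels(factor(q_labels))))
  true_of_cell <- function(cells) {
    ql <- as.character(q_labels[cells])
    vapply(ql, function(l) {
      tr <- truth[[l]]
      if (is.null(tr)) NA_character_ else tr[1]
    }, "")
  }
  out <- lapply(rcl, function(r) {
    keep <- names(r_labels)[r_labels != r]
    r_lab2 <- cluster_labels(keep, as.character(r_labels[keep]))
    ref2 <- gene_matrix(reference$values[, keep, drop = FALSE],
                        layer = reference$layer,
                        platform = reference$platform)
    fit <- frmatch(query, ref2, q_labels, r_lab2, markers,
                   scheme = "cell2cluster", params = params,
                   normalization = normalization)
    asn <- fit$assignments
    truth_cell <- true_of_cell(asn$unit)
    obs_pos <- !is.na(truth_cell) & truth_cell == r
    pred_pos <- asn$matched == UNASSIGNED
    tp <- sum(obs_pos & pred_pos); fp <- sum(!obs_pos & pred_pos)
    tn <- sum(!obs_pos & !pred_pos); fn <- sum(obs_pos & !pred_pos)
    data.frame(left_out = r,
               accuracy = (tp + tn) / (tp + tn + fp + fn),
               type1_error = if (fp + tn > 0) fp / (fp + tn) else 0,
               tp = tp, fp = fp, tn = tn, fn = fn)
  })
  do.call(rbind, out)
}
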