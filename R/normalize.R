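#' Normalization configuration
#'
#' Controls the cross-platform normalization applied before matching.
#' Min-max rescaling is always applied; the cluster-summary weighting step
#' (which suppresses low-level background expression typical of plate-based
#' SMART-seq barcodes) is applied only to matrices whose platform tag is in
#' `apply_weighting_to`, and only when `norm_by` is not `"none"`.
#'
#' @param norm_by `"mean"`, `"median"`, or `"none"` (disables weighting).
#' @param apply_weighting_to character vector of platform tags that receive
#'   weighting; default `"smartseq"`.
#' @return Object of class `norm_config`.
#' @export
norm_config <- function(norm_by = c("mean", "median", "none"),
                        apply_weighting_to = "smartseq") {
  norm_by <- match.arg(norm_by)
  structure(list(norm_by = norm_by,
                 apply_weighting_to = apply_weighting_to),
            class = "norm_config")
}

#' Gene-wise min-max rescaling
#'
#' Divides every gene row by its maximum over all cells, aligning dynamic
#' ranges to \[0, 1\] across platforms. All-zero rows stay zero (0/0 is
#' defined as 0, since dropout-heavy panels contain such rows). Idempotent.
#'
#' @param x a [gene_matrix()] with non-negative values.
#' @return A `gene_matrix` with `layer = "rescaled"`.
#' @export
minmax_rescale <- function(x) {
  stopifnot(inherits(x, "gene_matrix"))
  mx <- apply(x$values, 1, max)
  scale <- ifelse(mx > 0, mx, 1)
  gene_matrix(x$values / scale, layer = "rescaled", platform = x$platform)
}

#' Cluster-summary weighting of a rescaled matrix
#'
#' For each cluster the gene rows of the cluster submatrix are multiplied by
#' that row's within-cluster summary (mean or median), then the whole
#' submatrix is divided by its global maximum so the dynamic range tops out
#' at 1 again. On near-binary marker genes the weights are close to 0 or 1,
#' so genes expressed in only a minority of a cluster's cells (median 0) are
#' zeroed within that cluster — the background-noise suppression step.
#'
#' @param x a [gene_matrix()] with `layer = "rescaled"` (see
#'   [minmax_rescale()]).
#' @param labels a [cluster_labels()] covering the cells of `x`.
#' @param norm_by `"mean"` or `"median"`.
#' @return A `gene_matrix` with `layer = "normalized"`; cell order is
#'   preserved.
#' @export
weight_by_cluster_summary <- function(x, labels,
                                      norm_by = c("mean", "median")) {
  norm_by <- match.arg(norm_by)
  stopifnot(inherits(x, "gene_matrix"))
  if (x$layer != "rescaled")
    stop("weighting operates on the min-max rescaled matrix; run ",
         "minmax_rescale() first (layer is '", x$layer, "')")
  if (!all(colnames(x$values) %in% names(labels)))
    stop("labels must cover every cell of the matrix")
  lab <- labels[colnames(x$values)]
  out <- x$values
  for (b in levels(factor(lab))) {
    idx <- which(lab == b)
    sub <- x$values[, idx, drop = FALSE]
    w <- if (norm_by == "mean") rowMeans(sub) else apply(sub, 1, median)
    wsub <- sub * w
    mx <- max(wsub)
    if (mx > 0) {
      out[, idx] <- wsub / mx
    } else {
      warning("cluster '", b, "' is entirely zero after weighting")
      out[, idx] <- 0
    }
  }
  gene_matrix(out, layer = "normalized", platform = x$platform)
}

#' Normalize a query/reference pair for matching
#'
#' Both matrices (already projected to the same marker feature space) are
#' min-max rescaled; cluster-summary weighting is additionally applied to
#' each side whose platform tag is listed in the configuration, unless
#' `norm_by = "none"`. For same-platform droplet pairs only the min-max
#' scaling is applied.
#'
#' @param query,reference [gene_matrix()] objects over identical gene lists.
#' @param q_labels,r_labels matching [cluster_labels()].
#' @param config a [norm_config()].
#' @return `list(query = , reference = )`, both with `layer = "normalized"`.
#' @export
normalize_pair <- function(query, reference, q_labels, r_labels,
                           config = norm_config()) {
  stopifnot(inherits(query, "gene_matrix"), inherits(reference, "gene_matrix"))
  if (!identical(rownames(query$values), rownames(reference$values)))
    stop("query and reference are not in the same feature space; ",
         "project both to the same marker set first")
  one_side <- function(x, labels) {
    r <- minmax_rescale(x)
    if (config$norm_by != "none" && x$platform %in% config$apply_weighting_to) {
      weight_by_cluster_summary(r, labels, norm_by = config$norm_by)
    } else {
      gene_matrix(r$values, layer = "normalized", platform = x$platform)
    }
  }
  list(query = one_side(query, q_labels),
       reference = one_side(reference, r_labels))
}
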