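open_device <- function(file, width = 7, height = 6) {
  if (grepl("\\.png$", file)) {
    grDevices::png(file, width = width * 100, height = height * 100,
                   res = 100)
  } else if (grepl("\\.svg$", file)) {
    grDevices::svg(file, width = width, height = height)
  } else {
    grDevices::pdf(file, width = width, height = height)
  }
}

#' Dot plot of cell-to-cluster matching proportions
#'
#' Columns are query clusters, rows are reference clusters with the
#' unassigned row rendered last (bottom); circle size and fill intensity
#' encode the proportion of the query cluster's cells matched to each
#' reference cluster, with a calibration legend on the right.
#'
#' @param proportions matrix from [cell2cluster_proportions()] (columns sum
#'   to 1).
#' @param file optional output file (`.png`, `.svg`, or `.pdf`); `NULL`
#'   draws on the current device.
#' @param main plot title.
#' @param return_value if `TRUE`, return the plotted matrix (visibly).
#' @return The proportions matrix, invisibly unless `return_value = TRUE`.
#' @export
plot_cell2cluster <- function(proportions, file = NULL,
                              main = "Cell-to-cluster matching",
                              return_value = FALSE) {
  stopifnot(is.matrix(proportions))
  if (max(abs(colSums(proportions) - 1)) > 1e-8)
    stop("proportions columns must sum to 1")
  # unassigned row last => plotted at the bottom
  rows <- c(setdiff(rownames(proportions), UNASSIGNED),
            intersect(UNASSIGNED, rownames(proportions)))
  pm <- proportions[rows, , drop = FALSE]
  K <- nrow(pm); L <- ncol(pm)
  if (!is.null(file)) {
    open_device(file, width = 2 + 0.5 * L + 1.5, height = 1.5 + 0.4 * K)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(6, 8, 3, 6), xpd = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  plot(NA, xlim = c(0.5, L + 0.5), ylim = c(0.5, K + 0.5),
       xlab = "", ylab = "", axes = FALSE, main = main)
  graphics::axis(1, at = seq_len(L), labels = colnames(pm), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = rev(seq_len(K)), labels = rownames(pm), las = 2,
                 cex.axis = 0.8)
  shade <- function(p) grDevices::gray(1 - 0.85 * p)
  for (i in seq_len(K)) {
    for (j in seq_len(L)) {
      p <- pm[i, j]
      if (p > 0)
        graphics::symbols(j, K - i + 1, circles = 0.45 * sqrt(p),
                          inches = FALSE, add = TRUE, bg = shade(p),
                          fg = "gray30")
    }
  }
  leg <- c(0.1, 0.25, 0.5, 1)
  graphics::legend("topright", inset = c(-0.18, 0),
                   legend = sprintf("%.2f", leg),
                   pt.cex = 2.2 * sqrt(leg), pch = 21,
                   pt.bg = shade(leg), title = "proportion", bty = "n")
  if (return_value) return(pm)
  invisible(pm)
}

#' Grid plot of cluster-to-cluster matching
#'
#' Query clusters in columns, reference clusters in rows; filled squares
#' mark pairs whose adjusted p-value is at or above the significance
#' threshold.
#'
#' @param pvalues adjusted cluster-to-cluster `pvalue_matrix` (query rows x
#'   reference columns; plotted transposed to keep the query-in-columns
#'   convention).
#' @param sig_level significance threshold.
#' @param file optional output file.
#' @param main plot title.
#' @return The logical matched matrix (reference x query), invisibly.
#' @export
plot_cluster_grid <- function(pvalues, sig_level = 0.1, file = NULL,
                              main = "Cluster-to-cluster matching") {
  v <- t(unclass(pvalues)) # reference rows x query columns
  K <- nrow(v); L <- ncol(v)
  if (!is.null(file)) {
    open_device(file, width = 2 + 0.5 * L, height = 1.5 + 0.4 * K)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(6, 8, 3, 2))
  on.exit(graphics::par(op), add = TRUE)
  matched <- !is.na(v) & v >= sig_level
  graphics::image(seq_len(L), seq_len(K),
                  t(matched[rev(seq_len(K)), , drop = FALSE]) * 1,
                  col = c("white", "firebrick"), axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(L), labels = colnames(v), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = rev(seq_len(K)), labels = rownames(v), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(matched)
}

#' Cell type barcode heatmap
#'
#' Marker genes in rows (marker-set order, grouped by defining cluster when
#' available), cells in columns grouped by cluster; intensity encodes
#' normalized expression. On well-partitioned data the barcode is
#' block-diagonal; an under-partitioned cluster shows two interleaved
#' patterns.
#'
#' @param x a normalized [gene_matrix()].
#' @param labels [cluster_labels()] for the cells of `x`.
#' @param markers a [marker_set()].
#' @param clusters clusters to display (default all, in label order).
#' @param file optional output file.
#' @param main plot title.
#' @return Invisibly, the plotted submatrix.
#' @export
plot_barcode <- function(x, labels, markers, clusters = NULL, file = NULL,
                         main = "Cell type barcode") {
  stopifnot(inherits(x, "gene_matrix"))
  lab <- factor(as.character(labels[colnames(x$values)]))
  if (is.null(clusters)) clusters <- levels(lab)
  absent <- setdiff(clusters, levels(lab))
  if (length(absent))
    stop("requested cluster(s) not present: ", paste(absent, collapse = ", "))
  mk <- markers$markers
  if (!is.null(markers$group_of)) mk <- mk[order(match(markers$group_of, clusters),
                                                 seq_along(mk))]
  mk <- intersect(mk, rownames(x$values))
  cells <- unlist(lapply(clusters, function(b)
    colnames(x$values)[lab == b]), use.names = FALSE)
  sub <- x$values[mk, cells, drop = FALSE]
  if (!is.null(file)) {
    open_device(file, width = 8, height = 1 + 0.2 * length(mk))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(4, 7, 3, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(ncol(sub)), seq_len(nrow(sub)),
                  t(sub[rev(seq_len(nrow(sub))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "cells (grouped by cluster)",
                  ylab = "", main = main, zlim = c(0, max(sub, 1e-9)))
  graphics::axis(2, at = rev(seq_len(nrow(sub))), labels = rownames(sub),
                 las = 2, cex.axis = 0.7)
  breaks <- cumsum(vapply(clusters, function(b) sum(lab == b), 0L))
  graphics::abline(v = breaks[-length(breaks)] + 0.5, col = "gray40")
  graphics::axis(1, at = breaks - diff(c(0, breaks)) / 2, labels = clusters,
                 tick = FALSE, cex.axis = 0.8)
  graphics::box()
  invisible(sub)
}
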